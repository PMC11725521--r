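# Shared helpers: tiny on-disk fixtures built in code, plus an independent
# pure-R canonical k-mer tally used as the oracle for the C++ counter.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

toy_quadripartite_gfa <- function(lsc = strrep("A", 60), ir = strrep("C", 30),
                                  ssc = strrep("G", 40), overlap = "0M") {
  write_lines_tmp(c(
    "H\tVN:Z:1.0",
    paste("S", "L", lsc, sep = "\t"),
    paste("S", "R", ir, sep = "\t"),
    paste("S", "S", ssc, sep = "\t"),
    paste("L", "L", "+", "R", "+", overlap, sep = "\t"),
    paste("L", "R", "+", "S", "+", overlap, sep = "\t"),
    paste("L", "S", "+", "R", "-", overlap, sep = "\t"),
    paste("L", "R", "-", "L", "+", overlap, sep = "\t")
  ), ".gfa")
}

# Independent canonical k-mer tally: substring windows, Biostrings reverse
# complement, lexicographic minimum, run-length counting. Shares no code
# with the packaged counter.
naive_kmer_tally <- function(seqs, k) {
  words <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    w <- substring(s, 1:(n - k + 1), k:n)
    w[!grepl("[^ACGT]", w)]
  }))
  if (!length(words)) {
    return(data.frame(kmer = character(), count = integer()))
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
  canon <- ifelse(words <= rc, words, rc)
  r <- rle(sort(canon))
  data.frame(kmer = r$values, count = r$lengths, stringsAsFactors = FALSE)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
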