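hsp <- function(s_start, s_end, pident = 95, bitscore = 100, sseqid = "nuc1",
                length = s_end - s_start + 1L) {
  tibble::tibble(
    qseqid = "org", sseqid = sseqid, pident = pident, length = as.integer(length),
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = as.integer(length),
    s_start = as.integer(s_start), s_end = as.integer(s_end), strand = "+",
    evalue = 0, bitscore = bitscore
  )
}

test_that("HSP entry thresholds are strict on both identity and length", {
  h <- dplyr::bind_rows(
    hsp(1, 500, pident = 80.0),                 # identity on the boundary
    hsp(1, 100, pident = 95.0, length = 100L),  # length on the boundary
    hsp(1, 101, pident = 95.0, length = 101L)   # both pass
  )
  kept <- filter_hsps(h)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$length, 101L)
})

test_that("embedded HSPs are dropped; duplicates resolved by bitscore", {
  h <- dplyr::bind_rows(
    hsp(50, 600, bitscore = 500),
    hsp(100, 500, bitscore = 400),   # embedded in [50,600]
    hsp(400, 900, bitscore = 300)    # partial overlap, kept
  )
  out <- remove_embedded(h)
  expect_equal(out$s_start, c(50L, 400L))

  dup <- dplyr::bind_rows(hsp(100, 500, bitscore = 200),
                          hsp(100, 500, bitscore = 180))
  expect_equal(remove_embedded(dup)$bitscore, 200)

  # shared endpoint still counts as embedded when the container is longer
  shared <- dplyr::bind_rows(hsp(100, 700), hsp(100, 500))
  expect_equal(remove_embedded(shared)$s_end, 700L)

  # removing embedded HSPs never changes the union of covered bases
  set.seed(41)
  rand <- dplyr::bind_rows(lapply(1:40, function(i) {
    s <- sample(1:5000, 1); hsp(s, s + sample(50:800, 1))
  }))
  union_bases <- function(h) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(h$s_start, h$s_end))))
  }
  expect_equal(union_bases(remove_embedded(rand)), union_bases(rand))
})

test_that("merging is transitive, book-ended, averaged and idempotent", {
  h <- dplyr::bind_rows(
    hsp(101, 300, pident = 90),
    hsp(251, 400, pident = 94)
  )
  m <- merge_insertions(h, "NUPT")
  expect_equal(m$start, 101L)
  expect_equal(m$end, 400L)
  expect_equal(m$mean_identity, 92)
  expect_equal(m$n_hsps, 2L)
  expect_equal(m$source, "NUPT")

  book <- dplyr::bind_rows(hsp(101, 300), hsp(301, 450))
  expect_equal(nrow(merge_insertions(book, "NUMT")), 1)

  single <- merge_insertions(hsp(10, 200, pident = 87.5), "NUPT")
  expect_equal(single$mean_identity, 87.5)

  # idempotence + disjoint sorted output, and length never exceeds footprint
  set.seed(42)
  rand <- dplyr::bind_rows(lapply(1:60, function(i) {
    s <- sample(1:8000, 1)
    hsp(s, s + sample(50:500, 1), pident = runif(1, 81, 100),
        sseqid = sample(c("nuc1", "nuc2"), 1))
  }))
  m1 <- merge_insertions(rand, "NUPT")
  for (ch in unique(m1$chrom)) {
    mm <- m1[m1$chrom == ch, ]
    expect_true(all(diff(mm$start) > 0))
    expect_true(all(mm$start[-1] > mm$end[-nrow(mm)] + 1L))
  }
  again <- merge_insertions(
    dplyr::mutate(m1, sseqid = chrom, s_start = start, s_end = end,
                  pident = mean_identity, length = end - start + 1L,
                  bitscore = 0), "NUPT")
  expect_equal(again$start, m1$start)
  expect_equal(again$end, m1$end)
  expect_equal(again$mean_identity, m1$mean_identity)
  expect_true(sum(m1$end - m1$start + 1) <= sum(rand$s_end - rand$s_start + 1))
})

test_that("cs difference strings yield positioned, context-annotated substitutions", {
  #           1234567890123456
  organelle <- "AACCGGTTACGTACGT"
  paf <- tibble::tibble(
    qname = "q", qlen = 10L, qstart = 0L, qend = 10L, strand = "+",
    tname = "org", tlen = 16L, tstart = 100L, tend = 110L,
    matches = 9L, blocklen = 10L, mapq = 60L, cs = ":5*ct:4"
  )
  long_org <- paste0(random_seq(100), "AAAAACGGGG", random_seq(20))
  subs <- call_substitutions(paf, long_org)
  expect_equal(nrow(subs), 1)
  expect_equal(subs$organelle_pos, 106L) # tstart 100 + 5 matched + 1
  expect_equal(subs$ref, "C")
  expect_equal(subs$alt, "T")

  # contexts read from the organellar sequence on the pyrimidine strand
  org <- "TTACGTTACCGTT"
  #       pos: C at 4 followed by G -> CG; C at 9 then C,G -> CHG
  expect_equal(cytosine_context(org, 4L, "C"), "CG")
  expect_equal(cytosine_context(org, 9L, "C"), "CHG")
  # G at position 5 preceded by C -> CG via the reverse complement
  expect_equal(cytosine_context(org, 5L, "G"), "CG")
  # within 2 bases of an end the context is undefined
  expect_true(is.na(cytosine_context(org, 12L, "C")))
  expect_true(is.na(cytosine_context(org, 2L, "G")))

  bad <- dplyr::mutate(paf, cs = NA_character_)
  expect_error(call_substitutions(bad, long_org), "cs tag absent")
})

test_that("spectrum collapses strands and accounts every substitution once", {
  subs <- tibble::tibble(
    organelle_pos = c(10L, 20L, 30L),
    ref = c("G", "C", "T"),
    alt = c("A", "T", "G"),
    context = c("CG", "CHH", NA)
  )
  sp <- substitution_spectrum(subs)
  cls <- sp$classes
  expect_equal(cls$count[cls$class == "C:G>T:A"], 2L) # G>A collapses to C:G>T:A
  expect_equal(cls$count[cls$class == "T:A>G:C"], 1L)
  expect_equal(sum(cls$count), nrow(subs))
  expect_equal(sum(sp$contexts$count), 2L) # only cytosine-class substitutions

  many <- tibble::tibble(organelle_pos = 1:100, ref = "C", alt = "T",
                         context = "CG")
  sp100 <- substitution_spectrum(many)
  expect_equal(sp100$classes$count[sp100$classes$class == "C:G>T:A"], 100L)
  expect_equal(sum(sp100$classes$count[-1]), 0L)
})

test_that("class counts survive reverse-complementing the organellar genome", {
  set.seed(43)
  org <- random_seq(5000)
  fix <- plant_insertions(40000, org, n = 8, identity_targets = 96, seed = 44)
  subs <- call_substitutions(insertion_paf(fix), org)
  sp_fwd <- substitution_spectrum(subs)

  n <- nchar(org)
  org_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(org)))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  subs_rc <- dplyr::mutate(subs,
    organelle_pos = n - organelle_pos + 1L,
    ref = unname(comp[ref]), alt = unname(comp[alt]))
  subs_rc$context <- cytosine_context(org_rc, subs_rc$organelle_pos, subs_rc$ref)
  sp_rc <- substitution_spectrum(subs_rc)
  expect_equal(sp_rc$classes$count, sp_fwd$classes$count)
  expect_equal(sort(sp_rc$contexts$count), sort(sp_fwd$contexts$count))
  expect_equal(sp_rc$contexts$count, sp_fwd$contexts$count)
})

test_that("cross-species summaries reproduce closed-form Pearson correlations", {
  ins <- tibble::tibble(
    species = rep(c("sp1", "sp2"), each = 2),
    chrom = "nuc1",
    start = c(1L, 1000L, 1L, 1000L),
    end = c(500L, 1400L, 300L, 1200L),
    mean_identity = c(99, 95, 92, 88),
    source = c("NUPT", "NUMT", "NUPT", "NUMT")
  )
  sizes <- tibble::tibble(species = c("sp1", "sp2"), nuclear_size = c(1e8, 2e8))
  s2 <- summarize_insertions(ins, sizes)
  expect_true(all(is.na(s2$correlations$r_raw))) # < 3 species: undefined

  set.seed(45)
  n <- 10
  tab <- tibble::tibble(
    species = sprintf("sp%02d", 1:n),
    nupt = runif(n, 1e4, 1e6),
    numt = runif(n, 1e4, 1e6),
    size = runif(n, 1e8, 1e10)
  )
  ins10 <- dplyr::bind_rows(
    tibble::tibble(species = tab$species, chrom = "nuc1", start = 1L,
                   end = as.integer(tab$nupt), mean_identity = 95,
                   source = "NUPT"),
    tibble::tibble(species = tab$species, chrom = "nuc1", start = 1L,
                   end = as.integer(tab$numt), mean_identity = 93,
                   source = "NUMT")
  )
  s10 <- summarize_insertions(
    ins10, tibble::tibble(species = tab$species, nuclear_size = tab$size))
  pearson <- function(x, y) {
    n <- length(x)
    (n * sum(x * y) - sum(x) * sum(y)) /
      sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  }
  x <- as.integer(tab$nupt) # insertion lengths as realized in the table
  r_expect <- pearson(x, tab$size)
  r_got <- s10$correlations$r_raw[s10$correlations$pair == "NUPT_length~nuclear_size"]
  expect_equal(r_got, r_expect, tolerance = 1e-12)

  # perfectly correlated and anticorrelated columns
  expect_equal(pearson(1:5, 2 * (1:5) + 3), 1.0)
  expect_equal(pearson(1:5, -(1:5)), -1.0)
})
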