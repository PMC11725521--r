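#' Read HiFi reads from FASTA or FASTQ
#'
#' Parses sequence reads into the tabular form used throughout the package.
#' Gzipped input is handled transparently. Sequences are uppercased and any
#' character outside ACGTN is replaced by N.
#'
#' @param path Path to a FASTA or FASTQ file, optionally gzipped. The format
#'   is inferred from the file extension (`.fq`/`.fastq` imply FASTQ).
#' @param label Optional class label to attach to every read, one of
#'   `"plastid"`, `"mitochondrion"`, `"nuclear"`, `"unknown"`.
#' @return A tibble with columns `id`, `seq`, `qual` (NA for FASTA) and
#'   `label`.
#' @export
read_reads <- function(path, label = NA_character_) {
  stopifnot(file.exists(path))
  base <- sub("\\.gz$", "", path)
  is_fastq <- grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)
  if (is_fastq) {
    # the reader re-wraps the set and warns about (empty) mcols
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    qual <- as.character(methods::slot(x, "quality"))
  } else {
    x <- Biostrings::readDNAStringSet(path)
    qual <- NA_character_
  }
  ids <- sub("\\s.*$", "", names(x))
  tibble::tibble(
    id = ids,
    seq = clean_dna(as.character(x)),
    qual = qual,
    label = label
  )
}

#' Write reads to FASTA or FASTQ
#'
#' @param reads A tibble with columns `id` and `seq` (and `qual` for FASTQ).
#' @param path Output path; `.fq`/`.fastq` extensions select FASTQ.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  is_fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  if (is_fastq) {
    qual <- reads$qual
    qual[is.na(qual)] <- vapply(nchar(reads$seq[is.na(qual)]),
                                function(n) strrep("I", n), character(1))
    # the constructor re-wraps the set and warns about (empty) mcols
    x <- withCallingHandlers(
      Biostrings::QualityScaledDNAStringSet(x, Biostrings::PhredQuality(qual)),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    Biostrings::writeQualityScaledXStringSet(x, path)
  } else {
    Biostrings::writeXStringSet(x, path)
  }
  invisible(path)
}

#' Assembly graph constructor
#'
#' An assembly graph is a set of segments (nodes carrying sequence) plus
#' oriented links between segment ends, as produced by long-read assemblers
#' in GFA form.
#'
#' @param segments Tibble with columns `id`, `seq` (may be NA), `length`.
#' @param links Tibble with columns `from_id`, `from_orient`, `to_id`,
#'   `to_orient`, `overlap` (bases of exact overlap; 0 = blunt join).
#' @return An object of class `assembly_graph`.
#' @export
assembly_graph <- function(segments, links) {
  segments <- tibble::as_tibble(segments)
  links <- tibble::as_tibble(links)
  if (nrow(links)) {
    unknown <- setdiff(c(links$from_id, links$to_id), segments$id)
    if (length(unknown)) {
      stop("link references unknown segment(s): ", paste(unknown, collapse = ", "))
    }
    stopifnot(all(links$overlap >= 0))
  }
  structure(list(segments = segments, links = links), class = "assembly_graph")
}

#' @export
print.assembly_graph <- function(x, ...) {
  cat("<assembly_graph> ", nrow(x$segments), " segments, ",
      nrow(x$links), " links\n", sep = "")
  invisible(x)
}

#' Read a GFA 1.x assembly graph
#'
#' Only S (segment) and L (link) records are interpreted; other record types
#' are ignored. Link overlaps must be `*`, `0M` or `<n>M` (exact match);
#' CIGARs containing insertions, deletions or mismatches are rejected as an
#' unsupported dialect.
#'
#' @param path Path to a GFA file.
#' @return An [assembly_graph()] with records in file order.
#' @export
read_gfa <- function(path) {
  lines <- readLines(path)
  seg_rows <- list()
  link_rows <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(lines[[i]])) next
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (f[1] == "S") {
      if (length(f) < 3) stop("malformed S record at line ", i)
      seq <- if (f[3] == "*") NA_character_ else clean_dna(f[3])
      len <- if (!is.na(seq)) {
        nchar(seq)
      } else {
        ln_tag <- grep("^LN:i:", f, value = TRUE)
        if (length(ln_tag)) as.integer(sub("^LN:i:", "", ln_tag[1])) else NA_integer_
      }
      seg_rows[[length(seg_rows) + 1]] <- tibble::tibble(id = f[2], seq = seq, length = len)
    } else if (f[1] == "L") {
      if (length(f) < 6) stop("malformed L record at line ", i)
      ov_str <- f[6]
      ov <- if (ov_str == "*") {
        0L
      } else if (grepl("^[0-9]+M$", ov_str)) {
        as.integer(sub("M$", "", ov_str))
      } else {
        stop("unsupported overlap CIGAR '", ov_str, "' at line ", i,
             " (only exact-match overlaps are supported)")
      }
      link_rows[[length(link_rows) + 1]] <- tibble::tibble(
        from_id = f[2], from_orient = f[3], to_id = f[4], to_orient = f[5],
        overlap = ov, line = i
      )
    }
  }
  segments <- if (length(seg_rows)) dplyr::bind_rows(seg_rows) else {
    tibble::tibble(id = character(), seq = character(), length = integer())
  }
  links <- if (length(link_rows)) dplyr::bind_rows(link_rows) else {
    tibble::tibble(from_id = character(), from_orient = character(),
                   to_id = character(), to_orient = character(),
                   overlap = integer(), line = integer())
  }
  if (nrow(links)) {
    bad <- !(links$from_id %in% segments$id) | !(links$to_id %in% segments$id)
    if (any(bad)) {
      stop("link at line ", links$line[which(bad)[1]],
           " references unknown segment")
    }
  }
  assembly_graph(segments, dplyr::select(links, -"line"))
}

#' Write an assembly graph to GFA 1.0
#'
#' @param graph An [assembly_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  s_lines <- purrr::pmap_chr(graph$segments, function(id, seq, length, ...) {
    paste("S", id, ifelse(is.na(seq), "*", seq), sep = "\t")
  })
  l_lines <- if (nrow(graph$links)) {
    purrr::pmap_chr(graph$links, function(from_id, from_orient, to_id, to_orient, overlap, ...) {
      paste("L", from_id, from_orient, to_id, to_orient, paste0(overlap, "M"), sep = "\t")
    })
  } else character()
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines), path)
  invisible(path)
}

#' Read graph alignments (GAF)
#'
#' Parses the 12 standard GAF columns as produced by graph aligners. Query
#' coordinates are kept in GAF's native 0-based half-open convention (so
#' `qstart` is also the left clip length and `qlen - qend` the right clip).
#' Trailing tag columns are ignored.
#'
#' @param path Path to a GAF file.
#' @return A tibble with columns `qname`, `qlen`, `qstart`, `qend`, `strand`,
#'   `path`, `plen`, `pstart`, `pend`, `matches`, `blocklen`, `mapq`.
#' @export
read_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(
      qname = character(), qlen = integer(), qstart = integer(),
      qend = integer(), strand = character(), path = character(),
      plen = integer(), pstart = integer(), pend = integer(),
      matches = integer(), blocklen = integer(), mapq = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 12
  if (any(short)) stop("GAF record with fewer than 12 columns at line ", which(short)[1])
  out <- tibble::tibble(
    qname = vapply(fields, `[`, character(1), 1),
    qlen = as.integer(vapply(fields, `[`, character(1), 2)),
    qstart = as.integer(vapply(fields, `[`, character(1), 3)),
    qend = as.integer(vapply(fields, `[`, character(1), 4)),
    strand = vapply(fields, `[`, character(1), 5),
    path = vapply(fields, `[`, character(1), 6),
    plen = as.integer(vapply(fields, `[`, character(1), 7)),
    pstart = as.integer(vapply(fields, `[`, character(1), 8)),
    pend = as.integer(vapply(fields, `[`, character(1), 9)),
    matches = as.integer(vapply(fields, `[`, character(1), 10)),
    blocklen = as.integer(vapply(fields, `[`, character(1), 11)),
    mapq = as.integer(vapply(fields, `[`, character(1), 12))
  )
  bad <- out$matches > out$blocklen
  if (any(bad)) stop("malformed GAF record (matches > blocklen) at line ", which(bad)[1])
  out
}

#' Parse an oriented GAF path string
#'
#' @param path A GAF path string such as `">seg1<seg2"`.
#' @return A tibble with columns `seg` and `orient` (`+`/`-`), one row per
#'   path step.
#' @export
parse_gaf_path <- function(path) {
  m <- stringr::str_match_all(path, "([<>])([^<>]+)")[[1]]
  tibble::tibble(
    seg = m[, 3],
    orient = ifelse(m[, 2] == ">", "+", "-")
  )
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Reads the 12 standard columns of BLAST's tabular format (query here is the
#' organellar genome, subject the nuclear genome). Subject coordinates with
#' `sstart > send` indicate a minus-strand hit; the subject interval is
#' normalized so that `s_start < s_end` (1-based inclusive) and the strand
#' recorded in `strand`.
#'
#' @param path Path to a 12-column tabular file.
#' @return A tibble of HSPs with columns `qseqid`, `sseqid`, `pident`,
#'   `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `s_start`, `s_end`,
#'   `strand`, `evalue`, `bitscore`.
#' @export
read_blast6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(tibble::tibble(
      qseqid = character(), sseqid = character(), pident = double(),
      length = integer(), mismatch = integer(), gapopen = integer(),
      qstart = integer(), qend = integer(), s_start = integer(),
      s_end = integer(), strand = character(), evalue = double(),
      bitscore = double()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 12)) {
    stop("expected 12 tab-separated columns, got ", nf[nf < 12][1],
         " at line ", which(nf < 12)[1])
  }
  col <- function(j) vapply(fields, `[`, character(1), j)
  sstart <- as.integer(col(9))
  send <- as.integer(col(10))
  tibble::tibble(
    qseqid = col(1), sseqid = col(2),
    pident = as.numeric(col(3)), length = as.integer(col(4)),
    mismatch = as.integer(col(5)), gapopen = as.integer(col(6)),
    qstart = as.integer(col(7)), qend = as.integer(col(8)),
    s_start = pmin(sstart, send), s_end = pmax(sstart, send),
    strand = ifelse(sstart > send, "-", "+"),
    evalue = as.numeric(col(11)), bitscore = as.numeric(col(12))
  )
}

#' Read pairwise alignments (PAF), keeping the cs tag
#'
#' Parses the 12 standard PAF columns plus, when present, the `cs:Z:`
#' difference tag used for substitution calling.
#'
#' @param path Path to a PAF file.
#' @return A tibble with columns `qname`, `qlen`, `qstart`, `qend` (0-based
#'   half-open, as in PAF), `strand`, `tname`, `tlen`, `tstart`, `tend`,
#'   `matches`, `blocklen`, `mapq`, `cs` (NA when absent).
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(
      qname = character(), qlen = integer(), qstart = integer(),
      qend = integer(), strand = character(), tname = character(),
      tlen = integer(), tstart = integer(), tend = integer(),
      matches = integer(), blocklen = integer(), mapq = integer(),
      cs = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 12)) stop("PAF record with fewer than 12 columns at line ", which(nf < 12)[1])
  col <- function(j) vapply(fields, `[`, character(1), j)
  cs <- vapply(fields, function(f) {
    tag <- grep("^cs:Z:", f, value = TRUE)
    if (length(tag)) sub("^cs:Z:", "", tag[1]) else NA_character_
  }, character(1))
  tibble::tibble(
    qname = col(1), qlen = as.integer(col(2)),
    qstart = as.integer(col(3)), qend = as.integer(col(4)),
    strand = col(5), tname = col(6), tlen = as.integer(col(7)),
    tstart = as.integer(col(8)), tend = as.integer(col(9)),
    matches = as.integer(col(10)), blocklen = as.integer(col(11)),
    mapq = as.integer(col(12)), cs = cs
  )
}

#' Read BED intervals
#'
#' BED's 0-based half-open coordinates are converted to the 1-based inclusive
#' convention used internally, so `end - start + 1` is the interval width.
#'
#' @param path Path to a BED file (3 or more columns).
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (!length(lines)) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- min(vapply(fields, length, integer(1)))
  if (nf < 3) stop("BED requires at least 3 columns")
  col <- function(j) vapply(fields, `[`, character(1), j)
  out <- tibble::tibble(
    chrom = col(1),
    start = as.integer(col(2)) + 1L,
    end = as.integer(col(3))
  )
  if (nf >= 4) out$name <- col(4)
  if (nf >= 5) out$score <- suppressWarnings(as.numeric(col(5)))
  if (nf >= 6) out$strand <- col(6)
  out
}

#' Write intervals to BED
#'
#' Converts from the package's 1-based inclusive coordinates back to BED's
#' 0-based half-open convention. Extra columns beyond `chrom`, `start`, `end`
#' are written in order after the first three.
#'
#' @param x A tibble with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  extra <- setdiff(names(x), c("chrom", "start", "end"))
  df <- data.frame(chrom = x$chrom, start = x$start - 1L, end = x$end)
  for (nm in extra) df[[nm]] <- x[[nm]]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
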