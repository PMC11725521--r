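#' Canonical k-mers of a sequence
#'
#' Enumerates every window of length `k`, skipping windows that contain a
#' base outside ACGT, and reports each window as its canonical form: the
#' lexicographically smaller of the word and its reverse complement. Canonical
#' counting collapses the two strands, matching the default of k-mer counting
#' tools used on HiFi data.
#'
#' @param seq A single nucleotide string.
#' @param k Word length (1-32).
#' @return Character vector of canonical k-mers, one per N-free window, in
#'   window order. Sequences shorter than `k` yield an empty vector.
#' @export
canonical_kmers <- function(seq, k) {
  stopifnot(length(seq) == 1, k >= 1)
  cpp_canonical_kmers(seq, as.integer(k))
}

#' Build a canonical k-mer count table from reads
#'
#' Tallies canonical k-mers over a read set, the analogue of building a k-mer
#' count database from classifier-labeled reads before coverage-based
#' filtering.
#'
#' @param reads Tibble of reads with a `seq` column (see [read_reads()]).
#' @param k Word length, default 31.
#' @return A tibble of class `kmer_count_table` with columns `kmer`, `count`,
#'   sorted by `kmer`; the word length is stored in attribute `k`.
#' @export
kmer_count_table <- function(reads, k = 31) {
  if (nrow(reads) == 0) stop("no reads for counting")
  res <- cpp_count_kmers(reads$seq, as.integer(k))
  out <- tibble::tibble(kmer = res$kmer, count = res$count)
  attr(out, "k") <- as.integer(k)
  class(out) <- c("kmer_count_table", class(out))
  out
}

# Median defined as the mean of the two middle values for even n.
median_mid <- function(x) stats::median(x)

#' Per-read k-mer coverage profiles
#'
#' For each read, looks up the count of every N-free k-mer window in a count
#' table built from `counts_from` (by default the reads themselves) and
#' summarizes the read by its median per-window count (`rmkc`), the
#' representative read coverage statistic.
#'
#' @param reads Tibble of reads with columns `id` and `seq`.
#' @param k Word length, default 31.
#' @param counts_from Tibble of reads the count table is built from; defaults
#'   to `reads`. Pass the full class-labeled read set to profile a subset
#'   against the class-wide table.
#' @return A tibble with columns `read_id`, `n_kmers`, `rmkc` and a
#'   list-column `window_counts` holding the per-window counts (used by
#'   [kmer_filter_reads()] to evaluate outlier fractions).
#' @export
kmer_profiles <- function(reads, k = 31, counts_from = reads) {
  if (nrow(counts_from) == 0) stop("no reads for counting")
  wc <- cpp_window_counts(reads$seq, counts_from$seq, as.integer(k))
  tibble::tibble(
    read_id = reads$id,
    n_kmers = vapply(wc, length, integer(1)),
    rmkc = vapply(wc, function(w) if (length(w)) median_mid(w) else NA_real_, double(1)),
    window_counts = wc
  )
}

#' Coverage-filter thresholds from read profiles
#'
#' The class-wide median of read medians (`mkc`) anchors a low threshold
#' `lkc = low_mult * mkc` and a high threshold `hkc = high_mult * mkc`.
#' Reads dominated by counts below `lkc` likely carry nuclear sequence
#' (NUPTs/NUMTs at ~1x nuclear coverage); reads dominated by counts above
#' `hkc` likely come from high-copy nuclear repeats (centromeres, rDNA).
#'
#' @param profiles Tibble from [kmer_profiles()].
#' @param low_mult Multiplier for the low threshold, default 0.3.
#' @param high_mult Multiplier for the high threshold, default 5.
#' @param max_outlier_frac A read is removed when more than this fraction of
#'   its k-mer counts fall outside `[lkc, hkc]`; default 1/5.
#' @return A list of class `kmer_thresholds` with elements `mkc`, `lkc`,
#'   `hkc`, `max_outlier_frac`.
#' @export
kmer_thresholds <- function(profiles, low_mult = 0.3, high_mult = 5,
                            max_outlier_frac = 1 / 5) {
  usable <- profiles$rmkc[!is.na(profiles$rmkc)]
  if (!length(usable)) stop("no usable read profiles (all reads shorter than k)")
  mkc <- median_mid(usable)
  structure(
    list(mkc = mkc, lkc = low_mult * mkc, hkc = high_mult * mkc,
         max_outlier_frac = max_outlier_frac),
    class = "kmer_thresholds"
  )
}

#' @export
print.kmer_thresholds <- function(x, ...) {
  cat(sprintf("<kmer_thresholds> mkc=%g lkc=%g hkc=%g max_outlier_frac=%g\n",
              x$mkc, x$lkc, x$hkc, x$max_outlier_frac))
  invisible(x)
}

#' Filter reads by k-mer coverage profile
#'
#' Annotates each read with the fraction of its k-mer counts strictly below
#' `lkc` (`frac_low`) and strictly above `hkc` (`frac_high`), and removes the
#' read when `frac_low + frac_high` exceeds `max_outlier_frac` (strictly;
#' exactly one fifth outliers keeps the read). Reads too short to contain a
#' single k-mer are removed with reason `"too_short"`.
#'
#' @param reads Tibble of reads with columns `id` and `seq`.
#' @param thresholds A [kmer_thresholds()] object, or NULL to compute them
#'   from these reads.
#' @param k Word length, default 31.
#' @param profiles Optional precomputed [kmer_profiles()] for `reads` (must
#'   be row-aligned); computed when NULL.
#' @param counts_from Reads to build the count table from when profiles are
#'   computed here; defaults to `reads`.
#' @return The input tibble with added columns `n_kmers`, `rmkc`,
#'   `frac_low`, `frac_high`, `kept` (logical) and `reason`
#'   (`"low_kmer"`, `"high_kmer"`, `"too_short"`, or NA when kept).
#'   Row order is preserved; kept and removed rows partition the input.
#' @export
kmer_filter_reads <- function(reads, thresholds = NULL, k = 31,
                              profiles = NULL, counts_from = reads) {
  if (is.null(profiles)) profiles <- kmer_profiles(reads, k = k, counts_from = counts_from)
  stopifnot(nrow(profiles) == nrow(reads))
  if (is.null(thresholds)) thresholds <- kmer_thresholds(profiles)
  frac_low <- vapply(profiles$window_counts, function(w) {
    if (!length(w)) return(NA_real_)
    mean(w < thresholds$lkc)
  }, double(1))
  frac_high <- vapply(profiles$window_counts, function(w) {
    if (!length(w)) return(NA_real_)
    mean(w > thresholds$hkc)
  }, double(1))
  too_short <- profiles$n_kmers == 0
  outlier <- !too_short & (frac_low + frac_high > thresholds$max_outlier_frac)
  reason <- rep(NA_character_, nrow(reads))
  reason[too_short] <- "too_short"
  reason[outlier] <- ifelse(frac_low[outlier] >= frac_high[outlier],
                            "low_kmer", "high_kmer")
  dplyr::mutate(reads,
    n_kmers = profiles$n_kmers,
    rmkc = profiles$rmkc,
    frac_low = frac_low,
    frac_high = frac_high,
    kept = is.na(reason),
    reason = reason
  )
}
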