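#' Filter HSPs by identity and length
#'
#' Retains hits with percent identity strictly above `min_identity` and
#' alignment length strictly above `min_length` — the entry criteria for
#' candidate nuclear insertions of organellar DNA.
#'
#' @param hsps Tibble of HSPs from [read_blast6()].
#' @param min_identity Exclusive identity bound in percent, default 80.
#' @param min_length Exclusive alignment-length bound in bases, default 100.
#' @return The retained rows.
#' @export
filter_hsps <- function(hsps, min_identity = 80, min_length = 100) {
  dplyr::filter(hsps, .data$pident > min_identity, .data$length > min_length)
}

#' Remove HSPs embedded in longer HSPs
#'
#' BLAST output is redundant: shorter local alignments are often wholly
#' contained in longer ones. An HSP is dropped when its nuclear interval is
#' contained (shared endpoints allowed) within the nuclear interval of a
#' strictly longer HSP on the same nuclear sequence. Exact-duplicate
#' intervals keep a single representative (highest bitscore, then input
#' order).
#'
#' @param hsps Tibble of HSPs with columns `sseqid`, `s_start`, `s_end` and
#'   `bitscore`.
#' @return The surviving rows, in input order.
#' @export
remove_embedded <- function(hsps) {
  if (!nrow(hsps)) return(hsps)
  hsps$.row <- seq_len(nrow(hsps))
  keep <- unlist(lapply(split(hsps, hsps$sseqid), function(h) {
    w <- h$s_end - h$s_start + 1L
    n <- nrow(h)
    drop <- logical(n)
    for (i in seq_len(n)) {
      container <- h$s_start <= h$s_start[i] & h$s_end >= h$s_end[i]
      if (any(container & w > w[i])) {
        drop[i] <- TRUE
        next
      }
      dup <- container & h$s_start == h$s_start[i] & h$s_end == h$s_end[i]
      if (sum(dup) > 1) {
        best <- which(dup)[order(-h$bitscore[dup], h$.row[dup])][1]
        if (best != i) drop[i] <- TRUE
      }
    }
    h$.row[!drop]
  }))
  out <- hsps[hsps$.row %in% keep, , drop = FALSE]
  out$.row <- NULL
  out
}

#' Merge overlapping HSPs into insertion intervals
#'
#' Overlapping or book-ended HSP intervals on the same nuclear sequence are
#' merged transitively (bedtools distance-0 semantics). The identity of a
#' merged interval is the unweighted arithmetic mean of its member HSP
#' identities — each local alignment contributes equally regardless of
#' length — unless `weight_by_length` is set.
#'
#' @param hsps Embedded-free HSP tibble for one source genome.
#' @param source `"NUPT"` (plastid origin) or `"NUMT"` (mitochondrial).
#' @param weight_by_length Weight member identities by alignment length;
#'   default FALSE.
#' @return A tibble of class `merged_insertions` with columns `chrom`,
#'   `start`, `end` (1-based inclusive), `mean_identity`, `n_hsps`,
#'   `source`, sorted by `(chrom, start)` with disjoint intervals per chrom.
#' @export
merge_insertions <- function(hsps, source = c("NUPT", "NUMT"),
                             weight_by_length = FALSE) {
  source <- match.arg(source)
  empty <- tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    mean_identity = double(), n_hsps = integer(), source = character()
  )
  if (!nrow(hsps)) return(structure(empty, class = c("merged_insertions", class(empty))))
  out <- purrr::map_dfr(split(hsps, hsps$sseqid), function(h) {
    ir <- IRanges::IRanges(start = h$s_start, end = h$s_end)
    merged <- IRanges::reduce(ir, min.gapwidth = 1L)
    ov <- IRanges::findOverlaps(ir, merged)
    grp <- S4Vectors::subjectHits(ov)
    ident <- vapply(seq_along(merged), function(j) {
      members <- S4Vectors::queryHits(ov)[grp == j]
      if (weight_by_length) {
        stats::weighted.mean(h$pident[members], h$length[members])
      } else {
        mean(h$pident[members])
      }
    }, double(1))
    tibble::tibble(
      chrom = h$sseqid[1],
      start = IRanges::start(merged),
      end = IRanges::end(merged),
      mean_identity = ident,
      n_hsps = tabulate(grp, nbins = length(merged)),
      source = source
    )
  })
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  structure(out, class = c("merged_insertions", class(empty)))
}

# Methylation context of a cytosine at 1-based position pos of seq, given the
# strand carrying the pyrimidine: ref "C" reads downstream, ref "G" reads the
# reverse complement (upstream). NA within 2 bases of a sequence end, for
# non-C/G references, and when a neighboring base is N.
cytosine_context <- function(seq, pos, ref) {
  n <- nchar(seq)
  at <- function(i) {
    out <- rep(NA_character_, length(i))
    ok <- i >= 1 & i <= n
    if (any(ok)) out[ok] <- substring(seq, i[ok], i[ok])
    out
  }
  ctx <- rep(NA_character_, length(pos))
  h_down <- c("A", "C", "T")
  h_up <- c("A", "G", "T") # complement of H on the reverse strand

  is_c <- ref == "C" & pos <= n - 2
  d1 <- at(pos + 1)
  d2 <- at(pos + 2)
  ctx[is_c & d1 == "G"] <- "CG"
  ctx[is_c & d1 %in% h_down & d2 == "G"] <- "CHG"
  ctx[is_c & d1 %in% h_down & d2 %in% h_down] <- "CHH"

  is_g <- ref == "G" & pos >= 3
  u1 <- at(pos - 1)
  u2 <- at(pos - 2)
  ctx[is_g & u1 == "C"] <- "CG"
  ctx[is_g & u1 %in% h_up & u2 == "C"] <- "CHG"
  ctx[is_g & u1 %in% h_up & u2 %in% h_up] <- "CHH"
  ctx
}

parse_cs_items <- function(cs) {
  stringr::str_match_all(cs, "(:[0-9]+|\\*[a-zA-Z][a-zA-Z]|\\+[a-zA-Z]+|-[a-zA-Z]+|=[A-Za-z]+)")[[1]][, 2]
}

#' Call substitutions from cs-tagged alignments
#'
#' Walks the `cs` difference string of each alignment of nuclear insertion
#' sequence (query) against its source organellar genome (target) and emits
#' one record per single-base substitution, positioned on the organellar
#' genome. Insertions and deletions are ignored. Each substitution at a C:G
#' pair is annotated with the methylation context (CG, CHG, CHH) read from
#' the organellar sequence — the pre-insertion ancestral state — on the
#' strand carrying the cytosine.
#'
#' @param paf Tibble from [read_paf()] with non-NA `cs` values.
#' @param organelle_seq The organellar genome as a single string.
#' @return A tibble with columns `organelle_pos` (1-based), `ref`, `alt`,
#'   `context` (`"CG"`, `"CHG"`, `"CHH"` or NA).
#' @export
call_substitutions <- function(paf, organelle_seq) {
  if (any(is.na(paf$cs))) {
    stop("cs tag absent for record ", paf$qname[which(is.na(paf$cs))[1]])
  }
  rows <- purrr::map_dfr(seq_len(nrow(paf)), function(i) {
    items <- parse_cs_items(paf$cs[i])
    pos <- paf$tstart[i] + 1L # target coordinate, 1-based
    refs <- character()
    alts <- character()
    at <- integer()
    for (it in items) {
      op <- substr(it, 1, 1)
      if (op == ":") {
        pos <- pos + as.integer(substr(it, 2, nchar(it)))
      } else if (op == "=") {
        pos <- pos + nchar(it) - 1L
      } else if (op == "*") {
        at <- c(at, pos)
        refs <- c(refs, toupper(substr(it, 2, 2)))
        alts <- c(alts, toupper(substr(it, 3, 3)))
        pos <- pos + 1L
      } else if (op == "-") {
        pos <- pos + nchar(it) - 1L
      }
      # '+' (insertion in the query) does not advance the target
    }
    tibble::tibble(organelle_pos = at, ref = refs, alt = alts)
  })
  if (!nrow(rows)) {
    return(tibble::tibble(organelle_pos = integer(), ref = character(),
                          alt = character(), context = character()))
  }
  actual <- substring(organelle_seq, rows$organelle_pos, rows$organelle_pos)
  if (any(actual != rows$ref)) {
    warning(sum(actual != rows$ref),
            " substitution record(s) disagree with the organellar sequence")
  }
  rows$context <- cytosine_context(organelle_seq, rows$organelle_pos, rows$ref)
  rows
}

spectrum_classes <- c("C:G>T:A", "C:G>A:T", "C:G>G:C",
                      "T:A>C:G", "T:A>A:T", "T:A>G:C")

# Strand-collapsed substitution class; purine references are complemented.
collapse_class <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, comp[ref], ref)
  a <- ifelse(pur, comp[alt], alt)
  paste0(r, ":", comp[r], ">", a, ":", comp[a])
}

#' Substitution spectrum with cytosine-context resolution
#'
#' Tallies substitutions into the six strand-collapsed classes and, for the
#' cytosine classes (C:G>*), into CG/CHG/CHH methylation contexts. When the
#' organellar sequence and the aligned intervals are supplied, per-context
#' site counts over the aligned organellar bases are computed as
#' denominators, giving per-context substitution rates (spontaneous
#' deamination of methylated cytosine elevates C:G>T:A at CG and CHG sites).
#'
#' @param substitutions Tibble from [call_substitutions()].
#' @param organelle_seq Optional organellar genome string for denominators.
#' @param aligned Optional tibble of aligned organellar intervals with
#'   columns `start`, `end` (1-based inclusive); a [read_paf()] tibble is
#'   accepted (target intervals are used).
#' @return A list of class `spectrum_table`: `classes` (tibble `class`,
#'   `count`, `fraction`), `contexts` (tibble `context`, `count`, `sites`,
#'   `rate`; `sites`/`rate` NA without denominators), `n` (total
#'   substitutions).
#' @export
substitution_spectrum <- function(substitutions, organelle_seq = NULL,
                                  aligned = NULL) {
  cls <- collapse_class(substitutions$ref, substitutions$alt)
  counts <- table(factor(cls, levels = spectrum_classes))
  classes <- tibble::tibble(
    class = spectrum_classes,
    count = as.integer(counts),
    fraction = if (sum(counts) > 0) as.numeric(counts) / sum(counts) else NA_real_
  )
  is_cyt <- startsWith(cls, "C:G")
  ctx_counts <- table(factor(substitutions$context[is_cyt],
                             levels = c("CG", "CHG", "CHH")))
  sites <- rep(NA_integer_, 3)
  if (!is.null(organelle_seq) && !is.null(aligned)) {
    if (all(c("tstart", "tend") %in% names(aligned))) {
      aligned <- tibble::tibble(start = aligned$tstart + 1L, end = aligned$tend)
    }
    ir <- IRanges::reduce(IRanges::IRanges(aligned$start, aligned$end))
    pos <- unlist(lapply(seq_along(ir), function(j) {
      seq.int(IRanges::start(ir)[j], IRanges::end(ir)[j])
    }))
    base <- substring(organelle_seq, pos, pos)
    ctx <- cytosine_context(organelle_seq, pos, base)
    sites <- as.integer(table(factor(ctx, levels = c("CG", "CHG", "CHH"))))
  }
  contexts <- tibble::tibble(
    context = c("CG", "CHG", "CHH"),
    count = as.integer(ctx_counts),
    sites = sites,
    rate = as.integer(ctx_counts) / sites
  )
  structure(list(classes = classes, contexts = contexts,
                 n = length(cls)),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat("<spectrum_table>", x$n, "substitutions\n")
  print(x$classes)
  invisible(x)
}

#' Permutation test for interval overlap enrichment
#'
#' Tests whether a feature set (e.g. siRNA loci) overlaps an annotation set
#' (e.g. NUPTs or NUMTs) more than expected by chance. The null is built by
#' re-placing every feature uniformly at random within its own chromosome
#' (lengths preserved, features free to overlap each other), `n_samples`
#' times. The empirical p-value is `(1 + #\{null >= observed\}) /
#' (1 + n_samples)`; the fold is observed over null mean, with a 95%
#' interval obtained from the 2.5th and 97.5th percentiles of the null
#' overlap distribution (`ci_low = observed / q97.5`,
#' `ci_high = observed / q2.5`).
#'
#' @param features Tibble of intervals (`chrom`, `start`, `end`, 1-based
#'   inclusive) to randomize.
#' @param annotations Tibble of fixed intervals to test overlap against.
#' @param genome Chromosome sizes: a named numeric vector or a tibble with
#'   columns `chrom` and `length`.
#' @param n_samples Number of permutations, default 1000.
#' @param seed Optional RNG seed for reproducible sampling.
#' @return A list of class `enrichment_result` with elements
#'   `observed_overlap`, `null_mean`, `fold`, `p_empirical`, `ci_low`,
#'   `ci_high`, `n_samples`, `null_overlaps`.
#' @export
enrichment_test <- function(features, annotations, genome, n_samples = 1000,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(genome)) {
    sizes <- stats::setNames(genome$length, genome$chrom)
  } else {
    sizes <- genome
  }
  missing_chr <- setdiff(features$chrom, names(sizes))
  if (length(missing_chr)) {
    stop("feature chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  }
  flen <- features$end - features$start + 1L
  too_long <- flen > sizes[features$chrom]
  if (any(too_long)) {
    stop("feature longer than its chromosome: ",
         features$chrom[which(too_long)[1]])
  }

  # per-chromosome cumulative coverage of the (merged) annotations, so the
  # overlap of any interval is two lookups
  cum_by_chrom <- lapply(stats::setNames(names(sizes), names(sizes)), function(ch) {
    L <- as.integer(sizes[[ch]])
    a <- annotations[annotations$chrom == ch, , drop = FALSE]
    if (!nrow(a)) return(NULL)
    ir <- IRanges::reduce(IRanges::IRanges(pmax(a$start, 1L), pmin(a$end, L)))
    cov <- integer(L)
    for (j in seq_along(ir)) {
      cov[IRanges::start(ir)[j]:IRanges::end(ir)[j]] <- 1L
    }
    cumsum(cov)
  })
  interval_overlap <- function(ch, s, e) {
    cum <- cum_by_chrom[[ch]]
    if (is.null(cum)) return(numeric(length(s)))
    before <- numeric(length(s)) # zero-indexing guard: cum[0] drops, not NA
    inside <- s > 1
    before[inside] <- cum[s[inside] - 1]
    cum[e] - before
  }

  observed <- sum(unlist(lapply(seq_len(nrow(features)), function(i) {
    interval_overlap(features$chrom[i], features$start[i], features$end[i])
  })))

  null_overlaps <- numeric(n_samples)
  for (i in seq_len(nrow(features))) {
    ch <- features$chrom[i]
    L <- as.integer(sizes[[ch]])
    len <- flen[i]
    starts <- sample.int(L - len + 1L, n_samples, replace = TRUE)
    null_overlaps <- null_overlaps + interval_overlap(ch, starts, starts + len - 1L)
  }

  null_mean <- mean(null_overlaps)
  q <- stats::quantile(null_overlaps, c(0.025, 0.975), names = FALSE)
  structure(
    list(
      observed_overlap = observed,
      null_mean = null_mean,
      fold = if (null_mean > 0) observed / null_mean else 0,
      p_empirical = (1 + sum(null_overlaps >= observed)) / (1 + n_samples),
      ci_low = if (q[2] > 0) observed / q[2] else NA_real_,
      ci_high = if (q[1] > 0) observed / q[1] else NA_real_,
      n_samples = n_samples,
      null_overlaps = null_overlaps
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> observed=%g null_mean=%.2f fold=%.2f [%.2f, %.2f] p=%.4g (n=%d)\n",
    x$observed_overlap, x$null_mean, x$fold, x$ci_low, x$ci_high,
    x$p_empirical, x$n_samples
  ))
  invisible(x)
}

#' Cross-species insertion summaries and correlations
#'
#' Computes, per species, the cumulative NUPT and NUMT lengths and mean
#' identities, a cumulative-length histogram over 1-point identity bins on
#' (80, 100], and pairwise Pearson correlations (on raw and log10 scales for
#' the length pairs) among cumulative lengths and nuclear genome size.
#'
#' @param insertions Tibble of merged insertions across species, with
#'   columns `species`, `chrom`, `start`, `end`, `mean_identity`, `source`.
#' @param genome_sizes Tibble with columns `species` and `nuclear_size`
#'   (bases).
#' @return A list of class `insertion_summary`: `species` (per-species
#'   table), `identity_hist` (per source and identity bin), `correlations`
#'   (tibble `pair`, `r_raw`, `r_log`; NA with fewer than 3 species).
#' @export
summarize_insertions <- function(insertions, genome_sizes) {
  per <- insertions |>
    dplyr::mutate(width = .data$end - .data$start + 1L) |>
    dplyr::group_by(.data$species, .data$source) |>
    dplyr::summarise(
      total_length = sum(.data$width),
      mean_identity = mean(.data$mean_identity),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(
      names_from = "source",
      values_from = c("total_length", "mean_identity"),
      values_fill = list(total_length = 0)
    )
  for (col in c("total_length_NUPT", "total_length_NUMT",
                "mean_identity_NUPT", "mean_identity_NUMT")) {
    if (!col %in% names(per)) per[[col]] <- NA_real_
  }
  species <- dplyr::left_join(per, tibble::as_tibble(genome_sizes), by = "species")

  identity_hist <- insertions |>
    dplyr::mutate(
      width = .data$end - .data$start + 1L,
      bin = cut(.data$mean_identity, breaks = 80:100, right = TRUE)
    ) |>
    dplyr::group_by(.data$source, .data$bin) |>
    dplyr::summarise(total_length = sum(.data$width), .groups = "drop")

  safe_cor <- function(x, y, log_scale = FALSE) {
    ok <- stats::complete.cases(x, y)
    if (log_scale) ok <- ok & x > 0 & y > 0
    x <- x[ok]
    y <- y[ok]
    if (log_scale) {
      x <- log10(x)
      y <- log10(y)
    }
    # undefined with fewer than 3 species or a degenerate column
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y)
  }
  correlations <- tibble::tibble(
    pair = c("NUPT_length~nuclear_size", "NUMT_length~nuclear_size",
             "NUPT_length~NUMT_length", "NUPT_identity~NUMT_identity"),
    r_raw = c(
      safe_cor(species$total_length_NUPT, species$nuclear_size),
      safe_cor(species$total_length_NUMT, species$nuclear_size),
      safe_cor(species$total_length_NUPT, species$total_length_NUMT),
      safe_cor(species$mean_identity_NUPT, species$mean_identity_NUMT)
    ),
    r_log = c(
      safe_cor(species$total_length_NUPT, species$nuclear_size, TRUE),
      safe_cor(species$total_length_NUMT, species$nuclear_size, TRUE),
      safe_cor(species$total_length_NUPT, species$total_length_NUMT, TRUE),
      NA_real_
    )
  )
  structure(list(species = species, identity_hist = identity_hist,
                 correlations = correlations),
            class = "insertion_summary")
}
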