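#' Synthetic quadripartite chloroplast genome
#'
#' Generates a random chloroplast-like genome with the canonical four-part
#' architecture LSC + IR + SSC + inverted IR, together with its ground
#' truth: region boundaries, the 3-segment assembly graph a perfect
#' assembler would emit, and both heteroplasmic isomer sequences.
#'
#' @param lsc_len,ssc_len,ir_len Region lengths in bases; all must be at
#'   least `4 * k`. Defaults give a 23 kb miniature genome.
#' @param seed Optional RNG seed for reproducibility.
#' @param k Word length the minimum-size rule is checked against, default 31.
#' @return A list of class `fixture_chloroplast`: `genome` (string),
#'   `regions` (tibble `region`, `start`, `end` tiling the genome),
#'   `graph` (truth [assembly_graph()]), `isomers` (named character,
#'   `isomer_A`/`isomer_B`).
#' @export
make_quadripartite_genome <- function(lsc_len = 12000, ssc_len = 5000,
                                      ir_len = 3000, seed = NULL, k = 31) {
  if (any(c(lsc_len, ssc_len, ir_len) < 4 * k)) {
    stop("all region lengths must be at least 4*k = ", 4 * k, " bases")
  }
  if (!is.null(seed)) set.seed(seed)
  lsc <- random_dna(lsc_len)
  ir <- random_dna(ir_len)
  ssc <- random_dna(ssc_len)
  genome <- paste0(lsc, ir, ssc, revcomp(ir))
  regions <- tibble::tibble(
    region = c("LSC", "IRa", "SSC", "IRb"),
    start = c(1L, lsc_len + 1L, lsc_len + ir_len + 1L,
              lsc_len + ir_len + ssc_len + 1L),
    end = c(lsc_len, lsc_len + ir_len, lsc_len + ir_len + ssc_len,
            lsc_len + 2L * ir_len + ssc_len)
  )
  graph <- assembly_graph(
    segments = tibble::tibble(
      id = c("LSC", "IR", "SSC"),
      seq = c(lsc, ir, ssc),
      length = c(lsc_len, ir_len, ssc_len)
    ),
    links = tibble::tibble(
      from_id = c("LSC", "IR", "SSC", "IR"),
      from_orient = c("+", "+", "+", "-"),
      to_id = c("IR", "SSC", "IR", "LSC"),
      to_orient = c("+", "+", "-", "+"),
      overlap = 0L
    )
  )
  isomers <- c(
    isomer_A = genome,
    isomer_B = paste0(lsc, ir, revcomp(ssc), revcomp(ir))
  )
  structure(list(genome = genome, regions = regions, graph = graph,
                 isomers = isomers),
            class = "fixture_chloroplast")
}

#' Synthetic mitochondrial genome
#'
#' Generates one circular main chromosome, optionally plus a small
#' independent circle (plant mitochondrial genomes frequently carry small
#' circular DNAs), together with the truth assembly graph (one self-closing
#' segment per circle) and the set of conserved panel genes the genome is
#' considered to carry for completeness scoring.
#'
#' @param main_len Length of the main circle, default 30000.
#' @param small_circle_len Length of an optional small circle (NULL for
#'   none), default 5000.
#' @param n_genes Number of panel genes planted, default 38 of the 41.
#' @param seed Optional RNG seed.
#' @return A list of class `fixture_mitochondrion`: `seqs` (tibble `name`,
#'   `seq`, `circular`), `graph` (truth graph), `genes` (character).
#' @export
make_mito_genome <- function(main_len = 30000, small_circle_len = 5000,
                             n_genes = 38, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  names <- "mito_main"
  seqs <- random_dna(main_len)
  if (!is.null(small_circle_len)) {
    names <- c(names, "mito_small")
    seqs <- c(seqs, random_dna(small_circle_len))
  }
  graph <- assembly_graph(
    segments = tibble::tibble(id = names, seq = seqs, length = nchar(seqs)),
    links = tibble::tibble(
      from_id = names, from_orient = "+", to_id = names, to_orient = "+",
      overlap = 0L
    )
  )
  genes <- sort(sample(mito_gene_panel(), n_genes))
  structure(
    list(
      seqs = tibble::tibble(name = names, seq = seqs, circular = TRUE),
      graph = graph,
      genes = genes
    ),
    class = "fixture_mitochondrion"
  )
}

default_class_probs <- c(
  "C:G>T:A" = 0.60, "C:G>A:T" = 0.08, "C:G>G:C" = 0.08,
  "T:A>C:G" = 0.08, "T:A>A:T" = 0.08, "T:A>G:C" = 0.08
)

# alt base for a given reference base under a strand-collapsed class
class_alt <- function(class, ref) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pyr_alt <- substr(class, 5, 5) # W in X:Y>W:Z
  ifelse(ref %in% c("C", "T"), pyr_alt, unname(comp[pyr_alt]))
}

#' Plant organellar insertions into a synthetic nuclear genome
#'
#' Copies `n` random fragments of the organellar genome into non-overlapping
#' positions of a random nuclear sequence, mutating each copy down to a
#' target identity. Substitution classes are drawn from `class_probs`
#' (default dominated by C:G>T:A, emulating deamination of methylated
#' cytosines) and cytosine-class substitutions are concentrated at CG and
#' CHG sites according to `ctx_weights`. Every planted substitution is
#' recorded so downstream spectrum recovery can be scored exactly.
#'
#' @param nuclear_len Length of the nuclear sequence.
#' @param organelle_seq Source organellar genome (string).
#' @param n Number of insertions.
#' @param identity_targets Percent identities in (80, 100], recycled over
#'   insertions; default 98 (recent insertions dominate real genomes).
#' @param frag_len_range Fragment length range in bases, default 500-3000.
#' @param class_probs Named probabilities over the six substitution classes.
#' @param ctx_weights Relative sampling weights for cytosine sites by
#'   context, default `c(CG = 6, CHG = 3, CHH = 1)`.
#' @param seed Optional RNG seed.
#' @return A list of class `fixture_insertions`: `nuclear_seq`, `insertions`
#'   (truth tibble with nuclear and organellar coordinates, target and
#'   realized identity), `substitutions` (truth tibble with `organelle_pos`,
#'   `ref`, `alt`, `context`, `class`), `organelle_seq`.
#' @export
plant_insertions <- function(nuclear_len, organelle_seq, n = 20,
                             identity_targets = 98,
                             frag_len_range = c(500, 3000),
                             class_probs = default_class_probs,
                             ctx_weights = c(CG = 6, CHG = 3, CHH = 1),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(identity_targets > 80), all(identity_targets <= 100))
  stopifnot(abs(sum(class_probs) - 1) < 1e-8)
  org_len <- nchar(organelle_seq)
  identity_targets <- rep_len(identity_targets, n)
  nuclear <- strsplit(random_dna(nuclear_len), "")[[1]]

  if (n == 0) {
    return(structure(list(
      nuclear_seq = paste(nuclear, collapse = ""),
      insertions = tibble::tibble(
        chrom = character(), start = integer(), end = integer(),
        org_start = integer(), org_end = integer(),
        identity_target = double(), realized_identity = double(),
        n_subs = integer()
      ),
      substitutions = tibble::tibble(
        insertion = integer(), organelle_pos = integer(), ref = character(),
        alt = character(), context = character(), class = character()
      ),
      organelle_seq = organelle_seq
    ), class = "fixture_insertions"))
  }

  # sample.int avoids base::sample's scalar-argument surprise when the
  # length range is degenerate
  frag_lens <- frag_len_range[1] - 1L +
    sample.int(frag_len_range[2] - frag_len_range[1] + 1L, n, replace = TRUE)
  if (sum(frag_lens) > nuclear_len * 0.8) {
    stop("insertions cannot fit disjointly in the nuclear sequence")
  }

  # reserve non-overlapping nuclear slots by rejection sampling
  slots <- IRanges::IRanges()
  starts <- integer(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:1000) {
      s <- sample.int(nuclear_len - frag_lens[i] + 1L, 1)
      cand <- IRanges::IRanges(s, s + frag_lens[i] - 1L)
      if (!length(slots) || !length(IRanges::findOverlaps(cand, slots))) {
        slots <- c(slots, cand)
        starts[i] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("insertions cannot fit disjointly in the nuclear sequence")
  }

  ins_rows <- list()
  sub_rows <- list()
  for (i in seq_len(n)) {
    len <- frag_lens[i]
    org_start <- sample.int(org_len - len + 1L, 1)
    org_pos <- org_start:(org_start + len - 1L)
    frag <- strsplit(substring(organelle_seq, org_start, org_start + len - 1L), "")[[1]]
    n_subs <- round((1 - identity_targets[i] / 100) * len)

    ctx_all <- cytosine_context(organelle_seq, org_pos, frag)
    cyt_idx <- which(frag %in% c("C", "G"))
    ta_idx <- which(frag %in% c("A", "T"))
    w_cyt <- ctx_weights[ctx_all[cyt_idx]]
    w_cyt[is.na(w_cyt)] <- min(ctx_weights)

    classes <- sample(names(class_probs), n_subs, replace = TRUE, prob = class_probs)
    n_cyt <- sum(startsWith(classes, "C:G"))
    n_ta <- n_subs - n_cyt
    n_cyt <- min(n_cyt, length(cyt_idx))
    n_ta <- min(n_ta, length(ta_idx))
    pick_cyt <- if (n_cyt) sample(cyt_idx, n_cyt, prob = w_cyt) else integer()
    pick_ta <- if (n_ta) sample(ta_idx, n_ta) else integer()
    picked <- c(pick_cyt, pick_ta)
    picked_class <- c(classes[startsWith(classes, "C:G")][seq_len(n_cyt)],
                      classes[!startsWith(classes, "C:G")][seq_len(n_ta)])

    ref <- frag[picked]
    alt <- class_alt(picked_class, ref)
    frag[picked] <- alt
    nuclear[starts[i]:(starts[i] + len - 1L)] <- frag

    ord <- order(picked)
    ins_rows[[i]] <- tibble::tibble(
      chrom = "nuc1", start = starts[i], end = starts[i] + len - 1L,
      org_start = org_start, org_end = org_start + len - 1L,
      identity_target = identity_targets[i],
      realized_identity = 100 * (1 - length(picked) / len),
      n_subs = length(picked)
    )
    sub_rows[[i]] <- tibble::tibble(
      insertion = i,
      organelle_pos = org_pos[picked[ord]],
      ref = ref[ord],
      alt = alt[ord],
      context = ctx_all[picked[ord]],
      class = picked_class[ord]
    )
  }

  structure(list(
    nuclear_seq = paste(nuclear, collapse = ""),
    insertions = dplyr::bind_rows(ins_rows),
    substitutions = dplyr::bind_rows(sub_rows),
    organelle_seq = organelle_seq
  ), class = "fixture_insertions")
}

#' Truth HSP table for planted insertions
#'
#' Emits one BLAST-6-style HSP per planted insertion, as an idealized
#' similarity search would report them, for exercising the HSP filtering and
#' merging stages without an external search tool.
#'
#' @param fix A [plant_insertions()] fixture.
#' @param qseqid Query (organelle) sequence name, default `"organelle"`.
#' @return A tibble in [read_blast6()] layout.
#' @export
insertion_hsps <- function(fix, qseqid = "organelle") {
  ins <- fix$insertions
  tibble::tibble(
    qseqid = qseqid,
    sseqid = ins$chrom,
    pident = ins$realized_identity,
    length = ins$end - ins$start + 1L,
    mismatch = ins$n_subs,
    gapopen = 0L,
    qstart = ins$org_start,
    qend = ins$org_end,
    s_start = ins$start,
    s_end = ins$end,
    strand = "+",
    evalue = 0,
    bitscore = 2 * (ins$end - ins$start + 1L)
  )
}

#' Truth cs-tagged PAF for planted insertions
#'
#' Builds the alignment each nuclear insertion would produce against its
#' source organellar genome, with an exact `cs` difference string derived
#' from the recorded truth substitutions, for exercising substitution
#' calling without an external aligner.
#'
#' @param fix A [plant_insertions()] fixture.
#' @param tname Target (organelle) sequence name, default `"organelle"`.
#' @return A tibble in [read_paf()] layout with `cs` strings.
#' @export
insertion_paf <- function(fix, tname = "organelle") {
  ins <- fix$insertions
  subs <- fix$substitutions
  purrr::map_dfr(seq_len(nrow(ins)), function(i) {
    len <- ins$end[i] - ins$start[i] + 1L
    s <- subs[subs$insertion == i, , drop = FALSE]
    s <- s[order(s$organelle_pos), , drop = FALSE]
    cs <- character()
    prev <- ins$org_start[i] - 1L
    for (j in seq_len(nrow(s))) {
      gap <- s$organelle_pos[j] - prev - 1L
      if (gap > 0) cs <- c(cs, paste0(":", gap))
      cs <- c(cs, paste0("*", tolower(s$ref[j]), tolower(s$alt[j])))
      prev <- s$organelle_pos[j]
    }
    tail_gap <- ins$org_end[i] - prev
    if (tail_gap > 0) cs <- c(cs, paste0(":", tail_gap))
    tibble::tibble(
      qname = paste0("ins", i), qlen = len, qstart = 0L, qend = len,
      strand = "+", tname = tname, tlen = nchar(fix$organelle_seq),
      tstart = ins$org_start[i] - 1L, tend = ins$org_end[i],
      matches = len - ins$n_subs[i], blocklen = len, mapq = 60L,
      cs = paste(cs, collapse = "")
    )
  })
}

#' Simulate HiFi-like reads from a set of genomes
#'
#' Draws reads with lognormal lengths and uniform start positions (circular
#' genomes are sampled across the origin), applies uniform substitution
#' errors, and records the true origin of every read. Read counts per genome
#' are `coverage * copy * length / mean_len`, so organelle/nuclear coverage
#' asymmetry is expressed through the `copy` column.
#'
#' @param genomes Tibble with columns `name`, `seq`, `circular` (logical),
#'   `copy` (copy-number ratio) and `label` (true class:
#'   `"plastid"`, `"mitochondrion"`, `"nuclear"`).
#' @param coverage Base coverage per genome copy, default 1.
#' @param mean_len,len_sd Lognormal read-length mean and standard deviation
#'   in bases, defaults 2000 and 500.
#' @param error_rate Per-base substitution error rate, default 0.001
#'   (HiFi-like).
#' @param seed Optional RNG seed.
#' @return A tibble of reads (`id`, `seq`, `qual`, `label`) plus truth
#'   columns `source` (genome name), `start`, `length`.
#' @export
simulate_reads <- function(genomes, coverage = 1, mean_len = 2000,
                           len_sd = 500, error_rate = 0.001, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(coverage > 0)
  sdlog <- sqrt(log(1 + (len_sd / mean_len)^2))
  meanlog <- log(mean_len) - sdlog^2 / 2
  bases <- c("A", "C", "G", "T")
  purrr::map_dfr(seq_len(nrow(genomes)), function(g) {
    glen <- nchar(genomes$seq[g])
    n_reads <- max(1L, round(coverage * genomes$copy[g] * glen / mean_len))
    lens <- pmin(glen, pmax(50L, round(stats::rlnorm(n_reads, meanlog, sdlog))))
    if (genomes$circular[g]) {
      starts <- sample.int(glen, n_reads, replace = TRUE)
      doubled <- paste0(genomes$seq[g], genomes$seq[g])
      seqs <- substring(doubled, starts, starts + lens - 1L)
    } else {
      starts <- vapply(lens, function(l) sample.int(glen - l + 1L, 1), integer(1))
      seqs <- substring(genomes$seq[g], starts, starts + lens - 1L)
    }
    if (error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        n_err <- stats::rbinom(1, nchar(s), error_rate)
        if (n_err == 0) return(s)
        pos <- sample.int(nchar(s), n_err)
        ch <- strsplit(s, "")[[1]]
        ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(bases, b), 1),
                          character(1))
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    tibble::tibble(
      id = sprintf("%s_read%05d", genomes$name[g], seq_len(n_reads)),
      seq = seqs,
      qual = NA_character_,
      label = genomes$label[g],
      source = genomes$name[g],
      start = starts,
      length = lens
    )
  })
}

#' Default classifier confusion matrix
#'
#' Identity minus a uniform off-diagonal confusion rate over the three true
#' classes.
#'
#' @param error Total misclassification probability per true class,
#'   default 0.05, split evenly over the two wrong labels.
#' @return A 3x3 row-stochastic matrix over plastid / mitochondrion /
#'   nuclear.
#' @export
default_confusion <- function(error = 0.05) {
  labs <- c("plastid", "mitochondrion", "nuclear")
  m <- matrix(error / 2, 3, 3, dimnames = list(labs, labs))
  diag(m) <- 1 - error
  m
}

#' Stub read classifier with programmable confusion
#'
#' Emulates a neural read classifier: each read's predicted label is drawn
#' from the confusion-matrix row of its true label. Nuclear reads that carry
#' organellar insertions can be forced to organelle labels (`force_labels`),
#' emulating the documented failure mode where insertion-bearing nuclear
#' reads are classified as organellar.
#'
#' @param reads Tibble of reads with a truth `label` column.
#' @param confusion Row-stochastic matrix, rows/columns named by class;
#'   default [default_confusion()].
#' @param force_labels Optional tibble (`id`, `label`) of post-hoc label
#'   overrides.
#' @param seed Optional RNG seed.
#' @return The reads with `label` replaced by the predicted label and the
#'   truth preserved in `true_label`.
#' @export
stub_classifier <- function(reads, confusion = default_confusion(),
                            force_labels = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rownames(confusion)) || is.null(colnames(confusion)) ||
      any(abs(rowSums(confusion) - 1) > 1e-8)) {
    stop("malformed confusion matrix: rows must be named and sum to 1")
  }
  unknown <- setdiff(unique(reads$label), rownames(confusion))
  if (length(unknown)) {
    stop("no confusion row for true label(s): ", paste(unknown, collapse = ", "))
  }
  predicted <- vapply(reads$label, function(tr) {
    sample(colnames(confusion), 1, prob = confusion[tr, ])
  }, character(1), USE.NAMES = FALSE)
  out <- dplyr::mutate(reads, true_label = .data$label, label = predicted)
  if (!is.null(force_labels)) {
    idx <- match(force_labels$id, out$id)
    out$label[idx[!is.na(idx)]] <- force_labels$label[!is.na(idx)]
  }
  out
}

#' Oracle assembler adapter over fixture truth
#'
#' Returns an assembler function usable by the pipeline: it emits the truth
#' assembly graph when the supplied read pool is pure enough (at least
#' `min_frac` of reads from the target genomes) and deep enough (total bases
#' at least `min_cov` times the genome length); otherwise it emits a
#' deliberately broken graph with dangling segments, so retry logic can be
#' exercised without an external assembler binary.
#'
#' @param truth_graph The truth [assembly_graph()].
#' @param target_sources Character vector of genome names counted as
#'   on-target.
#' @param genome_len Total target genome length, for the coverage check.
#' @param min_frac Minimum on-target read fraction, default 0.9.
#' @param min_cov Minimum coverage, default 20.
#' @return A function `f(reads) -> assembly_graph`.
#' @export
make_oracle_assembler <- function(truth_graph, target_sources, genome_len,
                                  min_frac = 0.9, min_cov = 20) {
  force(truth_graph)
  function(reads) {
    if (!nrow(reads)) stop("no reads supplied to assembler")
    frac <- mean(reads$source %in% target_sources)
    cov <- sum(nchar(reads$seq)) / genome_len
    if (frac >= min_frac && cov >= min_cov) {
      truth_graph
    } else {
      # dangling two-segment graph: classified as incomplete downstream
      assembly_graph(
        segments = tibble::tibble(
          id = c("frag1", "frag2"),
          seq = c(strrep("A", 200), strrep("C", 200)),
          length = c(200L, 200L)
        ),
        links = tibble::tibble(from_id = "frag1", from_orient = "+",
                               to_id = "frag2", to_orient = "+", overlap = 0L)
      )
    }
  }
}

#' Stub graph aligner adapter over fixture truth
#'
#' Returns a graph-aligner function for the refinement stage: reads whose
#' true source is one of the chloroplast genomes receive an end-to-end
#' alignment at the given identity; other reads receive a heavily clipped,
#' lower-identity alignment that fails the end-to-end criteria.
#'
#' @param chloro_sources Genome names whose reads align end-to-end.
#' @param identity Identity of end-to-end alignments, default 0.99.
#' @return A function `f(reads, graph) -> GAF tibble`.
#' @export
make_stub_graph_aligner <- function(chloro_sources, identity = 0.99) {
  function(reads, graph) {
    purrr::map_dfr(seq_len(nrow(reads)), function(i) {
      qlen <- nchar(reads$seq[i])
      if (reads$source[i] %in% chloro_sources) {
        tibble::tibble(
          qname = reads$id[i], qlen = qlen, qstart = 0L, qend = qlen,
          strand = "+", path = ">LSC", plen = qlen, pstart = 0L, pend = qlen,
          matches = as.integer(round(identity * qlen)), blocklen = qlen,
          mapq = 60L
        )
      } else {
        # spurious partial hit: large clips, sub-threshold identity
        half <- qlen %/% 2L
        tibble::tibble(
          qname = reads$id[i], qlen = qlen, qstart = as.integer(qlen - half),
          qend = qlen, strand = "+", path = ">LSC", plen = half,
          pstart = 0L, pend = half,
          matches = as.integer(round(0.85 * half)), blocklen = half,
          mapq = 0L
        )
      }
    })
  }
}

#' Stub gene-hit table for completeness scoring
#'
#' @param genes Character vector of genes present in the fixture genome.
#' @param evalue Hit e-value, default 1e-10.
#' @return A tibble (`gene`, `evalue`) consumable by
#'   [assess_completeness()].
#' @export
stub_gene_hits <- function(genes, evalue = 1e-10) {
  tibble::tibble(gene = genes, evalue = evalue)
}

#' Downsample reads to a target coverage
#'
#' Samples reads without replacement, in random order, accumulating bases
#' until the target coverage of the given genome size is reached (the read
#' crossing the target is included).
#'
#' @param reads Tibble of reads.
#' @param genome_size Genome size in bases the coverage refers to.
#' @param target_coverage Desired coverage.
#' @param seed Optional RNG seed.
#' @return The sampled subset of `reads` (all reads, with a warning, when
#'   the input does not reach the target).
#' @export
downsample_reads <- function(reads, genome_size, target_coverage, seed = NULL) {
  stopifnot(target_coverage > 0)
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(nrow(reads))
  cum <- cumsum(nchar(reads$seq[perm]))
  target <- target_coverage * genome_size
  if (cum[length(cum)] < target) {
    warning("input reads provide less than the target coverage; returning all")
    return(reads)
  }
  k <- which(cum >= target)[1]
  reads[perm[seq_len(k)], , drop = FALSE]
}
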