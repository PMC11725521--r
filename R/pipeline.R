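#' Pipeline configuration
#'
#' Collects every tunable constant of the assembly pipeline with the
#' defaults used throughout: k-mer length 31, coverage-filter multipliers
#' 0.3 and 5 around the class median with a 1/5 outlier budget, 800 reads
#' per assembly round (about 100x coverage of a typical chloroplast genome;
#' excess coverage degrades assembler results), at most 10 rounds, and
#' end-to-end refinement bounds of 100 bases clip and 95% identity.
#'
#' @param k K-mer word length.
#' @param low_mult,high_mult Low/high coverage-threshold multipliers.
#' @param max_outlier_frac Outlier-fraction budget per read.
#' @param reads_per_round Reads sampled per chloroplast assembly round.
#' @param max_rounds Maximum chloroplast assembly rounds.
#' @param max_clip Maximum end clip in the refinement step (bases).
#' @param min_identity Minimum alignment identity in the refinement step.
#' @param seed Base RNG seed; round r draws with `seed + r`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(k = 31, low_mult = 0.3, high_mult = 5,
                            max_outlier_frac = 1 / 5, reads_per_round = 800,
                            max_rounds = 10, max_clip = 100,
                            min_identity = 0.95, seed = 1) {
  cfg <- list(
    k = k, low_mult = low_mult, high_mult = high_mult,
    max_outlier_frac = max_outlier_frac, reads_per_round = reads_per_round,
    max_rounds = max_rounds, max_clip = max_clip,
    min_identity = min_identity, seed = seed
  )
  stopifnot(all(vapply(cfg, function(x) is.numeric(x) && x > 0, logical(1))))
  structure(cfg, class = "pipeline_config")
}

kmer_filter_stage <- function(reads, config) {
  profiles <- kmer_profiles(reads, k = config$k)
  thresholds <- kmer_thresholds(profiles, low_mult = config$low_mult,
                                high_mult = config$high_mult,
                                max_outlier_frac = config$max_outlier_frac)
  annotated <- kmer_filter_reads(reads, thresholds = thresholds,
                                 k = config$k, profiles = profiles)
  list(kept = dplyr::filter(annotated, .data$kept),
       removed = dplyr::filter(annotated, !.data$kept),
       thresholds = thresholds)
}

#' Iterative chloroplast assembly with structure recognition
#'
#' Repeatedly samples `reads_per_round` reads (without replacement, seeded
#' with `seed + round`), runs the assembler adapter, and classifies the
#' resulting graph, stopping as soon as the graph shows the quadripartite
#' chloroplast structure or a single circle, at which point the isomer
#' sequences are extracted. After `max_rounds` unsuccessful rounds the last
#' graph is returned with its (non-walkable) classification.
#'
#' @param reads Coverage-filtered plastid-labeled reads.
#' @param config A [pipeline_config()].
#' @param assembler Function `f(reads) -> assembly_graph` (an external
#'   assembler adapter or [make_oracle_assembler()]).
#' @return A list of class `chloroplast_result`: `graph`, `call`, `isomers`
#'   (NULL on failure), `success`, `rounds` (per-round log tibble).
#' @export
assemble_chloroplast <- function(reads, config = pipeline_config(), assembler) {
  log_rows <- list()
  graph <- NULL
  call <- NULL
  for (r in seq_len(config$max_rounds)) {
    set.seed(config$seed + r)
    if (nrow(reads) <= config$reads_per_round) {
      if (r == 1) warning("fewer reads than reads_per_round; using all reads")
      round_reads <- reads
    } else {
      round_reads <- reads[sample.int(nrow(reads), config$reads_per_round), ,
                           drop = FALSE]
    }
    graph <- tryCatch(assembler(round_reads), error = function(e) {
      tryCatch(assembler(round_reads),
               error = function(e2) stop("assembler failed twice: ",
                                         conditionMessage(e2)))
    })
    call <- classify_graph(graph)
    log_rows[[r]] <- tibble::tibble(round = r, n_reads = nrow(round_reads),
                                    klass = call$klass)
    if (call$klass %in% c("quadripartite", "circular")) {
      return(structure(list(
        graph = graph, call = call, isomers = extract_isomers(graph, call),
        success = TRUE, rounds = dplyr::bind_rows(log_rows)
      ), class = "chloroplast_result"))
    }
    if (nrow(reads) <= config$reads_per_round) break # nothing new to sample
  }
  structure(list(graph = graph, call = call, isomers = NULL, success = FALSE,
                 rounds = dplyr::bind_rows(log_rows)),
            class = "chloroplast_result")
}

#' Mitochondrial assembly with chloroplast-read refinement
#'
#' Aligns mitochondrion-labeled reads to the chloroplast assembly graph and
#' removes those aligning almost end-to-end (misclassified chloroplast
#' reads), then applies the k-mer coverage filter with thresholds computed
#' freshly on the refined mitochondrial pool, and finally runs the assembler
#' once on all remaining reads (no subsampling).
#'
#' @param reads Mitochondrion-labeled reads.
#' @param chloro_graph The finished chloroplast [assembly_graph()].
#' @param config A [pipeline_config()].
#' @param assembler Function `f(reads) -> assembly_graph`.
#' @param graph_aligner Function `f(reads, graph) -> GAF tibble` (see
#'   [make_stub_graph_aligner()]).
#' @param gene_hits Optional gene-hit tibble for completeness scoring.
#' @return A list of class `mitochondrion_result`: `graph`, `completeness`
#'   (NULL without `gene_hits`), `reads` (final pool), `counts` (stage
#'   bookkeeping).
#' @export
assemble_mitochondrion <- function(reads, chloro_graph,
                                   config = pipeline_config(), assembler,
                                   graph_aligner, gene_hits = NULL) {
  if (!nrow(reads)) stop("no mitochondrial signal: empty read set")
  gaf <- graph_aligner(reads, chloro_graph)
  refined <- refine_mito_reads(reads, gaf, max_clip = config$max_clip,
                               min_identity = config$min_identity)
  mito <- dplyr::filter(refined, !.data$chloroplast_like)
  if (!nrow(mito)) stop("no mitochondrial signal: all reads chloroplast-like")
  filt <- kmer_filter_stage(mito, config)
  if (!nrow(filt$kept)) stop("no mitochondrial signal: all reads filtered")
  graph <- assembler(filt$kept)
  completeness <- if (!is.null(gene_hits)) assess_completeness(gene_hits) else NULL
  structure(list(
    graph = graph,
    completeness = completeness,
    reads = filt$kept,
    counts = tibble::tibble(
      stage = c("input", "refined", "kmer_filtered"),
      n_reads = c(nrow(reads), nrow(mito), nrow(filt$kept))
    )
  ), class = "mitochondrion_result")
}

#' Run the full organelle assembly pipeline
#'
#' Classify reads, coverage-filter the plastid pool, assemble the
#' chloroplast iteratively until its typical structure appears, then refine
#' and assemble the mitochondrial pool. Chloroplast-first ordering is
#' enforced: the mitochondrial coverage median is computed only after
#' chloroplast-read removal. Reads labeled neither plastid nor mitochondrion
#' are discarded at the branch point.
#'
#' @param reads Tibble of input reads.
#' @param config A [pipeline_config()].
#' @param adapters List of adapters: `classifier` (`f(reads) -> labeled
#'   reads`), `chloro_assembler`, `mito_assembler`, `graph_aligner`, and
#'   optionally `gene_hits`. See [stub_adapters()] for a fixture-backed set.
#' @param outdir Optional output directory; when given, writes
#'   `isomers.fasta`, `chloroplast.gfa`, `mitochondrion.gfa`,
#'   `completeness.tsv` and a `stages.json` log.
#' @return A list of class `pipeline_result` with elements `chloroplast`,
#'   `mitochondrion`, `stages` (per-stage read counts).
#' @export
run_organelle_pipeline <- function(reads, config = pipeline_config(),
                                   adapters, outdir = NULL) {
  needed <- c("classifier", "chloro_assembler", "mito_assembler", "graph_aligner")
  missing <- needed[!needed %in% names(adapters)]
  if (length(missing)) {
    stop("missing adapter(s): ", paste(missing, collapse = ", "))
  }
  labeled <- adapters$classifier(reads)
  plastid <- dplyr::filter(labeled, .data$label == "plastid")
  mito_pool <- dplyr::filter(labeled, .data$label == "mitochondrion")
  if (!nrow(plastid)) stop("no plastid-labeled reads")

  pfilt <- kmer_filter_stage(plastid, config)
  chloro <- assemble_chloroplast(pfilt$kept, config, adapters$chloro_assembler)
  mito <- assemble_mitochondrion(mito_pool, chloro$graph, config,
                                 adapters$mito_assembler,
                                 adapters$graph_aligner,
                                 gene_hits = adapters$gene_hits)
  stages <- tibble::tibble(
    stage = c("input", "plastid_labeled", "plastid_filtered",
              "mitochondrion_labeled", "mitochondrion_final"),
    n_reads = c(nrow(reads), nrow(plastid), nrow(pfilt$kept),
                nrow(mito_pool), nrow(mito$reads))
  )
  result <- structure(list(chloroplast = chloro, mitochondrion = mito,
                           stages = stages),
                      class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(result$chloroplast$isomers)) {
    iso <- result$chloroplast$isomers
    write_reads(tibble::tibble(id = names(iso), seq = unname(iso)),
                file.path(outdir, "isomers.fasta"))
  }
  write_gfa(result$chloroplast$graph, file.path(outdir, "chloroplast.gfa"))
  write_gfa(result$mitochondrion$graph, file.path(outdir, "mitochondrion.gfa"))
  comp <- result$mitochondrion$completeness
  if (!is.null(comp)) {
    utils::write.table(tidy(comp), file.path(outdir, "completeness.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(list(stages = result$stages,
                              rounds = result$chloroplast$rounds),
                         file.path(outdir, "stages.json"), auto_unbox = TRUE)
  }
  invisible(outdir)
}

#' Fixture-backed stub adapters
#'
#' Builds the full adapter set for [run_organelle_pipeline()] from synthetic
#' fixtures, with a programmable classifier confusion rate.
#'
#' @param chloro_fix A [make_quadripartite_genome()] fixture.
#' @param mito_fix A [make_mito_genome()] fixture.
#' @param confusion_error Classifier misclassification rate, default 0.05.
#' @param seed RNG seed for the stub classifier.
#' @return An adapter list.
#' @export
stub_adapters <- function(chloro_fix, mito_fix, confusion_error = 0.05,
                          seed = 1) {
  chloro_len <- nchar(chloro_fix$genome)
  mito_len <- sum(nchar(mito_fix$seqs$seq))
  mito_sources <- mito_fix$seqs$name
  list(
    classifier = function(reads) {
      stub_classifier(reads, default_confusion(confusion_error), seed = seed)
    },
    chloro_assembler = make_oracle_assembler(chloro_fix$graph, "chloroplast",
                                             chloro_len),
    mito_assembler = make_oracle_assembler(mito_fix$graph, mito_sources,
                                           mito_len, min_cov = 15),
    graph_aligner = make_stub_graph_aligner("chloroplast"),
    gene_hits = stub_gene_hits(mito_fix$genes)
  )
}

#' Default end-to-end synthetic fixture
#'
#' One call producing everything the stubbed pipeline needs: a 23 kb
#' quadripartite chloroplast, a 30 kb mitochondrion with a 5 kb small
#' circle, a nuclear sequence carrying planted organellar insertions, and a
#' HiFi-like read set with copy ratios chloroplast 50x, mitochondrion 20x,
#' nuclear 1x.
#'
#' @param seed RNG seed.
#' @param nuclear_len Nuclear sequence length, default 100000.
#' @param n_insertions Planted NUPT count, default 10.
#' @param coverage Base coverage per genome copy, default 1.
#' @return A list: `chloro`, `mito`, `insertions`, `genomes`, `reads`.
#' @export
make_pipeline_fixture <- function(seed = 42, nuclear_len = 100000,
                                  n_insertions = 10, coverage = 1) {
  set.seed(seed)
  chloro <- make_quadripartite_genome()
  mito <- make_mito_genome()
  ins <- plant_insertions(nuclear_len, chloro$genome, n = n_insertions,
                          identity_targets = 97)
  genomes <- tibble::tibble(
    name = c("chloroplast", "mito_main", "mito_small", "nuclear"),
    seq = c(chloro$genome, mito$seqs$seq, ins$nuclear_seq),
    circular = c(TRUE, TRUE, TRUE, FALSE),
    copy = c(50, 20, 20, 1),
    label = c("plastid", "mitochondrion", "mitochondrion", "nuclear")
  )
  reads <- simulate_reads(genomes, coverage = coverage)
  list(chloro = chloro, mito = mito, insertions = ins, genomes = genomes,
       reads = reads)
}
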