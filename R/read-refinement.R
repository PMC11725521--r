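#' Flag graph alignments as chloroplast-like
#'
#' An alignment of a mitochondrion-labeled read against the chloroplast
#' assembly graph marks the read as chloroplast-derived when it is almost
#' end-to-end: left clip `qstart <= max_clip`, right clip
#' `qlen - qend <= max_clip` (both inclusive), and identity
#' `matches / blocklen` strictly greater than `min_identity`.
#'
#' @param gaf Tibble of graph alignments from [read_gaf()].
#' @param max_clip Maximum clip length on either read end, default 100 bases.
#' @param min_identity Identity threshold (exclusive), default 0.95.
#' @return Logical vector, one element per alignment record.
#' @export
gaf_chloroplast_like <- function(gaf, max_clip = 100, min_identity = 0.95) {
  if (any(gaf$blocklen == 0)) {
    stop("malformed GAF record with blocklen 0: ",
         gaf$qname[which(gaf$blocklen == 0)[1]])
  }
  gaf$qstart <= max_clip &
    (gaf$qlen - gaf$qend) <= max_clip &
    gaf$matches / gaf$blocklen > min_identity
}

#' Remove chloroplast-derived reads from a mitochondrial read pool
#'
#' Reads misclassified as mitochondrial are purged using their alignments to
#' the chloroplast assembly graph: a read is removed when any of its
#' alignment records is chloroplast-like (see [gaf_chloroplast_like()]).
#' Reads without alignments are kept.
#'
#' @param reads Tibble of reads with an `id` column.
#' @param gaf Tibble of graph alignments of `reads` against the chloroplast
#'   assembly graph.
#' @param max_clip,min_identity Passed to [gaf_chloroplast_like()].
#' @return The input tibble with an added logical column `chloroplast_like`;
#'   rows with `chloroplast_like == FALSE` are the refined mitochondrial
#'   pool.
#' @export
refine_mito_reads <- function(reads, gaf, max_clip = 100, min_identity = 0.95) {
  removed_ids <- if (nrow(gaf)) {
    unique(gaf$qname[gaf_chloroplast_like(gaf, max_clip, min_identity)])
  } else {
    character()
  }
  dplyr::mutate(reads, chloroplast_like = .data$id %in% removed_ids)
}
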