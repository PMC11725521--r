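#' The default panel of 41 conserved mitochondrial protein-coding genes
#'
#' Plant mitochondrial genomes are too structurally diverse for graph-based
#' completeness checks, so completeness is scored on the presence of a panel
#' of conserved protein-coding genes (ATP synthase, cytochrome c maturation
#' and oxidase, NADH dehydrogenase, ribosomal proteins and succinate
#' dehydrogenase subunits).
#'
#' @return Character vector of 41 gene names.
#' @export
mito_gene_panel <- function() {
  c(
    "atp1", "atp4", "atp6", "atp8", "atp9",
    "ccmB", "ccmC", "ccmFC", "ccmFN",
    "cob",
    "cox1", "cox2", "cox3",
    "matR", "mttB",
    "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6", "nad7", "nad9",
    "rpl2", "rpl5", "rpl10", "rpl16",
    "rps1", "rps2", "rps3", "rps4", "rps7", "rps10", "rps11", "rps12",
    "rps13", "rps14", "rps19",
    "sdh3", "sdh4"
  )
}

#' Score assembly completeness from gene hits
#'
#' A gene is present when it has at least one hit with
#' `evalue <= evalue_threshold`; copy number and orientation are ignored
#' (assembly graphs collapse long repeats into single nodes, so counting
#' copies would be misleading). Hits naming genes outside the panel are
#' skipped with a warning.
#'
#' @param hits Tibble of translated-search hits with columns `gene` and
#'   `evalue` (a BLAST-6 tibble is accepted; the subject id is used as the
#'   gene name).
#' @param panel Character vector of panel gene names, default
#'   [mito_gene_panel()].
#' @param evalue_threshold Inclusive e-value cutoff, default 1e-3.
#' @return A list of class `completeness_report` with elements `present`,
#'   `absent`, `n_present`, `panel_size`.
#' @export
assess_completeness <- function(hits, panel = mito_gene_panel(),
                                evalue_threshold = 1e-3) {
  if (!length(panel)) stop("empty gene panel")
  stopifnot(!anyDuplicated(panel))
  if (!"gene" %in% names(hits) && "sseqid" %in% names(hits)) {
    hits <- dplyr::rename(hits, gene = "sseqid")
  }
  unknown <- setdiff(unique(hits$gene), panel)
  if (length(unknown)) {
    warning("skipping hits to genes outside the panel: ",
            paste(unknown, collapse = ", "))
    hits <- hits[hits$gene %in% panel, , drop = FALSE]
  }
  present <- sort(unique(hits$gene[hits$evalue <= evalue_threshold]))
  structure(
    list(
      present = present,
      absent = setdiff(panel, present),
      n_present = length(present),
      panel_size = length(panel)
    ),
    class = "completeness_report"
  )
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("<completeness_report> %d/%d panel genes present\n",
              x$n_present, x$panel_size))
  invisible(x)
}
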