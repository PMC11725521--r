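#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a completeness report into one row per panel gene
#'
#' @param x A `completeness_report`.
#' @param ... Unused.
#' @return Tibble with columns `gene`, `present`.
#' @export
tidy.completeness_report <- function(x, ...) {
  genes <- c(x$present, x$absent)
  tibble::tibble(gene = genes, present = genes %in% x$present) |>
    dplyr::arrange(.data$gene)
}

#' One-row summary of a completeness report
#'
#' @param x A `completeness_report`.
#' @param ... Unused.
#' @export
glance.completeness_report <- function(x, ...) {
  tibble::tibble(
    n_present = x$n_present,
    panel_size = x$panel_size,
    fraction = x$n_present / x$panel_size
  )
}

#' Tidy a substitution spectrum into one row per class
#'
#' @param x A `spectrum_table`.
#' @param ... Unused.
#' @export
tidy.spectrum_table <- function(x, ...) x$classes

#' One-row summary of a substitution spectrum
#'
#' Reports the total substitution count, the C:G>T:A fraction, and the
#' CG-to-CHH rate ratio when per-context denominators are available.
#'
#' @param x A `spectrum_table`.
#' @param ... Unused.
#' @export
glance.spectrum_table <- function(x, ...) {
  cgta <- x$classes$fraction[x$classes$class == "C:G>T:A"]
  rates <- stats::setNames(x$contexts$rate, x$contexts$context)
  tibble::tibble(
    n = x$n,
    frac_cg_ta = cgta,
    rate_cg = rates[["CG"]],
    rate_chg = rates[["CHG"]],
    rate_chh = rates[["CHH"]],
    cg_chh_ratio = rates[["CG"]] / rates[["CHH"]]
  )
}

#' Tidy an enrichment result into a single row
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(
    observed_overlap = x$observed_overlap,
    null_mean = x$null_mean,
    fold = x$fold,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    p_empirical = x$p_empirical,
    n_samples = x$n_samples
  )
}

#' @rdname tidy.enrichment_result
#' @export
glance.enrichment_result <- tidy.enrichment_result

#' Tidy a topology call into a single row
#'
#' @param x A `topology_call`.
#' @param ... Unused.
#' @export
tidy.topology_call <- function(x, ...) {
  tibble::tibble(
    klass = x$klass, lsc_id = x$lsc_id, ssc_id = x$ssc_id,
    ir_id = x$ir_id, circle_id = x$circle_id
  )
}

#' Tidy an insertion summary into the per-species table
#'
#' @param x An `insertion_summary`.
#' @param ... Unused.
#' @export
tidy.insertion_summary <- function(x, ...) x$species

#' Correlation summary of an insertion summary
#'
#' @param x An `insertion_summary`.
#' @param ... Unused.
#' @export
glance.insertion_summary <- function(x, ...) x$correlations

#' Bar chart of a substitution spectrum
#'
#' @param object A `spectrum_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrum_table <- function(object, ...) {
  ggplot2::ggplot(object$classes,
                  ggplot2::aes(x = .data$class, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "Fraction of substitutions") +
    ggplot2::theme_minimal()
}

#' Null distribution plot for an enrichment test
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot with the null overlap histogram and the observed value.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(overlap = object$null_overlaps),
                  ggplot2::aes(x = .data$overlap)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed_overlap,
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "Null overlap (bases)", y = "Permutations") +
    ggplot2::theme_minimal()
}

#' Presence/absence tile plot of a completeness report
#'
#' @param object A `completeness_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.completeness_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = 1,
                                   fill = .data$present)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "#d95f0e")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Present") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5),
                   axis.text.y = ggplot2::element_blank())
}

#' Identity histogram of merged insertions
#'
#' Cumulative insertion length per 1-point identity bin, by source.
#'
#' @param object An `insertion_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.insertion_summary <- function(object, ...) {
  ggplot2::ggplot(object$identity_hist,
                  ggplot2::aes(x = .data$bin, y = .data$total_length)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~source, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Identity bin (%)", y = "Cumulative length (bp)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
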