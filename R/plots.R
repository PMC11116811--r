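# Plot helpers. Figures mirror the QC and validation views practitioners
# expect: TIN by marker module (degradation structure), per-sample class
# probabilities (call confidence), and the predicted-vs-benchmark
# contingency table.

#' TIN distribution per gene module
#'
#' Box plot of TIN scores grouped by marker module, the standard view of
#' module-specific degradation (immune transcripts degrade hardest in FFPE
#' tissue).
#'
#' @param tin Wide gene-by-sample TIN tibble.
#' @param gene_modules Tibble `gene_id`, `module`.
#' @return A ggplot object.
#' @export
plot_module_tin <- function(tin, gene_modules) {
  long <- tidyr::pivot_longer(tin, -1, names_to = "sample_id",
                              values_to = "tin")
  names(long)[1] <- "gene_id"
  long <- dplyr::inner_join(long, gene_modules, by = "gene_id")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$module, y = .data$tin)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "TIN") +
    ggplot2::theme_minimal()
}

#' Per-sample subtype probability profile
#'
#' Stacked bars of the four class probabilities per sample, ordered by call.
#'
#' @param calls A `cms_calls` tibble.
#' @return A ggplot object.
#' @export
plot_cms_probabilities <- function(calls) {
  x <- as_tibble(calls)
  x$sample_id <- factor(x$sample_id, levels = x$sample_id[order(x$cms)])
  long <- tidyr::pivot_longer(x, dplyr::starts_with("p_"),
                              names_to = "class", values_to = "probability")
  long$class <- sub("^p_", "", long$class)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                     y = .data$probability,
                                     fill = .data$class)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "tree-vote probability", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
autoplot.cms_calls <- function(object, ...) plot_cms_probabilities(object)

#' @export
autoplot.cms_contingency <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$benchmark, y = .data$predicted,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "benchmark CMS", y = "predicted CMS") +
    ggplot2::theme_minimal()
}
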