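#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot verdict categories per protein
#'
#' Bar chart of variant counts by final category, faceted by protein.
#'
#' @param object a `phos_verdicts` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.phos_verdicts <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$category <- factor(df$category,
                        levels = c("abolishing", "abolishing_and_creating",
                                   "creating", "rescued", "none"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(~protein_id) +
    ggplot2::labs(x = "category", y = "distinct variants") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the stratified altering fractions
#'
#' @param object a `phos_summary`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.phos_summary <- function(object, ...) {
  df <- object$per_protein
  ggplot2::ggplot(df, ggplot2::aes(x = .data$protein, y = .data$pct_altering)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d/%d", .data$n_altering, .data$n_analyzed)),
      vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% variants altering phosphorylation") +
    ggplot2::theme_minimal()
}

#' Plot per-column conservation of an alignment
#'
#' Information content per column with the reliability window shaded.
#'
#' @param msa a `phos_msa`.
#' @param config a [pipeline_config()].
#' @return A ggplot object.
#' @export
plot_conservation <- function(msa, config = pipeline_config()) {
  med <- median_conservation(msa, config)
  df <- tibble::tibble(column = seq_along(med$per_column),
                       information = med$per_column)
  rng <- config$median_conservation_range
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$information)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = rng[1], ymax = rng[2], alpha = 0.15) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = med$score, linetype = 2) +
    ggplot2::labs(y = "column information (bits)") +
    ggplot2::theme_minimal()
}
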