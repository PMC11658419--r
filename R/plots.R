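#' Nuclear volume histogram
#'
#' Frequency distribution of nuclear volumes — the bimodal structure
#' (fibroblast-like mode near 500 \eqn{\mu m^3}, tumor-like near 1200
#' \eqn{\mu m^3}) is the morphological basis of cell-type discrimination in
#' co-cultures.
#'
#' @param records Cell table or truth table with a `volume_um3` column;
#'   an optional `type` or `cell_type` column colours the populations.
#' @param binwidth Histogram bin width in \eqn{\mu m^3}.
#' @return A ggplot object.
#' @export
plot_volume_histogram <- function(records, binwidth = 100) {
  type_col <- intersect(c("cell_type", "type"), names(records))[1]
  p <- ggplot2::ggplot(records, ggplot2::aes(x = .data$volume_um3))
  p <- if (!is.na(type_col))
    p + ggplot2::geom_histogram(ggplot2::aes(fill = .data[[type_col]]),
                                binwidth = binwidth, alpha = 0.7,
                                position = "identity")
  else p + ggplot2::geom_histogram(binwidth = binwidth)
  p + ggplot2::labs(x = expression("nuclear volume (" * mu * m^3 * ")"),
                    y = "nuclei") +
    ggplot2::theme_minimal()
}

#' Shell marker-distribution bars
#'
#' Stacked-bar view of the per-shell percentage distribution of
#' marker-positive cells (columns `pct_*` of a [shell_statistics()] table).
#'
#' @param shell_table Output of [shell_statistics()].
#' @return A ggplot object.
#' @export
plot_shell_distribution <- function(shell_table) {
  pct <- grep("^pct_", names(shell_table), value = TRUE)
  assert_that(length(pct) > 0, "shell table has no pct_* marker columns")
  long <- tidyr::pivot_longer(shell_table, dplyr::all_of(pct),
                              names_to = "marker", values_to = "pct")
  long$marker <- sub("^pct_", "", long$marker)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$marker, y = .data$pct,
                                     fill = .data$shell)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "% of marker-positive cells") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.shell_partition <- function(object, ...) {
  ggplot2::ggplot(object$fractions,
                  ggplot2::aes(x = .data$shell,
                               y = .data$achieved_fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$fractions$target_fraction[1],
                        linetype = "dashed") +
    ggplot2::labs(y = "volume fraction", x = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.condition_table <- function(object, subtract_reference = FALSE, ...) {
  z <- condition_zscores(object, subtract_reference)
  num <- setdiff(names(z)[vapply(z, is.numeric, logical(1))], "condition")
  long <- tidyr::pivot_longer(z, dplyr::all_of(num),
                              names_to = "metric", values_to = "zscore")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$condition,
                                     fill = .data$zscore)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "grey95",
                                  high = "darkred") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
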