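#' Plot normalized coverage of candidate markers per individual
#'
#' One point per marker x individual, faceted or coloured by a grouping
#' of individuals (typically phenotype or inferred karyotype), with
#' reference lines at 1.0 (diploid expectation) and 0.5 (hemizygous
#' expectation).
#'
#' @param cov A `rad_normcov` from [normalize_depths()].
#' @param markers Marker ids to display.
#' @param groups Optional named character vector mapping individual id
#'   to a group label.
#' @return A ggplot object.
#' @export
plot_marker_coverage <- function(cov, markers, groups = NULL) {
  df <- cov |> dplyr::filter(.data$marker_id %in% markers)
  df$group <- if (is.null(groups)) "all" else groups[df$individual_id]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$individual_id, y = .data$value, colour = .data$group
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(0.5, 1), linetype = "dotted") +
    ggplot2::facet_wrap(ggplot2::vars(.data$marker_id)) +
    ggplot2::labs(x = NULL, y = "normalized coverage", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Scatter plot of two W-specific markers' coverage in hermaphrodites
#'
#' The classic two-marker view separating monogenic (WW, coverage near
#' 1, 1) from amphigenic (ZW, near 0.5, 0.5) hermaphrodites.
#'
#' @param cov A `rad_normcov`.
#' @param w_markers Exactly two W-specific marker ids.
#' @param hermaphrodites Individual ids to display.
#' @return A ggplot object.
#' @export
plot_hermaphrodite_coverage <- function(cov, w_markers, hermaphrodites) {
  stopifnot(length(w_markers) == 2L)
  df <- cov |>
    dplyr::filter(.data$marker_id %in% w_markers,
                  .data$individual_id %in% hermaphrodites) |>
    tidyr::pivot_wider(names_from = "marker_id", values_from = "value")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[w_markers[1]]], y = .data[[w_markers[2]]]
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(0.5, 1), linetype = "dotted") +
    ggplot2::geom_vline(xintercept = c(0.5, 1), linetype = "dotted") +
    ggplot2::labs(
      x = paste(w_markers[1], "normalized coverage"),
      y = paste(w_markers[2], "normalized coverage")
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.zw_herm_class <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$individual_id, .data$mean_w_coverage),
    y = .data$mean_w_coverage, colour = .data$karyotype_call
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = c(0.5, 1), linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "mean W-specific normalized coverage",
                  colour = "karyotype call") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @exportS3Method ggplot2::autoplot
autoplot.rad_ld <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(bins = 20, boundary = 0) +
    ggplot2::geom_vline(xintercept = attr(object, "alpha"),
                        linetype = "dashed") +
    ggplot2::labs(x = "permutation p-value", y = "marker pairs") +
    ggplot2::theme_minimal()
}
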