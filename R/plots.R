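#' Trans-count histogram with the noise threshold
#'
#' Shows the bimodal per-fragment trans-count distribution (log10 scale) and
#' the derived noise threshold separating stochastic-noise fragments from
#' genuinely interacting ones.
#'
#' @param background a `chic_background` from [fit_background()], or an
#'   interactability profile tibble plus an explicit `threshold`.
#' @param threshold count threshold drawn as a vertical line (taken from the
#'   background object when omitted).
#' @param bins histogram bins.
#' @return a ggplot object.
#' @export
plot_trans_counts <- function(background, threshold = NULL, bins = 60) {
  if (inherits(background, "chic_background")) {
    profile <- background$profile
    threshold <- threshold %||% background$threshold
  } else {
    profile <- background
  }
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$trans_count + 1)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "trans di-tags per fragment (+1)", y = "fragments")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, colour = "firebrick",
                                 linetype = 2)
  }
  p
}

#' Heatmap of the cross-experiment enrichment grid
#'
#' @param object a `chic_enrichment` tibble from [enrichment_grid()].
#' @param ... ignored.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.chic_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$j), y = factor(.data$i),
                                       fill = .data$x)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$x)),
                       colour = "white") +
    ggplot2::labs(x = "promoter capture FDR (j)", y = "region capture FDR (i)",
                  fill = "X[i,j]")
}

#' Distance decay of observed pair counts
#'
#' Median observed count in log-spaced distance bins, against the fitted
#' background expectation if a model is given.
#'
#' @param pairs combined pair counts.
#' @param bins number of log-spaced distance bins.
#' @return a ggplot object.
#' @export
plot_distance_decay <- function(pairs, bins = 25) {
  df <- pairs |>
    dplyr::filter(!is.na(.data$distance)) |>
    dplyr::mutate(bin = cut(log10(.data$distance), bins)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(distance = exp(mean(log(.data$distance))),
                     count = stats::median(.data$count), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance (bp)", y = "median di-tag count")
}
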