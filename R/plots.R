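#' Plot ranked candidate edge scores
#'
#' Rank plot of normalized MNN scores over all node pairs, with the
#' candidacy threshold drawn as a horizontal line.
#'
#' @param candidates An `edge_candidates` object.
#' @param threshold Score threshold to draw (default 1).
#' @return A ggplot.
#' @export
plot_edge_scores <- function(candidates, threshold = 1) {
  stopifnot(inherits(candidates, "edge_candidates"))
  df <- dplyr::mutate(candidates$edges, rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                   y = .data$normalized_score,
                                   colour = .data$candidate)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = "edge rank", y = "normalized MNN score",
                  colour = "candidate") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.edge_candidates <- function(object, ...) plot_edge_scores(object, ...)

#' Plot an edge's time profile
#'
#' @param profile Tibble from [edge_time_profile()].
#' @return A ggplot of percent inter-node MNN cells per time bin.
#' @export
plot_time_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$bin, y = .data$pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time bin (embryonic day)",
                  y = "% inter-node MNN cells") +
    ggplot2::theme_minimal()
}

#' Plot timepoint purity values
#'
#' @param purity Tibble from [timepoint_purity()].
#' @return A ggplot; a dip at the final timepoint marks an abrupt shift.
#' @export
plot_purity <- function(purity) {
  ggplot2::ggplot(purity, ggplot2::aes(x = .data$timepoint, y = .data$purity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "timepoint (embryonic day)",
                  y = "mean proportion of neighbors from other timepoints") +
    ggplot2::theme_minimal()
}

#' Plot a growth model curve
#'
#' @param object A `growth_model`.
#' @param days Days to evaluate (default: 100 points over the fitted range,
#'   or E8.5 to E19.5).
#' @param ... Unused.
#' @return A ggplot of predicted cell number (log10 y-axis) versus day.
#' @exportS3Method ggplot2::autoplot
autoplot.growth_model <- function(object, days = NULL, ...) {
  if (is.null(days)) {
    rng <- if (is.null(object$day_range)) c(8.5, 19.5) else object$day_range
    days <- seq(rng[1], rng[2], length.out = 100)
  }
  df <- tibble::tibble(day = days, cells = predict_cells(object, days))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$cells)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "embryonic day", y = "predicted cell number") +
    ggplot2::theme_minimal()
}

#' Plot progenitor mapping fractions
#'
#' @param object A `progenitor_map`.
#' @param ... Unused.
#' @return A ggplot tile map of derivative-by-territory MNN fractions.
#' @exportS3Method ggplot2::autoplot
autoplot.progenitor_map <- function(object, ...) {
  ggplot2::ggplot(object$distribution,
                  ggplot2::aes(x = .data$territory, y = .data$derivative,
                               fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "progenitor territory", y = "derivative type",
                  fill = "MNN fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
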