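#' Cubic growth model of whole-embryo cell number
#'
#' Constructs a degree-3 polynomial model of log2 cell number versus
#' embryonic day, `log2(N) = a0 + a1*day + a2*day^2 + a3*day^3`.
#' Usually produced by [fit_growth()]; construct directly to evaluate a known
#' coefficient set.
#'
#' @param coefficients Length-4 numeric `(intercept, day, day^2, day^3)`.
#' @param adj_r_squared Optional adjusted R-squared of the originating fit.
#' @param day_range Optional fitted day range; predictions outside it warn.
#' @return A `growth_model` object.
#' @export
growth_model <- function(coefficients, adj_r_squared = NA_real_,
                         day_range = NULL) {
  coefficients <- as.numeric(coefficients)
  stopifnot(length(coefficients) == 4, all(is.finite(coefficients)))
  names(coefficients) <- c("intercept", "day", "day^2", "day^3")
  structure(list(coefficients = coefficients, adj_r_squared = adj_r_squared,
                 day_range = day_range),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "<growth_model> log2(N) = %.6f + %.6f d + %.6f d^2 + %.6f d^3\n",
    cf[1], cf[2], cf[3], cf[4]))
  if (!is.na(x$adj_r_squared)) {
    cat(sprintf("  adj R^2 = %.4f\n", x$adj_r_squared))
  }
  invisible(x)
}

#' Fit the cubic growth model
#'
#' Ordinary least squares of log2 cell number on a cubic polynomial of
#' embryonic day. By convention the day of birth (P0) is encoded as E19.5 by
#' the caller.
#'
#' @param days Numeric embryonic days (>= 5 points required).
#' @param cell_counts Positive cell counts, same length.
#' @return A `growth_model` with `adj_r_squared` and `day_range` filled in.
#' @export
fit_growth <- function(days, cell_counts) {
  stopifnot(length(days) == length(cell_counts))
  if (length(days) < 5) stop("fit_growth needs at least 5 points")
  if (any(cell_counts <= 0)) stop("cell counts must be positive")
  l2 <- log2(cell_counts)
  fit <- stats::lm(l2 ~ days + I(days^2) + I(days^3))
  adj <- suppressWarnings(summary(fit)$adj.r.squared)
  growth_model(stats::coef(fit), adj_r_squared = adj,
               day_range = range(days))
}

poly_eval <- function(cf, day) cf[1] + cf[2] * day + cf[3] * day^2 + cf[4] * day^3

#' Predict whole-embryo cell number
#'
#' Evaluates the cubic log2 growth polynomial and exponentiates:
#' `N = 2^(a0 + a1 d + a2 d^2 + a3 d^3)`.
#'
#' @param model A `growth_model`.
#' @param day Embryonic day(s); values outside the fitted range warn.
#' @return Predicted cell count(s).
#' @export
predict_cells <- function(model, day) {
  stopifnot(inherits(model, "growth_model"))
  if (!is.null(model$day_range) &&
      any(day < model$day_range[1] | day > model$day_range[2])) {
    warning("prediction outside the fitted day range (extrapolation)")
  }
  unname(2^poly_eval(model$coefficients, day))
}

#' Cell-number doubling time
#'
#' The derivative of the log2 growth polynomial is the log2-scaled
#' proliferation rate `p(day) = a1 + 2 a2 day + 3 a3 day^2` (doublings per
#' day); the doubling time in hours is `24 * 2 / 2^p(day)`. Where
#' `p(day) <= 0` (no net growth) the doubling time is undefined and `NA` is
#' returned.
#'
#' @param model A `growth_model`.
#' @param day Embryonic day(s).
#' @return Doubling time(s) in hours.
#' @export
doubling_time <- function(model, day) {
  stopifnot(inherits(model, "growth_model"))
  cf <- model$coefficients
  p <- cf[2] + 2 * cf[3] * day + 3 * cf[4] * day^2
  out <- ifelse(p > 0, 24 * 2 / 2^p, NA_real_)
  unname(out)
}

#' @exportS3Method generics::tidy
tidy.growth_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @exportS3Method generics::glance
glance.growth_model <- function(x, ...) {
  tibble::tibble(adj.r.squared = x$adj_r_squared,
                 day_min = if (is.null(x$day_range)) NA_real_ else x$day_range[1],
                 day_max = if (is.null(x$day_range)) NA_real_ else x$day_range[2])
}

#' Timepoint purity of a cell type
#'
#' Quantifies how transcriptionally mixed a cell type is across timepoints.
#' Eligible types (>= `min_cells` at the final timepoint and at >=
#' `min_pre_final_timepoints` earlier timepoints) are processed as follows:
#' timepoints with >= `min_cells` are selected, each is downsampled to the
#' median selected size, cells are embedded by PCA (top `n_hvg` HVGs, `d`
#' components), and each cell's k nearest neighbors are found with
#' `k = round(log2(median size))` (minimum 2). The statistic per timepoint is
#' the mean proportion of neighbors drawn from a *different* timepoint: a low
#' value flags an abrupt transcriptional shift at that timepoint.
#'
#' @param table A [cell_table] (already restricted to one cell type, or use
#'   `cell_type` to filter on `type_label`).
#' @param cell_type Optional type label to filter on.
#' @param min_cells Minimum cells per usable timepoint (default 200).
#' @param min_pre_final_timepoints Minimum earlier timepoints required
#'   (default 5).
#' @param final_timepoint Timepoint treated as "final" (default: the maximum
#'   in the table).
#' @param n_hvg,d Embedding parameters (defaults 2,500 and 30).
#' @param seed Seed for the downsampling.
#' @return Tibble `(timepoint, n_cells, purity)` with attributes `k` and
#'   `eligible`; when the type is ineligible, a zero-row tibble whose
#'   `reason` attribute explains why.
#' @export
timepoint_purity <- function(table, cell_type = NULL, min_cells = 200,
                             min_pre_final_timepoints = 5,
                             final_timepoint = NULL,
                             n_hvg = 2500, d = 30, seed = 0L) {
  stopifnot(inherits(table, "cell_table"))
  if (!is.null(cell_type)) {
    table <- filter_cells(table, table$cell_meta$type_label == cell_type)
  }
  tp <- table$cell_meta$timepoint
  if (is.null(final_timepoint)) final_timepoint <- max(tp)
  sizes <- table(tp)
  ok_tp <- as.numeric(names(sizes))[sizes >= min_cells]
  ineligible <- function(reason) {
    out <- tibble::tibble(timepoint = numeric(), n_cells = integer(),
                          purity = numeric())
    attr(out, "eligible") <- FALSE
    attr(out, "reason") <- reason
    out
  }
  if (!final_timepoint %in% ok_tp) {
    return(ineligible(sprintf("fewer than %d cells at the final timepoint",
                              min_cells)))
  }
  if (sum(ok_tp < final_timepoint) < min_pre_final_timepoints) {
    return(ineligible(sprintf(
      "fewer than %d pre-final timepoints with >= %d cells",
      min_pre_final_timepoints, min_cells)))
  }
  med <- as.integer(round(stats::median(sizes[as.character(ok_tp)])))
  keep <- with_seed(seed, {
    unlist(lapply(ok_tp, function(t) {
      cand <- which(tp == t)
      if (length(cand) > med) sample(cand, med) else cand
    }))
  })
  keep <- sort(keep)
  sub <- filter_cells(table, keep)
  emb <- embed_cells(sub, n_hvg = n_hvg, d = d)
  k <- max(2L, as.integer(round(log2(med))))
  nn <- knn_graph(emb, k)
  t_sub <- sub$cell_meta$timepoint
  other <- rowMeans(matrix(t_sub[nn$idx] != rep(t_sub, nn$k), nrow = nn$n))
  out <- tibble::tibble(timepoint = t_sub, frac_other = other) |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     purity = mean(.data$frac_other), .groups = "drop")
  attr(out, "k") <- k
  attr(out, "eligible") <- TRUE
  out
}

#' Timepoint correlation of neighbor times
#'
#' For each group of cells, computes the Pearson correlation between each
#' cell's timepoint and the mean timepoint of its k nearest neighbors in the
#' *global* embedding. High correlations indicate rapid, synchronized
#' transcriptional change along the time axis.
#'
#' @param embedding A `cell_embedding` or coordinate matrix over all cells.
#' @param times Numeric timepoint per cell (duplicated values permitted).
#' @param groups Group label per cell (e.g. major cell cluster).
#' @param k Neighborhood size (default 10).
#' @return Tibble `(group, n, r)`; `r` is `NA` for groups with fewer than
#'   `k + 1` cells or zero time variance.
#' @export
timepoint_correlation <- function(embedding, times, groups, k = 10) {
  coords <- if (inherits(embedding, "cell_embedding")) embedding$coords else embedding
  n <- nrow(coords)
  stopifnot(length(times) == n, length(groups) == n)
  nn <- knn_graph(coords, k)
  nb_mean <- rowMeans(matrix(times[nn$idx], nrow = n))
  tibble::tibble(group = groups, t = times, nb = nb_mean) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      r = if (dplyr::n() < k + 1 || stats::sd(.data$t) == 0 ||
              stats::sd(.data$nb) == 0) NA_real_
          else stats::cor(.data$t, .data$nb),
      .groups = "drop")
}
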