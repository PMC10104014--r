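#' Correlate features with principal components
#'
#' Pearson correlation of each feature (typically the scaled log-normalized
#' expression of highly variable genes, or a covariate such as somite count)
#' with the requested principal components. A feature is flagged significant
#' for a PC when its correlation lies beyond one standard deviation of the
#' mean of all correlations for that PC *and* its Benjamini-Hochberg
#' adjusted p-value is below `alpha`. Constant features have undefined
#' correlations and are excluded.
#'
#' @param embedding A `cell_embedding` (or coordinate matrix with `PC`
#'   columns).
#' @param features Matrix (cells x features, with colnames) or a single
#'   named numeric vector.
#' @param pcs Integer vector of components (default 1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Tibble `(pc, feature, r, p, adj_p, significant, sign)`; the
#'   significance flag is a deterministic function of the r vector.
#' @export
pc_feature_correlation <- function(embedding, features, pcs = 1,
                                   alpha = 0.05) {
  coords <- if (inherits(embedding, "cell_embedding")) embedding$coords else embedding
  if (is.null(dim(features))) {
    nm <- deparse(substitute(features))
    features <- matrix(features, ncol = 1, dimnames = list(NULL, nm))
  }
  features <- as.matrix(features)
  stopifnot(nrow(features) == nrow(coords), max(pcs) <= ncol(coords))
  n <- nrow(features)
  sds <- apply(features, 2, stats::sd)
  if (any(sds == 0)) features <- features[, sds > 0, drop = FALSE]
  purrr::map_dfr(pcs, function(pc) {
    r <- suppressWarnings(as.vector(stats::cor(features, coords[, pc])))
    tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[abs(r) >= 1] <- 0
    adj_p <- stats::p.adjust(p, method = "BH")
    mu <- mean(r); sdr <- stats::sd(r)
    tibble::tibble(pc = pc, feature = colnames(features), r = r, p = p,
                   adj_p = adj_p,
                   significant = (r < mu - sdr | r > mu + sdr) & adj_p < alpha,
                   sign = as.integer(sign(r)))
  })
}

as_signed_list <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("gene", "sign") %in% names(x)))
    stats::setNames(sign(x$sign), x$gene)
  } else {
    stats::setNames(sign(x), names(x))
  }
}

#' Sign concordance between two gene lists
#'
#' Computes the overlap between two signed gene lists, the fraction with
#' matching signs, and a one-cell chi-squared goodness-of-fit test of the
#' concordant count against `null_fraction * n_overlap`.
#'
#' @param list_a,list_b Tibbles with `gene` and `sign` columns (or named
#'   sign vectors).
#' @param null_fraction Expected concordant fraction under the null
#'   (default 0.5 for two independent signed lists).
#' @return One-row tibble `(n_overlap, n_concordant, concordant_fraction,
#'   chi2_statistic, p, null_fraction)`; statistics are `NA` (with a
#'   message) for an empty overlap.
#' @export
concordance_test <- function(list_a, list_b, null_fraction = 0.5) {
  stopifnot(null_fraction > 0, null_fraction < 1)
  a <- as_signed_list(list_a)
  b <- as_signed_list(list_b)
  shared <- intersect(names(a), names(b))
  n <- length(shared)
  if (n == 0) {
    message("empty overlap; concordance undefined")
    return(tibble::tibble(n_overlap = 0L, n_concordant = 0L,
                          concordant_fraction = NA_real_,
                          chi2_statistic = NA_real_, p = NA_real_,
                          null_fraction = null_fraction))
  }
  k <- sum(a[shared] == b[shared])
  ct <- suppressWarnings(stats::chisq.test(
    c(k, n - k), p = c(null_fraction, 1 - null_fraction)))
  tibble::tibble(n_overlap = n, n_concordant = as.integer(k),
                 concordant_fraction = k / n,
                 chi2_statistic = unname(ct$statistic),
                 p = unname(ct$p.value),
                 null_fraction = null_fraction)
}

#' Replication of concordant genes in an independent dataset
#'
#' A discovery gene replicates when its direction of change matches the
#' discovery sign in *both* replication contexts (e.g. early-versus-late
#' differences measured separately in two tissues). The expected replication
#' fraction under an independence null of two random signs is 0.25.
#'
#' @param discovery Tibble `(gene, sign)` of the discovery concordant set.
#' @param replication Tibble `(gene, context, diff)`: per-gene
#'   mean-expression differences in exactly two contexts.
#' @param expected_fraction Null fraction (default 0.25).
#' @return One-row tibble `(n_discovery, n_tested, n_missing, n_replicating,
#'   fraction, expected_fraction, chi2_statistic, p)`.
#' @export
replication_check <- function(discovery, replication,
                              expected_fraction = 0.25) {
  discovery <- tibble::as_tibble(discovery)
  replication <- tibble::as_tibble(replication)
  stopifnot(all(c("gene", "sign") %in% names(discovery)),
            all(c("gene", "context", "diff") %in% names(replication)))
  contexts <- unique(replication$context)
  if (length(contexts) != 2) stop("replication table needs exactly 2 contexts")
  wide <- tidyr::pivot_wider(replication, names_from = "context",
                             values_from = "diff")
  merged <- dplyr::inner_join(discovery, wide, by = "gene")
  merged <- merged[stats::complete.cases(merged), ]
  n_missing <- nrow(discovery) - nrow(merged)
  rep_ok <- sign(merged[[contexts[1]]]) == sign(merged$sign) &
    sign(merged[[contexts[2]]]) == sign(merged$sign)
  n <- nrow(merged); k <- sum(rep_ok)
  ct <- if (n > 0) {
    suppressWarnings(stats::chisq.test(
      c(k, n - k), p = c(expected_fraction, 1 - expected_fraction)))
  } else NULL
  tibble::tibble(n_discovery = nrow(discovery), n_tested = n,
                 n_missing = n_missing, n_replicating = as.integer(k),
                 fraction = if (n > 0) k / n else NA_real_,
                 expected_fraction = expected_fraction,
                 chi2_statistic = if (n > 0) unname(ct$statistic) else NA_real_,
                 p = if (n > 0) unname(ct$p.value) else NA_real_)
}
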