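#' Library-size normalize and log-transform UMI counts
#'
#' Scales every cell's counts to a common total and applies `log(1 + x)`.
#' Entry (c, g) becomes `ln(1 + count * scale_target / umi_total_c)`. The
#' sparsity pattern is preserved: zeros stay zero.
#'
#' @param x A [cell_table] or a sparse cell x gene count matrix.
#' @param scale_target Per-cell total after rescaling (default 10,000).
#' @return A sparse `dgCMatrix` of log-normalized expression, cells x genes.
#' @export
normalize_log <- function(x, scale_target = 1e4) {
  counts <- if (inherits(x, "cell_table")) x$counts else x
  totals <- Matrix::rowSums(counts)
  if (any(totals <= 0)) {
    bad <- rownames(counts)[which(totals <= 0)]
    stop("cells with zero total counts cannot be normalized: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  norm <- Matrix::Diagonal(x = scale_target / totals) %*% counts
  norm <- methods::as(norm, "CsparseMatrix")
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  norm
}

# Per-gene (column) means and unbiased variances of a sparse matrix.
sparse_col_stats <- function(m) {
  n <- nrow(m)
  mu <- Matrix::colMeans(m)
  m2 <- m
  m2@x <- m2@x^2
  ex2 <- Matrix::colSums(m2) / n
  v <- (ex2 - mu^2) * n / max(1, n - 1)
  v[v < 0] <- 0
  list(mean = mu, var = v)
}

#' Select highly variable genes
#'
#' Ranks genes of a log-normalized matrix by variance (default) or by
#' dispersion (variance / mean) and returns the top `n`, descending, with
#' deterministic ties broken by gene id.
#'
#' @param norm_matrix Log-normalized sparse matrix (cells x genes) with gene
#'   colnames, e.g. from [normalize_log()].
#' @param n Number of genes to return; must not exceed the number of genes
#'   with nonzero variance.
#' @param flavor `"variance"` or `"dispersion"`.
#' @return Character vector of `n` gene ids, ordered by decreasing criterion.
#' @export
select_hvg <- function(norm_matrix, n, flavor = c("variance", "dispersion")) {
  flavor <- match.arg(flavor)
  st <- sparse_col_stats(norm_matrix)
  crit <- switch(flavor,
                 variance = st$var,
                 dispersion = ifelse(st$mean > 0, st$var / st$mean, 0))
  ids <- colnames(norm_matrix)
  keep <- st$var > 0
  if (n > sum(keep)) {
    stop(sprintf("requested %d HVGs but only %d genes have nonzero variance",
                 n, sum(keep)))
  }
  ord <- order(-crit[keep], ids[keep])
  ids[keep][ord][seq_len(n)]
}

#' Principal component embedding of a scaled expression matrix
#'
#' Centers and scales the selected genes to zero mean / unit variance, then
#' projects cells onto the top `d` principal axes. The sign of each component
#' is fixed so that its largest-magnitude gene loading is positive, making
#' downstream correlations reproducible.
#'
#' @param norm_matrix Log-normalized matrix (cells x genes).
#' @param genes Genes to use (e.g. from [select_hvg()]); default all.
#' @param d Number of components (default 30). Reduced with a warning when it
#'   exceeds the matrix rank.
#' @param scale Logical; scale genes to unit variance (default TRUE).
#' @return A `cell_embedding`: list with `coords` (cells x d), `d`, `hvg`,
#'   `center`, `scale`, `var_frac` (per-component variance fractions,
#'   non-increasing), `loadings`.
#' @export
pca_embed <- function(norm_matrix, genes = NULL, d = 30, scale = TRUE) {
  if (is.null(genes)) genes <- colnames(norm_matrix)
  x <- as.matrix(norm_matrix[, genes, drop = FALSE])
  ctr <- colMeans(x)
  sdv <- if (scale) apply(x, 2, stats::sd) else rep(1, ncol(x))
  sdv[sdv == 0] <- 1
  x <- sweep(sweep(x, 2, ctr, "-"), 2, sdv, "/")
  d_req <- d
  s <- svd(x, nu = 0, nv = min(d, ncol(x)))
  tol <- max(dim(x)) * max(s$d) * .Machine$double.eps
  rank <- sum(s$d > tol)
  if (d > rank) {
    warning(sprintf("d = %d exceeds rank %d; using %d components", d, rank, rank))
    d <- rank
  }
  v <- s$v[, seq_len(d), drop = FALSE]
  # sign convention: largest-|loading| gene positive per component
  for (j in seq_len(d)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  coords <- x %*% v
  rownames(coords) <- rownames(norm_matrix)
  colnames(coords) <- paste0("PC", seq_len(d))
  var_frac <- (s$d^2 / sum(s$d^2))[seq_len(d)]
  structure(list(coords = coords, d = d, d_requested = d_req, hvg = genes,
                 center = ctr, scale = sdv, var_frac = var_frac,
                 loadings = v),
            class = "cell_embedding")
}

#' @export
print.cell_embedding <- function(x, ...) {
  cat(sprintf("<cell_embedding> %d cells x %d PCs (%d HVGs; PC1 %.1f%% var)\n",
              nrow(x$coords), x$d, length(x$hvg), 100 * x$var_frac[1]))
  invisible(x)
}

#' One-call embedding recipe: normalize, HVG, scale, PCA
#'
#' The standard recipe used throughout the pipeline: total-count normalize and
#' log-transform, select the top highly variable genes, scale them to zero
#' mean / unit variance, and reduce by PCA.
#'
#' @param table A [cell_table].
#' @param n_hvg Number of highly variable genes (default 2,500; capped at the
#'   number of informative genes).
#' @param d Number of principal components (default 30).
#' @param scale_target Normalization total (default 10,000).
#' @param flavor HVG criterion, see [select_hvg()].
#' @param exclude_genes Genes to drop before HVG selection (e.g. sex
#'   chromosome genes).
#' @return A `cell_embedding`.
#' @export
embed_cells <- function(table, n_hvg = 2500, d = 30, scale_target = 1e4,
                        flavor = "variance", exclude_genes = NULL) {
  norm <- normalize_log(table, scale_target)
  if (!is.null(exclude_genes)) {
    norm <- norm[, setdiff(colnames(norm), exclude_genes), drop = FALSE]
  }
  st <- sparse_col_stats(norm)
  n_hvg <- min(n_hvg, sum(st$var > 0))
  hvg <- select_hvg(norm, n_hvg, flavor)
  pca_embed(norm, hvg, d = d)
}

# Exact Euclidean kNN of `query` rows against `ref` rows (compiled search).
# Returns list(idx, dist): n_query x k matrices, distances ascending, ties
# broken by ascending ref index. When the i-th query equals the i-th ref
# (same row set), pass self = TRUE to drop self-matches.
knn_blocks <- function(query, ref, k, self = FALSE) {
  nr <- nrow(ref)
  k <- min(k, nr - as.integer(self))
  if (k < 1) stop("k must be >= 1 (and < number of reference points)")
  storage.mode(query) <- "double"
  storage.mode(ref) <- "double"
  knn_cpp(t(query), t(ref), as.integer(k), isTRUE(self))
}

#' Exact k-nearest-neighbor graph
#'
#' Computes exact Euclidean k-nearest neighbors (self excluded) in an
#' embedding, with ties broken by ascending cell index.
#'
#' @param embedding A `cell_embedding` or a numeric cells x d matrix.
#' @param k Number of neighbors (positive, `< n_cells`; silently reduced to
#'   `n - 1` when fewer cells are available).
#' @return A `neighbor_graph`: list with `idx` (n x k neighbor indices),
#'   `dist` (sorted ascending per row), `k`.
#' @export
knn_graph <- function(embedding, k) {
  coords <- if (inherits(embedding, "cell_embedding")) embedding$coords else embedding
  if (k <= 0) stop("k must be positive")
  if (nrow(coords) == 1) {
    return(structure(list(idx = matrix(0L, 1, 0), dist = matrix(0, 1, 0),
                          k = 0L, n = 1L), class = "neighbor_graph"))
  }
  res <- knn_blocks(coords, coords, k, self = TRUE)
  structure(list(idx = res$idx, dist = res$dist, k = ncol(res$idx),
                 n = nrow(coords)),
            class = "neighbor_graph")
}

#' Mutual nearest neighbor pairs
#'
#' Finds unordered pairs of cells that are each within the other's k nearest
#' neighbors. In `"global"` mode neighbors are searched over all cells; in
#' `"cross"` mode neighbors are searched from group A into group B only and
#' vice versa (the construction used for progenitor mapping and dataset
#' bridging).
#'
#' @param embedding A `cell_embedding` or coordinate matrix.
#' @param k Neighborhood size.
#' @param mode `"global"` or `"cross"`.
#' @param group_a,group_b Disjoint index vectors (or logical masks) into the
#'   cells; required for `"cross"` mode.
#' @return A tibble with integer columns `i`, `j` (`i < j` in global mode;
#'   `i` in A and `j` in B in cross mode), carrying attributes `k` and `mode`.
#' @export
mnn_pairs <- function(embedding, k, mode = c("global", "cross"),
                      group_a = NULL, group_b = NULL) {
  mode <- match.arg(mode)
  coords <- if (inherits(embedding, "cell_embedding")) embedding$coords else embedding
  n <- nrow(coords)
  if (mode == "global") {
    nn <- knn_graph(coords, k)
    adj <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(nn$idx)),
                                j = as.vector(nn$idx), x = TRUE,
                                dims = c(n, n))
    mutual <- adj & Matrix::t(adj)
    tr <- Matrix::which(Matrix::triu(mutual), arr.ind = TRUE)
    out <- tibble::tibble(i = as.integer(tr[, 1]), j = as.integer(tr[, 2]))
    out <- dplyr::arrange(out, .data$i, .data$j)
  } else {
    if (is.logical(group_a)) group_a <- which(group_a)
    if (is.logical(group_b)) group_b <- which(group_b)
    if (length(intersect(group_a, group_b)) > 0) {
      stop("cross-group MNN requires disjoint groups")
    }
    if (length(group_a) == 0 || length(group_b) == 0) {
      stop("cross-group MNN requires non-empty groups")
    }
    ka <- min(k, length(group_b)); kb <- min(k, length(group_a))
    ab <- knn_blocks(coords[group_a, , drop = FALSE],
                     coords[group_b, , drop = FALSE], ka)
    ba <- knn_blocks(coords[group_b, , drop = FALSE],
                     coords[group_a, , drop = FALSE], kb)
    na <- length(group_a); nb <- length(group_b)
    m_ab <- Matrix::sparseMatrix(i = rep(seq_len(na), ka),
                                 j = as.vector(ab$idx), x = TRUE,
                                 dims = c(na, nb))
    m_ba <- Matrix::sparseMatrix(i = as.vector(ba$idx),
                                 j = rep(seq_len(nb), kb), x = TRUE,
                                 dims = c(na, nb))
    hit <- Matrix::which(m_ab & m_ba, arr.ind = TRUE)
    out <- tibble::tibble(i = group_a[hit[, 1]], j = group_b[hit[, 2]])
    out <- dplyr::arrange(out, .data$i, .data$j)
  }
  attr(out, "k") <- k
  attr(out, "mode") <- mode
  out
}

# Evaluate `expr` under a fixed RNG seed, restoring caller RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Cluster cells on a k-nearest-neighbor graph
#'
#' Builds an undirected graph from the kNN relation and partitions it with
#' the Leiden or Louvain community detection algorithm.
#'
#' @param nn A `neighbor_graph` from [knn_graph()].
#' @param resolution Positive resolution parameter (default 1).
#' @param method `"leiden"` or `"louvain"`.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return Integer vector of dense cluster labels starting at 0, ordered as
#'   the input cells.
#' @export
cluster_graph <- function(nn, resolution = 1, method = c("leiden", "louvain"),
                          seed = 0L) {
  method <- match.arg(method)
  if (resolution <= 0) stop("resolution must be positive")
  n <- nn$n
  if (n == 1) return(0L)
  edges <- cbind(rep(seq_len(n), ncol(nn$idx)), as.vector(nn$idx))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  memb <- with_seed(seed, {
    if (method == "leiden") {
      igraph::membership(igraph::cluster_leiden(
        g, objective_function = "modularity",
        resolution = resolution, n_iterations = 5))
    } else {
      igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
    }
  })
  # dense labels from 0, in order of first appearance
  as.integer(factor(memb, levels = unique(memb))) - 1L
}

#' Smooth per-point values by k-nearest-neighbor averaging
#'
#' Replaces each value by the mean over its k nearest points (self included)
#' and min-max rescales the result to `[0, 1]`. By default
#' `k = round(ln(n))`, the natural-log scaling rule used for smoothing voxel
#' mapping probabilities on spatial sections. A constant input maps to all
#' zeros (degenerate min-max convention).
#'
#' @param values Numeric vector, one value per point.
#' @param coords Numeric matrix of point coordinates (rows = points).
#' @param k Neighborhood size; default `max(1, round(log(n)))`.
#' @return Numeric vector in `[0, 1]`, same length as `values`.
#' @export
neighbor_smooth <- function(values, coords, k = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(values) == n, n >= 2)
  if (is.null(k)) k <- max(1L, as.integer(round(log(n))))
  k <- min(k, n)
  nb <- knn_blocks(coords, coords, k, self = FALSE)
  sm <- rowMeans(matrix(values[nb$idx], nrow = n))
  rng <- range(sm)
  out <- if (rng[1] == rng[2]) rep(0, n) else (sm - rng[1]) / (rng[2] - rng[1])
  attr(out, "k") <- k
  out
}
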