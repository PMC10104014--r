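test_that("normalize_log matches the closed form and an elementwise oracle", {
  # counts (2, 0) at scale 100 -> (ln(101), 0)
  tab <- toy_table(matrix(c(2, 0), 1, 2))
  norm <- normalize_log(tab, scale_target = 100)
  expect_equal(as.numeric(norm[1, ]), c(log(101), 0))

  # proportional rows normalize identically
  tab2 <- toy_table(rbind(c(1, 2, 3), c(3, 6, 9)))
  norm2 <- normalize_log(tab2)
  expect_equal(as.numeric(norm2[1, ]), as.numeric(norm2[2, ]))

  # random matrix vs brute-force loop
  set.seed(7)
  m <- matrix(rpois(1000, 2), 50, 20)
  m[1, ] <- m[1, ] + 1  # guard against all-zero rows
  tot <- rowSums(m)
  expect_gt(min(tot), 0)
  oracle <- m
  for (i in 1:50) for (j in 1:20) {
    oracle[i, j] <- log(1 + m[i, j] * 1e4 / tot[i])
  }
  norm3 <- normalize_log(toy_table(m))
  expect_equal(unname(as.matrix(norm3)), unname(oracle), tolerance = 1e-12)

  # zero-total cell is rejected by name
  z <- matrix(c(0, 1, 0, 1), 2, 2)
  expect_error(normalize_log(toy_table(z)), "c001")
})

test_that("select_hvg ranks planted high-variance genes first", {
  set.seed(3)
  base <- matrix(rpois(500 * 100, 2), 500, 100)
  hot <- sample(100, 10)
  base[, hot] <- rpois(500 * 10, 2) * rbinom(500 * 10, 1, 0.5) * 8
  tab <- toy_table(base)
  norm <- normalize_log(tab)
  # independent loop-based variance oracle
  v <- apply(as.matrix(norm), 2, stats::var)
  top10 <- select_hvg(norm, 10)
  expect_setequal(top10, colnames(norm)[order(-v)][1:10])
  expect_setequal(top10, colnames(norm)[hot])

  # a gene constant in the normalized matrix is never selected; asking for
  # every nonconstant gene returns exactly those
  norm_c <- methods::as(cbind(as.matrix(norm), zzz_const = 1),
                        "CsparseMatrix")
  nz <- sum(apply(as.matrix(norm_c), 2, stats::var) > 0)
  all_sel <- select_hvg(norm_c, nz)
  expect_false("zzz_const" %in% all_sel)
  expect_equal(length(all_sel), ncol(norm_c) - 1L)
  expect_error(select_hvg(norm_c, nz + 1), "nonzero variance")
})

test_that("pca_embed matches a dense eigendecomposition oracle", {
  set.seed(11)
  x <- matrix(rnorm(200 * 30), 200, 30)
  rownames(x) <- sprintf("c%03d", 1:200)
  colnames(x) <- sprintf("g%04d", 1:30)
  emb <- pca_embed(x, d = 10, scale = FALSE)
  # oracle: eigendecomposition of the covariance of centered data
  xc <- scale(x, scale = FALSE)
  ev <- eigen(cov(xc))
  for (j in 1:10) {
    expect_equal(abs(as.numeric(emb$coords[, j])),
                 abs(as.numeric(xc %*% ev$vectors[, j])), tolerance = 1e-8)
  }
  expect_equal(emb$var_frac, ev$values[1:10] / sum(ev$values),
               tolerance = 1e-8)
  expect_true(all(diff(emb$var_frac) <= 1e-12))
})

test_that("pca_embed handles collinear data, rotations, and rank deficits", {
  # points on a line: PC1 carries all variance
  t <- seq(-1, 1, length.out = 50)
  line <- cbind(2 * t, -t, 3 * t)
  colnames(line) <- c("a", "b", "c"); rownames(line) <- sprintf("r%d", 1:50)
  expect_warning(emb <- pca_embed(line, d = 3, scale = FALSE), "rank")
  expect_equal(emb$var_frac[1], 1, tolerance = 1e-10)

  # orthogonal rotation leaves variance fractions unchanged
  set.seed(5)
  x <- matrix(rnorm(100 * 6), 100, 6)
  dimnames(x) <- list(sprintf("r%d", 1:100), sprintf("g%d", 1:6))
  q <- qr.Q(qr(matrix(rnorm(36), 6)))
  xr <- x %*% q
  dimnames(xr) <- dimnames(x)
  e1 <- pca_embed(x, d = 4, scale = FALSE)
  e2 <- pca_embed(xr, d = 4, scale = FALSE)
  expect_equal(e1$var_frac, e2$var_frac, tolerance = 1e-10)

  # reconstruction at full rank is exact
  ef <- pca_embed(x, d = 6, scale = FALSE)
  recon <- ef$coords %*% t(ef$loadings)
  expect_lt(max(abs(recon - scale(x, scale = FALSE))), 1e-8)
})

test_that("knn_graph matches an O(n^2) brute-force oracle and tie rules", {
  # 3 collinear equidistant points, k = 1: middle point picks the lower index
  pts <- matrix(c(0, 1, 2), 3, 1)
  nn <- knn_graph(pts, 1)
  expect_equal(nn$idx[2, 1], 1L)
  # duplicated points are mutual nearest neighbors at distance 0
  dup <- matrix(c(0, 0, 5), 3, 1)
  nnd <- knn_graph(dup, 1)
  expect_equal(nnd$idx[1, 1], 2L)
  expect_equal(nnd$idx[2, 1], 1L)
  expect_equal(nnd$dist[1, 1], 0)
  expect_error(knn_graph(pts, 0), "positive")

  set.seed(21)
  x <- matrix(rnorm(500 * 8), 500, 8)
  nn <- knn_graph(x, 10)
  d <- as.matrix(dist(x)); diag(d) <- Inf
  for (i in seq_len(500)) {
    o <- order(d[i, ], seq_len(500))[1:10]
    expect_identical(as.integer(nn$idx[i, ]), as.integer(o))
  }
  expect_true(all(apply(nn$dist, 1, function(v) all(diff(v) >= 0))))
})

test_that("mnn_pairs equals the brute-force mutual test in both modes", {
  set.seed(31)
  x <- matrix(rnorm(300 * 6), 300, 6)
  k <- 10
  d <- as.matrix(dist(x)); diag(d) <- Inf
  nbr <- lapply(1:300, function(i) order(d[i, ], 1:300)[1:k])
  pairs <- mnn_pairs(x, k, mode = "global")
  oracle <- list()
  for (i in 1:299) for (j in (i + 1):300) {
    if (j %in% nbr[[i]] && i %in% nbr[[j]]) {
      oracle[[length(oracle) + 1]] <- c(i, j)
    }
  }
  om <- do.call(rbind, oracle)
  expect_equal(nrow(pairs), nrow(om))
  expect_equal(pairs$i, om[, 1])
  expect_equal(pairs$j, om[, 2])
  # pair set is a subset of the kNN relation (definitional)
  for (r in seq_len(nrow(pairs))) {
    expect_true(pairs$j[r] %in% nbr[[pairs$i[r]]])
    expect_true(pairs$i[r] %in% nbr[[pairs$j[r]]])
  }

  # cross mode vs brute force
  ga <- 1:120; gb <- 121:300
  ab <- lapply(ga, function(i) gb[order(d[i, gb], gb)[1:k]])
  ba <- lapply(gb, function(j) ga[order(d[j, ga], ga)[1:k]])
  cross <- mnn_pairs(x, k, mode = "cross", group_a = ga, group_b = gb)
  oc <- list()
  for (ii in seq_along(ga)) for (jj in seq_along(gb)) {
    if (gb[jj] %in% ab[[ii]] && ga[ii] %in% ba[[jj]]) {
      oc[[length(oc) + 1]] <- c(ga[ii], gb[jj])
    }
  }
  ocm <- do.call(rbind, oc)
  ocm <- ocm[order(ocm[, 1], ocm[, 2]), , drop = FALSE]
  expect_equal(cross$i, ocm[, 1])
  expect_equal(cross$j, ocm[, 2])

  # two cells, any k: exactly one pair
  two <- mnn_pairs(matrix(c(0, 1), 2, 1), k = 3)
  expect_equal(nrow(two), 1L)
  expect_error(mnn_pairs(x, k, mode = "cross", group_a = 1:10, group_b = 5:20),
               "disjoint")
})

test_that("cluster_graph separates blobs, is deterministic, handles one cell", {
  # with k covering each blob, the kNN graph has two components and both
  # algorithms return exactly the two blobs at resolution 1
  set.seed(41)
  blob <- rbind(matrix(rnorm(80 * 2), 80, 2),
                matrix(rnorm(80 * 2, mean = 30), 80, 2))
  nn <- knn_graph(blob, 79)
  for (method in c("leiden", "louvain")) {
    cl <- cluster_graph(nn, resolution = 1, method = method, seed = 1)
    expect_equal(sort(unique(cl)), c(0L, 1L))
    expect_equal(length(unique(cl[1:80])), 1L)
    expect_equal(length(unique(cl[81:160])), 1L)
    cl2 <- cluster_graph(nn, resolution = 1, method = method, seed = 1)
    expect_identical(cl, cl2)
  }
  # at atlas-like k (sparse within-blob graphs) communities may refine the
  # blobs, but never mix them
  big <- rbind(matrix(rnorm(200 * 2), 200, 2),
               matrix(rnorm(200 * 2, mean = 30), 200, 2))
  nn_big <- knn_graph(big, 15)
  cl_big <- cluster_graph(nn_big, resolution = 1, method = "leiden", seed = 1)
  expect_equal(length(intersect(unique(cl_big[1:200]),
                                unique(cl_big[201:400]))), 0L)
  expect_error(cluster_graph(nn_big, resolution = 0), "positive")
  single <- knn_graph(matrix(0, 1, 2), 5)
  expect_equal(cluster_graph(single), 0L)
})

test_that("neighbor_smooth follows the ln-n rule and a loop oracle", {
  # constant input: degenerate min-max convention gives zeros
  set.seed(51)
  pts <- matrix(rnorm(40), 20, 2)
  out <- neighbor_smooth(rep(3.3, 20), pts)
  expect_equal(as.numeric(out), rep(0, 20))
  expect_equal(attr(out, "k"), max(1, round(log(20))))
  # the ln rule at the scale used for spatial sections: n = 9000 -> k = 9
  expect_equal(round(log(9000)), 9)

  vals <- rnorm(100)
  pts2 <- matrix(rnorm(200), 100, 2)
  sm <- neighbor_smooth(vals, pts2, k = 7)
  d <- as.matrix(dist(pts2))
  oracle <- sapply(1:100, function(i) {
    nb <- order(d[i, ], 1:100)[1:7]  # self included: d[i, i] = 0
    mean(vals[nb])
  })
  oracle <- (oracle - min(oracle)) / (max(oracle) - min(oracle))
  expect_equal(as.numeric(sm), oracle, tolerance = 1e-12)
  expect_true(all(sm >= 0 & sm <= 1))
})
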