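#' QC filter configuration
#'
#' Thresholds for per-cell quality filtering. Defaults follow the aggressive
#' filtering recipe used for whole-embryo sci-RNA-seq3 nuclei: UMI < 200,
#' detected genes < 100, unmatched read rate >= 0.4, final doublet score >
#' 0.15, ribosomal percentage > 5, mitochondrial percentage > 10; a doublet
#' score > 0.2 defines step-1 doublet calls and subclusters with > 15%
#' detected doublets are flagged wholesale.
#'
#' @param min_umi,min_genes,max_unmatched_rate,score_threshold_step1,
#'   subcluster_doublet_frac,final_score_threshold,max_ribo_pct,max_mito_pct
#'   Numeric thresholds (see description for defaults).
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_umi = 200, min_genes = 100, max_unmatched_rate = 0.4,
                      score_threshold_step1 = 0.2,
                      subcluster_doublet_frac = 0.15,
                      final_score_threshold = 0.15,
                      max_ribo_pct = 5, max_mito_pct = 10) {
  structure(list(min_umi = min_umi, min_genes = min_genes,
                 max_unmatched_rate = max_unmatched_rate,
                 score_threshold_step1 = score_threshold_step1,
                 subcluster_doublet_frac = subcluster_doublet_frac,
                 final_score_threshold = final_score_threshold,
                 max_ribo_pct = max_ribo_pct, max_mito_pct = max_mito_pct),
            class = "qc_config")
}

#' Score cells for doublet likelihood with simulated doublets
#'
#' Simulates `sim_doublet_ratio * n` artificial doublets by summing the
#' counts of random observed cell pairs, co-embeds observed and simulated
#' cells in a shared HVG/PCA space fit on the observed cells, and scores each
#' observed cell by its simulated-doublet neighborhood. With `q` the fraction
#' of a cell's k nearest neighbors that are simulated doublets, `r` the
#' simulated:observed ratio and `rho` the expected doublet rate, the score is
#' the posterior doublet probability
#' `q rho / (q rho + r (1 - q) (1 - rho))` (0 when q = 0, 1 when q = 1).
#' The prior `rho` keeps homotypic simulated doublets — which co-locate with
#' the singlet cores of their source types — from inflating singlet scores.
#' The neighborhood size is enlarged to `round(n_neighbors * (1 + r))` to
#' account for the enlarged co-embedded set.
#'
#' @param table A [cell_table] with >= 100 cells.
#' @param sim_doublet_ratio Simulated doublets per observed cell (default 2).
#' @param expected_doublet_rate Prior doublet rate `rho` (default 0.06).
#' @param n_pc Principal components (default 30).
#' @param n_neighbors Base neighborhood size (default 30).
#' @param hvg_percentile Variance percentile above which genes enter the
#'   scoring embedding (default 85, i.e. the top 15% most variable genes).
#' @param min_count,min_cells A gene enters the embedding only when it has
#'   at least `min_count` counts in at least `min_cells` cells (defaults 3
#'   and 3).
#' @param seed Integer seed; scores are deterministic given it.
#' @return Tibble `(cell_id, doublet_score)` in input cell order, scores in
#'   `[0, 1]`.
#' @export
score_doublets <- function(table, sim_doublet_ratio = 2,
                           expected_doublet_rate = 0.06, n_pc = 30,
                           n_neighbors = 30, hvg_percentile = 85,
                           min_count = 3, min_cells = 3, seed = 0L) {
  stopifnot(inherits(table, "cell_table"))
  n <- nrow(table$counts)
  if (n < 100) stop("score_doublets needs at least 100 cells")
  if (n <= n_neighbors) stop("fewer cells than n_neighbors")
  r <- sim_doublet_ratio
  with_seed(seed, {
    n_sim <- round(r * n)
    a <- sample.int(n, n_sim, replace = TRUE)
    b <- sample.int(n, n_sim, replace = TRUE)
    sim <- table$counts[a, , drop = FALSE] + table$counts[b, , drop = FALSE]
    # thin each simulated doublet to a library size sampled from the observed
    # cells, matching the doublet model (a doublet is sequenced at a single
    # cell's depth) and equalizing technical noise between simulated doublets
    # and singlets
    tot_obs <- Matrix::rowSums(table$counts)
    target <- tot_obs[sample.int(n, n_sim, replace = TRUE)]
    sim <- methods::as(sim, "CsparseMatrix")
    thin_p <- pmin(1, target / pmax(1, Matrix::rowSums(sim)))
    # binomial thinning on the sparse triplet representation
    trip <- Matrix::mat2triplet(sim)
    sim@x <- as.numeric(stats::rbinom(length(trip$x), size = as.integer(trip$x),
                                      prob = thin_p[trip$i]))
    sim <- Matrix::drop0(sim)
    rownames(sim) <- sprintf("simdbl_%06d", seq_len(n_sim))
    keep_g <- Matrix::colSums(table$counts >= min_count) >= min_cells
    norm_obs <- normalize_log(table$counts)[, keep_g, drop = FALSE]
    norm_sim <- normalize_log(sim)[, keep_g, drop = FALSE]
    st <- sparse_col_stats(norm_obs)
    n_hvg <- max(n_pc + 1,
                 min(ceiling((1 - hvg_percentile / 100) * sum(st$var > 0)),
                     sum(st$var > 0)))
    hvg <- select_hvg(norm_obs, n_hvg)
    emb <- pca_embed(norm_obs, hvg, d = n_pc)
    # project simulated doublets with the observed-cell scaling + loadings
    xs <- as.matrix(norm_sim[, emb$hvg, drop = FALSE])
    xs <- sweep(sweep(xs, 2, emb$center, "-"), 2, emb$scale, "/")
    coords <- rbind(emb$coords, xs %*% emb$loadings)
    k_adj <- as.integer(round(n_neighbors * (1 + r)))
    nn <- knn_blocks(coords[seq_len(n), , drop = FALSE], coords, k_adj + 1L)
    # drop the self-match (observed block is a prefix of the reference)
    q <- numeric(n)
    for (i in seq_len(n)) {
      nb <- nn$idx[i, ]
      nb <- nb[nb != i][seq_len(k_adj)]
      q[i] <- mean(nb > n)
    }
    rho <- expected_doublet_rate
    score <- ifelse(q == 0, 0,
                    q * rho / (q * rho + r * (1 - q) * (1 - rho)))
    tibble::tibble(cell_id = rownames(table$counts), doublet_score = score)
  })
}

# shared subcluster recipe: embed, cluster, subcluster per cluster
cluster_then_subcluster <- function(table, n_hvg, d, n_neighbors,
                                    res_main, res_sub, method, seed,
                                    exclude_genes = NULL) {
  emb <- embed_cells(table, n_hvg = n_hvg, d = d,
                     exclude_genes = exclude_genes)
  nn <- knn_graph(emb, min(n_neighbors, nrow(emb$coords) - 1))
  cl <- cluster_graph(nn, resolution = res_main, method = method, seed = seed)
  sub <- integer(length(cl))
  for (c0 in unique(cl)) {
    idx <- which(cl == c0)
    if (length(idx) < 10) { sub[idx] <- 0L; next }
    tsub <- filter_cells(table, idx)
    esub <- embed_cells(tsub, n_hvg = n_hvg,
                        d = min(d, length(idx) - 1),
                        exclude_genes = exclude_genes)
    nsub <- knn_graph(esub, min(n_neighbors, length(idx) - 1))
    sub[idx] <- cluster_graph(nsub, resolution = res_sub, method = method,
                              seed = seed)
  }
  tibble::tibble(cell_id = rownames(table$counts), cluster = cl,
                 subcluster = sub)
}

#' Flag doublet-enriched subclusters
#'
#' Second doublet-removal round: clusters cells (sex-chromosome genes
#' excluded, top HVGs, PCA, Louvain at `res_main`), subclusters each cluster
#' at `res_sub`, and flags every cell of any subcluster whose fraction of
#' step-1 doublet calls (score > `score_threshold`) exceeds `frac`.
#'
#' @param table A [cell_table].
#' @param scores Tibble from [score_doublets()] (or a numeric vector in cell
#'   order).
#' @param score_threshold Step-1 call threshold (default 0.2).
#' @param res_main,res_sub Louvain resolutions (defaults 1 and 3).
#' @param frac Doublet-fraction threshold for flagging (default 0.15,
#'   i.e. "over 15%").
#' @param n_hvg,d,n_neighbors Embedding parameters (defaults 3,000 / 30 / 50).
#' @param exclude_genes Genes removed before embedding (default: the
#'   simulated sex genes, when present).
#' @param seed Clustering seed.
#' @return Tibble `(cell_id, cluster, subcluster, doublet_frac, flagged)`.
#' @export
flag_doublet_subclusters <- function(table, scores, score_threshold = 0.2,
                                     res_main = 1, res_sub = 3, frac = 0.15,
                                     n_hvg = 3000, d = 30, n_neighbors = 50,
                                     exclude_genes = NULL, seed = 0L) {
  stopifnot(inherits(table, "cell_table"))
  sc <- if (is.data.frame(scores)) scores$doublet_score else scores
  stopifnot(length(sc) == nrow(table$counts))
  if (is.null(exclude_genes)) {
    exclude_genes <- intersect(SEX_GENES, colnames(table$counts))
  }
  is_dbl <- sc > score_threshold
  cl <- cluster_then_subcluster(table, n_hvg, d, n_neighbors,
                                res_main, res_sub, method = "louvain",
                                seed = seed, exclude_genes = exclude_genes)
  cl |>
    dplyr::mutate(step1 = is_dbl) |>
    dplyr::group_by(.data$cluster, .data$subcluster) |>
    dplyr::mutate(doublet_frac = mean(.data$step1),
                  flagged = .data$doublet_frac > frac) |>
    dplyr::ungroup() |>
    dplyr::select("cell_id", "cluster", "subcluster", "doublet_frac",
                  "flagged")
}

# one-vs-rest AUROC per gene from a global rank matrix
marker_auroc <- function(ranks, in_cluster) {
  n1 <- sum(in_cluster); n0 <- nrow(ranks) - n1
  r1 <- colSums(ranks[in_cluster, , drop = FALSE])
  (r1 - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Flag subclusters deviating from their cluster's markers
#'
#' Third doublet-removal round, aimed at doublets hiding inside rare-type
#' clusters. Cells are filtered (optionally to protein-coding, lincRNA and
#' pseudogene biotypes; genes detected in >= `min_cells_gene` cells; cells
#' with >= `min_genes_cell` genes), clustered on a PCA(`d_main`) embedding of
#' the most highly dispersed genes, and each cluster's top `top_n` marker
#' genes are selected by one-vs-rest AUROC after dropping genes expressed in
#' < `min_frac_expr` of the cluster (clusters are downsampled to
#' `downsample` cells for marker selection). Cells are then re-embedded
#' per-cluster by PCA(`d_marker`) on the pooled marker panel and
#' subclustered. A subcluster is flagged when it expresses its own cluster's
#' markers weakly and another cluster's markers strongly: mean own-panel
#' score below the `theta_low` quantile of its cluster AND mean
#' best-other-panel score above the `theta_high` quantile.
#'
#' @param table A [cell_table].
#' @param biotypes Biotypes retained when `gene_meta$biotype` exists.
#' @param min_cells_gene,min_genes_cell Gene/cell detection filters
#'   (defaults 10 and 100).
#' @param n_hvg Dispersion-ranked genes for the main embedding (default
#'   5,000, capped).
#' @param d_main,d_marker PCA dimensions (defaults 50 and 10).
#' @param res_cluster,res_sub Louvain resolutions for the cluster and
#'   subcluster rounds (defaults 1 and 1).
#' @param downsample Cells per cluster used for marker selection (default
#'   2,500).
#' @param top_n Markers per cluster (default 10).
#' @param min_frac_expr Within-cluster detection floor for markers (default
#'   0.1).
#' @param theta_low,theta_high Quantile thresholds of the flagging rule
#'   (defaults 0.25 and 0.75).
#' @param n_neighbors kNN graph size (default 50).
#' @param seed Clustering/downsampling seed.
#' @return Tibble `(cell_id, cluster, subcluster, own_score, other_score,
#'   flagged)` over the cells that pass the filters; cells filtered out are
#'   absent (and never flagged). Clusters too small for a marker panel are
#'   skipped with a warning.
#' @export
flag_marker_deviant_subclusters <- function(
    table, biotypes = c("protein_coding", "lincRNA", "pseudogene"),
    min_cells_gene = 10, min_genes_cell = 100, n_hvg = 5000,
    d_main = 50, d_marker = 10, res_cluster = 1, res_sub = 1,
    downsample = 2500, top_n = 10, min_frac_expr = 0.1,
    theta_low = 0.25, theta_high = 0.75, n_neighbors = 50, seed = 0L) {
  stopifnot(inherits(table, "cell_table"))
  # substeps 1-2: biotype, gene and cell detection filters
  if ("biotype" %in% names(table$gene_meta)) {
    keep_g <- table$gene_meta$biotype %in% biotypes
    table <- cell_table(table$counts[, keep_g, drop = FALSE],
                        table$cell_meta, table$gene_meta[keep_g, ])
  }
  keep_g <- Matrix::colSums(table$counts > 0) >= min_cells_gene
  table <- cell_table(table$counts[, keep_g, drop = FALSE], table$cell_meta,
                      table$gene_meta[keep_g, ])
  keep_c <- Matrix::rowSums(table$counts > 0) >= min_genes_cell
  table <- filter_cells(table, which(keep_c))
  n <- nrow(table$counts)
  if (n < 50) stop("too few cells after filtering")
  # substeps 3-4: dispersion HVG, PCA, Louvain clusters
  norm <- normalize_log(table)
  st <- sparse_col_stats(norm)
  hvg <- select_hvg(norm, min(n_hvg, sum(st$var > 0)), flavor = "dispersion")
  emb <- pca_embed(norm, hvg, d = min(d_main, n - 1))
  nn <- knn_graph(emb, min(n_neighbors, n - 1))
  cl <- cluster_graph(nn, resolution = res_cluster, method = "louvain",
                      seed = seed)
  clusters <- sort(unique(cl))
  # substeps 5-6: top markers per cluster (AUROC, detection-filtered)
  ds_idx <- with_seed(seed, {
    unlist(lapply(clusters, function(c0) {
      idx <- which(cl == c0)
      if (length(idx) > downsample) sample(idx, downsample) else idx
    }))
  })
  dense <- as.matrix(norm[ds_idx, , drop = FALSE])
  ranks <- apply(dense, 2, rank)
  cl_ds <- cl[ds_idx]
  panels <- list()
  for (c0 in clusters) {
    inc <- cl_ds == c0
    if (sum(inc) < 3 || sum(!inc) < 3) {
      warning("cluster ", c0, " too small for marker selection; skipped")
      next
    }
    frac_expr <- Matrix::colMeans(norm[ds_idx[inc], , drop = FALSE] > 0)
    auc <- marker_auroc(ranks, inc)
    ok <- frac_expr >= min_frac_expr
    ord <- order(-auc[ok], colnames(norm)[ok])
    panels[[as.character(c0)]] <-
      colnames(norm)[ok][ord][seq_len(min(top_n, sum(ok)))]
  }
  if (length(panels) < 2) {
    return(tibble::tibble(cell_id = rownames(table$counts), cluster = cl,
                          subcluster = 0L, own_score = NA_real_,
                          other_score = NA_real_, flagged = FALSE))
  }
  # per-cell panel scores: mean z-scored expression of each panel
  panel_genes <- unique(unlist(panels))
  z <- as.matrix(norm[, panel_genes, drop = FALSE])
  z <- scale(z)
  z[is.nan(z)] <- 0
  panel_score <- vapply(panels, function(p) {
    rowMeans(z[, p, drop = FALSE])
  }, numeric(n))
  own <- rep(NA_real_, n); other <- rep(NA_real_, n)
  for (c0 in clusters) {
    key <- as.character(c0)
    idx <- which(cl == c0)
    if (!key %in% colnames(panel_score)) next
    own[idx] <- panel_score[idx, key]
    other[idx] <- apply(panel_score[idx, setdiff(colnames(panel_score), key),
                                    drop = FALSE], 1, max)
  }
  # substeps 7-9: per-cluster PCA on the marker panel, then subclusters
  sub <- integer(n)
  for (c0 in clusters) {
    idx <- which(cl == c0)
    if (length(idx) < 10) { sub[idx] <- 0L; next }
    esub <- pca_embed(norm[idx, panel_genes, drop = FALSE],
                      d = min(d_marker, length(idx) - 1))
    nsub <- knn_graph(esub, min(n_neighbors, length(idx) - 1))
    sub[idx] <- cluster_graph(nsub, resolution = res_sub, method = "louvain",
                              seed = seed)
  }
  # substep 10 (automated): quantile rule on panel scores
  out <- tibble::tibble(cell_id = rownames(table$counts), cluster = cl,
                        subcluster = sub, own_score = own, other_score = other)
  out |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(q_low = stats::quantile(.data$own_score, theta_low,
                                          na.rm = TRUE),
                  q_high = stats::quantile(.data$other_score, theta_high,
                                           na.rm = TRUE)) |>
    dplyr::group_by(.data$cluster, .data$subcluster) |>
    dplyr::mutate(flagged = !is.na(mean(.data$own_score)) &
                    mean(.data$own_score) < .data$q_low[1] &
                    mean(.data$other_score) > .data$q_high[1]) |>
    dplyr::ungroup() |>
    dplyr::select("cell_id", "cluster", "subcluster", "own_score",
                  "other_score", "flagged")
}

#' Apply per-cell QC filters
#'
#' Removes cells violating any configured threshold and reports a removal
#' ledger with (non-exclusive) per-rule counts. The unmatched-rate, ribosomal
#' and mitochondrial rules are skipped when the corresponding metadata
#' columns are absent; the doublet-score rule is skipped when `scores` is
#' `NULL`.
#'
#' @param table A [cell_table].
#' @param scores Optional [score_doublets()] output (or numeric vector).
#' @param cfg A [qc_config].
#' @return List with `table` (filtered [cell_table]) and `ledger` (tibble
#'   `rule`, `n_removed`).
#' @export
apply_cell_filters <- function(table, scores = NULL, cfg = qc_config()) {
  stopifnot(inherits(table, "cell_table"))
  meta <- table$cell_meta
  n <- nrow(meta)
  rules <- list(min_umi = meta$umi_total < cfg$min_umi,
                min_genes = meta$gene_count < cfg$min_genes)
  if ("unmatched_rate" %in% names(meta)) {
    rules$max_unmatched_rate <- meta$unmatched_rate >= cfg$max_unmatched_rate
  }
  if (!is.null(scores)) {
    sc <- if (is.data.frame(scores)) scores$doublet_score else scores
    rules$doublet_score <- sc > cfg$final_score_threshold
  }
  if ("ribo_pct" %in% names(meta)) {
    rules$max_ribo_pct <- meta$ribo_pct > cfg$max_ribo_pct
  }
  if ("mito_pct" %in% names(meta)) {
    rules$max_mito_pct <- meta$mito_pct > cfg$max_mito_pct
  }
  ledger <- tibble::tibble(rule = names(rules),
                           n_removed = unname(vapply(rules, sum, 0L)))
  drop <- Reduce(`|`, rules, rep(FALSE, n))
  list(table = filter_cells(table, which(!drop)), ledger = ledger)
}

#' Assign embryo sex from Xist versus chrY expression
#'
#' Sums reads per embryo for `Xist` and for chrY genes: more Xist reads means
#' female, more chrY reads means male, equal totals are reported as
#' `"ambiguous"`.
#'
#' @param table A [cell_table] with an `embryo_id` column.
#' @param xist_gene Xist gene id (default `"Xist"`).
#' @param chry_genes Character vector of chrY gene ids.
#' @return Tibble `(embryo_id, xist_total, chry_total, sex)`.
#' @export
assign_sex <- function(table, xist_gene = "Xist",
                       chry_genes = c("Ddx3y", "Eif2s3y", "Uty")) {
  stopifnot(inherits(table, "cell_table"))
  if (length(xist_gene) == 0 || length(chry_genes) == 0) {
    stop("gene lists must be non-empty")
  }
  missing <- setdiff(c(xist_gene, chry_genes), colnames(table$counts))
  if (length(missing) > 0) {
    stop("genes absent from the table: ", paste(missing, collapse = ", "))
  }
  xs <- Matrix::rowSums(table$counts[, xist_gene, drop = FALSE])
  ys <- Matrix::rowSums(table$counts[, chry_genes, drop = FALSE])
  tibble::tibble(embryo_id = table$cell_meta$embryo_id, xs = xs, ys = ys) |>
    dplyr::group_by(.data$embryo_id) |>
    dplyr::summarise(xist_total = sum(.data$xs), chry_total = sum(.data$ys),
                     .groups = "drop") |>
    dplyr::mutate(sex = dplyr::case_when(
      .data$xist_total > .data$chry_total ~ "F",
      .data$xist_total < .data$chry_total ~ "M",
      TRUE ~ "ambiguous"))
}

#' Run the full three-step doublet detection
#'
#' Convenience wrapper: simulated-doublet scoring, doublet-enriched
#' subcluster flagging, and marker-deviant subcluster flagging. A cell is
#' marked for removal when any step flags it.
#'
#' @param table A [cell_table].
#' @param cfg A [qc_config] (supplies the 0.2 score threshold and 15%
#'   subcluster rule).
#' @param seed Seed forwarded to every step.
#' @param ... Extra arguments to [flag_marker_deviant_subclusters()].
#' @return Tibble `(cell_id, doublet_score, score_flag, subcluster_flag,
#'   marker_flag, remove)`.
#' @export
detect_doublets <- function(table, cfg = qc_config(), seed = 0L, ...) {
  scores <- score_doublets(table, seed = seed)
  score_flag <- scores$doublet_score > cfg$score_threshold_step1
  sub <- flag_doublet_subclusters(table, scores,
                                  score_threshold = cfg$score_threshold_step1,
                                  frac = cfg$subcluster_doublet_frac,
                                  seed = seed)
  mk <- flag_marker_deviant_subclusters(table, seed = seed, ...)
  out <- scores |>
    dplyr::mutate(score_flag = score_flag) |>
    dplyr::left_join(dplyr::select(sub, "cell_id", subcluster_flag = "flagged"),
                     by = "cell_id") |>
    dplyr::left_join(dplyr::select(mk, "cell_id", marker_flag = "flagged"),
                     by = "cell_id") |>
    dplyr::mutate(
      subcluster_flag = dplyr::coalesce(.data$subcluster_flag, FALSE),
      marker_flag = dplyr::coalesce(.data$marker_flag, FALSE),
      remove = .data$score_flag | .data$subcluster_flag | .data$marker_flag)
  out
}
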