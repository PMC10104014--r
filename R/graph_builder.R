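#' Score candidate cell-type edges within a subsystem
#'
#' Embeds the subsystem's cells (HVG selection, scaling, PCA), finds global
#' mutual-nearest-neighbor pairs, and scores every pair of cell-type nodes by
#' its inter-node MNN pairs. The normalized MNN score is
#' `100 * n_mnn_pairs / min(|A|, |B|)` — the pair count as a percentage of
#' the smaller node — so the conventional candidacy threshold is a score
#' above 1. The raw pair count and a per-k normalization
#' (`n / (min(|A|,|B|) * k)`) are also reported for sensitivity analysis.
#'
#' @param table A [cell_table] whose `type_label` column names the nodes.
#' @param k MNN neighborhood size (10 for sparse early-development
#'   subsystems, 15 for organogenesis-scale ones).
#' @param n_hvg,d Embedding parameters (defaults 2,500 and 30).
#' @param score_threshold Candidacy threshold on the normalized score
#'   (default 1).
#' @param node_partition Optional character vector of node labels: when
#'   given, only edges touching at least one partition node are scored (the
#'   two-stage treatment used for very complex subsystems).
#' @param min_cells Nodes with fewer cells are excluded with a warning
#'   (default 2).
#' @param seed Reserved for future stochastic backends; the computation is
#'   deterministic.
#' @return An `edge_candidates` object: list with `edges` (tibble `node_a`,
#'   `node_b`, `n_a`, `n_b`, `n_mnn_pairs`, `normalized_score`,
#'   `score_per_k`, `candidate`, ranked by descending score), `pairs` (all
#'   MNN pairs, within- and inter-node, with node labels), `labels`,
#'   `times`, `embedding`, `k`.
#' @export
build_subsystem_candidates <- function(table, k = 15, n_hvg = 2500, d = 30,
                                       score_threshold = 1,
                                       node_partition = NULL,
                                       min_cells = 2, seed = 0L) {
  stopifnot(inherits(table, "cell_table"))
  labels <- table$cell_meta$type_label
  if (anyNA(labels)) stop("every cell must carry a node label")
  sizes <- table(labels)
  small <- names(sizes)[sizes < min_cells]
  if (length(small) > 0) {
    warning("excluding nodes with < ", min_cells, " cells: ",
            paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    table <- filter_cells(table, which(keep))
    labels <- labels[keep]
    sizes <- table(labels)
  }
  emb <- embed_cells(table, n_hvg = n_hvg, d = d)
  pairs <- mnn_pairs(emb, k, mode = "global")
  pairs$node_i <- labels[pairs$i]
  pairs$node_j <- labels[pairs$j]
  inter <- pairs[pairs$node_i != pairs$node_j, ]
  # canonical unordered node pair
  swap <- inter$node_i > inter$node_j
  na <- ifelse(swap, inter$node_j, inter$node_i)
  nb <- ifelse(swap, inter$node_i, inter$node_j)
  counts <- tibble::tibble(node_a = na, node_b = nb) |>
    dplyr::count(.data$node_a, .data$node_b, name = "n_mnn_pairs")
  nodes <- sort(names(sizes))
  all_pairs <- tidyr::expand_grid(node_a = nodes, node_b = nodes) |>
    dplyr::filter(.data$node_a < .data$node_b)
  edges <- all_pairs |>
    dplyr::left_join(counts, by = c("node_a", "node_b")) |>
    dplyr::mutate(
      n_mnn_pairs = dplyr::coalesce(.data$n_mnn_pairs, 0L),
      n_a = as.integer(sizes[.data$node_a]),
      n_b = as.integer(sizes[.data$node_b]),
      normalized_score = 100 * .data$n_mnn_pairs / pmin(.data$n_a, .data$n_b),
      score_per_k = .data$n_mnn_pairs / (pmin(.data$n_a, .data$n_b) * k),
      candidate = .data$normalized_score > score_threshold) |>
    dplyr::arrange(dplyr::desc(.data$normalized_score), .data$node_a,
                   .data$node_b)
  if (!is.null(node_partition)) {
    edges <- dplyr::filter(edges, .data$node_a %in% node_partition |
                             .data$node_b %in% node_partition)
  }
  structure(list(edges = edges, pairs = pairs, labels = labels,
                 times = table$cell_meta$timepoint, embedding = emb, k = k,
                 cell_ids = rownames(table$counts)),
            class = "edge_candidates")
}

#' @export
print.edge_candidates <- function(x, ...) {
  cat(sprintf("<edge_candidates> %d nodes, %d candidate edges (of %d pairs), k = %d\n",
              dplyr::n_distinct(x$labels), sum(x$edges$candidate),
              nrow(x$edges), x$k))
  invisible(x)
}

# median timepoint of the cells of `node` participating in pairs of one edge
edge_side_median_time <- function(cand, node_a, node_b, side) {
  p <- cand$pairs
  on_edge <- (p$node_i == node_a & p$node_j == node_b) |
    (p$node_i == node_b & p$node_j == node_a)
  cells <- unique(c(p$i[on_edge & p$node_i == side],
                    p$j[on_edge & p$node_j == side]))
  if (length(cells) == 0) return(NA_real_)
  stats::median(cand$times[cells])
}

#' Categorize and orient candidate edges
#'
#' Assigns each candidate edge a category (`developmental_progression`,
#' `spatial_continuity`, or `dataset_equivalence`) and an orientation.
#' Uncurated edges default to developmental progression oriented from the
#' node whose MNN-participating cells have the earlier median timepoint; a
#' curation table always wins, and spatial-continuity edges are left
#' bidirectional. Manually asserted edges (e.g. for sparsely sampled early
#' subsystems) can be injected.
#'
#' @param candidates An `edge_candidates` object.
#' @param curation Optional tibble `(node_a, node_b, category, orientation)`
#'   with `orientation` one of `"a_to_b"`, `"b_to_a"`, `"bidirectional"`, or
#'   `NA` to keep the heuristic value.
#' @param manual_edges Optional tibble of extra edges `(node_a, node_b,
#'   category, orientation)` appended as-is (score `NA`).
#' @param score_threshold Only edges whose normalized score exceeds this are
#'   kept (default 1).
#' @return Tibble `(node_a, node_b, n_mnn_pairs, normalized_score, category,
#'   orientation, from, to, median_time_a, median_time_b, curated)`; for
#'   bidirectional edges `from`/`to` are `NA`.
#' @export
categorize_and_orient <- function(candidates, curation = NULL,
                                  manual_edges = NULL, score_threshold = 1) {
  stopifnot(inherits(candidates, "edge_candidates"))
  edges <- dplyr::filter(candidates$edges,
                         .data$normalized_score > score_threshold)
  nodes <- unique(candidates$labels)
  if (!is.null(curation)) {
    curation <- tibble::as_tibble(curation)
    unknown <- setdiff(c(curation$node_a, curation$node_b), nodes)
    if (length(unknown) > 0) {
      stop("curation references unknown nodes: ",
           paste(unknown, collapse = ", "))
    }
  }
  out <- edges |>
    dplyr::rowwise() |>
    dplyr::mutate(
      median_time_a = edge_side_median_time(candidates, .data$node_a,
                                            .data$node_b, .data$node_a),
      median_time_b = edge_side_median_time(candidates, .data$node_a,
                                            .data$node_b, .data$node_b)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      node_time_a = purrr::map_dbl(.data$node_a, function(nd)
        stats::median(candidates$times[candidates$labels == nd])),
      node_time_b = purrr::map_dbl(.data$node_b, function(nd)
        stats::median(candidates$times[candidates$labels == nd])),
      category = "developmental_progression",
      orientation = dplyr::case_when(
        is.na(.data$median_time_a) | is.na(.data$median_time_b) ~ "a_to_b",
        .data$median_time_a < .data$median_time_b ~ "a_to_b",
        .data$median_time_a > .data$median_time_b ~ "b_to_a",
        # tie on the MNN cells: fall back to each node's overall median time
        .data$node_time_a <= .data$node_time_b ~ "a_to_b",
        TRUE ~ "b_to_a"),
      curated = FALSE)
  if (!is.null(curation)) {
    for (r in seq_len(nrow(curation))) {
      cr <- curation[r, ]
      hit <- (out$node_a == cr$node_a & out$node_b == cr$node_b) |
        (out$node_a == cr$node_b & out$node_b == cr$node_a)
      flip <- out$node_a[hit] == cr$node_b
      if (!is.na(cr$category)) out$category[hit] <- cr$category
      if (!is.null(cr$orientation) && !is.na(cr$orientation)) {
        ori <- rep(cr$orientation, sum(hit))
        ori[flip & cr$orientation == "a_to_b"] <- "b_to_a"
        ori[flip & cr$orientation == "b_to_a"] <- "a_to_b"
        out$orientation[hit] <- ori
      }
      out$curated[hit] <- TRUE
    }
  }
  out$orientation[out$category == "spatial_continuity"] <- "bidirectional"
  if (!is.null(manual_edges)) {
    manual_edges <- tibble::as_tibble(manual_edges)
    manual_edges$n_mnn_pairs <- NA_integer_
    manual_edges$normalized_score <- NA_real_
    manual_edges$curated <- TRUE
    out <- dplyr::bind_rows(out, manual_edges)
  }
  out |>
    dplyr::mutate(
      from = dplyr::case_when(.data$orientation == "a_to_b" ~ .data$node_a,
                              .data$orientation == "b_to_a" ~ .data$node_b,
                              TRUE ~ NA_character_),
      to = dplyr::case_when(.data$orientation == "a_to_b" ~ .data$node_b,
                            .data$orientation == "b_to_a" ~ .data$node_a,
                            TRUE ~ NA_character_))
}

#' Time profile of an edge's inter-node MNN cells
#'
#' For each time bin, the percentage of cells (from the whole subsystem in
#' that bin) that participate in the edge's inter-node MNN pairs. Transitions
#' appear as a peak at the time the two types bridge.
#'
#' @param candidates An `edge_candidates` object.
#' @param node_a,node_b The edge's nodes.
#' @param bins Numeric vector of bin values matched against cell timepoints
#'   (default: all observed timepoints).
#' @return Tibble `(bin, n_cells, n_mnn_cells, pct, empty)`; empty bins are
#'   reported as 0 with `empty = TRUE`. `pct` is always in `[0, 100]`.
#' @export
edge_time_profile <- function(candidates, node_a, node_b, bins = NULL) {
  stopifnot(inherits(candidates, "edge_candidates"))
  times <- candidates$times
  if (is.null(bins)) bins <- sort(unique(times))
  p <- candidates$pairs
  on_edge <- (p$node_i == node_a & p$node_j == node_b) |
    (p$node_i == node_b & p$node_j == node_a)
  cells <- unique(c(p$i[on_edge], p$j[on_edge]))
  part <- logical(length(times)); part[cells] <- TRUE
  purrr::map_dfr(bins, function(b) {
    in_bin <- times == b
    n <- sum(in_bin)
    tibble::tibble(bin = b, n_cells = n, n_mnn_cells = sum(part & in_bin),
                   pct = if (n == 0) 0 else 100 * sum(part & in_bin) / n,
                   empty = n == 0)
  })
}

#' Bridge two datasets with equivalence edges
#'
#' Restricts both tables to shared timepoints, intersects gene spaces,
#' co-embeds with a naive per-dataset batch adjustment (each dataset's scaled
#' expression is centered separately before the joint PCA), finds
#' cross-dataset MNN pairs, and scores cross-dataset node pairs as in
#' [build_subsystem_candidates()]. Reciprocal-best pairs above the score
#' threshold become `dataset_equivalence` edges, oriented forward in time
#' (from the dataset whose participating cells have the earlier median
#' timepoint). A manual equivalence table may supplement or override.
#'
#' Because cross-dataset kNN always finds *some* partner, a candidate must
#' also show that the two nodes interleave in the co-embedding: the median
#' distance of its cross-dataset MNN pairs may not exceed `max_dist_ratio`
#' times the median within-dataset neighbor distance of the two nodes'
#' cells. Distinct types forced together by the search fail this mixing
#' criterion. One degenerate case is undetectable by construction: when a
#' dataset contains a single node, per-dataset centering collapses both
#' clouds onto the origin and any label would appear to interleave.
#'
#' @param table_x,table_y Two [cell_table]s with `type_label` and
#'   `timepoint`.
#' @param shared_timepoints Timepoints retained in both (default: the
#'   intersection).
#' @param k MNN neighborhood size (default 15).
#' @param n_hvg,d Embedding parameters.
#' @param score_threshold Minimum normalized score (default 1).
#' @param max_dist_ratio Mixing criterion: maximum allowed ratio of median
#'   cross-pair distance to median within-dataset neighbor distance. True
#'   equivalences interleave at ratios near 0.9, distinct types sit near 2;
#'   the default 1.5 splits the difference (`Inf` disables).
#' @param manual Optional tibble `(node_x, node_y)` of equivalences appended
#'   (deduplicated against the inferred ones); manual rows bypass the mixing
#'   criterion.
#' @return Tibble `(node_x, node_y, n_x, n_y, n_mnn_pairs, normalized_score,
#'   category, orientation, from, to)`.
#' @export
bridge_datasets <- function(table_x, table_y, shared_timepoints = NULL,
                            k = 15, n_hvg = 2500, d = 30,
                            score_threshold = 1, max_dist_ratio = 1.5,
                            manual = NULL) {
  stopifnot(inherits(table_x, "cell_table"), inherits(table_y, "cell_table"))
  if (is.null(shared_timepoints)) {
    shared_timepoints <- intersect(table_x$cell_meta$timepoint,
                                   table_y$cell_meta$timepoint)
  }
  tx <- filter_cells(table_x, table_x$cell_meta$timepoint %in% shared_timepoints)
  ty <- filter_cells(table_y, table_y$cell_meta$timepoint %in% shared_timepoints)
  genes <- intersect(colnames(tx$counts), colnames(ty$counts))
  if (length(genes) == 0) stop("empty gene intersection between datasets")
  nx <- nrow(tx$counts); ny <- nrow(ty$counts)
  counts <- rbind(tx$counts[, genes, drop = FALSE],
                  ty$counts[, genes, drop = FALSE])
  rownames(counts) <- c(paste0("x_", rownames(tx$counts)),
                        paste0("y_", rownames(ty$counts)))
  norm <- normalize_log(counts)
  st <- sparse_col_stats(norm)
  hvg <- select_hvg(norm, min(n_hvg, sum(st$var > 0)))
  x <- as.matrix(norm[, hvg, drop = FALSE])
  x <- scale(x); x[is.nan(x)] <- 0
  ds <- rep(c("x", "y"), c(nx, ny))
  # naive batch adjustment: per-dataset centering of the scaled matrix
  for (dd in c("x", "y")) {
    rows <- ds == dd
    x[rows, ] <- sweep(x[rows, , drop = FALSE], 2,
                       colMeans(x[rows, , drop = FALSE]), "-")
  }
  s <- svd(x, nu = 0, nv = min(d, ncol(x)))
  coords <- x %*% s$v
  pr <- mnn_pairs(coords, k, mode = "cross",
                  group_a = which(ds == "x"), group_b = which(ds == "y"))
  lab <- c(tx$cell_meta$type_label, ty$cell_meta$type_label)
  tim <- c(tx$cell_meta$timepoint, ty$cell_meta$timepoint)
  if (nrow(pr) == 0) {
    return(tibble::tibble(node_x = character(), node_y = character(),
                          n_x = integer(), n_y = integer(),
                          n_mnn_pairs = integer(),
                          normalized_score = numeric(),
                          dist_ratio = numeric(),
                          category = character(), orientation = character(),
                          from = character(), to = character()))
  }
  sx <- table(tx$cell_meta$type_label); sy <- table(ty$cell_meta$type_label)
  # mixing criterion ingredients: cross-pair distances and each cell's mean
  # within-dataset neighbor distance
  pair_dist <- sqrt(rowSums((coords[pr$i, , drop = FALSE] -
                               coords[pr$j, , drop = FALSE])^2))
  kx <- min(k, nx - 1); ky <- min(k, ny - 1)
  within_nn <- c(
    rowMeans(knn_blocks(coords[seq_len(nx), , drop = FALSE],
                        coords[seq_len(nx), , drop = FALSE], kx,
                        self = TRUE)$dist),
    rowMeans(knn_blocks(coords[nx + seq_len(ny), , drop = FALSE],
                        coords[nx + seq_len(ny), , drop = FALSE], ky,
                        self = TRUE)$dist))
  scored <- tibble::tibble(node_x = lab[pr$i], node_y = lab[pr$j],
                           i = pr$i, j = pr$j, pair_dist = pair_dist) |>
    dplyr::group_by(.data$node_x, .data$node_y) |>
    dplyr::summarise(n_mnn_pairs = dplyr::n(),
                     med_t_x = stats::median(tim[.data$i]),
                     med_t_y = stats::median(tim[.data$j]),
                     med_cross_dist = stats::median(.data$pair_dist),
                     .groups = "drop") |>
    dplyr::mutate(n_x = as.integer(sx[.data$node_x]),
                  n_y = as.integer(sy[.data$node_y]),
                  normalized_score = 100 * .data$n_mnn_pairs /
                    pmin(.data$n_x, .data$n_y),
                  med_within_dist = purrr::map2_dbl(
                    .data$node_x, .data$node_y, function(a, b) {
                      stats::median(within_nn[lab == a | lab == b])
                    }),
                  dist_ratio = .data$med_cross_dist / .data$med_within_dist)
  # reciprocal best: best partner in each direction
  best_x <- scored |> dplyr::group_by(.data$node_x) |>
    dplyr::slice_max(.data$normalized_score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  best_y <- scored |> dplyr::group_by(.data$node_y) |>
    dplyr::slice_max(.data$normalized_score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  recip <- dplyr::inner_join(
    dplyr::select(best_x, "node_x", "node_y"),
    dplyr::select(best_y, "node_x", "node_y"),
    by = c("node_x", "node_y"))
  out <- scored |>
    dplyr::semi_join(recip, by = c("node_x", "node_y")) |>
    dplyr::filter(.data$normalized_score > score_threshold,
                  .data$dist_ratio <= max_dist_ratio)
  if (!is.null(manual)) {
    manual <- tibble::as_tibble(manual)
    add <- dplyr::anti_join(manual, out, by = c("node_x", "node_y"))
    if (nrow(add) > 0) {
      add$n_mnn_pairs <- NA_integer_
      add$normalized_score <- NA_real_
      add$dist_ratio <- NA_real_
      add$med_t_x <- NA_real_; add$med_t_y <- NA_real_
      out <- dplyr::bind_rows(out, add)
    }
  }
  out |>
    dplyr::mutate(
      category = "dataset_equivalence",
      orientation = dplyr::if_else(
        !is.na(.data$med_t_y) & .data$med_t_y < .data$med_t_x,
        "y_to_x", "x_to_y"),
      from = dplyr::if_else(.data$orientation == "x_to_y",
                            paste0("x:", .data$node_x),
                            paste0("y:", .data$node_y)),
      to = dplyr::if_else(.data$orientation == "x_to_y",
                          paste0("y:", .data$node_y),
                          paste0("x:", .data$node_x))) |>
    dplyr::select("node_x", "node_y", "n_x", "n_y", "n_mnn_pairs",
                  "normalized_score", "dist_ratio", "category", "orientation",
                  "from", "to")
}

#' Map derivative cell types to progenitor territories
#'
#' For each derivative type, takes its `n_early` earliest cells (by
#' timepoint, ties by cell index) and finds cross-group MNN pairs against the
#' progenitor pool; the derivative's inferred origin is the distribution of
#' pair counts over pool territories, normalized to 1. Derivatives with fewer
#' than `n_early` cells are excluded with a warning; derivatives with fewer
#' than `min_pairs` pairs are left unmapped and retried iteratively against
#' the pool augmented with the early cells of already-processed derivatives
#' (which then act as surrogate territories).
#'
#' @param embedding Co-embedding (`cell_embedding` or matrix) of pool and
#'   derivative cells.
#' @param labels Per-cell label: territory names for pool cells, type names
#'   for derivative cells.
#' @param times Per-cell timepoint.
#' @param derivatives Character vector of derivative type labels.
#' @param territories Character vector of pool territory labels.
#' @param k MNN neighborhood size (default 10).
#' @param n_early Earliest cells per derivative (default 500).
#' @param min_pairs Minimum MNN pairs for a mapping (default 50).
#' @param max_iter Iterative fallback rounds (default 3).
#' @return A `progenitor_map`: list with `distribution` (tibble `derivative`,
#'   `territory`, `n_pairs`, `fraction`, `iteration`; fractions sum to 1 per
#'   mapped derivative) and `unmapped` (tibble `derivative`, `reason`).
#' @export
map_progenitors <- function(embedding, labels, times, derivatives,
                            territories, k = 10, n_early = 500,
                            min_pairs = 50, max_iter = 3) {
  coords <- if (inherits(embedding, "cell_embedding")) embedding$coords else embedding
  n <- nrow(coords)
  stopifnot(length(labels) == n, length(times) == n)
  if (length(intersect(derivatives, territories)) > 0) {
    stop("derivative and territory label sets must be disjoint")
  }
  pool_idx <- which(labels %in% territories)
  early_of <- list()
  skipped <- tibble::tibble(derivative = character(), reason = character())
  for (dv in derivatives) {
    idx <- which(labels == dv)
    if (length(idx) < n_early) {
      warning("derivative ", dv, " has fewer than ", n_early,
              " cells; excluded")
      skipped <- dplyr::bind_rows(skipped, tibble::tibble(
        derivative = dv, reason = sprintf("fewer than %d cells", n_early)))
      next
    }
    early_of[[dv]] <- idx[order(times[idx], idx)][seq_len(n_early)]
  }
  todo <- if (length(early_of) > 0) names(early_of) else character(0)
  results <- list()
  mapped <- character()
  iter <- 0L
  while (length(todo) > 0 && iter < max_iter) {
    iter <- iter + 1L
    # fallback pool: territories plus early cells of other derivatives
    still <- character()
    for (dv in todo) {
      ref_idx <- pool_idx
      ref_lab <- labels[pool_idx]
      if (iter > 1) {
        others <- setdiff(names(early_of), dv)
        extra <- unlist(early_of[others], use.names = FALSE)
        ref_idx <- c(pool_idx, extra)
        ref_lab <- c(labels[pool_idx], labels[extra])
      }
      pr <- mnn_pairs(coords, k, mode = "cross",
                      group_a = early_of[[dv]], group_b = ref_idx)
      if (nrow(pr) < min_pairs) { still <- c(still, dv); next }
      terr <- ref_lab[match(pr$j, ref_idx)]
      dist <- tibble::tibble(derivative = dv, territory = terr) |>
        dplyr::count(.data$derivative, .data$territory, name = "n_pairs") |>
        dplyr::mutate(fraction = .data$n_pairs / sum(.data$n_pairs),
                      iteration = iter)
      results[[dv]] <- dist
      mapped <- c(mapped, dv)
    }
    if (identical(still, todo)) { todo <- still; break }
    todo <- still
  }
  unmapped <- dplyr::bind_rows(
    skipped,
    tibble::tibble(derivative = todo,
                   reason = rep(sprintf("fewer than %d MNN pairs", min_pairs),
                                length(todo))))
  structure(list(distribution = dplyr::bind_rows(results),
                 unmapped = unmapped, k = k, n_early = n_early,
                 min_pairs = min_pairs),
            class = "progenitor_map")
}

#' @export
print.progenitor_map <- function(x, ...) {
  cat(sprintf("<progenitor_map> %d mapped derivatives, %d unmapped\n",
              dplyr::n_distinct(x$distribution$derivative), nrow(x$unmapped)))
  invisible(x)
}

#' Assemble a rooted developmental graph
#'
#' Collects oriented edges into a rooted, directed graph object and checks
#' that every node is reachable from the root (bidirectional edges count both
#' ways). A small number of nodes with more than one parent is permitted —
#' the "tree" is formally a rooted directed graph.
#'
#' @param edges Tibble from [categorize_and_orient()] (and optionally
#'   [bridge_datasets()] rows) with `node_a`, `node_b`, `orientation`.
#' @param root Root node id.
#' @return A `dev_graph`: list with `nodes` (tibble `node`, `n_parents`,
#'   `reachable`), `edges`, `root`, and `graph` (an igraph object).
#' @export
dev_graph <- function(edges, root) {
  edges <- tibble::as_tibble(edges)
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  if (!root %in% nodes) stop("root must be one of the edge nodes")
  el <- dplyr::bind_rows(
    dplyr::transmute(dplyr::filter(edges, .data$orientation == "a_to_b"),
                     from = .data$node_a, to = .data$node_b),
    dplyr::transmute(dplyr::filter(edges, .data$orientation == "b_to_a"),
                     from = .data$node_b, to = .data$node_a),
    dplyr::transmute(dplyr::filter(edges, .data$orientation == "bidirectional"),
                     from = .data$node_a, to = .data$node_b),
    dplyr::transmute(dplyr::filter(edges, .data$orientation == "bidirectional"),
                     from = .data$node_b, to = .data$node_a))
  g <- igraph::graph_from_data_frame(el, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  reach <- igraph::subcomponent(g, root, mode = "out")$name
  indeg <- igraph::degree(g, mode = "in")
  node_tbl <- tibble::tibble(node = nodes,
                             n_parents = as.integer(indeg[nodes]),
                             reachable = nodes %in% reach)
  if (!all(node_tbl$reachable)) {
    warning("nodes not reachable from the root: ",
            paste(node_tbl$node[!node_tbl$reachable], collapse = ", "))
  }
  structure(list(nodes = node_tbl, edges = edges, root = root, graph = g),
            class = "dev_graph")
}

#' @export
print.dev_graph <- function(x, ...) {
  cat(sprintf("<dev_graph> %d nodes, %d edges, root = %s (%d unreachable)\n",
              nrow(x$nodes), nrow(x$edges), x$root, sum(!x$nodes$reachable)))
  invisible(x)
}
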