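# adjacency list of within-type MNN partners for one node label
within_partners <- function(pairs, labels, node) {
  w <- pairs[pairs$node_i == node & pairs$node_j == node, , drop = FALSE]
  w
}

expand_group <- function(group, within, min_group, exclude = integer()) {
  iterations <- 0L
  repeat {
    if (length(group) >= min_group) break
    nbrs <- unique(c(within$j[within$i %in% group],
                     within$i[within$j %in% group]))
    add <- setdiff(setdiff(nbrs, group), exclude)
    if (length(add) == 0) break
    iterations <- iterations + 1L
    group <- sort(c(group, add))
  }
  list(group = sort(group), iterations = iterations,
       exhausted = length(group) < min_group)
}

#' Stratify a cell-type transition into four phases
#'
#' Given an oriented edge A -> B and the subsystem's global MNN pairs, the
#' transition is modeled as four cell groups, 1 -> 2 -> 3 -> 4: group 2 are
#' the A-cells participating in inter-node pairs with B, group 3 their B-side
#' counterparts, group 1 the within-A MNN partners of group 2 (minus group
#' 2), and group 4 the within-B partners of group 3 (minus group 3). To gain
#' statistical power, each group is expanded to at least `min_group` cells by
#' iteratively including its within-type MNN partners; groups stay disjoint
#' (the MNN-participating groups 2/3 are expanded first, then groups 1/4
#' excluding them). If a node's within-type MNN closure is exhausted first,
#' the group is returned as-is with an `exhausted` flag.
#'
#' @param candidates An `edge_candidates` object (supplies pairs and labels).
#' @param node_a,node_b The edge's nodes, in transition order A -> B.
#' @param min_group Target group size (default 200).
#' @return A `phase_assignment`: list with `assignment` (tibble `cell`,
#'   `group` in 1..4), `expansion` (tibble `group`, `n_seed`, `n_final`,
#'   `iterations`, `exhausted`), `edge`.
#' @export
stratify_phases <- function(candidates, node_a, node_b, min_group = 200) {
  stopifnot(inherits(candidates, "edge_candidates"))
  p <- candidates$pairs
  inter_ab <- p[(p$node_i == node_a & p$node_j == node_b), , drop = FALSE]
  inter_ba <- p[(p$node_i == node_b & p$node_j == node_a), , drop = FALSE]
  g2 <- sort(unique(c(inter_ab$i, inter_ba$j)))
  g3 <- sort(unique(c(inter_ab$j, inter_ba$i)))
  if (length(g2) == 0 || length(g3) == 0) {
    stop("edge has no inter-node MNN pairs: ", node_a, " - ", node_b)
  }
  wa <- within_partners(p, candidates$labels, node_a)
  wb <- within_partners(p, candidates$labels, node_b)
  n2 <- length(g2); n3 <- length(g3)
  e2 <- expand_group(g2, wa, min_group)
  e3 <- expand_group(g3, wb, min_group)
  g1 <- setdiff(unique(c(wa$j[wa$i %in% e2$group], wa$i[wa$j %in% e2$group])),
                e2$group)
  g4 <- setdiff(unique(c(wb$j[wb$i %in% e3$group], wb$i[wb$j %in% e3$group])),
                e3$group)
  n1 <- length(g1); n4 <- length(g4)
  e1 <- expand_group(sort(g1), wa, min_group, exclude = e2$group)
  e4 <- expand_group(sort(g4), wb, min_group, exclude = e3$group)
  groups <- list(e1$group, e2$group, e3$group, e4$group)
  assignment <- tibble::tibble(
    cell = unlist(groups),
    group = rep(1:4, lengths(groups)))
  if (anyDuplicated(assignment$cell)) stop("phase groups are not disjoint")
  expansion <- tibble::tibble(
    group = 1:4,
    n_seed = c(n1, n2, n3, n4),
    n_final = lengths(groups),
    iterations = c(e1$iterations, e2$iterations, e3$iterations, e4$iterations),
    exhausted = c(e1$exhausted, e2$exhausted, e3$exhausted, e4$exhausted))
  structure(list(assignment = assignment, expansion = expansion,
                 edge = c(node_a, node_b)),
            class = "phase_assignment")
}

#' @export
print.phase_assignment <- function(x, ...) {
  cat(sprintf("<phase_assignment> %s -> %s, group sizes %s\n",
              x$edge[1], x$edge[2],
              paste(x$expansion$n_final, collapse = "/")))
  invisible(x)
}

# vectorized two-sided Wilcoxon rank-sum with tie and continuity correction
# (normal approximation), columns of `mat` are genes; x_idx/y_idx are row sets
wilcox_vec <- function(mat, x_idx, y_idx) {
  sub <- mat[c(x_idx, y_idx), , drop = FALSE]
  n1 <- length(x_idx); n2 <- length(y_idx); n <- n1 + n2
  ranks <- apply(sub, 2, rank)
  r1 <- colSums(ranks[seq_len(n1), , drop = FALSE])
  u <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_term <- apply(sub, 2, function(v) {
    t <- table(v); sum(t^3 - t)
  })
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  z <- u - mu
  z <- sign(z) * pmax(0, abs(z) - 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma2 == 0] <- 1
  pmin(1, p)
}

#' Differential expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test per gene on log-normalized expression,
#' after removing genes detected in fewer than `min_detect` of cells in
#' *both* groups. Fold changes are natural-log ratios of de-logged group
#' means with a pseudocount,
#' `lnFC = ln(mean(expm1(x)) + 1) - ln(mean(expm1(y)) + 1)` (positive =
#' higher in group X). Significance requires `|lnFC| > lnfc_threshold` and
#' Benjamini-Hochberg adjusted p below `alpha`.
#'
#' @param norm Log-normalized expression matrix (cells x genes), e.g. from
#'   [normalize_log()].
#' @param cells_x,cells_y Row indices of the two groups (non-empty).
#' @param min_detect Detection-fraction floor (default 0.1).
#' @param lnfc_threshold Absolute natural-log fold-change floor (default
#'   0.25).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Tibble `(gene, lnfc, p, adj_p, pct_x, pct_y, direction,
#'   significant)`, one row per tested gene, ordered by `adj_p` then
#'   descending `|lnfc|`.
#' @export
de_test <- function(norm, cells_x, cells_y, min_detect = 0.1,
                    lnfc_threshold = 0.25, alpha = 0.05) {
  if (length(cells_x) == 0 || length(cells_y) == 0) {
    stop("both groups must be non-empty")
  }
  x <- norm[cells_x, , drop = FALSE]
  y <- norm[cells_y, , drop = FALSE]
  pct_x <- Matrix::colMeans(x > 0)
  pct_y <- Matrix::colMeans(y > 0)
  keep <- pct_x >= min_detect | pct_y >= min_detect
  if (!any(keep)) {
    return(tibble::tibble(gene = character(), lnfc = numeric(), p = numeric(),
                          adj_p = numeric(), pct_x = numeric(),
                          pct_y = numeric(), direction = integer(),
                          significant = logical()))
  }
  genes <- colnames(norm)[keep]
  dense <- as.matrix(norm[c(cells_x, cells_y), keep, drop = FALSE])
  p <- wilcox_vec(dense, seq_along(cells_x),
                  length(cells_x) + seq_along(cells_y))
  mx <- Matrix::colMeans(x[, keep, drop = FALSE])
  my <- Matrix::colMeans(y[, keep, drop = FALSE])
  # means of de-logged expression, computed sparsely: mean(expm1(v))
  ex <- Matrix::colSums(expm1_sparse(x[, keep, drop = FALSE])) / nrow(x)
  ey <- Matrix::colSums(expm1_sparse(y[, keep, drop = FALSE])) / nrow(y)
  lnfc <- log(ex + 1) - log(ey + 1)
  adj_p <- stats::p.adjust(p, method = "BH")
  tibble::tibble(gene = genes, lnfc = lnfc, p = p, adj_p = adj_p,
                 pct_x = pct_x[keep], pct_y = pct_y[keep],
                 direction = as.integer(sign(lnfc)),
                 significant = adj_p < alpha & abs(lnfc) > lnfc_threshold) |>
    dplyr::arrange(.data$adj_p, dplyr::desc(abs(.data$lnfc)), .data$gene)
}

expm1_sparse <- function(m) {
  m <- methods::as(m, "CsparseMatrix")
  m@x <- expm1(m@x)
  m
}

#' Nominate transition driver genes and TFs for an edge
#'
#' Runs [de_test()] on the three portions of a four-phase transition —
#' early (group 1 vs 2), inter-node (2 vs 3), and late (3 vs 4) — and labels
#' each nominated gene with its phase, TF status, and whether it is
#' exclusively nominated in the early or late phase. Positive fold changes
#' point along the transition (higher in the later group).
#'
#' @param table A [cell_table] covering the subsystem the phases were
#'   derived from (same cell order as the `edge_candidates`).
#' @param phases A `phase_assignment` from [stratify_phases()].
#' @param tf_list Character vector of transcription-factor gene ids; when
#'   `NULL` (with a warning) only DEGs are reported.
#' @param ... Passed to [de_test()] (thresholds).
#' @return Tibble `(edge, phase, gene, lnfc, p, adj_p, pct_early, pct_late,
#'   is_tf, significant, exclusive_phase)`; significant rows constitute the
#'   nominations, ranked within phase by adjusted p then `|lnFC|`.
#' @export
nominate_edge_genes <- function(table, phases, tf_list = NULL, ...) {
  stopifnot(inherits(table, "cell_table"),
            inherits(phases, "phase_assignment"))
  if (is.null(tf_list)) {
    if ("is_tf" %in% names(table$gene_meta) && any(table$gene_meta$is_tf)) {
      tf_list <- table$gene_meta$gene_id[table$gene_meta$is_tf]
    } else {
      warning("no tf_list given and no is_tf metadata; reporting DEGs only")
      tf_list <- character()
    }
  }
  norm <- normalize_log(table)
  grp <- function(g) phases$assignment$cell[phases$assignment$group == g]
  contrasts <- list(early = c(1, 2), internode = c(2, 3), late = c(3, 4))
  res <- purrr::imap_dfr(contrasts, function(gg, phase) {
    de <- de_test(norm, grp(gg[2]), grp(gg[1]), ...)
    de$phase <- phase
    de
  })
  sig <- res[res$significant, ]
  phase_of <- split(sig$phase, sig$gene)
  excl <- vapply(phase_of, function(ph) {
    if (identical(unique(ph), "early")) "early"
    else if (identical(unique(ph), "late")) "late"
    else NA_character_
  }, character(1))
  res |>
    dplyr::mutate(edge = paste(phases$edge[1], phases$edge[2], sep = "->"),
                  is_tf = .data$gene %in% tf_list,
                  exclusive_phase = ifelse(
                    .data$significant, unname(excl[.data$gene]),
                    NA_character_)) |>
    dplyr::select("edge", "phase", "gene", "lnfc", "p", "adj_p",
                  pct_early = "pct_y", pct_late = "pct_x", "is_tf",
                  "significant", "exclusive_phase") |>
    dplyr::arrange(factor(.data$phase, levels = names(contrasts)),
                   .data$adj_p, dplyr::desc(abs(.data$lnfc)))
}
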