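test_that("score_doublets separates spiked heterotypic doublets from singlets", {
  sim <- simulate_atlas(two_type_spec(),
                        sim_config(8.5, cells_per_timepoint = 1000,
                                   doublet_rate = 0.08,
                                   doublet_mode = "heterotypic", seed = 12))
  sc <- score_doublets(sim$table, seed = 12)
  expect_true(all(sc$doublet_score >= 0 & sc$doublet_score <= 1))
  dbl <- sim$truth$true_is_doublet
  expect_gt(stats::median(sc$doublet_score[dbl]),
            stats::median(sc$doublet_score[!dbl]))
  # the step-1 call at the conventional 0.2 threshold is just {score > 0.2}
  expect_gt(mean(sc$doublet_score[dbl] > 0.2), 0.5)
  expect_lt(mean(sc$doublet_score[!dbl] > 0.2), 0.2)
})

test_that("score_doublets is invariant to cell order and seeded", {
  sim <- simulate_atlas(one_type_spec(),
                        sim_config(8.5, cells_per_timepoint = 200,
                                   doublet_rate = 0, seed = 13))
  s1 <- score_doublets(sim$table, seed = 1)
  s2 <- score_doublets(sim$table, seed = 1)
  expect_identical(s1, s2)
  set.seed(99)
  perm <- sample(nrow(sim$table$counts))
  s3 <- score_doublets(filter_cells(sim$table, perm), seed = 1)
  # the simulated pair draw differs under permutation, so compare the score
  # distribution, not per-cell identity
  expect_equal(mean(s3$doublet_score), mean(s1$doublet_score),
               tolerance = 0.02)
  expect_equal(stats::quantile(s3$doublet_score, 0.9),
               stats::quantile(s1$doublet_score, 0.9), tolerance = 0.05)
  expect_error(score_doublets(filter_cells(sim$table, 1:50)), "100 cells")
})

test_that("flag_doublet_subclusters applies the >15% rule on subclusters", {
  sim <- simulate_atlas(two_type_spec(),
                        sim_config(8.5, cells_per_timepoint = 1000,
                                   doublet_rate = 0.08,
                                   doublet_mode = "heterotypic", seed = 14))
  sc <- score_doublets(sim$table, seed = 14)
  sub <- flag_doublet_subclusters(sim$table, sc, seed = 14)
  # flag is exactly the >15% rule applied to subcluster doublet fractions
  agg <- dplyr::summarise(
    dplyr::group_by(sub, .data$cluster, .data$subcluster),
    frac = .data$doublet_frac[1], flag = .data$flagged[1], .groups = "drop")
  expect_equal(agg$flag, agg$frac > 0.15)
  # no step-1 doublets anywhere -> no flags
  sub0 <- flag_doublet_subclusters(sim$table, rep(0, nrow(sim$table$counts)),
                                   seed = 14)
  expect_false(any(sub0$flagged))
  # the doublet-dominated subclusters capture most spiked doublets
  dbl <- sim$truth$true_is_doublet
  expect_gt(mean(sub$flagged[dbl]), 0.5)
})

test_that("marker-deviant subclusters are flagged, homogeneous data is not", {
  # planted doublet-like subpopulation: 80/20 mix of two programs, rare
  genes <- sprintf("g%04d", 1:500)
  spec <- lineage_spec(
    types = tibble::tibble(
      type_id = c("A", "B", "D"), parent_id = c(NA, "A", "A"),
      birth_time = c(8.5, 8.5, 8.5), death_time = c(NA, NA, NA),
      program = list(
        stats::setNames(rep(10, 25), genes[101:125]),
        stats::setNames(rep(10, 25), genes[126:150]),
        c(stats::setNames(rep(10^0.75, 25), genes[101:125]),
          stats::setNames(rep(10^0.45, 25), genes[126:150])))),
    n_genes = 500, tf_genes = genes[1:100], bridge_fraction = 0)
  sim <- simulate_atlas(spec, sim_config(8.5, cells_per_timepoint = 3000,
                                         doublet_rate = 0, seed = 15))
  keep <- which(sim$truth$true_type != "D" |
                  seq_along(sim$truth$true_type) %in%
                    utils::head(which(sim$truth$true_type == "D"), 120))
  tab <- filter_cells(sim$table, keep)
  truth <- sim$truth[keep, ]
  mk <- flag_marker_deviant_subclusters(tab, seed = 15)
  flagged <- mk$flagged[match(rownames(tab$counts), mk$cell_id)]
  expect_gt(mean(flagged[truth$true_type == "D"]), 0.5)
  expect_lt(mean(flagged[truth$true_type != "D"]), 0.05)
  # marker panels carry at most 10 genes each
  expect_true(all(table(mk$cluster) >= 1))

  # homogeneous single type: no flags
  sim1 <- simulate_atlas(one_type_spec(),
                         sim_config(8.5, cells_per_timepoint = 600,
                                    doublet_rate = 0, seed = 16))
  mk1 <- flag_marker_deviant_subclusters(sim1$table, seed = 16)
  expect_lt(mean(mk1$flagged), 0.05)
})

test_that("apply_cell_filters removes rule violators and ledgers each rule", {
  m <- matrix(5L, 6, 60)
  m[1, ] <- c(rep(2L, 50), rep(0L, 10))        # umi 100 < 200
  m[2, ] <- c(rep(30L, 10), rep(0L, 50))       # 10 genes < 100 -> min_genes
  rownames(m) <- sprintf("c%d", 1:6); colnames(m) <- sprintf("g%04d", 1:60)
  meta <- tibble::tibble(
    cell_id = rownames(m), embryo_id = "e", timepoint = 9,
    unmatched_rate = c(0, 0, 0.5, 0, 0, 0),
    ribo_pct = c(0, 0, 0, 6, 0, 0),
    mito_pct = c(0, 0, 0, 0, 11, 0))
  tab <- cell_table(m, meta)
  scores <- c(0, 0, 0, 0, 0, 0.16)
  res <- apply_cell_filters(tab, scores, qc_config(min_genes = 20))
  led <- res$ledger
  expect_equal(led$n_removed[led$rule == "min_umi"], 1L)
  expect_equal(led$n_removed[led$rule == "min_genes"], 1L)
  expect_equal(led$n_removed[led$rule == "max_unmatched_rate"], 1L)
  expect_equal(led$n_removed[led$rule == "doublet_score"], 1L)
  expect_equal(led$n_removed[led$rule == "max_ribo_pct"], 1L)
  expect_equal(led$n_removed[led$rule == "max_mito_pct"], 1L)
  expect_equal(nrow(res$table$counts), 0L)

  # all-passing table is returned unchanged
  ok <- toy_table(matrix(10L, 4, 150))
  res_ok <- apply_cell_filters(ok, NULL, qc_config())
  expect_equal(dim(res_ok$table), dim(ok))
  expect_true(all(res_ok$ledger$n_removed == 0))

  # monotonicity: stricter thresholds remove a superset
  sim <- simulate_atlas(one_type_spec(),
                        sim_config(8.5, cells_per_timepoint = 300,
                                   doublet_rate = 0,
                                   library_size_log_sd = 1, seed = 17))
  loose <- apply_cell_filters(sim$table, cfg = qc_config(min_umi = 1000))
  strict <- apply_cell_filters(sim$table, cfg = qc_config(min_umi = 2000))
  expect_true(all(rownames(strict$table$counts) %in%
                    rownames(loose$table$counts)))
})

test_that("assign_sex recovers simulated embryo sexes and handles ties", {
  sim <- simulate_atlas(two_type_spec(),
                        sim_config(c(8.5, 9.0), cells_per_timepoint = 400,
                                   doublet_rate = 0, seed = 18))
  sx <- assign_sex(sim$table)
  truth <- dplyr::distinct(sim$table$cell_meta, .data$embryo_id, .data$sex)
  merged <- dplyr::inner_join(sx, truth, by = "embryo_id")
  expect_equal(merged$sex.x, merged$sex.y)

  # hand-built: clear female and an exact tie
  m <- rbind(c(500L, 5L, 3L, 2L), c(10L, 4L, 3L, 3L))
  rownames(m) <- c("c1", "c2")
  colnames(m) <- c("Xist", "Ddx3y", "Eif2s3y", "Uty")
  tab <- cell_table(m, tibble::tibble(cell_id = c("c1", "c2"),
                                      embryo_id = c("e1", "e2"),
                                      timepoint = 9))
  sx2 <- assign_sex(tab)
  expect_equal(sx2$sex[sx2$embryo_id == "e1"], "F")
  expect_equal(sx2$sex[sx2$embryo_id == "e2"], "ambiguous")
  expect_error(assign_sex(tab, xist_gene = "NotAGene"), "NotAGene")
})
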