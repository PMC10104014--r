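test_that("lineage_spec enforces its invariants", {
  expect_s3_class(default_lineage_spec(), "lineage_spec")
  genes <- sprintf("g%04d", 1:100)
  base <- tibble::tibble(
    type_id = c("A", "B"), parent_id = c(NA, "A"),
    birth_time = c(9, 8.5), death_time = c(NA, NA),
    program = list(stats::setNames(10, genes[1]),
                   stats::setNames(10, genes[2])))
  expect_error(lineage_spec(base, 100), "born before")
  two_roots <- base; two_roots$parent_id <- c(NA, NA)
  expect_error(lineage_spec(two_roots, 100), "exactly one root")
  neg <- base; neg$birth_time <- c(8.5, 9); neg$program[[1]] <- stats::setNames(-1, genes[1])
  expect_error(lineage_spec(neg, 100), "> 0")
  out_of_range <- base; out_of_range$birth_time <- c(8.5, 9)
  out_of_range$program[[2]] <- stats::setNames(10, "g9999")
  expect_error(lineage_spec(out_of_range, 100), "exceed the gene universe")
  expect_error(lineage_spec(dplyr::mutate(base, birth_time = c(8.5, 9)),
                            100, tf_genes = "nope"), "subset")
})

test_that("sim_config validates ranges", {
  expect_error(sim_config(c(9, 8.5)), "strictly increasing")
  expect_error(sim_config(9, doublet_rate = 0.5), "doublet_rate")
  expect_error(sim_config(9, cells_per_timepoint = 0), "cells_per_timepoint")
  expect_error(simulate_atlas(two_type_spec(),
                              sim_config(c(8.0, 9.0), seed = 1)),
               "before the root")
})

test_that("simulate_atlas is bit-reproducible from its seed", {
  spec <- chain_spec()
  cfg <- sim_config(c(8.5, 9.0, 9.5), cells_per_timepoint = 300, seed = 42)
  s1 <- simulate_atlas(spec, cfg)
  s2 <- simulate_atlas(spec, cfg)
  expect_identical(as.matrix(s1$table$counts), as.matrix(s2$table$counts))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_atlas(spec, sim_config(c(8.5, 9.0, 9.5),
                                        cells_per_timepoint = 300, seed = 43))
  expect_false(identical(as.matrix(s1$table$counts),
                         as.matrix(s3$table$counts)))
})

test_that("library sizes are calibrated to the assay's ~2,700 UMI median", {
  sim <- simulate_atlas(two_type_spec(),
                        sim_config(8.5, cells_per_timepoint = 2000,
                                   doublet_rate = 0, seed = 2))
  med <- stats::median(sim$table$cell_meta$umi_total)
  expect_gt(med, 2700 * 0.9)
  expect_lt(med, 2700 * 1.1)
})

test_that("doublet_rate 0 yields zero doublets; spiking matches the rate", {
  sim0 <- simulate_atlas(two_type_spec(),
                         sim_config(8.5, cells_per_timepoint = 500,
                                    doublet_rate = 0, seed = 3))
  expect_equal(sum(sim0$truth$true_is_doublet), 0L)

  sim6 <- simulate_atlas(two_type_spec(),
                         sim_config(8.5, cells_per_timepoint = 1000,
                                    doublet_rate = 0.06,
                                    doublet_mode = "heterotypic", seed = 3))
  expect_equal(sum(sim6$truth$true_is_doublet), 60L)
  het <- sim6$truth[sim6$truth$true_is_doublet, ]
  expect_true(all(het$doublet_type_a != het$doublet_type_b))
})

test_that("per-type program means recover configured effect sizes", {
  # low-noise limit: large NB size, disjoint strong programs, n = 2000
  spec <- two_type_spec()
  cfg <- sim_config(8.5, cells_per_timepoint = 2000, doublet_rate = 0,
                    nb_dispersion = 100, library_size_log_sd = 0.05,
                    add_sex_genes = FALSE, seed = 4)
  sim <- simulate_atlas(spec, cfg)
  cnt <- sim$table$counts
  lab <- sim$truth$true_type
  prog_a <- names(spec$types$program[[1]])
  bg <- setdiff(colnames(cnt), c(prog_a, names(spec$types$program[[2]])))
  mean_prog <- mean(Matrix::colMeans(cnt[lab == "A", prog_a]))
  mean_bg <- mean(Matrix::colMeans(cnt[lab == "A", bg]))
  expect_equal(mean_prog / mean_bg, 10, tolerance = 0.05)
})

test_that("heterotypic doublets co-express both programs more than singlets", {
  spec <- two_type_spec()
  sim <- simulate_atlas(spec, sim_config(8.5, cells_per_timepoint = 1000,
                                         doublet_rate = 0.1,
                                         doublet_mode = "heterotypic",
                                         seed = 5))
  norm <- normalize_log(sim$table)
  score_a <- Matrix::rowMeans(norm[, names(spec$types$program[[1]])])
  score_b <- Matrix::rowMeans(norm[, names(spec$types$program[[2]])])
  co <- score_a * score_b
  dbl <- sim$truth$true_is_doublet
  expect_gt(stats::median(co[dbl]), stats::median(co[!dbl]))
})

test_that("abrupt types switch programs at the final timepoint only", {
  spec <- abrupt_spec()
  sim <- simulate_atlas(spec, sim_config(seq(16.5, 19.5, 0.5),
                                         cells_per_timepoint = 200,
                                         doublet_rate = 0, seed = 6))
  cnt <- sim$table$counts
  meta <- sim$table$cell_meta
  alt <- names(spec$abrupt_programs$Z)
  z_final <- meta$type_label == "Z" & meta$timepoint == 19.5
  z_before <- meta$type_label == "Z" & meta$timepoint < 19.5
  # replacement, not addition: the alternate program lights up only at the
  # final timepoint, the original program goes dark there (10x weights)
  expect_gt(mean(as.matrix(cnt[z_final, alt])),
            5 * mean(as.matrix(cnt[z_before, alt])))
  old <- names(spec$types$program[[2]])
  expect_gt(mean(as.matrix(cnt[z_before, old])),
            5 * mean(as.matrix(cnt[z_final, old])))
})

test_that("simulate_growth_series honors the polynomial and noise contract", {
  gm <- growth_model(PRINTED_GROWTH)
  ser <- simulate_growth_series(gm, 8.5, noise_sd = 0)
  expect_equal(ser$cell_count, 2.13e5, tolerance = 0.01)

  const <- simulate_growth_series(c(7, 0, 0, 0), days = c(1, 5, 9),
                                  noise_sd = 0)
  expect_equal(const$cell_count, rep(2^7, 3))

  noisy1 <- simulate_growth_series(gm, seq(8.5, 19.5, 1), 0.1, seed = 9)
  noisy2 <- simulate_growth_series(gm, seq(8.5, 19.5, 1), 0.1, seed = 9)
  expect_identical(noisy1, noisy2)
  expect_true(all(noisy1$cell_count > 0))
})
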