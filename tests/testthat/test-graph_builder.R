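make_chain_candidates <- function(seed = 21, k = 10) {
  sim <- simulate_atlas(chain_spec(),
                        sim_config(c(8.5, 9.0, 9.5),
                                   cells_per_timepoint = 900,
                                   doublet_rate = 0, seed = seed))
  list(sim = sim, cand = build_subsystem_candidates(sim$table, k = k))
}

test_that("true chain edges outscore the non-adjacent pair", {
  x <- make_chain_candidates()
  e <- x$cand$edges
  s <- function(a, b) e$normalized_score[e$node_a == min(a, b) &
                                           e$node_b == max(a, b)]
  expect_gt(s("A", "B"), s("A", "C"))
  expect_gt(s("B", "C"), s("A", "C"))
  expect_true(e$candidate[e$node_a == "A" & e$node_b == "B"])
  # candidate threshold is score > 1
  expect_equal(e$candidate, e$normalized_score > 1)
  # normalized score definition and bounds
  expect_equal(e$normalized_score,
               100 * e$n_mnn_pairs / pmin(e$n_a, e$n_b))
  expect_true(all(e$normalized_score >= 0 &
                    e$normalized_score <= 100 * x$cand$k))
})

test_that("types with no MNN pairs score zero and are not candidates", {
  x <- make_chain_candidates()
  e <- x$cand$edges
  ac <- e[e$node_a == "A" & e$node_b == "C", ]
  expect_lt(ac$normalized_score, 1)
  expect_false(ac$candidate)
})

test_that("orientation heuristic recovers the chain and honors curation", {
  x <- make_chain_candidates()
  ori <- categorize_and_orient(x$cand)
  expect_true(any(ori$from == "A" & ori$to == "B"))
  expect_true(any(ori$from == "B" & ori$to == "C"))
  # early -> late orientation by median MNN-cell time
  ab <- ori[ori$node_a == "A" & ori$node_b == "B", ]
  expect_lte(ab$median_time_a, ab$median_time_b)
  # curation to spatial continuity forces bidirectional regardless of time
  cur <- tibble::tibble(node_a = "A", node_b = "B",
                        category = "spatial_continuity",
                        orientation = NA_character_)
  ori2 <- categorize_and_orient(x$cand, curation = cur)
  ab2 <- ori2[ori2$node_a == "A" & ori2$node_b == "B", ]
  expect_equal(ab2$category, "spatial_continuity")
  expect_equal(ab2$orientation, "bidirectional")
  expect_true(is.na(ab2$from))
  expect_error(categorize_and_orient(x$cand, curation = tibble::tibble(
    node_a = "Q", node_b = "A", category = NA, orientation = NA)),
    "unknown nodes")
})

test_that("edge time profiles peak at the transition and stay in [0, 100]", {
  x <- make_chain_candidates()
  prof <- edge_time_profile(x$cand, "B", "C")  # C born at 9.5
  expect_true(all(prof$pct >= 0 & prof$pct <= 100))
  expect_equal(prof$bin[which.max(prof$pct)], 9.5)
  # bins without cells report 0 and are flagged
  prof2 <- edge_time_profile(x$cand, "B", "C", bins = c(8.5, 9.0, 9.5, 99))
  expect_true(prof2$empty[prof2$bin == 99])
  expect_equal(prof2$pct[prof2$bin == 99], 0)
  # an edge with no pairs has an all-zero profile
  prof3 <- edge_time_profile(x$cand, "A", "C")
  expect_true(all(prof3$pct < 0.2))
})

test_that("dev_graph checks rootedness and reachability", {
  x <- make_chain_candidates()
  ori <- categorize_and_orient(x$cand)
  g <- dev_graph(ori, root = "A")
  expect_true(all(g$nodes$reachable))
  expect_error(dev_graph(ori, root = "nope"), "root")
  # orphan edge triggers a reachability warning
  bad <- dplyr::bind_rows(ori, tibble::tibble(
    node_a = "X1", node_b = "X2", orientation = "a_to_b"))
  expect_warning(dev_graph(bad, root = "A"), "not reachable")
})

test_that("bridge_datasets matches every shared type to itself", {
  sim <- simulate_atlas(chain_spec(),
                        sim_config(c(8.5, 9.0, 9.5),
                                   cells_per_timepoint = 600,
                                   doublet_rate = 0, seed = 23))
  n <- nrow(sim$table$counts)
  set.seed(23)
  half <- sort(sample(n, n %/% 2))
  tx <- filter_cells(sim$table, half)
  ty <- filter_cells(sim$table, setdiff(seq_len(n), half))
  # dataset-specific mean offset on a gene block
  ty$counts[, 1:40] <- ty$counts[, 1:40] * 3L
  be <- bridge_datasets(tx, ty, k = 15)
  expect_setequal(be$node_x, c("A", "B", "C"))
  expect_equal(be$node_x, be$node_y)
  expect_equal(unique(be$category), "dataset_equivalence")
  # equivalence edges oriented forward in time
  expect_true(all(be$orientation %in% c("x_to_y", "y_to_x")))
  # disjoint type sets fail the mixing criterion: no equivalence edges
  genes <- sprintf("g%04d", 1:400)
  spec4 <- lineage_spec(
    types = tibble::tibble(
      type_id = c("A", "B", "C", "D"), parent_id = c(NA, "A", "A", "A"),
      birth_time = rep(8.5, 4), death_time = rep(NA_real_, 4),
      program = list(stats::setNames(rep(20, 50), genes[101:150]),
                     stats::setNames(rep(20, 50), genes[151:200]),
                     stats::setNames(rep(20, 50), genes[201:250]),
                     stats::setNames(rep(20, 50), genes[251:300]))),
    n_genes = 400, tf_genes = genes[1:100], bridge_fraction = 0)
  sim4 <- simulate_atlas(spec4, sim_config(c(8.5, 9.0),
                                           cells_per_timepoint = 1200,
                                           doublet_rate = 0, seed = 23))
  lab4 <- sim4$table$cell_meta$type_label
  tx2 <- filter_cells(sim4$table, lab4 %in% c("A", "B"))
  ty2 <- filter_cells(sim4$table, lab4 %in% c("C", "D"))
  be2 <- bridge_datasets(tx2, ty2, k = 15)
  expect_equal(nrow(be2), 0L)
})

test_that("map_progenitors assigns derivatives to their true territory", {
  genes <- sprintf("g%04d", 1:400)
  spec <- lineage_spec(
    types = tibble::tibble(
      type_id = c("P1", "P2", "D"), parent_id = c(NA, "P1", "P2"),
      birth_time = c(8.5, 8.5, 9.0), death_time = c(NA, NA, NA),
      program = list(
        stats::setNames(rep(10, 25), genes[101:125]),
        stats::setNames(rep(10, 25), genes[126:150]),
        c(stats::setNames(rep(10, 12), genes[151:162]),
          stats::setNames(rep(4, 13), genes[126:138])))),
    n_genes = 400, tf_genes = genes[1:100], bridge_fraction = 0.2)
  sim <- simulate_atlas(spec, sim_config(c(8.5, 9.0, 9.5),
                                         cells_per_timepoint = 1800,
                                         doublet_rate = 0, seed = 24))
  emb <- embed_cells(sim$table)
  pm <- map_progenitors(emb, sim$table$cell_meta$type_label,
                        sim$table$cell_meta$timepoint,
                        derivatives = "D", territories = c("P1", "P2"))
  d <- pm$distribution
  expect_equal(sum(d$fraction), 1)
  expect_gt(d$fraction[d$territory == "P2"], 0.9)
  expect_equal(nrow(pm$unmapped), 0L)

  # a derivative with too few cells is excluded with a warning
  small <- c(which(sim$table$cell_meta$type_label != "D"),
             utils::head(which(sim$table$cell_meta$type_label == "D"), 100))
  tab2 <- filter_cells(sim$table, sort(small))
  emb2 <- embed_cells(tab2)
  expect_warning(
    pm2 <- map_progenitors(emb2, tab2$cell_meta$type_label,
                           tab2$cell_meta$timepoint,
                           derivatives = "D", territories = c("P1", "P2")),
    "fewer than 500")
  expect_equal(pm2$unmapped$derivative, "D")
  expect_error(map_progenitors(emb, sim$table$cell_meta$type_label,
                               sim$table$cell_meta$timepoint,
                               derivatives = "D",
                               territories = c("D", "P1")), "disjoint")
})
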