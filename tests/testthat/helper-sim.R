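# Shared fixture builders. All fixtures are generated in code, seeded.

GENES400 <- sprintf("g%04d", 1:400)

# two well-separated types, B a child of A; knobs for bridges/doublets/drivers
two_type_spec <- function(bridge_fraction = 0, drivers = NULL,
                          birth_b = 8.5, n_genes = 400) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  lineage_spec(
    types = tibble::tibble(
      type_id = c("A", "B"), parent_id = c(NA, "A"),
      birth_time = c(8.5, birth_b), death_time = c(NA, NA),
      program = list(stats::setNames(rep(10, 25), genes[101:125]),
                     stats::setNames(rep(10, 25), genes[126:150]))),
    n_genes = n_genes, tf_genes = genes[1:100],
    bridge_fraction = bridge_fraction, drivers = drivers)
}

# single homogeneous type (null fixtures)
one_type_spec <- function(n_genes = 300) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  lineage_spec(
    types = tibble::tibble(
      type_id = "A", parent_id = NA_character_,
      birth_time = 8.5, death_time = NA_real_,
      program = list(stats::setNames(rep(10, 25), genes[101:125]))),
    n_genes = n_genes, tf_genes = genes[1:100], bridge_fraction = 0)
}

# three-type chain A -> B -> C with bridge cells at each birth
chain_spec <- function(bridge_fraction = 0.15, n_genes = 400) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  lineage_spec(
    types = tibble::tibble(
      type_id = c("A", "B", "C"), parent_id = c(NA, "A", "B"),
      birth_time = c(8.5, 9.0, 9.5), death_time = c(NA, NA, NA),
      program = list(stats::setNames(rep(10, 25), genes[101:125]),
                     stats::setNames(rep(10, 25), genes[126:150]),
                     stats::setNames(rep(10, 25), genes[151:175]))),
    n_genes = n_genes, tf_genes = genes[1:100],
    bridge_fraction = bridge_fraction)
}

# abrupt perinatal-shift type Z plus a drift-only control A, long time series
abrupt_spec <- function(n_genes = 400) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  lineage_spec(
    types = tibble::tibble(
      type_id = c("A", "Z"), parent_id = c(NA, "A"),
      birth_time = c(16.5, 16.5), death_time = c(NA, NA),
      program = list(stats::setNames(rep(10, 25), genes[101:125]),
                     stats::setNames(rep(10, 25), genes[126:150]))),
    n_genes = n_genes, tf_genes = genes[1:100], bridge_fraction = 0,
    abrupt_types = "Z",
    abrupt_programs = list(Z = stats::setNames(rep(10, 25), genes[151:175])),
    drift = dplyr::bind_rows(
      tibble::tibble(type_id = "A", gene = genes[176:183], log_fc = 1),
      tibble::tibble(type_id = "Z", gene = genes[184:191], log_fc = 1)))
}

# tiny deterministic cell_table built by hand
toy_table <- function(counts, timepoint = 9, type = "A") {
  n <- nrow(counts)
  rownames(counts) <- sprintf("c%03d", seq_len(n))
  colnames(counts) <- sprintf("g%04d", seq_len(ncol(counts)))
  cell_table(counts,
             tibble::tibble(cell_id = rownames(counts),
                            embryo_id = "e1",
                            timepoint = rep_len(timepoint, n),
                            type_label = rep_len(type, n)))
}

PRINTED_GROWTH <- c(-35.469755, 10.397036, -0.583861, 0.011369)
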