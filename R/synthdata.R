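#' Specify a synthetic cell-type lineage
#'
#' A `lineage_spec` describes the ground truth of a synthetic embryo series:
#' a rooted tree of cell types, each with a birth/death window on the time
#' axis and a gene expression program; optional bridge cells along
#' parent-to-child transitions, designated transcription-factor genes, types
#' whose program switches abruptly at the final timepoint, planted
#' transition-driver genes, and per-type temporal drift.
#'
#' Expression programs are multiplicative weights over a flat baseline: a
#' program entry of 10 means that gene's expected share of the library is 10x
#' that of a background gene.
#'
#' @param types Tibble with columns `type_id`, `parent_id` (`NA` for the
#'   single root), `birth_time`, `death_time` (`NA` = persists to the end),
#'   and `program` (list column of named numeric vectors: gene id -> weight
#'   multiplier > 0).
#' @param n_genes Total number of genes `g0001 ... gNNNN`.
#' @param tf_genes Character vector of genes flagged as transcription
#'   factors; must be a subset of the gene universe.
#' @param bridge_fraction Fraction of all simulated cells placed on
#'   parent-to-child transitions, in `[0, 1)`; the budget is split evenly
#'   across transitions, and each transition's bridge cells are carved half
#'   from the parent's and half from the child's allocation at the child's
#'   birth timepoint.
#' @param abrupt_types Type ids whose program is replaced by `abrupt_programs`
#'   at the final simulated timepoint only.
#' @param abrupt_programs Named list (by type id) of replacement programs.
#' @param drivers Optional tibble `(parent, child, gene, lnfc, phase)` of
#'   planted transition drivers; `phase` is `"early"` (parent-side bridge
#'   cells), `"internode"` (all bridge cells) or `"late"` (child-side bridge
#'   cells). The gene's weight is multiplied by `exp(lnfc)` in those cells.
#' @param drift Optional tibble `(type_id, gene, log_fc)`: the gene's
#'   log-weight in that type increases linearly from 0 to `log_fc` across the
#'   type's alive window, emulating gradual temporal drift.
#' @return A validated `lineage_spec` object.
#' @export
lineage_spec <- function(types, n_genes, tf_genes = character(),
                         bridge_fraction = 0.1,
                         abrupt_types = character(),
                         abrupt_programs = list(),
                         drivers = NULL, drift = NULL) {
  types <- tibble::as_tibble(types)
  stopifnot(all(c("type_id", "parent_id", "birth_time", "death_time",
                  "program") %in% names(types)))
  genes <- gene_ids(n_genes)
  roots <- which(is.na(types$parent_id))
  if (length(roots) != 1) stop("lineage must have exactly one root")
  for (r in seq_len(nrow(types))) {
    pid <- types$parent_id[r]
    if (!is.na(pid)) {
      p <- match(pid, types$type_id)
      if (is.na(p)) stop("unknown parent_id: ", pid)
      if (types$birth_time[r] < types$birth_time[p]) {
        stop("child must not be born before its parent: ", types$type_id[r])
      }
    }
    prog <- types$program[[r]]
    if (length(prog) == 0 || any(prog <= 0)) {
      stop("program effect sizes must be > 0 for ", types$type_id[r])
    }
    if (!all(names(prog) %in% genes)) {
      stop("program genes exceed the gene universe for ", types$type_id[r])
    }
  }
  if (!all(tf_genes %in% genes)) stop("tf_genes must be a subset of all genes")
  if (bridge_fraction < 0 || bridge_fraction >= 1) {
    stop("bridge_fraction must be in [0, 1)")
  }
  if (!all(abrupt_types %in% types$type_id)) stop("unknown abrupt_types")
  for (a in abrupt_types) {
    if (is.null(abrupt_programs[[a]])) {
      stop("abrupt type ", a, " needs an entry in abrupt_programs")
    }
    if (!all(names(abrupt_programs[[a]]) %in% genes)) {
      stop("abrupt program genes exceed the gene universe for ", a)
    }
  }
  if (!is.null(drivers)) {
    drivers <- tibble::as_tibble(drivers)
    stopifnot(all(c("parent", "child", "gene", "lnfc", "phase") %in% names(drivers)))
    if (!all(drivers$gene %in% genes)) stop("driver genes exceed the gene universe")
  }
  if (!is.null(drift)) {
    drift <- tibble::as_tibble(drift)
    stopifnot(all(c("type_id", "gene", "log_fc") %in% names(drift)))
  }
  structure(list(types = types, n_genes = n_genes, genes = genes,
                 tf_genes = tf_genes, bridge_fraction = bridge_fraction,
                 abrupt_types = abrupt_types, abrupt_programs = abrupt_programs,
                 drivers = drivers, drift = drift),
            class = "lineage_spec")
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Default ten-type synthetic lineage
#'
#' A balanced ten-type tree staggered over eight half-day timepoints (E8.5 to
#' E12.0), each type alive for a window of three to four timepoints. Types
#' carry disjoint 25-gene programs (weight 10 over baseline), so that
#' transcriptional adjacency between types arises only through bridge cells;
#' the terminal type `T10` switches to a disjoint program at the final
#' timepoint, emulating an abrupt perinatal shift. Genes `g0001..g0100` are
#' flagged as transcription factors; each type additionally drifts mildly
#' (eight genes, one natural-log unit across its window) so that time is
#' weakly encoded in every type's transcriptome.
#'
#' @param n_genes Gene universe size (default 500).
#' @param program_size Genes per type program (default 25).
#' @param effect_size Program weight multiplier (default 10).
#' @param bridge_fraction Fraction of transition cells (default 0.1).
#' @param n_drift_genes,drift_log_fc Per-type drift configuration.
#' @return A `lineage_spec`.
#' @export
default_lineage_spec <- function(n_genes = 500, program_size = 25,
                                 effect_size = 10, bridge_fraction = 0.1,
                                 n_drift_genes = 8, drift_log_fc = 1) {
  genes <- gene_ids(n_genes)
  days <- seq(8.5, by = 0.5, length.out = 8)
  tree <- tibble::tribble(
    ~type_id, ~parent_id, ~b, ~d,
    "T1",  NA,   1, 3,
    "T2",  "T1", 2, 4,
    "T3",  "T1", 2, 4,
    "T4",  "T2", 3, 5,
    "T5",  "T2", 3, 5,
    "T6",  "T3", 3, 5,
    "T7",  "T4", 4, 6,
    "T8",  "T6", 4, 6,
    "T9",  "T7", 5, 7,
    "T10", "T8", 5, 8
  )
  n_types <- nrow(tree)
  # disjoint programs drawn from genes after the TF block (g0101 onward)
  need <- program_size * (n_types + 1)  # +1 for the abrupt replacement program
  if (100 + need > n_genes) stop("n_genes too small for disjoint programs")
  prog_pool <- genes[100 + seq_len(need)]
  programs <- lapply(seq_len(n_types), function(i) {
    g <- prog_pool[(i - 1) * program_size + seq_len(program_size)]
    stats::setNames(rep(effect_size, program_size), g)
  })
  abrupt_prog <- stats::setNames(
    rep(effect_size, program_size),
    prog_pool[n_types * program_size + seq_len(program_size)])
  types <- tibble::tibble(
    type_id = tree$type_id, parent_id = tree$parent_id,
    birth_time = days[tree$b], death_time = days[tree$d],
    program = programs)
  # deterministic per-type drift genes from the TF block tail + background
  drift_pool <- genes[seq(100 + need + 1, n_genes)]
  drift <- purrr::map_dfr(seq_len(n_types), function(i) {
    g <- drift_pool[((i - 1) * n_drift_genes + seq_len(n_drift_genes) - 1) %%
                      length(drift_pool) + 1]
    tibble::tibble(type_id = tree$type_id[i], gene = g, log_fc = drift_log_fc)
  })
  lineage_spec(types, n_genes = n_genes, tf_genes = genes[1:100],
               bridge_fraction = bridge_fraction,
               abrupt_types = "T10",
               abrupt_programs = list(T10 = abrupt_prog),
               drift = drift)
}

#' Simulation configuration for the synthetic embryo series
#'
#' Defaults emulate the statistical structure of a whole-embryo single-nucleus
#' atlas at desk scale: negative-binomial counts with lognormal library sizes
#' whose median matches the ~2,700 UMIs/nucleus reported for sci-RNA-seq3
#' nuclei, a 6% doublet rate, and two embryos (alternating sex) per timepoint.
#'
#' @param timepoints Strictly increasing vector of embryonic days.
#' @param cells_per_timepoint Singlet cells simulated per timepoint (>= 1).
#' @param doublet_rate Fraction of spiked doublets, in `[0, 0.5)`.
#' @param doublet_mode `"random"` (uniform same-timepoint pairs) or
#'   `"heterotypic"` (pairs forced across types where possible).
#' @param library_size_log_mean,library_size_log_sd Lognormal library size
#'   parameters; the default meanlog `log(2700)` puts the median total at
#'   ~2,700 UMIs.
#' @param nb_dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param embryos_per_timepoint Embryos per timepoint; cells are assigned
#'   round-robin and embryo sexes alternate.
#' @param add_sex_genes Append `Xist` and three chrY genes with sex-dependent
#'   expression (enables sex assignment testing).
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(timepoints, cells_per_timepoint = 2500,
                       doublet_rate = 0.06,
                       doublet_mode = c("random", "heterotypic"),
                       library_size_log_mean = log(2700),
                       library_size_log_sd = 0.35,
                       nb_dispersion = 2,
                       embryos_per_timepoint = 2,
                       add_sex_genes = TRUE,
                       seed = 1L) {
  doublet_mode <- match.arg(doublet_mode)
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  if (cells_per_timepoint < 1) stop("cells_per_timepoint must be >= 1")
  if (doublet_rate < 0 || doublet_rate >= 0.5) {
    stop("doublet_rate must be in [0, 0.5)")
  }
  structure(list(timepoints = timepoints,
                 cells_per_timepoint = cells_per_timepoint,
                 doublet_rate = doublet_rate, doublet_mode = doublet_mode,
                 library_size_log_mean = library_size_log_mean,
                 library_size_log_sd = library_size_log_sd,
                 nb_dispersion = nb_dispersion,
                 embryos_per_timepoint = embryos_per_timepoint,
                 add_sex_genes = add_sex_genes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

SEX_GENES <- c("Xist", "Ddx3y", "Eif2s3y", "Uty")

# weight vector over the full gene universe for one (type, timepoint)
type_weights <- function(spec, type_id, timepoint, final_timepoint) {
  r <- match(type_id, spec$types$type_id)
  w <- stats::setNames(rep(1, spec$n_genes), spec$genes)
  prog <- spec$types$program[[r]]
  if (type_id %in% spec$abrupt_types && timepoint == final_timepoint) {
    prog <- spec$abrupt_programs[[type_id]]
  }
  w[names(prog)] <- w[names(prog)] * prog
  if (!is.null(spec$drift)) {
    dr <- spec$drift[spec$drift$type_id == type_id, ]
    if (nrow(dr) > 0) {
      b <- spec$types$birth_time[r]
      d <- spec$types$death_time[r]
      if (is.na(d)) d <- final_timepoint
      frac <- if (d > b) pmin(1, pmax(0, (timepoint - b) / (d - b))) else 1
      w[dr$gene] <- w[dr$gene] * exp(dr$log_fc * frac)
    }
  }
  w
}

# NB counts for a block of cells sharing a weight matrix (cells x genes of
# relative weights); libs = target library sizes
nb_block <- function(wmat, libs, size) {
  p <- wmat / rowSums(wmat)
  mu <- p * libs
  cnt <- stats::rnbinom(length(mu), mu = as.vector(mu), size = size)
  matrix(cnt, nrow = nrow(mu), dimnames = dimnames(wmat))
}

#' Simulate a synthetic embryo-series atlas
#'
#' Draws a seeded cell-by-gene UMI matrix with known ground truth. Counts are
#' negative-binomial around type-program means scaled by lognormal library
#' sizes; bridge cells interpolate parent and child programs in log-weight
#' space with a Uniform(0,1) mixing weight; doublets are elementwise sums of
#' two same-timepoint cells binomially thinned to a single sampled library
#' size; abrupt types swap in a disjoint program at the final timepoint only.
#'
#' @param spec A [lineage_spec].
#' @param config A [sim_config].
#' @return An `atlas_sim`: list with `table` (a [cell_table]), `truth`
#'   (tibble: `cell_id`, `true_type`, `true_phase`, `true_is_doublet`,
#'   `doublet_type_a`, `doublet_type_b`, `bridge_lambda`), `driver_truth`
#'   (tibble of planted drivers, possibly empty), plus the `spec` and
#'   `config` used.
#' @export
simulate_atlas <- function(spec, config) {
  stopifnot(inherits(spec, "lineage_spec"), inherits(config, "sim_config"))
  tps <- config$timepoints
  root_birth <- spec$types$birth_time[is.na(spec$types$parent_id)]
  if (any(tps < root_birth)) {
    stop("timepoints before the root's birth_time are invalid")
  }
  final_tp <- tps[length(tps)]
  genes <- spec$genes
  all_genes <- if (config$add_sex_genes) c(genes, SEX_GENES) else genes
  # transition inventory: children born at a simulated timepoint with their
  # parent alive there; the bridge budget is bridge_fraction of all cells,
  # split evenly across these transitions
  alive_at <- function(t) spec$types$type_id[
    spec$types$birth_time <= t &
      (is.na(spec$types$death_time) | spec$types$death_time >= t)]
  n_transitions <- sum(vapply(tps, function(t) {
    b <- spec$types[spec$types$birth_time == t & !is.na(spec$types$parent_id), ]
    sum(b$parent_id %in% alive_at(t))
  }, 0))
  per_side <- if (n_transitions > 0) {
    round(spec$bridge_fraction * config$cells_per_timepoint * length(tps) /
            (2 * n_transitions))
  } else 0
  with_seed(config$seed, {
    blocks <- list(); meta <- list(); truth <- list()
    cell_no <- 0L
    for (ti in seq_along(tps)) {
      t <- tps[ti]
      alive <- spec$types$type_id[
        spec$types$birth_time <= t &
          (is.na(spec$types$death_time) | spec$types$death_time >= t)]
      if (length(alive) == 0) stop("no types alive at timepoint ", t)
      n_t <- config$cells_per_timepoint
      alloc <- rep(n_t %/% length(alive), length(alive))
      if (n_t %% length(alive) > 0) {
        alloc[seq_len(n_t %% length(alive))] <- alloc[seq_len(n_t %% length(alive))] + 1
      }
      names(alloc) <- alive
      # transitions whose child is born at this timepoint and parent alive
      born <- spec$types[spec$types$birth_time == t & !is.na(spec$types$parent_id), ]
      born <- born[born$parent_id %in% alive, ]
      # per-type singlet cells; carve out bridge cells per transition
      plan <- tibble::tibble(type = rep(alive, alloc), lambda = NA_real_,
                             bridge_parent = NA_character_,
                             bridge_child = NA_character_)
      if (nrow(born) > 0 && per_side > 0) {
        for (bi in seq_len(nrow(born))) {
          ch <- born$type_id[bi]; pa <- born$parent_id[bi]
          for (side in c(pa, ch)) {
            cand <- which(plan$type == side & is.na(plan$bridge_child))
            # leave at least 20% of the side settled
            n_br <- min(per_side, floor(0.8 * length(cand)))
            if (n_br > 0) {
              pick <- cand[seq_len(n_br)]
              plan$lambda[pick] <- stats::runif(n_br)
              plan$bridge_parent[pick] <- pa
              plan$bridge_child[pick] <- ch
            }
          }
        }
      }
      is_bridge <- !is.na(plan$bridge_child)
      # observed label for bridges follows the nearer end of the transition
      plan$label <- plan$type
      plan$label[is_bridge] <- ifelse(plan$lambda[is_bridge] < 0.5,
                                      plan$bridge_parent[is_bridge],
                                      plan$bridge_child[is_bridge])
      plan$phase <- "settled"
      plan$phase[is_bridge] <- "bridge"
      plan$phase[!is_bridge & plan$type %in% born$parent_id] <- "progenitor"
      m <- nrow(plan)
      # embryo assignment and sex
      emb_idx <- (seq_len(m) - 1L) %% config$embryos_per_timepoint + 1L
      embryo <- sprintf("embryo_t%02d_%d", ti, emb_idx)
      sex <- ifelse(emb_idx %% 2 == 1, "F", "M")
      # weight rows
      wcache <- lapply(stats::setNames(alive, alive), type_weights,
                       spec = spec, timepoint = t, final_timepoint = final_tp)
      wmat <- matrix(0, m, spec$n_genes, dimnames = list(NULL, genes))
      for (r in seq_len(m)) {
        if (is_bridge[r]) {
          wp <- log(wcache[[plan$bridge_parent[r]]])
          wc <- log(wcache[[plan$bridge_child[r]]])
          wmat[r, ] <- exp((1 - plan$lambda[r]) * wp + plan$lambda[r] * wc)
        } else {
          wmat[r, ] <- wcache[[plan$type[r]]]
        }
      }
      # planted drivers act on bridge cells of their edge
      if (!is.null(spec$drivers)) {
        for (di in seq_len(nrow(spec$drivers))) {
          dv <- spec$drivers[di, ]
          on_edge <- is_bridge & plan$bridge_parent == dv$parent &
            plan$bridge_child == dv$child
          hit <- switch(dv$phase,
                        early = on_edge & plan$lambda < 0.5,
                        internode = on_edge,
                        late = on_edge & plan$lambda >= 0.5)
          hit[is.na(hit)] <- FALSE
          wmat[hit, dv$gene] <- wmat[hit, dv$gene] * exp(dv$lnfc)
        }
      }
      if (config$add_sex_genes) {
        sexw <- matrix(0.05, m, length(SEX_GENES),
                       dimnames = list(NULL, SEX_GENES))
        sexw[sex == "F", "Xist"] <- 3
        sexw[sex == "M", c("Ddx3y", "Eif2s3y", "Uty")] <- 1
        wmat <- cbind(wmat, sexw)
      }
      libs <- stats::rlnorm(m, config$library_size_log_mean,
                            config$library_size_log_sd)
      cnt <- nb_block(wmat, libs, config$nb_dispersion)
      ids <- sprintf("cell_%06d", cell_no + seq_len(m))
      cell_no <- cell_no + m
      rownames(cnt) <- ids
      # spiked doublets for this timepoint
      n_d <- round(config$doublet_rate * m)
      d_truth <- NULL
      if (n_d > 0) {
        a <- sample.int(m, n_d, replace = TRUE)
        b <- sample.int(m, n_d, replace = TRUE)
        if (config$doublet_mode == "heterotypic") {
          for (r in seq_len(n_d)) {
            other <- which(plan$type != plan$type[a[r]])
            if (length(other) > 0) b[r] <- other[sample.int(length(other), 1)]
          }
        }
        dlib <- stats::rlnorm(n_d, config$library_size_log_mean,
                              config$library_size_log_sd)
        dsum <- cnt[a, , drop = FALSE] + cnt[b, , drop = FALSE]
        thin <- pmin(1, dlib / pmax(1, rowSums(dsum)))
        dcnt <- matrix(stats::rbinom(length(dsum), size = as.vector(dsum),
                                     prob = rep(thin, ncol(dsum))),
                       nrow = n_d, dimnames = list(NULL, colnames(dsum)))
        d_ids <- sprintf("cell_%06d", cell_no + seq_len(n_d))
        cell_no <- cell_no + n_d
        rownames(dcnt) <- d_ids
        cnt <- rbind(cnt, dcnt)
        ids <- c(ids, d_ids)
        d_emb <- embryo[a]; d_sex <- sex[a]
        embryo <- c(embryo, d_emb); sex <- c(sex, d_sex)
        plan_lab <- c(plan$label, plan$label[a])
        d_truth <- tibble::tibble(
          cell_id = d_ids, true_type = plan$label[a], true_phase = "doublet",
          true_is_doublet = TRUE, doublet_type_a = plan$label[a],
          doublet_type_b = plan$label[b], bridge_lambda = NA_real_)
      } else {
        plan_lab <- plan$label
      }
      blocks[[ti]] <- Matrix::Matrix(cnt, sparse = TRUE)
      meta[[ti]] <- tibble::tibble(
        cell_id = ids, embryo_id = embryo, timepoint = t,
        type_label = plan_lab, sex = sex)
      truth[[ti]] <- dplyr::bind_rows(
        tibble::tibble(cell_id = ids[seq_len(m)], true_type = plan$label,
                       true_phase = plan$phase, true_is_doublet = FALSE,
                       doublet_type_a = NA_character_,
                       doublet_type_b = NA_character_,
                       bridge_lambda = plan$lambda),
        d_truth)
    }
    counts <- do.call(rbind, blocks)
    cell_meta <- dplyr::bind_rows(meta)
    truth <- dplyr::bind_rows(truth)
    gene_meta <- tibble::tibble(
      gene_id = all_genes,
      is_tf = all_genes %in% spec$tf_genes,
      biotype = "protein_coding")
    tab <- cell_table(counts, cell_meta, gene_meta)
    # drop cells that drew an empty library (possible at tiny sizes)
    keep <- tab$cell_meta$umi_total > 0
    if (!all(keep)) {
      tab <- filter_cells(tab, which(keep))
      truth <- truth[keep, ]
    }
    driver_truth <- if (is.null(spec$drivers)) {
      tibble::tibble(parent = character(), child = character(),
                     gene = character(), lnfc = numeric(), phase = character())
    } else spec$drivers
    structure(list(table = tab, truth = truth, driver_truth = driver_truth,
                   spec = spec, config = config),
              class = "atlas_sim")
  })
}

#' @export
print.atlas_sim <- function(x, ...) {
  cat(sprintf("<atlas_sim> %d cells x %d genes, %d timepoints, %d doublets\n",
              nrow(x$table$counts), ncol(x$table$counts),
              length(x$config$timepoints), sum(x$truth$true_is_doublet)))
  invisible(x)
}

#' Simulate an embryo growth series
#'
#' Draws `(day, cell_count)` points from a cubic log2 growth law with
#' optional lognormal-in-log2 noise: `log2(count) = polynomial(day) +
#' Normal(0, noise_sd)`.
#'
#' @param model A `growth_model` (see [fit_growth()]) or a length-4 numeric
#'   vector of coefficients `(intercept, day, day^2, day^3)`.
#' @param days Non-empty numeric vector of embryonic days.
#' @param noise_sd Gaussian noise SD in log2 units (>= 0).
#' @param seed Optional integer seed.
#' @return Tibble with columns `day`, `cell_count` (positive).
#' @export
simulate_growth_series <- function(model, days, noise_sd = 0, seed = NULL) {
  stopifnot(length(days) >= 1, noise_sd >= 0)
  cf <- if (inherits(model, "growth_model")) model$coefficients else model
  cf <- unname(cf)
  stopifnot(length(cf) == 4)
  run <- function() {
    l2 <- cf[1] + cf[2] * days + cf[3] * days^2 + cf[4] * days^3 +
      stats::rnorm(length(days), 0, noise_sd)
    tibble::tibble(day = days, cell_count = 2^l2)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
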