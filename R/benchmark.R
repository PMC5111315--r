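# End-to-end benchmark on synthetic data: does greedy facility-location
# selection recover the planted block structure, and do its panels beat
# random panels on the three quality metrics? Used both by the acceptance
# tests and by scripts/acceptance.R.

#' Block-structure recovery rate of future-mode selection
#'
#' For each of `n_seeds` synthetic datasets, builds the future-mode
#' similarity over assay types for the first cell type (aggregating over
#' the other cell types), selects a panel of one slot per block, and checks
#' whether the panel covers every block exactly once.
#'
#' @param seed base RNG seed; dataset `i` uses `seed * 1000 + i`.
#' @param n_seeds number of replicate datasets (default 20).
#' @param config a [synthetic_config()].
#' @return list with `rate` (fraction of seeds recovering the structure)
#'   and `hits` (logical per seed).
#' @export
block_recovery <- function(seed = 1L, n_seeds = 20L,
                           config = synthetic_config()) {
  hits <- vapply(seq_len(n_seeds), function(i) {
    ds <- simulate_assays(config, seed = (seed * 1000 + i) %% .Machine$integer.max)
    sim <- build_similarity_future(ds$signal, ds$catalog, target_cell = "c1")
    panel <- ssa(sim, k = config$n_blocks)$items
    blocks <- ds$truth[panel]
    identical(sort(unname(blocks)), seq_len(config$n_blocks))
  }, logical(1))
  list(rate = mean(hits), hits = hits)
}

#' Compare facility-location panels to random panels on the three metrics
#'
#' Runs the source/target cross-validation design on one synthetic cell
#' type: the cell's assays are split into `n_folds` folds; for each fold
#' (the target set) a panel of size `k` is selected from the source assays
#' by past-mode facility-location maximization, alongside `n_random`
#' uniformly random source panels of the same size, and all panels are
#' scored with theta, gamma and alpha against the fold. Metrics are
#' averaged over folds, and the fraction of random panels strictly beaten
#' by the selected panel is reported per metric.
#'
#' Metric sample sizes default to values scaled to the synthetic genome
#' (see the package vignette); a single hyperparameter point is used so
#' that all `n_random + 1` panels are scored under identical settings.
#'
#' @param seed RNG seed controlling the dataset, folds and random panels.
#' @param n_random number of random comparison panels (default 40).
#' @param config a [synthetic_config()].
#' @param k panel size (default: number of blocks).
#' @param n_folds folds of the cell's assays (default 3, so each target
#'   set spans the blocks).
#' @param cell evaluated cell type (default `"c1"`).
#' @param imputation,elements metric configurations; defaults are scaled
#'   to `config$n_positions`.
#' @param n_labels,restarts annotation settings.
#' @return list with `ssa` (named fold-averaged metrics of the selected
#'   panel), `random` (matrix `n_random` x metrics), `frac_beaten` (named
#'   per-metric fraction of random panels with strictly lower fold-averaged
#'   score), `panels` (selected panel per fold), `objective`
#'   (facility-location value of the selected panel per fold) and
#'   `random_objective` (fold-averaged objective per random panel),
#'   plus the per-fold values `random_by_fold` (panel x metric x fold) and
#'   `random_objective_by_fold` (panel x fold) for relating the objective
#'   to the metrics panel by panel.
#' @export
panel_comparison <- function(seed = 1L, n_random = 40L,
                             config = synthetic_config(),
                             k = config$n_blocks, n_folds = 3L, cell = "c1",
                             imputation = NULL, elements = NULL,
                             n_labels = 15L, restarts = 5L) {
  ds <- simulate_assays(config, seed = (seed * 1000) %% .Machine$integer.max)
  ids <- assays_in_cell(ds$catalog, cell)
  n <- ds$config$n_positions
  imputation <- imputation %||%
    imputation_config(n_train = min(1200L, n %/% 4L),
                      n_test = min(600L, n %/% 8L),
                      cost = 10, gamma = NULL, seed = seed)
  elements <- elements %||% {
    npk <- round(config$peak_top_fraction * n)
    element_config(n_pos_train = ceiling(npk * 0.6),
                   n_neg_train = min(1500L, n %/% 3L),
                   n_pos_test = floor(npk * 0.4),
                   n_neg_test = min(1000L, n %/% 5L),
                   cost = 10, gamma = NULL, seed = seed)
  }
  folds <- make_folds(ids, n_folds = n_folds, seed = seed + 1)
  # one fixed family of random panels, re-drawn per fold from that fold's
  # source set
  metrics <- c("theta", "gamma", "alpha")
  acc_ssa <- matrix(NA_real_, n_folds, 3L, dimnames = list(NULL, metrics))
  acc_rand <- array(NA_real_, c(n_random, 3L, n_folds),
                    dimnames = list(NULL, metrics, NULL))
  panels <- list()
  objectives <- numeric(n_folds)
  rand_obj <- matrix(NA_real_, n_random, n_folds)
  for (i in seq_len(n_folds)) {
    targets <- folds[[i]]
    source_ids <- setdiff(ids, targets)
    sim <- build_similarity_past(ds$signal, assay_ids = source_ids)
    fit <- ssa(sim, k = k)
    panels[[i]] <- fit$items
    objectives[i] <- fit$objective
    score <- function(panel) {
      rep_i <- evaluate_panel(ds$signal, panel, targets, peaks = ds$peaks,
                              imputation = imputation, elements = elements,
                              n_labels = n_labels, restarts = restarts,
                              seed = seed)
      s <- attr(rep_i, "summary")
      vapply(metrics, function(mm) if (mm %in% names(s)) s[[mm]] else NA_real_,
             numeric(1))
    }
    acc_ssa[i, ] <- score(fit$items)
    rand_panels <- with_seed(seed + 100 + i, {
      lapply(seq_len(n_random), function(j) sample(source_ids, k))
    })
    for (j in seq_len(n_random)) {
      acc_rand[j, , i] <- score(rand_panels[[j]])
      rand_obj[j, i] <- facility_location(rand_panels[[j]], sim)
    }
  }
  ssa_avg <- colMeans(acc_ssa, na.rm = TRUE)
  rand_avg <- apply(acc_rand, c(1L, 2L), mean, na.rm = TRUE)
  frac_beaten <- vapply(metrics, function(mm) {
    mean(rand_avg[, mm] < ssa_avg[[mm]])
  }, numeric(1))
  list(ssa = ssa_avg, random = rand_avg, frac_beaten = frac_beaten,
       panels = panels, objective = objectives,
       random_objective = rowMeans(rand_obj),
       random_by_fold = acc_rand, random_objective_by_fold = rand_obj)
}

#' Worst-case ratio of greedy to exhaustive optimum on random instances
#'
#' Draws random facility-location instances (symmetric similarity entries
#' uniform on `[0, 1]`, unit diagonal) and returns the per-instance ratio
#' of the greedy objective to the exhaustive optimum. Theory guarantees
#' every ratio is at least `1 - 1/e`.
#'
#' @param n_instances number of random instances (default 200).
#' @param seed RNG seed.
#' @param m_max,k_max maximum ground-set size and panel size (defaults 12
#'   and 4).
#' @return numeric vector of ratios, one per instance.
#' @export
greedy_ratio_experiment <- function(n_instances = 200L, seed = 1L,
                                    m_max = 12L, k_max = 4L) {
  with_seed(seed, {
    vapply(seq_len(n_instances), function(i) {
      m <- sample(3:m_max, 1L)
      k <- sample(seq_len(min(k_max, m)), 1L)
      r <- random_similarity(m)
      g <- greedy_select(r, k)$objective
      opt <- brute_force_select(r, k)$objective
      g / opt
    }, numeric(1))
  })
}

# Random symmetric similarity matrix with entries U[0,1] and unit diagonal.
# Draws from the current RNG stream (wrap in with_seed for determinism).
random_similarity <- function(m) {
  r <- matrix(stats::runif(m * m), m, m)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(sprintf("i%02d", seq_len(m)), sprintf("i%02d", seq_len(m)))
  r
}
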