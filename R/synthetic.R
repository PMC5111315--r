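# Synthetic multi-cell-type signal generator with known block-redundancy
# structure. Groups ("blocks") of assay types share a genome-wide latent
# factor, so tracks within a block are strongly correlated across all cell
# types while tracks in different blocks share only a weak global factor --
# the redundancy structure that panel selection is meant to exploit.

#' Configuration for the synthetic dataset generator
#'
#' @param n_blocks number of redundant groups of assay types (default 5).
#' @param types_per_block assay types per block (default 3); the first type
#'   of each block is transcription-factor-like and receives peak calls.
#' @param n_cell_types number of cell types (default 4).
#' @param n_positions genomic bins per track (default 5000; minimum 100).
#' @param rho_within target Pearson correlation between tracks in the same
#'   block (default 0.9).
#' @param rho_between target correlation between tracks in different blocks
#'   (default 0.2); must be smaller than `rho_within`.
#' @param noise_sd standard deviation of the per-(assay, cell) noise term;
#'   the default `sqrt(1 - rho_within)` calibrates the empirical
#'   within-block correlation to approximately `rho_within`.
#' @param peak_top_fraction fraction of positions called as peaks for
#'   TF-like tracks (default 0.02), in `(0, 0.5)`.
#' @param bin_width bin width in base pairs (default 100).
#' @return a list of class `ssa_synthetic_config`.
#' @export
synthetic_config <- function(n_blocks = 5L, types_per_block = 3L,
                             n_cell_types = 4L, n_positions = 5000L,
                             rho_within = 0.9, rho_between = 0.2,
                             noise_sd = NULL, peak_top_fraction = 0.02,
                             bin_width = 100L) {
  if (n_positions < 100L) stopf("n_positions must be >= 100")
  if (!(rho_within > 0 && rho_within <= 1)) stopf("rho_within must be in (0, 1]")
  if (!(rho_between >= 0 && rho_between < rho_within)) {
    stopf("need 0 <= rho_between < rho_within")
  }
  noise_sd <- noise_sd %||% sqrt(1 - rho_within)
  if (noise_sd < 0) stopf("noise_sd must be nonnegative")
  structure(list(n_blocks = as.integer(n_blocks),
                 types_per_block = as.integer(types_per_block),
                 n_cell_types = as.integer(n_cell_types),
                 n_positions = as.integer(n_positions),
                 rho_within = rho_within, rho_between = rho_between,
                 noise_sd = noise_sd, peak_top_fraction = peak_top_fraction,
                 bin_width = as.integer(bin_width)),
            class = "ssa_synthetic_config")
}

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

#' Generate a synthetic multi-cell-type assay collection
#'
#' Each track is built from standard normal genome-wide factors:
#' `x = sqrt(rho_between) g + sqrt(rho_within - rho_between) z_b +
#' noise_sd e`, where `g` is a global factor shared by all tracks (broad
#' position effects), `z_b` is the factor of the track's block, and `e` is
#' independent per (assay type, cell type). With the default `noise_sd`
#' the correlation between two distinct tracks is `rho_within` within a
#' block and `rho_between` across blocks, in every cell-type combination.
#' Raw values are made nonnegative with a softplus, like fold-enrichment
#' signal, and asinh-transformed at ingestion. TF-like types (the first of
#' each block) get peak tracks: the top `peak_top_fraction` of positions.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed; the same config and seed give a bit-identical
#'   dataset.
#' @return a list of class `ssa_dataset` with elements `signal`
#'   (an [ssa_signal()] over all assays, asinh-transformed), `catalog`
#'   (an [ssa_catalog()]), `truth` (named block id per assay type),
#'   `is_tf` (named logical per assay type), `peaks` (named list of binary
#'   vectors per TF-like assay id), `config` and `seed`.
#' @export
simulate_assays <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "ssa_synthetic_config"))
  b <- config$n_blocks
  tpb <- config$types_per_block
  ncell <- config$n_cell_types
  n <- config$n_positions
  a_global <- sqrt(config$rho_between)
  a_block <- sqrt(config$rho_within - config$rho_between)

  types <- as.vector(t(outer(seq_len(b), seq_len(tpb),
                             function(i, j) sprintf("B%dT%d", i, j))))
  truth <- rep(seq_len(b), each = tpb)
  names(truth) <- types
  is_tf <- rep(seq_len(tpb) == 1L, times = b)
  names(is_tf) <- types
  cells <- sprintf("c%d", seq_len(ncell))

  raw <- with_seed(seed, {
    g <- stats::rnorm(n)
    z <- matrix(stats::rnorm(n * b), n, b)
    out <- matrix(NA_real_, n, length(types) * ncell)
    ids <- character(ncol(out))
    col <- 0L
    for (cc in cells) {
      for (ti in seq_along(types)) {
        col <- col + 1L
        ids[col] <- paste(types[ti], cc, sep = ".")
        out[, col] <- a_global * g + a_block * z[, truth[ti]] +
          config$noise_sd * stats::rnorm(n)
      }
    }
    colnames(out) <- ids
    out
  })
  raw <- softplus(raw)
  catalog <- ssa_catalog(data.frame(
    assay_id = colnames(raw),
    assay_type = rep(rep(types, times = ncell)),
    cell_type = rep(cells, each = length(types)),
    stringsAsFactors = FALSE))
  signal <- ssa_signal(raw, bin_width = config$bin_width, transform = TRUE)
  tf_ids <- catalog$assay_id[is_tf[catalog$assay_type]]
  peaks <- lapply(tf_ids, function(id) {
    derive_peaks(signal$values[, id], config$peak_top_fraction)
  })
  names(peaks) <- tf_ids
  structure(list(signal = signal, catalog = catalog, truth = truth,
                 is_tf = is_tf, peaks = peaks, config = config, seed = seed),
            class = "ssa_dataset")
}

#' @export
print.ssa_dataset <- function(x, ...) {
  cat(sprintf(paste0("ssa_dataset: %d blocks x %d types x %d cell types, ",
                     "%d positions (seed %s)\n"),
              x$config$n_blocks, x$config$types_per_block,
              x$config$n_cell_types, x$config$n_positions,
              format(x$seed)))
  invisible(x)
}

#' Threshold a track into a binary peak vector
#'
#' Marks the top `top_fraction` of positions (by signal value) as peaks,
#' standing in for peak calls on a TF track. Exactly
#' `round(top_fraction * n)` positions are set; ties at the threshold are
#' resolved deterministically in favour of earlier positions. Because the
#' rule is a quantile, any strictly increasing transform of the track
#' yields identical peaks.
#'
#' @param values numeric track.
#' @param top_fraction fraction of positions to call, in `(0, 0.5)`.
#' @return integer 0/1 vector with `round(top_fraction * length(values))`
#'   ones.
#' @export
derive_peaks <- function(values, top_fraction) {
  if (!(top_fraction > 0 && top_fraction < 0.5)) {
    stopf("top_fraction must be in (0, 0.5)")
  }
  n <- length(values)
  k <- round(top_fraction * n)
  if (k < 1L) stopf("top_fraction %g of %d positions yields no peaks",
                    top_fraction, n)
  p <- integer(n)
  p[order(values, seq_len(n), decreasing = c(TRUE, FALSE),
          method = "radix")[seq_len(k)]] <- 1L
  p
}
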