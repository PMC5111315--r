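#' Inverse hyperbolic sine transform of signal values
#'
#' Applies `asinh(x) = ln(x + sqrt(x^2 + 1))` elementwise. This log-like
#' compression is standard for fold-enrichment genomic signal: it behaves
#' like `log(x)` for large values but is defined at zero and nearly linear
#' near zero, which damps the influence of extreme values on Pearson
#' correlation. `NA` values are preserved (they mark unspecified positions);
#' non-finite values such as `Inf` or `NaN` are an error.
#'
#' @param values numeric vector or matrix of raw signal values.
#' @param id optional track identifier used in error messages.
#' @return the transformed values, same shape as the input.
#' @examples
#' asinh_transform(c(0, 1, 10))
#' @export
asinh_transform <- function(values, id = NULL) {
  bad <- is.nan(values) | is.infinite(values)
  if (any(bad)) {
    stopf("non-finite signal value%s in track '%s'",
          if (sum(bad) > 1L) "s" else "", id %||% "<unnamed>")
  }
  asinh(values)
}

#' Construct a signal matrix of binned genomic tracks
#'
#' A signal matrix holds one real-valued track per assay, all sampled on a
#' common grid of fixed-width genomic bins (0-based, half-open). Values are
#' asinh-transformed at ingestion (once) unless `transform = FALSE`; `NA`
#' entries mark unspecified positions and each track's missing fraction is
#' recorded.
#'
#' @param values numeric matrix, positions x assays, with unique column
#'   names (assay ids).
#' @param chrom character vector of chromosome names per position; defaults
#'   to a single synthetic chromosome.
#' @param start integer vector of 0-based bin starts per position, strictly
#'   increasing within each chromosome; defaults to consecutive bins.
#' @param bin_width bin width in base pairs (default 100).
#' @param transform apply [asinh_transform()] to each track (default `TRUE`).
#'   Set to `FALSE` when reading values that were already transformed.
#' @return an object of class `ssa_signal` with fields `values`, `chrom`,
#'   `start`, `bin_width`, `transformed` and `missing_fraction`.
#' @export
ssa_signal <- function(values, chrom = NULL, start = NULL, bin_width = 100L,
                       transform = TRUE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("signal values must be numeric")
  if (is.null(colnames(values)) || anyNA(colnames(values))) {
    stopf("signal matrix needs assay ids as column names")
  }
  if (anyDuplicated(colnames(values))) {
    stopf("duplicate assay id in signal matrix: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]),
                collapse = ", "))
  }
  n <- nrow(values)
  if (n < 1L) stopf("signal matrix has no positions")
  chrom <- as.character(chrom %||% rep("chrS", n))
  start <- as.integer(start %||% ((seq_len(n) - 1L) * as.integer(bin_width)))
  if (length(chrom) != n || length(start) != n) {
    stopf("chrom/start must have one entry per position")
  }
  for (ch in unique(chrom)) {
    s <- start[chrom == ch]
    if (any(diff(s) <= 0L)) {
      stopf("positions not strictly increasing within chromosome '%s'", ch)
    }
  }
  if (transform) {
    for (j in seq_len(ncol(values))) {
      values[, j] <- asinh_transform(values[, j], id = colnames(values)[j])
    }
  }
  structure(
    list(values = values, chrom = chrom, start = start,
         bin_width = as.integer(bin_width), transformed = isTRUE(transform),
         missing_fraction = colMeans(is.na(values))),
    class = "ssa_signal")
}

#' @export
print.ssa_signal <- function(x, ...) {
  cat(sprintf("ssa_signal: %d assays x %d positions (%d bp bins, %s)\n",
              ncol(x$values), nrow(x$values), x$bin_width,
              if (x$transformed) "asinh-transformed" else "raw"))
  cat("assays:", paste(utils::head(colnames(x$values), 8L), collapse = ", "),
      if (ncol(x$values) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Per-track fraction of unspecified (NA) positions
#' @param signal an [ssa_signal()] object.
#' @return named numeric vector of missing fractions in `[0, 1]`.
#' @export
missing_fractions <- function(signal) {
  stopifnot(inherits(signal, "ssa_signal"))
  signal$missing_fraction
}

#' Drop tracks with too many unspecified positions
#'
#' Assays with more than `max_missing` fraction of unspecified positions are
#' removed: a high missing fraction typically indicates processing or
#' mapping problems. The default keeps tracks with at most 1\% missing.
#'
#' @param signal an [ssa_signal()] object.
#' @param max_missing maximum tolerated missing fraction (default 0.01).
#' @return the filtered `ssa_signal`; removed assay ids are reported via
#'   `message()`.
#' @export
filter_by_coverage <- function(signal, max_missing = 0.01) {
  stopifnot(inherits(signal, "ssa_signal"))
  keep <- signal$missing_fraction <= max_missing
  if (!any(keep)) stopf("no assays survive coverage filter")
  if (any(!keep)) {
    message("filter_by_coverage: removed ",
            paste(colnames(signal$values)[!keep], collapse = ", "))
  }
  signal$values <- signal$values[, keep, drop = FALSE]
  signal$missing_fraction <- signal$missing_fraction[keep]
  signal
}

#' Subsample genomic positions for correlation estimation
#'
#' Correlations between tracks are estimated on a uniform random subset
#' `I'` of positions; by default about 1\% of the genome, which is ample for
#' a stable Pearson estimate and much cheaper than the full genome.
#'
#' @param n_total total number of positions.
#' @param fraction fraction to sample, in `(0, 1]` (default 0.01).
#' @param seed RNG seed; the same inputs and seed give the same index set.
#' @return sorted integer vector of distinct 1-based position indices of
#'   length `round(fraction * n_total)`.
#' @export
subsample_positions <- function(n_total, fraction = 0.01, seed = 1L) {
  n_total <- as.integer(n_total)
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    stopf("`fraction` must be in (0, 1]")
  }
  size <- round(fraction * n_total)
  if (size < 1L) stopf("subsample of %d positions at fraction %g is empty",
                       n_total, fraction)
  if (fraction == 1) return(seq_len(n_total))
  sort(with_seed(seed, sample.int(n_total, size)))
}

#' Construct an assay catalog
#'
#' The catalog maps each assay id to its assay type (the protocol, e.g.
#' "H3K4me3") and cell type. Each (cell type, assay type) pair may carry at
#' most one representative assay.
#'
#' @param x data frame with columns `assay_id`, `assay_type`, `cell_type`.
#' @param dedupe if `TRUE`, keep the first assay per (cell type, assay type)
#'   pair and drop the rest with a message; if `FALSE` (default) duplicates
#'   are an error.
#' @return a validated data frame of class `ssa_catalog`.
#' @export
ssa_catalog <- function(x, dedupe = FALSE) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("assay_id", "assay_type", "cell_type")
  if (!all(need %in% names(x))) {
    stopf("catalog must have columns %s", paste(need, collapse = ", "))
  }
  x <- x[need]
  for (cc in need) x[[cc]] <- as.character(x[[cc]])
  if (anyDuplicated(x$assay_id)) stopf("duplicate assay_id in catalog")
  key <- paste(x$cell_type, x$assay_type, sep = "\r")
  if (anyDuplicated(key)) {
    if (dedupe) {
      drop <- duplicated(key)
      message("ssa_catalog: dropped ", sum(drop),
              " duplicate (cell type, assay type) assays")
      x <- x[!drop, , drop = FALSE]
    } else {
      stopf("more than one assay for a (cell type, assay type) pair; use dedupe = TRUE")
    }
  }
  rownames(x) <- NULL
  class(x) <- c("ssa_catalog", "data.frame")
  x
}

#' Assays performed in one cell type
#' @param catalog an [ssa_catalog()].
#' @param cell cell type name.
#' @return character vector of assay ids.
#' @export
assays_in_cell <- function(catalog, cell) {
  catalog$assay_id[catalog$cell_type == cell]
}

#' Assays of one assay type (across all cell types)
#' @param catalog an [ssa_catalog()].
#' @param type assay type name.
#' @return character vector of assay ids.
#' @export
assays_of_type <- function(catalog, type) {
  catalog$assay_id[catalog$assay_type == type]
}
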