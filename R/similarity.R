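#' Absolute Pearson correlation between two tracks
#'
#' The similarity between two signal vectors is `|rho|`, the absolute value
#' of their Pearson correlation, which lies in `[0, 1]`. Positions missing
#' (`NA`) in either vector are dropped pairwise before the correlation is
#' computed. A constant vector has no linear information, so the similarity
#' is defined as 0 with a warning rather than `NA`.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return a single number in `[0, 1]`.
#' @examples
#' pearson_similarity(c(1, 2, 3), c(3, 2, 1))  # 1
#' @export
pearson_similarity <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch: %d vs %d",
                                    length(x), length(y))
  if (length(x) < 2L) stopf("need at least 2 positions")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) {
    warnf("fewer than 2 complete positions; similarity set to 0")
    return(0)
  }
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warnf("constant signal vector; similarity set to 0")
    return(0)
  }
  abs(stats::cor(x, y))
}

# Pairwise |Pearson| matrix over the columns of `v`, with pairwise deletion
# of missing positions. Constant (or all-missing) columns yield 0 against
# everything, with one warning.
abs_cor_matrix <- function(v) {
  suppressWarnings(r <- abs(stats::cor(v, use = "pairwise.complete.obs")))
  if (anyNA(r)) {
    warnf("constant or empty signal vector(s); affected similarities set to 0")
    r[is.na(r)] <- 0
  }
  r
}

#' Construct a similarity matrix object
#'
#' @param values symmetric numeric matrix with entries in `[0, 1]` and
#'   matching row/column names (the ground-set item labels).
#' @param mode `"past"` (similarities computed from the target cell's own
#'   tracks; diagonal is exactly 1) or `"future"` (similarities aggregated
#'   over reference cell types).
#' @return an object of class `ssa_similarity`.
#' @export
ssa_similarity <- function(values, mode = c("past", "future")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stopf("similarity matrix must be square")
  if (is.null(colnames(values))) stopf("similarity matrix needs item labels")
  if (!identical(rownames(values), colnames(values))) {
    rownames(values) <- colnames(values)
  }
  if (anyDuplicated(colnames(values))) stopf("duplicate item labels")
  if (max(abs(values - t(values))) > 1e-8) stopf("similarity matrix not symmetric")
  values <- (values + t(values)) / 2
  if (anyNA(values) || min(values) < -1e-12 || max(values) > 1 + 1e-12) {
    stopf("similarity entries must lie in [0, 1]")
  }
  values <- pmin(pmax(values, 0), 1)
  if (mode == "past" && any(abs(diag(values) - 1) > 1e-12)) {
    stopf("past-mode similarity must have unit diagonal")
  }
  structure(list(items = colnames(values), values = values, mode = mode),
            class = "ssa_similarity")
}

#' @export
print.ssa_similarity <- function(x, ...) {
  cat(sprintf("ssa_similarity (%s mode): %d items\n", x$mode, length(x$items)))
  print(round(x$values, 3))
  invisible(x)
}

#' @export
as.matrix.ssa_similarity <- function(x, ...) x$values

# Accept either an ssa_similarity or a plain labelled matrix.
sim_values <- function(R) {
  if (inherits(R, "ssa_similarity")) return(R$values)
  R <- as.matrix(R)
  if (is.null(colnames(R))) colnames(R) <- rownames(R) %||%
      paste0("item", seq_len(ncol(R)))
  if (is.null(rownames(R))) rownames(R) <- colnames(R)
  R
}

#' Past-mode similarity: correlate the cell's own tracks
#'
#' In the "past" setting the assays of interest have already been performed
#' in the cell type at hand, so each pairwise similarity is the absolute
#' Pearson correlation of the two signal vectors themselves, optionally on a
#' random subsample of positions. The diagonal (self-similarity) is 1.
#'
#' @param signal an [ssa_signal()] restricted to the tracks of one cell type
#'   (at least 2 tracks).
#' @param assay_ids optional subset of tracks to use (default: all columns).
#' @param fraction optional fraction of positions to subsample before
#'   correlating (see [subsample_positions()]); `NULL` uses all positions.
#' @param seed RNG seed for the subsample.
#' @return an `ssa_similarity` with `mode = "past"` over the assay ids.
#' @export
build_similarity_past <- function(signal, assay_ids = NULL, fraction = NULL,
                                  seed = 1L) {
  stopifnot(inherits(signal, "ssa_signal"))
  v <- signal$values
  if (!is.null(assay_ids)) {
    miss <- setdiff(assay_ids, colnames(v))
    if (length(miss)) stopf("unknown assay id(s): %s", paste(miss, collapse = ", "))
    v <- v[, assay_ids, drop = FALSE]
  }
  if (ncol(v) < 2L) stopf("need at least 2 tracks to build a similarity matrix")
  if (!is.null(fraction)) {
    v <- v[subsample_positions(nrow(v), fraction, seed), , drop = FALSE]
  }
  r <- abs_cor_matrix(v)
  diag(r) <- 1
  ssa_similarity(r, mode = "past")
}

#' Future-mode similarity: aggregate correlations over reference cell types
#'
#' In the "future" setting, the assays have not been performed in the target
#' cell type, so the similarity between two assay types is estimated from
#' reference cell types: the mean of `|rho|` over all pairs of assays of
#' those two types performed outside the target cell. For the same-type
#' (diagonal) entries, self-pairs are excluded and the mean runs over
#' distinct cross-cell pairs; a type observed in only one reference cell has
#' its diagonal pinned to 1 (self-similarity), since no cross-pair exists.
#'
#' @param signal an [ssa_signal()] covering all cell types.
#' @param catalog an [ssa_catalog()] for the tracks in `signal`.
#' @param target_cell the cell type being designed for; its assays (if any)
#'   are excluded from the aggregation.
#' @param fraction,seed optional position subsample, as in
#'   [build_similarity_past()].
#' @return an `ssa_similarity` with `mode = "future"` whose items are the
#'   assay types observed outside the target cell.
#' @export
build_similarity_future <- function(signal, catalog, target_cell,
                                    fraction = NULL, seed = 1L) {
  stopifnot(inherits(signal, "ssa_signal"))
  catalog <- ssa_catalog(catalog)
  miss <- setdiff(catalog$assay_id, colnames(signal$values))
  if (length(miss)) stopf("catalog assay(s) missing from signal: %s",
                          paste(miss, collapse = ", "))
  ref <- catalog[catalog$cell_type != target_cell, , drop = FALSE]
  types <- lex_sort(unique(catalog$assay_type))
  orphan <- setdiff(types, unique(ref$assay_type))
  if (length(orphan)) {
    stopf("assay type(s) with no assays outside cell '%s': %s",
          target_cell, paste(orphan, collapse = ", "))
  }
  types <- lex_sort(unique(ref$assay_type))
  v <- signal$values[, ref$assay_id, drop = FALSE]
  if (!is.null(fraction)) {
    v <- v[subsample_positions(nrow(v), fraction, seed), , drop = FALSE]
  }
  rho <- abs_cor_matrix(v)
  ids_by_type <- split(ref$assay_id, ref$assay_type)
  m <- length(types)
  r <- matrix(0, m, m, dimnames = list(types, types))
  for (i in seq_len(m)) {
    for (j in i:m) {
      si <- ids_by_type[[types[i]]]
      sj <- ids_by_type[[types[j]]]
      block <- rho[si, sj, drop = FALSE]
      if (i == j) {
        if (length(si) == 1L) {
          val <- 1  # single reference assay: no cross-cell pair, self-similarity
        } else {
          val <- mean(block[row(block) != col(block)])
        }
      } else {
        val <- mean(block)
      }
      r[i, j] <- r[j, i] <- val
    }
  }
  ssa_similarity(r, mode = "future")
}
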