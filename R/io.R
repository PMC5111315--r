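# Readers and writers for the supported plain-text formats: signal TSV,
# bedGraph tracks binned onto a fixed grid, BED peak calls, catalog TSV,
# similarity TSV, panel report TSV, and annotations (TSV or BED). All
# genomic coordinates are 0-based, half-open; one matrix-wide grid (bin
# width) is declared up front so tracks cannot be silently misaligned.

#' Write a signal matrix to TSV
#'
#' Columns are `chrom`, `start`, then one column per assay. Values are
#' written as stored (transformed if the object is transformed).
#'
#' @param signal an [ssa_signal()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signal_tsv <- function(signal, path) {
  stopifnot(inherits(signal, "ssa_signal"))
  df <- data.frame(chrom = signal$chrom, start = signal$start,
                   signal$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signal matrix from TSV
#'
#' Expects the layout written by [write_signal_tsv()]: `chrom` and `start`
#' columns followed by one numeric column per assay.
#'
#' @param path input file.
#' @param bin_width bin width of the grid (default 100).
#' @param transform apply the asinh transform on read (default `TRUE`; use
#'   `FALSE` if the file already holds transformed values).
#' @return an [ssa_signal()].
#' @export
read_signal_tsv <- function(path, bin_width = 100L, transform = TRUE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("chrom", "start") %in% names(df))) {
    stopf("signal TSV must have 'chrom' and 'start' columns")
  }
  v <- as.matrix(df[setdiff(names(df), c("chrom", "start"))])
  storage.mode(v) <- "double"
  ssa_signal(v, chrom = df$chrom, start = df$start, bin_width = bin_width,
             transform = transform)
}

# Import a bedGraph/BED file via rtracklayer and return a base data frame
# with 0-based half-open coordinates.
import_intervals <- function(path, format) {
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  data.frame(chrom = as.character(df$seqnames),
             start = df$start - 1L,   # to 0-based
             end = df$end,            # half-open
             score = if ("score" %in% names(df)) df$score else NA_real_,
             stringsAsFactors = FALSE)
}

# The declared grid: bins of `bin_width` bp tiling each chromosome.
make_grid <- function(chrom_sizes, bin_width) {
  if (is.null(names(chrom_sizes)) || !is.numeric(chrom_sizes)) {
    stopf("chrom_sizes must be a named numeric vector of chromosome lengths")
  }
  nb <- ceiling(chrom_sizes / bin_width)
  chrom <- rep(names(chrom_sizes), nb)
  start <- unlist(lapply(nb, function(k) (seq_len(k) - 1L) * bin_width),
                  use.names = FALSE)
  list(chrom = chrom, start = as.integer(start), bin_width = as.integer(bin_width),
       offset = c(0L, cumsum(nb))[seq_along(nb)], n_bins = as.integer(nb))
}

# Map one interval table onto grid bins; coverage-weighted mean per bin,
# NA where nothing covers the bin.
bin_intervals <- function(iv, grid, what = c("score", "presence")) {
  what <- match.arg(what)
  total <- sum(grid$n_bins)
  acc <- numeric(total)
  wt <- numeric(total)
  for (ci in seq_along(grid$n_bins)) {
    ch <- names(grid$n_bins)[ci] %||% unique(grid$chrom)[ci]
    rows <- iv$chrom == ch
    if (!any(rows)) next
    s <- iv$start[rows]; e <- iv$end[rows]; val <- iv$score[rows]
    o <- order(s)
    s <- s[o]; e <- e[o]; val <- val[o]
    if (any(utils::head(e, -1L) > utils::tail(s, -1L))) {
      stopf("overlapping intervals on chromosome '%s'", ch)
    }
    w <- grid$bin_width
    off <- grid$offset[ci]
    nb <- grid$n_bins[ci]
    for (ii in seq_along(s)) {
      b0 <- s[ii] %/% w
      b1 <- min((e[ii] - 1L) %/% w, nb - 1L)
      if (b1 < b0) next
      for (bb in b0:b1) {
        cov <- min(e[ii], (bb + 1L) * w) - max(s[ii], bb * w)
        j <- off + bb + 1L
        if (what == "score") acc[j] <- acc[j] + cov * val[ii]
        wt[j] <- wt[j] + cov
      }
    }
  }
  if (what == "presence") return(as.integer(wt > 0))
  out <- ifelse(wt > 0, acc / wt, NA_real_)
  out
}

#' Read bedGraph tracks binned onto a declared grid
#'
#' Each bedGraph file becomes one track: every grid bin takes the
#' coverage-weighted mean of the interval values overlapping it
#' (a single interval spanning several bins repeats its value), and bins
#' covered by no interval are missing (`NA`). Overlapping intervals within
#' one file are a format violation and raise an error.
#'
#' @param files named character vector of bedGraph paths; names are the
#'   assay ids.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param bin_width grid bin width in bp (default 100).
#' @param transform apply the asinh transform (default `TRUE`).
#' @return an [ssa_signal()] on the declared grid.
#' @export
read_bedgraph_tracks <- function(files, chrom_sizes, bin_width = 100L,
                                 transform = TRUE) {
  if (is.null(names(files)) || any(!nzchar(names(files)))) {
    stopf("`files` must be named by assay id")
  }
  grid <- make_grid(chrom_sizes, bin_width)
  names(grid$n_bins) <- names(chrom_sizes)
  v <- vapply(files, function(f) {
    bin_intervals(import_intervals(f, "bedGraph"), grid, "score")
  }, numeric(sum(grid$n_bins)))
  colnames(v) <- names(files)
  ssa_signal(v, chrom = grid$chrom, start = grid$start, bin_width = bin_width,
             transform = transform)
}

#' Read BED peak calls onto a declared grid
#'
#' A bin is a peak position (`1`) if any peak interval overlaps it;
#' duplicate or overlapping peak intervals are idempotent. An empty BED
#' file yields an all-zero vector with a warning.
#'
#' @param path BED file (BED3 or richer), 0-based half-open.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param bin_width grid bin width in bp (default 100).
#' @return integer 0/1 vector over the grid bins.
#' @export
read_peaks <- function(path, chrom_sizes, bin_width = 100L) {
  grid <- make_grid(chrom_sizes, bin_width)
  names(grid$n_bins) <- names(chrom_sizes)
  iv <- tryCatch(import_intervals(path, "BED"),
                 error = function(e) {
                   if (file.exists(path) && file.size(path) == 0) {
                     data.frame(chrom = character(), start = integer(),
                                end = integer(), score = numeric())
                   } else stop(e)
                 })
  if (nrow(iv) == 0L) {
    warnf("empty BED file '%s'; no peak positions", path)
    return(integer(sum(grid$n_bins)))
  }
  # peaks may legitimately overlap; merge before binning
  p <- integer(sum(grid$n_bins))
  for (ci in seq_along(grid$n_bins)) {
    ch <- names(grid$n_bins)[ci]
    rows <- which(iv$chrom == ch)
    w <- grid$bin_width
    nb <- grid$n_bins[ci]
    off <- grid$offset[ci]
    for (ii in rows) {
      b0 <- iv$start[ii] %/% w
      b1 <- min((iv$end[ii] - 1L) %/% w, nb - 1L)
      if (b1 >= b0) p[off + (b0:b1) + 1L] <- 1L
    }
  }
  p
}

#' Read an assay catalog TSV
#'
#' Header columns `assay_id`, `assay_type`, `cell_type`.
#'
#' @param path input file.
#' @param dedupe passed to [ssa_catalog()].
#' @return an [ssa_catalog()].
#' @export
read_catalog <- function(path, dedupe = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ssa_catalog(df, dedupe = dedupe)
}

#' Write a similarity matrix to TSV
#'
#' The mode is recorded on a leading comment line; the body is a labelled
#' square matrix.
#'
#' @param similarity an [ssa_similarity()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(similarity, path) {
  stopifnot(inherits(similarity, "ssa_similarity"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# mode: ", similarity$mode), con)
  utils::write.table(data.frame(item = similarity$items, similarity$values,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix from TSV
#' @param path file written by [write_similarity_tsv()].
#' @return an [ssa_similarity()].
#' @export
read_similarity_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  mode <- if (grepl("^# mode: ", first)) sub("^# mode: ", "", first) else "past"
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1L, drop = FALSE])
  rownames(v) <- df$item
  ssa_similarity(v, mode = mode)
}

#' Write a panel report TSV
#'
#' Columns `rank`, `item`, `singleton_score`, `gain`,
#' `cumulative_objective`, mirroring the standard panel table layout.
#'
#' @param panel an `ssa_panel` from [ssa()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_panel_report <- function(panel, path) {
  stopifnot(inherits(panel, "ssa_panel"))
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an annotation as label-per-bin TSV or BED
#'
#' TSV has columns `chrom`, `start`, `label`; BED writes one
#' resolution-sized interval per bin with the integer label in the name
#' column.
#'
#' @param annotation an `ssa_annotation` (or integer label vector).
#' @param path output file.
#' @param signal optional [ssa_signal()] supplying coordinates; defaults to
#'   consecutive bins on one synthetic chromosome.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, signal = NULL,
                             format = c("tsv", "bed")) {
  format <- match.arg(format)
  labels <- if (inherits(annotation, "ssa_annotation")) annotation$labels
            else as.integer(annotation)
  res <- if (inherits(annotation, "ssa_annotation")) annotation$resolution
         else 100L
  n <- length(labels)
  chrom <- if (!is.null(signal)) signal$chrom else rep("chrS", n)
  start <- if (!is.null(signal)) signal$start else (seq_len(n) - 1L) * res
  if (format == "tsv") {
    utils::write.table(data.frame(chrom = chrom, start = start, label = labels),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(data.frame(chrom, start, start + res, labels),
                       path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read an annotation label vector from TSV
#'
#' Accepts the TSV written by [write_annotation()] (or any table whose last
#' column is the integer label), enabling externally produced genome
#' annotations to be scored with [variance_explained()].
#'
#' @param path input file.
#' @param n_labels optional number of labels (default: max observed).
#' @param resolution base pairs per position (default 100).
#' @return an `ssa_annotation`.
#' @export
read_annotation <- function(path, n_labels = NULL, resolution = 100L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  labels <- as.integer(df[[ncol(df)]])
  if (anyNA(labels)) stopf("non-integer labels in '%s'", path)
  structure(list(labels = labels,
                 n_labels = as.integer(n_labels %||% max(labels)),
                 resolution = as.integer(resolution)),
            class = "ssa_annotation")
}

#' Write a synthetic dataset to a directory
#'
#' Writes `signal.tsv` (transformed values), `catalog.tsv`, one
#' `peaks_<assay>.bed` per TF-like assay, and `truth.json` holding the
#' block assignment of each assay type and the generator settings.
#'
#' @param dataset an `ssa_dataset` from [simulate_assays()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ssa_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_signal_tsv(dataset$signal, file.path(dir, "signal.tsv"))
  utils::write.table(as.data.frame(dataset$catalog),
                     file.path(dir, "catalog.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  w <- dataset$signal$bin_width
  for (id in names(dataset$peaks)) {
    p <- dataset$peaks[[id]]
    on_idx <- which(p == 1L) - 1L
    utils::write.table(
      data.frame(dataset$signal$chrom[on_idx + 1L],
                 dataset$signal$start[on_idx + 1L],
                 dataset$signal$start[on_idx + 1L] + w),
      file.path(dir, paste0("peaks_", gsub("[^A-Za-z0-9._-]", "_", id), ".bed")),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(truth = as.list(dataset$truth), is_tf = as.list(dataset$is_tf),
         seed = dataset$seed, config = unclass(dataset$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
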