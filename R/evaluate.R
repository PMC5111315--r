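# Panel-quality evaluation: fold construction, the three metrics
# (imputation theta, element-prediction gamma, annotation-based alpha),
# and the source/target cross-validation driver.

#' Partition assays into disjoint, balanced folds
#'
#' The cross-validation design holds one fold out as the target set (the
#' assays a panel is judged against) and selects panels from the remaining
#' source set. Folds are disjoint, cover all assays, and differ in size by
#' at most one.
#'
#' @param assay_ids character vector of assay ids.
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed; the same ids and seed give the same partition.
#' @return list of character vectors of class `ssa_folds`.
#' @export
make_folds <- function(assay_ids, n_folds = 10L, seed = 1L) {
  n <- length(assay_ids)
  n_folds <- as.integer(n_folds)
  if (n_folds < 1L) stopf("need at least one fold")
  if (n_folds > n) stopf("too few assays (%d) for %d folds", n, n_folds)
  perm <- with_seed(seed, sample(assay_ids))
  sizes <- rep(n %/% n_folds, n_folds)
  extra <- n %% n_folds
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  folds <- split(perm, rep(seq_len(n_folds), times = sizes))
  names(folds) <- paste0("fold", seq_len(n_folds))
  structure(folds, class = "ssa_folds", seed = seed)
}

#' Configuration for the assay imputation metric
#'
#' Support vector regression with a Gaussian kernel predicts a held-out
#' target track from the panel tracks on `n_train` random positions and is
#' scored on `n_test` disjoint positions. When the hyperparameter grid has
#' more than one point, the pair minimizing `cv_folds`-fold cross-validated
#' mean squared error on the training positions is used.
#'
#' @param n_train,n_test numbers of training and test genomic positions
#'   (defaults 5000 and 2000); the two sets are disjoint.
#' @param cv_folds folds for hyperparameter tuning (default 5).
#' @param cost SVR cost grid (default `c(1, 10, 100)`).
#' @param gamma Gaussian kernel width grid; `NULL` (default) uses `1/p` for
#'   `p` panel tracks.
#' @param epsilon SVR tube width (default 0.1).
#' @param seed RNG seed for position sampling and fold assignment.
#' @return a list of class `ssa_imputation_config`.
#' @export
imputation_config <- function(n_train = 5000L, n_test = 2000L, cv_folds = 5L,
                              cost = c(1, 10, 100), gamma = NULL,
                              epsilon = 0.1, seed = 1L) {
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 cv_folds = as.integer(cv_folds), cost = cost, gamma = gamma,
                 epsilon = epsilon, seed = seed),
            class = "ssa_imputation_config")
}

# Grid search by cv mean squared error; returns the chosen (cost, gamma).
tune_svr <- function(x, y, grid, cv_folds, epsilon, seed) {
  if (nrow(grid) == 1L) return(grid[1L, ])
  n <- nrow(x)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  errs <- vapply(seq_len(nrow(grid)), function(g) {
    mse <- 0
    for (fd in seq_len(cv_folds)) {
      tr <- fold_id != fd
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = "eps-regression",
                        kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], epsilon = epsilon)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      mse <- mse + mean((pred - y[!tr])^2)
    }
    mse / cv_folds
  }, numeric(1))
  grid[which.min(errs), ]
}

#' Assay imputation metric (theta)
#'
#' Trains Gaussian-kernel support vector regression to predict the target
#' track from the panel tracks at random training positions and reports the
#' squared Pearson correlation between predictions and truth at disjoint
#' test positions. `theta = 1` means the panel fully determines the target;
#' near 0 means the panel carries no linear information about it.
#'
#' @param panel_values numeric matrix, positions x panel tracks.
#' @param target numeric vector, the held-out track at the same positions.
#' @param config an [imputation_config()].
#' @return `theta` in `[0, 1]`.
#' @export
impute_assay <- function(panel_values, target, config = imputation_config()) {
  panel_values <- as.matrix(panel_values)
  if (ncol(panel_values) < 1L) stopf("panel is empty")
  n <- nrow(panel_values)
  if (length(target) != n) stopf("target length %d != %d positions",
                                 length(target), n)
  need <- config$n_train + config$n_test
  if (need > n) stopf("n_train + n_test = %d exceeds %d positions", need, n)
  idx <- with_seed(config$seed, sample.int(n, need))
  tr <- idx[seq_len(config$n_train)]
  te <- idx[config$n_train + seq_len(config$n_test)]
  if (stats::sd(target[te]) == 0) {
    warnf("constant target on test positions; theta set to 0")
    return(0)
  }
  gamma <- config$gamma %||% (1 / ncol(panel_values))
  grid <- expand.grid(cost = config$cost, gamma = gamma)
  pick <- tune_svr(panel_values[tr, , drop = FALSE], target[tr], grid,
                   config$cv_folds, config$epsilon, config$seed)
  fit <- e1071::svm(panel_values[tr, , drop = FALSE], target[tr],
                    type = "eps-regression", kernel = "radial",
                    cost = pick$cost, gamma = pick$gamma,
                    epsilon = config$epsilon)
  pred <- stats::predict(fit, panel_values[te, , drop = FALSE])
  if (stats::sd(pred) == 0) {
    warnf("constant predictions; theta set to 0")
    return(0)
  }
  unname(stats::cor(pred, target[te])^2)
}

#' Area under the precision-recall curve
#'
#' Step-wise (average-precision) integration: with thresholds at the
#' distinct score values in decreasing order, `AUC-PR = sum over thresholds
#' of (recall_t - recall_{t-1}) * precision_t`. This handles ties exactly
#' (all-equal scores give the class prevalence) and avoids the optimistic
#' bias of linear interpolation in precision-recall space. The result lies
#' in `[0, 1]`, with 1 for a perfect ranking.
#'
#' @param scores numeric vector of classifier scores (higher = more
#'   positive).
#' @param labels binary vector (0/1 or logical) of true classes.
#' @return the area, a single number in `[0, 1]`.
#' @export
auc_pr <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  P <- sum(labels)
  if (P == 0L || P == length(labels)) stopf("labels contain a single class")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  tp <- cumsum(l)
  fp <- cumsum(1L - l)
  last <- c(which(diff(s) != 0), length(s))  # end of each tied score group
  recall <- tp[last] / P
  precision <- tp[last] / (tp[last] + fp[last])
  sum(diff(c(0, recall)) * precision)
}

#' Configuration for the functional element prediction metric
#'
#' A Gaussian-kernel support vector machine is trained to classify peak
#' versus non-peak positions from the panel tracks. Because peaks cover a
#' tiny fraction of the genome, training and test sets are built by
#' sampling fixed numbers of positive and negative positions (disjoint
#' between train and test), and performance is the area under the
#' precision-recall curve.
#'
#' @param n_pos_train,n_neg_train training positives/negatives (defaults
#'   200 and 20000).
#' @param n_pos_test,n_neg_test test positives/negatives (defaults 100 and
#'   10000).
#' @param cv_folds folds for hyperparameter tuning (default 5).
#' @param cost SVM cost grid (default `c(1, 10, 100)`).
#' @param gamma kernel width grid; `NULL` uses `1/p`.
#' @param seed RNG seed.
#' @return a list of class `ssa_element_config`.
#' @export
element_config <- function(n_pos_train = 200L, n_neg_train = 20000L,
                           n_pos_test = 100L, n_neg_test = 10000L,
                           cv_folds = 5L, cost = c(1, 10, 100), gamma = NULL,
                           seed = 1L) {
  structure(list(n_pos_train = as.integer(n_pos_train),
                 n_neg_train = as.integer(n_neg_train),
                 n_pos_test = as.integer(n_pos_test),
                 n_neg_test = as.integer(n_neg_test),
                 cv_folds = as.integer(cv_folds), cost = cost, gamma = gamma,
                 seed = seed),
            class = "ssa_element_config")
}

svm_scores <- function(fit, x) {
  pred <- stats::predict(fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # libsvm orients the decision value toward the first factor level seen in
  # training; flip so that larger = more positive.
  if (colnames(dv)[1L] == "0/1") -dv[, 1L] else dv[, 1L]
}

#' Functional element prediction metric (gamma)
#'
#' Samples disjoint training/test sets of peak (positive) and non-peak
#' (negative) positions, trains a Gaussian-kernel SVM on the panel tracks,
#' and returns the area under the precision-recall curve on the test
#' sample. High `gamma` means the panel suffices to locate the peaks of the
#' held-out factor.
#'
#' @param panel_values numeric matrix, positions x panel tracks.
#' @param peaks binary vector over the same positions (1 = peak).
#' @param config an [element_config()].
#' @param assay_id identifier used in error messages.
#' @return `gamma` in `[0, 1]`.
#' @export
predict_elements <- function(panel_values, peaks,
                             config = element_config(), assay_id = "target") {
  panel_values <- as.matrix(panel_values)
  if (ncol(panel_values) < 1L) stopf("panel is empty")
  peaks <- as.integer(as.logical(peaks))
  if (length(peaks) != nrow(panel_values)) stopf("peaks length mismatch")
  pos <- which(peaks == 1L)
  neg <- which(peaks == 0L)
  if (length(pos) < config$n_pos_train + config$n_pos_test) {
    stopf("assay '%s': %d peak positions < %d needed", assay_id, length(pos),
          config$n_pos_train + config$n_pos_test)
  }
  if (length(neg) < config$n_neg_train + config$n_neg_test) {
    stopf("assay '%s': %d non-peak positions < %d needed", assay_id,
          length(neg), config$n_neg_train + config$n_neg_test)
  }
  samp <- with_seed(config$seed, {
    p <- sample(pos, config$n_pos_train + config$n_pos_test)
    m <- sample(neg, config$n_neg_train + config$n_neg_test)
    list(pos_tr = p[seq_len(config$n_pos_train)],
         pos_te = p[config$n_pos_train + seq_len(config$n_pos_test)],
         neg_tr = m[seq_len(config$n_neg_train)],
         neg_te = m[config$n_neg_train + seq_len(config$n_neg_test)])
  })
  x_tr <- panel_values[c(samp$pos_tr, samp$neg_tr), , drop = FALSE]
  y_tr <- factor(rep(c(1L, 0L), c(config$n_pos_train, config$n_neg_train)),
                 levels = c(0L, 1L))
  x_te <- panel_values[c(samp$pos_te, samp$neg_te), , drop = FALSE]
  y_te <- rep(c(1L, 0L), c(config$n_pos_test, config$n_neg_test))

  gamma_grid <- config$gamma %||% (1 / ncol(panel_values))
  grid <- expand.grid(cost = config$cost, gamma = gamma_grid)
  if (nrow(grid) > 1L) {
    fold_id <- with_seed(config$seed, sample(rep_len(seq_len(config$cv_folds),
                                                     nrow(x_tr))))
    aucs <- vapply(seq_len(nrow(grid)), function(g) {
      a <- 0
      for (fd in seq_len(config$cv_folds)) {
        tr <- fold_id != fd
        if (length(unique(y_tr[tr])) < 2L || length(unique(y_tr[!tr])) < 2L) next
        fit <- e1071::svm(x_tr[tr, , drop = FALSE], y_tr[tr],
                          type = "C-classification", kernel = "radial",
                          cost = grid$cost[g], gamma = grid$gamma[g])
        a <- a + auc_pr(svm_scores(fit, x_tr[!tr, , drop = FALSE]),
                        y_tr[!tr] == "1")
      }
      a
    }, numeric(1))
    pick <- grid[which.max(aucs), ]
  } else {
    pick <- grid[1L, ]
  }
  fit <- e1071::svm(x_tr, y_tr, type = "C-classification", kernel = "radial",
                    cost = pick$cost, gamma = pick$gamma)
  auc_pr(svm_scores(fit, x_te), y_te)
}

#' Stand-in genome segmenter (partition clustering)
#'
#' Produces an integer annotation of the genome from a panel of tracks by
#' multivariate partition clustering: positions with similar joint signal
#' receive the same label. The best of `restarts` random initializations
#' (by total within-cluster sum of squares) is kept, and the run is
#' deterministic for a fixed seed. This is a clustering stand-in, not a
#' probabilistic segmentation model: it ignores genomic ordering and
#' segment lengths. The variance-explained metric
#' ([variance_explained()]) is defined for any annotation source, and an
#' externally produced label vector (e.g. from a dedicated segmentation
#' tool) can be supplied in its place via [read_annotation()].
#'
#' @param panel_values numeric matrix, positions x panel tracks.
#' @param n_labels number of labels (default 15).
#' @param restarts random initializations (default 10).
#' @param seed RNG seed.
#' @param resolution base pairs per position, recorded for export
#'   (default 100).
#' @return an object of class `ssa_annotation`: integer `labels` in
#'   `1..n_labels` per position, plus `n_labels` and `resolution`.
#' @export
segment_standin <- function(panel_values, n_labels = 15L, restarts = 10L,
                            seed = 1L, resolution = 100L) {
  panel_values <- as.matrix(panel_values)
  n <- nrow(panel_values)
  n_labels <- as.integer(n_labels)
  if (n_labels < 1L) stopf("n_labels must be >= 1")
  if (n_labels > n) stopf("n_labels = %d exceeds %d positions", n_labels, n)
  if (n_labels == 1L) {
    return(structure(list(labels = rep(1L, n), n_labels = 1L,
                          resolution = as.integer(resolution)),
                     class = "ssa_annotation"))
  }
  ux <- unique(panel_values)
  if (nrow(ux) < n_labels) {
    stopf("only %d distinct signal profiles for %d labels", nrow(ux), n_labels)
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      centers <- ux[sample.int(nrow(ux), n_labels), , drop = FALSE]
      km <- tryCatch(
        suppressWarnings(stats::kmeans(panel_values, centers = centers,
                                       iter.max = 100L)),
        error = function(e) NULL)
      if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss)) {
        best <- km
      }
    }
  })
  if (is.null(best)) stopf("all clustering restarts failed")
  structure(list(labels = as.integer(best$cluster), n_labels = n_labels,
                 resolution = as.integer(resolution)),
            class = "ssa_annotation")
}

#' @export
print.ssa_annotation <- function(x, ...) {
  cat(sprintf("ssa_annotation: %d positions, %d labels (%d bp resolution)\n",
              length(x$labels), x$n_labels, x$resolution))
  print(table(label = x$labels))
  invisible(x)
}

#' Annotation-based variance explained (alpha)
#'
#' Measures how well an integer genome annotation explains a held-out
#' track: each position is predicted by the mean signal of its label,
#' residuals `d_i = shat(i) - s(i)` are formed, and
#' `alpha = (sigma_ov - sigma_res) / sigma_ov` where `sigma_res` is the
#' (population) standard deviation of the residuals and `sigma_ov` that of
#' the track. Because the label means are least-squares fits,
#' `sigma_ov >= sigma_res` always, so `alpha` lies in `[0, 1]`; `alpha = 1`
#' means the annotation captures the track exactly. Labels with no
#' positions are skipped (no mean can be formed).
#'
#' @param annotation an `ssa_annotation` or an integer label vector.
#' @param target numeric track over the same positions; must not be
#'   constant.
#' @return `alpha` in `[0, 1]`.
#' @export
variance_explained <- function(annotation, target) {
  labels <- if (inherits(annotation, "ssa_annotation")) annotation$labels
            else as.integer(annotation)
  if (length(labels) != length(target)) stopf("annotation/target length mismatch")
  if (anyNA(labels) || anyNA(target)) stopf("missing values not supported here")
  sigma_ov <- sqrt(mean((target - mean(target))^2))
  if (sigma_ov == 0) stopf("constant target track; variance explained undefined")
  mu <- tapply(target, labels, mean)           # per-label means, absent labels skipped
  shat <- unname(mu[as.character(labels)])
  d <- shat - target
  sigma_res <- sqrt(mean(d^2))
  alpha <- (sigma_ov - sigma_res) / sigma_ov
  min(max(alpha, 0), 1)
}

#' Evaluate a panel against a target set of held-out assays
#'
#' Applies the three quality metrics to one panel and one target set:
#' imputation `theta` for every target, peak-prediction `gamma` for targets
#' with peak calls (transcription-factor-like assays), and annotation-based
#' `alpha` for every target, using a single annotation built from the panel
#' by [segment_standin()]. A panel must not be evaluated on an assay it
#' contains, so a non-empty intersection is an error.
#'
#' @param signal an [ssa_signal()] holding the cell type's tracks (panel
#'   and targets).
#' @param panel character vector of panel assay ids.
#' @param targets character vector of held-out target assay ids.
#' @param peaks named list of binary peak vectors (names are assay ids);
#'   targets present here are scored with `gamma`.
#' @param imputation an [imputation_config()].
#' @param elements an [element_config()].
#' @param n_labels,restarts,seed annotation settings for
#'   [segment_standin()].
#' @return a data frame of class `ssa_evaluation` with columns `target`,
#'   `metric` (`"theta"`, `"gamma"`, `"alpha"`) and `value`; per-metric
#'   means over targets are attached as attribute `summary`.
#' @export
evaluate_panel <- function(signal, panel, targets, peaks = list(),
                           imputation = imputation_config(),
                           elements = element_config(),
                           n_labels = 15L, restarts = 10L, seed = 1L) {
  stopifnot(inherits(signal, "ssa_signal"))
  ids <- colnames(signal$values)
  miss <- setdiff(c(panel, targets), ids)
  if (length(miss)) stopf("unknown assay id(s): %s", paste(miss, collapse = ", "))
  bad <- intersect(panel, targets)
  if (length(bad)) {
    stopf("a panel must not be evaluated on an assay it contains: %s",
          paste(bad, collapse = ", "))
  }
  if (!length(panel)) stopf("panel is empty")
  if (!length(targets)) stopf("no target assays")
  pv <- signal$values[, panel, drop = FALSE]
  ann <- segment_standin(pv, n_labels = n_labels, restarts = restarts,
                         seed = seed)
  rows <- list()
  for (tg in targets) {
    y <- signal$values[, tg]
    rows[[length(rows) + 1L]] <- data.frame(
      target = tg, metric = "theta",
      value = impute_assay(pv, y, imputation), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      target = tg, metric = "alpha",
      value = variance_explained(ann, y), stringsAsFactors = FALSE)
    if (tg %in% names(peaks)) {
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg, metric = "gamma",
        value = predict_elements(pv, peaks[[tg]], elements, assay_id = tg),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  means <- tapply(out$value, out$metric, mean)
  structure(out, summary = means, class = c("ssa_evaluation", "data.frame"))
}

#' @export
print.ssa_evaluation <- function(x, ...) {
  cat("Panel evaluation (per-target metrics):\n")
  print(as.data.frame(x), row.names = FALSE)
  s <- attr(x, "summary")
  cat("means:", paste(sprintf("%s = %.3f", names(s), s), collapse = ", "), "\n")
  invisible(x)
}

#' Cross-validated panel evaluation
#'
#' The full source/target design: each fold in turn is held out as the
#' target set, a panel is chosen from the remaining source assays (by
#' default, facility-location selection on the past-mode similarity of the
#' source tracks), the three metrics are computed against the fold, and
#' results are averaged over folds.
#'
#' @param signal an [ssa_signal()] for one cell type.
#' @param folds an [make_folds()] partition of the cell's assay ids.
#' @param k panel size.
#' @param peaks named list of binary peak vectors for TF-like assays.
#' @param panel_fn optional `function(source_ids, fold_index)` returning
#'   the panel to evaluate for that fold; `NULL` (default) selects with
#'   [ssa()] on [build_similarity_past()] of the source tracks.
#' @param imputation,elements,n_labels,restarts,seed as in
#'   [evaluate_panel()].
#' @return a list of class `ssa_cv` with `per_fold` (data frame of fold,
#'   target, metric, value), `panels` (list of panels per fold) and
#'   `summary` (mean of per-fold metric means).
#' @export
evaluate_cv <- function(signal, folds, k, peaks = list(), panel_fn = NULL,
                        imputation = imputation_config(),
                        elements = element_config(),
                        n_labels = 15L, restarts = 10L, seed = 1L) {
  stopifnot(inherits(signal, "ssa_signal"), inherits(folds, "ssa_folds"))
  all_ids <- unlist(folds, use.names = FALSE)
  per_fold <- list()
  panels <- list()
  fold_means <- list()
  for (i in seq_along(folds)) {
    targets <- folds[[i]]
    source_ids <- setdiff(all_ids, targets)
    panel <- if (is.null(panel_fn)) {
      sim <- build_similarity_past(signal, assay_ids = source_ids)
      ssa(sim, k = min(k, length(source_ids)))$items
    } else {
      panel_fn(source_ids, i)
    }
    rep_i <- evaluate_panel(signal, panel, targets, peaks = peaks,
                            imputation = imputation, elements = elements,
                            n_labels = n_labels, restarts = restarts,
                            seed = seed)
    df <- as.data.frame(rep_i)
    df$fold <- names(folds)[i]
    per_fold[[i]] <- df
    panels[[names(folds)[i]]] <- panel
    fold_means[[i]] <- attr(rep_i, "summary")
  }
  per_fold <- do.call(rbind, per_fold)
  metrics <- unique(per_fold$metric)
  summary <- vapply(metrics, function(mm) {
    mean(vapply(fold_means, function(fm)
      if (mm %in% names(fm)) fm[[mm]] else NA_real_, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  structure(list(per_fold = per_fold[, c("fold", "target", "metric", "value")],
                 panels = panels, summary = summary),
            class = "ssa_cv")
}

#' @export
print.ssa_cv <- function(x, ...) {
  cat(sprintf("Cross-validated panel evaluation over %d folds\n",
              length(x$panels)))
  cat("fold-averaged metrics:",
      paste(sprintf("%s = %.3f", names(x$summary), x$summary), collapse = ", "),
      "\n")
  invisible(x)
}
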