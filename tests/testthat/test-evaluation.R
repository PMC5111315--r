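# The three panel-quality metrics and the cross-validation plumbing.

test_that("folds are disjoint, balanced, covering and seed-deterministic", {
  ids <- sprintf("a%02d", 1:20)
  f <- make_folds(ids, 10, seed = 3)
  expect_length(f, 10)
  expect_true(all(lengths(f) == 2))
  expect_setequal(unlist(f), ids)
  expect_identical(unname(lengths(f)), rep(2L, 10))
  expect_identical(f, make_folds(ids, 10, seed = 3))
  # 11 assays in 10 folds: sizes 2,1,...,1
  f11 <- make_folds(sprintf("b%02d", 1:11), 10, seed = 1)
  expect_identical(sort(unname(lengths(f11)), decreasing = TRUE),
                   c(2L, rep(1L, 9)))
  expect_error(make_folds(ids[1:5], 10), "too few")
})

test_that("AUC-PR handles perfect, constant and tied scorings exactly", {
  labels <- c(rep(1, 5), rep(0, 45))
  expect_equal(auc_pr(c(rep(2, 5), rep(1, 45)), labels), 1)
  expect_equal(auc_pr(rep(0.5, 50), labels), 5 / 50)
  expect_error(auc_pr(1:5, rep(1, 5)), "single class")
  # step-wise integration: a worked 4-point case
  # scores 4,3,2,1 with labels 1,0,1,0: thresholds give
  # (recall, precision) = (.5, 1), (.5, .5), (1, 2/3), (1, .5)
  expect_equal(auc_pr(c(4, 3, 2, 1), c(1, 0, 1, 0)),
               0.5 * 1 + 0 * 0.5 + 0.5 * (2 / 3) + 0 * 0.5)
})

test_that("AUC-PR of random scores concentrates at the class prevalence", {
  set.seed(77)
  labels <- c(rep(1, 100), rep(0, 10000))
  prev <- 100 / 10100
  aucs <- replicate(300, auc_pr(runif(10100), labels))
  expect_lt(abs(mean(aucs) - prev), 0.25 * prev)
})

test_that("variance explained matches the worked examples exactly", {
  expect_equal(variance_explained(c(1, 1, 2, 2), c(1, 1, 3, 3)), 1)
  expect_equal(variance_explained(c(1, 2, 1, 2), c(1, 1, 3, 3)), 0)
  expect_error(variance_explained(c(1, 2), c(5, 5)), "constant target")
  expect_error(variance_explained(c(1, 2, 3), c(1, 2)), "length mismatch")
})

test_that("the annotation's label means never increase the residual sd", {
  set.seed(19)
  for (trial in 1:1000) {
    n <- sample(20:200, 1)
    k <- sample(2:10, 1)
    y <- sample(k, n, replace = TRUE)
    s <- rnorm(n)
    a <- variance_explained(y, s)
    expect_gte(a, 0)  # equivalent to sigma_ov >= sigma_res
    expect_lte(a, 1)
  }
})

test_that("labels absent from the annotation are skipped", {
  # labels drawn from {1,3,7}: means form only for observed labels
  y <- c(1, 1, 3, 3, 7, 7)
  s <- c(1, 1.5, 4, 4.5, 9, 9.5)
  a <- variance_explained(y, s)
  mu <- tapply(s, y, mean)
  d <- unname(mu[as.character(y)]) - s
  expect_equal(a, 1 - sqrt(mean(d^2)) / sqrt(mean((s - mean(s))^2)))
})

test_that("the stand-in segmenter recovers separable blocks and is deterministic", {
  blocks <- rep(1:3, each = 50)
  pv <- cbind(c(0, 5, 10)[blocks] + rnorm(150, sd = 0.1),
              c(10, 0, 5)[blocks] + rnorm(150, sd = 0.1))
  ann <- segment_standin(pv, n_labels = 3, restarts = 5, seed = 2)
  # constant within blocks up to relabeling
  expect_equal(length(unique(ann$labels)), 3)
  for (b in 1:3) expect_length(unique(ann$labels[blocks == b]), 1)
  expect_identical(segment_standin(pv, 3, 5, seed = 2)$labels, ann$labels)
  one <- segment_standin(pv, n_labels = 1)
  expect_true(all(one$labels == 1L))
  expect_error(segment_standin(pv, n_labels = 200), "exceeds")
})

test_that("imputation recovers targets determined by the panel", {
  set.seed(42)
  n <- 1500
  x <- matrix(rnorm(n * 3), n, 3)
  cfg <- imputation_config(n_train = 600, n_test = 300, cost = 100,
                           gamma = c(0.05, 1 / 3), epsilon = 0.01, seed = 3)
  # target is a member of the panel (cv tuning picks the kernel width)
  expect_gte(impute_assay(x, x[, 2], cfg), 0.99)
  # fresh noise target: near-null squared correlation
  expect_lte(impute_assay(x, rnorm(n), cfg), 0.05)
  # noisy linear combination of two panel tracks
  y <- 0.7 * x[, 1] - 0.5 * x[, 3]
  y <- y + rnorm(n, sd = 0.1 * sd(y))
  cfg_cv <- imputation_config(n_train = 600, n_test = 300, cost = c(1, 10),
                              gamma = c(0.1, 0.5), seed = 3)
  expect_gte(impute_assay(x, y, cfg_cv), 0.9)
  expect_error(impute_assay(x, y, imputation_config(n_train = 5000,
                                                    n_test = 2000)),
               "exceeds")
  expect_warning(th0 <- impute_assay(x, rep(1, n),
                                     imputation_config(n_train = 200,
                                                       n_test = 100,
                                                       cost = 1)),
                 "constant target")
  expect_identical(th0, 0)
})

test_that("element prediction separates threshold peaks from shuffled peaks", {
  set.seed(9)
  n <- 4000
  f <- matrix(rnorm(n * 2), n, 2)
  pk <- derive_peaks(f[, 1], 0.05)
  cfg <- element_config(n_pos_train = 80, n_neg_train = 1200,
                        n_pos_test = 60, n_neg_test = 800, cost = 10, seed = 5)
  expect_gte(predict_elements(f, pk, cfg), 0.9)
  prev <- 60 / 860
  g0 <- predict_elements(f, sample(pk), cfg)
  expect_lt(g0, 0.15)  # near the test prevalence, far from the signal case
  expect_error(predict_elements(f, pk,
                                element_config(n_pos_train = 500,
                                               n_neg_train = 100,
                                               n_pos_test = 100,
                                               n_neg_test = 100),
                                assay_id = "tfX"),
               "tfX")
})

test_that("evaluation refuses panels that contain a target assay", {
  ds <- simulate_assays(small_config(), seed = 4)
  ids <- assays_in_cell(ds$catalog, "c1")
  expect_error(evaluate_panel(ds$signal, panel = ids[1:3],
                              targets = c(ids[3], ids[4])),
               "must not be evaluated")
})

test_that("panel evaluation reports per-target metrics in [0,1]", {
  ds <- simulate_assays(small_config(), seed = 4)
  ids <- assays_in_cell(ds$catalog, "c1")
  panel <- ids[c(1, 3, 5)]  # one type per block
  targets <- setdiff(ids, panel)[1:2]
  rep <- evaluate_panel(
    ds$signal, panel, targets, peaks = ds$peaks,
    imputation = imputation_config(n_train = 300, n_test = 150, cost = 10,
                                   seed = 2),
    elements = element_config(n_pos_train = 15, n_neg_train = 300,
                              n_pos_test = 10, n_neg_test = 200, cost = 10,
                              seed = 2),
    n_labels = 6, restarts = 3, seed = 2)
  expect_s3_class(rep, "ssa_evaluation")
  expect_true(all(rep$value >= 0 & rep$value <= 1))
  expect_setequal(unique(rep$metric[rep$metric != "gamma"]),
                  c("theta", "alpha"))
  s <- attr(rep, "summary")
  expect_true(all(c("theta", "alpha") %in% names(s)))
})

test_that("adding an informative track does not hurt expected imputation", {
  # target depends on two features; panels with both features beat panels
  # with one, on average over replicates
  deltas <- vapply(1:20, function(sd_i) {
    set.seed(100 + sd_i)
    n <- 800
    x <- matrix(rnorm(n * 2), n, 2)
    y <- x[, 1] + x[, 2] + rnorm(n, sd = 0.3)
    cfg <- imputation_config(n_train = 300, n_test = 200, cost = 10,
                             seed = sd_i)
    impute_assay(x, y, cfg) - impute_assay(x[, 1, drop = FALSE], y, cfg)
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("cross-validated evaluation averages folds and stores panels", {
  ds <- simulate_assays(small_config(), seed = 6)
  ids <- assays_in_cell(ds$catalog, "c1")
  folds <- make_folds(ids, n_folds = 2, seed = 1)
  cv <- evaluate_cv(
    ds$signal, folds, k = 2,
    peaks = ds$peaks,
    imputation = imputation_config(n_train = 250, n_test = 120, cost = 10,
                                   seed = 1),
    elements = element_config(n_pos_train = 12, n_neg_train = 200,
                              n_pos_test = 8, n_neg_test = 150, cost = 10,
                              seed = 1),
    n_labels = 5, restarts = 2, seed = 1)
  expect_s3_class(cv, "ssa_cv")
  expect_length(cv$panels, 2)
  expect_true(all(cv$per_fold$value >= 0 & cv$per_fold$value <= 1))
  expect_true(all(c("theta", "alpha") %in% names(cv$summary)))
  # no selected panel overlaps its fold's targets
  for (i in 1:2) expect_length(intersect(cv$panels[[i]], folds[[i]]), 0)
})
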