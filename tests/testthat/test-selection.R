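# Facility location objective, greedy/lazy/exhaustive selection and panel
# diagnostics, checked against hand-computed values on the 3-item example
# and against each other on random instances.

test_that("facility location matches hand-computed values and is normalized", {
  r <- toy3()
  expect_identical(facility_location(character(0), r), 0)
  expect_equal(facility_location("A", r), 1.9)
  expect_equal(facility_location("B", r), 2.1)
  expect_equal(facility_location("C", r), 1.4)
  expect_equal(facility_location(c("B", "C"), r), 2.8)
  expect_equal(facility_location(c("A", "B", "C"), r), 3)  # m with unit diag
  expect_error(facility_location("Z", r), "not in ground set")
})

test_that("singleton scores are weighted row sums and scale linearly in weights", {
  r <- toy3()
  expect_equal(singleton_scores(r), c(A = 1.9, B = 2.1, C = 1.4))
  expect_equal(singleton_scores(diag(3) |>
                                  (\(x) {dimnames(x) <- list(letters[1:3], letters[1:3]); x})()),
               c(a = 1, b = 1, c = 1))
  expect_equal(singleton_scores(r, weights = rep(2, 3)),
               2 * singleton_scores(r))
  # named partial weights up-weight coverage of that item
  w <- singleton_scores(r, weights = c(A = 3))
  expect_equal(unname(w["C"]), 3 * 0.1 + 0.3 + 1)
})

test_that("memoized marginal gain equals the naive objective difference", {
  r <- toy3()
  state_B <- r[, "B"]
  expect_equal(marginal_gain("C", state_B, r), 0.7)
  expect_equal(marginal_gain("B", state_B, r), 0)  # re-adding gains nothing
  expect_equal(marginal_gain("A", numeric(3), r), 1.9)  # empty state: singleton
  expect_error(marginal_gain("A", numeric(2), r), "length")
  set.seed(31)
  for (trial in 1:25) {
    m <- sample(4:10, 1)
    r <- rand_sim(m)
    s <- sample(colnames(r), sample(0:(m - 1), 1))
    state <- if (length(s)) apply(r[, s, drop = FALSE], 1, max) else numeric(m)
    item <- sample(setdiff(colnames(r), s), 1)
    naive <- facility_location(c(s, item), r) - facility_location(s, r)
    expect_equal(marginal_gain(item, state, r), naive, tolerance = 1e-12)
  }
})

test_that("greedy selection reproduces the worked example", {
  fit <- greedy_select(toy3(), k = 2)
  expect_identical(fit$items, c("B", "C"))
  expect_equal(fit$gains, c(2.1, 0.7))
  expect_equal(fit$objective, 2.8)
  expect_equal(unname(fit$singleton_scores), c(2.1, 1.4))
  expect_equal(fit$objective, facility_location(fit$items, toy3()))
  empty <- greedy_select(toy3(), k = 0)
  expect_length(empty$items, 0)
  expect_identical(empty$objective, 0)
  expect_error(greedy_select(toy3(), k = 4), "outside")
})

test_that("forced items come first with their conditional gains", {
  fit <- greedy_select(toy3(), k = 2, forced = "A")
  expect_identical(fit$items, c("A", "C"))  # f(A,C)=2.8 beats f(A,B)=2.3
  expect_equal(fit$gains, c(1.9, 0.9))
  expect_equal(fit$objective, 2.8)
  expect_error(greedy_select(toy3(), k = 1, forced = c("A", "B")),
               "forced")
})

test_that("greedy gains are non-increasing (diminishing returns)", {
  set.seed(17)
  for (trial in 1:20) {
    r <- rand_sim(sample(5:20, 1))
    k <- sample(2:ncol(r), 1)
    fit <- greedy_select(r, k)
    expect_true(all(diff(fit$gains) <= 1e-12))
  }
})

test_that("lazy greedy returns the identical panel to standard greedy", {
  expect_identical(lazy_greedy_select(toy3(), 2)$items, c("B", "C"))
  set.seed(23)
  for (trial in 1:100) {
    r <- rand_sim(sample(3:50, 1))
    k <- sample(1:min(10, ncol(r)), 1)
    g <- greedy_select(r, k)
    l <- lazy_greedy_select(r, k)
    expect_identical(l$items, g$items)
    expect_equal(l$gains, g$gains, tolerance = 1e-12)
  }
  # k = m selects everything; objective is f(V)
  r <- rand_sim(6)
  full <- lazy_greedy_select(r, 6)
  expect_setequal(full$items, colnames(r))
  expect_equal(full$objective, facility_location(colnames(r), r))
})

test_that("exhaustive search finds the optimum with deterministic ties", {
  bf <- brute_force_select(toy3(), 2)
  expect_equal(bf$objective, 2.8)
  # {A,C} and {B,C} tie at 2.8; the lexicographically first subset wins
  expect_identical(bf$items, c("A", "C"))
  expect_identical(brute_force_select(toy3(), 1)$items, "B")
  expect_equal(brute_force_select(toy3(), 1)$objective, 2.1)
  expect_setequal(brute_force_select(toy3(), 3)$items, c("A", "B", "C"))
  expect_error(brute_force_select(rand_sim(30), 15, cap = 1000), "cap")
})

test_that("greedy achieves at least (1 - 1/e) of the optimum", {
  ratios <- greedy_ratio_experiment(n_instances = 200, seed = 12)
  expect_length(ratios, 200)
  expect_true(all(ratios >= 1 - exp(-1)))
  expect_true(all(ratios <= 1 + 1e-12))
})

test_that("facility location is submodular and monotone; counterexamples are caught", {
  set.seed(41)
  for (m in c(5, 6)) {
    r <- rand_sim(m)
    chk <- check_submodular_monotone(function(S) facility_location(S, r),
                                     colnames(r))
    expect_true(chk$submodular)
    expect_true(chk$monotone)
    expect_null(chk$witness)
  }
  mod <- check_submodular_monotone(function(S) length(S), letters[1:4])
  expect_true(mod$submodular && mod$monotone)
  sq <- check_submodular_monotone(function(S) length(S)^2, letters[1:4])
  expect_false(sq$submodular)
  expect_length(sq$witness$S, 1)
  expect_length(sq$witness$T, 1)
  expect_error(check_submodular_monotone(length, letters[1:9]), "8 items")
})

test_that("facility location is monotone under set inclusion (exhaustive)", {
  set.seed(6)
  r <- rand_sim(7)
  items <- colnames(r)
  for (trial in 1:50) {
    s <- sample(items, sample(0:6, 1))
    t_ <- union(s, sample(items, sample(1:7, 1)))
    expect_lte(facility_location(s, r),
               facility_location(t_, r) + 1e-12)
  }
})

test_that("swap-out analysis reports the best swap and signed loss", {
  r <- toy3()
  sw <- swap_out_analysis(r, c("B", "C"), "A")
  expect_equal(sw$loss, 0)
  expect_identical(sw$removed, "B")
  expect_equal(sw$objective, 2.8)
  # swapping B into a singleton panel {A} improves the objective: loss < 0
  sw2 <- swap_out_analysis(r, "A", "B")
  expect_equal(sw2$loss, 1.9 - 2.1)
  expect_error(swap_out_analysis(r, c("B", "C"), "B"), "already in the panel")
  # excluded item identical to a panel member's row: loss 0
  r4 <- cbind(rbind(r, D = r["B", ]), D = c(r["B", ], 1))
  sw3 <- swap_out_analysis(r4, c("B", "C"), "D")
  expect_equal(sw3$loss, 0)
})

test_that("coverage weights steer selection toward preferred items", {
  r <- toy3()
  expect_equal(facility_location(c("B", "C"), r, weights = c(2, 1, 1)),
               2 * 0.8 + 1 + 1)
  # heavily weighting coverage of A makes A's column decisive
  fit <- greedy_select(r, 1, weights = c(A = 10))
  expect_identical(fit$items, "A")
  expect_error(greedy_select(r, 1, weights = c(-1, 1, 1)), "nonnegative")
})

test_that("the ssa() interface dispatches algorithms and prints a report", {
  fit <- ssa(toy3(), 2)
  expect_s3_class(fit, "ssa_panel")
  expect_identical(fit$algorithm, "lazy")
  expect_identical(ssa(toy3(), 2, algorithm = "greedy")$items, fit$items)
  ex <- ssa(toy3(), 2, algorithm = "exhaustive")
  expect_equal(ex$objective, 2.8)
  expect_equal(sum(ex$gains), ex$objective, tolerance = 1e-12)
  df <- as.data.frame(fit)
  expect_identical(names(df), c("rank", "item", "singleton_score", "gain",
                                "cumulative_objective"))
  expect_equal(df$cumulative_objective[nrow(df)], fit$objective)
  expect_output(print(fit), "objective")
  expect_output(summary(fit), "coverage")
})
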