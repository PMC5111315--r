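# Greedy maximization of the facility location objective, its lazy
# (priority-queue) acceleration, an exhaustive oracle, and panel
# diagnostics. All tie-breaks are deterministic: among equal gains the
# lexicographically smallest item label wins, so runs are reproducible.

new_ssa_panel <- function(items, gains, R, weights, algorithm, forced, mode) {
  Rm <- sim_values(R)
  structure(
    list(items = items,
         gains = gains,
         objective = sum(gains),
         singleton_scores = if (length(items)) singleton_scores(Rm, weights)[items]
                            else numeric(0),
         forced = forced,
         weights = weights,
         algorithm = algorithm,
         mode = mode,
         m = ncol(Rm)),
    class = "ssa_panel")
}

sim_mode <- function(R) if (inherits(R, "ssa_similarity")) R$mode else NA_character_

# Shared engine for greedy and lazy greedy. Forced items are added first,
# in the user's order, charged their true conditional gains, so the final
# objective is still f(S).
greedy_engine <- function(R, k, forced = NULL, weights = NULL, lazy = FALSE) {
  Rm <- sim_values(R)
  m <- ncol(Rm)
  w <- resolve_weights(weights, Rm)
  labs <- colnames(Rm)
  k <- as.integer(k)
  if (k < 0L || k > m) stopf("panel size k = %d outside [0, %d]", k, m)
  forced <- resolve_items(forced, Rm)
  if (anyDuplicated(forced)) stopf("duplicate forced items")
  if (length(forced) > k) stopf("more forced items (%d) than panel slots (%d)",
                                length(forced), k)

  state <- numeric(m)
  sel <- character(0)
  gains <- numeric(0)
  gain_of <- function(it) sum(w * pmax(0, Rm[, it] - state))
  take <- function(it) {
    state <<- pmax(state, Rm[, it])
    sel <<- c(sel, it)
  }
  for (it in forced) {
    gains <- c(gains, gain_of(it))
    take(it)
  }
  remaining <- setdiff(labs, sel)
  # lexicographic processing order => which.max resolves ties to the
  # smallest label
  remaining <- lex_sort(remaining)

  if (!lazy) {
    while (length(sel) < k) {
      g <- vapply(remaining, gain_of, numeric(1))
      best <- which.max(g)
      gains <- c(gains, g[best])
      take(remaining[best])
      remaining <- remaining[-best]
    }
  } else {
    # CELF-style lazy evaluation: cached gains are upper bounds (by
    # submodularity); re-evaluate the head of the queue until it is fresh.
    ub <- vapply(remaining, gain_of, numeric(1))
    while (length(sel) < k) {
      fresh <- rep(FALSE, length(remaining))
      repeat {
        head_i <- which.max(ub)  # ties -> first in lexicographic order
        if (fresh[head_i]) break
        ub[head_i] <- gain_of(remaining[head_i])
        fresh[head_i] <- TRUE
        # a stale item ordered before head with an equal bound must be
        # re-examined; which.max already revisits it if its ub >= new value
      }
      gains <- c(gains, ub[head_i])
      take(remaining[head_i])
      remaining <- remaining[-head_i]
      ub <- ub[-head_i]
    }
  }
  list(items = sel, gains = unname(gains))
}

#' Greedy facility-location panel selection
#'
#' Starting from the forced set (empty by default), each step adds the item
#' with the largest conditional gain `f(s | S)` until the panel has `k`
#' items. For a normalized monotone submodular objective such as facility
#' location this achieves at least `(1 - 1/e) ~ 0.632` of the optimal
#' objective in the worst case, and in practice is usually near-optimal.
#' Coverage is memoized so each gain evaluation costs O(m).
#'
#' @param R similarity matrix or [ssa_similarity()].
#' @param k panel size (including forced items).
#' @param forced item labels that must be in the panel; they are placed
#'   first, in the given order, and charged their conditional gains.
#' @param weights optional nonnegative per-item coverage weights.
#' @return an object of class `ssa_panel` with the ordered selection, the
#'   per-step gains (non-increasing after the forced prefix), the final
#'   objective `f(S)` and the singleton scores of the selected items.
#' @seealso [ssa()] for the high-level interface, [lazy_greedy_select()],
#'   [brute_force_select()].
#' @export
greedy_select <- function(R, k, forced = NULL, weights = NULL) {
  res <- greedy_engine(R, k, forced, weights, lazy = FALSE)
  new_ssa_panel(res$items, res$gains, R, weights, "greedy", forced, sim_mode(R))
}

#' Lazy greedy (accelerated) panel selection
#'
#' Identical output to [greedy_select()] under the same tie-breaking, but
#' exploits submodularity: cached gains from earlier iterations are valid
#' upper bounds, so most items need no re-evaluation, bringing the running
#' time to nearly O(m^2) overall.
#'
#' @inheritParams greedy_select
#' @return an `ssa_panel`, identical to the one from [greedy_select()].
#' @export
lazy_greedy_select <- function(R, k, forced = NULL, weights = NULL) {
  res <- greedy_engine(R, k, forced, weights, lazy = TRUE)
  new_ssa_panel(res$items, res$gains, R, weights, "lazy", forced, sim_mode(R))
}

#' Exhaustive maximization over all size-k panels
#'
#' Enumerates every size-`k` subset and returns the exact maximizer of the
#' facility location objective. Only feasible for small ground sets; used
#' as an optimality oracle. Ties are broken deterministically in favour of
#' the lexicographically first subset.
#'
#' @inheritParams greedy_select
#' @param cap maximum number of subsets to enumerate (default 1e6).
#' @return list with `items` (the optimal subset, lexicographic order) and
#'   `objective`.
#' @export
brute_force_select <- function(R, k, weights = NULL, cap = 1e6) {
  Rm <- sim_values(R)
  m <- ncol(Rm)
  k <- as.integer(k)
  if (k < 0L || k > m) stopf("panel size k = %d outside [0, %d]", k, m)
  if (k == 0L) return(list(items = character(0), objective = 0))
  if (choose(m, k) > cap) {
    stopf("C(%d, %d) = %.3g subsets exceeds cap %g", m, k, choose(m, k), cap)
  }
  labs <- lex_sort(colnames(Rm))
  w <- resolve_weights(weights, Rm)
  sets <- utils::combn(labs, k, simplify = FALSE)
  best <- -Inf
  best_set <- NULL
  for (s in sets) {
    val <- sum(w * apply(Rm[, s, drop = FALSE], 1L, max))
    if (val > best + 1e-15) {  # strict improvement keeps the first maximizer
      best <- val
      best_set <- s
    }
  }
  list(items = best_set, objective = best)
}

#' Swap-out analysis of a selected panel
#'
#' Answers "how much would the objective decrease if we were forced to swap
#' one panel member for this excluded item?": over all members `p`, it
#' evaluates `f(panel - p + excluded)` and reports the best swap. The loss
#' `f(panel) - best` is signed; a negative loss means the swap improves the
#' objective (possible since greedy panels need not be optimal).
#'
#' @param R similarity matrix or [ssa_similarity()].
#' @param panel character vector of selected items.
#' @param excluded an item not in the panel to be swapped in.
#' @param weights optional per-item weights.
#' @return list with `loss`, `removed` (the member whose removal is best),
#'   `objective` (after the best swap) and `panel_objective`.
#' @export
swap_out_analysis <- function(R, panel, excluded, weights = NULL) {
  Rm <- sim_values(R)
  panel <- resolve_items(panel, Rm)
  excluded <- resolve_items(excluded, Rm)
  stopifnot(length(excluded) == 1L)
  if (excluded %in% panel) stopf("'%s' is already in the panel", excluded)
  f0 <- facility_location(panel, Rm, weights)
  ord <- lex_sort(panel)
  objs <- vapply(ord, function(p) {
    facility_location(c(setdiff(panel, p), excluded), Rm, weights)
  }, numeric(1))
  best <- which.max(objs)  # ties -> lexicographically first removed member
  list(loss = unname(f0 - objs[best]),
       removed = ord[best],
       objective = unname(objs[best]),
       panel_objective = f0)
}

#' Exhaustively verify submodularity and monotonicity of a set function
#'
#' Checks the defining inequality `f(S) + f(T) >= f(S u T) + f(S n T)` over
#' all subset pairs, and monotonicity `f(S + s) >= f(S)` over all `(s, S)`,
#' for a ground set of at most 8 items (so at most 256 subsets). Returns
#' the first violating witness, if any.
#'
#' @param f a function taking a character vector (a subset of `items`) and
#'   returning a number; must satisfy `f(character(0)) = 0` to be normalized.
#' @param items ground-set labels (length <= 8).
#' @param tol numerical tolerance (default 1e-9).
#' @return list with logicals `submodular` and `monotone`, and `witness`
#'   (`NULL`, or the offending sets).
#' @export
check_submodular_monotone <- function(f, items, tol = 1e-9) {
  n <- length(items)
  if (n > 8L) stopf("exhaustive check limited to 8 items (got %d)", n)
  nsub <- bitwShiftL(1L, n)
  masks <- 0:(nsub - 1L)
  subset_of <- function(mask) items[bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L]
  vals <- vapply(masks, function(mk) f(subset_of(mk)), numeric(1))

  witness <- NULL
  submodular <- TRUE
  for (a in masks) {
    fa <- vals[a + 1L]
    or_ab <- bitwOr(a, masks)
    and_ab <- bitwAnd(a, masks)
    viol <- fa + vals - (vals[or_ab + 1L] + vals[and_ab + 1L]) < -tol
    if (any(viol)) {
      b <- masks[which(viol)[1L]]
      witness <- list(S = subset_of(a), T = subset_of(b))
      submodular <- FALSE
      break
    }
  }
  monotone <- TRUE
  for (a in masks) {
    for (bit in 0:(n - 1L)) {
      bmask <- bitwShiftL(1L, bit)
      if (bitwAnd(a, bmask) != 0L) next
      if (vals[bitwOr(a, bmask) + 1L] - vals[a + 1L] < -tol) {
        monotone <- FALSE
        if (is.null(witness)) {
          witness <- list(S = subset_of(a), s = items[bit + 1L])
        }
        break
      }
    }
    if (!monotone) break
  }
  list(submodular = submodular, monotone = monotone, witness = witness)
}

#' Select an assay panel by submodular optimization
#'
#' High-level interface: given an assay-similarity matrix (from
#' [build_similarity_past()] or [build_similarity_future()]), selects a
#' panel of `k` items maximizing the facility location objective.
#'
#' @param similarity an [ssa_similarity()] or labelled similarity matrix.
#' @param k panel size.
#' @param forced items that must appear in the panel (e.g. assays already
#'   performed); placed first and charged their conditional gains.
#' @param weights optional nonnegative per-item preference weights; higher
#'   weight on an item rewards panels that cover it well.
#' @param algorithm `"lazy"` (default; identical result to `"greedy"`,
#'   faster), `"greedy"`, or `"exhaustive"` (exact, small ground sets only).
#' @return an object of class `ssa_panel`; see [greedy_select()].
#' @examples
#' r <- matrix(c(1, .8, .1, .8, 1, .3, .1, .3, 1), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' fit <- ssa(r, k = 2)
#' fit
#' @export
ssa <- function(similarity, k, forced = NULL, weights = NULL,
                algorithm = c("lazy", "greedy", "exhaustive")) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "exhaustive") {
    if (!is.null(forced)) stopf("forced items are supported for greedy algorithms only")
    res <- brute_force_select(similarity, k, weights)
    Rm <- sim_values(similarity)
    w <- weights
    state <- numeric(nrow(Rm))
    gains <- numeric(0)
    for (it in res$items) {  # report conditional gains in set order
      gains <- c(gains, marginal_gain(it, state, Rm, w))
      state <- pmax(state, Rm[, it])
    }
    return(new_ssa_panel(res$items, gains, similarity, weights, "exhaustive",
                         NULL, sim_mode(similarity)))
  }
  if (algorithm == "greedy") greedy_select(similarity, k, forced, weights)
  else lazy_greedy_select(similarity, k, forced, weights)
}

#' @export
print.ssa_panel <- function(x, digits = 3, ...) {
  cat(sprintf("Assay panel (%s%s): k = %d of m = %d, objective f(S) = %s\n",
              x$algorithm,
              if (!is.na(x$mode) && nzchar(x$mode)) paste0(", ", x$mode, " mode") else "",
              length(x$items), x$m, format(x$objective, digits = digits + 2)))
  if (length(x$items)) {
    print(as.data.frame(x), digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.ssa_panel <- function(x, ...) {
  data.frame(rank = seq_along(x$items),
             item = x$items,
             singleton_score = unname(x$singleton_scores),
             gain = x$gains,
             cumulative_objective = cumsum(x$gains),
             stringsAsFactors = FALSE)
}

#' @export
summary.ssa_panel <- function(object, ...) {
  cat("Submodular selection of assays\n")
  print(object)
  if (length(object$forced)) {
    cat("forced items:", paste(object$forced, collapse = ", "), "\n")
  }
  frac <- object$objective / max(object$m, 1)
  cat(sprintf("coverage: f(S)/m = %.3f (1 when every item has a perfect representative)\n",
              frac))
  invisible(object)
}

#' Plot the per-step objective gains of a panel
#'
#' Bar heights are the conditional gains `f(s_i | S_{i-1})` in selection
#' order (non-increasing for an unforced greedy run); the line is the
#' cumulative objective.
#'
#' @param x an `ssa_panel`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot.ssa_panel <- function(x, ...) {
  if (!length(x$items)) {
    warnf("empty panel; nothing to plot")
    return(invisible(NULL))
  }
  mids <- graphics::barplot(x$gains, names.arg = x$items, las = 2,
                            ylab = "objective gain f(s | S)",
                            ylim = c(0, max(x$gains, cumsum(x$gains)) * 1.05),
                            ...)
  graphics::lines(mids, cumsum(x$gains), type = "b", pch = 19)
  graphics::legend("topright", legend = c("gain", "cumulative f(S)"),
                   pch = c(22, 19), bty = "n")
  invisible(mids)
}
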