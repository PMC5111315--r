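#' Facility location objective
#'
#' For a similarity matrix `R` over a ground set `V` and a selected set `S`,
#' the facility location function is
#' \deqn{f(S) = \sum_{s' \in V} w_{s'} \max_{s \in S} r_{s',s},}
#' with the empty max defined as 0 so that `f({}) = 0` (the function is
#' normalized). It is high when every item in `V` has at least one similar
#' representative in `S`; it is monotone non-decreasing and submodular
#' whenever all `r >= 0`, which enables the greedy (1 - 1/e) guarantee.
#' Optional nonnegative weights `w` up-weight coverage of preferred items.
#'
#' @param S character vector of selected item labels (subset of the ground
#'   set), or integer indices.
#' @param R an [ssa_similarity()] or a labelled similarity matrix.
#' @param weights optional nonnegative per-item weights, recycled or named
#'   by item; default all 1.
#' @return the objective value, a single number.
#' @export
facility_location <- function(S, R, weights = NULL) {
  Rm <- sim_values(R)
  w <- resolve_weights(weights, Rm)
  S <- resolve_items(S, Rm)
  if (length(S) == 0L) return(0)
  sum(w * apply(Rm[, S, drop = FALSE], 1L, max))
}

# Map item labels/indices onto columns of Rm, with membership errors.
resolve_items <- function(S, Rm) {
  labs <- colnames(Rm)
  if (is.null(S) || length(S) == 0L) return(character(0))
  if (is.numeric(S)) {
    if (any(S < 1L | S > ncol(Rm))) stopf("item index out of range")
    return(labs[S])
  }
  S <- as.character(S)
  miss <- setdiff(S, labs)
  if (length(miss)) stopf("item(s) not in ground set: %s",
                          paste(miss, collapse = ", "))
  S
}

resolve_weights <- function(weights, Rm) {
  m <- nrow(Rm)
  if (is.null(weights)) return(rep(1, m))
  if (!is.null(names(weights))) {
    w <- rep(1, m)
    names(w) <- colnames(Rm)
    miss <- setdiff(names(weights), colnames(Rm))
    if (length(miss)) stopf("weight for unknown item(s): %s",
                            paste(miss, collapse = ", "))
    w[names(weights)] <- weights
    weights <- w
  }
  if (length(weights) != m) stopf("need one weight per ground-set item")
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stopf("weights must be finite and nonnegative")
  }
  unname(weights)
}

#' Marginal gain of adding one item, from a memoized coverage state
#'
#' The greedy algorithm never needs the full objective: given the current
#' per-item coverage state `state[s'] = max_{s in S} r_{s',s}` (all zeros
#' for the empty set), the gain of adding `item` is
#' `sum_{s'} w_{s'} max(0, r_{s',item} - state_{s'})`, an O(m) evaluation
#' that equals `f(S + item) - f(S)` exactly.
#'
#' @param item a single item label (or index).
#' @param state numeric vector of length `m`, the current row-wise maxima.
#' @param R similarity matrix or [ssa_similarity()].
#' @param weights optional per-item weights as in [facility_location()].
#' @return the conditional gain, a single number.
#' @export
marginal_gain <- function(item, state, R, weights = NULL) {
  Rm <- sim_values(R)
  if (length(state) != nrow(Rm)) {
    stopf("coverage state has length %d, expected %d", length(state), nrow(Rm))
  }
  w <- resolve_weights(weights, Rm)
  item <- resolve_items(item, Rm)
  stopifnot(length(item) == 1L)
  sum(w * pmax(0, Rm[, item] - state))
}

#' Singleton scores
#'
#' The singleton score of item `s` is `f({s})`, the objective value of a
#' panel containing only that item: the (weighted) sum of its similarities
#' to every ground-set item. Items with high singleton scores are centrally
#' located; the greedy panel often includes low-singleton items because
#' they cover activity the rest of the panel does not.
#'
#' @param R similarity matrix or [ssa_similarity()].
#' @param weights optional per-item weights.
#' @return named numeric vector of `f({s})` for every item.
#' @export
singleton_scores <- function(R, weights = NULL) {
  Rm <- sim_values(R)
  w <- resolve_weights(weights, Rm)
  colSums(Rm * w)
}
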