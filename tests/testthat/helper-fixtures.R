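# Shared fixtures, built in code.

# Worked 3-item similarity matrix used throughout: singleton scores
# {A: 1.9, B: 2.1, C: 1.4}, greedy k=2 panel [B, C] with gains [2.1, 0.7].
toy3 <- function() {
  matrix(c(1, .8, .1,
           .8, 1, .3,
           .1, .3, 1), 3, 3,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

# Random symmetric similarity matrix, entries U[0,1], unit diagonal.
# Draws from the current RNG stream.
rand_sim <- function(m) {
  r <- matrix(runif(m * m), m, m)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(sprintf("i%02d", 1:m), sprintf("i%02d", 1:m))
  r
}

# Small synthetic dataset settings used by unit tests (fast).
small_config <- function(...) {
  args <- utils::modifyList(list(n_blocks = 3L, types_per_block = 2L,
                                 n_cell_types = 3L, n_positions = 1500L),
                            list(...))
  do.call(synthetic_config, args)
}
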