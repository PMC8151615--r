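# Independent right-hand-side oracles, coded directly from the model
# equations (no term machinery), used to cross-check the term lists and the
# channel drift.

rhs_nonlinear_direct <- function(state, R) {
  p1 <- state[1]; p2 <- state[2]
  r2 <- R^2 - p1^2 - p2^2
  c(-p2 + p1 * r2, p1 + p2 * r2)
}

rhs_linear_direct <- function(state, n, eps) {
  A <- outer(seq_len(n), seq_len(n), function(i, j) (i - j)^2) * eps
  p <- state[seq_len(n)]
  z <- state[n + seq_len(n)]
  c(as.numeric(A %*% p) - z - p, p)
}

# Minimal hand-built channel set: a single constant-rate birth channel for
# variable 1, realised through a dummy always-one second variable. Used to
# test the simulator core against Poisson-process theory.
birth_channels <- function(rate) {
  tab <- matrix(c(0, 2, rate, 1, 1, 0, 0), nrow = 1)
  colnames(tab) <- c("eval_kind", "source", "coef", "target", "dt_target",
                     "aux", "dt_aux")
  ch <- list(list(label = "birth", kind = "coupling",
                  propensity = function(s) rate * s[2],
                  stoichiometry = function(s) c(1L, 0L)))
  attr(ch, "table") <- tab
  attr(ch, "rowcoef") <- matrix(0, 1, 2)
  attr(ch, "n_vars") <- 2L
  attr(ch, "var_names") <- c("count", "unit")
  ch
}

random_signed_states <- function(m, n = 100, scale = 20, seed = 42) {
  set.seed(seed)
  matrix(sample(-scale:scale, n * m, replace = TRUE), nrow = n)
}
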