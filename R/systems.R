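#' @useDynLib oscnoise, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft lm coef residuals aggregate setNames
#' @importFrom utils head tail write.csv
NULL

#' Squared-index-distance coupling matrix
#'
#' Builds the hollow, symmetric n-by-n matrix with entries
#' \eqn{A_{ij} = (i-j)^2 \epsilon} (1-based process indices). This matrix
#' wires the linear system of coupled oscillators: each process is a fixed
#' linear combination of all others, with weights growing as the squared
#' index distance.
#'
#' @param n number of p-processes (integer, at least 2).
#' @param epsilon coupling parameter; the matrix is linear in it.
#' @return an n-by-n numeric matrix with zero diagonal.
#' @examples
#' coupling_matrix(2, 1)      # antidiagonal ones
#' coupling_matrix(4, 1)[1, ] # 0 1 4 9
#' @export
coupling_matrix <- function(n, epsilon) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L)
    stop("'n' must be a single integer >= 2", call. = FALSE)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon))
  idx <- seq_len(n)
  outer(idx, idx, function(i, j) (i - j)^2) * epsilon
}

## Internal term constructor. Every right-hand-side term is one of:
##   linear : value = coef * state[source]
##   radial : value = state[source] * (R^2 - p1^2 - p2^2)   (nonlinear family)
## The term contributes dt_target * value to d(state[target])/dt and, for
## transfer terms, dt_aux * value to d(state[aux])/dt as well.
new_term <- function(label, kind, eval, target, source, coef = 1,
                     dt_target = 1L, aux = NA_integer_, dt_aux = 0L) {
  list(label = label, kind = kind, eval = eval, target = as.integer(target),
       source = as.integer(source), coef = coef,
       dt_target = as.integer(dt_target), aux = as.integer(aux),
       dt_aux = as.integer(dt_aux))
}

#' Two-process nonlinear limit-cycle oscillator
#'
#' Defines the planar system
#' \deqn{dp_1/dt = -p_2 + p_1 (R^2 - p_1^2 - p_2^2)}
#' \deqn{dp_2/dt = +p_1 + p_2 (R^2 - p_1^2 - p_2^2)}
#' which has the attracting periodic solution \eqn{p_1 = R\cos t},
#' \eqn{p_2 = R\sin t}: a circular limit cycle of radius R. Each equation is
#' stored as an ordered list of additive terms so that the same definition
#' drives both deterministic integration and the stochastic channel
#' decomposition.
#'
#' @param R limit-cycle radius, positive.
#' @return an object of class \code{osc_system}.
#' @seealso [linear_system()], [system_rhs()], [decompose_channels()]
#' @export
nonlinear_system <- function(R) {
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R))
  if (R <= 0) stop("'R' must be positive", call. = FALSE)
  terms <- list(
    new_term("drive p2->p1", "coupling", "linear", target = 1L, source = 2L,
             coef = -1),
    new_term("radial p1", "nonlinear_term", "radial", target = 1L,
             source = 1L, coef = R^2),
    new_term("drive p1->p2", "coupling", "linear", target = 2L, source = 1L,
             coef = +1),
    new_term("radial p2", "nonlinear_term", "radial", target = 2L,
             source = 2L, coef = R^2)
  )
  structure(list(name = "nonlinear", family = "nonlinear", n_p = 2L,
                 n_z = 0L, params = list(R = R), terms = terms,
                 var_names = c("p1", "p2")),
            class = "osc_system")
}

#' Linear system of coupled oscillating processes
#'
#' Defines the 2 n_p-variable system
#' \deqn{dP/dt = A P - (Z + P), \qquad dZ/dt = P}
#' with A the squared-index-distance coupling matrix of
#' [coupling_matrix()]. Every p-process drives its companion z-process,
#' which inhibits it back: n_p negative feedback loops coupled through A.
#' The \eqn{-P} term of the first block and the \eqn{+P} of the second are
#' stored as a single transfer term per process (mass moving from p_i to
#' z_i), which leaves the deterministic right-hand side unchanged while
#' giving the stochastic decomposition its transition channel.
#'
#' State ordering is \code{p_1..p_n, z_1..z_n}.
#'
#' @param n_p number of p-processes (the system has 2 n_p variables).
#' @param epsilon coupling parameter of the matrix A.
#' @return an object of class \code{osc_system}.
#' @seealso [coupling_matrix()], [hopf_point()]
#' @export
linear_system <- function(n_p, epsilon) {
  n_p <- as.integer(n_p)
  if (length(n_p) != 1L || is.na(n_p) || n_p < 2L)
    stop("'n_p' must be a single integer >= 2", call. = FALSE)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, is.finite(epsilon))
  terms <- list()
  for (i in seq_len(n_p)) {
    for (j in seq_len(n_p)) {
      if (i == j) next
      terms[[length(terms) + 1L]] <- new_term(
        sprintf("coupling p%d->p%d", j, i), "coupling", "linear",
        target = i, source = j, coef = (i - j)^2 * epsilon)
    }
    terms[[length(terms) + 1L]] <- new_term(
      sprintf("inhibition z%d-|p%d", i, i), "z_inhibition", "linear",
      target = i, source = n_p + i, coef = 1, dt_target = -1L)
    terms[[length(terms) + 1L]] <- new_term(
      sprintf("transfer p%d->z%d", i, i), "p_to_z_transfer", "linear",
      target = i, source = i, coef = 1, dt_target = -1L,
      aux = n_p + i, dt_aux = +1L)
  }
  structure(list(name = sprintf("linear_%d", n_p), family = "linear",
                 n_p = n_p, n_z = n_p, params = list(epsilon = epsilon),
                 terms = terms,
                 var_names = c(paste0("p", seq_len(n_p)),
                               paste0("z", seq_len(n_p)))),
            class = "osc_system")
}

#' @export
print.osc_system <- function(x, ...) {
  cat(sprintf("<osc_system> %s family, %d p-process(es), %d z-process(es)\n",
              x$family, x$n_p, x$n_z))
  cat("  parameters:",
      paste(sprintf("%s = %g", names(x$params), unlist(x$params)),
            collapse = ", "), "\n")
  cat(sprintf("  %d additive terms over variables %s\n", length(x$terms),
              paste(x$var_names, collapse = ", ")))
  invisible(x)
}

n_vars <- function(spec) spec$n_p + spec$n_z

## Signed value of one term at a state.
term_value <- function(term, state, spec) {
  switch(term$eval,
         linear = term$coef * state[term$source],
         radial = state[term$source] *
           (term$coef - state[1L]^2 - state[2L]^2),
         stop("unknown term evaluation kind: ", term$eval, call. = FALSE))
}

#' Right-hand side of a system at a state
#'
#' Sums the additive terms of an \code{osc_system} to the ODE right-hand
#' side. Transfer terms contribute to both their p- and z-variables.
#'
#' @param spec an \code{osc_system}.
#' @param state numeric state vector (length \code{n_p + n_z}).
#' @return numeric vector of time derivatives.
#' @export
system_rhs <- function(spec, state) {
  stopifnot(inherits(spec, "osc_system"))
  m <- n_vars(spec)
  if (length(state) != m)
    stop(sprintf("state must have length %d", m), call. = FALSE)
  rhs <- numeric(m)
  for (term in spec$terms) {
    v <- term_value(term, state, spec)
    rhs[term$target] <- rhs[term$target] + term$dt_target * v
    if (!is.na(term$aux))
      rhs[term$aux] <- rhs[term$aux] + term$dt_aux * v
  }
  rhs
}

#' Deterministic integration of a system
#'
#' Integrates the ODEs of an \code{osc_system} on a supplied time grid with
#' \code{deSolve::ode} (lsoda).
#'
#' @param spec an \code{osc_system}.
#' @param init initial state, length \code{n_p + n_z}.
#' @param t_grid strictly increasing time points; the first is the initial
#'   time.
#' @param rtol,atol relative and absolute integrator tolerances.
#' @return a matrix with a \code{time} column followed by one column per
#'   state variable.
#' @examples
#' sys <- nonlinear_system(R = 1)
#' out <- integrate_system(sys, c(1, 0), seq(0, 2 * pi, length.out = 101))
#' max(abs(out[, "p1"] - cos(out[, "time"])))  # ~ integrator tolerance
#' @export
integrate_system <- function(spec, init, t_grid, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(spec, "osc_system"))
  m <- n_vars(spec)
  if (length(init) != m)
    stop(sprintf("'init' must have length %d", m), call. = FALSE)
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0))
    stop("'t_grid' must be strictly increasing with length >= 2",
         call. = FALSE)
  deriv <- function(t, y, parms) list(system_rhs(spec, y))
  out <- deSolve::ode(y = setNames(as.numeric(init), spec$var_names),
                      times = t_grid, func = deriv, parms = NULL,
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1L] < 0)
    stop("integration failed: ", paste(deSolve::diagnostics(out),
                                       collapse = " "), call. = FALSE)
  class(out) <- "matrix"
  out
}

#' Serialize / deserialize a system definition
#'
#' A compact JSON-friendly representation (name, family, sizes, parameter)
#' used by the command-line interface for round-trips. Only the two built-in
#' families are representable.
#'
#' @param spec an \code{osc_system}.
#' @return \code{system_to_list}: a plain named list;
#'   \code{system_from_list}: the reconstructed \code{osc_system}.
#' @export
system_to_list <- function(spec) {
  stopifnot(inherits(spec, "osc_system"))
  c(list(name = spec$name, family = spec$family, n_p = spec$n_p,
         n_z = spec$n_z), spec$params)
}

#' @rdname system_to_list
#' @param x a list as produced by \code{system_to_list}.
#' @export
system_from_list <- function(x) {
  switch(x$family,
         nonlinear = nonlinear_system(x$R),
         linear = linear_system(x$n_p, x$epsilon),
         stop("unknown system family: ", x$family, call. = FALSE))
}
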