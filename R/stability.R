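#' Jacobian matrix of a system
#'
#' Analytic Jacobian of the right-hand side. For the linear family this is
#' the state-independent block matrix \eqn{[[A - I, -I], [I, 0]]}; for the
#' nonlinear family it is evaluated at the given state.
#'
#' @param spec an \code{osc_system}.
#' @param state state vector at which to evaluate (ignored by the linear
#'   family beyond a length check; defaults to the origin).
#' @return a square numeric matrix of dimension \code{n_p + n_z}.
#' @export
system_jacobian <- function(spec, state = numeric(n_vars(spec))) {
  stopifnot(inherits(spec, "osc_system"))
  m <- n_vars(spec)
  if (length(state) != m)
    stop(sprintf("state must have length %d", m), call. = FALSE)
  if (spec$family == "linear") {
    n <- spec$n_p
    A <- coupling_matrix(n, spec$params$epsilon)
    I <- diag(n)
    rbind(cbind(A - I, -I),
          cbind(I, matrix(0, n, n)))
  } else {
    R2 <- spec$params$R^2
    p1 <- state[1L]; p2 <- state[2L]
    r2 <- p1^2 + p2^2
    matrix(c(R2 - r2 - 2 * p1^2, -1 - 2 * p1 * p2,
             1 - 2 * p1 * p2,     R2 - r2 - 2 * p2^2),
           nrow = 2L, byrow = TRUE)
  }
}

## Eigenvalues of the linear system's Jacobian at a given epsilon, sorted
## by imaginary then real part so curves trace continuously over a grid.
linear_eigenvalues <- function(n_p, epsilon) {
  J <- system_jacobian(linear_system(n_p, epsilon))
  ev <- eigen(J, only.values = TRUE)$values
  ev[order(Im(ev), Re(ev))]
}

#' Eigenvalue curves over a coupling-parameter grid
#'
#' Eigenvalues of the 2 n_p-dimensional Jacobian of the linear system at
#' each value of the coupling parameter. Each pair of system eigenvalues is
#' a root of \eqn{\lambda^2 - (a - 1)\lambda + 1 = 0} for an eigenvalue a of
#' the coupling matrix, so the curves inherit the structure of the
#' squared-distance spectrum scaled by epsilon.
#'
#' @param n_p number of p-processes.
#' @param eps_grid numeric vector of coupling values.
#' @return a list with one element per grid value, each a list with fields
#'   \code{epsilon} and \code{eigenvalues} (complex, length 2 n_p, sorted by
#'   imaginary then real part).
#' @export
eigenvalues_vs_epsilon <- function(n_p, eps_grid) {
  stopifnot(n_p >= 2, is.numeric(eps_grid), length(eps_grid) >= 1L)
  lapply(eps_grid, function(e)
    list(epsilon = e, eigenvalues = linear_eigenvalues(n_p, e)))
}

## Largest real part over complex-conjugate eigenvalue pairs; -Inf when the
## spectrum is entirely real. Real-axis crossings are not Hopf points.
max_re_complex <- function(n_p, epsilon, im_tol = 1e-9) {
  ev <- linear_eigenvalues(n_p, epsilon)
  cx <- ev[abs(Im(ev)) > im_tol]
  if (length(cx) == 0L) -Inf else max(Re(cx))
}

#' Locate a Hopf bifurcation of the linear system
#'
#' Finds the coupling value nearest zero on the requested branch at which
#' the largest real part over complex-conjugate Jacobian eigenvalue pairs
#' crosses zero: a coarse scan over the branch followed by bisection.
#' Real-eigenvalue zero crossings are ignored (no imaginary part means no
#' oscillation is born).
#'
#' The two branches are not mirror images for n_p >= 3: the squared-distance
#' matrix spectrum is asymmetric, so the negative-branch magnitude
#' (1/|most negative eigenvalue|) differs from the positive-branch value
#' (1/largest eigenvalue). Both are located honestly by the same scan.
#'
#' @param n_p number of p-processes.
#' @param branch \code{"positive"} or \code{"negative"}: the sign of the
#'   coupling values searched.
#' @param scan_max magnitude bound of the scan range.
#' @param scan_points grid points of the coarse scan.
#' @param tol bisection tolerance on the coupling value.
#' @return an object of class \code{hopf_point}: a list with fields
#'   \code{epsilon}, \code{branch}, \code{imag_at_crossing}, \code{n_p}.
#' @examples
#' hopf_point(2, "positive")$epsilon   # 1
#' hopf_point(3, "negative")$epsilon   # -0.25
#' @export
hopf_point <- function(n_p, branch = c("positive", "negative"),
                       scan_max = 2, scan_points = 2001L, tol = 1e-10) {
  branch <- match.arg(branch)
  stopifnot(n_p >= 2)
  sgn <- if (branch == "positive") 1 else -1
  grid <- sgn * seq(0, scan_max, length.out = scan_points)
  g <- vapply(grid, function(e) max_re_complex(n_p, e), numeric(1))
  cross <- which(is.finite(g[-length(g)]) & is.finite(g[-1L]) &
                   g[-length(g)] < 0 & g[-1L] >= 0)
  if (length(cross) == 0L)
    stop(sprintf("no Hopf crossing found for n_p = %d on the %s branch within |epsilon| <= %g",
                 n_p, branch, scan_max), call. = FALSE)
  lo <- grid[cross[1L]]; hi <- grid[cross[1L] + 1L]
  while (abs(hi - lo) > tol) {
    mid <- (lo + hi) / 2
    if (max_re_complex(n_p, mid) < 0) lo <- mid else hi <- mid
  }
  eps <- (lo + hi) / 2
  ev <- linear_eigenvalues(n_p, eps)
  cx <- ev[abs(Im(ev)) > 1e-9]
  im <- abs(Im(cx[which.max(Re(cx))]))
  structure(list(epsilon = eps, branch = branch, imag_at_crossing = im,
                 n_p = n_p),
            class = "hopf_point")
}

#' @export
print.hopf_point <- function(x, ...) {
  cat(sprintf(
    "<hopf_point> n_p = %d, %s branch: epsilon = %.10g (crossing frequency %.6g rad/time)\n",
    x$n_p, x$branch, x$epsilon, x$imag_at_crossing))
  invisible(x)
}

#' Classify the dynamical regime of the linear system
#'
#' From the sign of the largest real part over complex-conjugate eigenvalue
#' pairs: negative gives a spiral sink (decaying oscillation), positive a
#' spiral source (growing oscillation), and within tolerance of zero the
#' marginal constant-amplitude oscillation at the Hopf point.
#'
#' @param n_p number of p-processes.
#' @param epsilon coupling parameter.
#' @param tol half-width of the marginal band on the real part.
#' @return one of \code{"spiral_sink"}, \code{"spiral_source"},
#'   \code{"marginal_oscillation"}.
#' @export
classify_regime <- function(n_p, epsilon, tol = 1e-9) {
  stopifnot(is.finite(epsilon))
  mre <- max_re_complex(n_p, epsilon)
  if (!is.finite(mre))
    stop("no complex eigenvalue pair at this coupling value", call. = FALSE)
  if (abs(mre) <= tol) "marginal_oscillation"
  else if (mre < 0) "spiral_sink"
  else "spiral_source"
}

#' One-parameter bifurcation diagram of the linear system
#'
#' Tabulates, over a grid of coupling values, the steady state (the origin),
#' its stability classification, and an oscillation amplitude estimated by a
#' short deterministic simulation past an initial transient (no numerical
#' continuation is attempted: sinks decay to 0, sources grow, the marginal
#' point holds its initial amplitude).
#'
#' @param n_p number of p-processes.
#' @param eps_range length-2 numeric, the coupling interval.
#' @param n_points grid size.
#' @param t_max simulation horizon for the amplitude estimate.
#' @param init_amplitude initial p_1 value for the amplitude simulation.
#' @return a data.frame with columns \code{epsilon}, \code{steady_state},
#'   \code{regime}, \code{amplitude} (max |p_1| over the trailing half of
#'   the simulation, clipped at overflow for sources).
#' @export
bifurcation_diagram <- function(n_p, eps_range = c(-1.5, 1.5),
                                n_points = 61L, t_max = 60,
                                init_amplitude = 1) {
  stopifnot(length(eps_range) == 2L, all(is.finite(eps_range)))
  eps <- seq(eps_range[1L], eps_range[2L], length.out = n_points)
  regime <- vapply(eps, function(e) classify_regime(n_p, e), character(1))
  amp <- vapply(eps, function(e) {
    spec <- linear_system(n_p, e)
    init <- c(init_amplitude, numeric(2 * n_p - 1))
    tg <- seq(0, t_max, length.out = 257L)
    out <- tryCatch(integrate_system(spec, init, tg),
                    error = function(err) NULL)
    if (is.null(out)) return(Inf)
    tail_p1 <- out[tg > t_max / 2, "p1"]
    max(abs(tail_p1))
  }, numeric(1))
  data.frame(epsilon = eps, steady_state = 0, regime = regime,
             amplitude = amp)
}
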