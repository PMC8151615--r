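## Cache of located Hopf points: the scan+bisection is deterministic, so
## repeated experiment calls reuse it.
.hopf_cache <- new.env(parent = emptyenv())

#' Default coupling value for stochastic runs of the linear system
#'
#' The negative-branch Hopf value for the given size, located by
#' [hopf_point()] and cached. At this coupling the system is exactly
#' marginal: one eigenvalue pair sits on the imaginary axis and sustained
#' constant-amplitude oscillations persist, which is the regime in which
#' the stochastic trajectories of all sizes remain bounded and oscillating
#' over the full horizon. (The positive branch lies closer to zero for
#' three or more p-processes, so a positive coupling of the same magnitude
#' would be a spiral source and blow up.)
#'
#' @param n_p number of p-processes.
#' @return the (negative) coupling value.
#' @export
default_epsilon <- function(n_p) {
  key <- as.character(n_p)
  if (is.null(.hopf_cache[[key]]))
    .hopf_cache[[key]] <- hopf_point(n_p, "negative")$epsilon
  .hopf_cache[[key]]
}

## Shared pipeline: event trajectory -> 1024-point zero-order-hold series
## -> one-sided PSD -> normalized -> spectral entropy.
trajectory_entropy <- function(traj, variable, n_points = 1024L,
                               t_max = NULL) {
  series <- resample_zoh(traj, variable, n_points, t_max)
  spectral_entropy(normalize_psd(power_spectrum(series)))
}

#' Stochastic limit-cycle demonstration
#'
#' Runs the full pipeline on the nonlinear two-process oscillator: an exact
#' stochastic simulation started on the cycle at (R, 0), the phase-plane
#' trajectory, the normalized power spectrum, and the spectral entropy of
#' each process.
#'
#' @param R limit-cycle radius (at least 10; below that the unit jumps of
#'   the stochastic states are too coarse relative to the cycle).
#' @param t_max simulation horizon.
#' @param seed RNG seed.
#' @param n_points resampling resolution (power of two).
#' @return a list with \code{trajectory}, \code{spectra} (normalized, one
#'   per process), \code{entropy} (named numeric, one value per process),
#'   \code{phase_plane} (two-column matrix of resampled p1, p2).
#' @examples
#' \donttest{
#' demo <- run_nonlinear_demo(R = 100, t_max = 370, seed = 1)
#' demo$entropy   # ~0.5 for both processes
#' }
#' @export
run_nonlinear_demo <- function(R = 100, t_max = 370, seed = 1,
                               n_points = 1024L) {
  if (R < 10)
    stop("'R' must be at least 10: unit state jumps are too coarse below that",
         call. = FALSE)
  spec <- nonlinear_system(R)
  traj <- ssa_run(spec, c(round(R), 0), t_max = t_max, seed = seed)
  if (traj$terminated_reason == "extinction")
    stop("trajectory went extinct before t_max; increase R to deepen the cycle",
         call. = FALSE)
  spectra <- lapply(1:2, function(v)
    normalize_psd(power_spectrum(resample_zoh(traj, v, n_points, t_max))))
  entropy <- vapply(spectra, spectral_entropy, numeric(1))
  names(entropy) <- names(spectra) <- spec$var_names
  series <- lapply(1:2, function(v)
    resample_zoh(traj, v, n_points, t_max)$values)
  list(trajectory = traj, spectra = spectra, entropy = entropy,
       phase_plane = cbind(p1 = series[[1L]], p2 = series[[2L]]))
}

#' Spectral entropy as a function of system size
#'
#' For each size, simulates the linear system of coupled oscillators at its
#' marginal (Hopf) coupling value and computes the spectral entropy of
#' every p-process (z-processes are companions and are excluded from the
#' summary). One trajectory supplies the entropies of all processes of a
#' size; replicates repeat the whole run with derived seeds.
#'
#' @param sizes numbers of p-processes (each at least 2).
#' @param replicates independent runs per size.
#' @param seed master seed; run seeds are derived from it deterministically.
#' @param epsilon optional named or positional vector of coupling values
#'   overriding [default_epsilon()] per size.
#' @param init_amplitude initial p_1 value (all other variables start at
#'   0).
#' @param t_max simulation horizon.
#' @param n_points resampling resolution.
#' @param max_retries bounded reseeding on extinction or overflow.
#' @return an object of class \code{entropy_table}: list with \code{rows}
#'   (data.frame: n_p, replicate, process, S, seed), \code{averages}
#'   (data.frame: n_p, S_mean), and the configuration used.
#' @examples
#' \donttest{
#' tab <- run_entropy_vs_size(sizes = c(2, 4, 8), seed = 1)
#' tab$averages
#' }
#' @export
run_entropy_vs_size <- function(sizes = c(2, 4, 8), replicates = 1L,
                                seed = 1, epsilon = NULL,
                                init_amplitude = 100, t_max = 370,
                                n_points = 1024L, max_retries = 3L) {
  stopifnot(all(sizes >= 2), replicates >= 1)
  rows <- list()
  for (si in seq_along(sizes)) {
    n <- as.integer(sizes[si])
    eps <- if (is.null(epsilon)) default_epsilon(n) else epsilon[si]
    spec <- linear_system(n, eps)
    init <- c(round(init_amplitude), integer(2L * n - 1L))
    for (rep in seq_len(replicates)) {
      run_seed <- (as.integer(seed) + 1009L * si + 97L * rep) %% .Machine$integer.max
      attempt <- 0L
      repeat {
        traj <- tryCatch(
          ssa_run(spec, init, t_max = t_max, seed = run_seed),
          error = function(e) e)
        ok <- inherits(traj, "ssa_trajectory") &&
          traj$terminated_reason == "t_max"
        if (ok || attempt >= max_retries) break
        attempt <- attempt + 1L
        run_seed <- (run_seed + 7919L * attempt) %% .Machine$integer.max
      }
      if (!inherits(traj, "ssa_trajectory"))
        stop("simulation failed for n_p = ", n, ": ",
             conditionMessage(traj), call. = FALSE)
      S <- vapply(seq_len(n), function(v)
        trajectory_entropy(traj, v, n_points, t_max), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        n_p = n, replicate = rep, process = paste0("p", seq_len(n)),
        S = S, seed = run_seed)
    }
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  averages <- aggregate(S ~ n_p, rows, mean)
  names(averages)[2L] <- "S_mean"
  structure(list(rows = rows, averages = averages,
                 config = list(sizes = sizes, replicates = replicates,
                               seed = seed,
                               epsilon = if (is.null(epsilon))
                                 vapply(sizes, default_epsilon, numeric(1))
                               else epsilon,
                               init_amplitude = init_amplitude,
                               t_max = t_max, n_points = n_points)),
            class = "entropy_table")
}

#' @export
print.entropy_table <- function(x, ...) {
  cat("<entropy_table> spectral entropy by system size\n")
  print(x$rows[, c("n_p", "process", "S")], row.names = FALSE)
  cat("averages:\n")
  print(x$averages, row.names = FALSE)
  invisible(x)
}

#' Linear fit of average spectral entropy against log2 system size
#'
#' Ordinary least squares of the per-size average entropy on
#' \eqn{\log_2 n_p}: the slope is the entropy change per doubling of the
#' system.
#'
#' @param table an \code{entropy_table}, or a data.frame with columns
#'   \code{n_p} and \code{S_mean}.
#' @return an object of class \code{scaling_fit}: list with \code{slope},
#'   \code{intercept}, \code{r_squared} and the fitted \code{lm} object.
#' @export
fit_entropy_scaling <- function(table) {
  av <- if (inherits(table, "entropy_table")) table$averages else table
  stopifnot(all(c("n_p", "S_mean") %in% names(av)))
  if (length(unique(av$n_p)) < 3L)
    stop("at least 3 distinct sizes are needed for a scaling fit",
         call. = FALSE)
  d <- data.frame(x = log2(av$n_p), y = av$S_mean)
  fit <- lm(y ~ x, data = d)
  sst <- sum((d$y - mean(d$y))^2)
  r2 <- if (sst > 0) 1 - sum(residuals(fit)^2) / sst else 1
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = r2,
                 x_definition = "log2(n_p)", lm = fit),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<scaling_fit> S = %.4f %+.4f * log2(n_p)   (R^2 = %.4f)\n",
    x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Dominant spectral frequency as a function of system size
#'
#' For each size, simulates the linear system under the default
#' configuration and reports the modal frequency of the normalized power
#' spectrum averaged over the p-processes (the per-process spectra are
#' nearly identical; averaging reduces the Monte-Carlo error of the mode
#' location).
#'
#' @inheritParams run_entropy_vs_size
#' @return a data.frame with columns \code{n_p}, \code{peak_frequency};
#'   the attribute \code{"monotone_increasing"} reports whether the peak
#'   frequency increases with size (NA for a single size).
#' @export
run_spectrum_shift_check <- function(sizes = c(2, 8), seed = 1,
                                     epsilon = NULL, init_amplitude = 100,
                                     t_max = 370, n_points = 1024L) {
  stopifnot(length(sizes) >= 1L)
  peak <- numeric(length(sizes))
  for (si in seq_along(sizes)) {
    n <- as.integer(sizes[si])
    eps <- if (is.null(epsilon)) default_epsilon(n) else epsilon[si]
    spec <- linear_system(n, eps)
    init <- c(round(init_amplitude), integer(2L * n - 1L))
    run_seed <- (as.integer(seed) + 1009L * si) %% .Machine$integer.max
    traj <- ssa_run(spec, init, t_max = t_max, seed = run_seed)
    psd <- 0
    for (v in seq_len(n))
      psd <- psd + normalize_psd(power_spectrum(
        resample_zoh(traj, v, n_points, t_max)))$psd
    psd <- psd / n
    freqs <- seq_len(n_points %/% 2L) / t_max
    if (all(psd == 0)) stop("degenerate spectrum", call. = FALSE)
    peak[si] <- freqs[which.max(psd)]
  }
  out <- data.frame(n_p = as.integer(sizes), peak_frequency = peak)
  attr(out, "monotone_increasing") <-
    if (length(sizes) < 2L) NA else all(diff(peak[order(sizes)]) > 0)
  out
}
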