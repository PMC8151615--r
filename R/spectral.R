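#' Resample an event trajectory onto a uniform grid
#'
#' Zero-order-hold resampling: the value at grid time t is the state at the
#' last event time at or before t (right-continuous at event times). This
#' is the exact sample-path interpretation of a jump-process trajectory.
#' The grid has \code{n_points} samples at spacing \code{t_max/n_points}
#' starting at 0; a trajectory ending before \code{t_max} is extended by
#' holding its final state.
#'
#' @param traj an \code{ssa_trajectory}, or a list with \code{times} and a
#'   \code{states} matrix.
#' @param variable column index (or name) of the variable to extract.
#' @param n_points number of samples, a power of two (default 1024).
#' @param t_max total time spanned by the grid (default: the trajectory's
#'   final time).
#' @return an object of class \code{uniform_series}: list with
#'   \code{values}, \code{dt}, \code{t0}.
#' @export
resample_zoh <- function(traj, variable = 1L, n_points = 1024L,
                         t_max = NULL) {
  if (is.null(traj$times) || length(traj$times) == 0L)
    stop("empty trajectory", call. = FALSE)
  n_points <- as.integer(n_points)
  if (n_points < 2L || bitwAnd(n_points, n_points - 1L) != 0L)
    stop("'n_points' must be a power of two", call. = FALSE)
  if (is.null(t_max)) t_max <- max(traj$times)
  stopifnot(t_max > 0)
  dt <- t_max / n_points
  grid <- (seq_len(n_points) - 1L) * dt
  x <- traj$states[, variable]
  idx <- findInterval(grid, traj$times)  # last event time <= t
  idx[idx < 1L] <- 1L
  structure(list(values = as.numeric(x[idx]), dt = dt, t0 = 0),
            class = "uniform_series")
}

#' One-sided power spectral density of a uniform series
#'
#' Mean-subtracts the series, takes its discrete Fourier transform (no
#' window), and returns the one-sided spectrum over bins i = 1..N/2 with
#' \eqn{PSD_i = |p(f_i)|^2 / (2\Delta f)}, \eqn{f_i = i\,\Delta f} and
#' \eqn{\Delta f = 1/(N\,dt)}. The DC bin is excluded; mean subtraction
#' makes it zero anyway, and would otherwise let a constant state offset
#' dominate the entropy of the normalized spectrum.
#'
#' @param series a \code{uniform_series}.
#' @return an object of class \code{power_spectrum}: list with
#'   \code{frequencies}, \code{psd} (both length N/2), \code{df},
#'   \code{normalized} flag.
#' @export
power_spectrum <- function(series) {
  stopifnot(inherits(series, "uniform_series"))
  x <- series$values
  if (any(!is.finite(x))) stop("non-finite values in series", call. = FALSE)
  N <- length(x)
  X <- fft(x - mean(x))
  df <- 1 / (N * series$dt)
  i <- seq_len(N %/% 2L)
  structure(list(frequencies = i * df,
                 psd = Mod(X[i + 1L])^2 / (2 * df),
                 df = df, normalized = FALSE),
            class = "power_spectrum")
}

#' Normalize a power spectrum to unit total power
#'
#' @param ps a \code{power_spectrum}.
#' @return the same spectrum with \code{psd} summing to 1 and the
#'   \code{normalized} flag set.
#' @export
normalize_psd <- function(ps) {
  stopifnot(inherits(ps, "power_spectrum"))
  total <- sum(ps$psd)
  if (total <= 0)
    stop("degenerate all-zero spectrum: normalization (and entropy) undefined",
         call. = FALSE)
  ps$psd <- ps$psd / total
  ps$normalized <- TRUE
  ps
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, df = %.5g, %s\n",
              length(x$psd), x$df,
              if (x$normalized) "normalized" else "unnormalized"))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, ...) {
  graphics::plot(x$frequencies, x$psd, type = "h",
                 xlab = "frequency (1/arb. u.)",
                 ylab = if (x$normalized) "normalized PSD" else "PSD", ...)
  invisible(x)
}

#' Spectral entropy of a normalized power spectrum
#'
#' Shannon entropy of the normalized spectral distribution, scaled to
#' [0, 1]:
#' \deqn{S = -k \sum_i \hat{PSD}_i \log_2 \hat{PSD}_i, \qquad
#'       k = 1/\log_2(\mathrm{n~bins})}
#' with the convention \eqn{0 \log 0 = 0}. For the default 512 bins
#' \eqn{k = 1/\log_2(512) = 1/9 \approx 0.1}. S is 1 for a flat (white)
#' spectrum and 0 for a single pure tone; it measures how noise-like a
#' signal's frequency content is.
#'
#' @param ps a normalized \code{power_spectrum}, or a bare numeric vector
#'   of normalized spectral weights.
#' @return spectral entropy in [0, 1].
#' @examples
#' spectral_entropy(rep(1 / 512, 512))      # 1
#' spectral_entropy(c(1, numeric(511)))     # 0
#' @export
spectral_entropy <- function(ps) {
  p <- if (inherits(ps, "power_spectrum")) {
    if (!ps$normalized)
      stop("spectrum must be normalized first (see normalize_psd)",
           call. = FALSE)
    ps$psd
  } else {
    stopifnot(is.numeric(ps), all(ps >= 0))
    if (abs(sum(ps) - 1) > 1e-8)
      stop("spectral weights must sum to 1", call. = FALSE)
    ps
  }
  k <- 1 / log2(length(p))
  nz <- p[p > 0]
  -k * sum(nz * log2(nz))
}

#' Occupancy histogram of a trajectory variable
#'
#' Histogram of a variable's values over the uniformly resampled
#' trajectory, so each state is weighted by its holding time. Counts sum to
#' the number of resampled points.
#'
#' @param traj an \code{ssa_trajectory}.
#' @param variable column index (or name).
#' @param n_bins number of equal-width bins over the observed range.
#' @param n_points resampling resolution.
#' @param t_max end of the occupancy window; the final state is held until
#'   this time. Defaults to the last event time.
#' @return a list with \code{breaks} (length n_bins + 1) and \code{counts}
#'   (length n_bins).
#' @export
state_histogram <- function(traj, variable = 1L, n_bins = 30L,
                            n_points = 1024L, t_max = NULL) {
  if (n_bins < 1L) stop("'n_bins' must be at least 1", call. = FALSE)
  if (is.null(t_max)) t_max <- max(traj$times)
  if (t_max <= 0) t_max <- 1  # single event at t = 0: any hold length works
  x <- resample_zoh(traj, variable, n_points, t_max = t_max)$values
  rng <- range(x)
  if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  list(breaks = h$breaks, counts = h$counts)
}

#' Write a spectrum to CSV
#'
#' Columns \code{frequency}, \code{psd}, \code{psd_normalized}.
#'
#' @param ps a \code{power_spectrum} (normalized or not).
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_spectrum <- function(ps, file) {
  stopifnot(inherits(ps, "power_spectrum"))
  raw <- if (ps$normalized) ps$psd * NA_real_ else ps$psd
  norm <- if (ps$normalized) ps$psd else ps$psd / sum(ps$psd)
  write.csv(data.frame(frequency = ps$frequencies, psd = raw,
                       psd_normalized = norm),
            file, row.names = FALSE)
  invisible(file)
}
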