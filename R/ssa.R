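#' Decompose a system into stochastic event channels
#'
#' Builds the event channels for exact stochastic simulation. A channel
#' with signed value v at the current state fires with propensity |v| and
#' moves its target variable by sign(v) (times the channel's direction), so
#' the expected drift of the jump process equals the deterministic
#' right-hand side at every state. The transfer channel of the linear
#' family fires with propensity |p_i| and moves one unit from p_i to z_i
#' when p_i is positive, and the reverse when it is negative.
#'
#' Two granularities are available for the linear family's coupling drive.
#' With \code{coupling = "net"} (the default) each process has one drive
#' channel whose value is the whole row sum \eqn{(A p)_i}: the process
#' increases or decreases at the net drive rate, giving three event kinds
#' per process (drive increase/decrease, inhibition by z_i, transition to
#' z_i). With \code{coupling = "per_term"} every pairwise coupling term
#' j -> i is its own channel; the drift is identical but opposing terms no
#' longer cancel inside a channel, so the jump noise is larger (by the sum
#' of the cancelled magnitudes), increasingly so for larger systems.
#'
#' States are signed counts: the deterministic solutions oscillate through
#' negative values, so propensities use magnitudes with sign-directed
#' stoichiometry.
#'
#' @param spec an \code{osc_system}.
#' @param coupling \code{"net"} (one drive channel per process) or
#'   \code{"per_term"} (one channel per additive coupling term).
#' @return a list of channels, each with fields \code{label}, \code{kind},
#'   \code{propensity} (state -> non-negative rate) and
#'   \code{stoichiometry} (state -> integer delta vector), plus the numeric
#'   encoding consumed by the compiled simulator as attributes.
#' @seealso [ssa_run()]
#' @export
decompose_channels <- function(spec, coupling = c("net", "per_term")) {
  stopifnot(inherits(spec, "osc_system"))
  coupling <- match.arg(coupling)
  m <- n_vars(spec)

  ## channel descriptors: like terms, but coupling rows may be merged
  descr <- list()
  if (spec$family == "linear" && coupling == "net") {
    A <- coupling_matrix(spec$n_p, spec$params$epsilon)
    for (term in spec$terms) {
      if (term$kind == "coupling") next
      descr[[length(descr) + 1L]] <- term
    }
    for (i in seq_len(spec$n_p)) {
      row <- numeric(m)
      row[seq_len(spec$n_p)] <- A[i, ]
      descr[[length(descr) + 1L]] <- list(
        label = sprintf("drive p%d", i), kind = "coupling", eval = "row",
        target = i, source = i, coef = 1, dt_target = 1L,
        aux = NA_integer_, dt_aux = 0L, row = row)
    }
  } else {
    descr <- spec$terms
  }

  value_of <- function(d, state) {
    if (identical(d$eval, "row")) sum(d$row * state)
    else term_value(d, state, spec)
  }
  channels <- lapply(descr, function(d) {
    force(d)
    list(
      label = d$label,
      kind = d$kind,
      propensity = function(state) abs(value_of(d, state)),
      stoichiometry = function(state) {
        v <- value_of(d, state)
        delta <- integer(m)
        delta[d$target] <- d$dt_target * sign(v)
        if (!is.na(d$aux))
          delta[d$aux] <- d$dt_aux * sign(v)
        delta
      }
    )
  })
  tab <- t(vapply(descr, function(d) {
    c(eval_kind = switch(d$eval, linear = 0, radial = 1, row = 2),
      source = d$source, coef = d$coef, target = d$target,
      dt_target = d$dt_target,
      aux = if (is.na(d$aux)) 0 else d$aux,
      dt_aux = d$dt_aux)
  }, numeric(7)))
  rowcoef <- matrix(0, nrow = length(descr), ncol = m)
  for (k in seq_along(descr))
    if (identical(descr[[k]]$eval, "row"))
      rowcoef[k, ] <- descr[[k]]$row
  attr(channels, "table") <- tab
  attr(channels, "rowcoef") <- rowcoef
  attr(channels, "n_vars") <- m
  attr(channels, "var_names") <- spec$var_names
  channels
}

#' Expected drift of a channel set
#'
#' Sums propensity times stoichiometry over all channels at a state. By
#' construction this equals [system_rhs()] exactly; exposed for
#' consistency checking.
#'
#' @param channels a channel list from [decompose_channels()].
#' @param state numeric state vector.
#' @return numeric drift vector.
#' @export
channel_drift <- function(channels, state) {
  m <- attr(channels, "n_vars")
  drift <- numeric(m)
  for (ch in channels)
    drift <- drift + ch$propensity(state) * ch$stoichiometry(state)
  drift
}

#' Waiting time and channel choice for one stochastic event
#'
#' The direct-method sampling step: given the propensities a and two
#' uniform(0,1) variates, the waiting time is \eqn{\tau = -\ln(r_1)/\sum a}
#' and the fired channel is the unique i with
#' \eqn{\sum_{k<i} a_k / \sum a \le r_2 < \sum_{k \le i} a_k / \sum a}
#' (left-closed, right-open at the cumulative boundaries).
#'
#' @param propensities non-negative rates, at least one positive.
#' @param r1,r2 uniform(0,1) variates.
#' @return a list with \code{tau} (waiting time) and \code{channel}
#'   (1-based index), or \code{NULL} when all propensities are zero
#'   (extinction: the caller terminates the run).
#' @export
next_event <- function(propensities, r1, r2) {
  stopifnot(all(propensities >= 0), r1 > 0, r1 < 1, r2 >= 0, r2 < 1)
  total <- sum(propensities)
  if (total <= 0) return(NULL)
  tau <- -log(r1) / total
  cum <- cumsum(propensities) / total
  channel <- which(r2 < cum)[1L]
  list(tau = tau, channel = channel)
}

#' Run an exact stochastic simulation
#'
#' Simulates the continuous-time Markov jump process defined by a system's
#' event channels with the Gillespie direct method: repeatedly compute all
#' propensities, draw an exponential waiting time from the total, pick a
#' channel proportionally to its propensity, apply its stoichiometry and
#' advance time. Every event is recorded. The run terminates at the time
#' horizon, at the event cap, or when every propensity is zero (the origin
#' is absorbing).
#'
#' @param x an \code{osc_system} or a channel list from
#'   [decompose_channels()].
#' @param init integer initial state.
#' @param t_max time horizon (arbitrary units), positive.
#' @param seed integer seed; the run is reproducible given it.
#' @param max_events cap on the number of events.
#' @param coupling channel granularity, passed to [decompose_channels()]
#'   when \code{x} is a system.
#' @return an object of class \code{ssa_trajectory}: list with
#'   \code{times} (length n_events + 1, starting at 0), \code{states}
#'   (integer matrix, one row per recorded step), \code{var_names},
#'   \code{seed}, \code{n_events}, \code{terminated_reason}.
#' @examples
#' sys <- nonlinear_system(R = 100)
#' traj <- ssa_run(sys, c(100, 0), t_max = 10, seed = 1)
#' traj
#' @export
ssa_run <- function(x, init, t_max, seed, max_events = 5e6,
                    coupling = c("net", "per_term")) {
  channels <- if (inherits(x, "osc_system"))
    decompose_channels(x, match.arg(coupling)) else x
  tab <- attr(channels, "table")
  if (is.null(tab))
    stop("'x' must be an osc_system or the result of decompose_channels()",
         call. = FALSE)
  m <- attr(channels, "n_vars")
  if (length(init) != m)
    stop(sprintf("'init' must have length %d", m), call. = FALSE)
  stopifnot(t_max > 0, max_events > 0)
  init <- as.integer(round(init))
  set.seed(as.integer(seed))
  res <- .ssa_core(tab, attr(channels, "rowcoef"), init,
                   as.numeric(t_max), as.numeric(max_events))
  states <- res$states
  colnames(states) <- attr(channels, "var_names")
  structure(list(times = res$times, states = states,
                 var_names = attr(channels, "var_names"),
                 seed = as.integer(seed), n_events = res$n_events,
                 terminated_reason = res$terminated_reason),
            class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ssa_trajectory> %d variable(s), %g event(s), t in [0, %.4g], seed %d, terminated: %s\n",
    ncol(x$states), x$n_events, max(x$times), x$seed, x$terminated_reason))
  invisible(x)
}

#' @export
plot.ssa_trajectory <- function(x, variables = seq_len(ncol(x$states)),
                                ...) {
  pal <- grDevices::hcl.colors(max(length(variables), 2L), "Dark 2")
  graphics::matplot(x$times, x$states[, variables, drop = FALSE],
                    type = "s", lty = 1, col = pal,
                    xlab = "time (arb. u.)", ylab = "state", ...)
  graphics::legend("topright", legend = x$var_names[variables], col = pal,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Write a trajectory to CSV (with a JSON metadata sidecar)
#'
#' @param traj an \code{ssa_trajectory}.
#' @param file output CSV path; the sidecar is written next to it with a
#'   \code{.json} extension when the jsonlite package is available.
#' @return the CSV path, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "ssa_trajectory"))
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  write.csv(df, file, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    meta <- list(seed = traj$seed, n_events = traj$n_events,
                 terminated_reason = traj$terminated_reason,
                 variables = traj$var_names)
    jsonlite::write_json(meta, sub("\\.csv$", ".json", file),
                         auto_unbox = TRUE)
  }
  invisible(file)
}
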