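## Replicator dynamics on the strategy simplex: right-hand sides, numerical
## integration (deSolve, adaptive explicit Runge-Kutta), and oscillation
## detection for long-run trajectory classification.

#' Gradient of selection of the two-strategy model
#'
#' `dx/dt = x (1 - x) (P_C - P_D)` evaluated at the state `(x, 1 - x, 0)`.
#' Its sign pattern over `[0, 1]` defines the game regime (defection-only,
#' coordination, or cooperation-only).
#'
#' @param x Cooperator frequency (vectorized), in `[0, 1]`.
#' @param params A [qs_params()] object.
#' @return `dx/dt` at each `x`; zero at the boundaries.
#' @examples
#' gradient_of_selection(c(0, 0.5, 1), qs_params(p = 0.6, q = 0, Delta = 0))
#' @export
gradient_of_selection <- function(x, params) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("x must lie in [0, 1]")
  vapply(x, function(xi) {
    pay <- expected_payoffs(c(xi, 1 - xi, 0), params)
    xi * (1 - xi) * (pay[["pC"]] - pay[["pD"]])
  }, numeric(1))
}

#' Replicator right-hand side on the simplex
#'
#' `dx/dt = x (P_C - Pbar)`, `dy/dt = y (P_D - Pbar)`,
#' `dz/dt = z (P_CD - Pbar)` with `Pbar` the population-mean payoff. The
#' components sum to zero, so the flow is tangent to the simplex, and every
#' vertex is a fixed point.
#'
#' @param state A simplex state `(x, y, z)`.
#' @param params A [qs_params()] object.
#' @return Named numeric vector `c(x = , y = , z = )` of time derivatives.
#' @export
replicator_rhs <- function(state, params) {
  check_state(state)
  pay <- expected_payoffs(state, params)
  d <- as.numeric(state) * (pay[c("pC", "pD", "pCD")] - pay[["pBar"]])
  names(d) <- c("x", "y", "z")
  d
}

## RHS used inside the solver: skips revalidation, tolerates the tiny
## off-simplex excursions of intermediate RK stages by clipping for the
## payoff evaluation only.
replicator_rhs_ode <- function(t, state, parms) {
  s <- pmax(state, 0)
  s <- s / sum(s)
  pay <- expected_payoffs_raw(s, parms)
  list(state * (pay[1:3] - pay[4]))
}

## expected_payoffs without state validation (solver hot path).
expected_payoffs_raw <- function(state, params) {
  tab <- composition_table(params$N)
  pC <- expected_payoff_one("C", state, params, tab)
  pD <- expected_payoff_one("D", state, params, tab)
  pCD <- expected_payoff_one("CD", state, params, tab)
  c(pC, pD, pCD, state[[1]] * pC + state[[2]] * pD + state[[3]] * pCD)
}

#' Integrate the replicator dynamics
#'
#' Solves the three-strategy replicator system with an adaptive explicit
#' Runge-Kutta method (Dormand-Prince 4(5) via \pkg{deSolve}), returning the
#' trajectory at equally spaced output times. Boundary faces of the simplex
#' are invariant: a strategy starting at exactly 0 stays at exactly 0.
#' After integration, roundoff-scale negative components (above `-1e-9`) are
#' clipped to zero and each state renormalized; larger violations raise an
#' error carrying the last valid state.
#'
#' @param state0 Initial simplex state.
#' @param params A [qs_params()] object.
#' @param t_end Time horizon in model time units (> 0). Default 2000, long
#'   enough for fixation/oscillation classification.
#' @param n_out Number of equally spaced output points (default 2001).
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return An object of class `qs_trajectory`: list with `times` (length
#'   `n_out`), `states` (`n_out` x 3 matrix, columns `x`, `y`, `z`), and
#'   `params`.
#' @examples
#' tr <- integrate_replicator(pop_state(0.4, 0.3, 0.3), qs_params(),
#'                            t_end = 50, n_out = 101)
#' head(as.data.frame(tr))
#' @export
integrate_replicator <- function(state0, params, t_end = 2000, n_out = 2001,
                                 rtol = 1e-8, atol = 1e-10) {
  check_state(state0)
  stopifnot("t_end must be positive" = t_end > 0,
            "n_out must be >= 2" = n_out >= 2)
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = as.numeric(state0), times = times,
                      func = replicator_rhs_ode, parms = params,
                      method = "ode45", rtol = rtol, atol = atol)
  states <- unname(sol[, 2:4, drop = FALSE])
  if (nrow(states) < n_out || any(!is.finite(states))) {
    last <- max(which(apply(is.finite(states), 1, all)))
    stop(sprintf(
      "replicator solver failed at t = %g; last valid state (%g, %g, %g)",
      sol[last, 1], states[last, 1], states[last, 2], states[last, 3]))
  }
  if (min(states) < -1e-9) {
    i <- which(states < -1e-9, arr.ind = TRUE)[1, 1]
    stop(sprintf(
      "simplex violation beyond tolerance at t = %g; state (%g, %g, %g)",
      times[i], states[i, 1], states[i, 2], states[i, 3]))
  }
  states[states < 0] <- 0
  states <- states / rowSums(states)
  colnames(states) <- c("x", "y", "z")
  structure(list(times = times, states = states, params = params),
            class = "qs_trajectory")
}

#' @export
print.qs_trajectory <- function(x, ...) {
  n <- length(x$times)
  final <- x$states[n, ]
  cat(sprintf("Replicator trajectory: %d points over t = [%g, %g]\n",
              n, x$times[1], x$times[n]))
  cat(sprintf("  final state: x = %.4f, y = %.4f, z = %.4f\n",
              final[1], final[2], final[3]))
  invisible(x)
}

#' @export
as.data.frame.qs_trajectory <- function(x, ...) {
  data.frame(t = x$times, x = x$states[, "x"], y = x$states[, "y"],
             z = x$states[, "z"])
}

#' Plot a replicator trajectory as frequency time series
#'
#' Cooperator in black, defector in red, conditional defector in blue — the
#' conventional colour coding for the three strategists.
#'
#' @param x A `qs_trajectory`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.qs_trajectory <- function(x, ...) {
  graphics::matplot(x$times, x$states, type = "l", lty = 1,
                    col = c("black", "red", "blue"),
                    xlab = "time (model units)", ylab = "frequency",
                    ylim = c(0, 1), ...)
  graphics::legend("topright", legend = c("C", "D", "CD"),
                   col = c("black", "red", "blue"), lty = 1, bty = "n")
}

#' Detect sustained oscillations in a trajectory
#'
#' Discards an initial transient, then finds strict three-point local maxima
#' of the cooperator frequency `x(t)`. The trajectory is called oscillating
#' when at least 3 peaks remain and the peak-to-trough amplitude of `x(t)`
#' exceeds the threshold. The coexistence flag records whether every
#' frequency stays inside `(1e-6, 1 - 1e-6)` over the whole trajectory.
#'
#' @param traj A `qs_trajectory`.
#' @param transient_fraction Fraction of initial samples discarded before
#'   peak counting (default 0.2).
#' @param amplitude_threshold Minimum peak-to-trough range of `x(t)` for the
#'   oscillating call (default 1e-3).
#' @return An object of class `qs_oscillation`: list with `oscillating`,
#'   `n_peaks`, `period_estimate` (mean peak spacing; `NA` with < 2 peaks),
#'   `amplitude`, and `coexistence`.
#' @export
detect_oscillation <- function(traj, transient_fraction = 0.2,
                               amplitude_threshold = 1e-3) {
  stopifnot(inherits(traj, "qs_trajectory"),
            transient_fraction >= 0, transient_fraction < 1)
  n <- length(traj$times)
  start <- floor(n * transient_fraction) + 1L
  if (n - start + 1L < 50)
    stop("trajectory too short: need >= 50 samples after transient removal")
  xs <- traj$states[start:n, "x"]
  ts <- traj$times[start:n]
  m <- length(xs)
  ## strict three-point maxima; a flat run of tied samples yields no peak,
  ## so ties never double count
  is_peak <- xs[2:(m - 1)] > xs[1:(m - 2)] & xs[2:(m - 1)] > xs[3:m]
  peak_idx <- which(is_peak) + 1L
  amplitude <- max(xs) - min(xs)
  oscillating <- length(peak_idx) >= 3 && amplitude > amplitude_threshold
  period <- if (length(peak_idx) >= 2) mean(diff(ts[peak_idx])) else NA_real_
  coexistence <- all(traj$states > 1e-6) && all(traj$states < 1 - 1e-6)
  structure(list(oscillating = oscillating, n_peaks = length(peak_idx),
                 period_estimate = period, amplitude = amplitude,
                 coexistence = coexistence),
            class = "qs_oscillation")
}

#' @export
print.qs_oscillation <- function(x, ...) {
  cat(sprintf("Oscillation report: %s\n",
              if (x$oscillating) "oscillating" else "not oscillating"))
  cat(sprintf("  peaks = %d, amplitude = %.4g, period = %s\n",
              x$n_peaks, x$amplitude,
              if (is.na(x$period_estimate)) "NA"
              else sprintf("%.4g", x$period_estimate)))
  cat(sprintf("  coexistence of all strategies: %s\n", x$coexistence))
  invisible(x)
}
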