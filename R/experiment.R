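## Statistics on (real or emulated) experimental observations: the
## competition-assay relative-fitness statistic, colony-count frequency
## tables with Wilson intervals, and grid-search calibration of game
## parameters against observed frequency trajectories.

#' Relative fitness from a pairwise competition assay
#'
#' `v = log10[x1 (1 - x0) / (x0 (1 - x1))]`, comparing the focal strain's
#' initial frequency `x0` with its final frequency `x1` in co-culture.
#' `v > 0` means the focal strain grew faster than its opponent, `v < 0`
#' slower. The statistic is undefined at fixation or extinction
#' (`x0` or `x1` in {0, 1}); no silent pseudocount is applied.
#'
#' @param x0,x1 Initial and final focal-strain frequencies, strictly inside
#'   (0, 1). Vectorized.
#' @return The relative fitness `v` (dimensionless, log10 scale).
#' @examples
#' relative_fitness(0.1, 0.5)   # log10(9)
#' @export
relative_fitness <- function(x0, x1) {
  if (any(!is.finite(x0)) || any(!is.finite(x1)) ||
      any(x0 <= 0) || any(x0 >= 1) || any(x1 <= 0) || any(x1 >= 1))
    stop("fixation/extinction: x0 and x1 must lie strictly in (0, 1)")
  log10(x1 * (1 - x0) / (x0 * (1 - x1)))
}

## Wilson score interval (no continuity correction) for k successes in n.
wilson_interval <- function(k, n, confidence) {
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Strategy proportions with Wilson intervals from colony counts
#'
#' Converts a colony-count table (one row per sampled cycle/time point, with
#' counts of cooperator, conditional-defector, and defector colonies) into
#' per-strategy proportions with Wilson score confidence intervals. Wilson
#' rather than Wald intervals because colony samples are small (typically
#' 100) and proportions often sit near 0 or 1.
#'
#' @param counts A colony-count data frame with columns `cycle`, `time_h`,
#'   `n_sampled`, `n_C`, `n_CD`, `n_D` (see [read_colony_table()]); row
#'   counts must satisfy `n_C + n_CD + n_D = n_sampled`.
#' @param confidence Confidence level of the intervals (default 0.95).
#' @return A data frame, rows in input order, with the input columns plus
#'   `prop_C`, `prop_CD`, `prop_D` and interval columns
#'   `lo_C`, `hi_C`, `lo_CD`, `hi_CD`, `lo_D`, `hi_D`.
#' @export
frequency_table <- function(counts, confidence = 0.95) {
  check_colony_table(counts)
  if (any(counts$n_sampled == 0))
    stop("rows with n_sampled = 0 have no defined proportions")
  out <- counts
  for (strat in c("C", "CD", "D")) {
    k <- counts[[paste0("n_", strat)]]
    n <- counts$n_sampled
    out[[paste0("prop_", strat)]] <- k / n
    ci <- t(mapply(wilson_interval, k, n,
                   MoreArgs = list(confidence = confidence)))
    out[[paste0("lo_", strat)]] <- ci[, "lower"]
    out[[paste0("hi_", strat)]] <- ci[, "upper"]
  }
  out
}

check_colony_table <- function(counts) {
  need <- c("cycle", "time_h", "n_sampled", "n_C", "n_CD", "n_D")
  if (!is.data.frame(counts) || !all(need %in% names(counts)))
    stop("colony table needs columns ", paste(need, collapse = ", "))
  if (any(counts$n_C + counts$n_CD + counts$n_D != counts$n_sampled))
    stop("colony counts must sum to n_sampled in every row")
  if (any(counts$n_C < 0 | counts$n_CD < 0 | counts$n_D < 0))
    stop("colony counts must be non-negative")
  invisible(counts)
}

## Model-predicted (C, CD, D) frequencies at the observation rows of a
## colony table: one integration, sampled at the mapped model times.
model_frequencies_at <- function(counts, params, state0, time_scale,
                                 cycle_hours) {
  t_obs <- ((counts$cycle - 1) * cycle_hours + counts$time_h) * time_scale
  o <- order(t_obs)
  times <- sort(unique(c(0, t_obs)))
  sol <- deSolve::ode(y = as.numeric(state0), times = times,
                      func = replicator_rhs_ode, parms = params,
                      method = "ode45", rtol = 1e-8, atol = 1e-10)
  idx <- match(t_obs, times)
  states <- sol[idx, 2:4, drop = FALSE]
  ## columns in colony-table order (C, CD, D) = (x, z, y)
  cbind(C = states[, 1], CD = states[, 3], D = states[, 2])
}

#' Grid-search calibration of game parameters against colony counts
#'
#' Fits free game parameters by exhaustive grid search: for every grid
#' point, the three-strategy replicator model is integrated from `state0`,
#' sampled at the observation times (hours mapped to model time via
#' `time_scale`), and scored by the sum of squared differences between
#' observed colony proportions and model frequencies over all rows and all
#' three strategies. Ties are broken to the first grid point in
#' column-major [expand.grid()] order, i.e. the lexicographically smallest.
#'
#' @param observed A colony-count table (see [frequency_table()]).
#' @param params A [qs_params()] object supplying the fixed parameters.
#' @param state0 Initial state of the underlying model, `(x, y, z)`.
#' @param grid Named list of candidate value vectors for the free
#'   parameters; names must be `qs_params` fields (e.g.
#'   `list(p = seq(0, 1, 0.1), q = seq(0, 1, 0.1))`). Must be non-empty.
#' @param time_scale Model time units per laboratory hour (default 1, so a
#'   24-h cycle spans 24 model units).
#' @param cycle_hours Duration of one serial-passage cycle in hours
#'   (default 24).
#' @return An object of class `qs_calibration`: list with `best` (named
#'   vector of fitted values), `sse` (its sum of squares), `surface` (data
#'   frame of the full grid with an `sse` column), and the fit inputs.
#' @examples
#' \donttest{
#' des <- assay_design(n_cycles = 3, seed = 1)
#' obs <- generate_evolution_assay(pop_state(0.4, 0.3, 0.3), qs_params(), des)
#' fit <- calibrate_parameters(obs, qs_params(), pop_state(0.4, 0.3, 0.3),
#'                             grid = list(p = c(0.5, 1)))
#' coef(fit)
#' }
#' @export
calibrate_parameters <- function(observed, params, state0, grid,
                                 time_scale = 1, cycle_hours = 24) {
  check_colony_table(observed)
  check_state(state0)
  if (!is.list(grid) || length(grid) == 0 || is.null(names(grid)) ||
      !all(names(grid) %in% c("N", "r", "c", "delta", "p", "q", "Delta")))
    stop("grid must be a non-empty named list of qs_params fields")
  if (nrow(observed) < length(grid))
    stop("need at least as many observation rows as free parameters")
  obs_prop <- as.matrix(observed[, c("n_C", "n_CD", "n_D")]) /
    observed$n_sampled
  colnames(obs_prop) <- c("C", "CD", "D")
  surface <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  sse <- numeric(nrow(surface))
  for (i in seq_len(nrow(surface))) {
    cand <- params
    for (nm in names(grid)) cand[[nm]] <- surface[i, nm]
    pred <- model_frequencies_at(observed, cand, state0, time_scale,
                                 cycle_hours)
    sse[i] <- sum((obs_prop - pred)^2)
  }
  surface$sse <- sse
  ibest <- which.min(sse)   # which.min takes the first minimum: ties break
                            # to the lexicographically smallest grid point
  best <- unlist(surface[ibest, names(grid), drop = FALSE])
  names(best) <- names(grid)
  structure(list(best = best, sse = sse[ibest], surface = surface,
                 params = params, state0 = state0, grid = grid,
                 time_scale = time_scale, cycle_hours = cycle_hours,
                 observed = observed),
            class = "qs_calibration")
}

#' @export
print.qs_calibration <- function(x, ...) {
  cat("Grid-search calibration of the public-goods game\n")
  cat(sprintf("  free parameters: %s\n", paste(names(x$best), collapse = ", ")))
  cat(sprintf("  best fit: %s  (SSE = %.6g over %d grid points)\n",
              paste(sprintf("%s = %g", names(x$best), x$best),
                    collapse = ", "),
              x$sse, nrow(x$surface)))
  invisible(x)
}

#' @export
coef.qs_calibration <- function(object, ...) object$best

#' Model-predicted strategy frequencies at the best-fit parameters
#'
#' @param object A `qs_calibration` fit.
#' @param newdata Optional colony-count table whose `cycle`/`time_h` rows
#'   define the prediction times; defaults to the table used for fitting.
#' @param ... Unused.
#' @return Matrix of predicted (C, CD, D) frequencies, one row per
#'   observation row.
#' @export
predict.qs_calibration <- function(object, newdata = NULL, ...) {
  tab <- if (is.null(newdata)) object$observed else newdata
  check_colony_table(tab)
  cand <- object$params
  for (nm in names(object$best)) cand[[nm]] <- object$best[[nm]]
  model_frequencies_at(tab, cand, object$state0, object$time_scale,
                       object$cycle_hours)
}

#' Plot a calibration sum-of-squares surface
#'
#' For two free parameters, an image map of SSE over the grid with the best
#' fit marked; for one, an SSE profile curve.
#'
#' @param x A `qs_calibration` fit.
#' @param ... Passed to [graphics::image()] or [graphics::plot()].
#' @export
plot.qs_calibration <- function(x, ...) {
  free <- names(x$grid)
  if (length(free) == 2) {
    g1 <- sort(unique(x$surface[[free[1]]]))
    g2 <- sort(unique(x$surface[[free[2]]]))
    zmat <- matrix(NA_real_, length(g1), length(g2))
    for (i in seq_len(nrow(x$surface))) {
      zmat[match(x$surface[i, free[1]], g1),
           match(x$surface[i, free[2]], g2)] <- x$surface$sse[i]
    }
    graphics::image(g1, g2, zmat, xlab = free[1], ylab = free[2], ...)
    graphics::points(x$best[1], x$best[2], pch = 4, cex = 2)
  } else {
    graphics::plot(x$surface[[free[1]]], x$surface$sse, type = "b",
                   xlab = free[1], ylab = "SSE", ...)
  }
  invisible(x)
}
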