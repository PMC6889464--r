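## Seeded generators emulating the statistical structure of the wet-lab
## experiments: serial-passage colony sampling, pairwise competition assays,
## and a finite-population stochastic simulator that converges to the
## replicator limit for large populations.

#' Design of a serial-passage evolution assay
#'
#' Describes when and how deeply the emulated population is sampled: cycles
#' of fixed duration (dilution-regrowth), sampling times within each cycle,
#' and the number of colonies picked per sampling point. Dilution is
#' frequency-neutral in this model (the dynamics track frequencies, not
#' absolute densities), so cycles only define the sampling grid. Defaults
#' mirror the common design: 24-h cycles sampled at 8, 16, and 24 h with
#' 100 colonies per point.
#'
#' @param n_cycles Number of dilution-regrowth cycles (>= 1).
#' @param cycle_hours Cycle duration in hours (default 24).
#' @param sampling_times_h Sampling times within a cycle, in
#'   `(0, cycle_hours]` (default `c(8, 16, 24)`).
#' @param n_colonies Colonies sampled per time point (>= 1; default 100).
#' @param time_scale Model time units per hour (default 1).
#' @param seed Integer seed; required.
#' @return A validated list of class `qs_assay_design`.
#' @export
assay_design <- function(n_cycles, cycle_hours = 24,
                         sampling_times_h = c(8, 16, 24),
                         n_colonies = 100, time_scale = 1, seed) {
  stopifnot(
    "n_cycles must be >= 1" = n_cycles >= 1,
    "cycle_hours must be positive" = cycle_hours > 0,
    "sampling times must lie in (0, cycle_hours]" =
      all(sampling_times_h > 0 & sampling_times_h <= cycle_hours),
    "n_colonies must be >= 1" = n_colonies >= 1,
    "time_scale must be positive" = time_scale > 0,
    "seed must be a single finite integer" =
      length(seed) == 1 && is.finite(seed)
  )
  structure(list(n_cycles = as.integer(n_cycles), cycle_hours = cycle_hours,
                 sampling_times_h = sort(sampling_times_h),
                 n_colonies = as.integer(n_colonies),
                 time_scale = time_scale, seed = as.integer(seed)),
            class = "qs_assay_design")
}

#' Generate a serial-passage colony-count table
#'
#' Integrates the three-strategy replicator model over the whole assay and,
#' at each sampling point, draws colony counts from a multinomial
#' distribution with the model frequencies mapped to table columns as
#' `(C, CD, D) = (x, z, y)`. Reproducible: identical seed and inputs give
#' identical tables.
#'
#' @param state0 Initial simplex state.
#' @param params A [qs_params()] object.
#' @param design An [assay_design()].
#' @return A colony-count data frame with columns `cycle`, `time_h`,
#'   `n_sampled`, `n_C`, `n_CD`, `n_D`, one row per sampling point in
#'   chronological order.
#' @examples
#' des <- assay_design(n_cycles = 2, seed = 42)
#' generate_evolution_assay(pop_state(0.4, 0.3, 0.3), qs_params(), des)
#' @export
generate_evolution_assay <- function(state0, params, design) {
  check_state(state0)
  stopifnot(inherits(design, "qs_assay_design"))
  grid <- expand.grid(time_h = design$sampling_times_h,
                      cycle = seq_len(design$n_cycles))
  t_model <- ((grid$cycle - 1) * design$cycle_hours + grid$time_h) *
    design$time_scale
  times <- sort(unique(c(0, t_model)))
  sol <- deSolve::ode(y = as.numeric(state0), times = times,
                      func = replicator_rhs_ode, parms = params,
                      method = "ode45", rtol = 1e-8, atol = 1e-10)
  freq <- sol[match(t_model, times), 2:4, drop = FALSE]
  freq <- pmax(freq, 0)
  freq <- freq / rowSums(freq)
  set.seed(design$seed)
  counts <- t(vapply(seq_len(nrow(freq)), function(i) {
    stats::rmultinom(1, design$n_colonies,
                     c(freq[i, 1], freq[i, 3], freq[i, 2]))[, 1]
  }, integer(3)))
  data.frame(cycle = grid$cycle, time_h = grid$time_h,
             n_sampled = design$n_colonies,
             n_C = counts[, 1], n_CD = counts[, 2], n_D = counts[, 3])
}

#' Generate pairwise competition-assay records
#'
#' Emulates co-culture competition between two of the three strategists at a
#' series of initial frequencies of the focal (first-named) strain. The
#' three-strategy model is restricted to the pair (third frequency 0),
#' integrated for the assay duration, and the final focal frequency is
#' resampled binomially at the CFU-plating depth before the relative fitness
#' is computed with [relative_fitness()]. Rows whose resampled final
#' frequency hits 0 or 1 carry `fixation = TRUE` and `v = NA` rather than a
#' pseudocount-corrected value; setting `continuity_correction = TRUE`
#' applies `(count + 0.5) / (n + 1)` to such rows instead.
#'
#' @param pair Character vector of two distinct strategy labels from
#'   `c("C", "D", "CD")`; the first is the focal strain.
#' @param initial_ratios Focal-strain initial frequencies, strictly in
#'   (0, 1).
#' @param params A [qs_params()] object.
#' @param duration_h Assay duration in hours (default 24).
#' @param n_cfu Colonies counted when plating the final culture (default
#'   100).
#' @param seed Integer seed; required.
#' @param time_scale Model time units per hour (default 1).
#' @param continuity_correction Apply the `(k + 0.5)/(n + 1)` correction to
#'   fixation rows instead of flagging them (default `FALSE`).
#' @return Data frame of class `qs_competition` with columns `pair`, `x0`,
#'   `x1_model` (pre-resampling final frequency), `x1` (resampled), `v`,
#'   and `fixation`.
#' @examples
#' generate_competition_assay(c("D", "CD"), c(0.1, 0.5, 0.9), qs_params(),
#'                            seed = 7)
#' @export
generate_competition_assay <- function(pair, initial_ratios, params,
                                       duration_h = 24, n_cfu = 100, seed,
                                       time_scale = 1,
                                       continuity_correction = FALSE) {
  if (length(pair) != 2 || anyDuplicated(pair) ||
      !all(pair %in% QS_STRATEGIES))
    stop("pair must be two distinct labels from C, D, CD")
  if (any(initial_ratios <= 0 | initial_ratios >= 1))
    stop("initial ratios must lie strictly in (0, 1)")
  stopifnot("seed must be a single finite integer" =
              length(seed) == 1 && is.finite(seed))
  slot <- c(C = 1L, D = 2L, CD = 3L)
  x1_model <- vapply(initial_ratios, function(x0) {
    s0 <- c(0, 0, 0)
    s0[slot[pair[1]]] <- x0
    s0[slot[pair[2]]] <- 1 - x0
    traj <- integrate_replicator(s0, params,
                                 t_end = duration_h * time_scale,
                                 n_out = 101)
    traj$states[nrow(traj$states), slot[pair[1]]]
  }, numeric(1))
  set.seed(as.integer(seed))
  k <- stats::rbinom(length(x1_model), n_cfu, x1_model)
  x1 <- k / n_cfu
  fix <- x1 <= 0 | x1 >= 1
  if (continuity_correction) {
    x1[fix] <- (k[fix] + 0.5) / (n_cfu + 1)
    fix[] <- FALSE
  }
  v <- rep(NA_real_, length(x1))
  ok <- !fix
  if (any(ok)) v[ok] <- relative_fitness(initial_ratios[ok], x1[ok])
  structure(
    data.frame(pair = paste(pair, collapse = "-"), x0 = initial_ratios,
               x1_model = x1_model, x1 = x1, v = v, fixation = fix),
    class = c("qs_competition", "data.frame"))
}

#' Finite-population simulator configuration
#'
#' @param M Population size in individuals (>= group size `N`).
#' @param generations Number of discrete generations to simulate (>= 1).
#' @param fitness_scale Selection intensity of the exponential
#'   payoff-to-fitness map `f = exp(fitness_scale * P)` (> 0; default 1).
#'   The exponential map keeps fitness positive even for negative payoffs
#'   such as the bare perception cost.
#' @param seed Integer seed; required.
#' @return A validated list of class `qs_finite_pop_config`.
#' @export
finite_pop_config <- function(M, generations, fitness_scale = 1, seed) {
  stopifnot(
    "M must be a positive integer" = M >= 1 && M == round(M),
    "generations must be >= 1" = generations >= 1,
    "fitness_scale must be positive" = fitness_scale > 0,
    "seed must be a single finite integer" =
      length(seed) == 1 && is.finite(seed)
  )
  structure(list(M = as.integer(M), generations = as.integer(generations),
                 fitness_scale = fitness_scale, seed = as.integer(seed)),
            class = "qs_finite_pop_config")
}

#' Wright-Fisher style finite-population simulation
#'
#' Discrete-generation stochastic counterpart of the replicator dynamics.
#' Each generation, every individual's expected payoff is evaluated at the
#' current empirical strategy frequencies via [expected_payoffs()], mapped
#' to fitness `f_I = exp(fitness_scale * P_I)`, and the next generation of
#' `M` individuals is drawn from a multinomial with probabilities
#' proportional to `count_I * f_I`. For large `M` the sample paths track the
#' (time-rescaled) replicator flow; for small `M` drift dominates. This
#' simulator is a synthetic stand-in for round-based laboratory evolution,
#' not a mechanistic growth model.
#'
#' @param state0 Initial simplex state; `M * state0` is rounded to integer
#'   counts summing to `M` (largest-remainder rounding).
#' @param params A [qs_params()] object.
#' @param config A [finite_pop_config()].
#' @return A `qs_trajectory` with one state per generation (times
#'   `0:generations` in generation units).
#' @examples
#' cfg <- finite_pop_config(M = 1000, generations = 50, seed = 3)
#' simulate_finite_population(pop_state(0.4, 0.3, 0.3), qs_params(), cfg)
#' @export
simulate_finite_population <- function(state0, params, config) {
  check_state(state0)
  stopifnot(inherits(config, "qs_finite_pop_config"),
            "M must be at least the group size N" = config$M >= params$N)
  M <- config$M
  ## largest-remainder rounding of M * state0 to integer counts summing to M
  raw <- M * as.numeric(state0)
  counts <- floor(raw)
  rem <- M - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  set.seed(config$seed)
  states <- matrix(0, config$generations + 1L, 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  states[1, ] <- counts / M
  for (g in seq_len(config$generations)) {
    freq <- counts / M
    pay <- expected_payoffs_raw(freq, params)
    w <- counts * exp(config$fitness_scale * pay[1:3])
    counts <- stats::rmultinom(1, M, w / sum(w))[, 1]
    states[g + 1L, ] <- counts / M
  }
  structure(list(times = 0:config$generations, states = states,
                 params = params),
            class = "qs_trajectory")
}
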