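## Realized and expected payoffs of the N-player public-goods game with
## probabilistic exclusion. All formulas are implemented exactly as the model
## defines them; vectorized internal kernels back both the exact multinomial
## sums and the Monte-Carlo oracle.

## Vectorized payoff kernels over composition columns. Denominator counts the
## sharing pool: cooperating co-players + cheating CDs + surviving defectors
## + the focal individual.
pi_C_vec <- function(nC, nCD, nW, params) {
  denom <- nC + nCD + nW + 1
  params$r * params$c * (nC + 1) / denom - params$c - params$delta
}

pi_D_vec <- function(nC, nCD, nW, params) {
  denom <- nC + nCD + nW + 1
  (1 - params$p)^nC * params$r * params$c * nC / denom
}

pi_CD_vec <- function(nC, nCD, nW, params) {
  denom <- nC + nCD + nW + 1
  (1 - params$q) * params$r * params$c * nC / denom +
    params$q * (params$r * params$c * (nC + 1) / denom -
                  params$c - params$delta) -
    params$Delta
}

check_composition <- function(comp, params) {
  if (inherits(comp, "qs_composition")) return(invisible(comp))
  if (length(comp) != 4)
    stop("comp must be a qs_composition or a vector (nC, nD, nCD, nW)")
  group_composition(comp[[1]], comp[[2]], comp[[3]], comp[[4]], params)
}

#' Realized payoff of a focal cooperator
#'
#' `pi_C = r c (N_C + 1) / (N_C + N_CD + N_W + 1) - c - delta`: the focal
#' cooperator's share of the multiplied contributions, minus its contribution
#' cost and the per-round exclusion cost. May be negative.
#'
#' @param comp A [group_composition()] of the focal individual's co-players.
#' @param params A [qs_params()] object.
#' @return The realized payoff (payoff units).
#' @examples
#' p <- qs_params()
#' payoff_cooperator(group_composition(4, 0, 0, 0, p), p)  # 0.3
#' @export
payoff_cooperator <- function(comp, params) {
  comp <- check_composition(comp, params)
  pi_C_vec(comp[["nC"]], comp[["nCD"]], comp[["nW"]], params)
}

#' Realized payoff of a focal defector
#'
#' `pi_D = (1 - p)^{N_C} r c N_C / (N_C + N_CD + N_W + 1)`: the defector's
#' share of the pool, discounted by its own probability of surviving the
#' `N_C` excluders. Zero whenever no cooperator is present, and whenever
#' `p = 1` with at least one cooperator.
#'
#' @inheritParams payoff_cooperator
#' @return The realized payoff, in `[0, r c]`.
#' @export
payoff_defector <- function(comp, params) {
  comp <- check_composition(comp, params)
  pi_D_vec(comp[["nC"]], comp[["nCD"]], comp[["nW"]], params)
}

#' Realized payoff of a focal conditional defector
#'
#' A conditional defector cheats with probability `1 - q` (taking the
#' defector's share without exclusion risk) and cooperates with probability
#' `q` (taking the cooperator's net payoff), always paying the perception
#' cost `Delta`. Conditional defectors are never excluded in this model.
#'
#' @inheritParams payoff_cooperator
#' @return The realized payoff; equals `-Delta` when `N_C = 0` and `q = 0`.
#' @export
payoff_conditional_defector <- function(comp, params) {
  comp <- check_composition(comp, params)
  pi_CD_vec(comp[["nC"]], comp[["nCD"]], comp[["nW"]], params)
}

#' Effective number of excluders faced by each defector co-player
#'
#' Each defector in the group survives exclusion independently with
#' probability `(1 - p)^E`. The exponent `E` counts the cooperators that can
#' exclude it, which depends on the focal individual's strategy: a focal
#' cooperator adds itself (`N_C + 1`), a focal defector adds nothing (`N_C`),
#' and a focal conditional defector adds itself only in its cooperating
#' fraction, giving the real-valued `(1 - q) N_C + q (N_C + 1)`.
#'
#' @param focal Focal strategy label: `"C"`, `"D"`, or `"CD"`.
#' @param nC Number of cooperating co-players (>= 0).
#' @param params A [qs_params()] object (supplies `q`).
#' @return The exponent `E` (real-valued for focal `"CD"`).
#' @examples
#' excluder_exponent("C", 3, qs_params())            # 4
#' excluder_exponent("CD", 3, qs_params(q = 0.1))    # 3.1
#' @export
excluder_exponent <- function(focal, nC, params) {
  check_strategy(focal)
  if (any(nC < 0)) stop("nC must be non-negative")
  switch(focal,
         C  = nC + 1,
         D  = nC,
         CD = (1 - params$q) * nC + params$q * (nC + 1))
}

## --- exact expected payoffs -----------------------------------------------

## Cache of co-player composition tables, keyed by N. Each table enumerates
## every (nC, nD, nCD) with nC + nD + nCD = N - 1 expanded over all survivor
## counts nW = 0..nD, with multinomial and binomial coefficients precomputed.
.qs_comp_cache <- new.env(parent = emptyenv())

composition_table <- function(N) {
  key <- as.character(N)
  if (!is.null(.qs_comp_cache[[key]])) return(.qs_comp_cache[[key]])
  m <- N - 1L
  comps <- expand.grid(nC = 0:m, nD = 0:m, nCD = 0:m)
  comps <- comps[comps$nC + comps$nD + comps$nCD == m, , drop = FALSE]
  rows <- lapply(seq_len(nrow(comps)), function(i) {
    nD <- comps$nD[i]
    data.frame(nC = comps$nC[i], nD = nD, nCD = comps$nCD[i], nW = 0:nD)
  })
  tab <- do.call(rbind, rows)
  tab$multi <- exp(lfactorial(m) - lfactorial(tab$nC) -
                     lfactorial(tab$nD) - lfactorial(tab$nCD))
  tab$binW <- choose(tab$nD, tab$nW)
  .qs_comp_cache[[key]] <- tab
  tab
}

## Survival probability of one defector co-player given the focal strategy,
## vectorized over nC. R's 0^0 == 1 covers the p = 1, E = 0 corner exactly as
## the model requires.
survival_prob <- function(focal, nC, params) {
  (1 - params$p)^excluder_exponent(focal, nC, params)
}

expected_payoff_one <- function(focal, state, params, tab) {
  x <- state[[1]]; y <- state[[2]]; z <- state[[3]]
  w_comp <- tab$multi * (x + params$q * z)^tab$nC * y^tab$nD *
    ((1 - params$q) * z)^tab$nCD
  s <- survival_prob(focal, tab$nC, params)
  w_surv <- tab$binW * s^tab$nW * (1 - s)^(tab$nD - tab$nW)
  pay <- switch(focal,
                C  = pi_C_vec(tab$nC, tab$nCD, tab$nW, params),
                D  = pi_D_vec(tab$nC, tab$nCD, tab$nW, params),
                CD = pi_CD_vec(tab$nC, tab$nCD, tab$nW, params))
  sum(w_comp * w_surv * pay)
}

#' Exact expected payoffs at a population state
#'
#' Computes the expected payoffs `P_C`, `P_D`, `P_CD` by the exact finite
#' sums over all co-player compositions: a multinomial draw of the `N - 1`
#' co-players with category probabilities `(x + q z, y, (1 - q) z)` (the
#' transformed fraction of conditional defectors counts as cooperators),
#' nested over a binomial draw of surviving defectors with per-defector
#' survival `(1 - p)^E`, where the exponent `E` follows
#' [excluder_exponent()]. Also returns the population mean payoff
#' `pBar = x P_C + y P_D + z P_CD`.
#'
#' The two-strategy model is the restriction `z = 0`; no separate code path
#' exists.
#'
#' @param state A simplex state, e.g. from [pop_state()].
#' @param params A [qs_params()] object.
#' @return Named numeric vector `c(pC, pD, pCD, pBar)`.
#' @examples
#' expected_payoffs(pop_state(1, 0, 0), qs_params())   # pC = 0.3
#' @export
expected_payoffs <- function(state, params) {
  check_state(state)
  tab <- composition_table(params$N)
  pC <- expected_payoff_one("C", state, params, tab)
  pD <- expected_payoff_one("D", state, params, tab)
  pCD <- expected_payoff_one("CD", state, params, tab)
  pBar <- state[[1]] * pC + state[[2]] * pD + state[[3]] * pCD
  c(pC = pC, pD = pD, pCD = pCD, pBar = pBar)
}

#' Monte-Carlo estimate of the expected payoffs
#'
#' Independent stochastic oracle for [expected_payoffs()]: for each focal
#' strategy it samples `n_samples` groups of `N - 1` co-players from the
#' categorical distribution `(x + q z, y, (1 - q) z)`, applies independent
#' Bernoulli exclusion to each defector co-player with survival probability
#' `(1 - p)^E`, and averages the realized payoffs. Identical seed and inputs
#' give bit-identical output.
#'
#' @inheritParams expected_payoffs
#' @param n_samples Number of sampled groups per focal strategy (>= 1).
#' @param seed Integer seed; required.
#' @return A list with components `estimate` and `se`, each a named numeric
#'   vector over `pC`, `pD`, `pCD`, `pBar` (`pBar` combines the three
#'   estimates with the state weights; its standard error assumes their
#'   independence, which holds by construction).
#' @export
monte_carlo_payoffs <- function(state, params, n_samples, seed) {
  check_state(state)
  stopifnot("n_samples must be >= 1" = n_samples >= 1,
            "seed must be a single finite integer" =
              length(seed) == 1 && is.finite(seed))
  set.seed(as.integer(seed))
  probs <- c(state[[1]] + params$q * state[[3]], state[[2]],
             (1 - params$q) * state[[3]])
  probs <- pmax(probs, 0)
  est <- se <- numeric(3)
  for (k in seq_along(QS_STRATEGIES)) {
    focal <- QS_STRATEGIES[k]
    comp <- stats::rmultinom(n_samples, params$N - 1L, probs)
    nC <- comp[1, ]; nD <- comp[2, ]; nCD <- comp[3, ]
    s <- survival_prob(focal, nC, params)
    nW <- stats::rbinom(n_samples, nD, s)
    pay <- switch(focal,
                  C  = pi_C_vec(nC, nCD, nW, params),
                  D  = pi_D_vec(nC, nCD, nW, params),
                  CD = pi_CD_vec(nC, nCD, nW, params))
    est[k] <- mean(pay)
    se[k] <- stats::sd(pay) / sqrt(n_samples)
  }
  w <- as.numeric(state)
  estimate <- c(est, sum(w * est))
  serr <- c(se, sqrt(sum((w * se)^2)))
  names(estimate) <- names(serr) <- c("pC", "pD", "pCD", "pBar")
  list(estimate = estimate, se = serr)
}
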