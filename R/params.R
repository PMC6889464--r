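#' Game parameters for the public-goods game with exclusion
#'
#' Bundles the seven constants of the N-player public-goods game in which
#' cooperators (C) contribute to a shared pool and punish defectors (D) by
#' probabilistic exclusion, while conditional defectors (CD) pay a perception
#' cost to monitor the environment and switch to cooperation with a fixed
#' probability. Defaults are the headline parameter set of the
#' oscillatory-coexistence regime.
#'
#' @param N Integer group size (>= 2). Groups of `N` individuals are sampled
#'   from a well-mixed population; each payoff formula counts the `N - 1`
#'   co-players plus the focal individual.
#' @param r Enhancement (multiplication) factor applied to the summed
#'   contributions before equal redistribution; dimensionless, > 0.
#' @param c Contribution cost paid by each cooperating individual (payoff
#'   units, >= 0).
#' @param delta Exclusion (punishment) cost paid by each cooperator per round
#'   (payoff units, >= 0).
#' @param p Probability that a single cooperator successfully excludes a given
#'   defector from the sharing pool, in [0, 1]. A defector facing `E`
#'   excluders survives with probability `(1 - p)^E`.
#' @param q Fraction of conditional defectors that transform to cooperation in
#'   a given round, in [0, 1].
#' @param Delta Perception (observation) cost paid by every conditional
#'   defector (payoff units, >= 0).
#'
#' @return An object of class `qs_params`: a named list with the seven
#'   validated fields.
#' @examples
#' qs_params()                      # oscillatory-coexistence defaults
#' qs_params(p = 0.6, q = 0)       # coordination-game regime (two-strategy)
#' @export
qs_params <- function(N = 5, r = 3, c = 0.3, delta = 0.3,
                      p = 1, q = 0, Delta = 0.35) {
  stopifnot(
    "N must be a single integer >= 2" =
      length(N) == 1 && is.finite(N) && N >= 2 && N == round(N),
    "r must be a single positive number" =
      length(r) == 1 && is.finite(r) && r > 0,
    "c must be a single non-negative number" =
      length(c) == 1 && is.finite(c) && c >= 0,
    "delta must be a single non-negative number" =
      length(delta) == 1 && is.finite(delta) && delta >= 0,
    "p must lie in [0, 1]" =
      length(p) == 1 && is.finite(p) && p >= 0 && p <= 1,
    "q must lie in [0, 1]" =
      length(q) == 1 && is.finite(q) && q >= 0 && q <= 1,
    "Delta must be a single non-negative number" =
      length(Delta) == 1 && is.finite(Delta) && Delta >= 0
  )
  structure(
    list(N = as.integer(N), r = r, c = c, delta = delta,
         p = p, q = q, Delta = Delta),
    class = "qs_params"
  )
}

#' @export
print.qs_params <- function(x, ...) {
  cat("Public-goods game with exclusion\n")
  cat(sprintf("  group size N      = %d\n", x$N))
  cat(sprintf("  enhancement r     = %g\n", x$r))
  cat(sprintf("  contribution c    = %g\n", x$c))
  cat(sprintf("  exclusion cost d  = %g\n", x$delta))
  cat(sprintf("  exclusion prob p  = %g\n", x$p))
  cat(sprintf("  transform frac q  = %g\n", x$q))
  cat(sprintf("  perception cost D = %g\n", x$Delta))
  invisible(x)
}

#' Population state on the strategy simplex
#'
#' Constructs and validates a point `(x, y, z)` of cooperator, defector, and
#' conditional-defector frequencies. The two-strategy model is the
#' restriction `z = 0`.
#'
#' @param x,y,z Frequencies of C, D, and CD; non-negative and summing to 1
#'   within `1e-9`.
#' @return A named numeric vector `c(x = , y = , z = )`.
#' @examples
#' pop_state(0.4, 0.3, 0.3)
#' pop_state(0.2, 0.8)   # two-strategy state
#' @export
pop_state <- function(x, y, z = 0) {
  s <- c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  check_state(s)
  s
}

## Validate a length-3 state vector; tolerance matches the simplex invariant.
check_state <- function(state, tol = 1e-9) {
  if (length(state) != 3 || !all(is.finite(state)))
    stop("state must be a finite numeric vector (x, y, z)")
  if (any(state < -tol))
    stop("state frequencies must be non-negative")
  if (abs(sum(state) - 1) > tol)
    stop("state frequencies must sum to 1 (|x + y + z - 1| <= 1e-9)")
  invisible(state)
}

## Strategy labels are a closed enumeration used across modules.
QS_STRATEGIES <- c("C", "D", "CD")

check_strategy <- function(label) {
  if (length(label) != 1 || !label %in% QS_STRATEGIES)
    stop("strategy label must be one of \"C\", \"D\", \"CD\"")
  label
}

#' Group composition of co-players
#'
#' Counts of the `N - 1` co-players in one sampled group, plus the number of
#' surviving (not excluded) defectors. The focal individual is implicit: the
#' sharing-pool denominators in the payoff formulas add 1 for it.
#'
#' @param nC Number of cooperating co-players (in the three-strategy sampling
#'   this includes transformed conditional defectors).
#' @param nD Number of defector co-players.
#' @param nCD Number of cheating conditional-defector co-players.
#' @param nW Number of defectors that survived exclusion (`nW <= nD`).
#' @param params A [qs_params()] object, used to check `nC + nD + nCD <= N - 1`.
#' @return A named integer vector of class `qs_composition`.
#' @examples
#' group_composition(4, 0, 0, 0, qs_params())
#' @export
group_composition <- function(nC, nD, nCD = 0, nW = 0, params = qs_params()) {
  counts <- c(nC = nC, nD = nD, nCD = nCD, nW = nW)
  if (!all(is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("composition counts must be non-negative integers")
  if (nC + nD + nCD > params$N - 1)
    stop("composition counts exceed the N - 1 co-player slots")
  if (nW > nD)
    stop("surviving defectors nW cannot exceed defector count nD")
  structure(as.integer(counts), names = names(counts),
            class = "qs_composition")
}
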