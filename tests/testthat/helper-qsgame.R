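## Shared fixtures and independent reference implementations used as
## oracles against the package's vectorized payoff sums.

fig6_params <- function(...) qs_params(...)  # defaults are the Fig-6-style
                                             # oscillatory regime

## Independent two-strategy expected payoffs, written directly from the
## printed binomial forms: outer binomial over cooperator co-players,
## inner binomial over surviving defectors. Deliberately loop-based and
## separate from the package's multinomial machinery.
ref_two_strategy_payoffs <- function(x, params) {
  N <- params$N; r <- params$r; cc <- params$c
  delta <- params$delta; p <- params$p
  PC <- 0; PD <- 0
  for (nC in 0:(N - 1)) {
    w_comp <- choose(N - 1, nC) * x^nC * (1 - x)^(N - 1 - nC)
    nD <- N - 1 - nC
    sC <- (1 - p)^(nC + 1)
    sD <- (1 - p)^nC
    for (nW in 0:nD) {
      piC <- r * cc * (nC + 1) / (nC + nW + 1) - cc - delta
      piD <- (1 - p)^nC * r * cc * nC / (nC + nW + 1)
      PC <- PC + w_comp * choose(nD, nW) * sC^nW * (1 - sC)^(nD - nW) * piC
      PD <- PD + w_comp * choose(nD, nW) * sD^nW * (1 - sD)^(nD - nW) * piD
    }
  }
  c(pC = PC, pD = PD)
}

## Random interior simplex state from a given RNG stream.
random_state <- function() {
  v <- -log(runif(3))
  v / sum(v)
}

## Random valid parameter set (N fixed at 5, the group size used throughout).
random_params <- function() {
  qs_params(N = 5, r = runif(1, 1, 5), c = runif(1, 0.05, 0.5),
            delta = runif(1, 0, 0.5), p = runif(1), q = runif(1),
            Delta = runif(1, 0, 0.5))
}

## Constant trajectory fixture for the oscillation detector.
constant_trajectory <- function(state, n = 201, t_end = 200,
                                params = qs_params()) {
  structure(list(times = seq(0, t_end, length.out = n),
                 states = matrix(rep(as.numeric(state), each = n), n, 3,
                                 dimnames = list(NULL, c("x", "y", "z"))),
                 params = params),
            class = "qs_trajectory")
}
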