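test_that("realized payoffs match hand-computed values", {
  p <- qs_params()  # N=5, r=3, c=0.3, delta=0.3

  # focal cooperator among four cooperators: 3*0.3*5/5 - 0.3 - 0.3
  expect_equal(payoff_cooperator(group_composition(4, 0, 0, 0, p), p), 0.3)
  # focal cooperator among four surviving defectors: 0.9/5 - 0.6
  expect_equal(payoff_cooperator(group_composition(0, 4, 0, 4, p), p), -0.42)
  # zero contribution, zero exclusion cost: payoff identically 0
  p00 <- qs_params(c = 0, delta = 0)
  expect_equal(payoff_cooperator(group_composition(2, 1, 1, 1, p00), p00), 0)

  # defector with no cooperators gets nothing
  expect_equal(payoff_defector(group_composition(0, 3, 0, 2, p), p), 0)
  # deterministic exclusion kills the defector share
  expect_equal(payoff_defector(group_composition(2, 0, 0, 0, p), p), 0)
  # partial exclusion: 0.4^4 * (3*0.3*4/5)
  p06 <- qs_params(p = 0.6)
  expect_equal(payoff_defector(group_composition(4, 0, 0, 0, p06), p06),
               0.4^4 * 0.72)

  # pure cheating CD with no cooperators pays only the perception cost
  expect_equal(
    payoff_conditional_defector(group_composition(0, 0, 4, 0, p), p), -0.35)
})

test_that("conditional defector interpolates between C and unexcludable D", {
  comp_cases <- list(c(0, 4, 0, 2), c(2, 1, 1, 0), c(3, 1, 0, 1),
                     c(1, 2, 1, 2))
  # q = 1: identical to a cooperator minus the perception cost
  p1 <- qs_params(q = 1, Delta = 0.2)
  for (cc in comp_cases) {
    comp <- group_composition(cc[1], cc[2], cc[3], cc[4], p1)
    expect_equal(payoff_conditional_defector(comp, p1),
                 payoff_cooperator(comp, p1) - p1$Delta)
  }
  # q = 0, Delta = 0: identical to a defector that cannot be excluded
  p0 <- qs_params(q = 0, Delta = 0, p = 0.7)
  p0_free <- qs_params(q = 0, Delta = 0, p = 0)
  for (cc in comp_cases) {
    comp <- group_composition(cc[1], cc[2], cc[3], cc[4], p0)
    expect_equal(payoff_conditional_defector(comp, p0),
                 payoff_defector(comp, p0_free))
  }
})

test_that("excluder exponents follow the focal strategy", {
  p <- qs_params(q = 0.1)
  expect_equal(excluder_exponent("C", 3, p), 4)
  expect_equal(excluder_exponent("D", 3, p), 3)
  expect_equal(excluder_exponent("CD", 3, p), 0.9 * 3 + 0.1 * 4)
  expect_error(excluder_exponent("X", 3, p), "strategy label")
})

test_that("composition validation rejects impossible groups", {
  p <- qs_params()
  expect_error(group_composition(3, 2, 0, 0, p), "co-player slots")
  expect_error(group_composition(1, 1, 0, 2, p), "nW")
  expect_error(group_composition(-1, 0, 0, 0, p), "non-negative")
})

test_that("expected payoffs reproduce the degenerate-state hand values", {
  p <- qs_params()
  expect_equal(expected_payoffs(pop_state(1, 0, 0), p)[["pC"]], 0.3)
  expect_equal(expected_payoffs(pop_state(0, 1, 0), p)[["pD"]], 0)
  expect_equal(expected_payoffs(pop_state(0, 0, 1), p)[["pCD"]], -0.35)
})

test_that("population-mean payoff is the state-weighted payoff average", {
  set.seed(11)
  for (i in 1:20) {
    st <- random_state()
    pars <- random_params()
    pay <- expected_payoffs(st, pars)
    expect_equal(pay[["pBar"]], sum(st * pay[1:3]), tolerance = 1e-12)
  }
})

test_that("without punishment or costs the payoff gap is c(r - N)/N", {
  set.seed(12)
  for (i in 1:20) {
    st <- random_state()
    pars <- random_params()
    pars$p <- 0; pars$delta <- 0; pars$Delta <- 0; pars$q <- 0
    pay <- expected_payoffs(st, pars)
    expect_equal(pay[["pC"]] - pay[["pD"]],
                 pars$c * (pars$r - pars$N) / pars$N, tolerance = 1e-12)
  }
  pay <- expected_payoffs(c(0.3, 0.45, 0.25),
                          qs_params(p = 0, delta = 0, Delta = 0, q = 0))
  expect_equal(pay[["pC"]] - pay[["pD"]], -0.12, tolerance = 1e-12)
})

test_that("deterministic exclusion drives the defector payoff to zero", {
  set.seed(13)
  for (i in 1:10) {
    st <- random_state()
    pars <- random_params()
    pars$p <- 1; pars$q <- 0
    expect_lt(abs(expected_payoffs(st, pars)[["pD"]]), 1e-12)
  }
})

test_that("three-strategy sums restricted to z = 0 match the two-strategy
           binomial forms", {
  set.seed(14)
  for (i in 1:15) {
    x <- runif(1)
    pars <- random_params()
    ref <- ref_two_strategy_payoffs(x, pars)
    pay <- expected_payoffs(c(x, 1 - x, 0), pars)
    expect_equal(pay[["pC"]], ref[["pC"]], tolerance = 1e-12)
    expect_equal(pay[["pD"]], ref[["pD"]], tolerance = 1e-12)
  }
})

test_that("Monte-Carlo oracle is seeded, reproducible, and degenerate at
           pure-defector states", {
  p <- qs_params()
  a <- monte_carlo_payoffs(pop_state(0.5, 0.5, 0), p, 1000, seed = 9)
  b <- monte_carlo_payoffs(pop_state(0.5, 0.5, 0), p, 1000, seed = 9)
  expect_identical(a, b)
  d <- monte_carlo_payoffs(pop_state(0, 1, 0), p, 1000, seed = 1)
  expect_equal(d$estimate[["pD"]], 0)
  expect_equal(d$se[["pD"]], 0)
  pp <- qs_params(p = 1, q = 0)
  e <- monte_carlo_payoffs(pop_state(0.2, 0.5, 0.3), pp, 1000, seed = 2)
  expect_equal(e$estimate[["pD"]], 0)
})

test_that("Monte-Carlo estimates agree with the analytic sums", {
  p <- qs_params()
  st <- pop_state(0.5, 0.5, 0)
  mc <- monte_carlo_payoffs(st, p, 1e5, seed = 31)
  an <- expected_payoffs(st, p)
  for (k in c("pC", "pD", "pCD")) {
    tol <- max(4 * mc$se[[k]], 1e-12)
    expect_lt(abs(mc$estimate[[k]] - an[[k]]), tol)
  }
})

test_that("off-simplex states are rejected", {
  expect_error(expected_payoffs(c(0.5, 0.6, 0.1), qs_params()), "sum to 1")
  expect_error(pop_state(-0.1, 0.6, 0.5), "non-negative")
})
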