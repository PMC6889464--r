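test_that("generators are reproducible and respect degenerate inputs", {
  p <- qs_params()
  des <- assay_design(n_cycles = 3, seed = 7)
  a <- generate_evolution_assay(pop_state(0.4, 0.3, 0.3), p, des)
  b <- generate_evolution_assay(pop_state(0.4, 0.3, 0.3), p, des)
  expect_identical(a, b)
  expect_equal(nrow(a), 9)   # 3 cycles x 3 sampling times
  expect_true(all(a$n_C + a$n_CD + a$n_D == a$n_sampled))

  # cooperator-vertex start: every colony is a cooperator
  v <- generate_evolution_assay(pop_state(1, 0, 0), p, des)
  expect_true(all(v$n_C == 100 & v$n_CD == 0 & v$n_D == 0))

  r1 <- generate_competition_assay(c("D", "CD"), c(0.3, 0.5), p, seed = 5)
  r2 <- generate_competition_assay(c("D", "CD"), c(0.3, 0.5), p, seed = 5)
  expect_identical(r1, r2)
  expect_error(generate_competition_assay(c("D", "D"), 0.5, p, seed = 1),
               "distinct")
  expect_error(generate_competition_assay(c("D", "C"), 1, p, seed = 1),
               "strictly")
})

test_that("deep colony sampling converges to the model frequencies", {
  p <- qs_params()
  st0 <- pop_state(0.4, 0.3, 0.3)
  des <- assay_design(n_cycles = 1, n_colonies = 1e6, seed = 19)
  tab <- generate_evolution_assay(st0, p, des)
  tr <- integrate_replicator(st0, p, t_end = 24, n_out = 25)
  model <- tr$states[match(c(8, 16, 24), tr$times), c("x", "z", "y")]
  obs <- as.matrix(tab[, c("n_C", "n_CD", "n_D")]) / 1e6
  expect_lt(max(abs(obs - model)), 0.005)
})

test_that("every strategy is observed under oscillatory coexistence", {
  des <- assay_design(n_cycles = 10, seed = 3)
  tab <- generate_evolution_assay(pop_state(0.4, 0.3, 0.3), qs_params(), des)
  expect_gt(max(tab$n_C), 0)
  expect_gt(max(tab$n_CD), 0)
  expect_gt(max(tab$n_D), 0)
})

test_that("competition assays show the cyclic dominance directions", {
  # defector invades conditional defector when CD pays a perception cost
  rec <- generate_competition_assay(c("D", "CD"), 0.5, qs_params(),
                                    seed = 2)
  expect_gt(rec$x1_model, 0.5)
  # without punishment the defector also beats the cooperator
  rec2 <- generate_competition_assay(c("D", "C"), c(0.1, 0.5, 0.9),
                                     qs_params(p = 0), seed = 2)
  expect_true(all(rec2$x1_model > rec2$x0))
  # infinite sampling depth reproduces the model frequency exactly
  rec3 <- generate_competition_assay(c("CD", "C"), 0.5, qs_params(),
                                     duration_h = 2, n_cfu = 1e7, seed = 4)
  expect_equal(rec3$x1, rec3$x1_model, tolerance = 1e-3)
  # fixation rows carry the flag, not a value; the continuity correction
  # replaces the flag with a finite v
  fix <- generate_competition_assay(c("D", "C"), 0.9, qs_params(p = 0),
                                    seed = 6)
  if (any(fix$fixation)) expect_true(all(is.na(fix$v[fix$fixation])))
  cc <- generate_competition_assay(c("D", "C"), 0.9, qs_params(p = 0),
                                   seed = 6, continuity_correction = TRUE)
  expect_false(any(cc$fixation))
  expect_true(all(is.finite(cc$v)))
})

test_that("finite-population simulation is seeded, conserves size, and
           fixes vertices", {
  p <- qs_params()
  cfg <- finite_pop_config(M = 500, generations = 40, seed = 8)
  a <- simulate_finite_population(pop_state(0.4, 0.3, 0.3), p, cfg)
  b <- simulate_finite_population(pop_state(0.4, 0.3, 0.3), p, cfg)
  expect_identical(a$states, b$states)
  expect_equal(unname(rowSums(a$states)), rep(1, 41))
  expect_true(all(abs(a$states * 500 - round(a$states * 500)) < 1e-9))

  v <- simulate_finite_population(pop_state(0, 0, 1), p, cfg)
  expect_true(all(v$states[, "z"] == 1))
})

test_that("vanishing selection intensity reduces to neutral drift", {
  cfg <- finite_pop_config(M = 1e6, generations = 5,
                           fitness_scale = 1e-10, seed = 13)
  tr <- simulate_finite_population(pop_state(0.4, 0.3, 0.3), qs_params(),
                                   cfg)
  drift <- sweep(tr$states, 2, c(0.4, 0.3, 0.3))
  expect_lt(max(abs(drift)), 0.005)
})

test_that("large populations track the time-rescaled replicator flow", {
  p <- qs_params()
  st0 <- pop_state(0.4, 0.3, 0.3)
  cfg <- finite_pop_config(M = 1e5, generations = 200, seed = 17)
  fp <- simulate_finite_population(st0, p, cfg)
  tr <- integrate_replicator(st0, p, t_end = 400, n_out = 4001)
  # rescale generation time by matching cooperator-frequency peak times:
  # smooth the stochastic series, pair the peaks in order, and regress the
  # replicator peak times on the generation indices through the origin
  peaks_of <- function(x) which(x[2:(length(x) - 1)] > x[1:(length(x) - 2)] &
                                x[2:(length(x) - 1)] > x[3:length(x)]) + 1
  t_peaks <- tr$times[peaks_of(tr$states[, "x"])]
  sm <- as.numeric(stats::filter(fp$states[, "x"], rep(1 / 9, 9), sides = 2))
  idx <- which(!is.na(sm))
  g_peaks <- peaks_of(sm[idx]) + idx[1] - 1
  npk <- min(length(g_peaks), length(t_peaks))
  expect_gte(npk, 2)
  scale <- sum(t_peaks[1:npk] * g_peaks[1:npk]) / sum(g_peaks[1:npk]^2)
  matched <- vapply(fp$times * scale, function(t)
    which.min(abs(tr$times - t)), integer(1))
  dev <- abs(fp$states - tr$states[matched, ])
  expect_lt(mean(dev), 0.05)
  # the qualitative regime is preserved: all three strategies persist
  expect_true(all(fp$states > 0))
})
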