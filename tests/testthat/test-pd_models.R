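test_that("Hill effect: zero, half-maximum, published plug-in, bounds", {
  p <- sp$pd$group1   # E_max 303.77, EC_50 3.48, h 2
  expect_identical(hill_effect(0, p), 0)
  expect_equal(hill_effect(p$EC_50, p), p$E_max / 2)
  expect_equal(hill_effect(6.96, p), 303.77 * 0.8, tolerance = 1e-12)
  C <- c(0, 10^seq(-3, 6, by = 0.5), Inf)
  ce <- hill_effect(C, p)
  expect_true(all(ce >= 0 & ce <= p$E_max))
  expect_true(all(diff(ce) >= 0))
})

test_that("baseline model: steady state, asymptote, convergence", {
  p <- sp$pd$group1
  flat <- simulate_baseline(p, c(0, 1, 10, 336), R0 = p$k_in / p$k_out)
  expect_equal(flat$values, rep(4.25, 4), tolerance = 1e-12)
  s <- simulate_baseline(p, c(0, 336))
  expect_equal(s$values[2L], 4.25, tolerance = 1e-6)
  s_hi <- simulate_baseline(p, c(0, 336), R0 = 10)
  expect_equal(s_hi$values[2L], 4.25, tolerance = 1e-6)
})

test_that("stationary feedback closure F0 = k_out*R0/k_in", {
  p <- pd_params(k_in = 0.4, k_out = 0.1, k_f_on = 1, k_f_off = 1,
                 E_max = 1, EC_50 = 1, h = 1, R0 = 4)
  expect_equal(initial_feedback_state(p), 1)
  expect_equal(initial_feedback_state(sp$pd$group1), 1.024, tolerance = 1e-3)
  expect_equal(initial_feedback_state(sp$pd$group6), 0.702, tolerance = 1e-3)
})

test_that("zero drug with a jointly stationary set holds R at R0", {
  pc <- stationary_pd_params()
  s <- simulate_pd(pc, NULL, c(1, 2, 4, 8, 24 * c(1:7, 11, 14)))
  expect_lt(max(abs(s$values - pc$R0) / pc$R0), 1e-6)
  # E_max = 0 is indistinguishable from the zero-drug case
  p0 <- pd_params(pc$k_in, pc$k_out, pc$k_f_on, pc$k_f_off, E_max = 0,
                  EC_50 = pc$EC_50, h = pc$h, R0 = pc$R0)
  scen <- list(pk = sp$solution_iv, dose = dose_iv)
  s0 <- simulate_pd(p0, scen, c(1, 2, 4, 8, 24 * c(1:7, 11, 14)))
  expect_equal(s0$values, s$values, tolerance = 1e-12)
})

test_that("flare-then-suppress emerges for the Group 1 set (reciprocal)", {
  p <- sp$pd$group1
  tt <- c(0.25, 0.5, 1, 2, 4, 8, 24 * c(1:7, 11, 14))
  s <- simulate_pd(p, list(pk = sp$solution_iv, dose = dose_iv), tt)
  expect_gt(max(s$values), p$R0)               # flare above baseline
  expect_lt(tt[which.max(s$values)], 12)       # peak within the first hours
  expect_lt(min(s$values), p$R0)               # later undershoot
  expect_gt(min(s$values), 0)
  # feedback state stays positive
  expect_true(all(attr(s, "feedback") > 0))
  # the product form gives positive feedback: no suppression below baseline
  tt48 <- c(0.25, 0.5, 1, 2, 4, 8, 24, 48)
  s_prod <- simulate_pd(p, list(pk = sp$solution_iv, dose = dose_iv), tt48,
                        feedback_form = "product")
  expect_gte(min(s_prod$values), p$R0)
})

test_that("fast and generic engines agree bit-for-bit", {
  p <- sp$pd$group3
  tt <- c(0.25, 1, 2, 4, 8, 24, 72, 336)
  scen <- list(pk = sp$solution_sc, dose = dose_sc)
  expect_identical(simulate_pd(p, scen, tt)$values,
                   simulate_pd(p, scen, tt, engine = "generic")$values)
})

test_that("drug drivers: series interpolation matches the function form", {
  p <- stationary_pd_params(sp$pd$group3)
  dense <- seq(0, 48, by = 0.01)
  cs <- solution_closed_form(sp$solution_sc, dose_sc, dense[-1L])
  cs_full <- conc_series(dense, c(0, cs$values), "leuprolide")
  tt <- c(0.5, 1, 2, 4, 8, 24, 48)
  via_series <- simulate_pd(p, cs_full, tt)
  via_scen <- simulate_pd(p, list(pk = sp$solution_sc, dose = dose_sc), tt)
  expect_equal(via_series$values, via_scen$values, tolerance = 1e-3)
})

test_that("pathological parameters blowing up R raise a model error", {
  # loss rate far beyond the solver's stability limit at the default step
  p <- pd_params(k_in = 1e-8, k_out = 300, k_f_on = 1e-8, k_f_off = 1e-3,
                 E_max = 1, EC_50 = 1, h = 1, R0 = 4)
  expect_error(simulate_pd(p, NULL, c(1, 10)), "response")
})
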