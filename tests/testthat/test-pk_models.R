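test_that("IV bolus follows C0 * exp(-k t)", {
  p <- solution_pk_params(NA, CL = 1.386, V_d = 1)   # k = 1.386 h^-1
  d <- dose_spec(1e-5, 0.1, "IV")                    # amount = 1 ng
  s <- simulate_iv(p, d, c(1e-12, 0.5, 1))
  expect_equal(s$values[1L], d$amount / p$V_d, tolerance = 1e-6)
  expect_equal(s$values[2L], s$values[1L] / 2, tolerance = 1e-3)
  # reported IV elimination constant: C(2h)/C0 = exp(-2.84)
  p2 <- solution_pk_params(NA, CL = 1.42, V_d = 1)
  s2 <- simulate_iv(p2, dose_spec(1e-5, 0.1, "IV"), c(1e-12, 2))
  expect_equal(s2$values[2L] / s2$values[1L], exp(-2.84), tolerance = 1e-5)
})

test_that("Bateman closed form: origin, T_max, IV limit", {
  expect_equal(solution_closed_form(sp$solution_sc, dose_sc, c(0, 1))$values[1L],
               0)
  k <- sp$solution_sc$k
  ka <- sp$solution_sc$k_a
  tmax <- log(ka / k) / (ka - k)
  expect_equal(tmax, 0.1767, tolerance = 1e-3)
  grid <- seq(0.01, 1, by = 1e-4)
  cs <- solution_closed_form(sp$solution_sc, dose_sc, grid)
  expect_equal(grid[which.max(cs$values)], tmax, tolerance = 1e-3)
  # k_a -> Inf approaches the IV bolus curve
  fast <- solution_pk_params(1e6, sp$solution_sc$CL, sp$solution_sc$V_d)
  iv <- solution_pk_params(NA, sp$solution_sc$CL, sp$solution_sc$V_d)
  t_late <- c(0.1, 0.5, 1, 2)
  expect_equal(solution_closed_form(fast, dose_sc, t_late)$values,
               simulate_iv(iv, dose_spec(0.1, 0.3, "IV"), t_late)$values,
               tolerance = 1e-3)
})

test_that("k_a ~ k falls back to the limit form t*k*exp(-kt)*amount/Vd", {
  p <- solution_pk_params(k_a = 1, CL = 1, V_d = 1)
  d <- dose_spec(1e-5, 0.1, "SC-solution")   # amount = 1 ng
  s <- solution_closed_form(p, d, c(0.5, 1))
  expect_equal(s$values, d$amount * 1 * c(0.5, 1) * exp(-c(0.5, 1)),
               tolerance = 1e-8)
})

test_that("SC solution: zero dose limit and mass balance", {
  tiny <- dose_spec(1e-300, 0.3, "SC-solution")
  expect_lt(max(solution_closed_form(sp$solution_sc, tiny,
                                     study_times)$values), 1e-290)
  traj <- simulate_sc_solution(sp$solution_sc, dose_sc, study_times,
                               full = TRUE)
  total <- rowSums(traj)
  expect_equal(total, rep(dose_sc$amount, length(study_times)),
               tolerance = 1e-6)
  # everything absorbed and eliminated by 14 days
  expect_equal(unname(traj[length(study_times), "eliminated"]),
               dose_sc$amount, tolerance = 1e-6)
})

test_that("AUC_0_inf equals amount/CL for the solution route", {
  grid <- sort(unique(c(seq(0, 2, by = 0.002), seq(2, 60, by = 0.05))))
  cs <- solution_closed_form(sp$solution_sc, dose_sc, grid)
  auc <- auc_trapezoid(cs, extrapolate = TRUE, k = sp$solution_sc$k)
  expect_equal(auc$AUC_0_inf, dose_sc$amount / sp$solution_sc$CL,
               tolerance = 1e-3)
})

test_that("depot with N_R = 1 reduces to the SC solution model", {
  dp <- depot_params(1, 1e-12, 0, k_d = 0.08, k_t = 0.0078,
                     t_lag_d = 0.47, t_lag_e = 3.61, ES_n = 2L)
  a <- depot_closed_form(dp, sp$solution_sc, dose_dp, study_times)
  b <- solution_closed_form(sp$solution_sc, dose_sc, study_times)
  expect_equal(a$values, b$values, tolerance = 1e-9)
})

test_that("depot ODE: conservation at t = 0 and mass balance throughout", {
  traj <- simulate_depot(sp$depot_wistar, sp$solution_sc, dose_dp,
                         c(0, 1, 24, 336), full = TRUE)
  depot_states <- c("NS", "DS", "ES1", "ES2")
  expect_equal(sum(traj[1L, depot_states]), dose_dp$amount,
               tolerance = 1e-9)
  expect_equal(unname(rowSums(traj)), rep(dose_dp$amount, 4),
               tolerance = 1e-6)
  expect_true(all(traj >= 0))
})

test_that("depot ODE agrees with the closed form", {
  ode <- simulate_depot(sp$depot_wistar, sp$solution_sc, dose_dp,
                        study_times)
  cf <- depot_closed_form(sp$depot_wistar, sp$solution_sc, dose_dp,
                          study_times)
  # lag gating limits local order at the two switch instants
  expect_lt(max(abs(ode$values - cf$values) / pmax(cf$values, 1e-9)), 1e-3)
})

test_that("erosive-chain release by 14 days matches the gamma CDF", {
  w <- sp$depot_wistar
  frac_erosive <- stats::pgamma(336 - w$t_lag_e, shape = w$ES_n,
                                rate = w$k_t)
  expect_equal(frac_erosive, 0.736, tolerance = 0.01)
  expect_equal(w$E_R * frac_erosive, 0.40, tolerance = 0.025)
  # the simulated depot has released that much from the erosive chain
  traj <- simulate_depot(w, sp$solution_sc, dose_dp, c(0, 336),
                         full = TRUE)
  left <- sum(traj[2L, c("ES1", "ES2")])
  released <- (w$E_R * dose_dp$amount - left) / dose_dp$amount
  expect_equal(released, w$E_R * frac_erosive, tolerance = 1e-3)
})

test_that("release profile is a proper CDF mixture of the three sections", {
  w <- sp$depot_wistar
  tt <- c(0, 0.5, 1, 2, w$t_lag_e, 8, 24, 100, 336, 5000)
  rel <- depot_release_profile(w, sp$solution_sc, tt)
  expect_equal(rel[1L], 0)
  expect_true(all(diff(rel) >= 0))
  expect_equal(rel[length(rel)], 1, tolerance = 1e-6)
  # at the erosive lag only NS and DS have released
  expected <- w$N_R * (1 - exp(-sp$solution_sc$k_a * w$t_lag_e)) +
    w$D_R * (1 - exp(-w$k_d * (w$t_lag_e - w$t_lag_d)))
  expect_equal(rel[tt == w$t_lag_e], expected, tolerance = 1e-12)
})

test_that("parameter validation catches broken inputs", {
  expect_error(depot_params(0.19, 0.28, 0.54, 0.08, 0.0078, 0.47, 3.61),
               "sum to 1")
  expect_error(solution_pk_params(16, -1, 400))
  expect_error(simulate_iv(sp$solution_iv, dose_sc, c(0, 1)), "route")
})
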