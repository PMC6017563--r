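test_that("individual draws: degenerate CV, simplex closure, moments", {
  nm0 <- noise_model(iiv_cv = 0)
  set.seed(1)
  same <- draw_individual_params(sp$solution_sc, nm0, 3)
  expect_identical(same[[1L]], same[[2L]])
  expect_identical(unlist(same[[3L]]), unlist(sp$solution_sc))

  nm <- noise_model(iiv_cv = 0.3)
  set.seed(2)
  depots <- draw_individual_params(sp$depot_wistar, nm, 50)
  sums <- vapply(depots, function(d) d$N_R + d$D_R + d$E_R, numeric(1))
  expect_equal(sums, rep(1, 50), tolerance = 1e-12)
  expect_true(all(vapply(depots, function(d) d$ES_n, integer(1)) == 2L))

  set.seed(3)
  kas <- vapply(draw_individual_params(sp$solution_sc, nm, 1e4),
                function(p) p$k_a, numeric(1))
  cv <- stats::sd(kas) / mean(kas)
  expect_gt(cv, 0.29); expect_lt(cv, 0.31)
  expect_equal(mean(kas), 16.67, tolerance = 0.02)
})

test_that("zero-noise study equals the deterministic model curves", {
  quiet <- noise_model(iiv_cv = 0, residual_cv = 0,
                       testosterone_residual_cv = 0,
                       testosterone_additive_sd = 0, seed = 5)
  stud <- generate_study(study_design(n_per_group = 2L), noise = quiet)
  g3 <- stud[stud$group == 3 & stud$analyte == "leuprolide" &
               stud$subject_id == "G3-01", ]
  ref <- solution_closed_form(sp$solution_sc, dose_sc, g3$time_h)
  expect_equal(g3$conc_ng_ml, ref$values, tolerance = 1e-12)
  # both subjects identical without variability
  g3b <- stud[stud$group == 3 & stud$analyte == "leuprolide" &
                stud$subject_id == "G3-02", ]
  expect_identical(g3$conc_ng_ml, g3b$conc_ng_ml)
  # depot arm against the closed form
  g4 <- stud[stud$group == 4 & stud$analyte == "leuprolide" &
               stud$subject_id == "G4-01", ]
  ref4 <- depot_closed_form(sp$depot_wistar, sp$solution_sc, dose_dp,
                            g4$time_h)
  expect_equal(g4$conc_ng_ml, ref4$values, tolerance = 1e-12)
})

test_that("study structure follows the six-group design", {
  stud <- generate_study(noise = noise_model(seed = 6))
  expect_setequal(unique(stud$group), 1:6)
  expect_true(all(stud$conc_ng_ml >= 0))
  expect_identical(stud$bql_flag,
                   stud$conc_ng_ml < ifelse(stud$analyte == "leuprolide",
                                            0.01, 0.041))
  veh <- stud[stud$formulation == "vehicle", ]
  expect_true(all(veh$analyte == "testosterone"))
  expect_setequal(unique(veh$time_h), c(0, vehicle_times))
  drug <- stud[stud$group == 3 & stud$analyte == "testosterone", ]
  expect_true(all(table(drug$subject_id) == length(study_times) + 1L))
  # pre-dose testosterone recorded at t = 0 for every subject
  expect_true(all(vapply(split(stud[stud$analyte == "testosterone", ],
                               stud$subject_id[stud$analyte == "testosterone"]),
                         function(d) any(d$time_h == 0), logical(1))))
})

test_that("same seed reproduces the study; different seed does not", {
  a <- generate_study(noise = noise_model(seed = 7))
  b <- generate_study(noise = noise_model(seed = 7))
  expect_identical(a, b)
  c3 <- generate_study(noise = noise_model(seed = 8))
  expect_false(identical(a$conc_ng_ml, c3$conc_ng_ml))
})

test_that("vehicle arm is trendless and calibrated to the Wistar baseline", {
  des <- study_design(n_per_group = 200L)
  des$groups <- des$groups[des$groups$group == 2L, , drop = FALSE]
  veh <- generate_study(des, noise = noise_model())
  expect_equal(mean(veh$conc_ng_ml), 4.35, tolerance = 0.05)
  # no time trend beyond noise
  sl <- summary(stats::lm(conc_ng_ml ~ time_h, data = veh))$coefficients
  expect_gt(sl["time_h", "Pr(>|t|)"], 0.01)
})

test_that("residual error magnitude matches its declaration", {
  truth <- solution_closed_form(sp$solution_sc, dose_sc, c(1, 2))$values[1L]
  nmod <- noise_model(residual_cv = 0.10)
  set.seed(10)
  noisy <- depotpkpd:::.apply_residual(rep(truth, 1e4), "leuprolide", nmod)
  expect_equal(stats::sd(noisy / truth), 0.10, tolerance = 0.1)
})

test_that("fixture suite is deterministic and fit-ready", {
  d1 <- withr::local_tempdir()
  a <- fixture_suite(123, dir = d1)
  expect_setequal(unique(a$means_noisefree$group), 1:6)
  d2 <- withr::local_tempdir()
  b <- fixture_suite(123, dir = d2)
  for (f in c("means_noisefree.csv", "noisy_study.csv",
              "flat_baseline.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # the noise-free bundle round-trips through the fitters
  m <- a$means_noisefree
  g3 <- m[m$group == 3 & m$analyte == "leuprolide", ]
  fit <- fit_solution_pk(conc_series(g3$time_h, g3$conc_ng_ml,
                                     "leuprolide"),
                         "SC-solution", dose_sc, starts = 3)
  expect_equal(fit$params$k_a, 16.67, tolerance = 0.01)
  expect_equal(fit$params$CL, 514.46, tolerance = 0.01)
})
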