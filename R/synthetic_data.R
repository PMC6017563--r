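#' Synthetic six-group rat study generator
#'
#' Emulates the in-vivo study design the models were built for: six groups
#' of five rats (IV solution, SC vehicle, SC solution, SC depot in normal
#' Wistar rats; SC vehicle and SC depot in prostate-cancer Iar:COP rats),
#' sampled at 0.25, 1, 2, 4, 8 h and 1-7, 11, 14 days (vehicle groups at
#' 8 h, 1, 7, 14 days), with lognormal between-subject variability around
#' the published mean parameter sets and proportional residual error.
#'
#' @name synthetic_data
NULL

.h <- function(days) days * 24

#' Study design
#'
#' @param n_per_group Subjects per group (default 5).
#' @param body_weight Body weight (kg, default 0.3).
#' @return A `study_design` list with a `groups` data.frame (columns
#'   `group`, `species`, `route`, `formulation`, `dose_nominal`) and
#'   per-arm sampling times in hours.
#' @export
study_design <- function(n_per_group = 5L, body_weight = 0.3) {
  drug_times <- c(0.25, 1, 2, 4, 8, .h(c(1:7, 11, 14)))
  vehicle_times <- c(8, .h(c(1, 7, 14)))
  groups <- data.frame(
    group = 1:6,
    species = c("Wistar", "Wistar", "Wistar", "Wistar", "Iar:COP", "Iar:COP"),
    route = c("IV", "SC", "SC", "SC", "SC", "SC"),
    formulation = c("solution", "vehicle", "solution", "depot", "vehicle",
                    "depot"),
    dose_nominal = c(0.1, NA, 0.1, 0.1, NA, 0.1),
    stringsAsFactors = FALSE
  )
  structure(list(groups = groups, drug_times = drug_times,
                 vehicle_times = vehicle_times,
                 n_per_group = as.integer(n_per_group),
                 body_weight = body_weight),
            class = "study_design")
}

#' Noise model for the synthetic study
#'
#' Lognormal between-subject (inter-individual) variability applied
#' multiplicatively to every parameter, proportional residual error per
#' observation (leuprolide), proportional plus additive residual error for
#' testosterone, and the assay quantification limits used for flagging.
#'
#' @param iiv_cv Between-subject CV on each parameter (default 0.25).
#' @param residual_cv Proportional residual CV for leuprolide (default
#'   0.10).
#' @param testosterone_residual_cv Proportional residual CV for
#'   testosterone (default 0.15).
#' @param testosterone_additive_sd Additive residual SD for testosterone
#'   (ng/mL, default 0.1).
#' @param lloq_testosterone,uloq_testosterone Testosterone assay limits
#'   (ng/mL, defaults 0.041 and 10; values above the upper limit are
#'   flagged as diluted but kept numeric).
#' @param lloq_leuprolide Leuprolide quantification floor (ng/mL, default
#'   0.01).
#' @param seed Integer seed.
#' @return A `noise_model` list.
#' @export
noise_model <- function(iiv_cv = 0.25, residual_cv = 0.10,
                        testosterone_residual_cv = 0.15,
                        testosterone_additive_sd = 0.1,
                        lloq_testosterone = 0.041, uloq_testosterone = 10,
                        lloq_leuprolide = 0.01, seed = 20180415L) {
  stopifnot(iiv_cv >= 0, residual_cv >= 0, testosterone_residual_cv >= 0,
            testosterone_additive_sd >= 0,
            lloq_testosterone < uloq_testosterone)
  structure(list(iiv_cv = iiv_cv, residual_cv = residual_cv,
                 testosterone_residual_cv = testosterone_residual_cv,
                 testosterone_additive_sd = testosterone_additive_sd,
                 lloq_testosterone = lloq_testosterone,
                 uloq_testosterone = uloq_testosterone,
                 lloq_leuprolide = lloq_leuprolide,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# mean-1 lognormal deviates with coefficient of variation cv
.lnorm_dev <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

#' Draw individual parameter sets
#'
#' Each scalar parameter of `mean_params` is multiplied by an independent
#' mean-1 lognormal deviate with CV `noise$iiv_cv`; depot release fractions
#' are renormalised to sum to one afterwards. Transit counts are not
#' perturbed. The caller controls the RNG state (set a seed first);
#' [generate_study()] does this from `noise$seed`.
#'
#' @param mean_params A [solution_pk_params()], [depot_params()],
#'   [pd_params()] or plain named list of positive scalars.
#' @param noise A [noise_model()].
#' @param n Number of individuals.
#' @return List of `n` parameter objects of the same class.
#' @export
draw_individual_params <- function(mean_params, noise, n) {
  stopifnot(inherits(noise, "noise_model"), n >= 1L)
  cv <- noise$iiv_cv
  draw_one <- function() {
    if (inherits(mean_params, "solution_pk_params")) {
      ka <- if (is.na(mean_params$k_a)) NA_real_ else
        mean_params$k_a * .lnorm_dev(1, cv)
      solution_pk_params(ka, mean_params$CL * .lnorm_dev(1, cv),
                         mean_params$V_d * .lnorm_dev(1, cv))
    } else if (inherits(mean_params, "depot_params")) {
      fr <- c(mean_params$N_R, mean_params$D_R, mean_params$E_R) *
        .lnorm_dev(3, cv)
      fr <- fr / sum(fr)
      depot_params(fr[1L], fr[2L], fr[3L],
                   mean_params$k_d * .lnorm_dev(1, cv),
                   mean_params$k_t * .lnorm_dev(1, cv),
                   mean_params$t_lag_d * .lnorm_dev(1, cv),
                   mean_params$t_lag_e * .lnorm_dev(1, cv),
                   mean_params$ES_n)
    } else if (inherits(mean_params, "pd_params")) {
      v <- unlist(mean_params)
      v <- v * .lnorm_dev(length(v), cv)
      do.call(pd_params, as.list(v))
    } else if (is.list(mean_params)) {
      v <- unlist(mean_params)
      as.list(v * .lnorm_dev(length(v), cv))
    } else {
      stop("unsupported parameter container", call. = FALSE)
    }
  }
  lapply(seq_len(n), function(i) draw_one())
}

#' Default per-group parameter sets for the six-group design
#'
#' Maps the published mean parameter sets onto the study groups: solution
#' disposition for the IV and SC solution arms, depot release parameters
#' for the two depot arms (with the SC solution disposition), the matching
#' turnover/feedback PD set per drug arm, and the species baseline for the
#' vehicle arms.
#'
#' @return Named list `g1`..`g6` of per-group parameter bundles.
#' @export
default_group_params <- function() {
  sp <- study_params()
  list(
    g1 = list(pk = sp$solution_iv, pd = sp$pd$group1, route = "IV"),
    g2 = list(baseline = sp$pd$baseline_wistar),
    g3 = list(pk = sp$solution_sc, pd = sp$pd$group3,
              route = "SC-solution"),
    g4 = list(pk = sp$solution_sc, depot = sp$depot_wistar,
              pd = sp$pd$group4, route = "SC-depot"),
    g5 = list(baseline = sp$pd$baseline_iarcop),
    g6 = list(pk = sp$solution_sc, depot = sp$depot_iarcop,
              pd = sp$pd$group6, route = "SC-depot")
  )
}

.apply_residual <- function(values, analyte, noise) {
  n <- length(values)
  if (analyte == "leuprolide") {
    out <- values * (1 + noise$residual_cv * stats::rnorm(n))
  } else {
    out <- values * (1 + noise$testosterone_residual_cv * stats::rnorm(n)) +
      noise$testosterone_additive_sd * stats::rnorm(n)
  }
  pmax(out, 0)
}

.sim_drug_conc <- function(gp, dose, times) {
  switch(gp$route,
         "IV" = simulate_iv(gp$pk, dose, times),
         "SC-solution" = solution_closed_form(gp$pk, dose, times),
         "SC-depot" = depot_closed_form(gp$depot, gp$pk, dose, times))
}

#' Generate the full synthetic study
#'
#' For every subject: draw individual parameters, simulate leuprolide with
#' the route-appropriate PK model and testosterone with the linked feedback
#' turnover model (baseline model in the vehicle arms), apply residual
#' error, and flag quantification limits. Pre-dose testosterone is recorded
#' at `t = 0` for every subject.
#'
#' @param design A [study_design()].
#' @param group_params Per-group parameter bundles as from
#'   [default_group_params()]; names `g<group>`.
#' @param noise A [noise_model()]; `noise$seed` fixes the whole draw.
#' @return Long-format data.frame with columns `subject_id`, `group`,
#'   `species`, `route`, `formulation`, `analyte`, `time_h`, `conc_ng_ml`,
#'   `bql_flag`, `diluted_flag`.
#' @export
generate_study <- function(design = study_design(),
                           group_params = default_group_params(),
                           noise = noise_model()) {
  stopifnot(inherits(design, "study_design"), inherits(noise, "noise_model"))
  set.seed(noise$seed)
  rows <- list()
  for (gi in seq_len(nrow(design$groups))) {
    g <- design$groups[gi, ]
    gp <- group_params[[paste0("g", g$group)]]
    if (is.null(gp)) {
      stop("missing parameter set for group ", g$group, call. = FALSE)
    }
    vehicle <- g$formulation == "vehicle"
    times <- if (vehicle) design$vehicle_times else design$drug_times
    for (subj in seq_len(design$n_per_group)) {
      sid <- sprintf("G%d-%02d", g$group, subj)
      if (vehicle) {
        bp <- draw_individual_params(gp$baseline, noise, 1L)[[1L]]
        tt <- c(0, times)
        testo <- simulate_baseline(bp, tt)$values
        testo <- .apply_residual(testo, "testosterone", noise)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = g$group, species = g$species,
          route = g$route, formulation = g$formulation,
          analyte = "testosterone", time_h = tt, conc_ng_ml = testo,
          bql_flag = testo < noise$lloq_testosterone,
          diluted_flag = testo > noise$uloq_testosterone,
          stringsAsFactors = FALSE)
      } else {
        pk_i <- draw_individual_params(gp$pk, noise, 1L)[[1L]]
        depot_i <- if (!is.null(gp$depot)) {
          draw_individual_params(gp$depot, noise, 1L)[[1L]]
        }
        pd_i <- draw_individual_params(gp$pd, noise, 1L)[[1L]]
        route <- if (gp$route == "IV") "IV" else
          if (gp$route == "SC-solution") "SC-solution" else "SC-depot"
        dose <- dose_spec(g$dose_nominal, design$body_weight, route)
        gpi <- list(pk = pk_i, depot = depot_i, route = gp$route)
        drug <- .sim_drug_conc(gpi, dose, times)$values
        drug_noisy <- .apply_residual(drug, "leuprolide", noise)
        scen <- list(pk = pk_i, depot = depot_i, dose = dose)
        tt <- c(0, times)
        testo <- simulate_pd(pd_i, scen, tt)$values
        testo_noisy <- .apply_residual(testo, "testosterone", noise)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = g$group, species = g$species,
          route = g$route, formulation = g$formulation,
          analyte = c(rep("leuprolide", length(times)),
                      rep("testosterone", length(tt))),
          time_h = c(times, tt),
          conc_ng_ml = c(drug_noisy, testo_noisy),
          bql_flag = c(drug_noisy < noise$lloq_leuprolide,
                       testo_noisy < noise$lloq_testosterone),
          diluted_flag = c(rep(FALSE, length(times)),
                           testo_noisy > noise$uloq_testosterone),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- noise$seed
  out
}

#' Deterministic fixture bundle for tests and examples
#'
#' Three small canned datasets, byte-identical for a given seed: noise-free
#' group-mean profiles for all six arms, one noisy full study, and a
#' degenerate flat-baseline vehicle set. When `dir` is given, each element
#' is also written as a delimited file via [write_conc_table()].
#'
#' @param seed Integer seed stamped into the bundle.
#' @param dir Optional output directory.
#' @return List with `means_noisefree`, `noisy_study`, `flat_baseline`
#'   (data.frames) and `seed`.
#' @export
fixture_suite <- function(seed = 20180415L, dir = NULL) {
  quiet <- noise_model(iiv_cv = 0, residual_cv = 0,
                       testosterone_residual_cv = 0,
                       testosterone_additive_sd = 0, seed = seed)
  design1 <- study_design(n_per_group = 1L)
  means <- generate_study(design1, noise = quiet)
  means$subject_id <- sub("-01$", "-mean", means$subject_id)
  noisy <- generate_study(study_design(), noise = noise_model(seed = seed))
  flat_times <- c(0, study_design()$vehicle_times)
  flat <- data.frame(
    subject_id = "FLAT-01", group = 2L, species = "Wistar", route = "SC",
    formulation = "vehicle", analyte = "testosterone", time_h = flat_times,
    conc_ng_ml = rep(4.353, length(flat_times)), bql_flag = FALSE,
    diluted_flag = FALSE, stringsAsFactors = FALSE)
  bundle <- list(means_noisefree = means, noisy_study = noisy,
                 flat_baseline = flat, seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in c("means_noisefree", "noisy_study", "flat_baseline")) {
      write_conc_table(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                       seed = seed)
    }
  }
  bundle
}
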