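#' Parameter containers for the solution, depot and turnover models
#'
#' Constructors validate units and structural constraints once, so the
#' simulators and fitters can assume well-formed inputs.
#'
#' @name params
NULL

#' One-compartment solution PK parameters
#'
#' First-order absorption rate `k_a` (h^-1; `NA` for IV bolus), total
#' clearance `CL` (mL/h) and volume of distribution `V_d` (mL). The
#' elimination rate constant `k = CL/V_d` is derived. For subcutaneous routes
#' the clearance and volume are apparent (CL/F-style), since bioavailability
#' is not a separate structural parameter.
#'
#' @param k_a Absorption rate constant (h^-1), `> 0`, or `NA` for IV.
#' @param CL Total clearance (mL/h), `> 0`.
#' @param V_d Volume of distribution (mL), `> 0`.
#' @return A `solution_pk_params` list with derived element `k`.
#' @export
solution_pk_params <- function(k_a = NA_real_, CL, V_d) {
  stopifnot(is.numeric(CL), length(CL) == 1L, is.finite(CL), CL > 0,
            is.numeric(V_d), length(V_d) == 1L, is.finite(V_d), V_d > 0)
  if (!is.na(k_a)) {
    stopifnot(is.numeric(k_a), length(k_a) == 1L, is.finite(k_a), k_a > 0)
  }
  structure(list(k_a = as.numeric(k_a), CL = CL, V_d = V_d, k = CL / V_d),
            class = "solution_pk_params")
}

#' Sustained-release depot parameters
#'
#' The depot is modelled as three sections: a non-encapsulated section
#' (fraction `N_R`, absorbed at the solution-phase `k_a`), a diffusive
#' section (fraction `D_R`, released at `k_d` after lag `t_lag_d`) and an
#' erosive section (fraction `E_R`, released through a chain of `ES_n`
#' transit compartments at `k_t` after lag `t_lag_e`). The three fractions
#' must sum to one.
#'
#' @param N_R,D_R,E_R Release fractions in `[0, 1]`, summing to 1 within
#'   1e-9.
#' @param k_d Diffusive-release constant (h^-1), `> 0`.
#' @param k_t Erosive-release constant (h^-1), `> 0`.
#' @param t_lag_d,t_lag_e Release lag times (h), `>= 0`.
#' @param ES_n Integer number of erosive transit compartments, 1..10.
#' @return A `depot_params` list.
#' @export
depot_params <- function(N_R, D_R, E_R, k_d, k_t, t_lag_d, t_lag_e, ES_n = 2L) {
  for (f in list(N_R, D_R, E_R)) {
    stopifnot(is.numeric(f), length(f) == 1L, is.finite(f), f >= 0, f <= 1)
  }
  resid <- N_R + D_R + E_R - 1
  if (abs(resid) > 1e-9) {
    stop(sprintf(
      "release fractions must sum to 1: N_R + D_R + E_R = %.6f (residual %.3g)",
      N_R + D_R + E_R, resid), call. = FALSE)
  }
  stopifnot(is.finite(k_d), k_d > 0, is.finite(k_t), k_t > 0,
            is.finite(t_lag_d), t_lag_d >= 0, is.finite(t_lag_e), t_lag_e >= 0)
  ES_n <- as.integer(ES_n)
  stopifnot(ES_n >= 1L, ES_n <= 10L)
  structure(list(N_R = N_R, D_R = D_R, E_R = E_R, k_d = k_d, k_t = k_t,
                 t_lag_d = t_lag_d, t_lag_e = t_lag_e, ES_n = ES_n),
            class = "depot_params")
}

#' Turnover (indirect-response) PD parameters with feedback and Hill effect
#'
#' Testosterone is produced at a zero-order rate `k_in` (modulated by the
#' feedback state and the drug effect) and lost at a first-order rate
#' `k_out`. The drug effect is a Hill function of plasma drug concentration
#' with capacity `E_max`, potency `EC_50` and slope `h`. The feedback state
#' turns on at `k_f_on` and off at `k_f_off`. `R0` is the observed baseline
#' response used to initialise the system.
#'
#' @param k_in Zero-order production constant (response units/h).
#' @param k_out First-order loss constant (h^-1).
#' @param k_f_on Feedback onset constant (h^-1 * ng/mL).
#' @param k_f_off Feedback offset constant (h^-1).
#' @param E_max Maximum effect capacity (dimensionless), `>= 0`.
#' @param EC_50 Half-maximal drug concentration (ng/mL).
#' @param h Hill coefficient.
#' @param R0 Baseline response (ng/mL).
#' @return A `pd_params` list.
#' @export
pd_params <- function(k_in, k_out, k_f_on, k_f_off, E_max, EC_50, h, R0) {
  vals <- c(k_in = k_in, k_out = k_out, k_f_on = k_f_on, k_f_off = k_f_off,
            EC_50 = EC_50, h = h, R0 = R0)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all PD parameters except E_max must be finite and > 0", call. = FALSE)
  }
  stopifnot(is.finite(E_max), E_max >= 0)
  structure(as.list(c(vals[c("k_in", "k_out", "k_f_on", "k_f_off")],
                      E_max = E_max, vals[c("EC_50", "h", "R0")])),
            class = "pd_params")
}

#' Dose specification
#'
#' @param nominal Nominal dose (mg/kg), `> 0`.
#' @param body_weight Body weight (kg); rats in the modelled study design
#'   default to 0.3 kg.
#' @param route One of `"IV"`, `"SC-solution"`, `"SC-depot"`.
#' @return A `dose_spec` list with `amount` in ng
#'   (`nominal * body_weight * 1e6`).
#' @export
dose_spec <- function(nominal = 0.1, body_weight = 0.3,
                      route = c("IV", "SC-solution", "SC-depot")) {
  route <- match.arg(route)
  stopifnot(is.finite(nominal), nominal > 0, is.finite(body_weight),
            body_weight > 0)
  structure(list(nominal = nominal, body_weight = body_weight, route = route,
                 amount = nominal * body_weight * 1e6),
            class = "dose_spec")
}

#' Published mean parameter sets of the six-group rat study
#'
#' Mean parameter estimates reported for the rat leuprolide study this
#' package models: solution-phase disposition after IV (Group 1) and SC
#' (Group 3) dosing, sustained-release depot release parameters for normal
#' Wistar (Group 4) and prostate-cancer Iar:COP (Group 6) rats, the
#' testosterone turnover/feedback parameters per drug group, and the
#' reference AUC values used for bioavailability. These drive the synthetic
#' study generator and the worked examples.
#'
#' @return A nested list with elements `solution_iv`, `solution_sc`,
#'   `depot_wistar`, `depot_iarcop`, `pd` (one entry per drug group plus the
#'   two baselines), `auc_ref` and `dose`.
#' @export
study_params <- function() {
  list(
    solution_iv = solution_pk_params(k_a = NA, CL = 248.61, V_d = 192.95),
    # NCA-reported elimination constant for the IV group; the compartmental
    # CL/V_d ratio (1.29 h^-1) differs, both are kept as printed.
    k_iv_reported = 1.42,
    solution_sc = solution_pk_params(k_a = 16.67, CL = 514.46, V_d = 487.40),
    depot_wistar = depot_params(N_R = 0.18, D_R = 0.28, E_R = 0.54,
                                k_d = 0.08, k_t = 0.0078,
                                t_lag_d = 0.47, t_lag_e = 3.61, ES_n = 2L),
    depot_iarcop = depot_params(N_R = 0.08, D_R = 0.43, E_R = 0.49,
                                k_d = 0.08, k_t = 0.0193,
                                t_lag_d = 0.35, t_lag_e = 2.58, ES_n = 2L),
    pd = list(
      group1 = pd_params(k_in = 0.68, k_out = 0.16, k_f_on = 0.29,
                         k_f_off = 0.059, E_max = 303.77, EC_50 = 3.48,
                         h = 2.00, R0 = 4.353),
      group3 = pd_params(k_in = 0.68, k_out = 0.16, k_f_on = 0.14,
                         k_f_off = 0.02, E_max = 183.50, EC_50 = 6.17,
                         h = 2.02, R0 = 4.353),
      group4 = pd_params(k_in = 0.68, k_out = 0.16, k_f_on = 0.40,
                         k_f_off = 0.04, E_max = 380.00, EC_50 = 1.80,
                         h = 2.00, R0 = 4.353),
      group6 = pd_params(k_in = 0.35, k_out = 0.06, k_f_on = 0.083,
                         k_f_off = 0.45, E_max = 634.50, EC_50 = 3.34,
                         h = 3.18, R0 = 4.094),
      baseline_wistar = list(k_in = 0.68, k_out = 0.16, R0 = 4.353),
      baseline_iarcop = list(k_in = 0.35, k_out = 0.06, R0 = 4.094)
    ),
    auc_ref = list(iv_0_inf = 105.50, sc_0_inf = 53.33),
    dose = dose_spec(nominal = 0.1, body_weight = 0.3, route = "SC-solution")
  )
}
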