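#' Leuprolide pharmacokinetic models
#'
#' One-compartment IV bolus and first-order SC absorption ("solution")
#' models, and the three-section sustained-release depot model: a
#' non-encapsulated section absorbed like the solution, a diffusive section
#' released at `k_d` after a lag, and an erosive section released through a
#' transit-compartment chain at `k_t` after a longer lag. Plasma input is
#' `k_a*NS + k_d*DS + k_t*ES_n`, elimination is `CL/V_d`, concentration is
#' `A_p/V_d`. Both an RK4 (ODE) path and the exact closed-form solutions are
#' provided; the closed forms double as the fitting engine and as the oracle
#' for the ODE path.
#'
#' @name pk_models
NULL

#' Simulate an IV bolus with the one-compartment model
#'
#' `C(t) = (amount/V_d) * exp(-k t)` with `k = CL/V_d`.
#'
#' @param params [solution_pk_params()].
#' @param dose [dose_spec()] with route `"IV"`.
#' @param times Output times (h), strictly increasing.
#' @return A leuprolide [conc_series()].
#' @export
simulate_iv <- function(params, dose, times) {
  stopifnot(inherits(params, "solution_pk_params"),
            inherits(dose, "dose_spec"))
  if (dose$route != "IV") stop("dose route must be IV", call. = FALSE)
  C0 <- dose$amount / params$V_d
  conc_series(times, C0 * exp(-params$k * times), "leuprolide")
}

#' Bateman closed form for first-order SC absorption
#'
#' `C(t) = amount*k_a / (V_d*(k_a - k)) * (exp(-k t) - exp(-k_a t))`. When
#' `k_a` and `k` coincide within 1e-9 the limit form
#' `amount*k*t*exp(-k t)/V_d` is used.
#'
#' @inheritParams simulate_iv
#' @param dose [dose_spec()] with route `"SC-solution"`.
#' @return A leuprolide [conc_series()].
#' @export
solution_closed_form <- function(params, dose, times) {
  stopifnot(inherits(params, "solution_pk_params"),
            inherits(dose, "dose_spec"))
  if (dose$route != "SC-solution") {
    stop("dose route must be SC-solution", call. = FALSE)
  }
  conc_series(times, .bateman(times, dose$amount, params$k_a, params$k,
                              params$V_d), "leuprolide")
}

.bateman <- function(t, amount, ka, k, Vd) {
  if (is.na(ka)) stop("k_a required for SC absorption", call. = FALSE)
  if (abs(ka - k) < 1e-9) {
    amount * k * t * exp(-k * t) / Vd
  } else {
    amount * ka / (Vd * (ka - k)) * (exp(-k * t) - exp(-ka * t))
  }
}

#' Simulate SC solution dosing by integrating the depot/plasma ODEs
#'
#' RK4 realisation of the two-state system (drug depot, plasma amount);
#' agrees with [solution_closed_form()] to solver tolerance.
#'
#' @inheritParams solution_closed_form
#' @param step RK4 step (h).
#' @param full Return the full state trajectory (amounts plus cumulative
#'   elimination) instead of the concentration series.
#' @return A leuprolide [conc_series()], or a matrix when `full = TRUE`.
#' @export
simulate_sc_solution <- function(params, dose, times, step = 0.01,
                                 full = FALSE) {
  stopifnot(inherits(params, "solution_pk_params"),
            inherits(dose, "dose_spec"))
  if (dose$route != "SC-solution") {
    stop("dose route must be SC-solution", call. = FALSE)
  }
  ka <- params$k_a; kel <- params$k
  sys <- ode_system(
    c("Drug", "A_p", "eliminated"),
    function(t, y) c(-ka * y[1L],
                     ka * y[1L] - kel * y[2L],
                     kel * y[2L]),
    events = list(dose_event(0, "Drug", dose$amount))
  )
  t0 <- if (times[1L] > 0) c(0, times) else times
  traj <- rk4_integrate(sys, c(0, 0, 0), t0, step)
  if (times[1L] > 0) traj <- traj[-1L, , drop = FALSE]
  if (full) {
    attr(traj, "times") <- times
    return(traj)
  }
  conc_series(times, traj[, "A_p"] / params$V_d, "leuprolide")
}

# Derivative factory for the depot system. States:
# NS, DS, ES1..ESn, A_p, eliminated. Lags gate the release rate terms.
.depot_rhs <- function(depot, pk) {
  ka <- pk$k_a; kel <- pk$k
  kd <- depot$k_d; kt <- depot$k_t
  tld <- depot$t_lag_d; tle <- depot$t_lag_e
  n <- depot$ES_n
  function(t, y) {
    gd <- as.numeric(t >= tld)
    ge <- as.numeric(t >= tle)
    NS <- y[1L]; DS <- y[2L]; ES <- y[3:(2L + n)]; Ap <- y[3L + n]
    dES <- numeric(n)
    dES[1L] <- -ge * kt * ES[1L]
    if (n > 1L) {
      dES[2:n] <- ge * kt * (ES[1:(n - 1L)] - ES[2:n])
    }
    c(-ka * NS,
      -gd * kd * DS,
      dES,
      ka * NS + gd * kd * DS + ge * kt * ES[n] - kel * Ap,
      kel * Ap)
  }
}

#' Simulate the sustained-release depot model (RK4)
#'
#' The dose is split at `t = 0` into the three sections (`N_R`, `D_R`,
#' `E_R` fractions into NS, DS and the first erosive transit compartment);
#' diffusive and erosive release are gated off until their lag times.
#'
#' @param depot [depot_params()].
#' @param pk [solution_pk_params()] for the solution-phase disposition
#'   (`k_a`, `CL`, `V_d`), held as estimated from the solution groups.
#' @param dose [dose_spec()] with route `"SC-depot"`.
#' @param times Output times (h).
#' @param step RK4 step (h).
#' @param full Return the full state trajectory instead of concentrations.
#' @return A leuprolide [conc_series()], or a matrix when `full = TRUE`.
#' @export
simulate_depot <- function(depot, pk, dose, times, step = 0.01,
                           full = FALSE) {
  stopifnot(inherits(depot, "depot_params"),
            inherits(pk, "solution_pk_params"), inherits(dose, "dose_spec"))
  if (dose$route != "SC-depot") stop("dose route must be SC-depot",
                                     call. = FALSE)
  n <- depot$ES_n
  states <- c("NS", "DS", paste0("ES", seq_len(n)), "A_p", "eliminated")
  events <- list(dose_event(0, "NS", depot$N_R * dose$amount),
                 dose_event(0, "DS", depot$D_R * dose$amount),
                 dose_event(0, "ES1", depot$E_R * dose$amount))
  # lag instants inserted as breakpoints so gating switches on-grid
  events <- c(events, list(dose_event(depot$t_lag_d, "NS", 0),
                           dose_event(depot$t_lag_e, "NS", 0)))
  sys <- ode_system(states, .depot_rhs(depot, pk), events)
  t0 <- if (times[1L] > 0) c(0, times) else times
  traj <- rk4_integrate(sys, numeric(length(states)), t0, step)
  if (times[1L] > 0) traj <- traj[-1L, , drop = FALSE]
  if (full) {
    attr(traj, "times") <- times
    return(traj)
  }
  conc_series(times, traj[, "A_p"] / pk$V_d, "leuprolide")
}

# Plasma amount contributed by an n-stage transit chain (rate kt, unit
# amount entering stage 1 at tau = 0) with first-order elimination kel:
# A(tau) = (kt/(kt-kel))^n * (exp(-kel tau) - exp(-kt tau) *
#          sum_{j=0}^{n-1} ((kt-kel) tau)^j / j!)
.transit_plasma <- function(tau, n, kt, kel) {
  out <- numeric(length(tau))
  pos <- tau > 0
  if (!any(pos)) return(out)
  tp <- tau[pos]
  d <- kt - kel
  if (abs(d) < 1e-10 * max(kt, kel)) {
    # near-degenerate: Erlang input with rate == elimination
    out[pos] <- exp(-kt * tp) * (kt * tp)^n / factorial(n)
    return(out)
  }
  s <- rep(0, length(tp))
  term <- rep(1, length(tp))
  for (j in seq_len(n) - 1L) {
    if (j > 0) term <- term * (d * tp) / j
    s <- s + term
  }
  out[pos] <- (kt / d)^n * (exp(-kel * tp) - exp(-kt * tp) * s)
  out
}

#' Exact depot concentration (closed form)
#'
#' Superposition of the three sections: Bateman term for the
#' non-encapsulated section, lag-shifted Bateman for the diffusive section,
#' and a lag-shifted Erlang (transit-chain) input convolved with
#' first-order elimination for the erosive section. Identical to
#' [simulate_depot()] up to solver tolerance; used inside the fitters.
#'
#' @inheritParams simulate_depot
#' @return A leuprolide [conc_series()].
#' @export
depot_closed_form <- function(depot, pk, dose, times) {
  stopifnot(inherits(depot, "depot_params"),
            inherits(pk, "solution_pk_params"), inherits(dose, "dose_spec"))
  amt <- dose$amount
  kel <- pk$k
  ANS <- .bateman(times, depot$N_R * amt, pk$k_a, kel, 1)       # amounts
  tau_d <- pmax(times - depot$t_lag_d, 0)
  ADS <- .bateman(tau_d, depot$D_R * amt, depot$k_d, kel, 1)
  tau_e <- pmax(times - depot$t_lag_e, 0)
  AES <- depot$E_R * amt *
    .transit_plasma(tau_e, depot$ES_n, depot$k_t, kel)
  conc_series(times, (ANS + ADS + AES) / pk$V_d, "leuprolide")
}

#' Cumulative fraction of the dose released from the depot
#'
#' Analytic release CDF: `N_R*(1 - exp(-k_a t))` plus
#' `D_R*(1 - exp(-k_d (t - t_lag_d)))` after the diffusive lag plus
#' `E_R * P(Gamma(ES_n, k_t) <= t - t_lag_e)` after the erosive lag
#' (release from the chain means exit from its last compartment). Monotone
#' non-decreasing from 0 with asymptote 1.
#'
#' @param depot [depot_params()].
#' @param pk [solution_pk_params()] supplying `k_a` for the
#'   non-encapsulated section.
#' @param times Times (h), `>= 0`.
#' @return Numeric vector of cumulative released fractions.
#' @export
depot_release_profile <- function(depot, pk, times) {
  stopifnot(inherits(depot, "depot_params"),
            inherits(pk, "solution_pk_params"))
  ns <- depot$N_R * (1 - exp(-pk$k_a * times))
  ds <- depot$D_R * (1 - exp(-depot$k_d * pmax(times - depot$t_lag_d, 0)))
  es <- depot$E_R * stats::pgamma(pmax(times - depot$t_lag_e, 0),
                                  shape = depot$ES_n, rate = depot$k_t)
  ns + ds + es
}
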