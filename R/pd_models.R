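#' Testosterone turnover models
#'
#' Baseline indirect-response model `dR/dt = k_in - k_out*R` and the
#' drug-effect tolerance model with a feedback compartment:
#' `dR/dt = (1 + C_E)*k_in*F - k_out*R`, `dF/dt = k_f_on/R - k_f_off*F`
#' (reciprocal feedback, the default) with the Hill drug effect
#' `C_E = E_max*C^h/(C^h + EC_50^h)` driven by total plasma drug
#' concentration. A literal product form `dF/dt = k_f_on*R - k_f_off*F` is
#' available for sensitivity checks; it yields positive feedback and cannot
#' reproduce suppression below baseline.
#'
#' @name pd_models
NULL

#' Hill drug effect
#'
#' `C_E = E_max * C^h / (C^h + EC_50^h)`, bounded in `[0, E_max)` for
#' finite `C >= 0`.
#'
#' @param C Drug concentration(s), ng/mL, `>= 0`.
#' @param params [pd_params()].
#' @return Dimensionless effect value(s).
#' @export
hill_effect <- function(C, params) {
  stopifnot(inherits(params, "pd_params"))
  if (any(C < 0)) stop("concentration must be non-negative", call. = FALSE)
  # compute on the log scale to dodge overflow of C^h for large C
  r <- (C / params$EC_50)^params$h
  out <- params$E_max * r / (1 + r)
  out[is.infinite(r)] <- params$E_max      # C >> EC_50 saturates
  out[C == 0] <- 0
  out
}

#' Baseline response (no drug): exponential approach to k_in/k_out
#'
#' `R(t) = k_in/k_out + (R0 - k_in/k_out) * exp(-k_out t)`.
#'
#' @param params [pd_params()] or a list with `k_in`, `k_out`, `R0`.
#' @param times Output times (h).
#' @param R0 Optional initial response; defaults to `params$R0`.
#' @return A testosterone [conc_series()].
#' @export
simulate_baseline <- function(params, times, R0 = NULL) {
  R0 <- if (is.null(R0)) params$R0 else R0
  rss <- params$k_in / params$k_out
  conc_series(times, rss + (R0 - rss) * exp(-params$k_out * times),
              "testosterone")
}

#' Stationary feedback initial condition
#'
#' `F0 = k_out * R0 / k_in`, the value closing `dR/dt = 0` at `t = 0` with
#' no drug on board. Note the feedback equation itself is only stationary at
#' `(R0, F0)` when `k_f_on = k_f_off * F0 * R0` (reciprocal form); reported
#' parameter sets need not satisfy this, in which case the drug-free
#' baseline drifts slowly (see the methods vignette).
#'
#' @param params [pd_params()].
#' @return `F0` (dimensionless).
#' @export
initial_feedback_state <- function(params) {
  stopifnot(inherits(params, "pd_params"))
  params$k_out * params$R0 / params$k_in
}

# Resolve the drug driver into a function C(t).
# Accepts NULL (no drug), a function, a conc_series (linear interpolation),
# or a pk scenario list(route=, pk=, depot=, dose=) evaluated in closed form.
.drug_fun <- function(drug) {
  if (is.null(drug)) return(function(t) rep(0, length(t)))
  if (is.function(drug)) return(drug)
  if (inherits(drug, "conc_series")) return(conc_interpolant(drug))
  if (is.list(drug) && !is.null(drug$dose)) {
    route <- drug$dose$route
    if (route == "IV") {
      pk <- drug$pk
      return(function(t) (drug$dose$amount / pk$V_d) * exp(-pk$k * pmax(t, 0)))
    }
    if (route == "SC-solution") {
      pk <- drug$pk
      return(function(t) .bateman(pmax(t, 0), drug$dose$amount, pk$k_a,
                                  pk$k, pk$V_d))
    }
    if (route == "SC-depot") {
      return(function(t) {
        tt <- pmax(t, 0)
        # depot_closed_form needs strictly increasing times; evaluate and map
        u <- sort(unique(tt))
        v <- depot_closed_form(drug$depot, drug$pk, drug$dose, u)$values
        v[match(tt, u)]
      })
    }
  }
  stop("unsupported drug driver", call. = FALSE)
}

#' Simulate the testosterone response under a drug concentration profile
#'
#' Joint RK4 integration of response `R` and feedback state `F` with
#' `R(0) = R0` and `F(0) = `[initial_feedback_state()]. The drug driver may
#' be `NULL` (no drug), a function of time, a leuprolide [conc_series()]
#' (interpolated linearly), or a PK scenario list
#' `list(pk = , dose = , depot = )` evaluated with the exact PK solution at
#' every solver stage.
#'
#' @param params [pd_params()].
#' @param drug Drug concentration driver (see Details).
#' @param times Output times (h).
#' @param step RK4 step (h) after `refine_until`; the first part of the
#'   window is integrated at `fine_step` to resolve the fast absorption
#'   transient.
#' @param feedback_form `"reciprocal"` (default) or `"product"`.
#' @param fine_step,refine_until Fine step (h) and the time (h) up to which
#'   it is used.
#' @param engine `"fast"` (specialised RK4 loop with the drug driver
#'   pre-evaluated at all solver stages; the default) or `"generic"` (the
#'   general [rk4_integrate()] path). Both are the classical RK4 scheme on
#'   the same grid and agree to round-off.
#' @return A testosterone [conc_series()] with attribute `"feedback"`
#'   holding F at the output times.
#' @export
simulate_pd <- function(params, drug, times, step = 0.1,
                        feedback_form = c("reciprocal", "product"),
                        fine_step = 0.01, refine_until = 24,
                        engine = c("fast", "generic")) {
  stopifnot(inherits(params, "pd_params"))
  feedback_form <- match.arg(feedback_form)
  engine <- match.arg(engine)
  cf <- .drug_fun(drug)
  t0 <- if (times[1L] > 0) c(0, times) else times
  grid <- .pd_grid(t0, step, fine_step, refine_until)
  CE_nodes <- hill_effect(cf(grid), params)
  mids <- (grid[-length(grid)] + grid[-1L]) / 2
  CE_mids <- hill_effect(cf(mids), params)
  if (engine == "fast") {
    traj <- .pd_rk4_fast(grid, CE_nodes, CE_mids, params,
                         recip = feedback_form == "reciprocal")
  } else {
    traj <- .pd_rk4_generic(grid, cf, params,
                            recip = feedback_form == "reciprocal")
  }
  idx <- match(t0, grid)
  R <- traj$R[idx]; Fb <- traj$F[idx]
  if (times[1L] > 0) { R <- R[-1L]; Fb <- Fb[-1L] }
  out <- conc_series(times, pmax(R, 0), "testosterone")
  attr(out, "feedback") <- Fb
  out
}

# Two-resolution solver grid: fine_step up to refine_until (fast absorption
# transient), step afterwards; all output times included exactly.
.pd_grid <- function(t0, step, fine_step, refine_until) {
  tend <- max(t0)
  if (tend > refine_until) {
    grid <- sort(unique(c(
      refine_grid(c(min(t0), refine_until), list(), fine_step),
      refine_grid(c(refine_until, tend), list(), step), t0)))
  } else {
    grid <- refine_grid(t0, list(), fine_step)
  }
  grid
}

# Specialised RK4 for the 2-state (R, F) system with the Hill effect
# pre-evaluated at all stage times. CE_nodes: effect at grid points;
# CE_mids: effect at interval midpoints (stages 2 and 3).
.pd_rk4_fast <- function(grid, CE_nodes, CE_mids, params, recip = TRUE) {
  kin <- params$k_in; kout <- params$k_out
  kfon <- params$k_f_on; kfoff <- params$k_f_off
  m <- length(grid)
  Rv <- numeric(m); Fv <- numeric(m)
  R <- params$R0
  Fb <- initial_feedback_state(params)
  Rv[1L] <- R; Fv[1L] <- Fb
  sgn <- if (recip) 1 else -1  # reciprocal: kfon / R; product: kfon * R
  for (i in seq_len(m - 1L)) {
    h <- grid[i + 1L] - grid[i]
    h2 <- h / 2
    cn <- CE_nodes[i]; cm <- CE_mids[i]; c1 <- CE_nodes[i + 1L]
    k1R <- (1 + cn) * kin * Fb - kout * R
    k1F <- (if (recip) kfon / R else kfon * R) - kfoff * Fb
    Ra <- R + h2 * k1R; Fa <- Fb + h2 * k1F
    k2R <- (1 + cm) * kin * Fa - kout * Ra
    k2F <- (if (recip) kfon / Ra else kfon * Ra) - kfoff * Fa
    Rb <- R + h2 * k2R; Fbb <- Fb + h2 * k2F
    k3R <- (1 + cm) * kin * Fbb - kout * Rb
    k3F <- (if (recip) kfon / Rb else kfon * Rb) - kfoff * Fbb
    Rc <- R + h * k3R; Fc <- Fb + h * k3F
    k4R <- (1 + c1) * kin * Fc - kout * Rc
    k4F <- (if (recip) kfon / Rc else kfon * Rc) - kfoff * Fc
    R <- R + h / 6 * (k1R + 2 * k2R + 2 * k3R + k4R)
    Fb <- Fb + h / 6 * (k1F + 2 * k2F + 2 * k3F + k4F)
    if (!is.finite(R) || R <= 0) {
      stop(sprintf(
        "response became non-positive or non-finite (%.3g) at t = %.3g h (pathological parameters?)",
        R, grid[i + 1L]), call. = FALSE)
    }
    Rv[i + 1L] <- R; Fv[i + 1L] <- Fb
  }
  list(R = Rv, F = Fv)
}

# Same scheme through the generic engine (cross-validation path).
.pd_rk4_generic <- function(grid, cf, params, recip = TRUE) {
  kin <- params$k_in; kout <- params$k_out
  kfon <- params$k_f_on; kfoff <- params$k_f_off
  rhs <- function(t, y) {
    R <- y[1L]; Fb <- y[2L]
    if (!is.finite(R) || R <= 0) {
      stop(sprintf(
        "response became non-positive or non-finite (%.3g) at t = %.3g h (pathological parameters?)",
        R, t), call. = FALSE)
    }
    CE <- hill_effect(cf(t), params)
    dF <- (if (recip) kfon / R else kfon * R) - kfoff * Fb
    c((1 + CE) * kin * Fb - kout * R, dF)
  }
  sys <- ode_system(c("R", "F"), rhs)
  traj <- rk4_integrate(sys, c(params$R0, initial_feedback_state(params)),
                        grid, step = Inf)
  list(R = traj[, "R"], F = traj[, "F"])
}
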