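#' Weighted least-squares estimation
#'
#' All models are fitted by minimising the weighted sum of squared
#' residuals, default weighting 1/pred^2 (proportional error). The search
#' is a multi-start Nelder-Mead simplex refined by Levenberg-Marquardt
#' (gradient) least squares; positivity is enforced by log transforms and
#' the depot release fractions are kept on the simplex by a two-parameter
#' stick-breaking (logit) reparameterisation. Model selection uses
#' `AIC = n*ln(SSR/n) + 2p`.
#'
#' @name estimation
NULL

.weight_fun <- function(weighting = c("prop2", "prop", "none")) {
  weighting <- match.arg(weighting)
  switch(weighting,
         prop2 = function(pred) 1 / pmax(pred, 1e-12)^2,
         prop = function(pred) 1 / pmax(pred, 1e-12),
         none = function(pred) rep(1, length(pred)))
}

# Multi-start weighted least squares on a transformed (unconstrained)
# parameter vector. resid_fn(p_trans) -> residual vector (sqrt(w)*(obs-pred)).
# Optional box bounds act on the transformed scale (soft penalty for the
# simplex phase, hard bounds for Levenberg-Marquardt). Returns the best
# start: parameters, objective, convergence info. The caller's RNG state is
# left untouched.
.ls_fit <- function(resid_fn, p0, starts = 5L, seed = 1L,
                    perturb_sd = 0.4, nm_maxit = 300L,
                    lower = NULL, upper = NULL) {
  k <- length(p0)
  if (is.null(lower)) lower <- rep(-Inf, k)
  if (is.null(upper)) upper <- rep(Inf, k)
  clamp <- function(p) pmin(pmax(p, lower), upper)
  n_res <- NULL  # residual length, fixed after the first successful eval
  safe_resid <- function(p) {
    r <- tryCatch(resid_fn(clamp(p)), error = function(e) NULL)
    if (is.null(r) || anyNA(r) || any(!is.finite(r))) return(NULL)
    if (is.null(n_res)) n_res <<- length(r)
    r
  }
  obj <- function(p) {
    r <- safe_resid(p)
    if (is.null(r)) return(1e12)
    sum(r * r) + 1e3 * sum((p - clamp(p))^2)
  }
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv),
            add = TRUE)
  }
  set.seed(seed)
  start_list <- list(p0)
  if (starts > 1L) {
    for (s in seq_len(starts - 1L)) {
      start_list[[s + 1L]] <- p0 + stats::rnorm(length(p0), 0, perturb_sd)
    }
  }
  best <- NULL
  n_iter <- 0L
  for (p_start in start_list) {
    nm <- tryCatch(
      stats::optim(p_start, obj, method = "Nelder-Mead",
                   control = list(maxit = nm_maxit, reltol = 1e-10)),
      error = function(e) NULL)
    p_nm <- clamp(if (is.null(nm)) p_start else nm$par)
    # individual starts may fail or stall; convergence is tracked per start
    lm <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(p_nm, fn = function(p) {
        r <- safe_resid(p)
        if (is.null(r)) rep(1e6, if (is.null(n_res)) 1L else n_res) else r
      }, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 400,
                                           ftol = 1e-14, ptol = 1e-12))),
      error = function(e) NULL)
    if (is.null(lm)) next
    o <- sum(lm$fvec^2)
    it <- (if (is.null(nm)) 0L else nm$counts[1L]) + lm$niter
    n_iter <- n_iter + it
    if (is.null(best) || o < best$objective) {
      best <- list(par = clamp(lm$par), objective = o,
                   converged = lm$info %in% 1:4, iterations = it)
    }
  }
  if (is.null(best)) stop("all optimisation starts failed", call. = FALSE)
  best$total_iterations <- n_iter
  best
}

# Finite-difference Jacobian of the residual vector at the optimum; used
# for asymptotic standard errors: cov = sigma^2 (J'J)^-1.
.resid_jacobian <- function(resid_fn, p, eps = 1e-6) {
  r0 <- resid_fn(p)
  J <- matrix(NA_real_, length(r0), length(p))
  for (j in seq_along(p)) {
    h <- eps * max(1, abs(p[j]))
    pj <- p; pj[j] <- pj[j] + h
    J[, j] <- (resid_fn(pj) - r0) / h
  }
  J
}

.trans_se <- function(resid_fn, p, objective, n_obs) {
  k <- length(p)
  if (n_obs <= k) return(rep(NA_real_, k))
  sigma2 <- objective / (n_obs - k)
  J <- tryCatch(.resid_jacobian(resid_fn, p), error = function(e) NULL)
  if (is.null(J) || anyNA(J)) return(rep(NA_real_, k))
  cv <- tryCatch(solve(crossprod(J)) * sigma2, error = function(e) NULL)
  if (is.null(cv)) return(rep(NA_real_, k))
  sqrt(pmax(diag(cv), 0))
}

.aic_ls <- function(ssr, n, p) n * log(max(ssr, 1e-300) / n) + 2 * p

.fit_data <- function(data, analyte, lloq) {
  s <- .as_series(data, analyte)
  keep <- s$values > lloq
  bql <- attr(data, "bql_flag")
  if (is.data.frame(data) && "bql_flag" %in% names(data)) {
    keep <- keep & !as.logical(data$bql_flag)
  }
  if (sum(keep) < 2L) stop("too few quantifiable observations", call. = FALSE)
  list(times = s$times[keep], obs = s$values[keep])
}

.mk_fit_result <- function(params, se, objective, n_obs, times, obs, pred,
                           wres, convergence, weighting, n_free,
                           extra = list()) {
  structure(c(list(
    params = params, se = se, objective = objective, n_obs = n_obs,
    n_free = n_free,
    predictions = conc_series(times, pmax(pred, 0),
                              if (!is.null(extra$analyte)) extra$analyte
                              else "leuprolide"),
    observations = obs, residuals = wres,
    convergence = convergence, weighting = weighting,
    AIC = .aic_ls(objective, n_obs, n_free)),
    extra[setdiff(names(extra), "analyte")]),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n  objective (wSSR):", format(x$objective, digits = 6),
      "\n  n_obs:", x$n_obs, "  AIC:", format(x$AIC, digits = 6),
      "\n  converged:", x$convergence$converged, "\n  parameters:\n")
  for (nm in names(x$params)) {
    cat(sprintf("    %-9s %.6g  (SE %.3g)\n", nm, x$params[[nm]],
                x$se[[nm]]))
  }
  invisible(x)
}

#' Fit the one-compartment solution model
#'
#' IV route: free `CL`, `V_d`. SC route: free `k_a`, `CL`, `V_d` (apparent
#' values). Predictions use the exact closed forms.
#'
#' @param data Observed leuprolide [conc_series()] or data.frame with
#'   `time_h`, `conc_ng_ml`.
#' @param route `"IV"` or `"SC-solution"`.
#' @param dose [dose_spec()].
#' @param init Optional named list of natural-scale starting values
#'   (`k_a`, `CL`, `V_d`); defaults derived from NCA.
#' @param weighting `"prop2"` (1/pred^2, default), `"prop"`, or `"none"`.
#' @param starts Multi-start count (first start is `init`, the rest are
#'   lognormal perturbations of it).
#' @param seed Seed for the start perturbations.
#' @param lloq Quantification floor (ng/mL); observations at or below it
#'   are excluded (M1).
#' @return A `fit_result`.
#' @export
fit_solution_pk <- function(data, route = c("SC-solution", "IV"), dose,
                            init = NULL, weighting = "prop2", starts = 5L,
                            seed = 1L, lloq = 1e-3) {
  route <- match.arg(route)
  d <- .fit_data(data, "leuprolide", lloq)
  wf <- .weight_fun(weighting)
  amt <- dose$amount

  if (is.null(init)) {
    s <- conc_series(d$times, d$obs, "leuprolide")
    k0 <- tryCatch(max(estimate_k(s), 1e-3), error = function(e) 0.5)
    auc <- auc_trapezoid(s)$AUC_0_t
    CL0 <- amt / max(auc, 1e-6)
    init <- list(k_a = 10 * k0, CL = CL0, V_d = CL0 / k0)
  }
  free <- if (route == "IV") c("CL", "V_d") else c("k_a", "CL", "V_d")
  p0 <- log(unlist(init)[free])

  predict_fn <- function(pn) {
    if (route == "IV") {
      (amt / pn[["V_d"]]) * exp(-(pn[["CL"]] / pn[["V_d"]]) * d$times)
    } else {
      .bateman(d$times, amt, pn[["k_a"]], pn[["CL"]] / pn[["V_d"]],
               pn[["V_d"]])
    }
  }
  resid_fn <- function(p) {
    pn <- exp(p); names(pn) <- free
    pred <- predict_fn(pn)
    sqrt(wf(pred)) * (d$obs - pred)
  }
  best <- .ls_fit(resid_fn, p0, starts = starts, seed = seed)
  pn <- exp(best$par); names(pn) <- free
  se_t <- .trans_se(resid_fn, best$par, best$objective, length(d$obs))
  se <- as.list(pn * se_t)  # delta method from the log scale
  pred <- predict_fn(pn)
  params <- as.list(pn)
  if (route == "IV") params$k_a <- NA_real_
  params$k <- params$CL / params$V_d
  .mk_fit_result(params, se, best$objective, length(d$obs), d$times, d$obs,
                 pred, sqrt(wf(pred)) * (d$obs - pred),
                 list(converged = best$converged,
                      iterations = best$total_iterations),
                 weighting, n_free = length(free))
}

#' Fit the sustained-release depot model with solution disposition fixed
#'
#' Free parameters: `N_R`, `D_R` (with `E_R = 1 - N_R - D_R` via the
#' stick-breaking simplex parameterisation), `k_d`, `k_t`, `t_lag_d`,
#' `t_lag_e`. `k_a`, `CL`, `V_d` are held at the solution-group estimates.
#'
#' @inheritParams fit_solution_pk
#' @param solution_params [solution_pk_params()] held fixed.
#' @param ES_n Transit-compartment count for this fit.
#' @param init Optional named list of natural-scale starting values
#'   (`N_R`, `D_R`, `k_d`, `k_t`, `t_lag_d`, `t_lag_e`).
#' @return A `fit_result`; `params` includes the derived `E_R`.
#' @export
fit_depot_pk <- function(data, dose, solution_params, ES_n = 2L,
                         init = NULL, weighting = "prop2", starts = 5L,
                         seed = 1L, lloq = 1e-3) {
  stopifnot(inherits(solution_params, "solution_pk_params"))
  d <- .fit_data(data, "leuprolide", lloq)
  wf <- .weight_fun(weighting)
  if (is.null(init)) {
    init <- list(N_R = 0.2, D_R = 0.3, k_d = 0.05, k_t = 0.01,
                 t_lag_d = 0.5, t_lag_e = 3)
  }
  # transformed vector: qlogis(N_R), qlogis(D_R/(1-N_R)), log rates/lags
  p0 <- c(stats::qlogis(init$N_R),
          stats::qlogis(init$D_R / (1 - init$N_R)),
          log(init$k_d), log(init$k_t), log(init$t_lag_d), log(init$t_lag_e))
  untrans <- function(p) {
    NR <- stats::plogis(p[1L])
    DR <- (1 - NR) * stats::plogis(p[2L])
    list(N_R = NR, D_R = DR, E_R = 1 - NR - DR,
         k_d = exp(p[3L]), k_t = exp(p[4L]),
         t_lag_d = exp(p[5L]), t_lag_e = exp(p[6L]))
  }
  predict_fn <- function(q) {
    dp <- depot_params(q$N_R, q$D_R, q$E_R, q$k_d, q$k_t, q$t_lag_d,
                       q$t_lag_e, ES_n)
    depot_closed_form(dp, solution_params, dose, d$times)$values
  }
  resid_fn <- function(p) {
    pred <- predict_fn(untrans(p))
    sqrt(wf(pred)) * (d$obs - pred)
  }
  best <- .ls_fit(resid_fn, p0, starts = starts, seed = seed)
  q <- untrans(best$par)
  se_t <- .trans_se(resid_fn, best$par, best$objective, length(d$obs))
  # delta method through the transforms
  grads <- c(q$N_R * (1 - stats::plogis(best$par[1L])),
             q$D_R * (1 - stats::plogis(best$par[2L])),
             q$k_d, q$k_t, q$t_lag_d, q$t_lag_e)
  se <- as.list(c(abs(grads) * se_t))
  names(se) <- c("N_R", "D_R", "k_d", "k_t", "t_lag_d", "t_lag_e")
  se <- c(se[1:2], list(E_R = NA_real_), se[3:6])
  pred <- predict_fn(q)
  .mk_fit_result(q[c("N_R", "D_R", "E_R", "k_d", "k_t", "t_lag_d",
                     "t_lag_e")],
                 se, best$objective, length(d$obs), d$times, d$obs, pred,
                 sqrt(wf(pred)) * (d$obs - pred),
                 list(converged = best$converged,
                      iterations = best$total_iterations),
                 weighting, n_free = 6L, extra = list(ES_n = ES_n))
}

#' Select the erosive transit-compartment count by AIC
#'
#' Fits [fit_depot_pk()] for each candidate count and returns the candidate
#' with minimal AIC (ties broken toward the smaller count). Non-convergent
#' candidates are excluded with a warning.
#'
#' @inheritParams fit_depot_pk
#' @param candidates Integer vector of transit counts to try.
#' @return List with `ES_n` (selected), `fits` (named list of
#'   `fit_result`s) and `aic` (named vector).
#' @export
select_transit_count <- function(data, dose, solution_params,
                                 candidates = 2:10, init = NULL,
                                 weighting = "prop2", starts = 3L,
                                 seed = 1L, lloq = 1e-3) {
  stopifnot(length(candidates) >= 1L)
  fits <- list(); aic <- numeric(0)
  for (n in sort(unique(as.integer(candidates)))) {
    f <- tryCatch(
      fit_depot_pk(data, dose, solution_params, ES_n = n, init = init,
                   weighting = weighting, starts = starts, seed = seed,
                   lloq = lloq),
      error = function(e) NULL)
    if (is.null(f) || !isTRUE(f$convergence$converged)) {
      warning("transit candidate ", n, " did not converge; excluded",
              call. = FALSE)
      next
    }
    fits[[as.character(n)]] <- f
    aic[as.character(n)] <- f$AIC
  }
  if (!length(fits)) stop("no transit candidate converged", call. = FALSE)
  # min AIC; names are sorted ascending so which.min's first match is the
  # smaller count on ties
  sel <- as.integer(names(aic)[which.min(aic)])
  list(ES_n = sel, fits = fits, aic = aic)
}

#' Fit the baseline turnover model to vehicle-group testosterone
#'
#' Fits `R(t) = k_in/k_out + (R0 - k_in/k_out) exp(-k_out t)` with `R0`
#' fixed (first observation by default). Flat profiles leave only the ratio
#' `k_in/k_out` identifiable; a warning is emitted and `k_out` is held at
#' its starting value.
#'
#' @param data Testosterone [conc_series()] or data.frame.
#' @param init Named list with starting `k_in`, `k_out`.
#' @param R0 Baseline used for initialisation (default: first observation).
#' @param weighting,starts,seed As in [fit_solution_pk()].
#' @return A `fit_result` with `params$k_in`, `params$k_out`, `params$R0`.
#' @export
fit_baseline_pd <- function(data, init = list(k_in = 0.5, k_out = 0.1),
                            R0 = NULL, weighting = "prop2", starts = 3L,
                            seed = 1L) {
  s <- .as_series(data, "testosterone")
  if (any(s$values < 0)) stop("negative concentrations in input",
                              call. = FALSE)
  if (length(s$times) < 2L) stop("need baseline data at >= 2 times",
                                 call. = FALSE)
  if (is.null(R0)) R0 <- s$values[1L]
  wf <- .weight_fun(weighting)
  flat <- stats::sd(s$values) / max(mean(s$values), 1e-12) < 1e-8
  if (flat) {
    warning(paste("flat baseline profile: only k_in/k_out is identifiable;",
                  "k_out held at its starting value"), call. = FALSE)
    k_out <- init$k_out
    k_in <- k_out * R0
    pred <- rep(R0, length(s$times))
    return(.mk_fit_result(
      list(k_in = k_in, k_out = k_out, R0 = R0),
      list(k_in = NA_real_, k_out = NA_real_, R0 = NA_real_),
      0, length(s$times), s$times, s$values, pred,
      rep(0, length(s$times)),
      list(converged = TRUE, iterations = 0L,
           note = "k_out unidentifiable (flat data)"),
      weighting, n_free = 0L, extra = list(analyte = "testosterone")))
  }
  predict_fn <- function(kin, kout) {
    rss <- kin / kout
    rss + (R0 - rss) * exp(-kout * s$times)
  }
  resid_fn <- function(p) {
    pred <- predict_fn(exp(p[1L]), exp(p[2L]))
    sqrt(wf(pred)) * (s$values - pred)
  }
  best <- .ls_fit(resid_fn, log(c(init$k_in, init$k_out)), starts = starts,
                  seed = seed)
  kin <- exp(best$par[1L]); kout <- exp(best$par[2L])
  se_t <- .trans_se(resid_fn, best$par, best$objective, length(s$times))
  pred <- predict_fn(kin, kout)
  .mk_fit_result(list(k_in = kin, k_out = kout, R0 = R0),
                 list(k_in = kin * se_t[1L], k_out = kout * se_t[2L],
                      R0 = NA_real_),
                 best$objective, length(s$times), s$times, s$values, pred,
                 sqrt(wf(pred)) * (s$values - pred),
                 list(converged = best$converged,
                      iterations = best$total_iterations),
                 weighting, n_free = 2L,
                 extra = list(analyte = "testosterone"))
}

#' Fit the feedback turnover drug-effect model
#'
#' `k_in`, `k_out` and `R0` are fixed from the baseline step; free
#' parameters are `E_max`, `EC_50`, `h`, `k_f_on`, `k_f_off` (all
#' log-transformed). The drug concentration driver is fixed during the fit,
#' so the Hill effect at every solver stage is recomputed cheaply from the
#' pre-evaluated drug profile.
#'
#' @param data Observed testosterone [conc_series()] or data.frame.
#' @param drug Drug driver as in [simulate_pd()] (PK scenario list,
#'   function, or [conc_series()]).
#' @param baseline_params List or `pd_params` with fixed `k_in`, `k_out`,
#'   `R0`.
#' @param init Named list of natural-scale starting values (`E_max`,
#'   `EC_50`, `h`, `k_f_on`, `k_f_off`).
#' @param bounds Named list `lower`/`upper` of natural-scale box bounds for
#'   the free parameters. The default keeps the Hill exponent in
#'   `[0.25, 16]`: beyond that the sigmoid is numerically a step function
#'   and the exponent is unidentifiable from sparse noisy sampling.
#' @param fix Named list of parameters (among `E_max`, `EC_50`, `h`,
#'   `k_f_on`, `k_f_off`) to hold at the given values instead of
#'   estimating them. `EC_50` and `h` trade off along a ridge on sparse
#'   noisy designs; fixing `h` restores sharp `EC_50` identifiability.
#' @param weighting,starts,seed As in [fit_solution_pk()].
#' @param feedback_form,step,fine_step,refine_until Passed to the
#'   simulator; see [simulate_pd()].
#' @return A `fit_result`.
#' @export
fit_pd <- function(data, drug, baseline_params,
                   init = list(E_max = 100, EC_50 = 5, h = 2,
                               k_f_on = 0.2, k_f_off = 0.05),
                   bounds = list(
                     lower = c(E_max = 1e-3, EC_50 = 1e-4, h = 0.25,
                               k_f_on = 1e-6, k_f_off = 1e-6),
                     upper = c(E_max = 1e6, EC_50 = 1e4, h = 16,
                               k_f_on = 100, k_f_off = 100)),
                   fix = list(),
                   weighting = "prop2", starts = 5L, seed = 1L,
                   feedback_form = c("reciprocal", "product"),
                   step = 0.1, fine_step = 0.01, refine_until = 24) {
  feedback_form <- match.arg(feedback_form)
  s <- .as_series(data, "testosterone")
  wf <- .weight_fun(weighting)
  kin <- baseline_params$k_in; kout <- baseline_params$k_out
  R0 <- baseline_params$R0
  stopifnot(is.finite(kin), is.finite(kout), is.finite(R0))

  cf <- .drug_fun(drug)
  t0 <- if (s$times[1L] > 0) c(0, s$times) else s$times
  grid <- .pd_grid(t0, step, fine_step, refine_until)
  C_nodes <- cf(grid)
  C_mids <- cf((grid[-length(grid)] + grid[-1L]) / 2)
  idx <- match(s$times, grid)
  all_pd <- c("E_max", "EC_50", "h", "k_f_on", "k_f_off")
  bad_fix <- setdiff(names(fix), all_pd)
  if (length(bad_fix)) {
    stop("unknown parameter(s) in fix: ", paste(bad_fix, collapse = ", "),
         call. = FALSE)
  }
  free <- setdiff(all_pd, names(fix))
  if (!length(free)) stop("no free parameters left to fit", call. = FALSE)
  p0 <- log(unlist(init)[free])

  predict_fn <- function(pn) {
    pn <- c(pn, unlist(fix))
    pdp <- pd_params(k_in = kin, k_out = kout, k_f_on = pn[["k_f_on"]],
                     k_f_off = pn[["k_f_off"]], E_max = pn[["E_max"]],
                     EC_50 = pn[["EC_50"]], h = pn[["h"]], R0 = R0)
    CEn <- hill_effect(C_nodes, pdp)
    CEm <- hill_effect(C_mids, pdp)
    traj <- .pd_rk4_fast(grid, CEn, CEm, pdp,
                         recip = feedback_form == "reciprocal")
    traj$R[idx]
  }
  resid_fn <- function(p) {
    pn <- exp(p); names(pn) <- free
    pred <- predict_fn(pn)
    sqrt(wf(pred)) * (s$values - pred)
  }
  best <- .ls_fit(resid_fn, p0, starts = starts, seed = seed,
                  nm_maxit = 250L,
                  lower = log(unlist(bounds$lower)[free]),
                  upper = log(unlist(bounds$upper)[free]))
  pn <- exp(best$par); names(pn) <- free
  se_t <- .trans_se(resid_fn, best$par, best$objective, length(s$times))
  se <- as.list(pn * se_t)
  pred <- predict_fn(pn)
  full <- c(as.list(pn), as.list(unlist(fix)))[all_pd]
  if (length(fix)) se[names(fix)] <- NA_real_
  params <- c(full, list(k_in = kin, k_out = kout, R0 = R0))
  .mk_fit_result(params, se, best$objective, length(s$times), s$times,
                 s$values, pred, sqrt(wf(pred)) * (s$values - pred),
                 list(converged = best$converged,
                      iterations = best$total_iterations),
                 weighting, n_free = length(free),
                 extra = list(analyte = "testosterone",
                              feedback_form = feedback_form))
}

#' Goodness-of-fit diagnostics
#'
#' Weighted residuals `r_i = (obs_i - pred_i) / (sigma * pred_i)` under
#' proportional weighting, with `sigma` estimated from the fit unless
#' supplied. Residuals with `|r| > 4` are flagged; points with zero
#' prediction are excluded with a warning.
#'
#' @param fit A `fit_result`.
#' @param sigma Proportional error SD; default
#'   `sqrt(objective/(n_obs - p))` when the fit used `prop2` weighting
#'   (its residuals are already relative), else estimated from relative
#'   residuals.
#' @return List with `obs_pred` (data.frame: time, observed, predicted)
#'   and `residuals` (data.frame: time, predicted, wres, flagged), plus
#'   `sigma` and `max_abs_wres`.
#' @export
fit_diagnostics <- function(fit, sigma = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  t <- fit$predictions$times
  pred <- fit$predictions$values
  obs <- fit$observations
  ok <- pred > 0
  if (any(!ok)) {
    warning(sum(!ok), " point(s) with zero prediction excluded from",
            " weighted residuals", call. = FALSE)
  }
  rel <- (obs[ok] - pred[ok]) / pred[ok]
  if (is.null(sigma)) {
    dof <- max(length(rel) - fit$n_free, 1L)
    sigma <- sqrt(sum(rel^2) / dof)
  }
  if (sigma <= 0 || !is.finite(sigma)) sigma <- 1
  wres <- rel / sigma
  list(obs_pred = data.frame(time_h = t, observed = obs, predicted = pred),
       residuals = data.frame(time_h = t[ok], predicted = pred[ok],
                              wres = wres, flagged = abs(wres) > 4),
       sigma = sigma, max_abs_wres = if (length(wres)) max(abs(wres)) else 0)
}
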