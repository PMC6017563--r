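#' Non-compartmental analysis and baseline-corrected AUEC
#'
#' Model-free PK summaries by the linear trapezoidal rule with terminal
#' log-linear extrapolation, the positive/negative decomposition of the
#' baseline-corrected area under the effect curve (AUEC), and the exact
#' small-sample Mann-Whitney U comparison used for group contrasts.
#'
#' @name nca
NULL

#' Linear trapezoidal AUC
#'
#' `AUC_0_t` over the observed window; with `extrapolate = TRUE` the tail
#' `C_last/k` is added to give `AUC_0_inf`.
#'
#' @param series A [conc_series()] (or data.frame with `time_h`,
#'   `conc_ng_ml`).
#' @param extrapolate Add the terminal extrapolation `C_last/k`.
#' @param k Terminal elimination constant (h^-1), required when
#'   `extrapolate = TRUE` (last value must be `> 0`).
#' @return List with `AUC_0_t` and (when extrapolating) `AUC_0_inf`
#'   (h*ng/mL).
#' @export
auc_trapezoid <- function(series, extrapolate = FALSE, k = NULL) {
  s <- .as_series(series)
  t <- s$times; v <- s$values
  if (length(t) < 2L) stop("need at least 2 points", call. = FALSE)
  auc <- sum(diff(t) * (v[-1L] + v[-length(v)]) / 2)
  out <- list(AUC_0_t = auc)
  if (extrapolate) {
    if (is.null(k) || !is.finite(k) || k <= 0) {
      stop("extrapolation requires k > 0", call. = FALSE)
    }
    if (v[length(v)] <= 0) {
      stop("extrapolation requires a positive last concentration",
           call. = FALSE)
    }
    out$AUC_0_inf <- auc + v[length(v)] / k
  }
  out
}

.as_series <- function(x, analyte = "leuprolide") {
  if (inherits(x, "conc_series")) return(x)
  if (is.data.frame(x)) {
    return(conc_series(x$time_h, x$conc_ng_ml, analyte))
  }
  stop("expected a conc_series or data.frame", call. = FALSE)
}

#' Terminal elimination rate constant
#'
#' Minus the least-squares slope of `ln(C)` against `t` over the last
#' `terminal_points` strictly positive observations.
#'
#' @param series A [conc_series()].
#' @param terminal_points Number of terminal positive points (default 3,
#'   reduced to what is available but at least 2).
#' @return `k` (h^-1).
#' @export
estimate_k <- function(series, terminal_points = 3L) {
  s <- .as_series(series)
  pos <- which(s$values > 0)
  if (length(pos) < 2L) {
    stop("need at least 2 strictly positive concentrations", call. = FALSE)
  }
  n <- min(max(terminal_points, 2L), length(pos))
  idx <- utils::tail(pos, n)
  t <- s$times[idx]; y <- log(s$values[idx])
  -unname(stats::coef(stats::lm(y ~ t))[2L])
}

#' Non-compartmental summary
#'
#' C_max and T_max by inspection; AUC by the linear trapezoidal rule with
#' terminal extrapolation `C_last/k`; `t_half = 0.693/k`;
#' `CL = dose/AUC_0_inf`; `V_d = CL/k`; and, when a reference IV
#' `AUC_0_inf` is supplied, `F = 100 * AUC_0_inf / reference_auc` (%).
#' For non-IV routes CL and V_d are apparent (CL/F, V/F).
#'
#' @param series A [conc_series()].
#' @param dose [dose_spec()] (its `amount` in ng).
#' @param reference_auc Optional IV `AUC_0_inf` (h*ng/mL) for
#'   bioavailability.
#' @param terminal_points Passed to [estimate_k()].
#' @param k Optional: supply the terminal constant instead of estimating it.
#' @return An `nca_result` list: `C_max`, `T_max`, `AUC_0_t`, `AUC_0_inf`,
#'   `k`, `t_half`, `CL`, `V_d`, and `F` (percent) if a reference was given.
#' @export
nca_summary <- function(series, dose, reference_auc = NULL,
                        terminal_points = 3L, k = NULL) {
  s <- .as_series(series)
  stopifnot(inherits(dose, "dose_spec"))
  if (is.null(k)) k <- estimate_k(s, terminal_points)
  imax <- which.max(s$values)
  aucs <- auc_trapezoid(s, extrapolate = TRUE, k = k)
  CL <- dose$amount / aucs$AUC_0_inf
  res <- list(C_max = s$values[imax], T_max = s$times[imax],
              AUC_0_t = aucs$AUC_0_t, AUC_0_inf = aucs$AUC_0_inf,
              k = k, t_half = 0.693 / k, CL = CL, V_d = CL / k)
  if (!is.null(reference_auc)) {
    stopifnot(is.finite(reference_auc), reference_auc > 0)
    res$F <- 100 * aucs$AUC_0_inf / reference_auc
  }
  structure(res, class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("<nca_result>\n")
  for (nm in names(x)) cat(sprintf("  %-9s %.4g\n", nm, x[[nm]]))
  invisible(x)
}

#' Baseline-corrected AUEC decomposed into positive and negative parts
#'
#' The effect curve minus the baseline is integrated by the linear
#' trapezoidal rule without extrapolation. Segments crossing the baseline
#' are split at the linear-interpolation crossing time; supra-baseline area
#' accrues to `positive_AUEC` (>= 0), sub-baseline area to `negative_AUEC`
#' (<= 0, sign preserved). By construction
#' `positive_AUEC + negative_AUEC = total_AUEC - baseline*(t_last - t_first)`.
#'
#' @param series A testosterone [conc_series()].
#' @param baseline Baseline level (ng/mL), `>= 0`.
#' @return An `auec_result` list: `baseline`, `total_AUEC`,
#'   `positive_AUEC`, `negative_AUEC` (h*ng/mL).
#' @export
auec_decompose <- function(series, baseline) {
  s <- .as_series(series, "testosterone")
  stopifnot(is.finite(baseline), baseline >= 0)
  t <- s$times; v <- s$values - baseline
  if (length(t) < 2L) stop("need at least 2 points", call. = FALSE)
  pos <- 0; neg <- 0
  for (i in seq_len(length(t) - 1L)) {
    t1 <- t[i]; t2 <- t[i + 1L]; y1 <- v[i]; y2 <- v[i + 1L]
    if (y1 * y2 < 0) {
      tc <- t1 + (t2 - t1) * y1 / (y1 - y2)  # linear crossing
      a1 <- (tc - t1) * y1 / 2
      a2 <- (t2 - tc) * y2 / 2
      if (y1 > 0) { pos <- pos + a1; neg <- neg + a2 }
      else        { neg <- neg + a1; pos <- pos + a2 }
    } else {
      a <- (t2 - t1) * (y1 + y2) / 2
      if (a >= 0) pos <- pos + a else neg <- neg + a
    }
  }
  total <- auc_trapezoid(s)$AUC_0_t
  structure(list(baseline = baseline, total_AUEC = total,
                 positive_AUEC = pos, negative_AUEC = neg),
            class = "auec_result")
}

#' Mann-Whitney U comparison of two groups
#'
#' Exact two-sided p from the permutation distribution for small samples
#' (combined n <= 20, no ties); normal approximation with tie correction
#' otherwise. If every value is tied across both groups, `U = n1*n2/2` and
#' `p = 1`.
#'
#' @param values_a,values_b Numeric vectors, each length `>= 1`.
#' @return List with `U` (statistic for group a) and `p` (two-sided).
#' @export
compare_groups <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 1L, length(values_b) >= 1L)
  n1 <- length(values_a); n2 <- length(values_b)
  if (length(unique(c(values_a, values_b))) == 1L) {
    return(list(U = n1 * n2 / 2, p = 1))
  }
  exact <- (n1 + n2) <= 20
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = min(1, wt$p.value))
}
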