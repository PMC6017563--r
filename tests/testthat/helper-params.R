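# Shared fixtures: published mean parameter sets, the study sampling grid,
# and a brute-force Mann-Whitney oracle.

sp <- study_params()
study_times <- c(0.25, 1, 2, 4, 8, 24 * c(1:7, 11, 14))
vehicle_times <- c(8, 24 * c(1, 7, 14))

dose_iv <- dose_spec(0.1, 0.3, "IV")
dose_sc <- dose_spec(0.1, 0.3, "SC-solution")
dose_dp <- dose_spec(0.1, 0.3, "SC-depot")

# PD parameter set that is jointly stationary at (R0, F0) with no drug:
# k_f_on = k_f_off * F0 * R0 closes dF/dt = 0 under the reciprocal form.
stationary_pd_params <- function(base = sp$pd$group1) {
  F0 <- initial_feedback_state(base)
  pd_params(base$k_in, base$k_out,
            k_f_on = base$k_f_off * F0 * base$R0,
            k_f_off = base$k_f_off, E_max = base$E_max,
            EC_50 = base$EC_50, h = base$h, R0 = base$R0)
}

# Exact Mann-Whitney two-sided p by enumeration of all group-a index
# choices; independent of stats::wilcox.test.
mw_enumerate <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    av <- pooled[idx]; bv <- pooled[-idx]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(n1 + n2, n1), 2L, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(U = u_obs, p = min(1, p))
}
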