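#' Dosing-driven ODE systems and the classical Runge-Kutta engine
#'
#' The models in this package are simulated with the fixed-step classical
#' fourth-order Runge-Kutta method, with instantaneous (bolus) dose events
#' deposited into named states. Lag-gated release is expressed inside the
#' derivative functions, so events here are only bolus additions.
#'
#' @name ode_engine
#' @keywords internal
NULL

# Default solver settings; step well below the shortest PK time constant
# (1/k_a ~ 0.06 h) and cheap enough for 14-day windows.
.default_step <- 0.01
.neg_clamp_tol <- 1e-9

#' Create a dose event
#'
#' A bolus addition of `amount` to state `target_state` at `time`. Events are
#' applied atomically at their event time, before the integration step that
#' leaves that time.
#'
#' @param time Event time (h), `>= 0`.
#' @param target_state Name of the state receiving the bolus.
#' @param amount Amount added (ng), `>= 0`.
#' @return A `dose_event` list.
#' @export
dose_event <- function(time, target_state, amount) {
  stopifnot(is.numeric(time), length(time) == 1L, is.finite(time), time >= 0,
            is.character(target_state), length(target_state) == 1L,
            is.numeric(amount), length(amount) == 1L, is.finite(amount),
            amount >= 0)
  structure(list(time = time, target_state = target_state, amount = amount),
            class = "dose_event")
}

#' Create an ODE system
#'
#' @param state_names Character vector of state labels.
#' @param rhs Function `(t, y)` returning the derivative vector (same length
#'   and order as `state_names`).
#' @param events List of [dose_event()] objects (may be empty).
#' @return An `ode_system` list.
#' @export
ode_system <- function(state_names, rhs, events = list()) {
  stopifnot(is.character(state_names), length(state_names) >= 1L,
            !anyDuplicated(state_names), is.function(rhs), is.list(events))
  for (ev in events) {
    if (!inherits(ev, "dose_event")) {
      stop("all events must be dose_event objects", call. = FALSE)
    }
    if (!ev$target_state %in% state_names) {
      stop("dose event targets unknown state '", ev$target_state, "'",
           call. = FALSE)
    }
  }
  structure(list(state_names = state_names, rhs = rhs, events = events),
            class = "ode_system")
}

#' Refine an output grid with event breakpoints and a maximum spacing
#'
#' Returns a strictly increasing grid containing every requested output time
#' and every event time, with consecutive spacing at most `step` (intervals
#' between breakpoints are subdivided uniformly).
#'
#' @param t_grid Strictly increasing output times (h).
#' @param events List of [dose_event()] objects whose times fall inside the
#'   integration window are inserted as breakpoints.
#' @param step Maximum spacing (h), `> 0`.
#' @return Numeric vector: the internal integration grid.
#' @export
refine_grid <- function(t_grid, events = list(), step = .default_step) {
  stopifnot(is.numeric(t_grid), length(t_grid) >= 1L, step > 0)
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("t_grid must be strictly increasing", call. = FALSE)
  }
  ev_times <- vapply(events, function(e) e$time, numeric(1))
  ev_times <- ev_times[ev_times >= t_grid[1L] & ev_times <= t_grid[length(t_grid)]]
  brk <- sort(unique(c(t_grid, ev_times)))
  if (length(brk) == 1L) return(brk)
  out <- lapply(seq_len(length(brk) - 1L), function(i) {
    a <- brk[i]; b <- brk[i + 1L]
    n <- max(1L, ceiling((b - a) / step - 1e-12))
    seq(a, b, length.out = n + 1L)[-(n + 1L)]
  })
  c(unlist(out), brk[length(brk)])
}

#' Integrate an ODE system with fixed-step classical Runge-Kutta (RK4)
#'
#' Bolus events are applied at their event time before the step that leaves
#' that time. States that go slightly negative from round-off (>= -1e-9
#' relative to the largest state magnitude) are clamped to zero; larger
#' negativity is left untouched (it signals genuine model dynamics, which the
#' callers validate themselves).
#'
#' @param system An [ode_system()].
#' @param y0 Named or unnamed initial state vector (order of
#'   `system$state_names`).
#' @param t_grid Strictly increasing output times (h). Integration starts at
#'   `t_grid[1]`.
#' @param step Maximum internal step (h).
#' @return Matrix with `length(t_grid)` rows and one column per state, column
#'   names from `state_names`; attribute `"times"` holds `t_grid`.
#' @export
rk4_integrate <- function(system, y0, t_grid, step = .default_step) {
  stopifnot(inherits(system, "ode_system"))
  ns <- length(system$state_names)
  if (length(y0) != ns) stop("y0 length must match state_names", call. = FALSE)
  y <- as.numeric(y0)
  grid <- refine_grid(t_grid, system$events, step)
  rhs <- system$rhs

  ev_times <- vapply(system$events, function(e) e$time, numeric(1))
  ev_idx <- vapply(system$events, function(e)
    match(e$target_state, system$state_names), integer(1))
  ev_amt <- vapply(system$events, function(e) e$amount, numeric(1))

  out <- matrix(NA_real_, nrow = length(t_grid), ncol = ns,
                dimnames = list(NULL, system$state_names))
  keep <- match(round(t_grid, 12), round(grid, 12))
  out_row <- 1L

  apply_events <- function(t, y) {
    hit <- which(abs(ev_times - t) < 1e-12)
    for (j in hit) y[ev_idx[j]] <- y[ev_idx[j]] + ev_amt[j]
    y
  }
  check_deriv <- function(d, t) {
    if (anyNA(d) || any(!is.finite(d))) {
      bad <- system$state_names[which(!is.finite(d))[1L]]
      stop(sprintf("non-finite derivative for state '%s' at t = %g h", bad, t),
           call. = FALSE)
    }
    d
  }

  # at each grid time: apply any bolus, record output, then step onward,
  # so samples at an event time see the post-bolus state (as at t = 0)
  for (i in seq_along(grid)) {
    t <- grid[i]
    y <- apply_events(t, y)
    if (out_row <= length(t_grid) && !is.na(keep[out_row]) &&
        keep[out_row] == i) {
      out[out_row, ] <- y
      out_row <- out_row + 1L
    }
    if (i == length(grid)) break
    h <- grid[i + 1L] - t
    k1 <- check_deriv(rhs(t, y), t)
    k2 <- check_deriv(rhs(t + h / 2, y + h / 2 * k1), t + h / 2)
    k3 <- check_deriv(rhs(t + h / 2, y + h / 2 * k2), t + h / 2)
    k4 <- check_deriv(rhs(t + h, y + h * k3), t + h)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    scale <- max(1, max(abs(y)))
    tiny <- y < 0 & y >= -.neg_clamp_tol * scale
    if (any(tiny)) y[tiny] <- 0
  }
  if (anyNA(out)) {
    stop("internal grid lost an output time (non-finite or duplicated t_grid?)",
         call. = FALSE)
  }
  attr(out, "times") <- t_grid
  out
}
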