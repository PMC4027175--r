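#' Pulse response of the non-dimensional model
#'
#' Integrates the non-dimensional model from its scaled steady state
#' `(x, y, z) = (1, 1, 1)` with the input stepping from 1 to `fold` at
#' `t = t_step`. Dense output (default grid 0.01 in dimensionless time) is
#' used so that pulse metrics can be extracted without interpolation error.
#'
#' @param p1,p2,p3 positive dimensionless parameters.
#' @param fold input fold change (`> 0`; values below 1 give an undershoot
#'   pulse).
#' @param t_step step time (dimensionless, default 1).
#' @param t_end end of integration; must exceed the adaptation time.
#' @param dt dense output grid spacing.
#' @return an `iffl_trace` with columns `t`, `x`, `y`, `z`, `u`.
#' @export
pulse_trace <- function(p1, p2, p3 = 1, fold = 2, t_step = 1, t_end = 200,
                        dt = 0.01) {
  stopifnot(p1 > 0, p2 > 0, p3 > 0, fold > 0, t_step >= 0)
  sch <- if (fold == 1) {
    input_schedule(time = 0, species = "A", amount = 1)
  } else if (fold > 1) {
    input_schedule(time = c(0, t_step), species = "A",
                   amount = c(1, fold - 1))
  } else {
    # fold < 1: the down-step is an inhibitor addition
    input_schedule(time = c(0, t_step), species = c("A", "I"),
                   amount = c(1, 1 - fold))
  }
  simulate_circuit("nondim", p = list(p1 = p1, p2 = p2, p3 = p3, u0 = 1),
                   schedule = sch, init = c(x = 1, y = 1, z = 1),
                   options = sim_options(t_end = t_end, dt = dt))
}

#' Pulse amplitude and adaptation time
#'
#' Amplitude `A = max(y) - 1` (dense maximum after the step) and adaptation
#' time `T`: the earliest time after which `y` stays within the band
#' `[1 - band, 1 + band]` (default `[0.99, 1.01]`). `T` is found by
#' scanning backward from the end of the trace for the last exit from the
#' band, which is robust to transient re-entries.
#'
#' @param trace an `iffl_trace` with a `y` column on a dense grid.
#' @param t_step time of the input step (metrics are evaluated for
#'   `t >= t_step`; a flat trace returns `A = 0`, `T = t_step`).
#' @param band half-width of the adaptation band around 1.
#' @return list of class `iffl_pulse_metrics` with `A` and `T`.
#' @export
pulse_metrics <- function(trace, t_step = 1, band = 0.01) {
  t <- trace$t; y <- trace$y
  sel <- t >= t_step
  A <- max(y[sel]) - 1
  outside <- which(sel & abs(y - 1) > band)
  if (length(outside) == 0L) {
    T1 <- t_step
  } else {
    last_out <- max(outside)
    if (last_out >= length(t))
      stop("pulse_metrics: T undefined before t_end (trace never settles)")
    T1 <- t[last_out + 1L]
  }
  structure(list(A = A, T = T1), class = "iffl_pulse_metrics")
}

#' Fold-change-detection pair metrics
#'
#' Compares the pulse of `P(p1, p2)` with the pulse of `P(p1, 2 p2)` --
#' the non-dimensional images of the same two-fold input step applied at a
#' baseline `u0` and at `2 u0`. Reports the amplitude ratio `R = A2 / A1`
#' and the normalized trace error
#' `E = integral_{t_step}^{T1} |y1 - y2| dt / (A1 T1)` (trapezoid on the
#' dense grid; the discrete-sum and time-average readings of the error
#' coincide under this normalization up to the grid spacing). `R` near 1
#' and `E` near 0 indicate fold-change detection.
#'
#' @inheritParams pulse_trace
#' @param band adaptation band for `T1`.
#' @return list of class `iffl_pulse_metrics` with `A1`, `A2`, `T1`, `R`,
#'   `E`.
#' @export
fcd_pair_metrics <- function(p1, p2, p3 = 1, fold = 2, t_step = 1,
                             t_end = 200, dt = 0.01, band = 0.01) {
  tr1 <- pulse_trace(p1, p2, p3, fold, t_step, t_end, dt)
  tr2 <- pulse_trace(p1, 2 * p2, p3, fold, t_step, t_end, dt)
  m1 <- pulse_metrics(tr1, t_step, band)
  m2 <- pulse_metrics(tr2, t_step, band)
  if (m1$A == 0) stop("fcd_pair_metrics: A1 = 0, metrics undefined")
  sel <- tr1$t >= t_step & tr1$t <= m1$T
  E <- trapz(tr1$t[sel], abs(tr1$y[sel] - tr2$y[sel])) / (m1$A * m1$T)
  structure(list(A1 = m1$A, A2 = m2$A, T1 = m1$T,
                 R = m2$A / m1$A, E = E),
            class = "iffl_pulse_metrics")
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Phase-space sweep of pulse metrics
#'
#' Evaluates amplitude `A`, adaptation time `T`, amplitude ratio `R` and
#' trace error `E` over a grid of `(p1, p2)` at fixed `p3`, mapping where
#' the circuit pulses, adapts quickly, and detects fold changes. Cells
#' where the integration or metric extraction fails are flagged `NA` and
#' recorded; they do not abort the sweep.
#'
#' @param p1_values,p2_values positive parameter grids (log-spacing
#'   recommended; defaults cover `p1` in `[1e-2, 1e1]`, `p2` in
#'   `[1e-1, 1e2]`).
#' @param p3 fixed third parameter (default 1, i.e. `beta1 = gamma1`).
#' @param fold input fold change.
#' @param t_end,dt integration horizon and dense grid.
#' @return list of class `iffl_sweep` with the grids, matrices `A`, `T`,
#'   `R`, `E` (rows index `p1`, columns `p2`), `p3`, and a data.frame
#'   `failures`.
#' @export
sweep_phase_space <- function(p1_values = 10^seq(-2, 1, length.out = 5),
                              p2_values = 10^seq(-1, 2, length.out = 5),
                              p3 = 1, fold = 2, t_end = 300, dt = 0.01) {
  stopifnot(all(p1_values > 0), all(p2_values > 0), p3 > 0)
  n1 <- length(p1_values); n2 <- length(p2_values)
  A <- T_ <- R <- E <- matrix(NA_real_, n1, n2)
  fails <- list()
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    res <- tryCatch(
      fcd_pair_metrics(p1_values[i], p2_values[j], p3, fold,
                       t_end = t_end, dt = dt),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(p1 = p1_values[i], p2 = p2_values[j],
                   message = conditionMessage(res))
    } else {
      A[i, j] <- res$A1; T_[i, j] <- res$T1
      R[i, j] <- res$R;  E[i, j] <- res$E
    }
  }
  structure(list(p1_grid = p1_values, p2_grid = p2_values, p3 = p3,
                 A = A, T = T_, R = R, E = E,
                 failures = if (length(fails)) do.call(rbind, fails)
                            else data.frame()),
            class = "iffl_sweep")
}

#' Fold-change-detection limit model
#'
#' In the limit of small `p1` and large `p2` the circuit reduces to
#' `dX/dt = F - X`, `y = F / X` with `F = u / u0` the input fold: the
#' output dynamics depend only on fold changes of the input, exactly.
#' Piecewise-constant schedules are integrated with the per-segment closed
#' form `X(t) = F + (X(t0) - F) exp(-(t - t0))`, so scale invariance holds
#' to machine precision. A step of fold `f` from steady state jumps `y`
#' to exactly `f` and relaxes back to 1.
#'
#' @param F_schedule data.frame with columns `time` (nondecreasing,
#'   starting at 0) and `F` (positive input fold per segment), or an
#'   [input_schedule()] interpreted through `u0`.
#' @param t_end,dt output horizon and grid (dimensionless time).
#' @param u0 baseline used to convert an `input_schedule` to folds
#'   (default: input level at time 0).
#' @param X0 initial `X`; defaults to the steady state `F(0)`.
#' @return an `iffl_trace` with columns `t`, `X`, `y`, `F`.
#' @export
fcd_limit_trace <- function(F_schedule, t_end = 20, dt = 0.01, u0 = NULL,
                            X0 = NULL) {
  if (inherits(F_schedule, "iffl_schedule")) {
    if (is.null(u0)) u0 <- input_u(F_schedule, 0)
    if (u0 <= 0) stop("fcd_limit_trace: baseline input must be > 0")
    tt <- c(0, schedule_event_times(F_schedule, Inf))
    F_schedule <- data.frame(time = tt, F = input_u(F_schedule, tt) / u0)
  }
  out <- fcd_limit_core(F_schedule, t_end, dt, X0)
  structure(out, class = c("iffl_trace", "data.frame"),
            model = "fcd_limit", units = "fold units; t dimensionless",
            schedule = F_schedule, options = sim_options(t_end = t_end,
                                                         dt = dt))
}

fcd_limit_core <- function(fsch, t_end, dt, X0 = NULL) {
  stopifnot(is.data.frame(fsch), all(c("time", "F") %in% names(fsch)))
  if (any(fsch$F <= 0)) stop("fcd_limit: input fold F must be > 0")
  if (is.unsorted(fsch$time)) stop("fcd_limit: times must be nondecreasing")
  grid <- seq(0, t_end, by = dt)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  times <- sort(unique(c(grid, fsch$time[fsch$time <= t_end])))
  Ffun <- stats::approxfun(fsch$time, fsch$F, method = "constant",
                           rule = 2, f = 0)
  X <- numeric(length(times))
  x_cur <- if (is.null(X0)) fsch$F[1] else X0
  t_cur <- times[1]
  X[1] <- x_cur
  seg_F <- Ffun(times[-length(times)] )  # F on [t_i, t_{i+1})
  for (i in seq_len(length(times) - 1L)) {
    Fi <- seg_F[i]
    x_cur <- Fi + (x_cur - Fi) * exp(-(times[i + 1L] - times[i]))
    X[i + 1L] <- x_cur
  }
  Ft <- Ffun(times)
  data.frame(t = times, X = X, y = Ft / X, F = Ft)
}
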