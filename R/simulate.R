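#' Solver and output options
#'
#' @param t_end end of integration (min, or dimensionless time for the
#'   non-dimensional and fold-change-limit models).
#' @param rtol,atol relative and absolute solver tolerances. The defaults
#'   (1e-8, 1e-10 nM) are tight because the system is stiff: hybridization
#'   (`k`, `k_plus`) is orders of magnitude faster than degradation.
#' @param dt output grid spacing.
#' @param max_step maximum internal step (`NULL` = solver default).
#' @param steady_band relative band used for settling detection.
#' @return list of class `iffl_sim_options`.
#' @export
sim_options <- function(t_end = 600, rtol = 1e-8, atol = 1e-10, dt = 0.1,
                        max_step = NULL, steady_band = 0.01) {
  stopifnot(t_end > 0, rtol > 0, atol > 0, dt > 0)
  structure(list(t_end = t_end, rtol = rtol, atol = atol, dt = dt,
                 max_step = max_step, steady_band = steady_band),
            class = "iffl_sim_options")
}

# piecewise integration: restart lsoda at every event time; state is
# continuous across events unless `impulse` modifies it
integrate_piecewise <- function(deriv, init, pars_for_segment, t_end, dt,
                                event_times, rtol, atol, max_step,
                                impulse = NULL) {
  grid <- seq(0, t_end, by = dt)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  breaks <- c(0, event_times, t_end)
  state <- init
  out <- NULL
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    if (!is.null(impulse)) state <- impulse(state, t0)
    times <- sort(unique(c(t0, grid[grid > t0 & grid < t1], t1)))
    pars <- pars_for_segment(t0)
    seg <- try(deSolve::lsoda(
      y = state, times = times, func = deriv, parms = pars,
      rtol = rtol, atol = atol,
      hmax = if (is.null(max_step)) Inf else max_step), silent = TRUE)
    if (inherits(seg, "try-error") ||
        abs(seg[nrow(seg), 1] - t1) > 1e-8)
      stop(sprintf(
        "integration failed in segment [%g, %g]; last good time %g",
        t0, t1, if (inherits(seg, "try-error")) t0 else seg[nrow(seg), 1]))
    state <- seg[nrow(seg), -1]
    out <- if (is.null(out)) seg else rbind(out, seg[-1, , drop = FALSE])
  }
  as.data.frame(out)
}

#' Simulate an IFFL circuit model
#'
#' Integrates one of the model variants under a piecewise-constant input
#' protocol. Integration is stopped and restarted at every addition time so
#' the input discontinuity never crosses a solver step; the RNA state is
#' continuous across events (an activator addition changes a parameter, not
#' the RNA pools). The returned trace is sampled on a uniform grid plus the
#' exact event times.
#'
#' @param model one of `"simple"`, `"mm"`, `"detailed"`, `"nondim"`,
#'   `"fcd_limit"`.
#' @param rates an [rate_params()] object (dimensional models).
#' @param config an [circuit_config()] object (dimensional models).
#' @param schedule an [input_schedule()]. For `"nondim"` and `"fcd_limit"`
#'   the event times are in dimensionless time and the amounts are divided
#'   by `u0` to give fold units.
#' @param p for `model = "nondim"`: a [nondim_params()] object or list with
#'   `p1`, `p2`, `p3` (and optionally `u0`, default 1).
#' @param u0 baseline input used to scale the schedule for `"fcd_limit"`
#'   (default: amount of the first event).
#' @param init initial state; defaults to zero concentrations (dimensional
#'   models) or the scaled steady state `(1, 1, 1)` (non-dimensional).
#' @param options an [sim_options()] object.
#' @return an `iffl_trace`: data.frame with column `t`, one column per
#'   species, and a `u` column with the driving input; metadata in
#'   attributes `model`, `units`, `schedule`, `options`.
#' @export
simulate_circuit <- function(model = c("simple", "mm", "detailed", "nondim",
                                       "fcd_limit"),
                             rates = NULL, config = NULL, schedule = NULL,
                             p = NULL, u0 = NULL, init = NULL,
                             options = sim_options()) {
  model <- match.arg(model)
  if (is.null(schedule)) schedule <- input_schedule()
  stopifnot(inherits(schedule, "iffl_schedule"),
            inherits(options, "iffl_sim_options"))
  t_end <- options$t_end
  ev <- schedule_event_times(schedule, t_end)

  if (model %in% c("simple", "mm")) {
    stopifnot(inherits(rates, "iffl_rates"), inherits(config, "iffl_config"))
    dr <- derived_rates(config, rates)
    if (is.null(init)) init <- c(x = 0, y = 0, z = 0)
    deriv <- if (model == "simple") deriv_simple else deriv_mm
    pars_fun <- function(t0) list(
      u = input_u(schedule, t0), dr = dr, k = rates$k,
      B = rates$B, tau_b = rates$tau_b, rates = rates)
    out <- integrate_piecewise(deriv, init, pars_fun, t_end, options$dt, ev,
                               options$rtol, options$atol, options$max_step)
    names(out) <- c("t", "x", "y", "z")
    out$u <- input_u(schedule, out$t)
    units <- "nM; t in min"
  } else if (model == "nondim") {
    stopifnot(!is.null(p))
    u0p <- if (!is.null(p$u0)) p$u0 else 1
    if (any(unlist(p[c("p1", "p2", "p3")]) <= 0))
      stop("simulate_circuit: p1, p2, p3 must be > 0")
    if (is.null(init)) init <- c(x = 1, y = 1, z = 1)
    pars_fun <- function(t0) list(u = input_u(schedule, t0) / u0p,
                                  p1 = p$p1, p2 = p$p2, p3 = p$p3)
    out <- integrate_piecewise(deriv_nondim, init, pars_fun, t_end,
                               options$dt, ev,
                               options$rtol, options$atol, options$max_step)
    names(out) <- c("t", "x", "y", "z")
    out$u <- input_u(schedule, out$t) / u0p
    units <- "dimensionless; t = beta1 * time"
  } else if (model == "detailed") {
    stopifnot(inherits(rates, "iffl_rates"), inherits(config, "iffl_config"))
    if (is.null(init))
      init <- c(TiA = 0, TrA = 0, x = 0, y = 0, z = 0, Afree = 0, Ifree = 0)
    # additions are impulses on the free strand pools
    impulse <- function(state, t0) {
      hit <- schedule$time == t0
      if (any(hit)) {
        state[["Afree"]] <- state[["Afree"]] +
          sum(schedule$amount[hit & schedule$species == "A"])
        state[["Ifree"]] <- state[["Ifree"]] +
          sum(schedule$amount[hit & schedule$species == "I"])
      }
      state
    }
    pars_fun <- function(t0) list(rates = rates, config = config)
    out <- integrate_piecewise(deriv_detailed, init, pars_fun, t_end,
                               options$dt, ev,
                               options$rtol, options$atol, options$max_step,
                               impulse = impulse)
    names(out) <- c("t", "TiA", "TrA", "x", "y", "z", "Afree", "Ifree")
    out$u <- input_u(schedule, out$t)
    units <- "nM; t in min"
  } else { # fcd_limit
    if (nrow(schedule) == 0L) stop("fcd_limit model needs a schedule")
    if (is.null(u0)) u0 <- input_u(schedule, 0)
    if (u0 <= 0) stop("fcd_limit: baseline input must be > 0")
    fsch <- data.frame(time = c(0, schedule_event_times(schedule, Inf)))
    fsch$F <- input_u(schedule, fsch$time) / u0
    out <- fcd_limit_core(fsch, t_end, options$dt)
    units <- "fold units; t dimensionless"
  }
  structure(out, class = c("iffl_trace", "data.frame"),
            model = model, units = units, schedule = schedule,
            options = options)
}

#' @export
print.iffl_trace <- function(x, ...) {
  cat("IFFL trace:", attr(x, "model"), "model,", nrow(x), "samples, t in [",
      min(x$t), ",", max(x$t), "] (", attr(x, "units"), ")\n")
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

# settling time into a +/- band around the final value; NA if never settles
settle_time <- function(t, v, band = 0.05) {
  final <- v[length(v)]
  scale <- max(abs(final), 1e-12)
  outside <- abs(v - final) > band * scale
  if (!any(outside)) return(t[1])
  last_out <- max(which(outside))
  if (last_out >= length(t)) return(NA_real_)
  t[last_out + 1L]
}
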