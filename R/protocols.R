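#' Fold-change-detection protocol
#'
#' Simulates a doubling (or arbitrary) input schedule, segments the trace
#' at each addition, and compares the pulses: amplitude (dense maximum
#' minus the output level at the addition time), ratio to the first
#' post-baseline pulse, and the count of pulses within a stated ratio
#' tolerance of the first. Segments that have not re-entered the settling
#' band before the next addition are flagged (`settled = FALSE`) but still
#' reported.
#'
#' For the non-dimensional model the default schedule doubles the input
#' `n_pulses` times from a settled baseline of 1, with inter-addition gaps
#' equal to `gap_factor` times the first pulse's adaptation time (the bench
#' protocol's "wait for the transient to settle"), all in dimensionless
#' time. Supplying `rates` and `config` instead runs the dimensional simple
#' model under the given `schedule` in minutes.
#'
#' @param p an [nondim_params()] (or list `p1`, `p2`, `p3`) for the
#'   non-dimensional model, or `NULL` to use `rates`/`config`.
#' @param rates,config dimensional inputs (used when `p` is `NULL`).
#' @param schedule an [input_schedule()]; `NULL` builds the default
#'   doubling schedule (non-dimensional mode only).
#' @param model `"nondim"`, `"simple"` or `"fcd_limit"`.
#' @param tolerance ratio tolerance defining "same amplitude"
#'   (default 0.3, i.e. within +/-30% of the first pulse).
#' @param n_pulses number of doublings for the default schedule.
#' @param gap_factor settling-gap multiplier for the default schedule.
#' @param band settling band for the per-segment settled flag.
#' @param options an [sim_options()]; `t_end` is extended to cover the
#'   schedule if needed.
#' @return data.frame of class `iffl_fcd_report` with one row per pulse:
#'   `t_add`, `u_before`, `u_after`, `baseline`, `amplitude`, `ratio`,
#'   `within_tol`, `settled`; attributes `n_within_tol`, `tolerance`,
#'   `trace`.
#' @export
run_fold_change <- function(p = NULL, rates = NULL, config = NULL,
                            schedule = NULL,
                            model = if (is.null(p)) "simple" else "nondim",
                            tolerance = 0.3, n_pulses = 4, gap_factor = 1.5,
                            band = 0.01, options = NULL) {
  if (model %in% c("nondim", "fcd_limit")) {
    if (model == "nondim") stopifnot(!is.null(p))
    if (is.null(schedule)) {
      # settling-based doubling schedule in dimensionless time
      T1 <- if (model == "nondim")
        pulse_metrics(pulse_trace(p$p1, p$p2, p$p3, fold = 2))$T
      else 8
      gap <- gap_factor * max(T1, 1)
      tt <- gap * seq_len(n_pulses)
      u0 <- if (model == "nondim" && !is.null(p$u0)) p$u0 else 1
      schedule <- input_schedule(
        time = c(0, tt), species = "A",
        amount = u0 * c(1, 2^seq_len(n_pulses) -
                          2^(seq_len(n_pulses) - 1L)))
    }
    t_end <- max(schedule$time) + 1.5 *
      max(diff(c(0, schedule$time[schedule$time > 0])), 1)
    if (is.null(options)) options <- sim_options(t_end = t_end, dt = 0.01)
    tr <- if (model == "nondim")
      simulate_circuit("nondim", p = p, schedule = schedule,
                       init = c(x = 1, y = 1, z = 1), options = options)
    else
      simulate_circuit("fcd_limit", schedule = schedule, options = options)
  } else {
    stopifnot(!is.null(rates), !is.null(config), !is.null(schedule))
    if (is.null(options))
      options <- sim_options(t_end = max(schedule$time) + 120, dt = 0.5)
    tr <- simulate_circuit("simple", rates = rates, config = config,
                           schedule = schedule, options = options)
  }
  if (!"u" %in% names(tr)) tr$u <- tr$F   # fcd_limit traces carry F
  t_add <- schedule$time[schedule$time > 0]
  if (length(t_add) == 0L)
    stop("run_fold_change: schedule has no post-baseline additions")
  seg_end <- c(t_add[-1L], max(tr$t))
  rows <- lapply(seq_along(t_add), function(k) {
    sel <- tr$t >= t_add[k] & tr$t <= seg_end[k]
    base <- tr$y[max(which(tr$t < t_add[k]))]  # level just before addition
    yfin <- tr$y[max(which(sel))]
    data.frame(t_add = t_add[k],
               u_before = utils::tail(tr$u[tr$t < t_add[k]], 1),
               u_after = tr$u[min(which(sel))],
               baseline = base,
               amplitude = max(tr$y[sel]) - base,
               settled = abs(yfin - base) <= band * max(abs(base), 1e-12))
  })
  tab <- do.call(rbind, rows)
  tab$ratio <- tab$amplitude / tab$amplitude[1]
  tab$within_tol <- abs(tab$ratio - 1) <= tolerance
  structure(tab, class = c("iffl_fcd_report", "data.frame"),
            n_within_tol = sum(tab$within_tol), tolerance = tolerance,
            trace = tr)
}

#' Multi-input perturbation protocol
#'
#' Simulates a schedule with several activator (and possibly inhibitor)
#' additions and reports, per perturbation, the response amplitude; for
#' negative inputs the undershoot depth and whether the output recovered
#' into the settling band of its pre-addition level.
#'
#' @param rates,config,schedule circuit inputs.
#' @param band recovery band (relative, default 5%).
#' @param init optional initial state, e.g. the closed-form equilibrium for
#'   protocols that start from a settled baseline.
#' @param options an [sim_options()].
#' @return data.frame of class `iffl_multiinput_report` with one row per
#'   post-baseline event: `t_add`, `species`, `u_after`, `amplitude`
#'   (positive events), `undershoot` (negative events), `recovered`;
#'   attribute `trace`.
#' @export
run_multi_input <- function(rates, config, schedule, band = 0.05,
                            init = NULL, options = NULL) {
  if (is.null(options))
    options <- sim_options(t_end = max(schedule$time) + 180, dt = 0.5)
  tr <- simulate_circuit("simple", rates = rates, config = config,
                         schedule = schedule, init = init,
                         options = options)
  ev <- schedule[schedule$time > 0, , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(structure(data.frame(), class = c("iffl_multiinput_report",
                                             "data.frame"), trace = tr))
  }
  seg_end <- c(ev$time[-1L], max(tr$t))
  rows <- lapply(seq_len(nrow(ev)), function(k) {
    sel <- tr$t >= ev$time[k] & tr$t <= seg_end[k]
    base <- tr$y[which.min(abs(tr$t - ev$time[k]))]
    yfin <- tr$y[max(which(sel))]
    pos <- ev$species[k] == "A"
    data.frame(t_add = ev$time[k], species = ev$species[k],
               u_after = input_u(schedule, ev$time[k]),
               amplitude = if (pos) max(tr$y[sel]) - base else NA_real_,
               undershoot = if (pos) NA_real_ else base - min(tr$y[sel]),
               recovered = abs(yfin - base) <= band * max(abs(base), 1e-12))
  })
  structure(do.call(rbind, rows),
            class = c("iffl_multiinput_report", "data.frame"), trace = tr)
}

#' Enzyme- and template-ratio condition sweeps
#'
#' Reproduces the pulse-response condition sweeps: vary RNAP, RNase R, or
#' the template ratio (total template held fixed), simulate a pulse, and
#' report per level the simulated and closed-form steady output, pulse
#' amplitude, peak time and settling time. Trend flags compare the
#' simulated steady state and response time against the simple-model
#' expectations (steady state flat in RNAP, increasing in RNase R and in
#' template ratio; response time decreasing in RNAP, increasing in RNase R
#' and in template ratio). The response-time trend is evaluated on the
#' pulse peak time: it tracks the enzyme mechanism monotonically, whereas
#' settling time into a relative band mixes in the amplitude-to-steady
#' ratio and is not monotone in RNase R (it is still reported).
#'
#' @param kind `"rnap"`, `"rnaser"` or `"ratio"`.
#' @param levels positive levels: enzyme concentrations (nM) or template
#'   ratios `TrMG_tot / TiMG_tot`.
#' @param rates an [rate_params()] object.
#' @param base_config an [circuit_config()]; for `kind = "ratio"` its
#'   total template concentration is preserved.
#' @param schedule input schedule (default: a single 20 nM activator
#'   addition at time 0).
#' @param options an [sim_options()].
#' @return data.frame of class `iffl_sweep_report` with one row per level
#'   plus attributes `trends` (named logical pass flags, `NA` for a single
#'   level) and `kind`.
#' @export
run_condition_sweep <- function(kind = c("rnap", "rnaser", "ratio"), levels,
                                rates, base_config,
                                schedule = input_schedule(0, "A", 20),
                                options = sim_options(t_end = 1500, dt = 0.5)) {
  kind <- match.arg(kind)
  stopifnot(all(levels > 0))
  tot <- base_config$TrMG_tot + base_config$TiMG_tot
  rows <- lapply(levels, function(lv) {
    cf <- base_config
    if (kind == "rnap") cf$rnap <- lv
    if (kind == "rnaser") cf$rnase_r <- lv
    if (kind == "ratio") {
      cf$TrMG_tot <- tot * lv / (1 + lv)
      cf$TiMG_tot <- tot / (1 + lv)
    }
    tr <- simulate_circuit("simple", rates = rates, config = cf,
                           schedule = schedule, options = options)
    n <- nrow(tr)
    data.frame(level = lv,
               steady_y = tr$y[n],
               steady_y_closed = steady_state_rmg(cf, rates),
               amplitude = max(tr$y) - tr$y[n],
               peak_time = tr$t[which.max(tr$y)],
               settle_time = settle_time(tr$t, tr$y))
  })
  tab <- do.call(rbind, rows[order(levels)])
  trends <- c(steady = NA, response_time = NA)
  if (length(levels) >= 2L) {
    mono <- function(v, dir) {
      d <- diff(v)
      if (dir == "up") all(d >= -1e-9 * max(abs(v)))
      else if (dir == "down") all(d <= 1e-9 * max(abs(v)))
      else all(abs(d) <= 1e-6 * max(abs(v)))
    }
    exp_steady <- switch(kind, rnap = "flat", rnaser = "up", ratio = "up")
    exp_rt <- switch(kind, rnap = "down", rnaser = "up", ratio = "up")
    trends["steady"] <- mono(tab$steady_y, exp_steady)
    trends["response_time"] <- mono(tab$peak_time, exp_rt)
  }
  structure(tab, class = c("iffl_sweep_report", "data.frame"),
            trends = trends, kind = kind,
            response_time_metric = paste(
              "time of the pulse peak (settling time into a +/-5% band",
              "is reported alongside but is not monotone in RNase R)"))
}
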