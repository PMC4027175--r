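#' Fit-result container
#'
#' @param estimates named numeric parameter estimates.
#' @param residual_ss sum of squared residuals.
#' @param converged logical convergence flag.
#' @param bounds list with `lower`, `upper` (or `NULL`).
#' @param stderr named standard errors where available.
#' @param info free-form diagnostics.
#' @return list of class `iffl_fit`.
#' @export
fit_result <- function(estimates, residual_ss, converged = TRUE,
                       bounds = NULL, stderr = NULL, info = NULL) {
  stopifnot(residual_ss >= -1e-12)
  structure(list(estimates = estimates, residual_ss = max(residual_ss, 0),
                 converged = converged, bounds = bounds, stderr = stderr,
                 info = info), class = "iffl_fit")
}

#' @export
print.iffl_fit <- function(x, ...) {
  cat("IFFL fit (", if (x$converged) "converged" else "NOT converged",
      "), residual SS = ", format(x$residual_ss, digits = 4), "\n", sep = "")
  print(x$estimates)
  invisible(x)
}

#' Background (dye-bleaching) correction
#'
#' Fits the pseudo-first-order bleaching background
#' `amp * exp(-rate * t)` and subtracts it from the signal. The fit runs on
#' a dye-blank series (column `blank`) when the trace carries one --
#' standard practice, and the well-conditioned option -- otherwise on the
#' signal itself restricted to `blank_window`, a pre-enzyme baseline
#' interval during which the signal is background only.
#'
#' @param raw trace with columns `t`, `signal`, optionally `blank`.
#' @param blank_window numeric `c(t0, t1)` delimiting the pre-enzyme
#'   baseline; required if there is no `blank` column.
#' @return list with `trace` (corrected signal) and `fit` (an
#'   [fit_result()] with `amp` and `rate`; a fitted `rate <= 0` sets a
#'   `warning` field and leaves the trace corrected by the fitted curve).
#' @export
correct_background <- function(raw, blank_window = NULL) {
  stopifnot(all(c("t", "signal") %in% names(raw)))
  if ("blank" %in% names(raw)) {
    tb <- raw$t; vb <- raw$blank
  } else {
    if (is.null(blank_window))
      stop("correct_background: need a blank series or a blank_window")
    sel <- raw$t >= blank_window[1] & raw$t <= blank_window[2]
    if (sum(sel) < 3L)
      stop("correct_background: blank window contains fewer than 3 samples")
    tb <- raw$t[sel]; vb <- raw$signal[sel]
  }
  amp0 <- max(vb[1], 1e-9)
  pos <- vb > amp0 * 1e-3
  rate0 <- if (sum(pos) >= 2L)
    max(-stats::coef(stats::lm(log(vb[pos]) ~ tb[pos]))[[2]], 1e-6) else 1e-4
  fit <- minpack.lm::nls.lm(
    par = c(amp = amp0, rate = rate0),
    fn = function(p) vb - p[["amp"]] * exp(-p[["rate"]] * tb),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  warn <- if (est[["rate"]] <= 0) "fitted background is non-decaying" else NULL
  corrected <- raw
  corrected$signal <- raw$signal - est[["amp"]] * exp(-est[["rate"]] * raw$t)
  fr <- fit_result(est, sum(fit$fvec^2),
                   converged = fit$info %in% 1:4,
                   info = fit$message)
  fr$warning <- warn
  list(trace = corrected, fit = fr)
}

#' Fluorescence-to-concentration calibration
#'
#' Linear scaling through the origin against standards of known aptamer
#' concentration: the slope is the least-squares solution of
#' `a.u. = slope * nM` and the signal is divided by it.
#'
#' @param trace trace with columns `t`, `signal` (a.u.), background
#'   corrected.
#' @param standards data.frame with columns `nM` and `au` (at least one
#'   positive standard).
#' @return the trace with `signal` converted to nM; the slope is attached
#'   as attribute `fluor_per_nM`.
#' @export
calibrate <- function(trace, standards) {
  stopifnot(is.data.frame(standards), all(c("nM", "au") %in% names(standards)),
            nrow(standards) >= 1L)
  slope <- sum(standards$au * standards$nM) / sum(standards$nM^2)
  if (!is.finite(slope) || slope <= 0)
    stop("calibrate: nonpositive calibration slope")
  out <- trace
  out$signal <- trace$signal / slope
  attr(out, "fluor_per_nM") <- slope
  attr(out, "units") <- "nM; t in min"
  out
}

#' Fit the rMG-iMG binding rate
#'
#' Nonlinear least squares of the equal-concentration second-order decay
#' `c(t) = 1 / (k t + 1 / c0)` with `k` free and the reciprocal intercept
#' fixed at `1 / c0` by the known initial concentration.
#'
#' @param trace calibrated trace (columns `t`, `signal` in nM).
#' @param c0 initial concentration of each strand (nM, `> 0`).
#' @param fit_intercept also free the intercept `b` of `1 / (k t + b)`
#'   (used to check the printed fit form rather than assume it).
#' @return an [fit_result()] with `k` (and `b` if freed).
#' @export
fit_binding <- function(trace, c0, fit_intercept = FALSE) {
  stopifnot(c0 > 0)
  t <- trace$t; v <- trace$signal
  if (stats::sd(diff(v)) > 0 && mean(diff(v) > 0) > 0.6)
    warning("fit_binding: trace is increasing beyond noise")
  k0 <- max((1 / max(v[length(v)], 1e-6) - 1 / c0) / max(t[length(t)], 1e-9),
            1e-8)
  if (fit_intercept) {
    fit <- minpack.lm::nls.lm(
      par = c(k = k0, b = 1 / c0),
      fn = function(p) v - 1 / (p[["k"]] * t + p[["b"]]),
      lower = c(0, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    fit <- minpack.lm::nls.lm(
      par = c(k = k0),
      fn = function(p) v - 1 / (p[["k"]] * t + 1 / c0),
      lower = 0,
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  fit_result(stats::coef(fit), sum(fit$fvec^2),
             converged = fit$info %in% 1:4, info = fit$message)
}

#' Joint fit of transcription traces
#'
#' Fits the production-only burst model
#' `y(t) = kp2 * fr * u * (t + B tau_b (1 - exp(-t / tau_b)))` jointly
#' across activator levels, with a single shared `kp2` (enforcing the
#' linearity of transcription rate in activator), shared `B` and `tau_b`.
#' `fr` is the rMG template fraction implied by `config` (1 when only the
#' rMG template is present).
#'
#' @param traces list of calibrated traces (columns `t`, `signal` in nM).
#' @param a_concs activator concentration per trace (nM).
#' @param config an [circuit_config()] describing the assay templates.
#' @param fit_burst fit `B` and `tau_b` (`FALSE` fixes `B = 0`).
#' @return an [fit_result()] with `kp2`, `B`, `tau_b`.
#' @export
fit_transcription <- function(traces, a_concs, config, fit_burst = TRUE) {
  stopifnot(length(traces) == length(a_concs), length(traces) >= 2L)
  if (any(vapply(traces, nrow, 1L) < 3L))
    stop("fit_transcription: traces need >= 3 time points")
  s_p <- if (config$rnap_ref > 0) config$rnap / config$rnap_ref else 1
  fr <- s_p * config$TrMG_tot / (config$TrMG_tot + config$TiMG_tot)
  model <- function(p, t, u) {
    base <- if (fit_burst)
      t + p[["B"]] * p[["tau_b"]] * (1 - exp(-t / p[["tau_b"]]))
    else t
    p[["kp2"]] * fr * u * base
  }
  resid <- function(p) unlist(lapply(seq_along(traces), function(i)
    traces[[i]]$signal - model(p, traces[[i]]$t, a_concs[i])))
  slope0 <- mean(vapply(seq_along(traces), function(i) {
    tr <- traces[[i]]; n <- nrow(tr)
    h <- tr$t >= stats::median(tr$t)
    stats::coef(stats::lm(tr$signal[h] ~ tr$t[h]))[[2]] /
      (fr * a_concs[i])
  }, 1))
  p0 <- if (fit_burst) c(kp2 = max(slope0, 1e-6), B = 1, tau_b = 20)
        else c(kp2 = max(slope0, 1e-6))
  lo <- if (fit_burst) c(0, 0, 1e-3) else 0
  fit <- minpack.lm::nls.lm(par = p0, fn = resid, lower = lo,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- stats::coef(fit)
  if (!fit_burst) est <- c(est, B = 0, tau_b = Inf)
  fit_result(est, sum(fit$fvec^2), converged = fit$info %in% 1:4,
             info = fit$message)
}

#' Fit degradation rates from the complex-degradation assay
#'
#' Least squares of the hybridization-plus-degradation mini-model (see
#' [gen_degradation_assay()]) against the free-rMG series, with `beta1` and
#' `gamma1` free and the binding rate `k` supplied (from the binding
#' assay).
#'
#' @param trace calibrated trace of free rMG (columns `t`, `signal` in nM).
#' @param rmg0,img0 initial concentrations (nM); `img0 > 0` is required for
#'   identifiability (without inhibitor nothing degrades).
#' @param k binding rate constant (1/(nM min)).
#' @param start optional named start values `c(beta1, gamma1)`.
#' @return an [fit_result()] with `beta1`, `gamma1` (at the assay's RNase R
#'   concentration).
#' @export
fit_degradation <- function(trace, rmg0, img0, k, start = NULL) {
  if (img0 <= 0)
    stop("fit_degradation: beta1, gamma1 not identifiable with img0 = 0")
  t <- trace$t; v <- trace$signal
  if (diff(range(v)) < 1e-6 * max(abs(v), 1))
    stop("fit_degradation: flat trace, rates not identifiable")
  fwd <- function(p) {
    sol <- deSolve::lsoda(c(r = rmg0, i = img0, cplx = 0), t,
                          deriv_degradation,
                          list(k = k, beta1 = p[["beta1"]],
                               gamma1 = p[["gamma1"]]),
                          rtol = 1e-8, atol = 1e-10)
    sol[, 2]
  }
  if (is.null(start)) start <- c(beta1 = 0.05, gamma1 = 0.05)
  fit <- minpack.lm::nls.lm(par = start, fn = function(p) v - fwd(p),
                            lower = c(0, 0),
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  fit_result(stats::coef(fit), sum(fit$fvec^2),
             converged = fit$info %in% 1:4, info = fit$message)
}

#' Global least-squares refinement of the circuit model
#'
#' Bounded Levenberg-Marquardt refinement of
#' `(kp1, kp2, B, tau_b, k, beta1, gamma1)` shared across a set of circuit
#' traces, with the simple model as forward operator. Transcription
#' parameters get a narrow default box (+/-30% around the initial
#' estimates, which elementary characterization pins down well); binding
#' and degradation rates get a wide box (a factor of 10 either way, the
#' parameters that circuit-level fitting is expected to move). Residuals
#' are weighted per trace by its maximum signal so that high-amplitude
#' conditions do not dominate. Five seeded jitters of the initial point are
#' refined and the best residual kept.
#'
#' @param traces list of calibrated traces (columns `t`, `signal` in nM).
#' @param conditions list (same length) of `list(config =, schedule =)` per
#'   trace.
#' @param init an [rate_params()] object with the starting estimates.
#' @param bounds optional list with named numeric `lower`, `upper` over the
#'   seven fitted parameters.
#' @param n_starts number of multi-start points (first = `init` itself).
#' @param seed RNG seed for the start-point jitter.
#' @param options an [sim_options()] for the forward simulations.
#' @return an [fit_result()] with the seven estimates, per-trace residual
#'   sums in `info$per_trace_ss`, and `info$at_bounds` naming estimates
#'   pinned at a bound.
#' @export
refine_global <- function(traces, conditions, init, bounds = NULL,
                          n_starts = 5, seed = 1,
                          options = sim_options(t_end = 360, dt = 1)) {
  stopifnot(length(traces) == length(conditions), length(traces) >= 1L,
            inherits(init, "iffl_rates"))
  pn <- c("kp1", "kp2", "B", "tau_b", "k", "beta1", "gamma1")
  p0 <- unlist(init[pn])
  if (is.null(bounds)) {
    narrow <- c("kp1", "kp2", "B", "tau_b")
    lower <- upper <- p0
    lower[narrow] <- p0[narrow] * 0.7
    upper[narrow] <- p0[narrow] * 1.3
    wide <- c("k", "beta1", "gamma1")
    lower[wide] <- p0[wide] / 10
    upper[wide] <- p0[wide] * 10
    bounds <- list(lower = lower, upper = upper)
  }
  w <- vapply(traces, function(tr) 1 / max(abs(tr$signal), 1e-9), 1)
  fwd_resid <- function(p) {
    r <- rate_params(kp1 = p[["kp1"]], kp2 = p[["kp2"]], B = p[["B"]],
                     tau_b = max(p[["tau_b"]], 1e-6), k_plus = init$k_plus,
                     k = p[["k"]], beta1 = p[["beta1"]],
                     gamma1 = p[["gamma1"]])
    unlist(lapply(seq_along(traces), function(i) {
      opt <- options
      opt$t_end <- max(traces[[i]]$t)
      sim <- simulate_circuit("simple", rates = r,
                              config = conditions[[i]]$config,
                              schedule = conditions[[i]]$schedule,
                              options = opt)
      yi <- stats::approx(sim$t, sim$y, xout = traces[[i]]$t)$y
      w[i] * (traces[[i]]$signal - yi)
    }))
  }
  starts <- with_local_seed(seed, {
    s <- list(pmin(pmax(p0, bounds$lower), bounds$upper))
    for (j in seq_len(max(n_starts - 1L, 0L))) {
      cand <- p0 * exp(stats::rnorm(length(p0), 0, 0.1))
      s[[j + 1L]] <- pmin(pmax(cand, bounds$lower), bounds$upper)
    }
    s
  })
  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = st, fn = fwd_resid,
      lower = bounds$lower, upper = bounds$upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
  }
  if (is.null(best)) stop("refine_global: all starts failed")
  est <- stats::coef(best)
  at_bounds <- pn[est <= bounds$lower * (1 + 1e-8) |
                    est >= bounds$upper * (1 - 1e-8)]
  res <- fwd_resid(est)
  lens <- vapply(traces, nrow, 1L)
  idx <- rep(seq_along(traces), lens)
  per_trace <- tapply((res / w[idx])^2, idx, sum)
  fit_result(est, sum(best$fvec^2),
             converged = best$info %in% 1:4, bounds = bounds,
             info = list(message = best$message,
                         at_bounds = at_bounds,
                         per_trace_ss = as.numeric(per_trace),
                         # rsstrace is only filled for performed iterations
                         deviance_path = c(
                           best$rsstrace[seq_len(min(best$niter,
                                                     length(best$rsstrace)))],
                           sum(best$fvec^2))))
}
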