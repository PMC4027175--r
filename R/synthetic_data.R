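#' Spectrofluorometer measurement model
#'
#' Forward model of the fluorescence readout: a linear calibration from rMG
#' concentration to fluorescence, an additive background from free MG dye
#' that bleaches with pseudo-first-order kinetics, additive Gaussian
#' instrument noise, and sampling once per minute. `bleach_amp` and
#' `noise_sd` given as `NA` are resolved when the model is applied, to 10%
#' and 2% of the maximum noiseless signal respectively (nominal fixture
#' values; the true bench bleaching rate is instrument- and batch-specific).
#'
#' @param fluor_per_nM calibration slope (a.u. per nM, `> 0`).
#' @param bleach_rate pseudo-first-order bleaching rate (1/min).
#' @param bleach_amp initial background amplitude (a.u.), `NA` = 10% of the
#'   maximum signal.
#' @param noise_sd additive Gaussian noise s.d. (a.u.), `NA` = 2% of the
#'   maximum signal.
#' @param sample_dt sampling interval (min).
#' @param seed integer seed making the generated noise reproducible;
#'   `NULL` uses the current RNG state.
#' @return list of class `iffl_measurement`.
#' @export
measurement_model <- function(fluor_per_nM = 1, bleach_rate = 0.004,
                              bleach_amp = NA, noise_sd = NA,
                              sample_dt = 1, seed = NULL) {
  stopifnot(fluor_per_nM > 0, bleach_rate >= 0, sample_dt > 0,
            is.na(noise_sd) || noise_sd >= 0)
  structure(list(fluor_per_nM = fluor_per_nM, bleach_rate = bleach_rate,
                 bleach_amp = bleach_amp, noise_sd = noise_sd,
                 sample_dt = sample_dt, seed = seed),
            class = "iffl_measurement")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

# concentration series -> raw fluorescence trace with blank control column
apply_measurement <- function(t, conc, mm) {
  signal0 <- mm$fluor_per_nM * conc
  amp <- if (is.na(mm$bleach_amp)) 0.1 * max(signal0, 1e-12)
         else mm$bleach_amp
  sd <- if (is.na(mm$noise_sd)) 0.02 * max(signal0, 1e-12) else mm$noise_sd
  bg <- amp * exp(-mm$bleach_rate * t)
  with_local_seed(mm$seed, {
    raw <- signal0 + bg + stats::rnorm(length(t), 0, sd)
    blank <- bg + stats::rnorm(length(t), 0, sd)
    data.frame(t = t, signal = raw, blank = blank)
  })
}

measurement_trace <- function(df, mm, truth, params) {
  structure(df, class = c("iffl_trace", "data.frame"),
            model = "measurement", units = "a.u.; t in min",
            measurement = mm, truth = truth, true_params = params)
}

#' Synthetic circuit fluorescence assay
#'
#' Simulates the full circuit (simple model) under a schedule, then pushes
#' the rMG concentration through the measurement model. The noiseless
#' concentration ground truth and the generating parameters travel with the
#' trace in attributes, so recovery tests can consume only the raw columns.
#'
#' @param rates,config,schedule circuit inputs as for [simulate_circuit()].
#' @param mm an [measurement_model()].
#' @param options an [sim_options()] (output grid is overridden by
#'   `mm$sample_dt`).
#' @return list with `raw` (trace with `t`, `signal`, `blank` in a.u.),
#'   `truth` (noiseless concentration trace), `params` (list of generating
#'   parameters).
#' @export
gen_circuit_assay <- function(rates, config, schedule, mm = measurement_model(),
                              options = sim_options(t_end = 360)) {
  options$dt <- mm$sample_dt
  tr <- simulate_circuit("simple", rates = rates, config = config,
                         schedule = schedule, options = options)
  df <- apply_measurement(tr$t, tr$y, mm)
  params <- list(rates = rates, config = config, schedule = schedule,
                 measurement = mm)
  list(raw = measurement_trace(df, mm, tr, params), truth = tr,
       params = params)
}

#' Synthetic rMG-iMG binding assay
#'
#' Equal concentrations of purified rMG and iMG are mixed and the
#' fluorescence decay followed: the noiseless core is the second-order
#' annihilation closed form `c(t) = 1 / (k t + 1 / c0)`, reported through
#' the measurement model.
#'
#' @param c0 initial concentration of each strand (nM, `> 0`).
#' @param k binding rate constant (1/(nM min)).
#' @param mm an [measurement_model()].
#' @param t_end assay duration (min).
#' @return list with `raw`, `truth` (data.frame `t`, `rmg`), `params`.
#' @export
gen_binding_assay <- function(c0 = 10, k = 0.005, mm = measurement_model(),
                              t_end = 240) {
  stopifnot(c0 > 0, k >= 0)
  t <- seq(0, t_end, by = mm$sample_dt)
  conc <- 1 / (k * t + 1 / c0)
  df <- apply_measurement(t, conc, mm)
  params <- list(c0 = c0, k = k, measurement = mm)
  list(raw = measurement_trace(df, mm, data.frame(t = t, rmg = conc), params),
       truth = data.frame(t = t, rmg = conc), params = params)
}

#' Synthetic transcription (production-only) assay
#'
#' One trace per activator level: rMG accumulates with no degradation,
#' `dy/dt = alpha2 u (1 + B exp(-t / tau_b))`, i.e. linear growth at rate
#' `alpha2 u` after the burst phase decays. Activator levels must not
#' exceed the total template so that production is linear in the input.
#'
#' @param a_concs activator concentrations (nM), each `<= TrMG_tot`.
#' @param rates,config circuit parameters; `alpha2` comes from
#'   [derived_rates()].
#' @param mm an [measurement_model()] (each trace gets an offset seed).
#' @param t_end assay duration (min).
#' @return list with `raw` (list of traces, one per level), `truth`,
#'   `params`.
#' @export
gen_transcription_assay <- function(a_concs, rates, config,
                                    mm = measurement_model(), t_end = 120) {
  stopifnot(all(a_concs > 0))
  if (any(a_concs > config$TrMG_tot + 1e-9))
    stop("gen_transcription_assay: activator must not exceed total template")
  dr <- derived_rates(config, rates)
  t <- seq(0, t_end, by = mm$sample_dt)
  core <- function(u) {
    if (rates$B == 0) dr$alpha2 * u * t
    else dr$alpha2 * u * (t + rates$B * rates$tau_b *
                            (1 - exp(-t / rates$tau_b)))
  }
  raws <- vector("list", length(a_concs))
  truths <- vector("list", length(a_concs))
  for (i in seq_along(a_concs)) {
    mi <- mm
    if (!is.null(mm$seed)) mi$seed <- mm$seed + i - 1L
    conc <- core(a_concs[i])
    truths[[i]] <- data.frame(t = t, rmg = conc)
    raws[[i]] <- measurement_trace(apply_measurement(t, conc, mi), mi,
                                   truths[[i]],
                                   list(u = a_concs[i], rates = rates))
  }
  names(raws) <- names(truths) <- paste0("A_", a_concs)
  list(raw = raws, truth = truths,
       params = list(a_concs = a_concs, rates = rates, config = config,
                     measurement = mm))
}

# mini-model of hybridization plus complex degradation with iMG recycling:
# r + i -> c (k); c -> i (gamma1, rMG degraded, iMG released); i -> 0 (beta1)
deriv_degradation <- function(t, s, pars) {
  bind <- pars$k * s[1] * s[2]
  list(c(-bind,
         -bind - pars$beta1 * s[2] + pars$gamma1 * s[3],
         bind - pars$gamma1 * s[3]))
}

#' Synthetic RNase-R degradation assay
#'
#' A substoichiometric amount of iMG is added to excess rMG together with
#' RNase R. Free rMG (the fluorescent species) is consumed by
#' hybridization; degradation of the rMG strand within the complex
#' (`gamma1`) releases the iMG strand to attack further rMG, so the total
#' rMG degraded can exceed the iMG dose (catalytic turnover), while free
#' iMG is itself degraded at `beta1`. Free rMG alone is not degraded
#' (`beta2 = 0`).
#'
#' @param rmg0,img0 initial rMG and iMG concentrations (nM).
#' @param rnase_r RNase R concentration (nM); scales `beta1`, `gamma1`
#'   linearly relative to `rates`' reference.
#' @param rates an [rate_params()] object (uses `k`, `beta1`, `gamma1`).
#' @param rnase_r_ref reference RNase R concentration (nM).
#' @param mm an [measurement_model()].
#' @param t_end assay duration (min).
#' @return list with `raw` (fluorescence of free rMG), `truth` (columns
#'   `t`, `rmg`, `img`, `complex`, `degraded` = total rMG degraded),
#'   `params`.
#' @export
gen_degradation_assay <- function(rmg0 = 1000, img0 = 100, rnase_r = 75,
                                  rates = default_rate_params(),
                                  rnase_r_ref = 75,
                                  mm = measurement_model(), t_end = 300) {
  stopifnot(rmg0 >= 0, img0 >= 0, rnase_r >= 0)
  s_r <- rnase_r / rnase_r_ref
  t <- seq(0, t_end, by = mm$sample_dt)
  pars <- list(k = rates$k, beta1 = rates$beta1 * s_r,
               gamma1 = rates$gamma1 * s_r)
  sol <- deSolve::lsoda(c(r = rmg0, i = img0, cplx = 0), t,
                        deriv_degradation, pars, rtol = 1e-8, atol = 1e-10)
  truth <- data.frame(t = sol[, 1], rmg = sol[, 2], img = sol[, 3],
                      complex = sol[, 4],
                      degraded = rmg0 - sol[, 2] - sol[, 4])
  df <- apply_measurement(truth$t, truth$rmg, mm)
  params <- list(rmg0 = rmg0, img0 = img0, rnase_r = rnase_r,
                 rnase_r_ref = rnase_r_ref, rates = rates, measurement = mm)
  list(raw = measurement_trace(df, mm, truth, params), truth = truth,
       params = params)
}
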