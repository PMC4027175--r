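#' Kinetic rate constants of the IFFL circuit
#'
#' Container for every rate constant and Michaelis constant of the
#' transcriptional adapter. The circuit couples transcription of the
#' malachite-green aptamer rMG (output, `y`) and its RNA inhibitor iMG
#' (repressor, `x`) to a common DNA activator input, with RNase R supplying
#' tunable degradation. By design two degradation pathways are negligible:
#' free rMG is protected from RNase R (`beta2 ~ 0`) and iMG within the
#' rMG-iMG duplex is protected (`gamma2 ~ 0`).
#'
#' @param kp1 transcription rate constant feeding iMG production (1/min).
#' @param kp2 transcription rate constant feeding rMG production (1/min).
#' @param B burst magnitude: relative increase of `kp2` during the initial
#'   burst phase of transcription (dimensionless, default 0 = no burst).
#' @param tau_b burst time constant (min). Must be positive when `B != 0`.
#' @param k_plus template-activator hybridization rate constant (1/(nM min)).
#' @param k rMG-iMG binding (toehold-mediated invasion) rate constant
#'   (1/(nM min)).
#' @param beta1 degradation rate constant of free iMG by RNase R (1/min).
#' @param beta2 degradation rate constant of free rMG (1/min, default 0).
#' @param gamma1 degradation rate constant of rMG within the rMG-iMG complex
#'   (1/min); releases iMG for further rounds of repression.
#' @param gamma2 degradation rate constant of iMG within the complex
#'   (1/min, default 0).
#' @param K_M RNA-polymerase Michaelis constant (nM). `Inf` (default)
#'   disables polymerase saturation.
#' @param K_M_R_x RNase-R Michaelis constant for free iMG (nM).
#' @param K_M_R_z RNase-R Michaelis constant for the rMG-iMG complex (nM).
#'
#' @return an object of class `iffl_rates` (a validated named list).
#' @seealso [circuit_config()], [derived_rates()], [burst_rate()]
#' @export
rate_params <- function(kp1, kp2, B = 0, tau_b = Inf,
                        k_plus = 1, k,
                        beta1, beta2 = 0, gamma1, gamma2 = 0,
                        K_M = Inf, K_M_R_x = Inf, K_M_R_z = Inf) {
  r <- list(kp1 = kp1, kp2 = kp2, B = B, tau_b = tau_b,
            k_plus = k_plus, k = k,
            beta1 = beta1, beta2 = beta2, gamma1 = gamma1, gamma2 = gamma2,
            K_M = K_M, K_M_R_x = K_M_R_x, K_M_R_z = K_M_R_z)
  bad <- vapply(r, function(v) !is.numeric(v) || length(v) != 1L ||
                  is.na(v) || v < 0, logical(1))
  if (any(bad))
    stop("rate_params: all fields must be single nonnegative numbers; bad: ",
         paste(names(r)[bad], collapse = ", "))
  if (r$B != 0 && !(r$tau_b > 0))
    stop("rate_params: tau_b must be > 0 when B != 0")
  if (any(c(r$K_M, r$K_M_R_x, r$K_M_R_z) <= 0))
    stop("rate_params: Michaelis constants must be > 0")
  structure(r, class = "iffl_rates")
}

#' Template and enzyme concentrations of a circuit preparation
#'
#' Concentrations that, together with [rate_params()], determine the
#' effective production and degradation coefficients of the circuit.
#' Transcription rate constants are assumed proportional to RNAP
#' concentration and degradation rate constants proportional to RNase R
#' concentration, relative to the reference concentrations at which the rate
#' constants were calibrated. (The proportionality is known to be
#' inaccurate at low RNAP concentrations; no correction is modeled.)
#'
#' @param TrMG_tot total rMG-template concentration (nM).
#' @param TiMG_tot total iMG-template concentration (nM).
#' @param rnap RNAP concentration (nM).
#' @param rnase_r RNase R concentration (nM).
#' @param rnap_ref,rnase_r_ref reference enzyme concentrations at which the
#'   rate constants were measured (nM). Defaults are the working
#'   concentrations used throughout the bench characterization
#'   (171 nM RNAP, 75 nM RNase R).
#'
#' @return an object of class `iffl_config`.
#' @export
circuit_config <- function(TrMG_tot, TiMG_tot, rnap = 171, rnase_r = 75,
                           rnap_ref = 171, rnase_r_ref = 75) {
  cf <- list(TrMG_tot = TrMG_tot, TiMG_tot = TiMG_tot,
             rnap = rnap, rnase_r = rnase_r,
             rnap_ref = rnap_ref, rnase_r_ref = rnase_r_ref)
  bad <- vapply(cf, function(v) !is.numeric(v) || length(v) != 1L ||
                  is.na(v) || v < 0, logical(1))
  if (any(bad))
    stop("circuit_config: all fields must be single nonnegative numbers; bad: ",
         paste(names(cf)[bad], collapse = ", "))
  if (cf$TrMG_tot + cf$TiMG_tot <= 0)
    stop("circuit_config: TrMG_tot + TiMG_tot must be > 0")
  structure(cf, class = "iffl_config")
}

#' Effective production and degradation coefficients
#'
#' Maps template and enzyme concentrations onto the coefficients of the
#' three-species model:
#' `alpha1 = kp1 * TiMG_tot / (TrMG_tot + TiMG_tot)` and
#' `alpha2 = kp2 * TrMG_tot / (TrMG_tot + TiMG_tot)`, with `kp1`, `kp2`
#' scaled linearly by `rnap / rnap_ref` and `beta1`, `gamma1` (and the
#' nominally zero `beta2`, `gamma2`) scaled by `rnase_r / rnase_r_ref`.
#'
#' @param config an [circuit_config()] object.
#' @param rates an [rate_params()] object.
#' @return list of class `iffl_derived` with fields `alpha1`, `alpha2`,
#'   `beta1_eff`, `beta2_eff`, `gamma1_eff`, `gamma2_eff` (all 1/min).
#' @export
derived_rates <- function(config, rates) {
  stopifnot(inherits(config, "iffl_config"), inherits(rates, "iffl_rates"))
  tot <- config$TrMG_tot + config$TiMG_tot
  if (tot <= 0) stop("derived_rates: zero total template concentration")
  if (config$rnap > 0 && config$rnap_ref <= 0)
    stop("derived_rates: rnap_ref must be > 0 when rnap > 0")
  if (config$rnase_r > 0 && config$rnase_r_ref <= 0)
    stop("derived_rates: rnase_r_ref must be > 0 when rnase_r > 0")
  s_p <- if (config$rnap_ref > 0) config$rnap / config$rnap_ref else 1
  s_r <- if (config$rnase_r_ref > 0) config$rnase_r / config$rnase_r_ref else 1
  structure(list(
    alpha1     = rates$kp1 * s_p * config$TiMG_tot / tot,
    alpha2     = rates$kp2 * s_p * config$TrMG_tot / tot,
    beta1_eff  = rates$beta1 * s_r,
    beta2_eff  = rates$beta2 * s_r,
    gamma1_eff = rates$gamma1 * s_r,
    gamma2_eff = rates$gamma2 * s_r
  ), class = "iffl_derived")
}

#' Burst-phase transcription rate
#'
#' Effective rMG transcription rate constant during the initial burst phase,
#' `kp2 * (1 + B * exp(-t / tau_b))`: the first rounds of transcription run
#' faster than steady-state turnover, decaying with time constant `tau_b`.
#' The burst clock runs from enzyme addition (`t = 0`), not from input
#' events.
#'
#' @param t time since enzyme addition (min); may be a vector.
#' @param rates an [rate_params()] object supplying `kp2`, `B`, `tau_b`.
#' @return effective `kp2` (1/min), same length as `t`.
#' @export
burst_rate <- function(t, rates) {
  stopifnot(inherits(rates, "iffl_rates"))
  rates$kp2 * burst_factor(t, rates$B, rates$tau_b)
}

# multiplicative burst factor 1 + B exp(-t/tau_b); B = 0 -> exactly 1
burst_factor <- function(t, B, tau_b) {
  if (B == 0) rep(1, length(t)) else 1 + B * exp(-t / tau_b)
}

#' Reference parameter sets
#'
#' Two self-consistent rate-constant sets used as package defaults, both
#' SYNTHETIC: plausible genelet-circuit kinetics constructed so that the
#' "optimized" set reproduces, at the fold-change experimental condition
#' (50 nM rMG template, 150 nM iMG template, 171 nM RNAP, 75 nM RNase R,
#' 10 nM baseline activator), the non-dimensional parameters
#' p1 = 0.19, p2 = 0.93, p3 = 0.61 of the characterized bench circuit.
#' The "default" set mimics elementary-reaction estimates before global
#' refinement: faster degradation (`beta1`, `gamma1`) and slightly faster
#' binding, the directions in which refinement against circuit-level traces
#' is known to adjust. Neither set is a measured quantity; both are
#' fixtures with realistic magnitudes.
#'
#' @return an [rate_params()] object.
#' @export
optimized_rate_params <- function() {
  rate_params(kp1 = 0.05, kp2 = 0.0285, B = 2, tau_b = 30,
              k_plus = 1, k = 0.005,
              beta1 = 0.0449, gamma1 = 0.0274)
}

#' @rdname optimized_rate_params
#' @export
default_rate_params <- function() {
  rate_params(kp1 = 0.06, kp2 = 0.03, B = 2.5, tau_b = 25,
              k_plus = 1, k = 0.007,
              beta1 = 0.12, gamma1 = 0.08)
}

#' @export
print.iffl_rates <- function(x, ...) {
  cat("IFFL rate parameters (1/min; k, k_plus in 1/(nM min); K's in nM):\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.iffl_config <- function(x, ...) {
  cat("IFFL circuit configuration (nM):\n")
  print(unlist(x))
  invisible(x)
}
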