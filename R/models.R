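#' Right-hand side of the three-species mass-action model
#'
#' The core IFFL model for `x = [iMG]`, `y = [rMG]`, `z = [rMG.iMG]` driven
#' by total activator `u`:
#' \deqn{\dot x = \alpha_1 u - \beta_1 x - k x y + \gamma_1 z}
#' \deqn{\dot y = \alpha_2 u - k x y}
#' \deqn{\dot z = k x y - \gamma_1 z}
#' Degradation of the rMG within the complex (rate `gamma1`) releases the
#' iMG strand, which recycles into `x`; free rMG is not degraded in this
#' model. Production coefficients come from [derived_rates()].
#'
#' @param state named numeric `c(x, y, z)` (nM).
#' @param u total activator concentration (nM).
#' @param dr an [derived_rates()] object (or list with `alpha1`, `alpha2`,
#'   `beta1_eff`, `gamma1_eff`).
#' @param k rMG-iMG binding rate constant (1/(nM min)).
#' @return named derivative vector `c(x, y, z)` (nM/min).
#' @export
rhs_simple <- function(state, u, dr, k) {
  x <- state[["x"]]; y <- state[["y"]]; z <- state[["z"]]
  kxy <- k * x * y
  c(x = dr$alpha1 * u - dr$beta1_eff * x - kxy + dr$gamma1_eff * z,
    y = dr$alpha2 * u - kxy,
    z = kxy - dr$gamma1_eff * z)
}

#' Right-hand side with Michaelis-Menten enzyme saturation
#'
#' Variant of [rhs_simple()] in which the first-order enzyme terms are
#' attenuated by saturation factors
#' `f(u) = 1 / (1 + u / K_M)` for RNAP and
#' `g(x, z) = 1 / (1 + x / K_M_R_x + z / K_M_R_z)` for RNase R:
#' \deqn{\dot x = \alpha_1 u f(u) - \beta_1 x g - k x y + \gamma_1 z g}
#' \deqn{\dot y = \alpha_2 u f(u) - k x y}
#' \deqn{\dot z = k x y - \gamma_1 z g}
#' With all Michaelis constants large the derivative reduces to the simple
#' model. Saturation of the degradation enzyme destroys exact adaptation.
#'
#' @inheritParams rhs_simple
#' @param rates an [rate_params()] object supplying the Michaelis constants.
#' @return named derivative vector `c(x, y, z)` (nM/min).
#' @export
rhs_mm <- function(state, u, dr, rates) {
  if (any(c(rates$K_M, rates$K_M_R_x, rates$K_M_R_z) <= 0))
    stop("rhs_mm: Michaelis constants must be > 0")
  x <- state[["x"]]; y <- state[["y"]]; z <- state[["z"]]
  f <- 1 / (1 + u / rates$K_M)
  g <- 1 / (1 + x / rates$K_M_R_x + z / rates$K_M_R_z)
  kxy <- rates$k * x * y
  c(x = dr$alpha1 * u * f - dr$beta1_eff * x * g - kxy + dr$gamma1_eff * z * g,
    y = dr$alpha2 * u * f - kxy,
    z = kxy - dr$gamma1_eff * z * g)
}

#' Right-hand side of the non-dimensional model
#'
#' The three-species model rescaled by its steady state (all variables equal
#' 1 at equilibrium) and by the iMG degradation timescale (`tau = beta1 t`):
#' \deqn{\dot x = u - x - p_1 (x y - z)}
#' \deqn{\dot y = p_2 (u - x y)}
#' \deqn{\dot z = p_3 (x y - z)}
#' with `p1 = alpha2 / alpha1`, `p2 = k alpha1 u0 / beta1^2`,
#' `p3 = gamma1 / beta1`, and `u` in units of the baseline input `u0`.
#'
#' @param state named numeric `c(x, y, z)` (dimensionless).
#' @param u input in fold units of the baseline.
#' @param p1,p2,p3 positive dimensionless parameters.
#' @return named derivative vector (per unit `tau`).
#' @export
rhs_nondim <- function(state, u, p1, p2, p3) {
  x <- state[["x"]]; y <- state[["y"]]; z <- state[["z"]]
  xy_z <- x * y - z
  c(x = u - x - p1 * xy_z,
    y = p2 * (u - x * y),
    z = p3 * xy_z)
}

#' Right-hand side of the detailed model with explicit template states
#'
#' Mass-action model in which the two switch templates are distinct
#' species: free activator A binds free templates TiMG and TrMG at rate
#' `k_plus` to form the transcribing complexes `TiA` and `TrA`; the
#' inhibitor strand I strips A from activated templates (and sequesters free
#' A) at the same hybridization rate. Transcription is proportional to the
#' activated-template concentrations, and the RNA species degrade as in the
#' simple model. The conservation relations
#' `[TiMG_free] = TiMG_tot - TiA` and `[TrMG_free] = TrMG_tot - TrA`
#' are built into the right-hand side. For fast `k_plus` and total templates
#' exceeding total activator, free A is driven to zero and the model
#' collapses onto [rhs_simple()].
#'
#' @param state named numeric
#'   `c(TiA, TrA, x, y, z, Afree, Ifree)` (nM).
#' @param t time since enzyme addition (min); drives the burst factor.
#' @param rates an [rate_params()] object.
#' @param config an [circuit_config()] object.
#' @return named derivative vector (nM/min).
#' @export
rhs_detailed <- function(state, t, rates, config) {
  dr <- derived_rates(config, rates)   # for enzyme scalings
  s_p <- if (config$rnap_ref > 0) config$rnap / config$rnap_ref else 1
  TiA <- state[["TiA"]]; TrA <- state[["TrA"]]
  x <- state[["x"]]; y <- state[["y"]]; z <- state[["z"]]
  A <- state[["Afree"]]; I <- state[["Ifree"]]
  if (TiA > config$TiMG_tot * (1 + 1e-6) + 1e-9 ||
      TrA > config$TrMG_tot * (1 + 1e-6) + 1e-9)
    stop("rhs_detailed: activated template exceeds total template")
  Ti_free <- config$TiMG_tot - TiA
  Tr_free <- config$TrMG_tot - TrA
  kp <- rates$k_plus
  kxy <- rates$k * x * y
  kp2_t <- rates$kp2 * s_p * burst_factor(t, rates$B, rates$tau_b)
  c(TiA   = kp * A * Ti_free - kp * I * TiA,
    TrA   = kp * A * Tr_free - kp * I * TrA,
    x     = rates$kp1 * s_p * TiA - dr$beta1_eff * x - kxy + dr$gamma1_eff * z,
    y     = kp2_t * TrA - dr$beta2_eff * y - kxy + dr$gamma2_eff * z,
    z     = kxy - dr$gamma1_eff * z - dr$gamma2_eff * z,
    Afree = -kp * A * (Ti_free + Tr_free) - kp * A * I,
    Ifree = -kp * I * (TiA + TrA + A))
}

# deSolve wrappers -----------------------------------------------------------

deriv_simple <- function(t, s, pars) {
  dr <- pars$dr
  bf <- burst_factor(t, pars$B, pars$tau_b)
  kxy <- pars$k * s[1] * s[2]
  list(c(dr$alpha1 * pars$u - dr$beta1_eff * s[1] - kxy + dr$gamma1_eff * s[3],
         dr$alpha2 * bf * pars$u - kxy,
         kxy - dr$gamma1_eff * s[3]))
}

deriv_mm <- function(t, s, pars) {
  dr <- pars$dr; r <- pars$rates; u <- pars$u
  bf <- burst_factor(t, r$B, r$tau_b)
  f <- 1 / (1 + u / r$K_M)
  g <- 1 / (1 + s[1] / r$K_M_R_x + s[3] / r$K_M_R_z)
  kxy <- r$k * s[1] * s[2]
  list(c(dr$alpha1 * u * f - dr$beta1_eff * s[1] * g - kxy +
           dr$gamma1_eff * s[3] * g,
         dr$alpha2 * bf * u * f - kxy,
         kxy - dr$gamma1_eff * s[3] * g))
}

deriv_nondim <- function(t, s, pars) {
  xy_z <- s[1] * s[2] - s[3]
  list(c(pars$u - s[1] - pars$p1 * xy_z,
         pars$p2 * (pars$u - s[1] * s[2]),
         pars$p3 * xy_z))
}

deriv_detailed <- function(t, s, pars) {
  names(s) <- c("TiA", "TrA", "x", "y", "z", "Afree", "Ifree")
  list(unname(rhs_detailed(s, t, pars$rates, pars$config)))
}
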