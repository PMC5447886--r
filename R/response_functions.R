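## Shared biochemical response functions: temperature scaling, nitrogen
## scaling, PSII electron transport and the stomatal VPD response.

#' Arrhenius temperature scaling normalised to 25 degC
#'
#' Scales a parameter value at 25 degC to leaf temperature `T_l` with an
#' exponential Arrhenius response, `p25 * exp[(1/298 - 1/(273 + T_l)) * E / R]`.
#' Applies to day respiration, `gamma*`, `Vcmax`, `KmC`, `KmO` and `u_oc`.
#'
#' @param p25 parameter value at 25 degC.
#' @param E activation energy (J mol-1); `E = 0` removes the temperature
#'   dependence.
#' @param T_l leaf temperature (degC), above absolute zero.
#' @return the parameter value at `T_l`, same units as `p25`.
#' @examples
#' arrhenius(1, 65330, 25) # exactly 1
#' arrhenius(80, 65330, 35)
#' @export
arrhenius <- function(p25, E, T_l) {
  p25 * exp((1 / 298 - 1 / (273 + T_l)) * E / .R_GAS)
}

#' Peaked (modified) Arrhenius temperature response
#'
#' Arrhenius scaling multiplied by a deactivation term so the response has an
#' interior optimum. Applies to `Jmax`, PEP carboxylation efficiency, and the
#' mesophyll and bundle-sheath conductances. Both correction factors equal 1
#' at 25 degC so `p25` is returned exactly there.
#'
#' @inheritParams arrhenius
#' @param D deactivation energy (J mol-1), positive.
#' @param S entropy term (J K-1 mol-1).
#' @return the parameter value at `T_l`.
#' @export
peaked_arrhenius <- function(p25, E, D, S, T_l) {
  stopifnot(all(D > 0))
  a <- (S - D / 298) / .R_GAS
  b <- (S - D / (273 + T_l)) / .R_GAS
  ## log1p(exp(x)) evaluated overflow-safely for large x
  l1e <- function(x) ifelse(x > 35, x, log1p(exp(x)))
  arrhenius(p25, E, T_l) * exp(l1e(a) - l1e(b))
}

#' Temperature factor for the quantum efficiency of PSII electron transport
#'
#' Gaussian-shaped factor `exp[-((T_l - T_opt)/Omega)^2]` multiplying the
#' limiting-light PSII quantum efficiency. `Omega` is the temperature
#' difference at which the factor has fallen to `exp(-1)`.
#'
#' @param T_opt optimum temperature (degC).
#' @param Omega width parameter (degC), positive.
#' @param T_l leaf temperature (degC).
#' @return dimensionless factor in (0, 1].
#' @export
phi2LL_t_factor <- function(T_opt, Omega, T_l) {
  stopifnot(all(Omega > 0))
  exp(-((T_l - T_opt) / Omega)^2)
}

#' Nitrogen scaling of photosynthetic capacity parameters at 25 degC
#'
#' Linear dependence of a capacity parameter on leaf nitrogen above the base
#' nitrogen `n_b` at and below which photosynthesis is zero:
#' `chi * max(n - n_b, 0)`. Applies to `Vcmax25`, `Jmax25`, the PEP
#' carboxylation efficiency, and the mesophyll and bundle-sheath conductance
#' at 25 degC.
#'
#' @param chi slope versus `n - n_b` (parameter units per g N m-2).
#' @param n leaf nitrogen content (g N m-2).
#' @param n_b base leaf nitrogen (g N m-2).
#' @return parameter value at 25 degC; zero when `n <= n_b`.
#' @export
n_scaled_param25 <- function(chi, n, n_b) {
  stopifnot(all(chi >= 0))
  chi * pmax(n - n_b, 0)
}

#' Total PSII electron transport rate
#'
#' Non-rectangular hyperbolic response of the PSII electron transport rate
#' `J2` to absorbed irradiance, with initial slope
#' `alpha2LL = Phi2LL_T * (1 - f_cyc) / (1 - f_cyc + r2_1)` so that a larger
#' cyclic electron fraction lowers the overall noncyclic transport
#' efficiency.
#'
#' @param I_abs absorbed irradiance (umol photons m-2 s-1).
#' @param Jmax maximum PSII electron transport rate (umol e- m-2 s-1) at the
#'   current leaf temperature.
#' @param Phi2LL_T limiting-light PSII quantum efficiency at the current leaf
#'   temperature (mol mol-1).
#' @param f_cyc fraction of PSI electron flux that is cyclic.
#' @param r2_1 ratio of PSII to PSI limiting-light quantum efficiencies.
#' @param theta convexity of the irradiance response in (0, 1]; `theta = 0`
#'   is accepted and evaluated as the rectangular-hyperbola limit.
#' @return `J2` (umol e- m-2 s-1), bounded by `alpha2LL * I_abs` and `Jmax`.
#' @export
j2_rate <- function(I_abs, Jmax, Phi2LL_T, f_cyc, r2_1, theta) {
  stopifnot(all(theta >= 0), all(theta <= 1), all(Jmax >= 0))
  a2 <- Phi2LL_T * (1 - f_cyc) / (1 - f_cyc + r2_1)
  ai <- a2 * I_abs
  if (all(theta < 1e-12)) {
    return(ifelse(ai + Jmax > 0, ai * Jmax / (ai + Jmax), 0))
  }
  disc <- pmax((ai + Jmax)^2 - 4 * theta * Jmax * ai, 0)
  (ai + Jmax - sqrt(disc)) / (2 * theta)
}

#' Stomatal sensitivity factor to vapour pressure deficit
#'
#' Phenomenological multiplier `1 / (1/max(a1 - b1 * VPD, 0.01) - 1)` in the
#' stomatal conductance submodel. `a1` is the Ci:Ca ratio in vapour-saturated
#' air and `b1` the slope of its decrease with VPD; the floor at 0.01 keeps
#' the factor defined at extreme VPD.
#'
#' @param VPD leaf-to-air vapour pressure deficit (kPa), non-negative.
#' @param a1 dimensionless intercept (default 0.9).
#' @param b1 slope (kPa-1, default 0.15).
#' @return dimensionless multiplier.
#' @export
fvpd <- function(VPD, a1 = 0.9, b1 = 0.15) {
  stopifnot(all(VPD >= 0))
  r <- pmax(a1 - b1 * VPD, 0.01)
  1 / (1 / r - 1)
}
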