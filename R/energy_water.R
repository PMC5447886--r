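## Leaf energy balance: Penman-Monteith transpiration, leaf temperature
## iteration, and the water-limitation stomatal adjustment.

.CP_MOL <- 29.3      # molar heat capacity of air, J mol-1 K-1
.LAMBDA_MOL <- 44100 # molar latent heat of vaporisation, J mol-1
.SIGMA_SB <- 5.67e-8 # Stefan-Boltzmann, W m-2 K-4
.EMISSIVITY <- 0.96
.MOL_TO_MM_S <- 18 / 1000 # mol H2O m-2 s-1 -> mm s-1

#' Saturation vapour pressure and its slope
#'
#' Tetens form, `0.6108 exp(17.27 T / (T + 237.3))` kPa.
#'
#' @param T_C air temperature (degC).
#' @return kPa (or kPa per degC for the slope).
#' @export
sat_vp <- function(T_C) 0.6108 * exp(17.27 * T_C / (T_C + 237.3))

#' @rdname sat_vp
#' @export
sat_vp_slope <- function(T_C) 4098 * sat_vp(T_C) / (T_C + 237.3)^2

#' Micrometeorological state for the leaf energy balance
#'
#' Derives the resistances and psychrometric quantities needed by the
#' Penman-Monteith equation. Resistances are on a molar basis
#' (1 / (mol m-2 s-1)); the heat resistance includes the radiative
#' conductance of an isothermal-radiation formulation with leaf emissivity
#' 0.96. Boundary-layer conductance follows the flat-plate relation
#' `g_bh = 0.135 sqrt(wind / leaf_width)` mol m-2 s-1 per unit leaf area,
#' scaled by `lai` for big leaves.
#'
#' @param T_air air temperature (degC).
#' @param vp actual vapour pressure (kPa).
#' @param wind wind speed (m s-1), floored at 0.1.
#' @param net_radiation absorbed net (isothermal) radiation (W m-2); may be
#'   `NA` when the caller supplies it later.
#' @param lai leaf area represented by the exchanging surface (default 1).
#' @param pressure air pressure (kPa).
#' @param leaf_width characteristic leaf dimension (m).
#' @return a `micromet` list: `T_air`, `vp`, `VPD_air`, `s_slope`,
#'   `gamma_psy`, `r_bh`, `r_bw`, `net_radiation`.
#' @export
micromet <- function(T_air, vp, wind, net_radiation = NA, lai = 1,
                     pressure = 101.3, leaf_width = 0.01) {
  wind <- pmax(wind, 0.1)
  g_bh <- 0.135 * sqrt(wind / leaf_width) * lai
  g_r <- 4 * .EMISSIVITY * .SIGMA_SB * (T_air + 273.15)^3 / .CP_MOL * lai
  g_bw <- 1.08 * g_bh
  es <- sat_vp(T_air)
  out <- list(T_air = T_air, vp = vp, VPD_air = pmax(es - vp, 0),
              s_slope = sat_vp_slope(T_air),
              gamma_psy = .CP_MOL * pressure / .LAMBDA_MOL,
              r_bh = 1 / (g_bh + g_r), r_bw = 1 / g_bw,
              net_radiation = net_radiation, lai = lai)
  structure(out, class = "micromet")
}

#' Penman-Monteith transpiration and leaf temperature
#'
#' Latent heat flux from available energy, air VPD and the stomatal plus
#' boundary-layer resistances to water vapour, with the stomatal resistance
#' taken as `r_sw = 1 / (1.6 g_s)` (the 1.6 ratio of water-vapour to CO2
#' stomatal conductance). Leaf temperature follows from the linearised
#' energy budget. Negative available energy (nocturnal) is allowed and `E`
#' may then be negative.
#'
#' @param g_s stomatal conductance to CO2 (mol m-2 s-1), positive; for big
#'   leaves, the aggregated class conductance.
#' @param mm a [micromet()] object with `net_radiation` set (W m-2).
#' @return list: `E_mm_h` (mm H2O h-1), `E_mol` (mol m-2 s-1), `lambdaE`
#'   (W m-2), `H` (W m-2), `T_l` (degC), `r_sw` (molar resistance).
#' @export
penman_monteith <- function(g_s, mm) {
  stopifnot(inherits(mm, "micromet"), all(g_s > 0),
            all(is.finite(mm$net_radiation)))
  r_sw <- 1 / (1.6 * g_s)
  g_w <- 1 / (r_sw + mm$r_bw)
  eps <- (mm$s_slope / mm$gamma_psy) * g_w * mm$r_bh
  lambdaE <- (eps * mm$net_radiation +
                (.CP_MOL * g_w / mm$gamma_psy) * mm$VPD_air) / (1 + eps)
  T_l <- mm$T_air + (mm$net_radiation - lambdaE) * mm$r_bh / .CP_MOL
  E_mol <- lambdaE / .LAMBDA_MOL
  list(E_mm_h = E_mol * .MOL_TO_MM_S * 3600, E_mol = E_mol,
       lambdaE = lambdaE, H = mm$net_radiation - lambdaE, T_l = T_l,
       r_sw = r_sw)
}

#' Actual stomatal resistance under water limitation
#'
#' Inverts the Penman-Monteith equation to find the stomatal resistance to
#' water vapour that realises the actual (water-limited) transpiration
#' `E_a` given the potential transpiration `E_p` and the potential
#' resistance `r_sw_p`:
#' `r_sw_a = (E_p - E_a)(s r_bh + gamma r_bw) / (gamma E_a) + r_sw_p E_p / E_a`.
#'
#' @param E_p potential transpiration (any unit shared with `E_a`),
#'   positive.
#' @param E_a actual transpiration, `0 < E_a <= E_p`.
#' @param r_sw_p potential stomatal resistance to water vapour.
#' @param mm a [micromet()] object (for `s_slope`, `gamma_psy`, `r_bh`,
#'   `r_bw`).
#' @return actual stomatal resistance `r_sw_a`, same units as `r_sw_p`.
#' @export
actual_stomatal_resistance <- function(E_p, E_a, r_sw_p, mm) {
  stopifnot(inherits(mm, "micromet"))
  if (any(E_a <= 0)) stop("E_a must be positive (floor tiny transpiration)")
  if (any(E_a > E_p * (1 + 1e-9))) stop("E_a must not exceed E_p")
  (E_p - E_a) * (mm$s_slope * mm$r_bh + mm$gamma_psy * mm$r_bw) /
    (mm$gamma_psy * E_a) + r_sw_p * E_p / E_a
}

#' Couple leaf photosynthesis to the energy balance
#'
#' Fixed-point iteration of leaf temperature: the leaf model is solved at
#' the current `T_l` (with leaf-to-air VPD recomputed from `T_l`), the
#' resulting stomatal conductance drives the Penman-Monteith equation, and
#' the new leaf temperature is fed back until the change is below `tol`
#' (default 0.01 degC). `T_l` starts at air temperature; after `max_plain`
#' undamped iterations a damping factor of 0.5 is applied, and failure to
#' converge within 200 iterations is an error.
#'
#' When `mm$net_radiation` is `NA` it is set to 1.3 times the absorbed PAR
#' energy flux (leaves absorb near-infrared far less efficiently than PAR,
#' adding roughly 30% to the shortwave load; longwave exchange enters
#' through the radiative conductance).
#'
#' @param env a [leaf_env()] object (its `T_l` and `VPD` fields are
#'   overwritten by the iteration).
#' @param params a `photo_params` object.
#' @param mm a [micromet()] object.
#' @param tol convergence tolerance on `T_l` (degC).
#' @param max_plain iterations before damping starts.
#' @param T_start optional starting leaf temperature (degC); defaults to
#'   air temperature.
#' @return list: `flux` (leaf_flux at convergence), `E_mm_h`, `E_mol`,
#'   `T_l`, `iterations`, and the potential stomatal resistance `r_sw`.
#' @export
iterate_leaf <- function(env, params, mm, tol = 0.01, max_plain = 50,
                         T_start = NULL) {
  out <- iterate_leaf_raw(env, params, mm, tol, max_plain, T_start)
  out$flux <- leaf_flux_frame(out$flux, env)
  out
}

## internal fast path returning the raw solver list
iterate_leaf_raw <- function(env, params, mm, tol = 0.01, max_plain = 50,
                             T_start = NULL) {
  stopifnot(inherits(env, "leaf_env"), inherits(mm, "micromet"))
  if (any(!is.finite(mm$net_radiation))) {
    mm$net_radiation <- 1.3 * env$I_inc * env$absorptance / 4.6
  }
  T_l <- rep_len(if (is.null(T_start)) mm$T_air else T_start,
                 length(env$I_inc))
  for (it in seq_len(200)) {
    env$T_l <- T_l
    env$VPD <- pmax(sat_vp(T_l) - mm$vp, 0)
    flux <- leaf_raw(env, params)
    pm <- penman_monteith(pmax(flux$gs, 1e-6), mm)
    d <- pm$T_l - T_l
    if (max(abs(d)) < tol) {
      return(list(flux = flux, E_mm_h = pm$E_mm_h, E_mol = pm$E_mol,
                  T_l = T_l, iterations = it, r_sw = pm$r_sw))
    }
    step <- if (it > max_plain) 0.5 else 1
    T_l <- T_l + step * d
  }
  stop("leaf temperature iteration failed to converge within 200 iterations")
}
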