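## Sun/shade two-big-leaf canopy model with exponential nitrogen profile,
## Gaussian integration over the photoperiod, and water partitioning.

#' Canopy structural state
#'
#' @param LAI leaf area index (m2 m-2).
#' @param n_avg canopy average leaf nitrogen (g N m-2 leaf).
#' @param leaf_angle mean leaf inclination from horizontal (degrees).
#' @param scattering leaf scattering coefficient for PAR.
#' @param n_b base leaf nitrogen (g N m-2).
#' @return a `canopy_state` list.
#' @export
canopy_state <- function(LAI, n_avg, leaf_angle = 65, scattering = 0.2,
                         n_b = 0.3) {
  stopifnot(LAI >= 0, scattering >= 0, scattering < 1)
  structure(list(LAI = LAI, n_avg = n_avg, leaf_angle = leaf_angle,
                 scattering = scattering, n_b = n_b),
            class = "canopy_state")
}

#' Beam extinction coefficient for black leaves
#'
#' Projection of foliage with a fixed inclination angle onto the solar beam
#' direction, divided by the sine of solar elevation.
#'
#' @param sin_beta sine of solar elevation, positive.
#' @param leaf_angle leaf inclination from horizontal (degrees).
#' @return extinction coefficient `k_b` (per unit LAI).
#' @export
beam_extinction <- function(sin_beta, leaf_angle) {
  sb <- pmax(sin_beta, 0.02)
  beta <- asin(pmin(sb, 1))
  aL <- leaf_angle * pi / 180
  proj <- ifelse(beta >= aL,
                 sin(beta) * cos(aL),
                 (2 / pi) * (sin(beta) * cos(aL) *
                               asin(pmin(pmax(tan(beta) / tan(aL), -1), 1)) +
                             sqrt(pmax(sin(aL)^2 - sin(beta)^2, 0))))
  proj / sb
}

## diffuse-sky zones (elevations 15, 45, 75 degrees) and their radiance
## weights for a uniform overcast sky
.DIFF_SIN <- sin(c(15, 45, 75) * pi / 180)
.DIFF_W <- c(0.178, 0.514, 0.308)

#' Diffuse extinction coefficient (with scattering) at a given LAI
#'
#' Effective extinction of diffuse PAR obtained from the transmission of
#' the three-zone overcast sky through the canopy.
#'
#' @param LAI leaf area index.
#' @param leaf_angle degrees.
#' @param scattering leaf scattering coefficient.
#' @return effective `k_d'` (per unit LAI).
#' @export
diffuse_extinction <- function(LAI, leaf_angle, scattering = 0.2) {
  sq <- sqrt(1 - scattering)
  kbz <- beam_extinction(.DIFF_SIN, leaf_angle) * sq
  if (LAI < 1e-6) return(sum(.DIFF_W * kbz))
  tau <- sum(.DIFF_W * exp(-kbz * LAI))
  -log(tau) / LAI
}

canopy_reflectances <- function(kb, leaf_angle, scattering) {
  sq <- sqrt(1 - scattering)
  rho_h <- (1 - sq) / (1 + sq)
  rho_cb <- 1 - exp(-2 * rho_h * kb / (1 + kb))
  kbz <- beam_extinction(.DIFF_SIN, leaf_angle)
  rho_cd <- sum(.DIFF_W * (1 - exp(-2 * rho_h * kbz / (1 + kbz))))
  list(rho_cb = rho_cb, rho_cd = rho_cd)
}

#' Sunlit/shaded partition of leaf area, absorbed PAR and nitrogen
#'
#' Splits the canopy into sunlit and shaded big leaves: sunlit LAI
#' `(1 - exp(-k_b LAI)) / k_b`, absorbed direct, diffuse and scattered-beam
#' PAR per class following the sun/shade canopy scheme, and
#' photosynthetically active nitrogen per class from an exponential
#' vertical nitrogen profile with extinction `k_N` set to the diffuse PAR
#' extinction coefficient (nitrogen tracking the time-averaged light
#' profile). Absorbed PAR is conserved: sunlit + shaded equals the total
#' canopy absorption.
#'
#' @param cs a [canopy_state()] object.
#' @param sin_beta sine of solar elevation; at or below zero nothing is
#'   absorbed.
#' @param I_dir direct-beam PAR on a horizontal plane (umol m-2 s-1).
#' @param I_diff diffuse PAR (umol m-2 s-1).
#' @return data frame with rows `sunlit`, `shaded` and columns `lai`,
#'   `abs_par` (umol m-2 ground s-1), `N_photo` (g N m-2 ground above
#'   `n_b`), plus attributes `abs_total` and `k_b`.
#' @export
sunlit_shaded_partition <- function(cs, sin_beta, I_dir, I_diff) {
  p <- partition_raw(cs, sin_beta, I_dir, I_diff)
  out <- data.frame(class = c("sunlit", "shaded"), lai = p$lai,
                    abs_par = p$abs_par, N_photo = p$N_photo)
  attr(out, "abs_total") <- p$abs_total
  attr(out, "k_b") <- p$k_b
  attr(out, "k_N") <- p$k_N
  attr(out, "nodes") <- p$nodes
  out
}

## 3-point Gauss-Legendre abscissae/weights on [0, 1], used for the
## within-class depth quadrature
.G3_X <- c(0.1127016653792583, 0.5, 0.8872983346207417)
.G3_W <- c(5 / 18, 4 / 9, 5 / 18)

partition_raw <- function(cs, sin_beta, I_dir, I_diff) {
  L <- cs$LAI
  if (sin_beta <= 0) {
    I_dir <- 0
    I_diff <- 0
    sin_beta <- 0.02
  }
  sq <- sqrt(1 - cs$scattering)
  kb <- beam_extinction(sin_beta, cs$leaf_angle)
  kb_s <- kb * sq
  kd_s <- diffuse_extinction(L, cs$leaf_angle, cs$scattering)
  refl <- canopy_reflectances(kb, cs$leaf_angle, cs$scattering)
  lai_sun <- if (L > 0) (1 - exp(-kb * L)) / kb else 0
  lai_sh <- L - lai_sun

  abs_tot <- (1 - refl$rho_cb) * I_dir * (1 - exp(-kb_s * L)) +
    (1 - refl$rho_cd) * I_diff * (1 - exp(-kd_s * L))
  abs_sun_dir <- I_dir * (1 - cs$scattering) * (1 - exp(-kb * L))
  abs_sun_diff <- I_diff * (1 - refl$rho_cd) * kd_s / (kd_s + kb) *
    (1 - exp(-(kd_s + kb) * L))
  abs_sun_scat <- I_dir * ((1 - refl$rho_cb) * kb_s / (kb_s + kb) *
                             (1 - exp(-(kb_s + kb) * L)) -
                           (1 - cs$scattering) * (1 - exp(-2 * kb * L)) / 2)
  abs_sun <- min(abs_sun_dir + abs_sun_diff + max(abs_sun_scat, 0), abs_tot)
  abs_sh <- max(abs_tot - abs_sun, 0)

  ## exponential N profile: n(l) - n_b = (n0 - n_b) exp(-k_N l)
  kN <- kd_s
  N_tot <- max(cs$n_avg - cs$n_b, 0) * L
  if (L > 1e-9 && N_tot > 0) {
    n0nb <- N_tot * kN / (1 - exp(-kN * L))
    N_sun <- n0nb * (1 - exp(-(kN + kb) * L)) / (kN + kb)
    N_sun <- min(N_sun, N_tot)
  } else {
    N_sun <- 0
  }
  ## within-class depth nodes: absorbed flux and leaf N per unit leaf
  ## area at three Gaussian depths, with the leaf-area weight of each
  ## node (sunlit fraction exp(-kb l), shaded 1 - exp(-kb l))
  n0nb <- if (L > 1e-9 && N_tot > 0) N_tot * kN / (1 - exp(-kN * L)) else 0
  l <- .G3_X * L
  f_sun <- exp(-kb * l)
  q_sh <- pmax(I_diff * (1 - refl$rho_cd) * kd_s * exp(-kd_s * l) +
                 I_dir * ((1 - refl$rho_cb) * kb_s * exp(-kb_s * l) -
                            (1 - cs$scattering) * kb * exp(-kb * l)), 0)
  q_sun <- q_sh + I_dir * (1 - cs$scattering) * kb
  n_l <- cs$n_b + n0nb * exp(-kN * l)
  nodes <- list(q = c(q_sun, q_sh), n = c(n_l, n_l),
                w_area = c(.G3_W * L * f_sun, .G3_W * L * (1 - f_sun)),
                class = rep(c(1L, 2L), each = 3))
  list(lai = c(lai_sun, lai_sh), abs_par = c(abs_sun, abs_sh),
       N_photo = c(N_sun, N_tot - N_sun), abs_total = abs_tot, k_b = kb,
       k_N = kN, nodes = nodes)
}

## 5-point Gauss-Legendre abscissae/weights on [0, 1]
.GAUSS_X <- c(0.046910077030668, 0.230765344947158, 0.5,
              0.769234655052842, 0.953089922969332)
.GAUSS_W <- c(0.118463442528095, 0.239314335249683, 0.284444444444444,
              0.239314335249683, 0.118463442528095)

#' Gaussian integration of a diurnal flux over the photoperiod
#'
#' Five-point Gauss-Legendre quadrature of `f(t)` over `[0, daylength]`
#' (exact for polynomials up to degree 9).
#'
#' @param f function of time-in-photoperiod (hours from sunrise) returning
#'   a flux; must accept vector input.
#' @param daylength photoperiod (h), positive.
#' @return integral of `f` over the photoperiod (flux unit x hours).
#' @export
gauss_integrate_day <- function(f, daylength) {
  stopifnot(daylength > 0)
  sum(.GAUSS_W * f(.GAUSS_X * daylength)) * daylength
}

#' Instantaneous sun/shade canopy fluxes
#'
#' Applies the coupled leaf solver (with leaf energy balance) to the sunlit
#' and shaded leaf classes. Each class is resolved at three Gaussian depth
#' nodes carrying the local absorbed PAR and leaf nitrogen of the
#' exponential profiles, and node results are aggregated to the class by
#' their leaf-area weights; this keeps the two-class sun/shade structure
#' while avoiding the saturation bias of a single aggregated evaluation.
#'
#' @param part partition from [sunlit_shaded_partition()].
#' @param params a `photo_params` object.
#' @param T_air air temperature (degC).
#' @param vp vapour pressure (kPa).
#' @param wind wind speed (m s-1).
#' @param C_a ambient CO2 (umol mol-1).
#' @param prescribe optional list with `T_l` and `VPD` to bypass the energy
#'   balance (leaf temperature prescribed).
#' @param n_b base leaf nitrogen (g N m-2).
#' @return list: `A` (umol CO2 m-2 ground s-1, summed over classes),
#'   `E_mol` (mol H2O m-2 s-1), per-class data frame `classes` (with `A`,
#'   `gs`, `E_mol`, `T_l`), and `abs_par_total`.
#' @export
instantaneous_canopy_flux <- function(part, params, T_air, vp, wind, C_a,
                                      prescribe = NULL, n_b = 0.3) {
  nodes <- if (is.data.frame(part)) attr(part, "nodes") else part$nodes
  if (is.null(nodes)) stop("partition lacks depth nodes")
  out <- canopy_nodes_flux(nodes, params, T_air, vp, wind, C_a, prescribe)
  agg <- function(v) {
    c(sum(v[nodes$class == 1] * nodes$w_area[nodes$class == 1]),
      sum(v[nodes$class == 2] * nodes$w_area[nodes$class == 2]))
  }
  wmean <- function(v) agg(v) / pmax(agg(rep(1, 6)), 1e-12)
  classes <- data.frame(class = c("sunlit", "shaded"), A = agg(out$A),
                        gs = agg(out$gs),
                        E_mol = if (is.null(prescribe)) agg(out$E_mol) else
                          NA_real_,
                        T_l = wmean(out$T_l))
  abs_total <- if (is.data.frame(part)) attr(part, "abs_total") else
    part$abs_total
  list(A = sum(classes$A), E_mol = sum(classes$E_mol),
       classes = classes, abs_par_total = abs_total, nodes_flux = out)
}

## leaf solve + energy balance on the six depth nodes; all quantities per
## unit leaf area
canopy_nodes_flux <- function(nodes, params, T_air, vp, wind, C_a,
                              prescribe = NULL) {
  env <- leaf_env(I_inc = nodes$q, C_a = C_a,
                  T_l = if (is.null(prescribe)) T_air else prescribe$T_l,
                  VPD = if (is.null(prescribe)) 1 else prescribe$VPD,
                  n_leaf = nodes$n, absorptance = 1, g_b = 3, g0_scale = 1)
  if (!is.null(prescribe)) {
    fl <- leaf_raw(env, params)
    return(list(A = fl$A, gs = fl$gs, E_mol = rep(NA_real_, 6),
                T_l = rep(prescribe$T_l, 6), r_sw = rep(NA_real_, 6),
                env = env, mm = NULL))
  }
  mm <- micromet(T_air, vp, wind, net_radiation = 1.3 * nodes$q / 4.6)
  ex <- iterate_leaf_raw(env, params, mm)
  list(A = ex$flux$A, gs = ex$flux$gs, E_mol = ex$E_mol, T_l = ex$T_l,
       r_sw = ex$r_sw, env = env, mm = mm)
}

## diurnal air temperature: sinusoid between tmin and tmax peaking 1.5 h
## after solar noon (h is solar hour of day)
diurnal_temperature <- function(h, tmax, tmin, daylength) {
  tm <- (tmax + tmin) / 2
  tm + (tmax - tmin) / 2 * cos(2 * pi * (h - 13.5) / 24)
}

#' Daily canopy photosynthesis and transpiration
#'
#' Generates diurnal courses of radiation (proportional to
#' `sin(beta) (1 + 0.4 sin(beta))`) and temperature from daily totals and
#' extremes, partitions the canopy at each of five Gaussian time points,
#' applies the big-leaf solver, and integrates to daily totals. Under water
#' limitation the available water follows the diurnal course of radiation,
#' is split between classes in proportion to their potential transpiration,
#' converted to an actual stomatal resistance, and the actual assimilation
#' is recomputed at the prescribed stomatal conductance.
#'
#' @param day list or one-row data frame with `radiation_MJ`, `tmax_C`,
#'   `tmin_C`, `vap_kPa`, `wind_ms`, `doy`.
#' @param cs a [canopy_state()] object.
#' @param params a `photo_params` object.
#' @param latitude degrees.
#' @param C_a ambient CO2 (umol mol-1).
#' @param water_supply_mm daily available water for transpiration (mm);
#'   `NULL` for potential production.
#' @param diffuse `"transmissivity"` (from daily clearness) or a fixed
#'   numeric fraction.
#' @param prescribe optional `list(T_l=, VPD=)` bypassing the energy
#'   balance (no transpiration computed).
#' @return list: `A_gCO2` (g CO2 m-2 ground d-1), `E_mm` (mm d-1),
#'   `PAR_abs_MJ`, `PAR_inc_MJ` (MJ m-2 d-1), `daylength` (h), and under
#'   water limitation also the potential totals `A_gCO2_pot`, `E_mm_pot`.
#' @export
daily_canopy_photosynthesis <- function(day, cs, params, latitude,
                                        C_a = 400, water_supply_mm = NULL,
                                        diffuse = "transmissivity",
                                        prescribe = NULL) {
  sol <- daylength_and_radiation(latitude, day$doy)
  D <- sol$daylength
  PAR_J <- 0.5 * day$radiation_MJ * 1e6 # J m-2 d-1 in the PAR band
  fd <- if (identical(diffuse, "transmissivity")) {
    diffuse_fraction_daily(day$radiation_MJ / max(sol$S0_MJ, 1e-6))
  } else {
    as.numeric(diffuse)
  }
  hours <- sol$sunrise + .GAUSS_X * D
  sinb <- pmax(sin_solar_elevation(latitude, day$doy, hours), 0)
  wgt <- sinb * (1 + 0.4 * sinb)
  denom <- sum(.GAUSS_W * wgt) * D * 3600 # s-weighted integral of wgt
  if (denom <= 0) {
    return(list(A_gCO2 = 0, E_mm = 0, PAR_abs_MJ = 0, PAR_inc_MJ = 0,
                daylength = D))
  }
  par_W <- PAR_J * wgt / denom                 # W m-2 PAR at each point
  par_umol <- par_W * 4.6
  Tair <- diurnal_temperature(hours, day$tmax_C, day$tmin_C, D)

  water_rate <- if (is.null(water_supply_mm)) NULL else {
    water_supply_mm / 18 * 1000 * wgt / denom # mol m-2 s-1 at each point
  }
  ## stack the five time points x six canopy depth nodes into one solve
  parts <- lapply(1:5, function(i) {
    partition_raw(cs, sinb[i], (1 - fd) * par_umol[i], fd * par_umol[i])
  })
  abs_pt <- vapply(parts, `[[`, numeric(1), "abs_total") / 4.6 # W m-2
  q_v <- unlist(lapply(parts, function(p) p$nodes$q))
  n_v <- unlist(lapply(parts, function(p) p$nodes$n))
  w_v <- unlist(lapply(parts, function(p) p$nodes$w_area))
  Tair_v <- rep(Tair, each = 6)
  pt_of <- rep(1:5, each = 6)
  env <- leaf_env(I_inc = q_v, C_a = C_a,
                  T_l = if (is.null(prescribe)) Tair_v else prescribe$T_l,
                  VPD = if (is.null(prescribe)) 1 else prescribe$VPD,
                  n_leaf = n_v, absorptance = 1, g_b = 3, g0_scale = 1)
  ptsum <- function(v) as.numeric(rowsum(v * w_v, pt_of))
  if (!is.null(prescribe)) {
    flux <- leaf_raw(env, params)
    A_pt <- ptsum(flux$A)
    E_pt <- rep(NA_real_, 5)
  } else {
    mm <- micromet(Tair_v, day$vap_kPa, day$wind_ms,
                   net_radiation = 1.3 * q_v / 4.6)
    ex <- iterate_leaf_raw(env, params, mm)
    A_pt <- ptsum(ex$flux$A)
    E_pt <- ptsum(ex$E_mol)
    if (!is.null(water_rate)) {
      ## supply split across nodes in proportion to potential
      ## transpiration: every node of a time point shares one stress ratio
      Ep_w <- pmax(ex$E_mol, 0) * w_v
      Ep_tot <- as.numeric(rowsum(Ep_w, pt_of))[pt_of]
      supply_v <- water_rate[pt_of]
      stressed <- Ep_tot > 1e-12 & supply_v < Ep_tot & ex$E_mol > 1e-10
      Aw_v <- ex$flux$A
      Ew_v <- pmax(ex$E_mol, 0)
      if (any(stressed)) {
        i <- which(stressed)
        ratio <- supply_v[i] / Ep_tot[i]
        Ep_i <- ex$E_mol[i]
        Ea_i <- pmax(ratio * Ep_i, 1e-9)
        mm_s <- micromet(Tair_v[i], day$vap_kPa, day$wind_ms,
                         net_radiation = 1.3 * q_v[i] / 4.6)
        r_swa <- actual_stomatal_resistance(Ep_i, Ea_i, ex$r_sw[i], mm_s)
        gs_a <- pmax(1 / (1.6 * r_swa), 1e-6)
        pm <- penman_monteith(gs_a, mm_s)
        env_s <- leaf_env(I_inc = q_v[i], C_a = C_a, T_l = pm$T_l,
                          VPD = pmax(sat_vp(pm$T_l) - day$vap_kPa, 0),
                          n_leaf = n_v[i], absorptance = 1, g_b = 3,
                          g0_scale = 1)
        fl <- leaf_raw(env_s, params, gs_fixed = gs_a)
        Aw_v[i] <- fl$A
        Ew_v[i] <- pmax(pm$E_mol, 0)
      }
      Aw_pt <- ptsum(Aw_v)
      Ew_pt <- ptsum(Ew_v)
    }
  }
  int_day <- function(v) sum(.GAUSS_W * v) * D * 3600 # per-second to daily
  out <- list(
    A_gCO2 = int_day(A_pt) * 44e-6,
    E_mm = if (is.null(prescribe)) int_day(E_pt) * 18 / 1000 else NA_real_,
    PAR_abs_MJ = int_day(abs_pt) / 1e6,
    PAR_inc_MJ = PAR_J / 1e6,
    daylength = D)
  if (!is.null(water_rate)) {
    out$A_gCO2_pot <- out$A_gCO2
    out$E_mm_pot <- out$E_mm
    out$A_gCO2 <- int_day(Aw_pt) * 44e-6
    out$E_mm <- int_day(Ew_pt) * 18 / 1000
  }
  out
}

#' Daily canopy photosynthesis grid over radiation and LAI
#'
#' Reproduces the structure of daily-canopy response surfaces: for each
#' route, LAI and daily radiation level, computes daily canopy
#' photosynthesis at fixed conditions (prescribed leaf temperature 25 degC,
#' VPD 2 kPa, canopy average leaf N 2.3 g m-2, daylength about 13 h,
#' diffuse fraction 0.2, leaf angle 65 degrees).
#'
#' @param route_ids integer vector of route ids.
#' @param LAI vector of leaf area indices.
#' @param radiation_MJ vector of daily global radiation (MJ m-2 d-1).
#' @param C_a ambient CO2 (umol mol-1).
#' @param n_avg canopy average leaf N (g m-2).
#' @param file optional CSV output path.
#' @return data frame (route, LAI, radiation, A_canopy_d in g CO2 m-2 d-1).
#' @export
canopy_daily_grid <- function(route_ids = 0:9, LAI = c(1, 3, 5, 7),
                              radiation_MJ = seq(5, 30, by = 5), C_a = 400,
                              n_avg = 2.3, file = NULL) {
  ## latitude/doy chosen to give a ~13 h photoperiod
  lat <- 25
  doy <- 135
  rows <- list()
  for (id in route_ids) {
    rt <- build_route(id)
    for (L in LAI) {
      cs <- canopy_state(LAI = L, n_avg = n_avg)
      for (S in radiation_MJ) {
        day <- list(radiation_MJ = S, tmax_C = 25, tmin_C = 25,
                    vap_kPa = sat_vp(25) - 2, wind_ms = 2, doy = doy)
        res <- daily_canopy_photosynthesis(
          day, cs, rt$params, latitude = lat, C_a = C_a, diffuse = 0.2,
          prescribe = list(T_l = 25, VPD = 2))
        rows[[length(rows) + 1]] <- data.frame(
          route = id, LAI = L, radiation_MJ = S, A_canopy_d = res$A_gCO2)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
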