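## Simplified daily crop simulator: phenology, nitrogen uptake, canopy
## assimilation, respiration, partitioning, LAI dynamics with
## carbon/nitrogen-determined senescence, and seasonal trait bookkeeping.

## Module constants not tied to a specific parameter table; documented in
## the methods vignette.
.YG <- 0.75            # growth conversion efficiency, g DM per g CH2O
.CM_MAINT <- 0.015     # maintenance respiration, g CH2O g-1 non-leaf N d-1 at 25 degC
.CH2O_PER_CO2 <- 30 / 44
.SLA <- 0.03           # specific leaf area of new leaves, m2 g-1
.TC_SEN <- 2           # senescence time constant, d
.N_UPTAKE_TOTAL <- 20  # seasonal N uptake, g N m-2

#' Crop input constants
#'
#' The standard rice input constants used by the seasonal simulator, in
#' one place: specific leaf area `S_la` (m2 g-1), base root/stem nitrogen
#' concentrations `n_Rmin`, `n_Smin` and reserve N concentration `n_RV`
#' (g g-1), potential single-grain weight `S_W` (g) and grain N
#' concentration `n_SO` (g g-1), maximum plant height `H_max` (m), and the
#' senescence time constant `TC_S` (d). The grain and height constants are
#' carried for completeness but unused: grain formation is not simulated
#' and shoot mass is the productivity proxy.
#'
#' @return named list of constants.
#' @export
crop_input_constants <- function() {
  list(S_la = 0.03, n_Rmin = 0.005, n_Smin = 0.005, n_RV = 0.0015,
       S_W = 0.025, n_SO = 0.0145, H_max = 1.0, TC_S = 2)
}

#' Thermal-day increment for one day
#'
#' Integrates a beta-shaped temperature response (0 at and below `T_b`, 1
#' at `T_o`, 0 at and above `T_c`) of the diurnal temperature course over
#' the five Gaussian points of the full day, divided by the day, so that a
#' day spent entirely at the optimum temperature contributes exactly 1.
#'
#' @param tmax,tmin daily temperature extremes (degC).
#' @param phen a [phenology_params()] object.
#' @return thermal days in `[0, 1]`.
#' @export
thermal_day_increment <- function(tmax, tmin, phen) {
  h <- .GAUSS_X * 24
  temp <- diurnal_temperature(h, tmax, tmin, 12)
  sum(.GAUSS_W * beta_temp_response(temp, phen))
}

#' Beta temperature response for development rate
#'
#' `[((T_c - T)/(T_c - T_o)) ((T - T_b)/(T_o - T_b))^((T_o - T_b)/(T_c - T_o))]`,
#' clamped to zero outside `(T_b, T_c)` and equal to 1 at `T_o`.
#'
#' @param T_C temperature (degC).
#' @param phen a [phenology_params()] object.
#' @return dimensionless rate factor in `[0, 1]`.
#' @export
beta_temp_response <- function(T_C, phen) {
  with(phen, {
    r <- rep(0, length(T_C))
    ok <- T_C > T_b & T_C < T_c
    ex <- (T_o - T_b) / (T_c - T_o)
    r[ok] <- ((T_c - T_C[ok]) / (T_c - T_o)) *
      ((T_C[ok] - T_b) / (T_o - T_b))^ex
    pmin(pmax(r, 0), 1)
  })
}

#' Advance the development stage
#'
#' Stage runs from 0 (emergence) through 1 (flowering) to 2 (maturity);
#' the thermal increment is divided by the pre-flowering requirement `m_V`
#' before flowering and by `m_R` after. Drought does not alter phenology.
#'
#' @param stage current development stage.
#' @param increment thermal-day increment of the day.
#' @param phen a [phenology_params()] object.
#' @return updated stage.
#' @export
advance_phenology <- function(stage, increment, phen) {
  stage2 <- if (stage < 1) {
    ## do not let leftover vegetative thermal time spill at the boundary
    min(stage + increment / phen$m_V, 1 + increment / phen$m_R)
  } else {
    stage + increment / phen$m_R
  }
  ## guard against float drift when thermal time accumulates in equal steps
  if (abs(stage2 - round(stage2)) < 1e-9) stage2 <- round(stage2)
  stage2
}

## beta-sigmoid cumulative N uptake over development stage (end te = 2,
## inflection tm = 1); reaches exactly 1 at maturity
sigmoid_uptake_fraction <- function(stage) {
  x <- pmin(pmax(stage, 0), 2)
  (3 - x) * (x / 2)^2
}

#' Daily nitrogen uptake
#'
#' Derivative (per stage step) of a beta-sigmoid cumulative uptake curve
#' scaled so that the seasonal total equals `total_N` at maturity.
#'
#' @param stage_old,stage_new development stage before and after the day.
#' @param total_N seasonal total uptake (g N m-2), default 20.
#' @return uptake of the day (g N m-2 d-1), non-negative.
#' @export
n_uptake_daily <- function(stage_old, stage_new,
                           total_N = .N_UPTAKE_TOTAL) {
  total_N * pmax(sigmoid_uptake_fraction(stage_new) -
                   sigmoid_uptake_fraction(stage_old), 0)
}

#' Nitrogen-determined LAI
#'
#' Logarithmic relation between canopy leaf nitrogen and the LAI that
#' nitrogen can sustain: `(1/k_N) ln(1 + k_N N_leaf / n_b)`.
#'
#' @param N_leaf canopy leaf nitrogen (g N m-2 ground).
#' @param k_N nitrogen extinction coefficient.
#' @param n_b base leaf nitrogen (g N m-2 leaf).
#' @return LAI (m2 m-2).
#' @export
lai_n_determined <- function(N_leaf, k_N, n_b) {
  log(1 + k_N * pmax(N_leaf, 0) / n_b) / k_N
}

#' Update LAI pools and apply senescence
#'
#' Carbon-determined LAI grows with new leaf mass times the specific leaf
#' area; when it exceeds the nitrogen-determined LAI, leaf area (and the
#' corresponding leaf mass, at the current mass per unit area) is shed at
#' rate `(LAI_C - LAI_N) / TC_S`. Dead leaves keep their base structural
#' nitrogen; the remainder stays in the live leaf N pool.
#'
#' @param state list with `LAI_C`, `mass_leaf`, `mass_dead`, `N_leaf`,
#'   `SENES`.
#' @param new_leaf_mass g DM m-2 allocated to leaves today.
#' @param k_N nitrogen extinction coefficient.
#' @param n_b base leaf nitrogen (g N m-2).
#' @param S_la specific leaf area (m2 g-1).
#' @param TC_S senescence time constant (d).
#' @return updated state, with `LAI` set to `min(LAI_C, LAI_N)`.
#' @export
update_lai_and_senescence <- function(state, new_leaf_mass, k_N, n_b,
                                      S_la = .SLA, TC_S = .TC_SEN) {
  state$LAI_C <- state$LAI_C + S_la * max(new_leaf_mass, 0)
  state$mass_leaf <- state$mass_leaf + max(new_leaf_mass, 0)
  lai_n <- lai_n_determined(state$N_leaf, k_N, n_b)
  if (state$LAI_C > lai_n) {
    dL <- min((state$LAI_C - lai_n) / TC_S, state$LAI_C)
    mpl <- if (state$LAI_C > 1e-9) state$mass_leaf / state$LAI_C else 0
    dm <- dL * mpl
    state$LAI_C <- state$LAI_C - dL
    state$mass_leaf <- max(state$mass_leaf - dm, 0)
    state$mass_dead <- state$mass_dead + dm
    state$SENES <- state$SENES + dm
    state$N_leaf <- max(state$N_leaf - dL * n_b, 0)
  }
  state$LAI_N <- lai_n
  state$LAI <- min(state$LAI_C, lai_n)
  state
}

#' Daily growth and maintenance respiration
#'
#' Growth respiration is `(1 - Y_G)` of the assimilate allocated to growth;
#' maintenance respiration depends on crop (non-leaf) nitrogen with a Q10
#' of 2 around 25 degC. Day respiration of leaves is already accounted in
#' net canopy photosynthesis; night leaf respiration is passed in
#' separately by the season loop.
#'
#' @param assimilate_CH2O allocatable assimilate (g CH2O m-2 d-1).
#' @param nonleaf_N non-leaf crop nitrogen (g N m-2).
#' @param T_mean daily mean temperature (degC).
#' @return list: `growth` and `maint` (g CH2O m-2 d-1), and `new_DM`
#'   (g DM m-2 d-1, negative when maintenance exceeds supply).
#' @export
respiration_daily <- function(assimilate_CH2O, nonleaf_N, T_mean) {
  maint <- .CM_MAINT * max(nonleaf_N, 0) * 2^((T_mean - 25) / 10)
  avail <- assimilate_CH2O - maint
  growth <- (1 - .YG) * max(avail, 0)
  list(growth = growth, maint = maint,
       new_DM = if (avail >= 0) .YG * avail else avail)
}

#' Root fraction of daily growth
#'
#' Functional-equilibrium proxy: a baseline that declines with development
#' stage, scaled up when the shoot carbon:nitrogen status is high (carbon
#' surplus relative to nitrogen), bounded to `[0.05, 0.6]`.
#'
#' @param stage development stage.
#' @param nc_shoot shoot nitrogen concentration (g N g-1 DM).
#' @return fraction of new dry matter allocated to roots.
#' @export
partition_root_shoot <- function(stage, nc_shoot) {
  base <- 0.05 + 0.30 * exp(-1.2 * stage)
  nc_ref <- 0.005 + 0.025 * exp(-1.5 * stage)
  f <- base * (nc_ref / max(nc_shoot, 1e-4))
  min(max(f, 0.05), 0.6)
}

## leaf fraction of new shoot mass and leaf share of new shoot N
leaf_mass_fraction <- function(stage) 0.62 / (1 + exp(6 * (stage - 0.9)))
leaf_n_share <- function(stage) 1 / (1 + exp(5 * (stage - 1.1)))

#' Run one growing season
#'
#' Daily loop from seedling emergence to maturity: phenology, prescribed
#' sigmoid nitrogen uptake (20 g N m-2 per season), sun/shade canopy
#' photosynthesis and transpiration with leaf energy balance, night leaf
#' respiration, maintenance and growth respiration, root/shoot and
#' leaf/stem partitioning, and LAI dynamics with C/N-determined senescence.
#'
#' Under `water = "limited"` the potential season is simulated first and
#' the daily available water is then fixed at 50% of the seasonal mean
#' daily potential transpiration for the same weather and route.
#'
#' @param weather data frame from [generate_weather()] (one or more years;
#'   the season starts at the site's `start_day` in the first year and may
#'   run into subsequent rows).
#' @param site a [site_config()] object.
#' @param route a `route_spec` from [build_route()].
#' @param water `"potential"` or `"limited"`.
#' @param C_a ambient CO2 (umol mol-1); overridden by a `C_a` attribute on
#'   `weather` (set by [apply_climate_2050()]).
#' @param water_supply_mm daily available water (mm d-1) for the limited
#'   mode; when `NULL` it is derived from a potential pre-run of the same
#'   weather and route (50% of mean daily potential transpiration).
#' @param max_days failure guard: error if maturity is not reached within
#'   this many days.
#' @return a `season_result` list: `days_to_flowering`, `days_to_maturity`,
#'   `shoot_mass` (live, g DM m-2), `mass_root`, `mass_dead`, `A_canopy_s`
#'   (g CO2 m-2), `PAR_int` (MJ m-2), `PLUE` (g CO2 MJ-1), `RESP`
#'   (g CO2 m-2), `F_root`, `SENES` (g DM m-2), `transpiration` (mm),
#'   `WUE` (g DM m-2 mm-1), `water_supply_mm`, and the daily trajectory in
#'   `$daily`.
#' @export
run_season <- function(weather, site, route, water = c("potential",
                                                       "limited"),
                       C_a = 400, water_supply_mm = NULL, max_days = 250) {
  water <- match.arg(water)
  if (!is.null(attr(weather, "C_a"))) C_a <- attr(weather, "C_a")
  supply <- NULL
  if (water == "limited") {
    supply <- water_supply_mm
    if (is.null(supply)) {
      pot <- run_season(weather, site, route, water = "potential",
                        C_a = C_a, max_days = max_days)
      supply <- 0.5 * pot$transpiration / pot$days_to_maturity
    }
  }
  phen <- site$phenology
  first_year <- weather$year[1]
  i0 <- which(weather$year == first_year & weather$doy == phen$start_day)
  if (length(i0) != 1) stop("weather does not cover the emergence day")

  state <- list(stage = 0, LAI_C = 0.06, LAI_N = 0.06, LAI = 0.06,
                mass_leaf = 2, mass_stem = 1, mass_root = 1, mass_dead = 0,
                N_leaf = 0.10, N_stem = 0.02, N_root = 0.01,
                SENES = 0)
  init_shoot <- state$mass_leaf + state$mass_stem
  init_root <- state$mass_root
  acc <- list(A = 0, PARabs = 0, PARinc = 0, RESP = 0, E = 0, root_g = 0,
              shoot_g = 0)
  flowering_day <- NA_integer_
  daily_cols <- c("day", "doy", "stage", "LAI", "A_gCO2", "E_mm",
                  "mass_leaf", "mass_stem", "mass_root")
  daily <- matrix(NA_real_, nrow = max_days, ncol = length(daily_cols),
                  dimnames = list(NULL, daily_cols))

  for (d in seq_len(max_days)) {
    idx <- i0 + d - 1
    if (idx > nrow(weather)) stop("weather series ended before maturity")
    wd <- weather[idx, ]
    inc <- thermal_day_increment(wd$tmax_C, wd$tmin_C, phen)
    stage_old <- state$stage
    state$stage <- advance_phenology(state$stage, inc, phen)
    if (is.na(flowering_day) && state$stage >= 1) flowering_day <- d

    dN <- n_uptake_daily(stage_old, state$stage)

    ## canopy assimilation with yesterday's canopy
    n_avg <- if (state$LAI > 1e-6) state$N_leaf / state$LAI else 0
    cs <- canopy_state(LAI = state$LAI, n_avg = n_avg, n_b = route$params$n_b)
    day <- list(radiation_MJ = wd$radiation_MJ, tmax_C = wd$tmax_C,
                tmin_C = wd$tmin_C, vap_kPa = wd$vap_kPa,
                wind_ms = wd$wind_ms, doy = ((wd$doy - 1) %% 365) + 1)
    dc <- daily_canopy_photosynthesis(day, cs, route$params, site$latitude,
                                      C_a = C_a, water_supply_mm = supply)

    ## night leaf dark respiration at night mean temperature
    tmean <- (wd$tmax_C + wd$tmin_C) / 2
    t_night <- tmean - 0.35 * (wd$tmax_C - wd$tmin_C) / 2
    N_photo <- max(state$N_leaf - route$params$n_b * state$LAI, 0)
    Rd_night_umol <- arrhenius(route$params$chi_Rd25 * N_photo,
                               route$params$E_Rd, t_night)
    night_h <- 24 - dc$daylength
    night_gCO2 <- Rd_night_umol * night_h * 3600 * 44e-6

    assim_CH2O <- (dc$A_gCO2 - night_gCO2) * .CH2O_PER_CO2
    nonleaf_N <- state$N_stem + state$N_root
    resp <- respiration_daily(assim_CH2O, nonleaf_N, tmean)
    resp_gCO2 <- night_gCO2 + (resp$maint + resp$growth) / .CH2O_PER_CO2

    ## partitioning
    nc_shoot <- (state$N_leaf + state$N_stem) /
      max(state$mass_leaf + state$mass_stem, 1e-6)
    fr <- partition_root_shoot(state$stage, nc_shoot)
    new_DM <- resp$new_DM
    if (new_DM >= 0) {
      root_new <- fr * new_DM
      shoot_new <- (1 - fr) * new_DM
      leaf_new <- leaf_mass_fraction(state$stage) * shoot_new
      state$mass_root <- state$mass_root + root_new
      state$mass_stem <- state$mass_stem + (shoot_new - leaf_new)
      acc$root_g <- acc$root_g + root_new
      acc$shoot_g <- acc$shoot_g + shoot_new
    } else {
      ## assimilate shortfall: drawn from stem reserves
      state$mass_stem <- max(state$mass_stem + new_DM, 0)
      acc$shoot_g <- acc$shoot_g + new_DM
      leaf_new <- 0
    }
    fr_N <- 0.10
    state$N_root <- state$N_root + fr_N * dN
    dN_shoot <- (1 - fr_N) * dN
    sL <- leaf_n_share(state$stage)
    state$N_leaf <- state$N_leaf + sL * dN_shoot
    state$N_stem <- state$N_stem + (1 - sL) * dN_shoot

    k_N <- diffuse_extinction(max(state$LAI, 0.5), 65, 0.2)
    state <- update_lai_and_senescence(state, leaf_new, k_N,
                                       route$params$n_b)

    acc$A <- acc$A + dc$A_gCO2
    acc$PARabs <- acc$PARabs + dc$PAR_abs_MJ
    acc$PARinc <- acc$PARinc + dc$PAR_inc_MJ
    acc$RESP <- acc$RESP + resp_gCO2
    acc$E <- acc$E + dc$E_mm
    daily[d, ] <- c(d, wd$doy, state$stage, state$LAI, dc$A_gCO2, dc$E_mm,
                    state$mass_leaf, state$mass_stem, state$mass_root)
    if (state$stage >= 2) break
  }
  if (state$stage < 2) {
    stop("season failed to reach maturity within ", max_days, " days")
  }
  shoot_live <- state$mass_leaf + state$mass_stem
  growth_tot <- acc$root_g + acc$shoot_g
  F_root <- if (growth_tot > 0) acc$root_g / growth_tot else 0
  res <- list(
    site = site$name, route_id = route$route_id, water = water, C_a = C_a,
    days_to_flowering = flowering_day, days_to_maturity = d,
    shoot_mass = shoot_live, mass_root = state$mass_root,
    mass_dead = state$mass_dead,
    A_canopy_s = acc$A, PAR_int = acc$PARabs, PAR_inc = acc$PARinc,
    PLUE = acc$A / max(acc$PARabs, 1e-9), RESP = acc$RESP,
    F_root = F_root, SENES = state$SENES, transpiration = acc$E,
    WUE = shoot_live / max(acc$E, 1e-9),
    water_supply_mm = if (is.null(supply)) NA_real_ else supply,
    init_shoot = init_shoot, init_root = init_root,
    daily = as.data.frame(daily[seq_len(d), , drop = FALSE]))
  structure(res, class = "season_result")
}

#' @export
print.season_result <- function(x, ...) {
  cat(sprintf("<season_result> %s, route %d, %s water, Ca = %g\n", x$site,
              x$route_id, x$water, x$C_a))
  cat(sprintf("  flowering day %d, maturity day %d\n", x$days_to_flowering,
              x$days_to_maturity))
  cat(sprintf("  shoot mass %.0f g DM m-2 (dead %.0f), WUE %.2f g mm-1\n",
              x$shoot_mass, x$mass_dead, x$WUE))
  cat(sprintf("  A_canopy,s %.0f g CO2 m-2, PAR_int %.0f MJ, PLUE %.2f\n",
              x$A_canopy_s, x$PAR_int, x$PLUE))
  invisible(x)
}

#' Mass decomposition of a season result
#'
#' Reconstructs live shoot mass from the trait components,
#' `(PAR_int x PLUE - RESP) (30/44) (1 - F_root) - SENES` plus the initial
#' shoot mass, and reports the residual.
#'
#' @param x a `season_result`.
#' @return list with `mass_pred`, `residual` and `residual_frac`
#'   (residual as a fraction of shoot mass).
#' @export
season_mass_decomposition <- function(x) {
  growth <- (x$PAR_int * x$PLUE - x$RESP) * .CH2O_PER_CO2
  pred <- growth * (1 - x$F_root) - x$SENES + x$init_shoot
  list(mass_pred = pred, residual = pred - x$shoot_mass,
       residual_frac = (pred - x$shoot_mass) / max(x$shoot_mass, 1e-9))
}
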