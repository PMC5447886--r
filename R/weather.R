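## Synthetic daily weather generator for the three site archetypes, and the
## 2050 climate transform.

#' Phenology parameters
#'
#' Cardinal temperatures and thermal-day requirements of the crop at one
#' site, plus the emergence day.
#'
#' @param m_V minimum pre-flowering duration (thermal days).
#' @param m_R minimum post-flowering duration (thermal days).
#' @param start_day day of year of seedling emergence.
#' @param T_b,T_o,T_c base, optimum and ceiling temperature (degC).
#' @return a `phenology_params` list.
#' @export
phenology_params <- function(m_V, m_R, start_day, T_b = 8, T_o = 30,
                             T_c = 42) {
  stopifnot(T_b < T_o, T_o < T_c, m_V > 0, m_R > 0)
  structure(list(T_b = T_b, T_o = T_o, T_c = T_c, m_V = m_V, m_R = m_R,
                 start_day = start_day), class = "phenology_params")
}

#' Site configuration for the weather generator
#'
#' Climatological constants of one site archetype. The seasonal temperature
#' cycle is `t_mean + t_amp * cos(2 pi (doy - t_peak_doy) / 365)` plus an
#' AR(1) daily anomaly; radiation is clearness times extraterrestrial
#' radiation; vapour pressure tracks saturation at the daily minimum
#' temperature.
#'
#' @param name site label.
#' @param latitude degrees north.
#' @param t_mean,t_amp,t_peak_doy annual mean temperature (degC), seasonal
#'   amplitude (degC) and day of the warm peak.
#' @param t_anom_sd standard deviation of daily temperature anomalies
#'   (degC).
#' @param diurnal_range mean daily temperature range (degC).
#' @param clearness_mean,clearness_amp,clearness_peak_doy,clearness_sd
#'   clearness-index climatology (mean, seasonal amplitude, peak day,
#'   anomaly SD).
#' @param vp_frac vapour pressure as a fraction of saturation at `tmin`.
#' @param wind_mean mean wind speed (m s-1).
#' @param phenology a [phenology_params()] object.
#' @return a `site_config` list.
#' @export
site_config <- function(name, latitude, t_mean, t_amp, t_peak_doy,
                        t_anom_sd, diurnal_range, clearness_mean,
                        clearness_amp, clearness_peak_doy, clearness_sd,
                        vp_frac, wind_mean, phenology) {
  stopifnot(latitude >= -60, latitude <= 60,
            clearness_mean > 0, clearness_mean <= 0.8)
  structure(list(name = name, latitude = latitude, t_mean = t_mean,
                 t_amp = t_amp, t_peak_doy = t_peak_doy,
                 t_anom_sd = t_anom_sd, diurnal_range = diurnal_range,
                 clearness_mean = clearness_mean,
                 clearness_amp = clearness_amp,
                 clearness_peak_doy = clearness_peak_doy,
                 clearness_sd = clearness_sd, vp_frac = vp_frac,
                 wind_mean = wind_mean, phenology = phenology),
            class = "site_config")
}

#' Built-in site archetypes
#'
#' Tropical (Los Banos-like, dry-season crop), subtropical (Nanjing-like,
#' single summer crop) and temperate (Shizukuishi-like) rice environments,
#' with their phenology calibrations (pre-/post-flowering thermal days
#' 70/28, 85/32 and 48/22, emergence days 10, 145 and 125).
#'
#' @return named list of [site_config()] objects
#'   (`los_banos`, `nanjing`, `shizukuishi`).
#' @export
site_presets <- function() {
  list(
    los_banos = site_config(
      "los_banos", latitude = 14.1, t_mean = 27.0, t_amp = 1.8,
      t_peak_doy = 135, t_anom_sd = 0.8, diurnal_range = 8.5,
      clearness_mean = 0.52, clearness_amp = 0.06, clearness_peak_doy = 105,
      clearness_sd = 0.10, vp_frac = 0.95, wind_mean = 1.5,
      phenology = phenology_params(m_V = 70, m_R = 28, start_day = 10)),
    nanjing = site_config(
      "nanjing", latitude = 32.9, t_mean = 16.3, t_amp = 12.5,
      t_peak_doy = 205, t_anom_sd = 2.0, diurnal_range = 8.0,
      clearness_mean = 0.46, clearness_amp = 0.03, clearness_peak_doy = 300,
      clearness_sd = 0.12, vp_frac = 0.90, wind_mean = 2.5,
      phenology = phenology_params(m_V = 85, m_R = 32, start_day = 145)),
    shizukuishi = site_config(
      "shizukuishi", latitude = 39.7, t_mean = 9.2, t_amp = 12.5,
      t_peak_doy = 210, t_anom_sd = 2.2, diurnal_range = 9.5,
      clearness_mean = 0.44, clearness_amp = 0.03, clearness_peak_doy = 180,
      clearness_sd = 0.12, vp_frac = 0.90, wind_mean = 2.0,
      phenology = phenology_params(m_V = 48, m_R = 22, start_day = 125)))
}

with_preserved_seed <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  force(code)
}

#' Generate synthetic daily weather for a site
#'
#' Deterministic (seeded) daily series of global radiation, temperature
#' extremes, vapour pressure and wind. Temperature and clearness anomalies
#' follow AR(1) processes (coefficient 0.6) around the site's seasonal
#' climatology; radiation is the clearness index times the extraterrestrial
#' radiation for the site latitude, so it can never exceed the
#' extraterrestrial bound.
#'
#' @param site a [site_config()] object.
#' @param n_years number of years (>= 1).
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @param start_year calendar year label of the first year.
#' @return data frame with columns `year`, `doy`, `radiation_MJ`, `tmax_C`,
#'   `tmin_C`, `vap_kPa`, `wind_ms`.
#' @export
generate_weather <- function(site, n_years, seed, start_year = 2001) {
  stopifnot(inherits(site, "site_config"), n_years >= 1)
  with_preserved_seed({
    set.seed(seed)
    rows <- vector("list", n_years)
    ar <- 0.6
    innov_sd <- sqrt(1 - ar^2)
    a_t <- 0
    a_c <- 0
    for (y in seq_len(n_years)) {
      doy <- 1:365
      sol <- daylength_and_radiation(site$latitude, doy)
      t_clim <- site$t_mean +
        site$t_amp * cos(2 * pi * (doy - site$t_peak_doy) / 365)
      c_clim <- site$clearness_mean +
        site$clearness_amp * cos(2 * pi * (doy - site$clearness_peak_doy) / 365)
      tanom <- numeric(365)
      canom <- numeric(365)
      et <- rnorm(365, 0, site$t_anom_sd * innov_sd)
      ec <- rnorm(365, 0, site$clearness_sd * innov_sd)
      for (d in 1:365) {
        a_t <- ar * a_t + et[d]
        a_c <- ar * a_c + ec[d]
        tanom[d] <- a_t
        canom[d] <- a_c
      }
      tau <- pmin(pmax(c_clim + canom, 0.10), 0.75)
      tmean <- t_clim + tanom
      dtr <- pmax(site$diurnal_range + rnorm(365, 0, 1), 2)
      tmax <- tmean + dtr / 2
      tmin <- tmean - dtr / 2
      vp <- pmin(site$vp_frac * sat_vp(tmin) * exp(rnorm(365, 0, 0.03)),
                 sat_vp(tmin))
      wind <- pmax(site$wind_mean * exp(rnorm(365, 0, 0.3) - 0.045), 0.2)
      rows[[y]] <- data.frame(
        year = start_year + y - 1, doy = doy,
        radiation_MJ = tau * sol$S0_MJ, tmax_C = tmax, tmin_C = tmin,
        vap_kPa = vp, wind_ms = wind)
    }
    do.call(rbind, rows)
  })
}

#' Apply the 2050 climate transform
#'
#' Adds exactly 2 degC to the daily maximum and minimum temperatures,
#' leaves radiation and wind unchanged, scales vapour pressure by the shift
#' of the saturation curve at the daily mean temperature (preserving
#' relative humidity), and sets ambient CO2 to 550 umol mol-1.
#'
#' @param weather data frame from [generate_weather()].
#' @param co2_baseline present-day CO2 (umol mol-1), default 400.
#' @return the transformed data frame, with attributes `C_a` (550) and
#'   `C_a_baseline`.
#' @export
apply_climate_2050 <- function(weather, co2_baseline = 400) {
  tmean <- (weather$tmax_C + weather$tmin_C) / 2
  scale <- sat_vp(tmean + 2) / sat_vp(tmean)
  out <- weather
  out$tmax_C <- weather$tmax_C + 2
  out$tmin_C <- weather$tmin_C + 2
  out$vap_kPa <- weather$vap_kPa * scale
  attr(out, "C_a") <- 550
  attr(out, "C_a_baseline") <- co2_baseline
  out
}

#' Read or write the weather CSV dialect
#'
#' Columns: `year`, `doy`, `radiation_MJ`, `tmax_C`, `tmin_C`, `vap_kPa`,
#' `wind_ms`.
#'
#' @param weather a weather data frame.
#' @param file path.
#' @export
write_weather_csv <- function(weather, file) {
  write.csv(weather, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(file) {
  wx <- read.csv(file)
  need <- c("year", "doy", "radiation_MJ", "tmax_C", "tmin_C", "vap_kPa",
            "wind_ms")
  miss <- setdiff(need, names(wx))
  if (length(miss)) stop("weather file lacks columns: ",
                         paste(miss, collapse = ", "))
  wx
}
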