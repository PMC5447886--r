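## Solar geometry and radiation partitioning used by the canopy and
## weather modules.

#' Solar declination
#'
#' @param doy day of year (1-366).
#' @return declination (radians).
#' @export
solar_declination <- function(doy) {
  -23.45 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
}

#' Daylength, extraterrestrial radiation and solar course
#'
#' Standard solar geometry: declination, daylength from the sunset hour
#' angle (clamped for polar day/night), daily extraterrestrial radiation,
#' and helpers for the within-day solar elevation course.
#'
#' @param latitude degrees (positive north).
#' @param doy day of year.
#' @return list: `daylength` (h), `S0_MJ` (daily extraterrestrial radiation,
#'   MJ m-2 d-1), `declination` (rad), `sunrise` (solar hour).
#' @export
daylength_and_radiation <- function(latitude, doy) {
  lat <- latitude * pi / 180
  dec <- solar_declination(doy)
  x <- -tan(lat) * tan(dec)
  ws <- acos(pmin(pmax(x, -1), 1)) # sunset hour angle
  daylength <- 24 * ws / pi
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  S0 <- (24 * 3600 / pi) * 1367e-6 * dr *
    (ws * sin(lat) * sin(dec) + cos(lat) * cos(dec) * sin(ws))
  list(daylength = daylength, S0_MJ = pmax(S0, 0), declination = dec,
       sunrise = 12 - daylength / 2)
}

#' Sine of solar elevation at a solar hour
#'
#' @inheritParams daylength_and_radiation
#' @param hour solar hour (12 = solar noon).
#' @return `sin(beta)`, negative below the horizon.
#' @export
sin_solar_elevation <- function(latitude, doy, hour) {
  lat <- latitude * pi / 180
  dec <- solar_declination(doy)
  sin(lat) * sin(dec) + cos(lat) * cos(dec) * cos(pi * (hour - 12) / 12)
}

#' Daily diffuse fraction from atmospheric transmissivity
#'
#' Piecewise relation between the daily clearness index
#' (global / extraterrestrial radiation) and the diffuse fraction of global
#' radiation, of the form commonly used with daily weather records.
#'
#' @param tau daily atmospheric transmissivity in (0, 1).
#' @return diffuse fraction in (0, 1).
#' @export
diffuse_fraction_daily <- function(tau) {
  f <- ifelse(tau < 0.07, 1,
       ifelse(tau < 0.35, 1 - 2.3 * (tau - 0.07)^2,
       ifelse(tau < 0.75, 1.33 - 1.46 * tau, 0.23)))
  pmin(pmax(f, 0.1), 1)
}
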