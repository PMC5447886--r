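## Factorial scenario experiment: sites x climates x water modes x routes
## x years, plus the summary tables and regressions.

#' Experiment configuration
#'
#' @param sites named list of [site_config()] objects (default: the three
#'   built-in archetypes).
#' @param n_years years of synthetic weather per site.
#' @param seed integer seed for the weather generator.
#' @param climates subset of `c("present", "2050")`.
#' @param waters subset of `c("potential", "limited")`.
#' @param route_ids integer vector of route ids.
#' @param C_a_present present-day CO2 (umol mol-1).
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(sites = site_presets(), n_years = 5,
                              seed = 1, climates = c("present", "2050"),
                              waters = c("potential", "limited"),
                              route_ids = 0:9, C_a_present = 400) {
  stopifnot(length(sites) > 0, n_years >= 1, length(climates) > 0,
            length(waters) > 0, length(route_ids) > 0)
  structure(list(sites = sites, n_years = n_years, seed = seed,
                 climates = climates, waters = waters,
                 route_ids = route_ids, C_a_present = C_a_present),
            class = "experiment_config")
}

#' Run the full factorial experiment
#'
#' For every site the same seeded weather series underlies all climates,
#' water modes and routes (the 2050 series is the transform of the present
#' series), so route contrasts within a stratum are paired. Water-limited
#' cells reuse the potential run of the same cell to set the 50% water
#' supply, so each cell costs one potential season plus (if requested) one
#' water-limited season.
#'
#' @param config an [experiment_config()] object.
#' @param progress print progress lines?
#' @return a `trait_table` data frame: one row per
#'   (site, climate, water, route, year) with the season traits and a
#'   `weather_checksum` identifying the weather realisation.
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  site_names <- names(config$sites)
  for (si in seq_along(config$sites)) {
    site <- config$sites[[si]]
    ## one extra year so late-start seasons can run across new year
    wx_all <- generate_weather(site, config$n_years + 1,
                               seed = config$seed + 1000 * si)
    years <- sort(unique(wx_all$year))[seq_len(config$n_years)]
    for (cl in config$climates) {
      for (yr in years) {
        wx <- wx_all[wx_all$year >= yr, ]
        C_a <- config$C_a_present
        if (cl == "2050") {
          wx <- apply_climate_2050(wx, config$C_a_present)
          C_a <- attr(wx, "C_a")
        }
        season_rows <- wx$year == yr
        chk <- round(sum(wx$radiation_MJ[season_rows]) +
                       sum(wx$tmax_C[season_rows]), 3)
        for (id in config$route_ids) {
          route <- build_route(id)
          pot <- run_season(wx, site, route, water = "potential", C_a = C_a)
          for (wmode in config$waters) {
            res <- if (wmode == "potential") pot else {
              supply <- 0.5 * pot$transpiration / pot$days_to_maturity
              run_season(wx, site, route, water = "limited", C_a = C_a,
                         water_supply_mm = supply)
            }
            rows[[length(rows) + 1]] <- data.frame(
              site = site_names[si], climate = cl, water = wmode,
              route = id, year = yr,
              days_to_flowering = res$days_to_flowering,
              days_to_maturity = res$days_to_maturity,
              shoot_mass = res$shoot_mass, mass_root = res$mass_root,
              A_canopy_s = res$A_canopy_s, PAR_int = res$PAR_int,
              PLUE = res$PLUE, RESP = res$RESP, F_root = res$F_root,
              SENES = res$SENES, transpiration = res$transpiration,
              WUE = res$WUE, weather_checksum = chk)
          }
          if (progress) {
            message(sprintf("%s %s %d route %d done", site_names[si], cl,
                            yr, id))
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Average traits over years
#'
#' @param traits a `trait_table`.
#' @return data frame averaged over years per (site, climate, water,
#'   route).
#' @export
average_traits <- function(traits) {
  num <- c("days_to_flowering", "days_to_maturity", "shoot_mass",
           "mass_root", "A_canopy_s", "PAR_int", "PLUE", "RESP", "F_root",
           "SENES", "transpiration", "WUE")
  aggregate(traits[num],
            by = traits[c("site", "climate", "water", "route")], FUN = mean)
}

#' Percentage change of multi-year average traits relative to a baseline
#'
#' Traits are first averaged over years within each
#' (site, climate, water, route) cell; the change of each route relative to
#' the baseline route is then `100 (mean_route - mean_base) / mean_base`.
#'
#' @param traits a `trait_table`.
#' @param baseline baseline route id (default 0).
#' @param trait_cols traits to difference.
#' @return data frame of percentage changes per stratum, route and trait.
#' @export
percent_change_table <- function(traits, baseline = 0,
                                 trait_cols = c("shoot_mass", "A_canopy_s",
                                                "PAR_int", "PLUE", "RESP",
                                                "F_root", "SENES", "WUE")) {
  av <- average_traits(traits)
  strata <- unique(av[c("site", "climate", "water")])
  rows <- list()
  for (k in seq_len(nrow(strata))) {
    sel <- av$site == strata$site[k] & av$climate == strata$climate[k] &
      av$water == strata$water[k]
    sub <- av[sel, ]
    base <- sub[sub$route == baseline, ]
    if (nrow(base) != 1) stop("baseline route missing in a stratum")
    for (r in sub$route) {
      rr <- sub[sub$route == r, ]
      pc <- vapply(trait_cols, function(tc) {
        b <- base[[tc]]
        if (abs(b) < 1e-12) NA_real_ else 100 * (rr[[tc]] - b) / b
      }, numeric(1))
      rows[[length(rows) + 1]] <- cbind(
        data.frame(site = strata$site[k], climate = strata$climate[k],
                   water = strata$water[k], route = r),
        as.data.frame(as.list(pc)))
    }
  }
  do.call(rbind, rows)
}

#' Trait decomposition of a trait table
#'
#' Recomputes shoot mass from
#' `(PAR_int x PLUE - RESP) (30/44) (1 - F_root) - SENES` for every row and
#' appends the reconstruction and its residual (small positive offset from
#' the initial seedling mass is absorbed in the residual).
#'
#' @param traits a `trait_table`.
#' @return the table with `mass_pred`, `residual`, `residual_frac` columns.
#' @export
trait_decomposition <- function(traits) {
  growth <- (traits$PAR_int * traits$PLUE - traits$RESP) * .CH2O_PER_CO2
  pred <- growth * (1 - traits$F_root) - traits$SENES
  traits$mass_pred <- pred
  traits$residual <- pred - traits$shoot_mass
  traits$residual_frac <- traits$residual / pmax(traits$shoot_mass, 1e-9)
  traits
}

check_full_rank <- function(X) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("regression design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
}

#' Regression of mass on the five component traits
#'
#' Ordinary least squares of multi-year-average shoot mass on `PAR_int`,
#' `PLUE`, `RESP`, `F_root` and `SENES`, fitted separately for the
#' potential stratum, the water-limited stratum, and the pooled data.
#'
#' @param traits a `trait_table`.
#' @return named list (`potential`, `limited`, `pooled`) of lists with
#'   `coefficients`, `p_values`, `r_squared`, `n` and the design condition
#'   number `kappa`.
#' @export
fit_mass_regression <- function(traits) {
  av <- average_traits(traits)
  fit_one <- function(dat) {
    if (nrow(dat) < 10) stop("need at least 10 rows for the regression")
    X <- stats::model.matrix(~ PAR_int + PLUE + RESP + F_root + SENES, dat)
    check_full_rank(X)
    fm <- lm(shoot_mass ~ PAR_int + PLUE + RESP + F_root + SENES, data = dat)
    sm <- summary(fm)
    list(coefficients = coef(fm), p_values = sm$coefficients[, 4],
         r_squared = sm$r.squared, n = nrow(dat), kappa = kappa(X),
         model = fm)
  }
  list(potential = fit_one(av[av$water == "potential", ]),
       limited = fit_one(av[av$water == "limited", ]),
       pooled = fit_one(av))
}

#' Regression of light-use efficiency on biochemical parameters
#'
#' For the C4-family routes (4-9), regresses multi-year-average PLUE on the
#' bundle-sheath conductance slope, the total ATP requirement per CO2
#' (`3 + phi`) and the `Jmax` nitrogen slope, with site as a covariate
#' (first site as the reference level), separately for each
#' water-mode x climate stratum.
#'
#' @param traits a `trait_table`.
#' @param reference_site site name used as the dummy-coding reference
#'   (default `"los_banos"`).
#' @return named list over strata (`water.climate`) with `coefficients`,
#'   `p_values`, `r_squared`, `n`.
#' @export
fit_plue_regression <- function(traits, reference_site = "los_banos") {
  av <- average_traits(traits)
  av <- av[av$route %in% 4:9, ]
  cov <- do.call(rbind, lapply(av$route, function(id) {
    route_biochem_covariates(build_route(id))
  }))
  av <- cbind(av, cov)
  lv <- unique(c(reference_site, sort(unique(av$site))))
  av$site <- factor(av$site, levels = lv[lv %in% av$site])
  out <- list()
  for (w in unique(av$water)) {
    for (cl in unique(av$climate)) {
      dat <- av[av$water == w & av$climate == cl, ]
      X <- stats::model.matrix(~ site + chi_gbs25 + ATP_req + chi_Jmax25,
                               dat)
      check_full_rank(X)
      fm <- lm(PLUE ~ site + chi_gbs25 + ATP_req + chi_Jmax25, data = dat)
      sm <- summary(fm)
      out[[paste(w, cl, sep = ".")]] <- list(
        coefficients = coef(fm), p_values = sm$coefficients[, 4],
        r_squared = sm$r.squared, n = nrow(dat))
    }
  }
  out
}
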