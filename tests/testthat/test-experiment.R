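tiny_config <- function() {
  experiment_config(sites = site_presets()["los_banos"], n_years = 1,
                    seed = 3, climates = c("present", "2050"),
                    waters = c("potential", "limited"),
                    route_ids = c(0, 9))
}

test_that("the factorial produces a complete, weather-paired trait table", {
  tt <- run_experiment(tiny_config())
  expect_s3_class(tt, "trait_table")
  expect_equal(nrow(tt), 1 * 1 * 2 * 2 * 2) # climates x waters x routes
  expect_false(any(is.na(tt$shoot_mass)))
  ## paired weather: both routes share the same realisation in a stratum
  for (cl in c("present", "2050")) {
    chk <- unique(tt$weather_checksum[tt$climate == cl])
    expect_length(chk, 1)
  }
  ## phenology is unaffected by water limitation
  base <- tt[tt$water == "potential", ]
  lim <- tt[tt$water == "limited", ]
  expect_equal(lim$days_to_maturity[order(lim$climate, lim$route)],
               base$days_to_maturity[order(base$climate, base$route)])
})

test_that("percentage changes are zero at baseline and exact for planted ratios", {
  tt <- data.frame(site = "s", climate = "present",
                   water = rep(c("potential", "limited"), each = 4),
                   route = rep(c(0, 0, 1, 1), 2),
                   year = rep(c(1, 2), 4),
                   days_to_flowering = 70, days_to_maturity = 100,
                   shoot_mass = c(100, 120, 150, 180, 50, 70, 90, 90),
                   mass_root = 1, A_canopy_s = 1, PAR_int = 1, PLUE = 1,
                   RESP = 1, F_root = 0.1, SENES = 1, transpiration = 1,
                   WUE = 1, weather_checksum = 0)
  pc <- percent_change_table(tt, trait_cols = "shoot_mass")
  expect_equal(pc$shoot_mass[pc$route == 0], c(0, 0))
  ## route mean 165 vs baseline mean 110 -> +50%; 90 vs 60 -> +50%
  expect_equal(pc$shoot_mass[pc$route == 1], c(50, 50))
  ## zero baseline is flagged, not divided
  tt$PLUE <- 0
  pc2 <- percent_change_table(tt, trait_cols = "PLUE")
  expect_true(all(is.na(pc2$PLUE)))
})

test_that("trait decomposition reconstructs mass and tracks perturbations", {
  site <- site_presets()$los_banos
  wx <- generate_weather(site, 2, seed = 12)
  res <- run_season(wx, site, build_route(0))
  row <- data.frame(site = "s", climate = "present", water = "potential",
                    route = 0, year = 1, shoot_mass = res$shoot_mass,
                    A_canopy_s = res$A_canopy_s, PAR_int = res$PAR_int,
                    PLUE = res$PLUE, RESP = res$RESP, F_root = res$F_root,
                    SENES = res$SENES)
  td <- trait_decomposition(row)
  ## residual equals the initial seedling shoot mass (small)
  expect_lt(abs(td$residual_frac), 0.01)
  ## +10% PLUE raises reconstructed mass by the closed-form amount
  row2 <- row
  row2$PLUE <- row$PLUE * 1.1
  td2 <- trait_decomposition(row2)
  dmass <- 0.1 * row$PLUE * row$PAR_int * (30 / 44) * (1 - row$F_root)
  expect_equal(td2$mass_pred - td$mass_pred, dmass, tolerance = 1e-9)
})

test_that("mass regression recovers planted coefficients exactly on noiseless data", {
  set.seed(55)
  n <- 30
  make_stratum <- function(water) {
    X <- data.frame(PAR_int = runif(n, 500, 900),
                    PLUE = runif(n, 5, 8), RESP = runif(n, 1000, 2000),
                    F_root = runif(n, 0.1, 0.3), SENES = runif(n, 50, 300))
    b <- c(-3000, 4, 400, -0.3, -2000, -1)
    mass <- b[1] + b[2] * X$PAR_int + b[3] * X$PLUE + b[4] * X$RESP +
      b[5] * X$F_root + b[6] * X$SENES
    cbind(data.frame(site = paste0("s", seq_len(n)), climate = "present",
                     water = water, route = seq_len(n), year = 1,
                     days_to_flowering = 1, days_to_maturity = 1,
                     shoot_mass = mass, mass_root = 1, A_canopy_s = 1,
                     transpiration = 1, WUE = 1, weather_checksum = 0), X)
  }
  tt <- rbind(make_stratum("potential"), make_stratum("limited"))
  fit <- suppressWarnings(fit_mass_regression(tt))
  b <- c(-3000, 4, 400, -0.3, -2000, -1)
  for (stratum in fit) {
    expect_equal(unname(stratum$coefficients), b, tolerance = 1e-8)
    expect_equal(stratum$r_squared, 1, tolerance = 1e-10)
  }
  ## collinear designs are rejected with the offending column named
  tt$SENES <- 2 * tt$PLUE
  expect_error(fit_mass_regression(tt), "SENES")
})

test_that("light-use-efficiency regression uses reference-site dummy coding", {
  set.seed(9)
  rows <- expand.grid(site = c("los_banos", "nanjing", "shizukuishi"),
                      route = 4:9, stringsAsFactors = FALSE)
  cov <- do.call(rbind, lapply(rows$route, function(id) {
    route_biochem_covariates(build_route(id))
  }))
  b <- c(10, -12, -1.2, 0.015) # intercept, chi_gbs25, ATP_req, chi_Jmax25
  plue <- b[1] + b[2] * cov$chi_gbs25 + b[3] * cov$ATP_req +
    b[4] * cov$chi_Jmax25
  tt <- data.frame(site = rows$site, climate = "present",
                   water = "potential", route = rows$route, year = 1,
                   days_to_flowering = 1, days_to_maturity = 1,
                   shoot_mass = 1, mass_root = 1, A_canopy_s = 1,
                   PAR_int = 1, PLUE = plue, RESP = 1, F_root = 0.1,
                   SENES = 1, transpiration = 1, WUE = 1,
                   weather_checksum = 0)
  fit <- suppressWarnings(fit_plue_regression(tt))$potential.present
  expect_equal(fit$n, 18)
  co <- fit$coefficients
  ## site terms vanish on noiseless site-free data; slopes are recovered
  expect_equal(unname(co["(Intercept)"]), 10, tolerance = 1e-8)
  expect_equal(unname(co["chi_gbs25"]), -12, tolerance = 1e-8)
  expect_equal(unname(co["ATP_req"]), -1.2, tolerance = 1e-8)
  expect_equal(unname(co["chi_Jmax25"]), 0.015, tolerance = 1e-8)
  expect_equal(unname(co["sitenanjing"]), 0, tolerance = 1e-8)
  ## the reference site has no dummy of its own
  expect_false("sitelos_banos" %in% names(co))
})
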