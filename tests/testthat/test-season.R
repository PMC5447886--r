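phen_std <- function() phenology_params(m_V = 70, m_R = 28, start_day = 10)

test_that("thermal days integrate the beta temperature response", {
  ph <- phen_std()
  ## a day at the optimum contributes exactly one thermal day
  expect_equal(thermal_day_increment(30, 30, ph), 1)
  expect_equal(thermal_day_increment(8, 8, ph), 0)
  expect_equal(thermal_day_increment(5, 1, ph), 0)
  expect_equal(thermal_day_increment(42, 42, ph), 0)
  ## constant mid-range temperature: direct closed-form beta evaluation
  Tm <- (8 + 30) / 2
  ex <- (30 - 8) / (42 - 30)
  direct <- ((42 - Tm) / (42 - 30)) * ((Tm - 8) / (30 - 8))^ex
  expect_equal(thermal_day_increment(Tm, Tm, ph), direct, tolerance = 1e-9)
  expect_equal(beta_temp_response(30, ph), 1)
})

test_that("phenology reaches flowering and maturity on schedule at optimal temperature", {
  ph <- phen_std()
  stage <- 0
  fl <- NA
  for (d in 1:120) {
    stage <- advance_phenology(stage, 1, ph)
    if (is.na(fl) && stage >= 1) fl <- d
    if (stage >= 2) break
  }
  expect_equal(fl, 70)
  expect_equal(d, 70 + 28)
})

test_that("cooler weather lengthens crop duration at identical phenology settings", {
  site_t <- site_presets()$los_banos
  site_c <- site_presets()$nanjing
  site_c$phenology <- site_t$phenology # same thermal requirements
  site_c$phenology$start_day <- 145    # emergence in the warm season
  wx_t <- generate_weather(site_t, 2, seed = 21)
  wx_c <- generate_weather(site_c, 2, seed = 21)
  r <- build_route(0)
  s_t <- run_season(wx_t, site_t, r)
  s_c <- run_season(wx_c, site_c, r)
  expect_gt(s_c$days_to_maturity, s_t$days_to_maturity)
})

test_that("nitrogen uptake follows a sigmoid reaching 20 g N m-2 at maturity", {
  stages <- seq(0, 2, by = 0.01)
  inc <- n_uptake_daily(stages[-length(stages)], stages[-1])
  expect_true(all(inc >= 0))
  expect_equal(sum(inc), 20, tolerance = 0.01)
  ## single inflection: the increment rises then falls
  i <- which.max(inc)
  expect_gt(i, 5)
  expect_lt(i, length(inc) - 5)
  expect_true(all(diff(inc[1:i]) >= -1e-12))
  expect_true(all(diff(inc[i:length(inc)]) <= 1e-12))
})

test_that("senescence removes leaf area at the prescribed relaxation rate", {
  st <- list(LAI_C = 3, mass_leaf = 100, mass_dead = 0, N_leaf = 6,
             SENES = 0)
  ## ample nitrogen: no senescence
  st1 <- update_lai_and_senescence(st, 0, k_N = 0.6, n_b = 0.3)
  expect_equal(st1$SENES, 0)
  expect_equal(st1$LAI, min(3, st1$LAI_N))
  ## nitrogen-poor canopy: shed (LAI_C - LAI_N)/TC_S per day
  st$N_leaf <- 0.8
  lai_n <- lai_n_determined(0.8, 0.6, 0.3)
  st2 <- update_lai_and_senescence(st, 0, k_N = 0.6, n_b = 0.3)
  expect_equal(st2$LAI_C, 3 - (3 - lai_n) / 2, tolerance = 1e-12)
  expect_equal(st2$SENES, (3 - lai_n) / 2 * (100 / 3), tolerance = 1e-12)
  ## with zero leaf N the gap relaxes with time constant TC_S = 2 days
  st$N_leaf <- 0
  gap <- st$LAI_C
  for (k in 1:6) {
    st <- update_lai_and_senescence(st, 0, k_N = 0.6, n_b = 0.3)
  }
  expect_equal(st$LAI_C, gap * (1 - 1 / 2)^6, tolerance = 1e-9)
})

test_that("respiration components behave as specified", {
  z <- respiration_daily(0, 0, 25)
  expect_equal(z$growth + z$maint, 0)
  ## growth respiration is (1 - Y_G) of allocatable assimilate
  r <- respiration_daily(10, 0, 25)
  expect_equal(r$growth, 2.5)
  expect_equal(r$new_DM, 7.5)
  ## maintenance increases with crop N
  m <- vapply(c(0, 5, 10, 20), function(N) {
    respiration_daily(10, N, 25)$maint
  }, numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("root fraction respects bounds and rises with carbon surplus", {
  set.seed(4)
  for (k in 1:50) {
    f <- partition_root_shoot(runif(1, 0, 2), runif(1, 0.002, 0.06))
    expect_gte(f, 0.05)
    expect_lte(f, 0.6)
  }
  ## lower shoot N concentration (carbon surplus) -> more roots
  expect_gt(partition_root_shoot(1, 0.008), partition_root_shoot(1, 0.02))
  ## late-stage balanced crop sits near the baseline minimum
  expect_lt(partition_root_shoot(1.9, 0.03), 0.1)
})

test_that("a full season closes its carbon books and responds to water limitation", {
  site <- site_presets()$los_banos
  wx <- generate_weather(site, 2, seed = 12)
  r <- build_route(0)
  pot <- run_season(wx, site, r)
  dec <- season_mass_decomposition(pot)
  expect_lt(abs(dec$residual_frac), 0.01)
  ## carbon mass balance: net assimilate converted to dry matter equals
  ## total biomass growth
  growth <- (pot$shoot_mass - pot$init_shoot) + pot$SENES +
    (pot$mass_root - pot$init_root)
  expect_lt(abs((pot$A_canopy_s - pot$RESP) * 30 / 44 - growth) /
              growth, 0.01)
  lim <- run_season(wx, site, r, water = "limited")
  expect_lt(lim$shoot_mass, pot$shoot_mass)
  expect_gt(lim$WUE, pot$WUE)
  expect_equal(lim$days_to_maturity, pot$days_to_maturity) # drought does
  ## not alter phenology
  expect_lte(lim$transpiration,
             lim$water_supply_mm * lim$days_to_maturity * 1.05)
})

test_that("season results surface the traits needed for decomposition", {
  site <- site_presets()$los_banos
  wx <- generate_weather(site, 2, seed = 12)
  res <- run_season(wx, site, build_route(2))
  expect_true(all(c("days_to_flowering", "days_to_maturity", "shoot_mass",
                    "A_canopy_s", "PAR_int", "PLUE", "RESP", "F_root",
                    "SENES", "transpiration", "WUE") %in% names(res)))
  expect_equal(res$PLUE, res$A_canopy_s / res$PAR_int)
  expect_gt(res$F_root, 0.05)
  expect_lt(res$F_root, 0.6)
  expect_gt(res$days_to_maturity, res$days_to_flowering)
  expect_output(print(res), "season_result")
})
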