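test_that("sunlit/shaded partition conserves absorbed PAR and leaf area", {
  set.seed(11)
  for (k in 1:25) {
    cs <- canopy_state(LAI = runif(1, 0.1, 8), n_avg = runif(1, 0.8, 3),
                       leaf_angle = runif(1, 20, 80))
    sb <- runif(1, 0.05, 1)
    Ib <- runif(1, 0, 1800)
    Id <- runif(1, 0, 600)
    p <- sunlit_shaded_partition(cs, sb, Ib, Id)
    expect_lt(abs(sum(p$abs_par) - attr(p, "abs_total")), 1e-9)
    expect_equal(sum(p$lai), cs$LAI, tolerance = 1e-12)
    expect_true(all(p$abs_par >= 0))
    expect_lte(attr(p, "abs_total"), Ib + Id + 1e-9)
    expect_equal(sum(p$N_photo), (cs$n_avg - cs$n_b) * cs$LAI,
                 tolerance = 1e-9)
  }
})

test_that("vanishing canopies are entirely sunlit and absorb nothing", {
  cs <- canopy_state(LAI = 1e-6, n_avg = 2.3)
  p <- sunlit_shaded_partition(cs, 0.7, 1500, 300)
  expect_equal(p$lai[1] / sum(p$lai), 1, tolerance = 1e-4)
  expect_lt(attr(p, "abs_total"), 1)
  ## below the horizon nothing is absorbed
  p0 <- sunlit_shaded_partition(canopy_state(5, 2.3), -0.1, 1500, 300)
  expect_equal(attr(p0, "abs_total"), 0)
})

test_that("black-leaf sunlit area follows the closed form", {
  cs <- canopy_state(LAI = 5, n_avg = 2.3, scattering = 0)
  sb <- 0.9
  kb <- beam_extinction(sb, 65)
  p <- sunlit_shaded_partition(cs, sb, 1000, 0)
  expect_equal(p$lai[1], (1 - exp(-kb * 5)) / kb, tolerance = 1e-12)
  ## with no scattering all intercepted beam is absorbed by sunlit leaves
  expect_equal(p$abs_par[1], 1000 * (1 - exp(-kb * 5)), tolerance = 1e-6)
})

test_that("Gaussian day integration is exact for polynomials and accurate for skewed courses", {
  expect_equal(gauss_integrate_day(function(t) rep(3.2, length(t)), 13),
               3.2 * 13)
  D <- 13.7
  expect_equal(gauss_integrate_day(function(t) t^4, D), D^5 / 5,
               tolerance = 1e-12)
  expect_equal(gauss_integrate_day(function(t) (D - t)^9, D), D^10 / 10,
               tolerance = 1e-9)
  ## skewed diurnal-like course vs dense trapezoid
  f <- function(t) pmax(sin(pi * t / D), 0)^1.3 * (1 + 0.3 * t / D)
  tt <- seq(0, D, length.out = 1001)
  trap <- sum(diff(tt) * (f(tt[-1]) + f(tt[-1001])) / 2)
  expect_equal(gauss_integrate_day(f, D), trap, tolerance = 1e-3)
})

test_that("instantaneous canopy flux matches a 100-layer integration within 5%", {
  cs <- canopy_state(LAI = 5, n_avg = 2.3, leaf_angle = 65)
  sb <- sin(70 * pi / 180) # near solar noon
  Ib <- 1400
  Id <- 350
  for (id in c(0, 6)) {
    p <- build_route(id)$params
    part <- sunlit_shaded_partition(cs, sb, Ib, Id)
    inst <- instantaneous_canopy_flux(part, p, T_air = 25, vp = 2, wind = 2,
                                      C_a = 400,
                                      prescribe = list(T_l = 25, VPD = 2))
    A_ml <- multilayer_canopy_A(cs, sb, Ib, Id, p, C_a = 400)
    expect_lt(abs(inst$A - A_ml) / abs(A_ml), 0.05)
  }
})

test_that("a dark canopy respires and a degenerate canopy matches the leaf solver", {
  cs <- canopy_state(LAI = 3, n_avg = 2.3)
  part <- sunlit_shaded_partition(cs, 0.5, 0, 0)
  p <- c3_default_params()
  inst <- instantaneous_canopy_flux(part, p, 25, 1.5, 2, 400,
                                    prescribe = list(T_l = 25, VPD = 2))
  Rd_canopy <- arrhenius(p$chi_Rd25 * (2.3 - 0.3) * 3, p$E_Rd, 25)
  expect_equal(inst$A, -Rd_canopy, tolerance = 1e-3)
  ## single-class consistency: a canopy thin enough to be all sunlit and
  ## optically uniform behaves as leaf area times the single-leaf rate
  cs0 <- canopy_state(LAI = 0.01, n_avg = 2.3)
  part0 <- sunlit_shaded_partition(cs0, 0.9, 1200, 100)
  expect_gt(part0$lai[1] / 0.01, 0.995)
  inst0 <- instantaneous_canopy_flux(part0, p, 25, 1.5, 2, 400,
                                     prescribe = list(T_l = 25, VPD = 2))
  nodes <- attr(part0, "nodes")
  qbar <- sum(nodes$q * nodes$w_area) / sum(nodes$w_area)
  A_leaf <- solve_leaf(leaf_env(I_inc = qbar, C_a = 400, T_l = 25, VPD = 2,
                                n_leaf = 2.3, absorptance = 1), p)$A
  expect_equal(inst0$A, A_leaf * 0.01, tolerance = 0.01)
})

test_that("daily canopy photosynthesis responds monotonically to radiation and LAI", {
  p <- c3_default_params()
  day <- function(S) list(radiation_MJ = S, tmax_C = 25, tmin_C = 25,
                          vap_kPa = sat_vp(25) - 2, wind_ms = 2, doy = 135)
  pres <- list(T_l = 25, VPD = 2)
  A_S <- vapply(c(2, 8, 16, 24, 30), function(S) {
    daily_canopy_photosynthesis(day(S), canopy_state(3, 2.3), p, 25,
                                diffuse = 0.2, prescribe = pres)$A_gCO2
  }, numeric(1))
  expect_true(all(diff(A_S) > 0))
  A_L <- vapply(c(0.5, 1, 2, 3, 5, 7), function(L) {
    daily_canopy_photosynthesis(day(18), canopy_state(L, 2.3), p, 25,
                                diffuse = 0.2, prescribe = pres)$A_gCO2
  }, numeric(1))
  expect_true(all(diff(A_L) > 0))
  ## without radiation only respiration remains
  A0 <- daily_canopy_photosynthesis(day(0), canopy_state(3, 2.3), p, 25,
                                    diffuse = 0.2, prescribe = pres)$A_gCO2
  expect_lte(A0, 0)
})

test_that("light response of daily canopy photosynthesis flattens in curvature as LAI grows", {
  p <- c3_default_params()
  S <- c(5, 15, 25)
  pres <- list(T_l = 25, VPD = 2)
  curvature <- vapply(c(1, 3, 5, 7), function(L) {
    A <- vapply(S, function(s) {
      day <- list(radiation_MJ = s, tmax_C = 25, tmin_C = 25,
                  vap_kPa = sat_vp(25) - 2, wind_ms = 2, doy = 135)
      daily_canopy_photosynthesis(day, canopy_state(L, 2.3), p, 25,
                                  diffuse = 0.2, prescribe = pres)$A_gCO2
    }, numeric(1))
    ## relative deviation of the midpoint from the chord (0 = linear)
    (A[2] - (A[1] + A[3]) / 2) / (A[3] - A[1])
  }, numeric(1))
  expect_true(all(diff(curvature) < 0))
})

test_that("water-limited daily transpiration respects the supplied water", {
  p <- c3_default_params()
  cs <- canopy_state(4, 2.3)
  day <- list(radiation_MJ = 22, tmax_C = 32, tmin_C = 22,
              vap_kPa = 2.0, wind_ms = 2, doy = 180)
  pot <- daily_canopy_photosynthesis(day, cs, p, 30)
  supply <- 0.4 * pot$E_mm
  lim <- daily_canopy_photosynthesis(day, cs, p, 30,
                                     water_supply_mm = supply)
  expect_lte(lim$E_mm, supply * 1.05)
  expect_lte(lim$A_gCO2, lim$A_gCO2_pot)
  expect_equal(lim$A_gCO2_pot, pot$A_gCO2)
})
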