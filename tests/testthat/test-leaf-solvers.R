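fig1_env <- function(I_inc, n_leaf = 2.3, ...) {
  leaf_env(I_inc = I_inc, C_a = 400, T_l = 25, VPD = 2, n_leaf = n_leaf,
           absorptance = 0.85, ...)
}

test_that("limitation-branch rates evaluate the biochemistry directly", {
  p <- c3_default_params()
  at <- params_at_leaf_T(p, 25, 2.3)
  GammaStar <- at$gamma_star * 210000
  ## Rubisco-limited rate at Cc = 300, direct hand evaluation
  x2 <- at$KmC * (1 + 210 / at$KmO)
  expect_equal(c3_limited_rate(300, 210, "Ac", at, p),
               (300 - GammaStar) * 150 / (300 + x2) - 1.5)
  J2 <- j2_rate(1500 * 0.85, at$Jmax, at$phi2LL_T, p$f_cyc, p$r2_1,
                p$theta)
  x1j <- (1 - p$f_pseudo / (1 - p$f_cyc)) * J2 / 4
  expect_equal(c3_limited_rate(300, 210, "Aj", at, p, J2 = J2),
               (300 - GammaStar) * x1j / (300 + 2 * 210000 * at$gamma_star)
               - 1.5)
  ## both branches return exactly -Rd at the compensation point
  expect_equal(c3_limited_rate(GammaStar, 210, "Ac", at, p), -at$Rd)
  expect_equal(c3_limited_rate(GammaStar, 210, "Aj", at, p, J2 = J2),
               -at$Rd)
  ## Rubisco-limited rate saturates at Vcmax - Rd
  expect_equal(c3_limited_rate(1e9, 210, "Ac", at, p), at$Vcmax - at$Rd,
               tolerance = 1e-5)
})

test_that("PEP carboxylation takes the minimum of enzyme and ATP-limited branches", {
  p <- c4_default_params()
  at <- params_at_leaf_T(p, 25, 2.3)
  expect_equal(at$z, 2.55 / 2.2) # (2 + f_Q - f_cyc) / (h (1 - f_cyc))
  expect_equal(vp_rate(0, 300, at, p)$Vp, 0)
  expect_identical(vp_rate(0, 300, at, p)$limitation, "enzyme")
  v <- vp_rate(500, 300, at, p)
  expect_equal(v$Vp, min(at$eps_p * 500, 0.4 * 300 * at$z / 2))
  expect_equal(x_from_phi(2), 0.4) # x arises from phi/(3 + phi)
})

test_that("dark leaves respire at Rd with stomata at g0", {
  for (id in c(0, 4, 6, 8, 9)) {
    p <- build_route(id)$params
    fl <- solve_leaf(fig1_env(0), p)
    at <- params_at_leaf_T(p, 25, 2.3)
    expect_equal(fl$A, -at$Rd, tolerance = 1e-9)
    expect_equal(fl$gs, p$g0, tolerance = 1e-9)
  }
  ## leaf nitrogen at the base value: no photosynthetic machinery
  p <- c3_default_params()
  fl <- solve_leaf(fig1_env(1500, n_leaf = 0.3), p)
  expect_equal(fl$A, 0)
  expect_equal(fl$gs, p$g0)
})

test_that("removing the diffusion limits recovers the biochemistry at Cc = Ca", {
  p <- photo_params(c3_default_params(), chi_gm25 = 1e6)
  env <- fig1_env(1500, g_b = 1e6)
  fl <- solve_leaf_given_gs(1e6, env, p)
  expect_equal(fl$Cc, 400, tolerance = 1e-3)
  at <- params_at_leaf_T(p, 25, 2.3)
  J2 <- j2_rate(1500 * 0.85, at$Jmax, at$phi2LL_T, p$f_cyc, p$r2_1,
                p$theta)
  A_direct <- min(c3_limited_rate(400, 210, "Ac", at, p),
                  c3_limited_rate(400, 210, "Aj", at, p, J2 = J2))
  expect_equal(fl$A, A_direct, tolerance = 1e-4)
})

test_that("coupled C3 solution matches the brute-force oracle at the standard conditions", {
  p <- c3_default_params()
  fl <- solve_c3_leaf(fig1_env(1500), p)
  A_or <- oracle_leaf_A(1500, 400, 25, 2, 2.3, p)
  expect_equal(fl$A, A_or, tolerance = 1e-6)
  ## solution satisfies the stomatal submodel and the diffusion chain
  at <- params_at_leaf_T(p, 25, 2.3)
  Ci_star <- at$gamma_star * 210000 - at$Rd / at$gm
  expect_equal(fl$gs,
               p$g0 + (fl$A + at$Rd) * fvpd(2) / (fl$Ci - Ci_star),
               tolerance = 1e-7)
  expect_equal(fl$Ci, 400 - fl$A * (1 / 3 + 1 / fl$gs), tolerance = 1e-7)
  expect_equal(fl$Cc, fl$Ci - fl$A / at$gm, tolerance = 1e-7)
})

test_that("converged C4 solutions satisfy the bundle-sheath mass balance", {
  for (id in c(4, 6, 7, 8, 9)) {
    p <- build_route(id)$params
    fl <- solve_c4_leaf(fig1_env(c(150, 800, 1500)), p)
    Rm <- p$Rm_factor * fl$Rd
    expect_lt(max(abs(fl$A - (fl$Vp - fl$L - Rm))), 1e-8)
  }
  ## route 6 at saturating light agrees with the nested-root-find oracle
  p <- build_route(6)$params
  fl <- solve_c4_leaf(fig1_env(1500), p)
  expect_equal(fl$A, oracle_leaf_A(1500, 400, 25, 2, 2.3, p),
               tolerance = 1e-6)
})

test_that("solving at the solver's own stomatal conductance reproduces A (round trip)", {
  for (id in c(0, 3, 6, 9)) {
    p <- build_route(id)$params
    env <- fig1_env(c(200, 1000, 1800))
    fl <- solve_leaf(env, p)
    fl2 <- solve_leaf_given_gs(fl$gs, env, p)
    expect_lt(max(abs(fl2$A - fl$A)), 1e-8)
  }
})

test_that("assimilation is non-decreasing in irradiance and ambient CO2 for all routes", {
  for (id in 0:9) {
    p <- build_route(id)$params
    A_I <- solve_leaf(fig1_env(seq(0, 2000, by = 100)), p)$A
    expect_true(all(diff(A_I) > -1e-8))
    A_C <- solve_leaf(leaf_env(I_inc = 1200, C_a = seq(150, 900, by = 50),
                               T_l = 25, VPD = 2, n_leaf = 2.3), p)$A
    expect_true(all(diff(A_C) > -1e-8))
  }
})

test_that("CCM model collapses to the C3 model when its CCM is switched off", {
  ## huge envelope conductance, no CCM ATP cost, C3 cyclic fraction:
  ## Cc approaches Ci and the C4 structure should mimic the C3 leaf
  p <- make_ccm_params()
  p <- photo_params(p, chi_gbs25 = 1e4, phi_ccm = 0, x_atp = 0,
                    f_cyc = 0.05, f_pseudo = 0.10, Rm_factor = 0)
  c3 <- c3_default_params()
  c3 <- photo_params(c3, chi_gm25 = 1e4)
  for (I in c(300, 800, 1500)) {
    a4 <- solve_c4_leaf(fig1_env(I), p)
    a3 <- solve_c3_leaf(fig1_env(I), c3)
    expect_equal(a4$Cc, a4$Ci, tolerance = 1e-2)
    expect_equal(a4$A, a3$A, tolerance = 0.02 * abs(a3$A))
  }
})

test_that("analytic solutions equal the independent oracle over random environments", {
  envs <- random_environments(40, 202)
  for (id in c(0, 6, 8)) {
    p <- build_route(id)$params
    for (i in seq_len(nrow(envs))) {
      fl <- solve_leaf(leaf_env(I_inc = envs$I_inc[i], C_a = envs$C_a[i],
                                T_l = envs$T_l[i], VPD = envs$VPD[i],
                                n_leaf = envs$n_leaf[i]), p)
      expect_equal(fl$A, oracle_leaf_A(envs$I_inc[i], envs$C_a[i],
                                       envs$T_l[i], envs$VPD[i],
                                       envs$n_leaf[i], p),
                   tolerance = 1e-6)
    }
  }
})

test_that("response-curve export writes the requested grid", {
  f <- tempfile(fileext = ".csv")
  cur <- leaf_response_curves(c(0, 6, 9), I_inc = seq(0, 2000, by = 50),
                              file = f)
  expect_equal(nrow(cur), 3 * 41)
  expect_true(file.exists(f))
  back <- read.csv(f)
  expect_equal(nrow(back), 3 * 41)
  expect_named(back, c("route", "I_inc", "A", "gs", "Ci", "Cc",
                       "limitation"))
  unlink(f)
})
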