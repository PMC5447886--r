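## Independent brute-force oracles for the coupled leaf solvers and the
## sun/shade canopy model. The leaf oracles re-derive the solution by
## scalar root-finding on an independently arranged residual, built from
## the exported scalar response functions (params_at_leaf_T, j2_rate,
## fvpd, c3_limited_rate, vp_rate); invalid states carry a signed
## sentinel so the bisection can cross the narrow validity boundary.

oracle_bisect <- function(resid, lo, hi, iter = 60) {
  rl <- resid(lo)
  if (rl >= 0) return(lo)
  if (resid(hi) < 0) return(NA_real_)
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (resid(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## C3: for a trial A, stomatal conductance is found by root-finding on gs
## (not via the solver's closed-form quadratic).
oracle_c3_branch <- function(which, I_inc, C_a, T_l, VPD, n, params,
                             absorptance = 0.85, O_i = 210, g_b = 3) {
  at <- params_at_leaf_T(params, T_l, n)
  J2 <- j2_rate(I_inc * absorptance, at$Jmax, at$phi2LL_T, params$f_cyc,
                params$r2_1, params$theta)
  fv <- fvpd(VPD, params$a1, params$b1)
  Ci_star <- at$gamma_star * O_i * 1000 - at$Rd / at$gm
  resid <- function(A) {
    high <- if (A + at$Rd > 0) 1e9 else -1e9
    gs <- if (abs(A + at$Rd) < 1e-13) params$g0 else {
      h <- function(gs) {
        Ci <- C_a - A * (1 / g_b + 1 / gs)
        gs - (params$g0 + (A + at$Rd) * fv / (Ci - Ci_star))
      }
      lo <- 1e-8
      if (A > 0) { # stay above the pole where Ci crosses Ci_star
        den <- C_a - Ci_star - A / g_b
        if (den <= 0) return(1e9)
        lo <- A / den * (1 + 1e-9) + 1e-12
      }
      if (h(lo) >= 0) return(high)
      tryCatch(uniroot(h, c(lo, 1e4), tol = 1e-14)$root,
               error = function(e) NA_real_)
    }
    if (!is.finite(gs) || gs <= 0) return(high)
    Ci <- C_a - A * (1 / g_b + 1 / gs)
    Cc <- Ci - A / at$gm
    if (Cc <= 0 || Ci <= 0) return(1e9)
    A - c3_limited_rate(Cc, O_i, which, at, params, J2 = J2)
  }
  x1 <- if (which == "Ac") at$Vcmax else
    (1 - params$f_pseudo / (1 - params$f_cyc)) * J2 / 4
  if (x1 <= 0) return(-at$Rd)
  oracle_bisect(resid, -at$Rd - 3, x1 - at$Rd + 1e-9)
}

## C4/CCM: direct chain from A (leaf-surface CO2, stomata, intercellular
## CO2, bundle-sheath O2 and CO2), with the biochemistry written from the
## exported vp_rate and the bundle-sheath mass balance A = Vp - L - Rm.
oracle_c4_branch <- function(which, I_inc, C_a, T_l, VPD, n, params,
                             absorptance = 0.85, O_i = 210, g_b = 3) {
  at <- params_at_leaf_T(params, T_l, n)
  J2 <- j2_rate(I_inc * absorptance, at$Jmax, at$phi2LL_T, params$f_cyc,
                params$r2_1, params$theta)
  fv <- fvpd(VPD, params$a1, params$b1)
  Oi_u <- O_i * 1000
  Cs_star <- (at$gbs * at$gamma_star * Oi_u -
                (1 + at$gamma_star * params$alpha_bs / at$u_oc) * at$Rd +
                at$Rm) / (at$gbs + at$eps_p)
  resid <- function(A) {
    Cs <- C_a - A / g_b
    gs <- if (abs(A + at$Rd) < 1e-13) params$g0 else {
      den <- Cs - Cs_star
      if (den <= 0) return(1e9)
      params$g0 + (A + at$Rd) * fv / den
    }
    if (gs <= 0) return(if (A + at$Rd > 0) 1e9 else -1e9)
    Ci <- Cs - A / gs
    if (Ci <= 0) return(1e9)
    O_u <- max(params$alpha_bs * A / (at$u_oc * at$gbs) + Oi_u, 1)
    Vp <- vp_rate(Ci, J2, at, params)$Vp
    Cc <- Ci + (Vp - A - at$Rm) / at$gbs
    if (Cc <= 0) return(1e9)
    Ab <- if (which == "Ac") {
      (Cc - at$gamma_star * O_u) * at$Vcmax /
        (Cc + at$KmC * (O_u / 1000) / at$KmO + at$KmC) - at$Rd
    } else {
      x1 <- (1 - params$f_pseudo / (1 - params$f_cyc)) * J2 / 4
      (Cc - at$gamma_star * O_u) * x1 /
        (Cc + 2 * at$gamma_star * O_u) - at$Rd
    }
    A - Ab
  }
  x1 <- if (which == "Ac") at$Vcmax else
    (1 - params$f_pseudo / (1 - params$f_cyc)) * J2 / 4
  if (x1 <= 0) return(-at$Rd)
  oracle_bisect(resid, -at$Rd - 3, x1 - at$Rd + 1e-9)
}

oracle_leaf_A <- function(I_inc, C_a, T_l, VPD, n, params, ...) {
  fam <- params$model_family
  if (fam == "C3") {
    a <- oracle_c3_branch("Ac", I_inc, C_a, T_l, VPD, n, params, ...)
    j <- oracle_c3_branch("Aj", I_inc, C_a, T_l, VPD, n, params, ...)
  } else {
    a <- oracle_c4_branch("Ac", I_inc, C_a, T_l, VPD, n, params, ...)
    j <- oracle_c4_branch("Aj", I_inc, C_a, T_l, VPD, n, params, ...)
  }
  min(a, j, na.rm = TRUE)
}

## random physiological environments under a fixed seed
random_environments <- function(n, seed) {
  set.seed(seed)
  data.frame(I_inc = runif(n, 0, 2000), C_a = runif(n, 250, 800),
             T_l = runif(n, 12, 38), VPD = runif(n, 0.3, 3),
             n_leaf = runif(n, 0.6, 3.5))
}

## fine multilayer canopy oracle (prescribed leaf temperature): splits the
## canopy into thin layers, computes per-layer sunlit/shaded absorbed PAR
## and leaf N from the same optical coefficients, and solves every layer
## with the leaf model.
multilayer_canopy_A <- function(cs, sin_beta, I_dir, I_diff, params, C_a,
                                T_l = 25, VPD = 2, n_layers = 100) {
  L <- cs$LAI
  dl <- L / n_layers
  mid <- (seq_len(n_layers) - 0.5) * dl
  sq <- sqrt(1 - cs$scattering)
  kb <- beam_extinction(sin_beta, cs$leaf_angle)
  kb_s <- kb * sq
  kd_s <- diffuse_extinction(L, cs$leaf_angle, cs$scattering)
  refl <- photoroutes:::canopy_reflectances(kb, cs$leaf_angle,
                                            cs$scattering)
  ## absorbed flux per unit leaf area at depth l
  q_diff <- I_diff * (1 - refl$rho_cd) * kd_s * exp(-kd_s * mid)
  q_beam_tot <- I_dir * (1 - refl$rho_cb) * kb_s * exp(-kb_s * mid)
  q_beam_dir <- I_dir * (1 - cs$scattering) * kb * exp(-kb * mid)
  q_sh <- q_diff + pmax(q_beam_tot - q_beam_dir, 0)
  q_sun <- q_sh + I_dir * (1 - cs$scattering) * kb
  f_sun <- exp(-kb * mid)
  ## exponential N profile identical to the big-leaf scheme
  kN <- kd_s
  N_tot <- max(cs$n_avg - cs$n_b, 0) * L
  n0nb <- if (N_tot > 0) N_tot * kN / (1 - exp(-kN * L)) else 0
  n_leaf <- cs$n_b + n0nb * exp(-kN * mid)
  env <- leaf_env(I_inc = c(q_sun, q_sh), C_a = C_a, T_l = T_l, VPD = VPD,
                  n_leaf = rep(n_leaf, 2), absorptance = 1, g_b = 3)
  fl <- solve_leaf(env, params)
  sum(fl$A[seq_len(n_layers)] * f_sun * dl) +
    sum(fl$A[n_layers + seq_len(n_layers)] * (1 - f_sun) * dl)
}
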