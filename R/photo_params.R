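## Parameter containers for the biochemical leaf photosynthesis models.

#' Construct a leaf photosynthesis parameter set
#'
#' Builds a validated `photo_params` object holding every biochemical,
#' diffusional and temperature-response constant of one model variant.
#' Most users should start from [c3_default_params()], [c4_default_params()]
#' or [build_route()] and override fields via `...`.
#'
#' @param base a `photo_params` object (or bare list) supplying defaults.
#' @param ... named overrides of individual fields.
#' @return a `photo_params` object (a named list).
#' @details Fields (units): `model_family` ("C3", "C4" or "CCM"); `phi2LL`
#'   (mol mol-1), `r2_1`, `theta`, `f_cyc`, `f_pseudo`, `f_Q` (fractions),
#'   `h` (mol H+ per ATP), `alpha_bs` (fraction of O2 evolution in the bundle
#'   sheath), `x_atp` (fraction of ATP for the CCM), `phi_ccm` (mol extra ATP
#'   per CO2), `T_opt`, `Omega` (degC), `S_co25` (mol mol-1), `gamma_star25`
#'   (= 0.5 / `S_co25`), `K_mC25` (umol mol-1), `K_mO25` (mmol mol-1),
#'   nitrogen slopes `chi_Vcmax25`, `chi_Jmax25` (umol s-1 g-1 N),
#'   `chi_epsp25`, `chi_gm25`, `chi_gbs25` (mol s-1 g-1 N), `chi_Rd25`
#'   (umol s-1 g-1 N, day respiration slope), `Rm_factor` (mesophyll share of
#'   `Rd`), `g0` (mol m-2 s-1), `a1`, `b1` (kPa-1), `u_oc25`, activation /
#'   deactivation / entropy constants `E_*`, `D_*`, `S_*` (J mol-1 or
#'   J K-1 mol-1) and base leaf nitrogen `n_b` (g N m-2). The switch
#'   `cs_star_alt` selects the alternative sign grouping
#'   `-(1 + gamma* alpha/u_oc) (Rd - Rm)` in the leaf-surface CO2
#'   compensation point of the C4 stomatal submodel.
#' @export
photo_params <- function(base = c3_default_params(), ...) {
  p <- unclass(base)
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown photo_params fields: ", paste(unknown, collapse = ", "))
    }
    p[names(dots)] <- dots
  }
  ## specificity and gamma* stay consistent unless gamma_star25 itself is set
  if ("S_co25" %in% names(dots) && !("gamma_star25" %in% names(dots))) {
    p$gamma_star25 <- 0.5 / p$S_co25
  }
  validate_photo_params(structure(p, class = "photo_params"))
}

validate_photo_params <- function(p) {
  stopifnot(p$model_family %in% c("C3", "C4", "CCM"))
  fr <- c("f_cyc", "f_pseudo", "theta", "phi2LL")
  for (f in fr) {
    v <- p[[f]]
    if (!is.na(v) && (v < 0 || v > 1)) stop(f, " must lie in [0, 1]")
  }
  if (p$f_cyc + p$f_pseudo >= 1) stop("f_cyc + f_pseudo must be < 1")
  if (p$theta <= 0 || p$theta > 1) stop("theta must lie in (0, 1]")
  if (p$S_co25 <= 0) stop("S_co25 must be positive")
  if (abs(p$gamma_star25 * p$S_co25 - 0.5) > 1e-12) {
    stop("gamma_star25 must equal 0.5 / S_co25")
  }
  chis <- c("chi_Vcmax25", "chi_Jmax25", "chi_Rd25", "chi_gm25",
            "chi_gbs25", "chi_epsp25")
  for (f in chis) {
    v <- p[[f]]
    if (!is.na(v) && v < 0) stop(f, " must be >= 0")
  }
  if (p$model_family != "C3") {
    if (is.na(p$phi_ccm) || p$phi_ccm < 0) stop("phi_ccm must be >= 0")
    needed <- c("f_Q", "h", "alpha_bs", "x_atp", "chi_epsp25", "chi_gbs25",
                "u_oc25", "Rm_factor")
    miss <- needed[vapply(needed, function(f) is.na(p[[f]]), logical(1))]
    if (length(miss)) {
      stop("C4-family parameter set is missing: ", paste(miss, collapse = ", "))
    }
  } else if (is.na(p$chi_gm25)) {
    stop("C3 parameter set requires chi_gm25")
  }
  p
}

#' Default C3 leaf parameter set
#'
#' Rice-type C3 parameterisation: FvCB kinetics with mesophyll conductance,
#' PSII electron transport with a small cyclic fraction, and the stomatal
#' VPD response.
#'
#' @return a `photo_params` object with `model_family = "C3"`.
#' @export
c3_default_params <- function() {
  p <- list(
    model_family = "C3", label = "default C3",
    phi2LL = 0.78, r2_1 = 0.85, theta = 0.8,
    f_cyc = 0.05, f_pseudo = 0.10, f_Q = NA_real_, h = NA_real_,
    alpha_bs = NA_real_, x_atp = NA_real_, phi_ccm = NA_real_,
    T_opt = 23, Omega = 36.8,
    S_co25 = 3022, gamma_star25 = 0.5 / 3022,
    K_mC25 = 291, K_mO25 = 194,
    chi_Vcmax25 = 75, chi_Jmax25 = 100, chi_epsp25 = NA_real_,
    chi_Rd25 = 0.01 * 75, Rm_factor = NA_real_,
    g0 = 0.01, a1 = 0.9, b1 = 0.15,
    chi_gm25 = 0.125, chi_gbs25 = NA_real_, u_oc25 = NA_real_,
    E_gamma_star = 24460, E_Vcmax = 65330, E_KmC = 80990, E_KmO = 23720,
    E_Rd = 46390,
    E_Jmax = 88380, D_Jmax = 200000, S_Jmax = 650,
    E_epsp = NA_real_, D_epsp = NA_real_, S_epsp = NA_real_,
    E_gm = 49600, D_gm = 437400, S_gm = 1400,
    E_gbs = NA_real_, D_gbs = NA_real_, S_gbs = NA_real_,
    E_uoc = NA_real_,
    n_b = 0.3,
    cs_star_alt = FALSE
  )
  structure(p, class = "photo_params")
}

#' Default C4 leaf parameter set
#'
#' Maize-type NADP-ME C4 parameterisation: PEP carboxylation in the
#' mesophyll, Rubisco confined to the bundle sheath with conductance
#' `g_bs` controlling CO2 leakage, a high cyclic electron fraction to supply
#' the extra 2 ATP per CO2 of the C4 cycle (`phi_ccm = 2`,
#' `x_atp = phi/(3 + phi) = 0.4`), and C4 Rubisco kinetics.
#'
#' The day-respiration nitrogen slope is kept at its C3 value so that model
#' variants differ only through their stated biochemical overrides.
#'
#' @return a `photo_params` object with `model_family = "C4"`.
#' @export
c4_default_params <- function() {
  p <- unclass(c3_default_params())
  p2 <- list(
    model_family = "C4", label = "default C4",
    f_cyc = 0.45, f_pseudo = 0.05, f_Q = 1, h = 4,
    alpha_bs = 0.1, x_atp = 0.4, phi_ccm = 2,
    T_opt = 34, Omega = 38.4,
    S_co25 = 2862, gamma_star25 = 0.5 / 2862,
    K_mC25 = 485, K_mO25 = 146,
    chi_Vcmax25 = 93, chi_Jmax25 = 200, chi_epsp25 = 0.791,
    Rm_factor = 0.5,
    chi_gm25 = NA_real_, chi_gbs25 = 0.007, u_oc25 = 0.047,
    E_gamma_star = 27417, E_Vcmax = 53400, E_KmC = 35600, E_KmO = 15100,
    E_Rd = 41853,
    E_Jmax = 116439, D_Jmax = 135982, S_Jmax = 458.7,
    E_epsp = 51029, D_epsp = 130363, S_epsp = 425.6,
    E_gm = NA_real_, D_gm = NA_real_, S_gm = NA_real_,
    E_gbs = 116767, D_gbs = 264604, S_gbs = 860,
    E_uoc = -1630
  )
  p[names(p2)] <- p2
  validate_photo_params(structure(p, class = "photo_params"))
}

#' Cyanobacterial CCM variant of the C4 leaf model
#'
#' Re-purposes the C4 model structure to represent a cyanobacterial
#' CO2-concentrating mechanism engineered into a C3 leaf: the bundle-sheath
#' conductance plays the role of the chloroplast-envelope (or carboxysome)
#' conductance, the PEP carboxylation rate stands for the combined
#' bicarbonate transport rate, mesophyll respiration equals day respiration,
#' and the lower ATP cost of bicarbonate transport (`phi_ccm = 0.75`) gives
#' `x_atp = 0.2` and a rebalanced cyclic electron fraction `f_cyc = 0.18`.
#'
#' @param base_c3 the C3 parameter set the CCM is layered onto.
#' @param elaborate if `TRUE`, the carboxysome-like low envelope conductance
#'   (`chi_gbs25 = 0.007`) is used; otherwise the leaky transporter-only
#'   value (`chi_gbs25 = 0.125`).
#' @param c4_capacity if `TRUE`, C4-level capacity slopes
#'   (`chi_Vcmax25 = 93`, `chi_Jmax25 = 200`) are also installed.
#' @return a `photo_params` object with `model_family = "CCM"`.
#' @export
make_ccm_params <- function(base_c3 = c3_default_params(), elaborate = FALSE,
                            c4_capacity = FALSE) {
  c4 <- unclass(c4_default_params())
  p <- unclass(base_c3)
  ## C4 machinery needed to run the bundle-sheath model structure
  carry <- c("f_Q", "h", "alpha_bs", "chi_epsp25", "u_oc25",
             "E_epsp", "D_epsp", "S_epsp", "E_gbs", "D_gbs", "S_gbs",
             "E_uoc")
  p[carry] <- c4[carry]
  p$f_pseudo <- c4$f_pseudo
  p$model_family <- "CCM"
  p$phi_ccm <- 0.75
  p$x_atp <- x_from_phi(0.75)
  p$f_cyc <- 0.18
  p$Rm_factor <- 1
  p$chi_gbs25 <- if (elaborate) 0.007 else 0.125
  p$chi_gm25 <- NA_real_
  p$label <- if (elaborate) "cyanobacterial CCM (carboxysome)" else
    "cyanobacterial CCM (transporters only)"
  if (c4_capacity) {
    p$chi_Vcmax25 <- 93
    p$chi_Jmax25 <- 200
    p$label <- "complete cyanobacterial CCM"
  }
  validate_photo_params(structure(p, class = "photo_params"))
}

#' @export
print.photo_params <- function(x, ...) {
  cat("<photo_params>", x$label, sprintf("[%s model]\n", x$model_family))
  cat(sprintf("  Vcmax25/Jmax25 N slopes: %.3g / %.3g umol s-1 g-1 N\n",
              x$chi_Vcmax25, x$chi_Jmax25))
  cat(sprintf("  S_c/o25 = %g, KmC25 = %g umol mol-1, KmO25 = %g mmol mol-1\n",
              x$S_co25, x$K_mC25, x$K_mO25))
  if (x$model_family != "C3") {
    cat(sprintf("  CCM: phi = %g (x = %.3g), f_cyc = %g, chi_gbs25 = %g\n",
                x$phi_ccm, x$x_atp, x$f_cyc, x$chi_gbs25))
  } else {
    cat(sprintf("  chi_gm25 = %g, f_cyc = %g\n", x$chi_gm25, x$f_cyc))
  }
  invisible(x)
}

#' Evaluate all temperature- and nitrogen-dependent leaf parameters
#'
#' Applies the nitrogen scaling at 25 degC and the (peaked) Arrhenius
#' temperature responses to produce the operative parameter values at leaf
#' temperature, plus the PSII quantum efficiency and the ATP conversion
#' factor `z`.
#'
#' @param params a `photo_params` object.
#' @param T_l leaf temperature (degC); may be a vector.
#' @param n leaf nitrogen (g N m-2); scalar or vector matching `T_l`.
#' @return a list of numeric vectors: `Vcmax`, `Jmax`, `Rd`, `Rm`, `KmC`,
#'   `KmO`, `gamma_star`, `gm`, `gbs`, `eps_p`, `u_oc`, `phi2LL_T`,
#'   `alpha2LL` and `z`.
#' @export
params_at_leaf_T <- function(params, T_l, n) {
  p <- params
  np <- pmax(n - p$n_b, 0)
  out <- list(
    Vcmax = arrhenius(p$chi_Vcmax25 * np, p$E_Vcmax, T_l),
    Jmax = peaked_arrhenius(p$chi_Jmax25 * np, p$E_Jmax, p$D_Jmax, p$S_Jmax,
                            T_l),
    Rd = arrhenius(p$chi_Rd25 * np, p$E_Rd, T_l),
    KmC = arrhenius(p$K_mC25, p$E_KmC, T_l),
    KmO = arrhenius(p$K_mO25, p$E_KmO, T_l),
    gamma_star = arrhenius(p$gamma_star25, p$E_gamma_star, T_l)
  )
  out$phi2LL_T <- p$phi2LL * phi2LL_t_factor(p$T_opt, p$Omega, T_l)
  out$alpha2LL <- out$phi2LL_T * (1 - p$f_cyc) / (1 - p$f_cyc + p$r2_1)
  if (p$model_family == "C3") {
    out$gm <- peaked_arrhenius(p$chi_gm25 * np, p$E_gm, p$D_gm, p$S_gm, T_l)
    out$Rm <- rep(NA_real_, length(out$Rd))
    out$gbs <- out$eps_p <- out$u_oc <- out$z <- rep(NA_real_, length(out$Rd))
  } else {
    out$gm <- rep(NA_real_, length(out$Rd))
    out$Rm <- p$Rm_factor * out$Rd
    out$gbs <- peaked_arrhenius(p$chi_gbs25 * np, p$E_gbs, p$D_gbs, p$S_gbs,
                                T_l)
    out$eps_p <- peaked_arrhenius(p$chi_epsp25 * np, p$E_epsp, p$D_epsp,
                                  p$S_epsp, T_l)
    out$u_oc <- arrhenius(p$u_oc25, p$E_uoc, T_l)
    out$z <- (2 + p$f_Q - p$f_cyc) / (p$h * (1 - p$f_cyc))
  }
  out
}
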