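## User-facing leaf-level solvers wrapping the compiled core.

#' Leaf environment driving variables
#'
#' Bundles the driving variables for a single-leaf (or big-leaf) solve.
#' All fields may be vectors of a common length; scalars are recycled.
#'
#' @param I_inc incident irradiance (umol photons m-2 s-1).
#' @param C_a ambient CO2 mole fraction (umol mol-1).
#' @param T_l leaf temperature (degC).
#' @param VPD leaf-to-air vapour pressure deficit (kPa).
#' @param n_leaf leaf nitrogen content (g N m-2 leaf; for big leaves, pass
#'   `n_b` plus photosynthetic N per unit ground area).
#' @param absorptance leaf photosynthetic absorptance (default 0.85).
#' @param O_i intercellular O2 mole fraction (mmol mol-1, default 210).
#' @param g_b boundary-layer conductance to CO2 (mol m-2 s-1, default 3:
#'   large enough that the boundary layer is immaterial for leaf-level
#'   response curves).
#' @param g0_scale multiplier on the residual stomatal conductance (used by
#'   the canopy module to scale `g0` with big-leaf area; default 1).
#' @return a `leaf_env` object (list of equal-length vectors).
#' @export
leaf_env <- function(I_inc, C_a = 400, T_l = 25, VPD = 2, n_leaf = 2.3,
                     absorptance = 0.85, O_i = 210, g_b = 3, g0_scale = 1) {
  env <- list(I_inc = I_inc, C_a = C_a, T_l = T_l, VPD = VPD,
              n_leaf = n_leaf, absorptance = absorptance, O_i = O_i,
              g_b = g_b, g0_scale = g0_scale)
  n <- max(lengths(env))
  env <- lapply(env, rep_len, n)
  stopifnot(all(env$I_inc >= 0), all(env$C_a > 0), all(env$O_i > 0),
            all(env$VPD >= 0), all(env$g_b > 0))
  structure(env, class = "leaf_env")
}

leaf_flux_frame <- function(sol, env) {
  out <- data.frame(A = sol$A, gs = sol$gs, Ci = sol$Ci, Cc = sol$Cc,
                    Cs = sol$Cs, O_bs = sol$O_bs, Vp = sol$Vp, L = sol$L,
                    J2 = sol$J2, Rd = sol$Rd,
                    limitation = c("enzyme", "e_transport")[sol$limitation],
                    T_l = env$T_l)
  class(out) <- c("leaf_flux", "data.frame")
  out
}

## internal fast path: returns the solver output as a plain list
leaf_raw <- function(env, params, gs_fixed = NULL) {
  np <- pmax(env$n_leaf - params$n_b, 0)
  leaf_solve_cpp(unclass(params), env$I_inc * env$absorptance,
                 env$C_a, env$O_i, env$T_l, env$VPD, env$g_b, np,
                 env$g0_scale, gs_fixed)
}

solve_leaf_core <- function(env, params, gs_fixed = NULL) {
  leaf_flux_frame(leaf_raw(env, params, gs_fixed), env)
}

#' Solve the coupled C3 leaf photosynthesis / stomatal conductance model
#'
#' Finds net assimilation `A`, stomatal conductance `gs`, and the
#' intercellular and chloroplast CO2 levels (`Ci`, `Cc`) that simultaneously
#' satisfy the FvCB biochemistry, the stomatal submodel and the
#' boundary-layer / mesophyll diffusion chain, at prescribed leaf
#' temperature. Each limitation branch (Rubisco, electron transport) is
#' solved to consistency and the lower `A` is returned.
#'
#' @param env a [leaf_env()] object.
#' @param params a `photo_params` object with `model_family = "C3"`.
#' @return a `leaf_flux` data frame with one row per environment: `A`
#'   (umol CO2 m-2 s-1), `gs` (mol m-2 s-1), `Ci`, `Cc`, `Cs`
#'   (umol mol-1), `J2`, `Rd` and the active `limitation`.
#' @examples
#' solve_c3_leaf(leaf_env(I_inc = 1500), c3_default_params())
#' @export
solve_c3_leaf <- function(env, params = c3_default_params()) {
  stopifnot(inherits(env, "leaf_env"), params$model_family == "C3")
  solve_leaf_core(env, params)
}

#' Solve the coupled C4/CCM leaf photosynthesis model
#'
#' As [solve_c3_leaf()] but for the bundle-sheath (C4) model structure, also
#' used for the cyanobacterial-CCM variant: PEP carboxylation (or
#' bicarbonate transport) limited by enzyme or electron transport, CO2
#' leakage through the bundle-sheath (or envelope) conductance, bundle-sheath
#' O2 accumulation, and the leaf-surface-based stomatal submodel.
#'
#' @inheritParams solve_c3_leaf
#' @param params a `photo_params` object with `model_family` `"C4"` or
#'   `"CCM"`.
#' @return a `leaf_flux` data frame; additionally `O_bs` (mmol mol-1),
#'   `Vp` and leakage `L` (umol m-2 s-1).
#' @export
solve_c4_leaf <- function(env, params = c4_default_params()) {
  stopifnot(inherits(env, "leaf_env"),
            params$model_family %in% c("C4", "CCM"))
  solve_leaf_core(env, params)
}

#' Solve any leaf model variant
#'
#' Dispatches to the C3 or C4/CCM solver on `params$model_family`.
#'
#' @inheritParams solve_c3_leaf
#' @param params a `photo_params` object of any model family.
#' @export
solve_leaf <- function(env, params) {
  if (params$model_family == "C3") solve_c3_leaf(env, params)
  else solve_c4_leaf(env, params)
}

#' Solve leaf photosynthesis at prescribed stomatal conductance
#'
#' Used under water limitation, where the actual stomatal conductance is
#' derived from the actual transpiration rate rather than from the stomatal
#' submodel: `A`, `Ci` and `Cc` are made consistent with the biochemistry
#' and the diffusion chain at the given `g_s`. Feeding back the `g_s`
#' returned by [solve_leaf()] reproduces the same `A`.
#'
#' @inheritParams solve_leaf
#' @param g_s prescribed stomatal conductance to CO2 (mol m-2 s-1),
#'   positive; scalar or vector.
#' @export
solve_leaf_given_gs <- function(g_s, env, params) {
  stopifnot(inherits(env, "leaf_env"), all(g_s > 0))
  solve_leaf_core(env, params, gs_fixed = rep_len(g_s, length(env$I_inc)))
}

#' C3 limitation-branch rate at known chloroplast CO2
#'
#' Evaluates one branch of the FvCB model directly,
#' `A = (C_c - Gamma*) x1 / (C_c + x2) - R_d`, with
#' `x1 = Vcmax`, `x2 = KmC (1 + O/KmO)` for the Rubisco-limited rate and
#' `x1 = [1 - f_pseudo/(1 - f_cyc)] J2 / 4`, `x2 = 2 O gamma*` for the
#' electron-transport-limited rate. Mainly useful for inspection and
#' testing; the coupled solvers use the same expressions internally.
#'
#' @param C_c chloroplast CO2 (umol mol-1), positive.
#' @param O O2 mole fraction (mmol mol-1).
#' @param which `"Ac"` or `"Aj"`.
#' @param at list of parameter values at leaf temperature, as returned by
#'   [params_at_leaf_T()].
#' @param params the `photo_params` object (for `f_cyc`, `f_pseudo`).
#' @param J2 PSII electron transport rate (umol e- m-2 s-1), required for
#'   `which = "Aj"`.
#' @return net rate (umol CO2 m-2 s-1).
#' @export
c3_limited_rate <- function(C_c, O, which = c("Ac", "Aj"), at, params,
                            J2 = NULL) {
  which <- match.arg(which)
  stopifnot(all(C_c > 0))
  O_umol <- O * 1000
  if (which == "Ac") {
    x1 <- at$Vcmax
    x2 <- at$KmC * (1 + O / at$KmO)
  } else {
    stopifnot(!is.null(J2))
    x1 <- (1 - params$f_pseudo / (1 - params$f_cyc)) * J2 / 4
    x2 <- 2 * O_umol * at$gamma_star
  }
  (C_c - at$gamma_star * O_umol) * x1 / (C_c + x2) - at$Rd
}

#' PEP carboxylation (or bicarbonate transport) rate
#'
#' `V_p = min(eps_p * C_i, x * J2 * z / phi)` with
#' `z = (2 + f_Q - f_cyc) / [h (1 - f_cyc)]` converting the PSII electron
#' transport rate into an ATP production rate. With `phi = 0` the electron
#' transport branch is unbounded and the enzyme branch is always selected.
#'
#' @param C_i intercellular CO2 (umol mol-1), non-negative.
#' @param J2 PSII electron transport rate (umol e- m-2 s-1).
#' @param at parameter values at leaf temperature ([params_at_leaf_T()]).
#' @param params the C4-family `photo_params` object.
#' @return list with `Vp` (umol m-2 s-1) and `limitation`
#'   (`"enzyme"` or `"e_transport"`).
#' @export
vp_rate <- function(C_i, J2, at, params) {
  stopifnot(all(C_i >= 0), params$model_family != "C3")
  v_enz <- at$eps_p * C_i
  v_e <- if (params$phi_ccm > 0) {
    params$x_atp * J2 * at$z / params$phi_ccm
  } else {
    rep(Inf, length(v_enz))
  }
  list(Vp = pmin(v_enz, v_e),
       limitation = ifelse(v_enz <= v_e, "enzyme", "e_transport"))
}

#' Light-response curves for a set of routes
#'
#' Convenience wrapper producing leaf light-response curves for several
#' model configurations under common input conditions, optionally written
#' to CSV.
#'
#' @param route_ids integer vector of route identifiers (0 = default C3).
#' @param I_inc vector of incident irradiances (umol m-2 s-1).
#' @param env_args named list of overrides passed to [leaf_env()].
#' @param file optional path; when given the table is also written as CSV.
#' @return data frame with columns `route`, `I_inc`, `A`, `gs`, `Ci`, `Cc`,
#'   `limitation`.
#' @export
leaf_response_curves <- function(route_ids = 0:9,
                                 I_inc = seq(0, 2000, by = 50),
                                 env_args = list(), file = NULL) {
  rows <- lapply(route_ids, function(id) {
    rt <- build_route(id)
    env <- do.call(leaf_env, c(list(I_inc = I_inc), env_args))
    fl <- solve_leaf(env, rt$params)
    data.frame(route = id, I_inc = I_inc, A = fl$A, gs = fl$gs, Ci = fl$Ci,
               Cc = fl$Cc, limitation = fl$limitation)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
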