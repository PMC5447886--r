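## Registry of the ten model configurations: the default C3 crop plus nine
## photosynthesis-enhancing engineering routes.

#' ATP partitioning fraction for a CO2-concentrating mechanism
#'
#' Fraction of ATP production allocated to the CCM, `x = phi / (3 + phi)`,
#' where `phi` is the extra ATP required by the CCM per CO2 fixed and 3 is
#' the Calvin-cycle ATP cost per CO2.
#'
#' @param phi extra ATP per CO2 (mol mol-1), non-negative.
#' @return dimensionless fraction in `[0, 1)`.
#' @examples
#' x_from_phi(2)    # 0.4, the C4 cycle
#' x_from_phi(0.75) # 0.2, cyanobacterial bicarbonate transport
#' @export
x_from_phi <- function(phi) {
  stopifnot(all(phi >= 0))
  phi / (3 + phi)
}

#' Total ATP requirement per CO2 assimilated
#'
#' `ATP_req = 3 + phi`: the Calvin-cycle cost plus the extra CCM cost.
#'
#' @inheritParams x_from_phi
#' @return mol ATP per mol CO2.
#' @export
atp_requirement <- function(phi) {
  stopifnot(all(phi >= 0))
  3 + phi
}

#' Combined ATP cost of the cyanobacterial bicarbonate transporters
#'
#' The two well-characterised single-gene transporters require 0.25 (BicA)
#' and 0.50 (SbtA) ATP per transport event; their sum is the extra ATP per
#' CO2 of the transporter-based CCM.
#'
#' @return 0.75 (mol ATP per mol CO2).
#' @export
ccm_transporter_atp_cost <- function() {
  bicA <- 0.25
  sbtA <- 0.50
  bicA + sbtA
}

route_descriptions <- c(
  "default C3",
  "improved mesophyll conductance",
  "improved Rubisco specificity",
  "improved mesophyll conductance and Rubisco specificity",
  "C4 biochemistry introduced",
  "C4 Kranz anatomy introduced (low bundle-sheath leakage)",
  "complete C4 mechanism",
  "cyanobacterial bicarbonate transporters",
  "elaborate cyanobacterial CCM (carboxysome)",
  "complete cyanobacterial CCM")

#' Construct a model configuration (route)
#'
#' Builds one of the ten model configurations: the default C3 crop
#' (route 0) or one of nine engineering routes layered over the default
#' parameter sets.
#'
#' Routes: 1 triples the mesophyll-conductance nitrogen slope
#' (`chi_gm25 = 0.375`); 2 raises Rubisco specificity to the red-algal value
#' (`S_co25 = 4427`); 3 combines 1 and 2; 4 installs C4 biochemistry with a
#' leaky bundle sheath (`chi_gbs25 = 0.125`); 5 installs effective Kranz
#' anatomy (`chi_gbs25 = 0.007`) on C3 enzyme kinetics; 6 is the complete C4
#' mechanism; 7 adds cyanobacterial bicarbonate transporters to a C3 leaf
#' (`chi_gbs25 = 0.125`, `phi = 0.75`, `x = 0.2`, `f_cyc = 0.18`,
#' `R_m = R_d`); 8 is route 7 with a carboxysome-like low envelope
#' conductance (`chi_gbs25 = 0.007`); 9 is route 8 plus C4-level capacity
#' slopes (`chi_Vcmax25 = 93`, `chi_Jmax25 = 200`).
#'
#' @param route_id integer 0 to 9.
#' @return a `route_spec` object: list with `route_id`, `label`,
#'   `model_family`, the parameter `overrides` applied, and the full
#'   `params` (`photo_params`).
#' @export
build_route <- function(route_id) {
  stopifnot(length(route_id) == 1, route_id %in% 0:9)
  id <- as.integer(route_id)
  ov <- switch(as.character(id),
    "0" = list(),
    "1" = list(chi_gm25 = 0.375),
    "2" = list(S_co25 = 4427),
    "3" = list(chi_gm25 = 0.375, S_co25 = 4427),
    "4" = list(chi_gbs25 = 0.125),
    "5" = list(S_co25 = 3022, K_mC25 = 291, K_mO25 = 194,
               chi_Vcmax25 = 75, chi_Jmax25 = 100,
               T_opt = 23, Omega = 36.8,
               E_gamma_star = 24460, E_Vcmax = 65330, E_KmC = 80990,
               E_KmO = 23720, E_Rd = 46390,
               E_Jmax = 88380, D_Jmax = 200000, S_Jmax = 650,
               chi_gbs25 = 0.007),
    "6" = list(chi_gbs25 = 0.007),
    "7" = list(),
    "8" = list(),
    "9" = list())
  params <- switch(as.character(id),
    "0" = , "1" = , "2" = , "3" = do.call(photo_params,
                                          c(list(c3_default_params()), ov)),
    "4" = , "5" = , "6" = do.call(photo_params,
                                  c(list(c4_default_params()), ov)),
    "7" = make_ccm_params(elaborate = FALSE, c4_capacity = FALSE),
    "8" = make_ccm_params(elaborate = TRUE, c4_capacity = FALSE),
    "9" = make_ccm_params(elaborate = TRUE, c4_capacity = TRUE))
  params$label <- route_descriptions[id + 1]
  structure(list(route_id = id, label = route_descriptions[id + 1],
                 model_family = params$model_family,
                 overrides = ov, params = params),
            class = "route_spec")
}

#' @export
print.route_spec <- function(x, ...) {
  cat(sprintf("<route_spec> route %d: %s (%s model)\n", x$route_id, x$label,
              x$model_family))
  invisible(x)
}

#' Biochemical covariates of a route
#'
#' Extracts the parameters used as regressors in the light-use-efficiency
#' regression: the bundle-sheath (envelope) conductance slope, the total
#' ATP requirement per CO2 and the `Jmax` nitrogen slope.
#'
#' @param route a `route_spec` object.
#' @return one-row data frame with `chi_gbs25`, `ATP_req`, `chi_Jmax25`.
#' @export
route_biochem_covariates <- function(route) {
  p <- route$params
  data.frame(chi_gbs25 = p$chi_gbs25,
             ATP_req = if (is.na(p$phi_ccm)) NA_real_ else
               atp_requirement(p$phi_ccm),
             chi_Jmax25 = p$chi_Jmax25)
}

#' Sensitivity variants of a route over the CCM ATP cost
#'
#' Builds copies of a route in which the CCM ATP cost `phi` is varied,
#' recomputing `x = phi/(3 + phi)` for each value. The cyclic electron
#' fraction can either be kept at the route's value (default, treating
#' `f_cyc` as an independently observed constant) or re-solved so that
#' linear plus cyclic electron transport exactly balance the ATP:NADPH
#' demand `(3 + phi):2` at the route's `h` and `f_Q`.
#'
#' @param route a C4-family `route_spec` (typically route 9).
#' @param phi_values numeric vector of ATP costs, non-negative.
#' @param rebalance_f_cyc logical; re-solve `f_cyc` for each `phi`?
#' @return list of `route_spec` objects, one per `phi`.
#' @export
atp_cost_sweep <- function(route, phi_values, rebalance_f_cyc = FALSE) {
  stopifnot(route$model_family != "C3", all(phi_values >= 0))
  lapply(phi_values, function(phi) {
    p <- route$params
    ov <- list(phi_ccm = phi, x_atp = x_from_phi(phi))
    if (rebalance_f_cyc) {
      ov$f_cyc <- balanced_f_cyc(phi, p$f_pseudo, p$h, p$f_Q)
    }
    r <- route
    r$params <- do.call(photo_params, c(list(p), ov))
    r$overrides <- modifyList(r$overrides, ov)
    r$label <- sprintf("%s (phi = %g)", route$label, phi)
    r
  })
}

## f_cyc at which ATP and NADPH production exactly match the (3 + phi):2
## demand: 2 (2 + f_Q - f_cyc) / [h (1 - f_cyc - f_pseudo)] = (3 + phi) / 2
balanced_f_cyc <- function(phi, f_pseudo, h, f_Q) {
  req <- (3 + phi) / 2
  fc <- (req * h * (1 - f_pseudo) - 2 * (2 + f_Q)) / (req * h - 2)
  min(max(fc, 0), 0.95)
}

#' Serialise a route to a YAML configuration file
#'
#' @param route a `route_spec` object.
#' @param file output path.
#' @export
write_route_config <- function(route, file) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required for route serialisation")
  }
  pl <- unclass(route$params)
  pl <- lapply(pl, function(v) if (is.na(v) && !is.logical(v)) "NA" else v)
  yaml::write_yaml(list(route_id = route$route_id, label = route$label,
                        model_family = route$model_family,
                        overrides = route$overrides, params = pl), file,
                   precision = 15)
  invisible(file)
}

#' Read a route from a YAML configuration file
#'
#' @param file path written by [write_route_config()].
#' @return a `route_spec` object.
#' @export
read_route_config <- function(file) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required for route serialisation")
  }
  x <- yaml::read_yaml(file)
  pl <- lapply(x$params, function(v) {
    if (identical(v, "NA")) NA_real_ else v
  })
  ## gamma* is derived from the specificity; recompute to full precision
  pl$gamma_star25 <- 0.5 / pl$S_co25
  params <- validate_photo_params(structure(pl, class = "photo_params"))
  structure(list(route_id = x$route_id, label = x$label,
                 model_family = x$model_family,
                 overrides = x$overrides, params = params),
            class = "route_spec")
}
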