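---
title: "From leaf biochemistry to crop mass: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From leaf biochemistry to crop mass: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoroutes)
```

`photoroutes` simulates how engineering changes to leaf photosynthesis
propagate to seasonal crop mass production. This vignette documents the
science the package implements, the parameters that matter, the numerical
machinery, and the design choices made where the underlying model
descriptions left the design open.

## 1. Leaf photosynthesis

### C3 leaves

Net assimilation is the minimum of a Rubisco-limited and an electron
transport (NADPH)-limited rate, both of the form
$A = (C_c - \Gamma^*)\,x_1/(C_c + x_2) - R_d$ with
$\Gamma^* = \gamma^* O$ (the CO2 compensation point without day
respiration, $\gamma^* = 0.5/S_{c/o}$):

* Rubisco limited: $x_1 = V_{cmax}$, $x_2 = K_{mC}(1 + O/K_{mO})$;
* e⁻-transport limited: $x_1 = [1 - f_{pseudo}/(1 - f_{cyc})]\,J_2/4$,
  $x_2 = 2\gamma^* O$.

The PSII electron transport rate $J_2$ follows a non-rectangular
hyperbola of absorbed light with initial slope
$\alpha_{2LL} = \Phi_{2LL}(1 - f_{cyc})/(1 - f_{cyc} + r_{2/1})$, so a
larger cyclic electron fraction $f_{cyc}$ *lowers* the efficiency of
noncyclic transport — the mechanism that makes ATP-hungry
CO2-concentrating mechanisms (CCMs) expensive in shade.

Stomata follow $g_s = g_0 + (A + R_d)\,f_{vpd}/(C_i - C_i^*)$ with
$f_{vpd} = 1/[1/\max(a_1 - b_1\mathrm{VPD}, 0.01) - 1]$, and CO2 diffuses
through boundary layer, stomata and mesophyll:
$C_i = C_a - A(1/g_b + 1/g_s)$, $C_c = C_i - A/g_m$.

$C_i^*$ is the intercellular CO2 at which $A + R_d = 0$; applying the
mesophyll-conductance relation at that point gives
$C_i^* = \Gamma^* - R_d/g_m$, which is what the solver uses.

### C4 leaves and the cyanobacterial CCM

The C4 variant adds PEP carboxylation
$V_p = \min(\varepsilon_p C_i,\; x J_2 z/\varphi)$ with
$z = (2 + f_Q - f_{cyc})/[h(1 - f_{cyc})]$ converting electron transport
to ATP production, bundle-sheath leakage $L = g_{bs}(C_c - C_i)$, the mass
balance $A = V_p - L - R_m$, bundle-sheath O2 enrichment
$O = \alpha A/(u_{oc} g_{bs}) + O_i$, and a leaf-surface-based stomatal
model with compensation point
$C_s^* = [g_{bs}\gamma^* O_i - (1 + \gamma^*\alpha/u_{oc})R_d + R_m]/(g_{bs} + \varepsilon_p)$.
The sign grouping of the $R_d$/$R_m$ terms in $C_s^*$ is ambiguous in the
usual verbal statement; the package implements the form above and exposes
the alternative grouping $-(1 + \gamma^*\alpha/u_{oc})(R_d - R_m)$ via
`photo_params(cs_star_alt = TRUE)`. For $R_m = 0.5 R_d$ the two differ
negligibly.

The cyanobacterial CCM reuses this structure: $g_{bs}$ plays the
chloroplast-envelope/carboxysome conductance, $V_p$ the combined
bicarbonate transport rate, $R_m = R_d$, and the cheaper transport
($\varphi = 0.75$, from 0.25 + 0.50 ATP per transport event of the two
characterised single-gene transporters) gives
$x = \varphi/(3 + \varphi) = 0.2$ and a rebalanced $f_{cyc} = 0.18$.
`atp_cost_sweep()` varies $\varphi$ for sensitivity analysis; by default
$f_{cyc}$ is held at the configured constant, and with
`rebalance_f_cyc = TRUE` it is re-solved from the ATP:NADPH balance
$2(2 + f_Q - f_{cyc})/[h(1 - f_{cyc} - f_{pseudo})] = (3 + \varphi)/2$,
which gives 0.205 at $\varphi = 0.75$ and 0.4375 at $\varphi = 2$
(close to, but not exactly, the configured constants 0.18 and 0.45 —
the configured values are treated as observationally grounded and are not
re-derived).

### Parameter conventions

CO2 is carried as µmol mol⁻¹ and O2 as mmol mol⁻¹ mole fractions;
conductances in mol m⁻² s⁻¹; no conversion to partial pressures. Ambient
O2 defaults to 210 mmol mol⁻¹. Capacity parameters scale linearly with
leaf nitrogen above the base value $n_b = 0.3$ g N m⁻²
($V_{cmax25} = \chi_{Vcmax25}(n - n_b)$, etc.), clamp to zero below it
(the leaf then only respires, and since day respiration itself scales with
$n - n_b$, a base-nitrogen leaf exchanges nothing). Day respiration uses
the *C3* capacity slope for every configuration
($R_{d25} = 0.01 \times 75\,(n - n_b)$), so engineered routes differ only
through their stated overrides. Temperature responses use the Arrhenius
form normalised at 25 °C, the peaked (deactivation) variant for
$J_{max}$, $\varepsilon_p$, $g_m$ and $g_{bs}$ (evaluated with an
overflow-safe log-sum formulation), and a Gaussian factor for
$\Phi_{2LL}$ whose width $\Omega$ is the offset at which the factor falls
to $e^{-1}$.

### The solver

Combining the biochemistry, the stomatal submodel and the diffusion chain
yields, per limitation branch, a single monotone residual in $A$: given a
trial $A$, the stomatal/diffusion subsystem is solved in closed form (a
quadratic in $C_i - C_i^*$ for C3; a direct chain for C4, whose stomatal
model was built on the leaf-surface CO2 precisely so that no inner
iteration is needed), and the residual is the mismatch with the
biochemical rate at the resulting $C_c$. Each branch is solved by guarded
bisection (80 halvings from bracket
$[-R_d - \text{margin},\, x_1 - R_d]$, i.e. well below 1e-9 µmol m⁻²
s⁻¹); invalid states (negative CO2, collapsed supply) carry a signed
sentinel so the bisection crosses validity boundaries correctly. The
final rate is the smaller of the two branch solutions, following the
minimum rule. The solver is implemented in C++ (Rcpp) and is vectorised
over environments; the test suite checks it against an independent
brute-force oracle (R-coded `uniroot` on a differently arranged residual)
to better than 1e-6 µmol m⁻² s⁻¹ over a thousand random physiological
environments, for all three model families.

`solve_leaf_given_gs()` solves the same chain at a prescribed stomatal
conductance — the entry point used under water limitation.

## 2. Energy balance and water limitation

Leaf temperature is solved by fixed-point iteration: the leaf model at the
current $T_l$ (with leaf-to-air VPD recomputed from $T_l$) gives $g_s$;
Penman–Monteith with $r_{sw} = 1/(1.6 g_s)$ gives transpiration and a new
$T_l$ from the linearised energy budget; iterate to 0.01 °C (damping 0.5
after 50 iterations, error after 200 — the tolerance and damping are
implementation decisions, not model claims). Resistances are molar;
boundary-layer conductance uses the flat-plate relation
$g_{bh} = 0.135\sqrt{u/d}$ with a 0.01 m characteristic leaf width; the
radiative conductance of an isothermal formulation (emissivity 0.96) is
folded into the heat resistance. Net radiation, where not supplied, is
taken as 1.3× the absorbed PAR energy flux: leaves absorb near-infrared
(≈0.25) far less efficiently than PAR (0.85), so the NIR load adds roughly
30%.

Under water limitation the available water is divided among leaves in
proportion to their potential transpiration $E_p$, and the actual
transpiration $E_a$ is converted back to an actual stomatal resistance by
inverting Penman–Monteith:
$r_{sw,a} = (E_p - E_a)(s r_{bh} + \gamma r_{bw})/(\gamma E_a) + r_{sw,p} E_p/E_a$,
after flooring $E_a$ at a tiny positive value. Assimilation is then
recomputed at the prescribed conductance, with leaf temperature
re-derived from the reduced evaporative cooling — so mild water stress in
cool air can occasionally *raise* instantaneous assimilation through leaf
warming, a deliberate consequence of modelling stomatal closure as the
only drought effect apart from temperature.

## 3. Canopy scaling

The canopy is split into sunlit and shaded classes. Beam extinction uses
the projection of foliage at a fixed mean inclination (default 65° from
horizontal, rice-like erect leaves); scattering 0.2 for PAR; canopy
reflection coefficients and a three-zone overcast sky for diffuse light;
the diffuse extinction coefficient is LAI-dependent. Nitrogen follows an
exponential profile whose extinction coefficient $k_N$ is set equal to
the scattered-diffuse PAR extinction coefficient — nitrogen tracking the
time-averaged light profile — a documented choice where the source
formulations are not printed.

Each class is evaluated at three Gaussian depth nodes carrying the local
absorbed flux and leaf nitrogen, and node results are combined with
leaf-area weights. A single aggregated evaluation per class (the classic
two-big-leaf shortcut) overestimates canopy photosynthesis by several
percent at high light because the sunlit class straddles the saturation
knee; with the depth nodes the scheme matches a 100-layer reference
integration to well under 1% while keeping the two-class structure.
Instantaneous fluxes are integrated over the photoperiod with five-point
Gauss–Legendre quadrature (exact to polynomial degree 9); the diurnal
radiation course is proportional to $\sin\beta(1 + 0.4\sin\beta)$,
normalised against the same quadrature so daily totals are conserved
exactly, and temperature follows a sinusoid peaking 1.5 h after solar
noon. The diffuse fraction comes from the daily clearness index in
weather-driven runs and is fixed (e.g. 0.2) only in grid-reproduction
mode. Available water under limitation follows the diurnal course of
radiation.

## 4. The seasonal crop simulator

The season loop is deliberately lightweight — a transparent simplification
of a full crop model, with the soil module replaced by a prescribed water
supply and all constants gathered here:

* **Phenology**: development stage 0 → 1 (flowering) → 2 (maturity);
  daily thermal increment from a beta response (base 8, optimum 30,
  ceiling 42 °C) of the diurnal temperature course, so a day at optimum
  contributes exactly one thermal day; stage advances by increment/$m_V$
  before and increment/$m_R$ after flowering. Drought does not affect
  phenology.
* **Nitrogen**: cumulative uptake follows a beta-sigmoid in development
  stage reaching exactly 20 g N m⁻² at maturity; 10% of uptake goes to
  roots, the shoot share splits between leaves and stem with
  stage-dependent sigmoids.
* **Canopy dynamics**: carbon-determined LAI grows with new leaf mass ×
  specific leaf area (0.03 m² g⁻¹); nitrogen-determined LAI is
  $\ln(1 + k_N N_{leaf}/n_b)/k_N$; when carbon outruns nitrogen the gap
  relaxes with a 2-day time constant, shed leaf mass accumulating as
  senesced matter (dead leaves keep their base structural nitrogen).
* **Respiration**: growth respiration $(1 - Y_G)$ with $Y_G = 0.75$ g DM
  per g CH2O; maintenance 0.015 g CH2O per g non-leaf N per day with Q10
  = 2; night leaf dark respiration from the Arrhenius response at the
  night mean temperature. CH2O↔CO2 conversion 30/44.
* **Partitioning**: root fraction declines with stage from a 0.35
  baseline and rises with shoot C:N surplus (functional equilibrium
  proxy), bounded to [0.05, 0.6].

The bookkeeping is exact by construction: seasonal
$(A_{canopy,s} - RESP)\times 30/44$ equals total biomass growth, and
shoot mass equals
$(PAR_{int}\,PLUE - RESP)(30/44)(1 - F_{root}) - SENES$ plus the small
initial seedling mass (worth well under 1% of final mass). Water-limited
seasons fix the daily supply at 50% of the mean daily potential
transpiration pre-computed for the same weather and configuration.

## 5. Synthetic weather

The generator emulates daily station weather for three rice-environment
archetypes — tropical (Los Baños-like dry season), subtropical
(Nanjing-like single summer crop) and temperate (Shizukuishi-like) — as
seasonal sinusoids plus AR(1) anomalies (coefficient 0.6) for temperature
and clearness, radiation = clearness × extraterrestrial radiation (so the
physical bound holds by construction), vapour pressure anchored to
saturation at the daily minimum, and lognormal wind. Climatological
constants were set from the sites' real-world climate normals and then
anchored so that the simulated baseline crop durations approximate the
documented standard-cultivar durations (≈107, 137 and 137 days to
maturity) — the same duration calibration a field-data-driven study
performs; they are constants, not fitted objects, and are not revisited
per run. The 2050 transform adds exactly 2 °C to both temperature
extremes, leaves radiation and wind untouched, rescales vapour pressure
along the saturation curve (preserving relative humidity) and sets CO2 to
550 µmol mol⁻¹.

What the generator does *not* emulate: observed interannual modes
(monsoon breaks, typhoons), radiation–temperature cross-correlation,
rainfall (irrelevant here because water limitation is a fixed fraction of
simulated potential transpiration rather than a rainfall balance). Tests
that pass on this weather therefore validate model structure and
directional behaviour, not site-specific magnitudes.

## 6. The experiment layer

`run_experiment()` crosses sites × climates × water modes × routes ×
years with paired weather (every cell of a site–climate stratum sees the
identical realisation, so route contrasts are exact pairwise contrasts),
reusing each potential run to set the water supply of its limited
counterpart. Percentage changes are computed on multi-year means.
Regressions are ordinary least squares with standard t-probabilities and
no multiple-testing correction; rank-deficient designs raise an error
naming the collinear columns, and the mass regression also reports the
design condition number because seasonal mass and senescence are strongly
collinear in simulated data.

## 7. Known limitations

* The canopy-ratio structure has two edges where this implementation's
  behaviour departs from the qualitative pattern it targets: the
  leaky-C4 configuration (route 4) crosses slightly above the C3 default
  at LAI 3 for daily radiation ≳ 25–30 MJ m⁻² (its saturated-light leaf
  advantage, driven by the maize-level capacity slopes, outweighs the
  shade penalty at the edge of physically attainable radiation), and the
  low-cost cyanobacterial routes show a slightly *higher* ratio at LAI 7
  than LAI 1 at the lowest radiation (5 MJ m⁻²), where photorespiration
  suppression outweighs their small quantum-efficiency penalty in deep
  shade. Both are properties of the printed parameter values under this
  canopy formulation, verified against the 100-layer reference, and are
  left visible rather than tuned away.
* Grain yield, harvest index and spikelet sterility are not simulated;
  live shoot mass (excluding dead leaves) is the productivity proxy.
* The leaf-N vertical redistribution and reserve dynamics of full crop
  models are simplified to the pooled stem/reserve nitrogen described
  above.
* Photorespiratory bypasses, triose-phosphate-utilisation limitation and
  C4 subtypes beyond the configured parameterisation are out of scope.

Default problem sizes (5 synthetic years per site for the factorial,
3 depth nodes × 5 time points per day, 80 bisection steps per leaf
solve) keep a full factorial of 1200 season runs in the
single-digit-minute range on one core while leaving every reported
quantity at numerical convergence.
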