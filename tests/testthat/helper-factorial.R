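## The synthetic-weather factorial used by the scenario-level tests:
## 3 sites x 2 climates x 2 water modes x 10 routes x 5 years, computed
## once per test session and cached.
.factorial_cache <- new.env(parent = emptyenv())

acceptance_factorial <- function() {
  if (is.null(.factorial_cache$tt)) {
    cfg <- experiment_config(n_years = 5, seed = 2024)
    .factorial_cache$tt <- run_experiment(cfg)
  }
  .factorial_cache$tt
}

## percentage change in multi-year mean shoot mass relative to route 0,
## as a (site, climate, water, route) table
mass_benefit_table <- function(tt) {
  pc <- percent_change_table(tt, trait_cols = "shoot_mass")
  pc[pc$route != 0, ]
}
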