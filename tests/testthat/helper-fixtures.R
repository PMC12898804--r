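# Small in-code fixtures shared across test files.

# hand-built ODC series: baseline, one dip to `nadir`, recovery
odc_dip_series <- function(nadir, baseline = 50000, len = 21) {
  half <- floor(len / 2)
  c(rep(baseline, 3),
    seq(baseline, nadir, length.out = half),
    seq(nadir, baseline, length.out = half),
    rep(baseline, 3))
}

tiny_scenario <- function(arms, n = 20, years = 2, seed = 42, ...) {
  list(name = "test", mode = "full", horizon_years = years, n_patients = n,
       master_seed = seed, arms = arms, ...)
}

grid_states <- function(tjp = 1, bmec = 1, peri = 1, damage = 0, U = 0) {
  bbb_state(tjp_level = tjp, bmec_density = bmec, pericyte_coverage = peri,
            damage = damage, repair_capital = U)
}
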