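# Preset trial runs are shared across acceptance blocks; cache them so each
# reference scenario is simulated once per test session.
.preset_cache <- new.env(parent = emptyenv())

run_preset_cached <- function(name) {
  if (is.null(.preset_cache[[name]])) {
    .preset_cache[[name]] <- run_scenario(scenario_preset(name))
  }
  .preset_cache[[name]]
}

# |x - target| within the stochastic band: 20% relative, and for event counts
# additionally one event
expect_band <- function(x, target, extra_abs = 0) {
  expect_lte(abs(x - target), max(0.2 * abs(target), extra_abs))
}
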