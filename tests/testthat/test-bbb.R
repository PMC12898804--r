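test_that("TEER equals baseline at full health and its floor at zero TJP", {
  p <- bbb_params()
  expect_equal(compute_teer(grid_states(), p), p$teer_baseline)
  expect_equal(compute_teer(grid_states(tjp = 0), p), p$teer_floor)
  expect_gt(compute_teer(grid_states(tjp = 0), p), 0)
})

test_that("TEER is strictly increasing in TJP level and BMEC density", {
  p <- bbb_params()
  tjp_grid <- seq(0.05, 1, by = 0.05)
  teer_tjp <- vapply(tjp_grid, function(x) compute_teer(grid_states(tjp = x), p), 0)
  expect_true(all(diff(teer_tjp) > 0))
  bmec_grid <- seq(0.05, 1, by = 0.05)
  teer_bmec <- vapply(bmec_grid, function(x) compute_teer(grid_states(bmec = x), p), 0)
  expect_true(all(diff(teer_bmec) > 0))
  expect_gt(compute_teer(grid_states(tjp = 0.9), p),
            compute_teer(grid_states(tjp = 0.8), p))
})

test_that("permeability is baseline-normalised, decreasing in TJP, higher at low BMEC", {
  p <- bbb_params()
  expect_equal(compute_permeability(grid_states(), p), p$perm_baseline)
  tjp_grid <- seq(0.2, 1, by = 0.05)
  perm <- vapply(tjp_grid, function(x) compute_permeability(grid_states(tjp = x), p), 0)
  expect_true(all(diff(perm) < 0))
  expect_gt(compute_permeability(grid_states(bmec = 0.5), p),
            compute_permeability(grid_states(bmec = 1), p))
})

test_that("TEER and permeability are inversely ordered under the default coupling", {
  p <- bbb_params()
  states <- lapply(seq(0.3, 1, by = 0.05), function(x) grid_states(tjp = x))
  teer <- vapply(states, compute_teer, 0, params = p)
  perm <- vapply(states, compute_permeability, 0, params = p)
  ord <- order(teer)
  expect_true(all(diff(perm[ord]) < 0))
})

test_that("invalid states are rejected rather than clipped", {
  expect_error(bbb_state(tjp_level = 1.2), class = "bbbms_error")
  expect_error(bbb_state(tjp_level = -0.1), class = "bbbms_error")
  expect_error(bbb_state(damage = -1), class = "bbbms_error")
  st <- grid_states()
  st$tjp_level <- NaN
  expect_error(compute_teer(st), class = "bbbms_error")
  expect_error(step_bbb(grid_states(), dt = -1), class = "bbbms_error")
  expect_error(step_bbb(grid_states(), infiltration_load = NA_real_),
               class = "bbbms_error")
})

test_that("discrete stepper matches the analytic decline law within 0.1% over 30 years", {
  p <- bbb_params()
  for (disease in c(FALSE, TRUE)) {
    st <- grid_states(tjp = 0.97)
    k <- p$healthy_decline_rate / 365 *
      if (disease) p$disease_decline_multiplier else 1
    for (d in seq_len(30 * 365)) {
      st <- step_bbb(st, p, disease = disease, dt = 1)
    }
    analytic <- p$tjp_floor + (0.97 - p$tjp_floor) * exp(-k * 30 * 365)
    expect_lt(abs(st$tjp_level - analytic) / analytic, 0.001)
    expect_equal(st$damage, 0)
  }
})

test_that("untreated trajectories decline monotonically; disease flag lowers the endpoint", {
  p <- bbb_params()
  sim_h <- simulate_bbb_cohort(1, p, years = 30, disease = FALSE)
  sim_d <- simulate_bbb_cohort(1, p, years = 30, disease = TRUE)
  expect_true(all(diff(sim_h$tjp[, 1]) < 0))
  expect_true(all(diff(sim_h$teer[, 1]) < 0))
  expect_lt(sim_d$tjp_final, sim_h$tjp_final)
  # holds for any multiplier > 1, not just the calibrated default
  p2 <- bbb_params(disease_decline_multiplier = 1.1)
  expect_lt(simulate_bbb_cohort(1, p2, 30, disease = TRUE)$tjp_final,
            simulate_bbb_cohort(1, p2, 30, disease = FALSE)$tjp_final)
})

test_that("a vanishing step leaves the state unchanged", {
  st <- grid_states(tjp = 0.8, damage = 0.3)
  out <- step_bbb(st, dt = 1e-12)
  expect_equal(out$tjp_level, st$tjp_level, tolerance = 1e-9)
  expect_equal(out$damage, st$damage, tolerance = 1e-9)
})

test_that("repair input raises the set point persistently and clears damage", {
  p <- bbb_params()
  st <- grid_states(tjp = 0.9, damage = 2)
  out <- step_bbb(st, p, repair_input = 1.5, dt = 1)
  expect_gt(out$repair_capital, st$repair_capital)
  expect_lt(out$damage, st$damage * exp(-p$damage_recovery_rate))
  # uplifted set point persists: later untreated steps decay toward it
  long <- out
  for (d in 1:2000) long <- step_bbb(long, p, disease = TRUE, dt = 5)
  setpoint <- p$tjp_floor + p$uplift_max * (1 - exp(-p$uplift_rate * out$repair_capital))
  expect_gt(long$tjp_level, setpoint - 1e-6)
})

test_that("infiltration probability: blockade, normalisation, monotone grid", {
  p <- bbb_params()
  expect_equal(infiltration_probability(1, 1, block_factor = 1, params = p), 0)
  expect_equal(infiltration_probability(p$perm_baseline, 1, 0, p),
               p$infil_baseline_prob)
  grid <- seq(0.2, 5, by = 0.2)
  probs <- infiltration_probability(grid, 1.5, 0.3, p)
  expect_true(all(diff(probs) >= 0))
  expect_true(all(probs >= 0 & probs <= 1))
  expect_error(infiltration_probability(1, 1, block_factor = 1.5),
               class = "bbbms_error")
  expect_error(infiltration_probability(-1, 1, 0), class = "bbbms_error")
})

test_that("bbb operations are deterministic", {
  st <- grid_states(tjp = 0.7, damage = 1)
  a <- step_bbb(st, disease = TRUE, infiltration_load = 3, repair_input = 0.1)
  b <- step_bbb(st, disease = TRUE, infiltration_load = 3, repair_input = 0.1)
  expect_identical(a, b)
})
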