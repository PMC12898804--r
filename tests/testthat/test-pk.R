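grid6h <- seq(0, 360, by = 1)

test_that("zero dose gives an all-zero concentration series", {
  r <- dose_regimen("NX210c", dose = 0, cycle_length_weeks = 0)
  pk <- simulate_pk(r, grid_min = grid6h)
  expect_true(all(pk$conc_nx210 == 0) && all(pk$conc_nx210c == 0))
})

test_that("stepper matches the closed-form infusion/washout solution within 0.1%", {
  pkp <- pk_params()
  r <- regimen_preset("sad_nx210c_10")
  pk <- simulate_pk(r, pkp, grid_min = seq(0, 720, by = 1))
  Tinf <- r$infusion_duration / 60
  k <- pkp$elimination_rate_nx210c
  rate <- r$dose / Tinf / pkp$volume_of_distribution
  tt <- pk$time_min / 60
  closed <- ifelse(tt <= Tinf,
                   rate / k * (1 - exp(-k * tt)),
                   rate / k * (1 - exp(-k * Tinf)) * exp(-k * (tt - Tinf)))
  expect_lt(max(abs(pk$conc_nx210c - closed)) / max(closed), 0.001)
})

test_that("NX210c rises then decays after linear NX210 dosing and is visible by 180 min", {
  pk <- simulate_pk(regimen_preset("sad_nx210_10"), grid_min = grid6h)
  imax <- which.max(pk$conc_nx210c)
  expect_gt(imax, 1)
  expect_lt(imax, nrow(pk))
  expect_gt(pk$conc_nx210c[pk$time_min == 180], 0.01)
})

test_that("kinetics are linear: doubling dose doubles concentrations; superposition holds", {
  pkp <- pk_params()
  g <- seq(0, 4320, by = 2)
  one <- simulate_pk(dose_regimen("NX210c", 5, cycle_length_weeks = 0), pkp, g)
  two <- simulate_pk(dose_regimen("NX210c", 10, cycle_length_weeks = 0), pkp, g)
  expect_equal(two$conc_nx210c, 2 * one$conc_nx210c, tolerance = 1e-6)
  # two doses on days 0 and 2 = single-dose profile + itself shifted by 2 days
  multi <- simulate_pk(dose_regimen("NX210c", 5, schedule_days = c(0, 2),
                                    cycle_length_weeks = 1), pkp, g)
  shift <- 2 * 1440 / 2 # grid steps corresponding to 2 days
  shifted <- c(rep(0, shift), one$conc_nx210c[seq_len(length(g) - shift)])
  expect_equal(multi$conc_nx210c, one$conc_nx210c + shifted, tolerance = 1e-4)
})

test_that("trapezoidal AUC: rectangle, zero, exponential closed form, additivity", {
  expect_equal(auc(c(0, 2, 4), c(3, 3, 3)), 12)
  expect_equal(auc(c(0, 1, 2), c(0, 0, 0)), 0)
  tt <- seq(0, 60, by = 0.01)
  expect_equal(auc(tt, 10 * exp(-0.5 * tt)), 10 / 0.5, tolerance = 1e-4)
  cut <- 3001
  expect_equal(auc(tt, 10 * exp(-0.5 * tt)),
               auc(tt[1:cut], 10 * exp(-0.5 * tt[1:cut])) +
                 auc(tt[cut:length(tt)], 10 * exp(-0.5 * tt[cut:length(tt)])))
  expect_error(auc(c(0, 2, 1), c(1, 1, 1)), class = "bbbms_error")
})

test_that("NX210c dosing yields ~10x the exposure of equal-dose NX210, invariant to dose", {
  er10 <- exposure_ratio(regimen_preset("sad_nx210c_10"),
                         regimen_preset("sad_nx210_10"))
  expect_equal(er10, 10, tolerance = 0.02)
  er5 <- exposure_ratio(regimen_preset("sad_nx210c_5"),
                        regimen_preset("sad_nx210_5"))
  expect_equal(er5, er10, tolerance = 1e-6)
  r <- regimen_preset("sad_nx210c_2.5")
  expect_equal(exposure_ratio(r, r), 1, tolerance = 1e-9)
  expect_error(exposure_ratio(regimen_preset("sad_nx210c_10"),
                              regimen_preset("sad_nx210_5")),
               class = "bbbms_error")
})

test_that("mass sanity: NX210c formed from NX210 dosing never exceeds the administered dose", {
  pkp <- pk_params()
  pk <- simulate_pk(regimen_preset("sad_nx210_10"), pkp, seq(0, 2880, by = 1))
  formed <- auc(pk) * pkp$elimination_rate_nx210c * pkp$volume_of_distribution
  expect_lt(formed, 10)
  expect_equal(formed,
               10 * pkp$cyclization_rate /
                 (pkp$cyclization_rate + pkp$elimination_rate_nx210),
               tolerance = 0.01)
})

test_that("grid validation: coarse grids and unordered time are rejected", {
  r <- regimen_preset("sad_nx210c_10") # 10-min infusion
  expect_error(simulate_pk(r, grid_min = seq(0, 360, by = 30)),
               class = "bbbms_error")
  expect_error(simulate_pk(r, grid_min = c(0, 10, 5)), class = "bbbms_error")
})

test_that("regimen presets include the SAD and MAD protocols", {
  for (d in c(0.4, 1.25, 2.5, 5, 10)) {
    r <- regimen_preset(paste0("sad_nx210_", d))
    expect_equal(r$dose, d)
    expect_identical(dosing_days(r), 0L)
  }
  mad <- regimen_preset("nx210c_10mgkg_cycle")
  expect_identical(dosing_days(mad),
                   as.integer(sort(outer(c(0, 2, 4), 7 * (0:3), `+`))))
  expect_equal(mad$infusion_duration, 10)
  rep6 <- regimen_preset("nx210c_10mgkg_repeat6mo", n_cycles = 2)
  expect_equal(length(dosing_days(rep6)), 24)
  expect_error(regimen_preset("nope"), class = "bbbms_error")
})
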