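test_that("relapse detector: constant series, clinical and subclinical dips", {
  expect_equal(nrow(detect_relapses(rep(50000, 100))), 0)
  clin <- detect_relapses(odc_dip_series(41000))
  expect_equal(nrow(clin), 1)
  expect_equal(clin$classification, "clinical")
  expect_equal(clin$nadir_odc, 41000)
  sub <- detect_relapses(odc_dip_series(45000))
  expect_equal(nrow(sub), 1)
  expect_equal(sub$classification, "subclinical")
  # boundary: exactly 42,500 is not below the clinical threshold
  expect_equal(detect_relapses(odc_dip_series(42500))$classification, "subclinical")
  expect_true(all(clin$onset <= clin$nadir_time))
})

test_that("relapse detector segments excursions and validates inputs", {
  two <- c(odc_dip_series(41000), odc_dip_series(44000))
  ev <- detect_relapses(two)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$classification, c("clinical", "subclinical"))
  # a dip that never recrosses the open threshold is a single event
  merged <- c(rep(50000, 3), seq(50000, 40000, length.out = 10),
              seq(40000, 46000, length.out = 5),
              seq(46000, 41000, length.out = 5),
              seq(41000, 50000, length.out = 10))
  expect_equal(nrow(detect_relapses(merged)), 1)
  # dips smaller than the subclinical threshold are not events
  expect_equal(nrow(detect_relapses(odc_dip_series(48500))), 0)
  expect_error(detect_relapses(odc_dip_series(41000), baseline = 0),
               class = "bbbms_error")
  expect_error(detect_relapses(odc_dip_series(41000),
                               subclinical_threshold_frac = 0.2),
               class = "bbbms_error")
})

test_that("scenario validation reports itemised schema violations", {
  err <- tryCatch(validate_scenario(list(mode = "banana", horizon_years = -1,
                                         arms = list(list(profile = "x")))),
                  error = function(e) conditionMessage(e))
  expect_match(err, "mode must be")
  expect_match(err, "horizon_years")
  expect_match(err, "missing name")
  expect_match(err, "unknown profile")
  expect_error(validate_scenario(list(horizon_years = 1)), "arm")
  cfg <- validate_scenario(tiny_scenario(list(list(name = "u", profile = "healthy"))))
  expect_equal(cfg$dt_days, 0.25)
})

test_that("duplicate arms on the same roster give identical endpoints (paired design)", {
  cfg <- tiny_scenario(list(
    list(name = "a", profile = "rrms_default"),
    list(name = "b", profile = "rrms_default")
  ), n = 15, years = 1)
  tr <- run_scenario(cfg)
  expect_identical(tr$arms$a$counts$total, tr$arms$b$counts$total)
  expect_identical(tr$arms$a$tjp_final, tr$arms$b$tjp_final)
  expect_identical(tr$arms$a$events, tr$arms$b$events)
})

test_that("rerunning a scenario reproduces it bit-for-bit; seeds change outcomes", {
  cfg <- tiny_scenario(list(list(name = "u", profile = "rrms_default")),
                       n = 10, years = 1)
  t1 <- run_scenario(cfg)
  t2 <- run_scenario(cfg)
  expect_identical(summary(t1), summary(t2))
  t3 <- run_scenario(cfg, master_seed = 99)
  expect_false(identical(t1$arms$u$counts$total, t3$arms$u$counts$total))
})

test_that("clinical and subclinical events add up to the total everywhere", {
  cfg <- tiny_scenario(list(list(name = "u", profile = "rrms_highly_active")),
                       n = 30, years = 2)
  a <- run_scenario(cfg)$arms$u
  expect_equal(a$counts$clinical + a$counts$subclinical, a$counts$total)
  expect_equal(a$mean_clinical + a$mean_subclinical, a$mean_total)
  expect_equal(nrow(a$events), sum(a$counts$total))
})

test_that("bbb_endpoint is zero for identical arms and rejects misaligned grids", {
  cfg <- tiny_scenario(list(
    list(name = "a", profile = "rrms_default"),
    list(name = "b", profile = "rrms_default")
  ), n = 5, years = 0.5)
  tr <- run_scenario(cfg)
  expect_equal(unname(bbb_endpoint(tr$arms$a, tr$arms$b)), c(0, 0))
  short <- tr$arms$b
  short$time_days <- short$time_days[-1]
  expect_error(bbb_endpoint(tr$arms$a, short), class = "bbbms_error")
})

test_that("trial outputs round-trip to disk", {
  cfg <- tiny_scenario(list(list(name = "u", profile = "rrms_highly_active")),
                       n = 8, years = 1)
  tr <- run_scenario(cfg)
  d <- file.path(tempdir(), "bbbms_out_test")
  write_trial_outputs(tr, d)
  expect_true(file.exists(file.path(d, "summary.json")))
  js <- jsonlite::read_json(file.path(d, "summary.json"))
  expect_equal(js[[1]]$arm, "u")
  if (sum(tr$arms$u$counts$total) > 0) {
    ev <- read.csv(file.path(d, "events.csv"))
    expect_equal(nrow(ev), sum(tr$arms$u$counts$total))
  }
  unlink(d, recursive = TRUE)
})

test_that("YAML scenarios load and validate", {
  f <- system.file("extdata", "scenarios", "two_arm_example.yaml",
                   package = "bbbms")
  cfg <- read_scenario(f)
  expect_equal(cfg$n_patients, 25)
  expect_equal(length(cfg$arms), 2)
  expect_error(read_scenario(tempfile()), class = "bbbms_error")
})
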