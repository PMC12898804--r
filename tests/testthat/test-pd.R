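test_that("Emax repair coupling: zero, midpoint, monotone, bounded", {
  p <- pd_params(ec50 = 5, emax_repair = 1, hill = 1)
  expect_equal(nx210c_effect(0, p), 0)
  expect_equal(nx210c_effect(5, p), 0.5)
  grid <- seq(0, 200, by = 0.5)
  eff <- nx210c_effect(grid, p)
  expect_true(all(diff(eff) >= 0))
  expect_true(all(eff >= 0 & eff <= p$emax_repair))
  expect_error(nx210c_effect(-1, p), class = "bbbms_error")
  # midpoint also under a steeper Hill slope
  p2 <- pd_params(ec50 = 5, hill = 2)
  expect_equal(nx210c_effect(5, p2), 0.5)
})

test_that("in vitro mode: vehicle neutral, concentration and time orderings", {
  v <- simulate_invitro(0, 24)
  expect_equal(unlist(v), c(claudin5_foldchange = 1, teer_foldchange = 1,
                            permeability_foldchange = 1))
  hi <- simulate_invitro(100, 120)
  lo <- simulate_invitro(1, 120)
  expect_gt(hi$claudin5_foldchange, lo$claudin5_foldchange)
  expect_gt(hi$teer_foldchange, lo$teer_foldchange)
  expect_lt(hi$permeability_foldchange, lo$permeability_foldchange)
  # fold-changes grow from 4 h to 5 days at fixed concentration
  for (conc in c(1, 10, 100)) {
    early <- simulate_invitro(conc, 4)
    late <- simulate_invitro(conc, 120)
    expect_lte(early$claudin5_foldchange, late$claudin5_foldchange)
    expect_lte(early$teer_foldchange, late$teer_foldchange)
    expect_gte(early$permeability_foldchange, late$permeability_foldchange)
    expect_gte(early$claudin5_foldchange, 1)
    expect_lte(early$permeability_foldchange, 1)
  }
  # non-decreasing across the tested concentration ladder
  cl5 <- vapply(c(0, 1, 10, 100),
                function(cc) simulate_invitro(cc, 48)$claudin5_foldchange, 0)
  expect_true(all(diff(cl5) >= 0))
  expect_error(simulate_invitro(10, 2), class = "bbbms_error")
  expect_error(simulate_invitro(10, 200), class = "bbbms_error")
})

test_that("soc_effect honours schedules and returns identity outside windows", {
  e <- soc_effect("natalizumab", t_days = 10)
  expect_gt(e$infiltration_block, 0)
  expect_equal(e$dc_activation_mult, 1)
  expect_equal(e$lymphocyte_prolif_mult, 1)
  expect_equal(e$bcell_depletion_frac, 0)
  # outside the dosing window of a short course
  short <- soc_regimen("natalizumab", horizon_days = 20)
  late <- soc_effect("natalizumab", short, t_days = 300)
  expect_equal(late$infiltration_block, 0)
  expect_false(late$active)
  # ocrelizumab depletes only at dosing events
  expect_gt(soc_effect("ocrelizumab", t_days = 0)$bcell_depletion_frac, 0)
  expect_equal(soc_effect("ocrelizumab", t_days = 50)$bcell_depletion_frac, 0)
  # cladribine doses the first 5 days of months 1, 2, 13, 14
  clad <- soc_regimen("cladribine")
  expect_equal(sort(clad$dose_days),
               sort(as.vector(outer(0:4, c(0, 30, 365, 395), `+`))))
  expect_gt(soc_effect("cladribine", t_days = 366)$lymphodepletion_frac, 0)
  expect_equal(soc_effect("cladribine", t_days = 100)$lymphodepletion_frac, 0)
  expect_error(soc_effect("aspirin"), class = "bbbms_error")
})

test_that("treatment effects compose without double counting", {
  nat <- soc_effect("natalizumab", t_days = 1)
  nx <- treatment_effect("nx210c", bbb_repair_input = 0.13)
  both <- combine_effects(list(nat, nx))
  expect_equal(both$infiltration_block, nat$infiltration_block)
  expect_equal(both$bbb_repair_input, 0.13)
  expect_equal(both$dc_activation_mult, 1)
  # composing with the identity changes nothing; order does not matter
  id <- combine_effects(list())
  again <- combine_effects(list(nx, nat, id))
  for (f in c("dc_activation_mult", "lymphocyte_prolif_mult",
              "infiltration_block", "bbb_repair_input")) {
    expect_equal(both[[f]], again[[f]])
  }
  # two blockers combine as independent filters
  b2 <- combine_effects(list(treatment_effect("natalizumab", infiltration_block = 0.5),
                             treatment_effect("natalizumab", infiltration_block = 0.5)))
  expect_equal(b2$infiltration_block, 0.75)
})

test_that("repair schedule places per-dose exposure on dosing days only", {
  rs <- repair_schedule(regimen_preset("nx210c_10mgkg_cycle"), horizon_days = 40)
  dd <- dosing_days(regimen_preset("nx210c_10mgkg_cycle")) + 1
  expect_true(all(rs[dd] > 0))
  expect_true(all(rs[-dd] == 0))
  # higher dose, higher per-dose exposure (saturating Emax)
  rs5 <- repair_schedule(regimen_preset("nx210c_5mgkg_cycle"), horizon_days = 40)
  expect_gt(max(rs), max(rs5))
  expect_lt(max(rs), 2 * max(rs5))
})
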