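test_that("gradient initial fractions interpolate the two observed anchors", {
  fr <- gradient_initial_fractions(c(10, 40, 1250, 5000))
  expect_equal(fr$fFe0NF[2], 0.15)
  expect_equal(fr$fFe0NF[3], 0.41)
  # clamped outside the anchors
  expect_equal(fr$fFe0NF[1], 0.15)
  expect_equal(fr$fFe0NF[4], 0.41)
  expect_true(all(diff(fr$fFe0NF) >= 0))
  expect_true(all(diff(fr$fFe0PS) <= 0))
})

test_that("default gradient levels are 10 log-spaced points over 20-1800 pM", {
  lv <- fe_gradient_levels()
  expect_length(lv, 10)
  expect_equal(lv[1], 20)
  expect_equal(lv[10], 1800)
  expect_equal(diff(log(lv)), rep(diff(log(lv))[1], 9), tolerance = 1e-12)
})

test_that("disabled translocation makes dynamic and fixed modes identical", {
  p <- tfp(TPSmaxBF = 1e-30, TBFmaxPS = 1e-30, TNFmaxBF = 1e-30)
  case_d <- case_config("dynamic", 0.6, 0.3)
  case_f <- case_config("fixed", 0.6, 0.3)
  rd <- simulate_day(90, p, forcing_constant(90), case_d)
  rf <- simulate_day(90, p, forcing_constant(90), case_f)
  expect_equal(rd$summary$G, rf$summary$G, tolerance = 1e-12)
  expect_equal(tidy(rd)$FeNF_act, tidy(rf)$FeNF_act, tolerance = 1e-10)
  mech <- decompose_mechanisms(rd, rf)
  expect_equal(mech$dO2_production_pct, 0, tolerance = 1e-9)
  expect_equal(mech$dRP_pct, 0, tolerance = 1e-9)
  expect_true(all(abs(mech$Fe_trapped_inactive$difference) < 1e-9))
})

test_that("gradient without re-optimization reports antisymmetric changes", {
  p <- tfp(TPSmaxBF = 1e-30, TBFmaxPS = 1e-30, TNFmaxBF = 1e-30)
  gr <- run_fe_gradient(levels = c(40, 400), params = p,
                        forcing = forcing_constant(90), reoptimize = FALSE)
  # identical physics in both modes -> zero relative change at every level
  expect_equal(gr$comparison$relative_change_G, c(0, 0), tolerance = 1e-9)
  # antisymmetry under mode swap: x' = -x / (1 + x/100)
  gr2 <- run_fe_gradient(levels = c(40, 400), params = tfp(),
                         forcing = forcing_constant(90), reoptimize = FALSE)
  x <- gr2$comparison$relative_change_G
  swapped <- 100 * (gr2$comparison$G_fixed - gr2$comparison$G_dynamic) /
    gr2$comparison$G_dynamic
  expect_equal(swapped, -x / (1 + x / 100), tolerance = 1e-9)
})

test_that("derived metrics are internally consistent with the summary", {
  run <- simulate_day(40, tfp(), forcing_constant(90),
                      case_config("dynamic"))
  dm <- derived_metrics(run)
  s <- run$summary
  expect_equal(dm$CN_ratio, s$CN_ratio, tolerance = 1e-9)
  expect_equal(dm$RP_fraction, s$RP_fraction, tolerance = 1e-9)
  expect_equal(dm$CUE, s$CUE, tolerance = 1e-9)
  # and against the stored time-series integrals
  expect_equal(s$grossCF, max(tidy(run)$int_CF), tolerance = 1e-9)
  expect_equal(s$RP_daily, max(tidy(run)$int_RP), tolerance = 1e-9)
})

test_that("mechanism decomposition rejects mismatched pairs", {
  r40 <- simulate_day(40, tfp(), forcing_constant(90))
  r90 <- simulate_day(90, tfp(), forcing_constant(90))
  expect_error(decompose_mechanisms(r40, r90), "share forcing")
})

test_that("instant decomposition of inactivated nitrogenase helps growth", {
  p <- tfp()
  fr <- gradient_initial_fractions(40)
  base <- simulate_day(40, p, forcing_constant(90),
                       case_config("dynamic", fr$fFe0PS, fr$fFe0NF))
  rec <- simulate_day(40, p, forcing_constant(90),
                      case_config("dynamic", fr$fFe0PS, fr$fFe0NF,
                                  decompose_inactivated = TRUE))
  # recycling trapped iron can only help at fixed parameters
  expect_gte(rec$summary$G, base$summary$G)
  expect_equal(max(tidy(rec)$FeNF_inact), 0)
})
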