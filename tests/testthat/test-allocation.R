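test_that("photosystem synthesis follows its light and Fe saturation law", {
  p <- tfp()
  expect_equal(ps_synthesis_rate(0, 10, Inf, p), 0)
  expect_equal(ps_synthesis_rate(1e6, 0, Inf, p), p$TPSmaxBF,
               tolerance = 1e-9)
  expect_equal(ps_synthesis_rate(1e6, p$kFePS_syn, Inf, p), p$TPSmaxBF / 2,
               tolerance = 1e-9)
  # source limitation: vanishes with an empty buffer
  expect_equal(ps_synthesis_rate(1e6, 0, 0, p), 0)
})

test_that("photosystem decomposition is Fe-saturating and RP-inhibited", {
  p <- tfp()
  expect_equal(ps_decomposition_rate(0, 0, p), 0)
  expect_equal(ps_decomposition_rate(p$kFePS_dec, 0, p), p$TBFmaxPS / 2)
  expect_equal(ps_decomposition_rate(1e12, log(2) / p$beta, p),
               p$TBFmaxPS / 2, tolerance = 1e-9)
})

test_that("nitrogenase synthesis needs both demand and buffer iron", {
  p <- tfp()
  expect_equal(nf_synthesis_rate(0, 50, p), 0)
  expect_equal(nf_synthesis_rate(1, 0, p), 0)
  expect_equal(nf_synthesis_rate(1, p$kFeBF_syn, p), p$TNFmaxBF / 2)
})

test_that("nitrogenase inactivation needs both enzyme and O2", {
  p <- tfp()
  expect_equal(nf_inactivation_rate(50, 0, p), 0)
  expect_equal(nf_inactivation_rate(p$kFeNF, p$kO2NF, p), p$TNFmaxNA / 4)
  expect_equal(nf_inactivation_rate(1e12, 1e12, p), p$TNFmaxNA,
               tolerance = 1e-6)
})

test_that("pool tendencies conserve allocatable iron in every mode", {
  p <- tfp()
  pools <- list(FePS = 30, FeBF = 8, FeNF_act = 12, FeNF_inact = 2)
  for (case in list(case_config("dynamic"), case_config("fixed"),
                    case_config("dynamic", decompose_inactivated = TRUE))) {
    td <- fe_pool_tendencies(pools, I = 300, Phi = 0.6, O2 = 0.4,
                             V_RP = 5e-5, p, case)
    expect_equal(td$dFePS + td$dFeBF + td$dFeNF_act + td$dFeNF_inact, 0)
  }
})

test_that("fixed mode freezes photosystems but still inactivates", {
  p <- tfp()
  pools <- list(FePS = 30, FeBF = 8, FeNF_act = 12, FeNF_inact = 0)
  td <- fe_pool_tendencies(pools, I = 300, Phi = 0.6, O2 = 0.4, V_RP = 0,
                           p, case_config("fixed"))
  expect_equal(td$dFePS, 0)
  expect_equal(td$T_PS_syn, 0)
  expect_equal(td$T_NF_syn, 0)
  expect_gt(td$dFeNF_inact, 0)
  expect_equal(td$dFeNF_act, -td$dFeNF_inact)
})

test_that("instant decomposition reroutes inactivated iron to the buffer", {
  p <- tfp()
  pools <- list(FePS = 30, FeBF = 8, FeNF_act = 12, FeNF_inact = 0)
  td <- fe_pool_tendencies(pools, I = 300, Phi = 0.6, O2 = 0.4, V_RP = 0,
                           p, case_config("dynamic",
                                          decompose_inactivated = TRUE))
  expect_equal(td$dFeNF_inact, 0)
  base <- fe_pool_tendencies(pools, I = 300, Phi = 0.6, O2 = 0.4, V_RP = 0,
                             p, case_config("dynamic"))
  expect_equal(td$dFeBF, base$dFeBF + base$T_NF_inact)
})

test_that("case configuration validates its fractions", {
  expect_error(case_config("dynamic", fFe0PS = 0.8, fFe0NF = 0.3), "<= 1")
  expect_error(case_config("dynamic", fFe0PS = -0.1), "fFe0PS")
  cs <- case_config("fixed", fFe0PS = 0.4, fFe0NF = 0.5)
  expect_s3_class(cs, "tf_case")
  expect_equal(cs$mode, "fixed")
})
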