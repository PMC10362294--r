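# The half-saturation / limiting-case identities of the instantaneous rate
# laws. Source-availability limiters are disabled (lim_* = 0) where an
# identity refers to the bare law.

test_that("PET rate satisfies its limiting-case identities", {
  p <- tfp()
  expect_equal(pet_rate(50, I = 0, V_RP = 0, p), 0)
  # half-saturation in photosystem iron at saturating light
  expect_equal(pet_rate(p$kFePS, I = 1e6, V_RP = 0, p), p$vPETmax / 2,
               tolerance = 1e-9)
  # RP inhibition halves PET when beta * V_RP = ln 2
  expect_equal(pet_rate(1e9, I = 1e6, V_RP = log(2) / p$beta, p),
               p$vPETmax / 2, tolerance = 1e-6)
  expect_error(pet_rate(-1, 10), ">= 0")
})

test_that("pet_rate is monotone in light, FePS and RP", {
  p <- tfp()
  set.seed(42)
  for (i in 1:25) {
    fe <- runif(1, 1, 200); I <- runif(1, 1, 800); rp <- runif(1, 0, 3e-4)
    expect_gte(pet_rate(fe + 5, I, rp, p), pet_rate(fe, I, rp, p))
    expect_gte(pet_rate(fe, I + 50, rp, p), pet_rate(fe, I, rp, p))
    expect_lte(pet_rate(fe, I, rp + 1e-5, p), pet_rate(fe, I, rp, p))
  }
})

test_that("N2-fixation requirement Phi behaves at its limits", {
  p <- tfp()
  expect_equal(nf_requirement(I = 500, CS = 0.2, N = p$N_max, p), 0)
  expect_equal(nf_requirement(I = 0, CS = 0.2, N = 0, p), 0)
  expect_equal(nf_requirement(I = 1e6, CS = p$kCS, N = 0, p), 0.5,
               tolerance = 1e-9)
  expect_error(nf_requirement(10, 0.1, p$N_max * 1.1, p), "N_max")
})

test_that("respiratory protection rises with demand, falls with O2", {
  p <- tfp(lim_O2 = 0, lim_CH2O = 0)
  expect_equal(rp_rate(0, 0.2, p), 0)
  expect_equal(rp_rate(1, 1e9, p), 0, tolerance = 1e-12)
  expect_equal(rp_rate(1, p$kO2RP, p), p$vRPmax / 2)
  # monotonicity on a random grid
  set.seed(7)
  for (i in 1:25) {
    phi <- runif(1); o2 <- runif(1, 0, 2)
    expect_lte(rp_rate(phi, o2 + 0.1, p), rp_rate(phi, o2, p))
    expect_gte(rp_rate(min(1, phi + 0.1), o2, p), rp_rate(phi, o2, p))
  }
})

test_that("nitrogenase kinetics obey Fe and O2 saturation identities", {
  p <- tfp()
  expect_equal(nf_rate(1e-5, FeNF = 1e12, O2 = 0, p), 1e-5, tolerance = 1e-9)
  expect_equal(nf_rate(1e-5, FeNF = p$kFeNF, O2 = p$kO2NF, p), 1e-5 / 4,
               tolerance = 1e-12)
  expect_equal(nf_rate(0, 50, 0.1, p), 0)
  # monotone: non-increasing in O2, non-decreasing in FeNF
  set.seed(11)
  for (i in 1:25) {
    fe <- runif(1, 1, 300); o2 <- runif(1, 0, 1)
    expect_lte(nf_rate(1e-5, fe, o2 + 0.05, p), nf_rate(1e-5, fe, o2, p))
    expect_gte(nf_rate(1e-5, fe + 10, o2, p), nf_rate(1e-5, fe, o2, p))
  }
})

test_that("carbon-skeleton production saturates and self-inhibits", {
  p <- tfp()
  expect_equal(cs_production_rate(0, 0.1, p), 0)
  expect_equal(cs_production_rate(1e12, 0, p), p$vCSmax, tolerance = 1e-9)
  expect_equal(cs_production_rate(p$kCH2O, p$kCSi, p), p$vCSmax / 4,
               tolerance = 1e-12)
})

test_that("O2 tendency decomposes into production, RP, RESP and exchange", {
  p <- tfp()
  # equilibrium: no biology, O2 at ambient
  expect_equal(o2_tendency(0, 0, 0, 0, O2 = 0.21, O2_ambient = 0.21, p), 0)
  # physical influx is positive below ambient
  expect_gt(o2_tendency(0, 0, 0, 0, O2 = 0.1, O2_ambient = 0.21, p), 0)
  # biological balance: production = RP consumption
  v <- 1e-4
  expect_equal(o2_tendency(1, v, v / p$e_per_O2, 0, O2 = 0.21,
                           O2_ambient = 0.21, p), 0, tolerance = 1e-18)
  terms <- o2_tendency(0.8, 2e-4, 5e-5, 1e-5, O2 = 0.3, O2_ambient = 0.21,
                       p, decompose = TRUE)
  expect_named(terms, c("production", "rp", "resp", "exchange"))
  expect_equal(terms$production + terms$rp + terms$resp + terms$exchange,
               o2_tendency(0.8, 2e-4, 5e-5, 1e-5, 0.3, 0.21, p))
})
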