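test_that("allocatable iron is conserved over a full day in both modes", {
  p <- tfp()
  for (case in list(case_config("dynamic", 0.75, 0.15),
                    case_config("fixed", 0.5, 0.4))) {
    run <- simulate_day(40, p, forcing_constant(90), case)
    ts <- tidy(run)
    tot <- ts$FePS + ts$FeBF + ts$FeNF_act + ts$FeNF_inact
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-9)
  }
})

test_that("darkness yields no carbon or nitrogen fixation", {
  run <- simulate_day(40, tfp(), forcing_constant(0),
                      case_config("dynamic"))
  expect_equal(run$summary$grossCF, 0)
  expect_equal(run$summary$NF_daily, 0)
  expect_equal(run$summary$G, 0)
})

test_that("inactivated nitrogenase iron is non-decreasing without recycling", {
  run <- simulate_day(40, tfp(), forcing_sinusoidal(),
                      case_config("dynamic", 0.6, 0.3))
  expect_true(all(diff(tidy(run)$FeNF_inact) > -1e-12))
})

test_that("O2 relaxes to ambient at rate kappa_O2 when biology is off", {
  p <- tfp(vPETmax = 1e-30, vRPmax = 1e-30, TNFmaxNA = 1e-30,
           vCSmax = 1e-30, atp_maintenance = 0, TPSmaxBF = 1e-30,
           TBFmaxPS = 1e-30, TNFmaxBF = 1e-30)
  s0 <- initial_state(40, case_config("dynamic"), p, O2_ambient = 0.21)
  s0[["O2"]] <- 0.05
  run <- simulate_day(40, p, forcing_constant(90), case_config("dynamic"),
                      state0 = s0)
  ts <- tidy(run)
  expected <- 0.21 - (0.21 - 0.05) * exp(-p$kappa_O2 * ts$t)
  expect_lt(max(abs(ts$O2 - expected) / expected), 1e-3)
})

test_that("the daily O2 budget closes against the terminal state", {
  p <- tfp()
  run <- simulate_day(40, p, forcing_sinusoidal(), case_config("dynamic"))
  s <- run$summary
  lhs <- p$rho_C * (s$O2prod_daily - s$RP_daily - s$RESP_daily) +
    s$O2exch_daily
  expect_lt(abs(lhs - (s$O2_T - 0.21)) / max(abs(s$O2exch_daily), 1e-6),
            1e-6)
})

test_that("halving the step changes growth by less than 1e-3 per day", {
  p <- tfp()
  g10 <- simulate_day(40, p, forcing_sinusoidal(),
                      case_config("dynamic"), dt = 10)$summary$G
  g1 <- simulate_day(40, p, forcing_sinusoidal(),
                     case_config("dynamic"), dt = 1,
                     save_every = 60)$summary$G
  expect_lt(abs(g10 - g1), 1e-3)
})

test_that("growth conversion follows the most limiting pool", {
  p <- tfp()
  expect_equal(end_of_day_growth(c(CH2O = 1, CS = 1, N = 0), p)[["G"]], 0)
  g1 <- end_of_day_growth(c(CH2O = 0.02, CS = 0.02, N = 0.002), p)
  g2 <- end_of_day_growth(c(CH2O = 0.04, CS = 0.04, N = 0.004), p)
  # for small increments ln(1 + x) is ~linear: doubling pools ~doubles G
  expect_equal(g2[["G"]] / g1[["G"]], 2, tolerance = 0.02)
  # nitrogen-limited case: dB = N / q_N
  st <- c(CH2O = 10, CS = 10, N = 0.05)
  expect_equal(end_of_day_growth(st, p)[["dB"]], 0.05 / p$q_N)
})

test_that("C++ integrator agrees with the R reference stepper", {
  # Same RK4 scheme built purely from the exported R rate-law functions;
  # coarse dt and a shortened horizon keep the R side fast.
  p <- tfp()
  for (case in list(case_config("dynamic", 0.75, 0.15),
                    case_config("fixed", 0.5, 0.4))) {
    yr <- trichofe:::simulate_day_r(40, p, forcing_constant(90), case,
                                    dt = 120, t_end = 14400)
    run <- simulate_day(40, p, forcing_constant(90), case, dt = 120,
                        save_every = 1)
    ts <- tidy(run)
    yc <- unlist(ts[ts$t == 14400,
                    c("CH2O", "CS", "N", "O2", "FePS", "FeBF",
                      "FeNF_act", "FeNF_inact")])
    expect_equal(unname(yc), unname(yr[c("CH2O", "CS", "N", "O2", "FePS",
                                         "FeBF", "FeNF_act",
                                         "FeNF_inact")]),
                 tolerance = 1e-8)
  }
})

test_that("non-finite states are reported with step and component", {
  p <- tfp()
  s0 <- initial_state(40, case_config("dynamic"), p)
  s0[["O2"]] <- NaN
  expect_error(simulate_day(40, p, forcing_constant(90),
                            case_config("dynamic"), state0 = s0),
               "non-finite state")
})

test_that("dt must divide the day length", {
  expect_error(simulate_day(40, tfp(), forcing_constant(90),
                            case_config("dynamic"), dt = 7),
               "divide")
})
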