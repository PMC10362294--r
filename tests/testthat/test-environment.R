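test_that("light forcing reproduces constant and sinusoidal shapes", {
  fs <- forcing_sinusoidal(I_max = 800)
  expect_equal(light_at(fs, 0), 0)
  expect_equal(light_at(fs, 43200), 0, tolerance = 1e-12)
  expect_equal(light_at(fs, 21600), 800)
  fc <- forcing_constant(90)
  expect_equal(light_at(fc, c(0, 1e4, 43200)), rep(90, 3))
  expect_error(light_at(fc, -1), "light period")
  expect_error(light_at(fs, 43201), "light period")
})

test_that("sinusoidal light integrates to I_max * day_length * 2/pi", {
  fs <- forcing_sinusoidal(I_max = 800, day_length = 43200)
  t <- seq(0, 43200, by = 1)
  I <- light_at(fs, t)
  integral <- sum((I[-1] + I[-length(I)]) / 2)   # trapezoid, 1 s grid
  expect_equal(integral, 800 * 43200 * 2 / pi, tolerance = 1e-3)
})

test_that("iron partition obeys the pool identities", {
  p <- tfp()
  # zero ambient iron -> empty cell
  z <- partition_iron(0, p)
  expect_true(all(unlist(z) == 0))
  # maintenance is 10% of metabolic iron at any positive Fe'
  fe <- c(1, 20, 40, 315, 1250, 1e4)
  pa <- partition_iron(fe, p)
  expect_equal(
    pa$Fe_maintenance / (pa$Fe_maintenance + pa$Fe_metabolic_allocatable),
    rep(0.10, length(fe)), tolerance = 1e-12)
  # partition identity to 1e-12 relative
  expect_equal(pa$Fe_storage + pa$Fe_maintenance +
                 pa$Fe_metabolic_allocatable,
               pa$Fe_total, tolerance = 1e-12)
  expect_error(partition_iron(-5, p), ">= 0")
})

test_that("total iron quota rises monotonically and saturates with Fe'", {
  p <- tfp()
  scan <- partition_iron(seq(20, 1800, by = 20), p)
  expect_true(all(diff(scan$Fe_total) > 0))
  # saturating: increments shrink
  expect_true(all(diff(diff(scan$Fe_total)) < 0))
  expect_lt(max(scan$Fe_total), p$Q_max)
})

test_that("config files round-trip through the key-value format", {
  p <- tf_params(vPETmax = 1.23e-3, kFeNF = 77)
  path <- tempfile(fileext = ".cfg")
  write_config(p, path)
  back <- read_config(path)
  expect_equal(unclass(back$params), unclass(p), tolerance = 1e-15)
  # namespaced keys and section keys
  writeLines(c("photo.vPETmax = 2e-3", "forcing.mode = constant",
               "forcing.I_const = 90", "environment.Fe_prime_pM = 40",
               "# a comment", "case.mode = dynamic"), path)
  cfg <- read_config(path)
  expect_equal(cfg$params$vPETmax, 2e-3)
  expect_equal(cfg$forcing$I_const, 90)
  expect_equal(cfg$forcing$mode, "constant")
  expect_equal(cfg$environment$Fe_prime_pM, 40)
  expect_error(tf_params(nonsense = 1), "unknown parameter")
})

test_that("the shipped default configuration matches tf_params()", {
  path <- system.file("extdata", "default-config.txt", package = "trichofe")
  cfg <- read_config(path)
  expect_identical(unclass(cfg$params), unclass(tf_params()))
  expect_equal(cfg$forcing$I_const, 90)
  expect_equal(cfg$environment$Fe_prime_pM, 40)
})
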