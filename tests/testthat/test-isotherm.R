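test_that("surface pressure is the tension deficit against clean water", {
  expect_equal(surface_pressure_from_tension(72.0), 0)
  expect_equal(surface_pressure_from_tension(23), 49)
  expect_equal(surface_pressure_from_tension(0), 72.0)
  expect_warning(surface_pressure_from_tension(80), "negative")
})

test_that("compression modulus reproduces closed-form curves", {
  a <- seq(100, 40, length.out = 200)

  # pi = k ln(A0/A)  ->  Cs^-1 = k everywhere
  iso_log <- isotherm(a, 60 * log(100 / a))
  mc <- compression_modulus(iso_log, window = 1L)
  interior <- mc$apl < 98 & mc$apl > 42
  expect_equal(mc$cs_inv[interior], rep(60, sum(interior)), tolerance = 1e-3)

  # constant pi -> zero modulus
  mc0 <- compression_modulus(isotherm(a, rep(5, 200)), window = 1L)
  expect_equal(mc0$cs_inv, rep(0, 200))

  # pi = c (A* - A)  ->  Cs^-1 = c A
  iso_lin <- isotherm(a, 0.5 * (100 - a))
  mcl <- compression_modulus(iso_lin, window = 1L)
  expect_equal(mcl$cs_inv[2:199], 0.5 * mcl$apl[2:199], tolerance = 1e-9)

  expect_error(compression_modulus(isotherm(c(3, 2, 1), c(0, 1, 2))),
               "at least 4")
})

test_that("modulus is invariant under rescaling of the area axis", {
  a <- seq(100, 40, length.out = 150)
  p <- 60 * log(100 / a)
  m1 <- compression_modulus(isotherm(a, p), window = 1L)
  m2 <- compression_modulus(isotherm(3 * a, p), window = 1L)
  expect_equal(m2$cs_inv, m1$cs_inv, tolerance = 1e-9)
})

test_that("Davies-Rideal phase bands are total, monotone, lower-band at ties", {
  expect_identical(classify_phase(10), "gaseous")
  expect_identical(classify_phase(75), "intermediate LE-LC")
  expect_identical(classify_phase(150), "LC")
  expect_identical(classify_phase(300), "solid")
  expect_identical(classify_phase(c(12.5, 50, 100, 250)),
                   c("gaseous", "LE", "intermediate LE-LC", "LC"))
  expect_error(classify_phase(-1), ">= 0")
  # monotone step function
  grid <- seq(0, 400, by = 0.5)
  lev <- match(classify_phase(grid),
               c("gaseous", "LE", "intermediate LE-LC", "LC", "solid"))
  expect_true(all(diff(lev) >= 0))
})

test_that("lift-off detection recovers the generator onset", {
  iso90 <- gen_isotherm(lift_off_apl = 90,
                        segments = data.frame(apl_from = 90, apl_to = 45,
                                              cs_inv = 60),
                        apl_max = 115)
  expect_equal(detect_lift_off(iso90), 90, tolerance = 0.1 / 90)

  flat <- isotherm(seq(110, 40, length.out = 50), rep(0, 50))
  expect_true(is.na(detect_lift_off(flat)))

  # noise at the instrument accuracy: within one grid step, many seeds
  grid_step <- (110 - 38) / 399
  for (s in 1:10) {
    est <- detect_lift_off(gen_isotherm(noise_sd = 0.1, seed = s))
    expect_lt(abs(est - 86), grid_step)
  }
})

test_that("collapse detection finds plateaus and kinks but not monotone rises", {
  expect_equal(detect_collapse(gen_isotherm())$pi_coll, 42, tolerance = 0.5 / 42)

  rising <- isotherm(seq(100, 40, length.out = 100),
                     60 * log(100 / seq(100, 40, length.out = 100)))
  expect_null(detect_collapse(rising))

  # two-segment curve with a kink at (pi* = 30, A* = 60)
  a <- seq(100, 40, length.out = 301)
  p <- pmin(0.75 * (100 - a), 30)
  kink <- detect_collapse(isotherm(a, p))
  expect_equal(kink$pi_coll, 30, tolerance = 0.01)
  expect_equal(kink$apl_coll, 60, tolerance = 2 * (100 - 40) / 300 / 60)
})

test_that("relaxation metrics recover decay constants and rates", {
  t <- seq(0, 600, by = 1)

  stable <- relaxation_trace(t, rep(1, length(t)))
  m <- relaxation_metrics(stable)
  expect_equal(m$area_loss_fraction, 0)
  expect_equal(m$initial_rate, 0)

  m_exp <- relaxation_metrics(gen_relaxation(k = 0.01, type = "exp"))
  expect_equal(m_exp$exp_constant, 0.01, tolerance = 1e-4 / 0.01)

  b <- 0.0005
  lin <- relaxation_trace(t, 1 - b * t)
  expect_equal(relaxation_metrics(lin)$initial_rate, b, tolerance = 1e-9)

  expect_error(relaxation_trace(c(0, 2, 1), c(1, 0.9, 0.8)), "increasing")
  expect_error(relaxation_trace(t, c(0.5, rep(1, length(t) - 1))), "start at 1")
})
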