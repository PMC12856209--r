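test_that("baseline correction subtracts the reference pointwise", {
  temps <- seq(95, 5, by = -1)
  sig <- 0.4 + 0.05 / (1 + exp((temps - 60) / 3))
  cv <- melting_curve(temps, sig, 295, "cooling", 0.2, "s")
  zero <- melting_curve(temps, rep(0, length(temps)), 335, "cooling", 0.2, "s")
  expect_equal(baseline_correct(cv, zero)$absorbance, cv$absorbance)

  self_ref <- melting_curve(temps, sig, 335, "cooling", 0.2, "s")
  expect_equal(baseline_correct(cv, self_ref)$absorbance, rep(0, length(temps)))

  const <- melting_curve(temps, rep(0.01, length(temps)), 335, "cooling", 0.2, "s")
  expect_equal(baseline_correct(cv, const)$absorbance, sig - 0.01)

  heat_ref <- melting_curve(rev(temps), rep(0, length(temps)), 335, "heating", 0.2, "s")
  expect_error(baseline_correct(cv, heat_ref), class = "pentaspec_pairing_error")

  short_ref <- melting_curve(seq(50, 5, -1), rep(0, 46), 335, "cooling", 0.2, "s")
  expect_error(baseline_correct(cv, short_ref), class = "pentaspec_range_error")
})

test_that("baseline correction interpolates a misaligned reference", {
  temps <- seq(90, 10, by = -1)
  cv <- melting_curve(temps, temps / 100, 295, "cooling", 0.2, "s")
  ref <- melting_curve(seq(95, 5, by = -0.7), seq(95, 5, by = -0.7) / 200,
    335, "cooling", 0.2, "s")
  corrected <- baseline_correct(cv, ref)
  expect_equal(corrected$absorbance, temps / 100 - temps / 200, tolerance = 1e-9)
})

test_that("TDS is the high-minus-low difference and is antisymmetric", {
  grid <- 220:335
  lo <- spectrum(grid, gauss_band(grid, 260, 15, 0.5), "ABS", 5, "s")
  hi <- spectrum(grid, gauss_band(grid, 262, 17, 0.55), "ABS", 95, "s")

  zero <- compute_tds(lo, lo)
  expect_equal(zero$value, rep(0, length(grid)))
  expect_identical(attr(zero, "temperature_label"), "TDS")

  shift <- spectrum(grid, lo$value + 0.1, "ABS", 95, "s")
  expect_equal(compute_tds(shift, lo)$value, rep(0.1, length(grid)))

  tds <- compute_tds(hi, lo)
  expect_equal(tds$value, hi$value - lo$value) # pointwise oracle
  expect_equal(compute_tds(lo, hi)$value, -tds$value)

  cd <- spectrum(grid, lo$value, "CD", 5, "s")
  expect_error(compute_tds(hi, cd), class = "pentaspec_channel_error")
})

test_that("TDS on mismatched grids equals brute-force subtraction", {
  g1 <- seq(218.5, 339.5, by = 1)
  g2 <- seq(220, 335, by = 0.5)
  hi <- spectrum(g1, gauss_band(g1, 273, 9, 0.3), "ABS", 95, "s")
  lo <- spectrum(g2, gauss_band(g2, 295, 6, 0.2), "ABS", 5, "s")
  tds <- compute_tds(hi, lo)
  common <- tds$wavelength_nm
  oracle <- approx(g1, hi$value, common)$y - approx(g2, lo$value, common)$y
  expect_equal(tds$value, oracle, tolerance = 1e-12)
})

test_that("signature classification is cosine-based, thresholded, scale-free", {
  templates <- signature_templates("CD")
  par <- templates$parallel_G4
  call <- classify_signature(par, templates, "CD")
  expect_identical(call$label, "parallel_G4")
  expect_equal(call$score, 1.0, tolerance = 1e-12)

  flat <- spectrum(220:335, rep(0, 116), "CD", 5, "flat")
  expect_identical(classify_signature(flat, templates, "CD")$label, "unclassified")
  expect_equal(classify_signature(flat, templates, "CD")$score, 0)

  set.seed(11)
  noisy_vals <- 0.9 * par$value + 0.1 * rnorm(nrow(par), sd = sd(par$value))
  noisy <- spectrum(par$wavelength_nm, noisy_vals, "CD", 5, "noisy")
  call2 <- classify_signature(noisy, templates, "CD")
  expect_identical(call2$label, "parallel_G4")
  # independent dot-product oracle on the same 220-335 grid
  a <- noisy_vals - mean(noisy_vals)
  b <- par$value - mean(par$value)
  expect_equal(call2$score, sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
    tolerance = 1e-10)

  # scale invariance of the call
  call3 <- classify_signature(
    spectrum(par$wavelength_nm, 0.037 * noisy_vals + 2, "CD", 5, "scaled"),
    templates, "CD"
  )
  expect_equal(call3$score, call2$score, tolerance = 1e-10)

  expect_error(classify_signature(par, list(), "CD"),
    class = "pentaspec_configuration_error")
})

test_that("derivative is exact for low-order polynomials", {
  temps <- seq(5, 95, by = 0.5)
  lin <- melting_curve(temps, 3 + 0.02 * temps, 295, "heating", 0.2, "lin")
  expect_lt(max(abs(derivative_curve(lin) - 0.02)), 1e-10)

  quad <- melting_curve(temps, (temps - 50)^2, 295, "heating", 0.2, "quad")
  expect_lt(max(abs(derivative_curve(quad) - 2 * (temps - 50))), 1e-8)

  expect_error(derivative_curve(lin, window_pts = 10),
    class = "pentaspec_parameter_error")
  short <- melting_curve(seq(5, 9, 1), rep(0, 5), 295, "heating", 0.2, "s")
  expect_error(derivative_curve(short, window_pts = 11),
    class = "pentaspec_parameter_error")
})

test_that("derivative of a van't Hoff curve matches central differences", {
  cv <- oracle_vanthoff_curve(tm_C = 60, dH_kcal = -50)
  d <- derivative_curve(cv)
  temps <- cv$temperature_C
  n <- length(temps)
  central <- (cv$absorbance[3:n] - cv$absorbance[1:(n - 2)]) /
    (temps[3:n] - temps[1:(n - 2)])
  # the window-11 smoother carries an O(window^2) attenuation bias through
  # the transition, so agreement is to the smoothing scale, and the
  # extremum position (what Tm estimation uses) must coincide
  dev <- abs(d[2:(n - 1)] - central)
  expect_lt(max(dev), 1e-2 * max(abs(central)))
  expect_lte(
    abs(temps[which.max(abs(d))] - temps[1 + which.max(abs(central))]),
    0.25
  )
})

test_that("flat curves yield no transition; logistic curves localize Tm", {
  temps <- seq(5, 95, by = 0.5)
  set.seed(3)
  flat <- melting_curve(temps, 0.40 + rnorm(length(temps), sd = 1e-4),
    295, "heating", 0.2, "flat")
  r <- estimate_tm(flat)
  expect_false(r$transition_detected)
  expect_true(is.na(r$tm_C))

  grid25 <- seq(5, 95, by = 0.25)
  logi <- melting_curve(grid25, 1 / (1 + exp(-(grid25 - 50) / 2.5)),
    295, "heating", 0.2, "logi")
  rl <- estimate_tm(logi)
  expect_true(rl$transition_detected)
  expect_lte(abs(rl$tm_C - 50), 0.25)
  expect_identical(rl$extremum_sign, "max")
  expect_equal(rl$amplitude, 1, tolerance = 1e-4)

  expect_error(estimate_tm(melting_curve(seq(5, 16, 0.5), rep(0, 23),
    295, "heating", 0.2, "tiny")), class = "pentaspec_insufficient_data_error")
})

test_that("Tm from a noise-free van't Hoff curve is within 0.5 C of model Tm", {
  cv <- oracle_vanthoff_curve(tm_C = 60, dH_kcal = -50)
  r <- estimate_tm(cv)
  expect_true(r$transition_detected)
  expect_lte(abs(r$tm_C - 60), 0.5)

  # the estimator finds the argmax of |dA/dT|; verify against a dense
  # numeric argmax on the analytic derivative of theta
  tm_dense <- local({
    tt <- seq(40, 80, by = 0.001)
    dH <- -50000
    dS <- dH / (60 + 273.15)
    K <- exp(-(dH - (tt + 273.15) * dS) / (1.987 * (tt + 273.15)))
    th <- K / (1 + K)
    tt[which.max(abs(diff(th) / diff(tt)))]
  })
  expect_lte(abs(r$tm_C - tm_dense), 0.25 + 1e-9)
})

test_that("Tm estimation is offset- and positive-scale-invariant", {
  cv <- oracle_vanthoff_curve(tm_C = 55, dH_kcal = -45)
  r0 <- estimate_tm(cv)
  shifted <- melting_curve(cv$temperature_C, cv$absorbance + 0.7,
    295, "cooling", 0.2, "s")
  scaled <- melting_curve(cv$temperature_C, 3.5 * cv$absorbance,
    295, "cooling", 0.2, "s")
  r1 <- estimate_tm(shifted)
  r2 <- estimate_tm(scaled)
  expect_equal(r1$tm_C, r0$tm_C)
  expect_equal(r2$tm_C, r0$tm_C)
  expect_equal(r1$amplitude, r0$amplitude)
  expect_equal(r2$amplitude, 3.5 * r0$amplitude)
})

test_that("hysteresis midpoint and flag follow the definitions", {
  mk <- function(tm, direction) {
    temps <- if (direction == "cooling") seq(95, 5, -0.5) else seq(5, 95, 0.5)
    cv <- melting_curve(temps, 1 / (1 + exp((temps - tm) / 2.5)),
      295, direction, 0.2, "h")
    estimate_tm(cv)
  }
  h <- hysteresis(mk(49, "cooling"), mk(57, "heating"))
  expect_equal(h$midpoint_C, 53.0)
  expect_true(h$hysteretic)

  h2 <- hysteresis(mk(60, "cooling"), mk(60, "heating"))
  expect_equal(h2$midpoint_C, 60.0)
  expect_false(h2$hysteretic)

  flatr <- estimate_tm(melting_curve(seq(5, 95, 0.5),
    rep(0.4, 181), 295, "heating", 0.2, "f"))
  expect_error(hysteresis(mk(60, "cooling"), flatr),
    class = "pentaspec_upstream_detection_error")
})

test_that("tidy/glance expose melt results as tibbles", {
  r <- estimate_tm(oracle_vanthoff_curve())
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("temperature_C", "dA_dT"))
  g <- glance(r)
  expect_identical(nrow(g), 1L)
  expect_true(g$transition_detected)
})
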