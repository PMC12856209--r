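test_that("equilibrium folded fraction obeys mass action", {
  # molecularity 1: theta = 0.5 exactly where dG = 0
  m1 <- two_state_model(-50, -50000 / 333.15)
  expect_equal(equilibrium_fraction_folded(m1, 333.15 - 273.15), 0.5,
    tolerance = 1e-12)
  # saturation 40 C below Tm
  expect_gte(equilibrium_fraction_folded(m1, 333.15 - 273.15 - 40), 0.999)

  # molecularity 2 vs an independent uniroot oracle on the mass-action balance
  m2 <- two_state_model(-60, -160, molecularity = 2, total_strand_conc_M = 6e-6)
  th <- equilibrium_fraction_folded(m2, 37)
  K <- exp(-(-60000 - (37 + 273.15) * (-160)) / (1.987 * (37 + 273.15)))
  oracle <- uniroot(function(x) x - 2 * K * 6e-6 * (1 - x)^2, c(0, 1),
    tol = 1e-14)$root
  expect_lt(abs(th - oracle), 1e-8)

  # molecularity 4 satisfies its own balance equation
  m4 <- two_state_model(-90, -240, molecularity = 4, total_strand_conc_M = 6e-6)
  th4 <- equilibrium_fraction_folded(m4, 40)
  K4 <- exp(-(-90000 - (40 + 273.15) * (-240)) / (1.987 * (40 + 273.15)))
  expect_lt(abs(th4 - 4 * K4 * (6e-6)^3 * (1 - th4)^4), 1e-10)

  expect_error(equilibrium_fraction_folded(m1, 150), class = "pentaspec_domain_error")
  expect_error(two_state_model(-60, -160, molecularity = 2),
    class = "pentaspec_domain_error")
  expect_error(two_state_model(-60, -160, molecularity = 3),
    class = "pentaspec_domain_error")
})

test_that("theta is monotone non-increasing in T for exothermic folding", {
  tt <- seq(0, 110, by = 0.25)
  for (m in list(
    two_state_model(-50, -150),
    two_state_model(-60, -160, molecularity = 2, total_strand_conc_M = 3e-6),
    two_state_model(-90, -230, molecularity = 4, total_strand_conc_M = 6e-6)
  )) {
    expect_true(all(diff(equilibrium_fraction_folded(m, tt)) <= 1e-12))
  }
})

test_that("closed-form Tm agrees with bisection on theta = 0.5", {
  m1 <- two_state_model(-50, -150.105)
  expect_equal(predict_tm(m1), -50000 / -150.105 - 273.15, tolerance = 1e-9)
  expect_equal(predict_tm(m1), 59.93, tolerance = 0.01)

  bisect_tm <- function(m) {
    uniroot(function(tc) equilibrium_fraction_folded(m, tc) - 0.5,
      c(1, 109), tol = 1e-10)$root
  }
  m2 <- two_state_model(-60, -157.9, molecularity = 2, total_strand_conc_M = 2e-6)
  expect_lt(abs(predict_tm(m2) - bisect_tm(m2)), 0.01)
  m4 <- two_state_model(-90, -233, molecularity = 4, total_strand_conc_M = 6e-6)
  expect_lt(abs(predict_tm(m4) - bisect_tm(m4)), 0.01)

  # intermolecular Tm increases with strand concentration
  m2hi <- two_state_model(-60, -157.9, molecularity = 2, total_strand_conc_M = 2e-5)
  expect_gt(predict_tm(m2hi), predict_tm(m2))
})

test_that("equilibrium simulation maps theta through the baselines", {
  m <- two_state_model(-50, -50000 / 333.15,
    folded_baseline = c(1, 0), unfolded_baseline = c(0, 0))
  proto <- ramp_protocol(95, 5, 0.2, 0.5)
  cv <- simulate_equilibrium_melt(m, proto)
  expect_s3_class(cv, "melting_curve")
  expect_identical(melting_meta(cv)$direction, "cooling")
  i_tm <- which(abs(cv$temperature_C - 60) < 1e-9)
  expect_equal(cv$absorbance[i_tm], 0.5, tolerance = 1e-3)

  # determinism under a fixed seed
  a <- simulate_equilibrium_melt(m, proto, noise_sd = 1e-3, seed = 77)
  b <- simulate_equilibrium_melt(m, proto, noise_sd = 1e-3, seed = 77)
  expect_identical(a$absorbance, b$absorbance)
  c2 <- simulate_equilibrium_melt(m, proto, noise_sd = 1e-3, seed = 78)
  expect_false(identical(a$absorbance, c2$absorbance))
})

test_that("equilibrium cooling and heating agree within one sample step", {
  m <- preset_model("intramolecular_G4")
  cool <- estimate_tm(simulate_equilibrium_melt(m, ramp_protocol(95, 5, 0.2, 0.5)))
  heat <- estimate_tm(simulate_equilibrium_melt(m, ramp_protocol(5, 95, 0.2, 0.5)))
  expect_true(cool$transition_detected && heat$transition_detected)
  expect_lte(abs(cool$tm_C - heat$tm_C), 0.5)
})

test_that("kinetic integration has correct fast and frozen limits", {
  slow <- preset_model("bimolecular_G4_slow")
  proto <- ramp_protocol(95, 5, 2)

  fast <- scale_kinetics(slow, 1e6)
  kin <- simulate_kinetic_ramp(fast, proto)
  eq <- simulate_equilibrium_melt(slow, proto)
  # compare in theta units: baselines are 0.02 apart
  theta_gap <- max(abs(kin$absorbance - eq$absorbance)) / 0.02
  expect_lt(theta_gap, 1e-3)

  frozen <- scale_kinetics(slow, 0)
  kf <- simulate_kinetic_ramp(frozen, proto)
  theta0 <- equilibrium_fraction_folded(slow, 95)
  expected <- theta0 * (0.45 + 1e-4 * kf$temperature_C) +
    (1 - theta0) * (0.43 + 1e-4 * kf$temperature_C)
  expect_equal(kf$absorbance, expected, tolerance = 1e-9)

  expect_error(
    simulate_kinetic_ramp(preset_model("intramolecular_G4"), proto),
    class = "pentaspec_domain_error"
  )
})

test_that("kinetic curves approach equilibrium as the ramp slows", {
  slow <- preset_model("bimolecular_G4_slow")
  gaps <- vapply(c(2, 0.2, 0.02), function(rate) {
    proto <- ramp_protocol(95, 5, rate)
    kin <- simulate_kinetic_ramp(slow, proto)
    eq <- simulate_equilibrium_melt(slow, proto)
    max(abs(kin$absorbance - eq$absorbance)) / 0.02
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("kinetic bimolecular ramps are hysteretic at 2 C/min, not at 0.02", {
  slow <- preset_model("bimolecular_G4_slow")
  tm_pair <- function(rate) {
    co <- estimate_tm(simulate_kinetic_ramp(slow, ramp_protocol(95, 5, rate)))
    he <- estimate_tm(simulate_kinetic_ramp(slow, ramp_protocol(5, 95, rate)))
    hysteresis(co, he)
  }
  h_fast <- tm_pair(2)
  expect_gt(h_fast$tm_heating_C - h_fast$tm_cooling_C, 1)
  expect_true(h_fast$hysteretic)
  expect_equal(h_fast$midpoint_C,
    (h_fast$tm_cooling_C + h_fast$tm_heating_C) / 2)

  h_slow <- tm_pair(0.02)
  expect_lt(abs(h_slow$tm_heating_C - h_slow$tm_cooling_C),
    h_fast$tm_heating_C - h_fast$tm_cooling_C)
  expect_false(h_slow$hysteretic)
})

test_that("band spectra evaluate Gaussian sums with preset extrema", {
  grid <- 220:335
  one <- generate_band_spectrum(
    bands = data.frame(center_nm = 280, width_nm = 9, amplitude = 2.5),
    grid = grid
  )
  expect_equal(one$value[one$wavelength_nm == 280], 2.5)

  b1 <- data.frame(center_nm = 264, width_nm = 7, amplitude = 6)
  b2 <- data.frame(center_nm = 245, width_nm = 7, amplitude = -3)
  both <- generate_band_spectrum(bands = rbind(b1, b2), grid = grid)
  expect_equal(
    both$value,
    generate_band_spectrum(bands = b1, grid = grid)$value +
      generate_band_spectrum(bands = b2, grid = grid)$value
  )

  dup <- generate_band_spectrum(preset = "non_G4_duplex_CD", grid = grid)
  expect_equal(dup$wavelength_nm[which.max(dup$value)], 280)
  expect_equal(dup$wavelength_nm[which.min(dup$value)], 258)

  expect_error(generate_band_spectrum(preset = "nope"),
    class = "pentaspec_domain_error")
})

test_that("mixture generation round-trips through fraction estimation", {
  b <- demo_basis()
  expect_equal(generate_mixture_spectrum(b, 0)$value, b$cd_g4)
  expect_equal(generate_mixture_spectrum(b, 1)$value, b$cd_non_g4)
  fit <- estimate_fraction(generate_mixture_spectrum(b, 0.55), b)
  expect_lt(abs(fit$f_refined - 0.55), 1e-9)

  m1 <- generate_mixture_spectrum(b, 0.3, noise_sd = 0.05, seed = 4)
  m2 <- generate_mixture_spectrum(b, 0.3, noise_sd = 0.05, seed = 4)
  expect_identical(m1$value, m2$value)
})

test_that("presets land in their stated regimes", {
  expect_equal(predict_tm(preset_model("intramolecular_G4")), 71, tolerance = 1e-6)
  expect_equal(predict_tm(preset_model("bimolecular_duplex")), 53, tolerance = 1e-6)
  expect_equal(predict_tm(preset_model("bimolecular_G4_slow")), 58, tolerance = 1e-6)
  # concentration dependence carried by mass action
  expect_gt(
    predict_tm(preset_model("bimolecular_duplex", total_strand_conc_M = 2e-5)),
    predict_tm(preset_model("bimolecular_duplex"))
  )
})
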