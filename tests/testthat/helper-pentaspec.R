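# Shared fixture builders. All fixtures are generated in code; no data files.

# single Gaussian band evaluated on a grid (independent of the package's
# band generator)
gauss_band <- function(grid, center, sigma, amplitude = 1) {
  amplitude * exp(-(grid - center)^2 / (2 * sigma^2))
}

# a small well-separated CD basis for decomposition tests
demo_basis <- function(grid = 230:320) {
  basis_set(
    grid,
    cd_g4 = gauss_band(grid, 264, 7, 6) + gauss_band(grid, 245, 7, -3),
    cd_non_g4 = gauss_band(grid, 280, 7, 3) + gauss_band(grid, 258, 7, -3)
  )
}

# noise-free intramolecular van't Hoff melting curve with flat 0/1 baselines,
# built without the package's simulator (independent oracle path):
# theta(T) = K/(1+K), K = exp(-(dH - T*dS)/(R*T_K))
oracle_vanthoff_curve <- function(tm_C = 60, dH_kcal = -50,
                                  temps = seq(95, 5, by = -0.25),
                                  direction = "cooling") {
  dH <- dH_kcal * 1000
  dS <- dH / (tm_C + 273.15)
  TK <- temps + 273.15
  K <- exp(-(dH - TK * dS) / (1.987 * TK))
  theta <- K / (1 + K)
  melting_curve(temps, 1 - theta,
    wavelength_nm = 295, direction = direction,
    ramp_rate_C_per_min = 0.2, sample_id = "oracle"
  )
}
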