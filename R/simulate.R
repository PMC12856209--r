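# Synthetic-data generation: mass-action two-state melting (molecularity 1,
# 2 or 4) under van't Hoff thermodynamics, finite-rate kinetic ramps that
# reproduce cooling/heating hysteresis, Gaussian-band CD/TDS spectra and
# noisy two-basis mixtures. These simulations stand in for raw instrument
# data when validating the analysis pipeline.

#' Two-state folding model
#'
#' Thermodynamic (and optionally kinetic) description of one folded species.
#' The equilibrium constant is K(T) = exp(-(dH - T*dS) / (R*T)) with
#' R = 1.987 cal mol^-1 K^-1 and T in Kelvin; the folded fraction theta is
#' defined per strand (the quantity absorbance reports). Conventions: dH < 0
#' and dS < 0 for folding (exothermic, order-forming).
#'
#' When `kinetics` is supplied (a list with `A_fold` and `Ea_fold_kcal_mol`,
#' the Arrhenius prefactor and activation energy of the folding/association
#' rate), the unfolding rate is derived from detailed balance,
#' k_unfold(T) = k_fold(T) / K(T), so the kinetic model is thermodynamically
#' consistent by construction. For molecularity m the association rate
#' constant has units M^-(m-1) s^-1.
#'
#' @param delta_H_kcal_mol Folding enthalpy, kcal/mol (negative).
#' @param delta_S_cal_mol_K Folding entropy, cal/(mol K) (negative).
#' @param molecularity 1 (intramolecular), 2 (bimolecular) or 4
#'   (tetramolecular).
#' @param total_strand_conc_M Total strand concentration in mol/L (required
#'   for molecularity > 1).
#' @param folded_baseline,unfolded_baseline Length-2 numeric
#'   `(intercept, slope per C)` giving the absorbance of the pure folded /
#'   unfolded forms as linear functions of temperature.
#' @param kinetics Optional list `list(A_fold = , Ea_fold_kcal_mol = )`.
#' @return An object of class `two_state_model`.
#' @export
two_state_model <- function(delta_H_kcal_mol, delta_S_cal_mol_K,
                            molecularity = 1,
                            total_strand_conc_M = NA_real_,
                            folded_baseline = c(1, 0),
                            unfolded_baseline = c(0, 0),
                            kinetics = NULL) {
  if (!molecularity %in% c(1, 2, 4)) {
    .ps_abort("`molecularity` must be 1, 2 or 4.", "domain_error")
  }
  if (molecularity > 1 && (is.na(total_strand_conc_M) || total_strand_conc_M <= 0)) {
    .ps_abort("intermolecular models need a positive `total_strand_conc_M`.",
      "domain_error")
  }
  if (!is.null(kinetics)) {
    if (!all(c("A_fold", "Ea_fold_kcal_mol") %in% names(kinetics))) {
      .ps_abort("`kinetics` needs elements A_fold and Ea_fold_kcal_mol.",
        "domain_error")
    }
    if (kinetics$A_fold < 0) {
      .ps_abort("`A_fold` must be >= 0.", "domain_error")
    }
  }
  structure(
    list(
      delta_H_kcal_mol = delta_H_kcal_mol,
      delta_S_cal_mol_K = delta_S_cal_mol_K,
      molecularity = as.integer(molecularity),
      total_strand_conc_M = total_strand_conc_M,
      folded_baseline = folded_baseline,
      unfolded_baseline = unfolded_baseline,
      kinetics = kinetics
    ),
    class = "two_state_model"
  )
}

#' @export
print.two_state_model <- function(x, ...) {
  cat(sprintf(
    "<two_state_model> m = %d, dH = %g kcal/mol, dS = %g cal/mol/K%s%s\n",
    x$molecularity, x$delta_H_kcal_mol, x$delta_S_cal_mol_K,
    if (x$molecularity > 1) sprintf(", C_T = %g M", x$total_strand_conc_M) else "",
    if (!is.null(x$kinetics)) " (kinetic)" else ""
  ))
  invisible(x)
}

#' Temperature ramp protocol
#'
#' @param start_C,end_C Ramp endpoints in Celsius (span >= 10 C). A start
#'   above the end defines a cooling ramp, below it a heating ramp.
#' @param rate_C_per_min Positive ramp rate.
#' @param sample_interval_C Sampling interval in Celsius (<= 1).
#' @return An object of class `ramp_protocol`.
#' @export
ramp_protocol <- function(start_C = 95, end_C = 5, rate_C_per_min = 0.2,
                          sample_interval_C = 0.5) {
  if (abs(start_C - end_C) < 10) {
    .ps_abort("ramp must span at least 10 C.", "domain_error")
  }
  if (rate_C_per_min <= 0) .ps_abort("rate must be positive.", "domain_error")
  if (sample_interval_C <= 0 || sample_interval_C > 1) {
    .ps_abort("`sample_interval_C` must be in (0, 1].", "domain_error")
  }
  structure(
    list(
      start_C = start_C, end_C = end_C,
      rate_C_per_min = rate_C_per_min,
      sample_interval_C = sample_interval_C,
      direction = if (start_C > end_C) "cooling" else "heating"
    ),
    class = "ramp_protocol"
  )
}

.ramp_temperatures <- function(protocol) {
  s <- if (protocol$direction == "cooling") -protocol$sample_interval_C else {
    protocol$sample_interval_C
  }
  seq(protocol$start_C, protocol$end_C, by = s)
}

# van't Hoff equilibrium constant (per-strand mass-action convention)
.equilibrium_K <- function(model, T_C) {
  T_K <- T_C + .T0_K
  dG <- model$delta_H_kcal_mol * 1000 - T_K * model$delta_S_cal_mol_K
  exp(-dG / (.R_CAL * T_K))
}

#' Equilibrium fraction of folded strands
#'
#' Fraction theta of strands in the folded species at temperature `T_C`.
#' Molecularity 1: theta = K / (1 + K). Molecularity m > 1: theta solves
#' theta = m * K * C_T^(m-1) * (1 - theta)^m (mass action with theta defined
#' per strand), found by bisection — the right-hand side is decreasing in
#' theta so the root is unique.
#'
#' @param model A `two_state_model`.
#' @param T_C Temperature(s) in Celsius, each in `[0, 110]`.
#' @return Numeric vector of folded fractions in `[0, 1]`.
#' @export
equilibrium_fraction_folded <- function(model, T_C) {
  stopifnot(inherits(model, "two_state_model"))
  if (any(T_C < 0 | T_C > 110)) {
    .ps_abort("`T_C` must lie in [0, 110] C.", "domain_error")
  }
  K <- .equilibrium_K(model, T_C)
  m <- model$molecularity
  if (m == 1L) {
    return(K / (1 + K))
  }
  cc <- model$total_strand_conc_M
  vapply(K, function(k) {
    a <- m * k * cc^(m - 1)
    # h(theta) = theta - a * (1 - theta)^m: h(0) <= 0, h(1) = 1 > 0
    lo <- 0
    hi <- 1
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (mid - a * (1 - mid)^m > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' Predicted melting temperature (theta = 0.5)
#'
#' Closed forms from the van't Hoff equilibrium at half-folding:
#' molecularity 1: Tm_K = dH / dS; molecularity 2: K(Tm) = 1/C_T gives
#' Tm_K = dH / (dS + R ln C_T); molecularity 4: K(Tm) = 2/C_T^3 gives
#' Tm_K = dH / (dS - R ln 2 + 3 R ln C_T). (dH in cal/mol here; exported
#' units are kcal/mol.) Results outside `[0, 110]` C are clamped with a
#' warning.
#'
#' @param model A `two_state_model` with nonzero enthalpy.
#' @return Melting temperature in Celsius.
#' @export
predict_tm <- function(model) {
  stopifnot(inherits(model, "two_state_model"))
  dH <- model$delta_H_kcal_mol * 1000
  dS <- model$delta_S_cal_mol_K
  if (dH == 0) .ps_abort("`delta_H_kcal_mol` must be nonzero.", "domain_error")
  cc <- model$total_strand_conc_M
  Tm_K <- switch(as.character(model$molecularity),
    "1" = dH / dS,
    "2" = dH / (dS + .R_CAL * log(cc)),
    "4" = dH / (dS - .R_CAL * log(2) + 3 * .R_CAL * log(cc))
  )
  Tm_C <- Tm_K - .T0_K
  if (is.na(Tm_C) || Tm_C < 0 || Tm_C > 110) {
    warn(sprintf("predicted Tm (%.1f C) outside [0, 110] C; clamped.", Tm_C))
    Tm_C <- min(110, max(0, Tm_C))
  }
  Tm_C
}

.baseline_eval <- function(b, T_C) b[1] + b[2] * T_C

.theta_to_curve <- function(theta, model, protocol, temps, wavelength_nm,
                            noise_sd, seed, sample_id) {
  A <- theta * .baseline_eval(model$folded_baseline, temps) +
    (1 - theta) * .baseline_eval(model$unfolded_baseline, temps)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit({
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    A <- A + rnorm(length(A), sd = noise_sd)
  }
  melting_curve(
    temps, A,
    wavelength_nm = wavelength_nm, direction = protocol$direction,
    ramp_rate_C_per_min = protocol$rate_C_per_min, sample_id = sample_id
  )
}

#' Simulate an equilibrium melting curve
#'
#' The absorbance track of a fully equilibrated ramp:
#' A(T) = theta(T) * folded_baseline(T) + (1 - theta(T)) *
#' unfolded_baseline(T), plus optional seeded Gaussian noise. Cooling and
#' heating ramps of the same model coincide (no hysteresis at equilibrium).
#'
#' @param model A `two_state_model`.
#' @param protocol A `ramp_protocol`.
#' @param wavelength_nm Nominal detection wavelength recorded in the output
#'   (default 295).
#' @param noise_sd Gaussian noise standard deviation in absorbance units
#'   (default 0).
#' @param seed Optional integer seed for the noise (the ambient RNG state is
#'   restored afterwards).
#' @param sample_id Sample identifier (default `"sim"`).
#' @return A `melting_curve`.
#' @export
simulate_equilibrium_melt <- function(model, protocol, wavelength_nm = 295,
                                      noise_sd = 0, seed = NULL,
                                      sample_id = "sim") {
  stopifnot(inherits(model, "two_state_model"), inherits(protocol, "ramp_protocol"))
  if (noise_sd < 0) .ps_abort("`noise_sd` must be >= 0.", "domain_error")
  temps <- .ramp_temperatures(protocol)
  theta <- equilibrium_fraction_folded(model, temps)
  .theta_to_curve(theta, model, protocol, temps, wavelength_nm, noise_sd, seed,
    sample_id)
}

# folding/unfolding rates at temperature T_C (detailed balance enforced)
.rates_at <- function(model, T_C) {
  T_K <- T_C + .T0_K
  kin <- model$kinetics
  k_f <- kin$A_fold * exp(-kin$Ea_fold_kcal_mol * 1000 / (.R_CAL * T_K))
  k_u <- k_f / .equilibrium_K(model, T_C)
  list(k_f = k_f, k_u = k_u)
}

#' Simulate a finite-rate (kinetic) melting ramp
#'
#' Integrates the per-strand folding kinetics along a linear temperature
#' ramp, which reproduces the hysteresis seen when a ramp outpaces slow
#' association/dissociation (as for long intermolecular G-quadruplexes).
#' The rate law by molecularity m is
#' dtheta/dt = m * k_fold(T) * C_T^(m-1) * (1 - theta)^m - k_unfold(T) * theta
#' (with C_T^0 = 1 for m = 1), k_unfold derived from detailed balance.
#' Integration uses the stiff-capable `deSolve::lsoda` solver with tight
#' tolerances; the initial condition is the equilibrium fraction at the
#' start temperature.
#'
#' @inheritParams simulate_equilibrium_melt
#' @param rtol,atol Integration tolerances passed to [deSolve::ode()].
#' @return A `melting_curve`.
#' @export
simulate_kinetic_ramp <- function(model, protocol, wavelength_nm = 295,
                                  noise_sd = 0, seed = NULL, sample_id = "sim",
                                  rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "two_state_model"), inherits(protocol, "ramp_protocol"))
  if (is.null(model$kinetics)) {
    .ps_abort("model has no kinetics; use simulate_equilibrium_melt().",
      "domain_error")
  }
  if (noise_sd < 0) .ps_abort("`noise_sd` must be >= 0.", "domain_error")
  temps <- .ramp_temperatures(protocol)
  rate_per_s <- protocol$rate_C_per_min / 60
  sign_dir <- if (protocol$direction == "cooling") -1 else 1
  times <- abs(temps - protocol$start_C) / rate_per_s

  m <- model$molecularity
  cc <- if (m > 1L) model$total_strand_conc_M else 1
  theta0 <- equilibrium_fraction_folded(model, protocol$start_C)

  deriv <- function(t, y, parms) {
    T_C <- protocol$start_C + sign_dir * rate_per_s * t
    r <- .rates_at(model, T_C)
    th <- min(1, max(0, y[1]))
    list(m * r$k_f * cc^(m - 1) * (1 - th)^m - r$k_u * th)
  }
  sol <- deSolve::ode(
    y = c(theta = theta0), times = times, func = deriv, parms = NULL,
    method = "lsoda", rtol = rtol, atol = atol
  )
  theta <- sol[, "theta"]
  if (any(theta < -1e-6 | theta > 1 + 1e-6)) {
    .ps_abort("integration left [0, 1]; tighten rtol/atol.", "integration_error")
  }
  theta <- pmin(1, pmax(0, theta))
  .theta_to_curve(theta, model, protocol, temps, wavelength_nm, noise_sd, seed,
    sample_id)
}

#' Scale the kinetic rates of a model
#'
#' Multiplies the folding prefactor by `factor` (the unfolding rate follows
#' through detailed balance). `factor` large approaches the equilibrium
#' limit; `factor = 0` freezes the system at its initial state.
#'
#' @param model A kinetic `two_state_model`.
#' @param factor Non-negative scale factor.
#' @return The rescaled model.
#' @export
scale_kinetics <- function(model, factor) {
  stopifnot(inherits(model, "two_state_model"))
  if (is.null(model$kinetics)) .ps_abort("model has no kinetics.", "domain_error")
  if (factor < 0) .ps_abort("`factor` must be >= 0.", "domain_error")
  model$kinetics$A_fold <- model$kinetics$A_fold * factor
  model
}

# Gaussian band presets. Band placements follow the classic CD signatures:
# parallel G4 (+265/-245 region), antiparallel G4 (+295/-265), non-G4
# homopurine duplex (+280/-258), and a G4-type TDS (+243, +273, -295).
# Amplitudes/widths are synthetic conventions (CD in mdeg, TDS in dA).
.band_presets <- list(
  parallel_G4_CD = tibble::tibble(
    center_nm = c(264, 245), width_nm = c(7, 7), amplitude = c(6, -3)
  ),
  antiparallel_G4_CD = tibble::tibble(
    center_nm = c(295, 265), width_nm = c(7, 8), amplitude = c(4, -3)
  ),
  hybrid_G4_CD = tibble::tibble(
    center_nm = c(290, 265, 240), width_nm = c(7, 7, 6), amplitude = c(4, 2.5, -2)
  ),
  non_G4_duplex_CD = tibble::tibble(
    center_nm = c(280, 258), width_nm = c(7, 7), amplitude = c(3, -3)
  ),
  G4_TDS = tibble::tibble(
    center_nm = c(243, 273, 295), width_nm = c(6, 7, 5),
    amplitude = c(0.05, 0.08, -0.06)
  )
)

#' Names of the bundled band presets
#' @return Character vector of preset names.
#' @export
band_preset_names <- function() names(.band_presets)

#' Generate a Gaussian-band spectrum
#'
#' Evaluates a sum of Gaussian bands, `sum_j a_j exp(-(lambda - c_j)^2 /
#' (2 w_j^2))`, on a wavelength grid, plus optional seeded noise. Either an
#' explicit band table or a bundled preset name may be given.
#'
#' @param bands Tibble/data frame with columns `center_nm`, `width_nm`
#'   (Gaussian sigma) and `amplitude`; or `NULL` to use `preset`.
#' @param preset One of [band_preset_names()].
#' @param grid Wavelength grid in nm, within `[200, 400]`
#'   (default `220:335`).
#' @param channel `"CD"` or `"ABS"` (default CD; the TDS preset is ABS-like).
#' @param noise_sd Gaussian noise sd (default 0).
#' @param seed Optional integer seed.
#' @param temperature_C,sample_id Metadata for the output spectrum.
#' @return A `spectrum`.
#' @examples
#' generate_band_spectrum(preset = "non_G4_duplex_CD")
#' @export
generate_band_spectrum <- function(bands = NULL, preset = NULL, grid = 220:335,
                                   channel = c("CD", "ABS"), noise_sd = 0,
                                   seed = NULL, temperature_C = 5,
                                   sample_id = preset %||% "bands") {
  channel <- match.arg(channel)
  if (is.null(bands)) {
    if (is.null(preset) || !preset %in% names(.band_presets)) {
      .ps_abort(sprintf("unknown preset; available: %s",
        paste(names(.band_presets), collapse = ", ")), "domain_error")
    }
    bands <- .band_presets[[preset]]
  }
  bands <- as_tibble(bands)
  if (any(bands$width_nm <= 0)) .ps_abort("band widths must be > 0.", "domain_error")
  if (min(grid) < 200 || max(grid) > 400) {
    .ps_abort("`grid` must lie within [200, 400] nm.", "domain_error")
  }
  v <- rep(0, length(grid))
  for (j in seq_len(nrow(bands))) {
    v <- v + bands$amplitude[j] *
      exp(-(grid - bands$center_nm[j])^2 / (2 * bands$width_nm[j]^2))
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit({
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    v <- v + rnorm(length(v), sd = noise_sd)
  }
  spectrum(grid, v, channel = channel, temperature_C = temperature_C,
    sample_id = sample_id)
}

#' Bundled signature template library
#'
#' CD (or TDS) templates built from the band presets, for use with
#' [classify_signature()].
#'
#' @param kind `"CD"` or `"TDS"`.
#' @param grid Wavelength grid (default `220:335`).
#' @return Named list of `spectrum` objects.
#' @export
signature_templates <- function(kind = c("CD", "TDS"), grid = 220:335) {
  kind <- match.arg(kind)
  if (kind == "CD") {
    nm <- c(
      parallel_G4 = "parallel_G4_CD",
      antiparallel_G4 = "antiparallel_G4_CD",
      hybrid_G4 = "hybrid_G4_CD",
      non_G4_duplex = "non_G4_duplex_CD"
    )
    imap(as.list(nm), function(p, lab) {
      generate_band_spectrum(preset = p, grid = grid, channel = "CD",
        sample_id = lab)
    })
  } else {
    list(G4 = generate_band_spectrum(preset = "G4_TDS", grid = grid,
      channel = "ABS", sample_id = "G4"))
  }
}

#' Generate a noisy two-basis mixture spectrum
#'
#' `calculated_spectrum(basis, f_true)` plus seeded Gaussian noise, packaged
#' as a CD `spectrum` — the test harness for fraction estimation.
#'
#' @param basis A `basis_set`.
#' @param f_true True non-G4 fraction in `[0, 1]`.
#' @param noise_sd Gaussian noise sd in the basis signal units (default 0).
#' @param seed Optional integer seed.
#' @param sample_id Sample identifier.
#' @return A CD `spectrum` on the basis grid.
#' @export
generate_mixture_spectrum <- function(basis, f_true, noise_sd = 0, seed = NULL,
                                      sample_id = "mixture") {
  stopifnot(inherits(basis, "basis_set"))
  v <- calculated_spectrum(basis, f_true)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit({
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    v <- v + rnorm(length(v), sd = noise_sd)
  }
  spectrum(basis$wavelength_nm, v, channel = "CD", temperature_C = 5,
    sample_id = sample_id)
}

# Entropy that places theta = 0.5 at Tm_C for the given molecularity
.delta_S_for_tm <- function(delta_H_kcal_mol, Tm_C, molecularity, conc_M = NA) {
  Tm_K <- Tm_C + .T0_K
  dH <- delta_H_kcal_mol * 1000
  switch(as.character(molecularity),
    "1" = dH / Tm_K,
    "2" = dH / Tm_K - .R_CAL * log(conc_M),
    "4" = dH / Tm_K + .R_CAL * log(2) - 3 * .R_CAL * log(conc_M)
  )
}

#' Bundled two-state model presets
#'
#' Three fixture regimes mirroring the behaviours the analysis pipeline must
#' handle (parameter values are simulation conventions, not measured
#' quantities):
#' \describe{
#'   \item{`intramolecular_G4`}{"TGGGT-like": molecularity 1, Tm 71 C,
#'     no hysteresis.}
#'   \item{`bimolecular_duplex`}{"AGGGA-duplex-like": molecularity 2 at
#'     2 uM strands, Tm ~ 53 C, concentration-dependent.}
#'   \item{`bimolecular_G4_slow`}{"AGGGA-G4-like": molecularity 2 at
#'     1.5 uM strands with slow association/dissociation kinetics;
#'     hysteretic at ordinary ramp rates (0.2-2 C/min).}
#' }
#'
#' @param name Preset name.
#' @param total_strand_conc_M Optional override of the strand concentration
#'   (intermolecular presets keep Tm consistent by reusing the preset
#'   entropy, so Tm then shifts with concentration as mass action demands).
#' @return A `two_state_model`.
#' @export
preset_model <- function(name = c(
                           "intramolecular_G4", "bimolecular_duplex",
                           "bimolecular_G4_slow"
                         ),
                         total_strand_conc_M = NULL) {
  name <- match.arg(name)
  switch(name,
    intramolecular_G4 = {
      dH <- -55
      two_state_model(
        delta_H_kcal_mol = dH,
        delta_S_cal_mol_K = .delta_S_for_tm(dH, 71, 1),
        molecularity = 1,
        folded_baseline = c(0.45, 1e-4),
        unfolded_baseline = c(0.40, 1e-4)
      )
    },
    bimolecular_duplex = {
      dH <- -60
      cc <- total_strand_conc_M %||% 2e-6
      two_state_model(
        delta_H_kcal_mol = dH,
        delta_S_cal_mol_K = .delta_S_for_tm(dH, 53, 2, 2e-6),
        molecularity = 2,
        total_strand_conc_M = cc,
        folded_baseline = c(0.42, 1e-4),
        unfolded_baseline = c(0.38, 1e-4)
      )
    },
    bimolecular_G4_slow = {
      dH <- -80
      cc <- total_strand_conc_M %||% 1.5e-6
      # association: k_f(Tm) = 400 M^-1 s^-1 with a negative activation
      # energy (association accelerates on cooling, as typical for nucleic
      # acid folding); dissociation follows from detailed balance and is
      # slow below Tm, which produces ramp-rate-dependent hysteresis
      Ea_f <- -12
      two_state_model(
        delta_H_kcal_mol = dH,
        delta_S_cal_mol_K = .delta_S_for_tm(dH, 58, 2, 1.5e-6),
        molecularity = 2,
        total_strand_conc_M = cc,
        folded_baseline = c(0.45, 1e-4),
        unfolded_baseline = c(0.43, 1e-4),
        kinetics = list(
          A_fold = 400 * exp(Ea_f * 1000 / (.R_CAL * (58 + .T0_K))),
          Ea_fold_kcal_mol = Ea_f
        )
      )
    }
  )
}
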