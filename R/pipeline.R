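# Pipeline wiring: a validated run configuration and a single entry point
# that strings the modules into the study workflow
# (design -> simulate/ingest -> correct -> TDS/melt/hysteresis -> decompose)
# and writes a versioned JSON report plus CSV artifacts. A thin command-line
# wrapper over run_pentaspec() ships in inst/scripts/pentaspec.R.

.ps_commands <- c("design", "simulate", "tds", "melt", "decompose")
.ps_param_keys <- c(
  "motif", "n", "base_conc_uM", "nucleic_acid",
  "preset", "ramp_rate_C_per_min", "noise_sd",
  "high_C", "low_C",
  "wavelength_nm", "reference_wavelength_nm", "window_pts", "poly_order",
  "noise_k", "threshold_C",
  "f_true", "f_grid_step", "wavelength_window"
)

#' Build and validate a run configuration
#'
#' @param command One of `design`, `simulate`, `tds`, `melt`, `decompose`.
#' @param input_paths Named character vector/list of input files (as each
#'   command requires).
#' @param output_dir Directory for artifacts (created if absent).
#' @param seed Integer seed recorded in, and used by, the run.
#' @param parameters Named list of command parameters; unknown keys are
#'   rejected.
#' @return An object of class `pentaspec_config`.
#' @export
pentaspec_config <- function(command, input_paths = list(),
                             output_dir = tempfile("pentaspec_run_"),
                             seed = 1L, parameters = list()) {
  if (!is.character(command) || length(command) != 1L ||
    !command %in% .ps_commands) {
    .ps_abort(sprintf("unknown command '%s' (expected one of: %s)",
      paste(command, collapse = ","), paste(.ps_commands, collapse = ", ")),
    "usage_error")
  }
  unknown <- setdiff(names(parameters), .ps_param_keys)
  if (length(unknown) > 0L) {
    .ps_abort(sprintf("unknown parameter key(s): %s",
      paste(unknown, collapse = ", ")), "usage_error")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    .ps_abort("`seed` must be a single integer.", "usage_error")
  }
  structure(
    list(
      command = command,
      input_paths = as.list(input_paths),
      output_dir = output_dir,
      seed = as.integer(seed),
      parameters = parameters
    ),
    class = "pentaspec_config"
  )
}

.report_skeleton <- function(config) {
  list(
    schema = "pentaspec_report_v1",
    package_version = as.character(utils::packageVersion("pentaspec")),
    command = config$command,
    seed = config$seed,
    parameters = config$parameters
  )
}

#' Run a configured pipeline step
#'
#' Executes one workflow command and writes a machine-readable JSON report
#' (schema `pentaspec_report_v1`, recording the seed, package version and
#' parameters) plus CSV/FASTA artifacts into `output_dir`.
#'
#' Commands:
#' \describe{
#'   \item{design}{parameters `motif`, `n`, optional `base_conc_uM`;
#'     writes the design table and a FASTA of the sequence.}
#'   \item{simulate}{parameters `preset` (see [preset_model()]), optional
#'     `ramp_rate_C_per_min`, `noise_sd`; simulates cooling + heating ramps
#'     (kinetic when the preset carries kinetics) and writes a melting-curve
#'     CSV.}
#'   \item{tds}{input `spectra` (CSV of ABS spectra), parameters `high_C`,
#'     `low_C`; writes the TDS per sample.}
#'   \item{melt}{input `melting` (CSV), parameters `wavelength_nm`,
#'     `reference_wavelength_nm` (optional baseline), `window_pts`,
#'     `noise_k`, `threshold_C`; reports Tm per direction and a hysteresis
#'     block when both directions are present.}
#'   \item{decompose}{inputs `measured`, `basis_g4`, `basis_non_g4` (spectra
#'     CSVs); reports `f_grid_best`, `f_refined`, the SSR profile, and
#'     writes the residual spectrum CSV.}
#' }
#'
#' @param config A `pentaspec_config`.
#' @return Invisibly, the report as a list (also written to
#'   `output_dir/report.json`).
#' @export
run_pentaspec <- function(config) {
  stopifnot(inherits(config, "pentaspec_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$parameters
  report <- .report_skeleton(config)
  report$results <- switch(config$command,
    design = .run_design(config, p),
    simulate = .run_simulate(config, p),
    tds = .run_tds(config, p),
    melt = .run_melt(config, p),
    decompose = .run_decompose(config, p)
  )
  path <- file.path(config$output_dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(report)
}

.run_design <- function(config, p) {
  if (is.null(p$motif) || is.null(p$n)) {
    .ps_abort("design needs parameters `motif` and `n`.", "usage_error")
  }
  base <- p$base_conc_uM %||% 24
  rs <- build_repeat(p$motif, p$n, p$nucleic_acid %||% "DNA")
  conc <- design_strand_concentration(p$n, base)
  summ <- design_summary(rs, conc)
  tab <- summ |>
    mutate(duplex_size_bp = predicted_species_size(rs, "bimolecular_duplex"))
  readr::write_csv(tab, file.path(config$output_dir, "design.csv"),
    progress = FALSE)
  write_repeat_fasta(rs, file.path(config$output_dir,
    sprintf("%s_x%d.fasta", rs$motif, rs$n_repeats)))
  as.list(tab)
}

.run_simulate <- function(config, p) {
  preset <- p$preset %||% "intramolecular_G4"
  model <- preset_model(preset)
  rate <- p$ramp_rate_C_per_min %||% 0.2
  noise <- p$noise_sd %||% 0
  cool <- ramp_protocol(95, 5, rate)
  heat <- ramp_protocol(5, 95, rate)
  sim <- function(proto, seed_offset) {
    if (!is.null(model$kinetics)) {
      simulate_kinetic_ramp(model, proto, noise_sd = noise,
        seed = config$seed + seed_offset, sample_id = preset)
    } else {
      simulate_equilibrium_melt(model, proto, noise_sd = noise,
        seed = config$seed + seed_offset, sample_id = preset)
    }
  }
  curves <- list(sim(cool, 0L), sim(heat, 1L))
  out_csv <- file.path(config$output_dir, "melting.csv")
  write_melting_table(curves, out_csv)
  list(preset = preset, ramp_rate_C_per_min = rate, n_points = nrow(curves[[1]]),
    melting_csv = out_csv)
}

.run_tds <- function(config, p) {
  path <- config$input_paths$spectra
  if (is.null(path)) .ps_abort("tds needs input `spectra`.", "usage_error")
  high <- p$high_C %||% 95
  low <- p$low_C %||% 5
  specs <- read_spectra_table(path)
  abs_specs <- specs[map_dbl(specs, ~ as.numeric(attr(.x, "channel") == "ABS")) == 1]
  ids <- unique(map_chr_ps(abs_specs, ~ attr(.x, "sample_id")))
  tds_list <- list()
  for (id in ids) {
    mine <- abs_specs[map_chr_ps(abs_specs, ~ attr(.x, "sample_id")) == id]
    temps <- map_dbl(mine, ~ attr(.x, "temperature_C"))
    i_hi <- which(abs(temps - high) < 1e-6)
    i_lo <- which(abs(temps - low) < 1e-6)
    if (length(i_hi) == 1L && length(i_lo) == 1L) {
      tds_list[[id]] <- compute_tds(mine[[i_hi]], mine[[i_lo]])
    }
  }
  if (length(tds_list) == 0L) {
    .ps_abort(sprintf("no sample has ABS spectra at both %g and %g C.",
      high, low), "usage_error")
  }
  out_csv <- file.path(config$output_dir, "tds.csv")
  write_spectra_table(tds_list, out_csv)
  list(samples = names(tds_list), high_C = high, low_C = low, tds_csv = out_csv)
}

.run_melt <- function(config, p) {
  path <- config$input_paths$melting
  if (is.null(path)) .ps_abort("melt needs input `melting`.", "usage_error")
  wl <- p$wavelength_nm %||% 295
  ref_wl <- p$reference_wavelength_nm
  curves <- read_melting_table(path)
  meta <- purrr::map_dfr(curves, melting_meta)
  pick <- function(sample, direction, wavelength) {
    i <- which(meta$sample_id == sample & meta$direction == direction &
      abs(meta$wavelength_nm - wavelength) < 1e-6)
    if (length(i) >= 1L) curves[[i[1]]] else NULL
  }
  results <- list()
  for (sample in unique(meta$sample_id)) {
    per_dir <- list()
    for (direction in c("cooling", "heating")) {
      cv <- pick(sample, direction, wl)
      if (is.null(cv)) next
      if (!is.null(ref_wl)) {
        ref <- pick(sample, direction, ref_wl)
        if (!is.null(ref)) cv <- baseline_correct(cv, ref)
      }
      mr <- estimate_tm(cv,
        noise_k = p$noise_k %||% 5,
        window_pts = p$window_pts %||% 11,
        poly_order = p$poly_order %||% 2
      )
      per_dir[[direction]] <- mr
    }
    entry <- map(per_dir, ~ as.list(glance(.x)))
    if (length(per_dir) == 2L &&
      per_dir$cooling$transition_detected &&
      per_dir$heating$transition_detected) {
      entry$hysteresis <- as.list(
        hysteresis(per_dir$cooling, per_dir$heating,
          threshold_C = p$threshold_C %||% 1.0)
      )
    }
    results[[sample]] <- entry
  }
  results
}

.run_decompose <- function(config, p) {
  need <- c("measured", "basis_g4", "basis_non_g4")
  if (!all(need %in% names(config$input_paths))) {
    .ps_abort("decompose needs inputs measured, basis_g4, basis_non_g4.",
      "usage_error")
  }
  one_spectrum <- function(key) {
    sp <- read_spectra_table(config$input_paths[[key]])
    if (length(sp) != 1L) {
      .ps_abort(sprintf("input '%s' must contain exactly one spectrum.", key),
        "usage_error")
    }
    sp[[1]]
  }
  measured <- one_spectrum("measured")
  g4 <- one_spectrum("basis_g4")
  non_g4 <- one_spectrum("basis_non_g4")
  grid <- common_grid(measured, g4, non_g4)
  if (!is.null(p$wavelength_window)) {
    grid <- grid[grid >= p$wavelength_window[1] & grid <= p$wavelength_window[2]]
  }
  b <- basis_set(grid, regrid(g4, grid)$value, regrid(non_g4, grid)$value)
  fit <- estimate_fraction(regrid(measured, grid), b,
    f_grid = seq(0.1, 0.9, by = p$f_grid_step %||% 0.1))
  readr::write_csv(fit$residual, file.path(config$output_dir, "residual.csv"),
    progress = FALSE)
  list(
    f_grid_best = fit$f_grid_best,
    f_refined = fit$f_refined,
    ssr_min = fit$ssr_min,
    ssr_refined = fit$ssr_refined,
    ssr_profile = fit$ssr_profile
  )
}
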