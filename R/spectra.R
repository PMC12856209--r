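# Data containers and CSV I/O for spectra and melting ramps, plus the
# wavelength regridding that precedes any cross-spectrum arithmetic.
#
# A `spectrum` is a tibble (wavelength_nm, value) carrying sample metadata
# as attributes; a `melting_curve` is a tibble (temperature_C, absorbance)
# carrying wavelength, ramp direction and rate. Both print and pipe like
# ordinary tibbles.

#' Construct a spectrum
#'
#' A signal-versus-wavelength record at one temperature: either an absorbance
#' spectrum (`channel = "ABS"`, absorbance units) or a CD spectrum
#' (`channel = "CD"`, raw instrument signal in mdeg).
#'
#' @param wavelength_nm Strictly increasing numeric vector (length >= 2).
#' @param value Numeric signal vector of the same length.
#' @param channel `"ABS"` or `"CD"`.
#' @param temperature_C Acquisition temperature in Celsius (`NA` allowed for
#'   derived spectra such as a TDS).
#' @param sample_id Sample identifier string.
#' @param strand_conc_uM Optional strand concentration (uM).
#' @param pathlength_cm Optional cuvette pathlength (cm).
#' @return A tibble of class `spectrum` with columns `wavelength_nm`, `value`
#'   and metadata attributes.
#' @examples
#' spectrum(240:320, exp(-((240:320) - 280)^2 / 200), "CD", 5, "demo")
#' @export
spectrum <- function(wavelength_nm, value, channel = c("ABS", "CD"),
                     temperature_C = NA_real_, sample_id = "sample",
                     strand_conc_uM = NA_real_, pathlength_cm = NA_real_) {
  channel <- match.arg(channel)
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) < 2L || length(wavelength_nm) != length(value)) {
    .ps_abort("wavelength and value must have equal length >= 2.", "domain_error")
  }
  if (any(is.na(wavelength_nm)) || any(diff(wavelength_nm) <= 0)) {
    .ps_abort("`wavelength_nm` must be strictly increasing.", "domain_error")
  }
  out <- tibble(wavelength_nm = wavelength_nm, value = value)
  attr(out, "channel") <- channel
  attr(out, "temperature_C") <- as.numeric(temperature_C)
  attr(out, "sample_id") <- as.character(sample_id)
  attr(out, "strand_conc_uM") <- as.numeric(strand_conc_uM)
  attr(out, "pathlength_cm") <- as.numeric(pathlength_cm)
  class(out) <- c("spectrum", class(out))
  out
}

#' Spectrum metadata
#'
#' @param x A `spectrum`.
#' @return A one-row tibble of the spectrum's metadata attributes.
#' @export
spectrum_meta <- function(x) {
  stopifnot(inherits(x, "spectrum"))
  tibble(
    sample_id = attr(x, "sample_id"),
    channel = attr(x, "channel"),
    temperature_C = attr(x, "temperature_C"),
    strand_conc_uM = attr(x, "strand_conc_uM"),
    pathlength_cm = attr(x, "pathlength_cm")
  )
}

#' Construct a melting curve
#'
#' Absorbance versus temperature at one wavelength, for one ramp direction
#' at one ramp rate. Temperatures must be monotone: decreasing for a cooling
#' ramp, increasing for a heating ramp.
#'
#' @param temperature_C Numeric temperature vector (length >= 5, monotone).
#' @param absorbance Numeric absorbance vector of the same length.
#' @param wavelength_nm Detection wavelength (nm).
#' @param direction `"cooling"` or `"heating"`.
#' @param ramp_rate_C_per_min Positive ramp rate (Celsius per minute).
#' @param sample_id Sample identifier string.
#' @return A tibble of class `melting_curve` with columns `temperature_C`,
#'   `absorbance` and metadata attributes.
#' @export
melting_curve <- function(temperature_C, absorbance, wavelength_nm,
                          direction = c("cooling", "heating"),
                          ramp_rate_C_per_min = 0.2, sample_id = "sample") {
  direction <- match.arg(direction)
  temperature_C <- as.numeric(temperature_C)
  absorbance <- as.numeric(absorbance)
  if (length(temperature_C) < 5L || length(temperature_C) != length(absorbance)) {
    .ps_abort("temperature and absorbance must have equal length >= 5.", "domain_error")
  }
  d <- diff(temperature_C)
  ok <- if (direction == "cooling") all(d < 0) else all(d > 0)
  if (!ok) {
    .ps_abort(
      sprintf("temperatures must be strictly %s for a %s ramp.",
        if (direction == "cooling") "decreasing" else "increasing", direction),
      "domain_error"
    )
  }
  if (!is.numeric(ramp_rate_C_per_min) || ramp_rate_C_per_min <= 0) {
    .ps_abort("`ramp_rate_C_per_min` must be positive.", "domain_error")
  }
  out <- tibble(temperature_C = temperature_C, absorbance = absorbance)
  attr(out, "wavelength_nm") <- as.numeric(wavelength_nm)
  attr(out, "direction") <- direction
  attr(out, "ramp_rate_C_per_min") <- as.numeric(ramp_rate_C_per_min)
  attr(out, "sample_id") <- as.character(sample_id)
  class(out) <- c("melting_curve", class(out))
  out
}

#' Melting-curve metadata
#'
#' @param x A `melting_curve`.
#' @return A one-row tibble of the curve's metadata attributes.
#' @export
melting_meta <- function(x) {
  stopifnot(inherits(x, "melting_curve"))
  tibble(
    sample_id = attr(x, "sample_id"),
    wavelength_nm = attr(x, "wavelength_nm"),
    direction = attr(x, "direction"),
    ramp_rate_C_per_min = attr(x, "ramp_rate_C_per_min")
  )
}

.spectra_cols <- c("sample_id", "channel", "temperature_C", "wavelength_nm", "value")
.melting_cols <- c(
  "sample_id", "wavelength_nm", "direction", "ramp_rate_C_per_min",
  "temperature_C", "absorbance"
)

.read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) {
    .ps_abort(sprintf("File not found: %s", path), "io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    .ps_abort(
      sprintf("Missing required column(s): %s", paste(missing, collapse = ", ")),
      "format_error"
    )
  }
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed) & !is.na(df[[col]]))
    if (length(bad) > 0L) {
      .ps_abort(
        sprintf("Non-numeric value in column '%s' at data row %d: '%s'",
          col, bad[1], df[[col]][bad[1]]),
        "parse_error"
      )
    }
    df[[col]] <- parsed
  }
  df
}

#' Read spectra from a long-format CSV
#'
#' The canonical dialect is a comma-separated, dot-decimal, UTF-8 table with
#' header `sample_id,channel,temperature_C,wavelength_nm,value` and optional
#' `strand_conc_uM,pathlength_cm` columns. Rows are grouped by
#' (sample_id, channel, temperature_C) into one [spectrum()] each, with
#' wavelengths sorted ascending within each group.
#'
#' @param path CSV file path.
#' @return A named list of `spectrum` objects; names are
#'   `"<sample_id>/<channel>/<temperature_C>"`.
#' @export
read_spectra_table <- function(path) {
  df <- .read_checked_csv(path, .spectra_cols,
    c("temperature_C", "wavelength_nm", "value"))
  bad_channel <- setdiff(unique(df$channel), c("ABS", "CD"))
  if (length(bad_channel) > 0L) {
    .ps_abort(
      sprintf("Unknown channel token(s): %s", paste(bad_channel, collapse = ", ")),
      "format_error"
    )
  }
  if (!"strand_conc_uM" %in% names(df)) df$strand_conc_uM <- NA_real_
  if (!"pathlength_cm" %in% names(df)) df$pathlength_cm <- NA_real_
  df$strand_conc_uM <- suppressWarnings(as.numeric(df$strand_conc_uM))
  df$pathlength_cm <- suppressWarnings(as.numeric(df$pathlength_cm))
  groups <- df |>
    group_by(.data$sample_id, .data$channel, .data$temperature_C) |>
    dplyr::group_split()
  out <- map(groups, function(g) {
    g <- arrange(g, .data$wavelength_nm)
    spectrum(
      g$wavelength_nm, g$value,
      channel = g$channel[1], temperature_C = g$temperature_C[1],
      sample_id = g$sample_id[1], strand_conc_uM = g$strand_conc_uM[1],
      pathlength_cm = g$pathlength_cm[1]
    )
  })
  names(out) <- map_chr_ps(out, function(s) {
    sprintf("%s/%s/%s", attr(s, "sample_id"), attr(s, "channel"),
      format(attr(s, "temperature_C")))
  })
  out
}

# purrr::map_chr with a forgiving name (keeps imports tight)
map_chr_ps <- function(x, f) vapply(x, purrr::as_mapper(f), character(1))

#' Write spectra to the canonical long-format CSV
#'
#' Inverse of [read_spectra_table()]; a read of the written file reproduces
#' the input exactly (values are written in shortest round-trippable
#' decimal form).
#'
#' @param spectra A `spectrum` or list of `spectrum` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  if (length(spectra) == 0L) {
    .ps_abort("`spectra` must be a nonempty list.", "domain_error")
  }
  rows <- map(spectra, function(s) {
    stopifnot(inherits(s, "spectrum"))
    tibble(
      sample_id = attr(s, "sample_id"),
      channel = attr(s, "channel"),
      temperature_C = attr(s, "temperature_C"),
      wavelength_nm = s$wavelength_nm,
      value = s$value,
      strand_conc_uM = attr(s, "strand_conc_uM"),
      pathlength_cm = attr(s, "pathlength_cm")
    )
  })
  readr::write_csv(bind_rows(rows), path, progress = FALSE)
  invisible(path)
}

#' Read melting curves from a long-format CSV
#'
#' Header: `sample_id,wavelength_nm,direction,ramp_rate_C_per_min,
#' temperature_C,absorbance`. One [melting_curve()] is built per
#' (sample_id, wavelength_nm, direction, ramp_rate_C_per_min) group, in row
#' order (the acquisition order defines the ramp).
#'
#' @param path CSV file path.
#' @return A named list of `melting_curve` objects.
#' @export
read_melting_table <- function(path) {
  df <- .read_checked_csv(path, .melting_cols,
    c("wavelength_nm", "ramp_rate_C_per_min", "temperature_C", "absorbance"))
  bad_dir <- setdiff(unique(df$direction), c("cooling", "heating"))
  if (length(bad_dir) > 0L) {
    .ps_abort(
      sprintf("Unknown direction token(s): %s (expected cooling/heating)",
        paste(bad_dir, collapse = ", ")),
      "format_error"
    )
  }
  groups <- df |>
    group_by(.data$sample_id, .data$wavelength_nm, .data$direction,
      .data$ramp_rate_C_per_min) |>
    dplyr::group_split()
  out <- map(groups, function(g) {
    melting_curve(
      g$temperature_C, g$absorbance,
      wavelength_nm = g$wavelength_nm[1], direction = g$direction[1],
      ramp_rate_C_per_min = g$ramp_rate_C_per_min[1], sample_id = g$sample_id[1]
    )
  })
  names(out) <- map_chr_ps(out, function(cv) {
    m <- melting_meta(cv)
    sprintf("%s/%gnm/%s/%g", m$sample_id, m$wavelength_nm, m$direction,
      m$ramp_rate_C_per_min)
  })
  out
}

#' Write melting curves to the canonical long-format CSV
#'
#' @param curves A `melting_curve` or list of `melting_curve` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_melting_table <- function(curves, path) {
  if (inherits(curves, "melting_curve")) curves <- list(curves)
  if (length(curves) == 0L) {
    .ps_abort("`curves` must be a nonempty list.", "domain_error")
  }
  rows <- map(curves, function(cv) {
    stopifnot(inherits(cv, "melting_curve"))
    m <- melting_meta(cv)
    tibble(
      sample_id = m$sample_id,
      wavelength_nm = m$wavelength_nm,
      direction = m$direction,
      ramp_rate_C_per_min = m$ramp_rate_C_per_min,
      temperature_C = cv$temperature_C,
      absorbance = cv$absorbance
    )
  })
  readr::write_csv(bind_rows(rows), path, progress = FALSE)
  invisible(path)
}

#' Regrid a spectrum by linear interpolation
#'
#' Interpolates a spectrum onto a new wavelength grid. Extrapolation is
#' refused: the target grid must lie within the source wavelength range.
#'
#' @param spec A `spectrum`.
#' @param target_grid Ascending numeric wavelength vector.
#' @return A `spectrum` on `target_grid` with the source metadata.
#' @export
regrid <- function(spec, target_grid) {
  stopifnot(inherits(spec, "spectrum"))
  target_grid <- as.numeric(target_grid)
  if (any(diff(target_grid) <= 0)) {
    .ps_abort("`target_grid` must be strictly increasing.", "domain_error")
  }
  rng <- range(spec$wavelength_nm)
  if (min(target_grid) < rng[1] || max(target_grid) > rng[2]) {
    .ps_abort(
      sprintf(
        "target grid [%g, %g] nm extends beyond source range [%g, %g] nm.",
        min(target_grid), max(target_grid), rng[1], rng[2]
      ),
      "range_error"
    )
  }
  v <- approx(spec$wavelength_nm, spec$value, xout = target_grid)$y
  spectrum(
    target_grid, v,
    channel = attr(spec, "channel"), temperature_C = attr(spec, "temperature_C"),
    sample_id = attr(spec, "sample_id"),
    strand_conc_uM = attr(spec, "strand_conc_uM"),
    pathlength_cm = attr(spec, "pathlength_cm")
  )
}

#' Common wavelength grid across spectra
#'
#' Intersection wavelength range of the supplied spectra, sampled at a fixed
#' step (1 nm by default, the typical spectrometer export resolution).
#'
#' @param ... `spectrum` objects (or one list of them).
#' @param step Grid step in nm (default 1).
#' @return Ascending numeric vector of wavelengths.
#' @export
common_grid <- function(..., step = 1) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1]], "spectrum")) specs <- specs[[1]]
  lo <- max(map_dbl(specs, ~ min(.x$wavelength_nm)))
  hi <- min(map_dbl(specs, ~ max(.x$wavelength_nm)))
  if (hi - lo < step) {
    .ps_abort("spectra share no usable wavelength overlap.", "range_error")
  }
  seq(ceiling(lo / step) * step, hi, by = step)
}
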