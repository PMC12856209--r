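# Melting-curve analysis: baseline correction against a transparent
# wavelength (335 nm), thermal difference spectra, derivative-extremum Tm
# estimation, hysteresis quantification and signature classification.
#
# Tm is defined operationally as the temperature of the extremum of dA/dT,
# which avoids assuming a two-state transition or fitting high/low
# temperature baselines.

#' Baseline-correct a melting curve
#'
#' Subtracts a reference trace recorded at a wavelength where nucleic acids
#' do not absorb (typically 335 nm), removing instrumental drift. If the two
#' temperature grids differ by more than 0.1 degrees C at any point, the
#' reference is linearly interpolated onto the curve's grid.
#'
#' @param curve A `melting_curve` at the analytical wavelength.
#' @param reference A `melting_curve` at the reference wavelength, same
#'   sample and ramp direction.
#' @return The corrected `melting_curve` (metadata of `curve` retained).
#' @export
baseline_correct <- function(curve, reference) {
  stopifnot(inherits(curve, "melting_curve"), inherits(reference, "melting_curve"))
  mc <- melting_meta(curve)
  mr <- melting_meta(reference)
  if (mc$direction != mr$direction) {
    .ps_abort("curve and reference have different ramp directions.", "pairing_error")
  }
  if (isTRUE(mc$wavelength_nm == mr$wavelength_nm)) {
    .ps_abort("reference wavelength must differ from the curve wavelength.",
      "pairing_error")
  }
  rng_c <- range(curve$temperature_C)
  rng_r <- range(reference$temperature_C)
  if (rng_c[1] < rng_r[1] - 1e-9 || rng_c[2] > rng_r[2] + 1e-9) {
    .ps_abort("reference does not cover the curve's temperature range.",
      "range_error")
  }
  aligned <- length(reference$temperature_C) == length(curve$temperature_C) &&
    all(abs(reference$temperature_C - curve$temperature_C) <= 0.1)
  ref_vals <- if (aligned && all(reference$temperature_C == curve$temperature_C)) {
    reference$absorbance
  } else {
    approx(reference$temperature_C, reference$absorbance,
      xout = curve$temperature_C)$y
  }
  melting_curve(
    curve$temperature_C, curve$absorbance - ref_vals,
    wavelength_nm = mc$wavelength_nm, direction = mc$direction,
    ramp_rate_C_per_min = mc$ramp_rate_C_per_min, sample_id = mc$sample_id
  )
}

#' Thermal difference spectrum (TDS)
#'
#' The absorbance spectrum at high temperature (unfolded, typically 95 C)
#' minus the spectrum at low temperature (folded, typically 5 C), computed
#' on the common wavelength grid. The shape of a TDS is a structural
#' fingerprint: G-quadruplexes, duplexes and single strands give distinct
#' band patterns.
#'
#' @param spec_high Absorbance `spectrum` at high temperature.
#' @param spec_low Absorbance `spectrum` at low temperature.
#' @param normalize If `TRUE`, divide by the maximum absolute value
#'   (default `FALSE`).
#' @param step Common-grid step in nm (default 1).
#' @return A `spectrum` (channel ABS) with `temperature_C = NA` and attribute
#'   `temperature_label = "TDS"`.
#' @export
compute_tds <- function(spec_high, spec_low, normalize = FALSE, step = 1) {
  stopifnot(inherits(spec_high, "spectrum"), inherits(spec_low, "spectrum"))
  if (attr(spec_high, "channel") != "ABS" || attr(spec_low, "channel") != "ABS") {
    .ps_abort("TDS requires two ABS-channel spectra.", "channel_error")
  }
  grid <- common_grid(spec_high, spec_low, step = step)
  hi <- regrid(spec_high, grid)
  lo <- regrid(spec_low, grid)
  v <- hi$value - lo$value
  if (normalize) {
    m <- max(abs(v))
    if (m > 0) v <- v / m
  }
  out <- spectrum(grid, v,
    channel = "ABS", temperature_C = NA_real_,
    sample_id = attr(spec_high, "sample_id"),
    strand_conc_uM = attr(spec_high, "strand_conc_uM"),
    pathlength_cm = attr(spec_high, "pathlength_cm")
  )
  attr(out, "temperature_label") <- "TDS"
  out
}

#' Classify a TDS or CD spectrum against template signatures
#'
#' Scores the spectrum against each template by cosine similarity of
#' mean-centered vectors on a common wavelength window (220-335 nm by
#' default), making the call scale- and offset-invariant. The label is the
#' best-scoring template when its score reaches the acceptance threshold,
#' otherwise `"unclassified"`.
#'
#' @param spec A `spectrum` to classify.
#' @param templates Named list of template `spectrum` objects (e.g. from
#'   [signature_templates()]).
#' @param kind `"TDS"` or `"CD"` (recorded in the result).
#' @param threshold Acceptance threshold on the cosine score (default 0.80).
#' @param window Wavelength window, nm (default `c(220, 335)`).
#' @param step Grid step in nm (default 1).
#' @return An object of class `signature_call`: list with `label`, `score`,
#'   `kind` and a tibble `scores` of per-template scores.
#' @export
classify_signature <- function(spec, templates, kind = c("TDS", "CD"),
                               threshold = 0.80, window = c(220, 335), step = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "spectrum"))
  if (!is.list(templates) || length(templates) == 0L ||
    is.null(names(templates)) || any(!nzchar(names(templates)))) {
    .ps_abort("`templates` must be a nonempty named list of spectra.",
      "configuration_error")
  }
  grid <- common_grid(c(list(spec), unname(templates)), step = step)
  grid <- grid[grid >= window[1] & grid <= window[2]]
  if (length(grid) < 3L) {
    .ps_abort("window leaves too few common wavelengths.", "range_error")
  }
  center <- function(v) v - mean(v)
  x <- center(regrid(spec, grid)$value)
  cosine <- function(a, b) {
    na <- sqrt(sum(a^2))
    nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0) # undefined similarity scored as 0
    sum(a * b) / (na * nb)
  }
  scores <- map_dbl(templates, function(tp) cosine(x, center(regrid(tp, grid)$value)))
  best <- which.max(scores)
  label <- if (scores[best] >= threshold) names(templates)[best] else "unclassified"
  structure(
    list(
      label = label,
      score = unname(scores[best]),
      kind = kind,
      threshold = threshold,
      scores = tibble(label = names(templates), score = unname(scores))
    ),
    class = "signature_call"
  )
}

#' @export
print.signature_call <- function(x, ...) {
  cat(sprintf("<signature_call> %s (%s, score %.3f, threshold %.2f)\n",
    x$label, x$kind, x$score, x$threshold))
  print(x$scores)
  invisible(x)
}

#' Smoothed first derivative of a melting curve
#'
#' Savitzky-Golay-style derivative: at each point a local polynomial of
#' degree `poly_order` is fitted by least squares over a centered window of
#' `window_pts` points (shrunken, one-sided windows at the ends) and
#' differentiated analytically. Exact for polynomials up to `poly_order`.
#'
#' @param curve A `melting_curve`.
#' @param window_pts Odd window width in points (default 11).
#' @param poly_order Polynomial degree (default 2).
#' @return Numeric vector dA/dT aligned to `curve$temperature_C`.
#' @export
derivative_curve <- function(curve, window_pts = 11, poly_order = 2) {
  stopifnot(inherits(curve, "melting_curve"))
  n <- nrow(curve)
  if (window_pts %% 2 != 1 || window_pts < poly_order + 2) {
    .ps_abort("`window_pts` must be odd and exceed `poly_order` + 1.",
      "parameter_error")
  }
  if (n < window_pts) {
    .ps_abort("curve has fewer points than the smoothing window.",
      "parameter_error")
  }
  tt <- curve$temperature_C
  aa <- curve$absorbance
  h <- (window_pts - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - h):min(n, i + h)
    x <- tt[idx] - tt[i]
    X <- outer(x, 0:poly_order, `^`)
    stats::lm.fit(X, aa[idx])$coefficients[2]
  }, numeric(1))
}

#' Estimate a melting temperature from the derivative extremum
#'
#' Computes the smoothed derivative dA/dT of a (baseline-corrected) melting
#' curve and reports the temperature of its global extremum over interior
#' points. A transition is called only when the extremal |dA/dT| exceeds
#' `noise_k` times a robust noise scale, estimated as the scaled median
#' absolute deviation of dA/dT over the coolest and hottest 10% of points
#' (where the signal derivative is near zero). The amplitude is the absolute
#' difference between the median corrected absorbance of the 5 lowest- and 5
#' highest-temperature points, avoiding any baseline fit.
#'
#' @param curve A baseline-corrected `melting_curve` with >= 25 points.
#' @param noise_k Detection multiplier on the noise scale (default 5).
#' @param window_pts,poly_order Passed to [derivative_curve()].
#' @param edge_exclude Points excluded at each end when locating the
#'   extremum (default 5).
#' @return An object of class `melt_result`: list with `tm_C` (`NA` when no
#'   transition), `amplitude`, `transition_detected`, `extremum_sign`
#'   (`"max"`/`"min"`), `derivative` (tibble), and the curve metadata.
#' @export
estimate_tm <- function(curve, noise_k = 5, window_pts = 11, poly_order = 2,
                        edge_exclude = 5) {
  stopifnot(inherits(curve, "melting_curve"))
  n <- nrow(curve)
  if (n < 25L) {
    .ps_abort("Tm estimation needs at least 25 points.", "insufficient_data_error")
  }
  d <- derivative_curve(curve, window_pts = window_pts, poly_order = poly_order)
  tt <- curve$temperature_C

  n_edge <- max(2L, ceiling(0.1 * n))
  ord <- order(tt)
  edge_idx <- c(head(ord, n_edge), tail(ord, n_edge))
  noise_scale <- mad(d[edge_idx]) # 1.4826 * MAD, robust sd of baseline slope

  interior <- (edge_exclude + 1L):(n - edge_exclude)
  i_ext <- interior[which.max(abs(d[interior]))]
  max_abs <- abs(d[i_ext])
  # floor at machine-precision scale so numerically flat curves never count
  eps_floor <- 1e-10 * max(abs(curve$absorbance)) / diff(range(tt))
  detected <- max_abs > eps_floor && max_abs >= noise_k * noise_scale

  cold5 <- head(order(tt), 5L)
  hot5 <- tail(order(tt), 5L)
  amplitude <- abs(median(curve$absorbance[cold5]) - median(curve$absorbance[hot5]))

  m <- melting_meta(curve)
  structure(
    list(
      tm_C = if (detected) tt[i_ext] else NA_real_,
      amplitude = amplitude,
      transition_detected = detected,
      extremum_sign = if (detected) {
        if (d[i_ext] > 0) "max" else "min"
      } else {
        NA_character_
      },
      derivative = tibble(temperature_C = tt, dA_dT = d),
      noise_scale = noise_scale,
      noise_k = noise_k,
      sample_id = m$sample_id,
      wavelength_nm = m$wavelength_nm,
      direction = m$direction,
      ramp_rate_C_per_min = m$ramp_rate_C_per_min
    ),
    class = "melt_result"
  )
}

#' @export
print.melt_result <- function(x, ...) {
  if (x$transition_detected) {
    cat(sprintf(
      "<melt_result> %s @ %g nm (%s): Tm = %.2f C (%s of dA/dT), amplitude %.4f\n",
      x$sample_id, x$wavelength_nm, x$direction, x$tm_C, x$extremum_sign,
      x$amplitude
    ))
  } else {
    cat(sprintf(
      "<melt_result> %s @ %g nm (%s): no transition detected\n",
      x$sample_id, x$wavelength_nm, x$direction
    ))
  }
  invisible(x)
}

#' Hysteresis between cooling and heating melting curves
#'
#' Non-coincidence of cooling and heating profiles indicates that the
#' temperature ramp outpaces the folding/unfolding kinetics, as for slow
#' intermolecular G-quadruplexes. The midpoint melting temperature is
#' (Tm_cooling + Tm_heating) / 2; the pair is flagged hysteretic when the
#' branches differ by more than `threshold_C`.
#'
#' @param cooling_result,heating_result `melt_result` objects for the two
#'   ramp directions (both with a detected transition).
#' @param threshold_C Hysteresis flag threshold in Celsius (default 1.0,
#'   the scale of instrument Tm repeatability).
#' @return A one-row tibble of class `hysteresis_result` with columns
#'   `tm_cooling_C`, `tm_heating_C`, `midpoint_C`, `hysteretic`,
#'   `threshold_C`.
#' @export
hysteresis <- function(cooling_result, heating_result, threshold_C = 1.0) {
  stopifnot(inherits(cooling_result, "melt_result"),
    inherits(heating_result, "melt_result"))
  if (!cooling_result$transition_detected || !heating_result$transition_detected) {
    .ps_abort("both branches must have a detected transition.",
      "upstream_detection_error")
  }
  tc <- cooling_result$tm_C
  th <- heating_result$tm_C
  out <- tibble(
    tm_cooling_C = tc,
    tm_heating_C = th,
    midpoint_C = (tc + th) / 2,
    hysteretic = abs(th - tc) > threshold_C,
    threshold_C = threshold_C
  )
  class(out) <- c("hysteresis_result", class(out))
  out
}
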