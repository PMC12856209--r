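# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' Tidy a melt result
#'
#' @param x A `melt_result`.
#' @param ... Unused.
#' @return The derivative track as a tibble (`temperature_C`, `dA_dT`).
#' @export
tidy.melt_result <- function(x, ...) x$derivative

#' One-row summary of a melt result
#'
#' @param x A `melt_result`.
#' @param ... Unused.
#' @return A one-row tibble: `sample_id`, `wavelength_nm`, `direction`,
#'   `tm_C`, `amplitude`, `transition_detected`, `extremum_sign`.
#' @export
glance.melt_result <- function(x, ...) {
  tibble(
    sample_id = x$sample_id,
    wavelength_nm = x$wavelength_nm,
    direction = x$direction,
    tm_C = x$tm_C,
    amplitude = x$amplitude,
    transition_detected = x$transition_detected,
    extremum_sign = x$extremum_sign %||% NA_character_
  )
}

#' Tidy a CD decomposition
#'
#' @param x A `cd_decomposition`.
#' @param ... Unused.
#' @return The SSR profile tibble (`f`, `ssr`).
#' @export
tidy.cd_decomposition <- function(x, ...) x$ssr_profile

#' One-row summary of a CD decomposition
#'
#' @param x A `cd_decomposition`.
#' @param ... Unused.
#' @return A one-row tibble: `f_refined`, `f_grid_best`, `ssr_min`,
#'   `ssr_refined`.
#' @export
glance.cd_decomposition <- function(x, ...) {
  tibble(
    f_refined = x$f_refined,
    f_grid_best = x$f_grid_best,
    ssr_min = x$ssr_min,
    ssr_refined = x$ssr_refined
  )
}

#' Tidy a signature call
#'
#' @param x A `signature_call`.
#' @param ... Unused.
#' @return The per-template score tibble.
#' @export
tidy.signature_call <- function(x, ...) x$scores

#' Plot a spectrum
#'
#' @param object A `spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrum <- function(object, ...) {
  ylab <- if (attr(object, "channel") == "CD") "CD (mdeg)" else "Absorbance"
  ggplot2::ggplot(as_tibble(object),
    ggplot2::aes(x = .data$wavelength_nm, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Wavelength (nm)", y = ylab,
      title = sprintf("%s (%s)", attr(object, "sample_id"),
        attr(object, "temperature_label") %||%
          sprintf("%g C", attr(object, "temperature_C")))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a melting curve
#'
#' @param object A `melting_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.melting_curve <- function(object, ...) {
  m <- melting_meta(object)
  ggplot2::ggplot(as_tibble(object),
    ggplot2::aes(x = .data$temperature_C, y = .data$absorbance)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Temperature (C)", y = "Absorbance",
      title = sprintf("%s @ %g nm (%s, %g C/min)", m$sample_id,
        m$wavelength_nm, m$direction, m$ramp_rate_C_per_min)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a melt result (curve derivative with the Tm marked)
#'
#' @param object A `melt_result`.
#' @param ... Unused.
#' @return A ggplot of dA/dT versus temperature.
#' @export
autoplot.melt_result <- function(object, ...) {
  p <- ggplot2::ggplot(object$derivative,
    ggplot2::aes(x = .data$temperature_C, y = .data$dA_dT)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Temperature (C)", y = "dA/dT",
      title = sprintf("%s @ %g nm (%s)", object$sample_id,
        object$wavelength_nm, object$direction)) +
    ggplot2::theme_minimal()
  if (object$transition_detected) {
    p <- p + ggplot2::geom_vline(xintercept = object$tm_C, linetype = "dashed")
  }
  p
}

#' Plot a CD decomposition (SSR profile and spectral fit)
#'
#' @param object A `cd_decomposition`.
#' @param which `"ssr"` for the SSR(f) profile or `"fit"` for the
#'   measured/calculated overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cd_decomposition <- function(object, which = c("ssr", "fit"), ...) {
  which <- match.arg(which)
  if (which == "ssr") {
    ggplot2::ggplot(object$ssr_profile, ggplot2::aes(x = .data$f, y = .data$ssr)) +
      ggplot2::geom_point() +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = object$f_refined, linetype = "dashed") +
      ggplot2::labs(x = "non-G4 fraction f", y = "SSR(f)",
        title = sprintf("f_refined = %.3f", object$f_refined)) +
      ggplot2::theme_minimal()
  } else {
    df <- tibble(
      wavelength_nm = rep(object$basis$wavelength_nm, 4),
      value = c(object$measured, object$calculated_best,
        object$basis$cd_g4, object$basis$cd_non_g4),
      trace = rep(c("measured", "calculated", "G4 basis", "non-G4 basis"),
        each = nrow(object$basis))
    )
    ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength_nm, y = .data$value,
      colour = .data$trace)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Wavelength (nm)", y = "CD (mdeg)") +
      ggplot2::theme_minimal()
  }
}
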