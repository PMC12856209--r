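# Two-basis CD decomposition: estimate the non-G4 fraction f of a measured
# CD spectrum as a convex combination of a G4 reference and a non-G4
# reference, and predict composite spectra of multi-G4-unit structures.
#
# Model: CD_calculated(f) = f * CD_non-G4 + (1 - f) * CD_G4.
# SSR(f) = sum_i [CD_measured(lambda_i) - CD_calculated(f, lambda_i)]^2 is a
# quadratic in f; the estimator uses both the figure-style coarse grid
# (f = 0.1 ... 0.9) and the exact closed-form minimizer clamped to [0, 1].

#' Construct a two-spectrum basis set
#'
#' Pairs a pure-G4 reference CD spectrum with a pure-non-G4 reference on a
#' shared wavelength grid. The intended pairing measures both references at
#' the same per-unit concentration as the sample (e.g. d(TGGGT)_n in K+ as
#' the G4 basis and the same-length oligo in Li+ as the non-G4 basis, both
#' at the 24/n uM design concentration); the caller is responsible for this
#' comparability.
#'
#' @param grid Ascending wavelength vector (nm), or a `spectrum` for the G4
#'   basis (then `cd_non_g4` must be a `spectrum` too and grids must match).
#' @param cd_g4,cd_non_g4 Numeric CD vectors on `grid` (mdeg), or spectra.
#' @param labels Character pair naming the two bases.
#' @return A tibble of class `basis_set` with columns `wavelength_nm`,
#'   `cd_g4`, `cd_non_g4`.
#' @export
basis_set <- function(grid, cd_g4, cd_non_g4, labels = c("G4", "non-G4")) {
  if (inherits(grid, "spectrum")) {
    g4_spec <- grid
    if (!inherits(cd_g4, "spectrum")) {
      .ps_abort("when `grid` is a spectrum, pass the non-G4 spectrum as `cd_g4`.",
        "domain_error")
    }
    non_g4_spec <- cd_g4
    grid <- common_grid(g4_spec, non_g4_spec)
    cd_g4 <- regrid(g4_spec, grid)$value
    cd_non_g4 <- regrid(non_g4_spec, grid)$value
  }
  grid <- as.numeric(grid)
  cd_g4 <- as.numeric(cd_g4)
  cd_non_g4 <- as.numeric(cd_non_g4)
  if (length(grid) < 2L || length(cd_g4) != length(grid) ||
    length(cd_non_g4) != length(grid)) {
    .ps_abort("grid and basis vectors must have equal length >= 2.", "domain_error")
  }
  if (any(diff(grid) <= 0)) {
    .ps_abort("`grid` must be strictly increasing.", "domain_error")
  }
  n1 <- sqrt(sum(cd_g4^2))
  n2 <- sqrt(sum(cd_non_g4^2))
  angle <- if (n1 == 0 || n2 == 0) 0 else {
    acos(pmin(1, abs(sum(cd_g4 * cd_non_g4)) / (n1 * n2)))
  }
  if (angle <= 1e-6) {
    .ps_abort("basis spectra are (near-)proportional; decomposition is ill-posed.",
      "degeneracy_error")
  }
  out <- tibble(wavelength_nm = grid, cd_g4 = cd_g4, cd_non_g4 = cd_non_g4)
  attr(out, "labels") <- labels
  class(out) <- c("basis_set", class(out))
  out
}

#' Calculated mixture spectrum at fraction f
#'
#' Pointwise convex combination `f * cd_non_g4 + (1 - f) * cd_g4` on the
#' basis grid.
#'
#' @param basis A `basis_set`.
#' @param f Non-G4 fraction in `[0, 1]`.
#' @return Numeric vector on the basis grid.
#' @export
calculated_spectrum <- function(basis, f) {
  stopifnot(inherits(basis, "basis_set"))
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1) {
    .ps_abort("`f` must be a single number in [0, 1].", "domain_error")
  }
  f * basis$cd_non_g4 + (1 - f) * basis$cd_g4
}

.measured_on_basis <- function(measured, basis) {
  if (inherits(measured, "spectrum")) {
    if (!isTRUE(all.equal(measured$wavelength_nm, basis$wavelength_nm))) {
      measured <- regrid(measured, basis$wavelength_nm)
    }
    measured$value
  } else if (is.numeric(measured) && length(measured) == nrow(basis)) {
    as.numeric(measured)
  } else {
    .ps_abort("`measured` must be a spectrum or a vector on the basis grid.",
      "domain_error")
  }
}

#' SSR profile over a grid of candidate fractions
#'
#' Sum of squared residuals between the measured spectrum and the calculated
#' mixture, for each candidate `f`.
#'
#' @param measured A CD `spectrum` (regridded onto the basis grid if needed)
#'   or a numeric vector on that grid.
#' @param basis A `basis_set`.
#' @param f_grid Candidate fractions (default `seq(0.1, 0.9, by = 0.1)`, the
#'   figure-style grid).
#' @return A tibble with columns `f` and `ssr`.
#' @export
ssr_profile <- function(measured, basis, f_grid = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(inherits(basis, "basis_set"))
  if (any(f_grid < 0 | f_grid > 1)) {
    .ps_abort("`f_grid` values must lie in [0, 1].", "domain_error")
  }
  y <- .measured_on_basis(measured, basis)
  tibble(
    f = as.numeric(f_grid),
    ssr = map_dbl(f_grid, function(f) sum((y - calculated_spectrum(basis, f))^2))
  )
}

#' Estimate the non-G4 fraction of a measured CD spectrum
#'
#' Evaluates SSR(f) over the coarse grid (argmin reported as `f_grid_best`,
#' ties broken toward smaller f) and refines with the exact closed-form
#' minimizer of the quadratic SSR — the least-squares projection of
#' (measured - cd_g4) onto (cd_non_g4 - cd_g4) — clamped to `[0, 1]`.
#'
#' @inheritParams ssr_profile
#' @return An object of class `cd_decomposition`: list with `f_grid_best`,
#'   `f_refined`, `ssr_profile` (tibble), `ssr_min` (minimum over the grid
#'   profile), `ssr_refined`, `residual` (tibble `wavelength_nm`,
#'   `residual`), and `calculated_best` (fitted spectrum at `f_refined`).
#' @examples
#' b <- basis_set(240:320,
#'   cd_g4 = 5 * exp(-((240:320) - 264)^2 / 98),
#'   cd_non_g4 = 3 * exp(-((240:320) - 280)^2 / 98))
#' fit <- estimate_fraction(calculated_spectrum(b, 0.55), b)
#' fit$f_refined
#' @export
estimate_fraction <- function(measured, basis, f_grid = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(inherits(basis, "basis_set"))
  y <- .measured_on_basis(measured, basis)
  profile <- ssr_profile(y, basis, f_grid)

  # ties toward smaller f: which.min returns the first index and the grid
  # is in increasing order
  f_best <- profile$f[which.min(profile$ssr)]

  d <- basis$cd_non_g4 - basis$cd_g4
  f_hat <- sum((y - basis$cd_g4) * d) / sum(d^2)
  f_refined <- min(1, max(0, f_hat))

  fitted <- calculated_spectrum(basis, f_refined)
  residual <- y - fitted
  structure(
    list(
      f_grid_best = f_best,
      f_refined = f_refined,
      ssr_profile = profile,
      ssr_min = min(profile$ssr),
      ssr_refined = sum(residual^2),
      residual = tibble(wavelength_nm = basis$wavelength_nm, residual = residual),
      calculated_best = fitted,
      measured = y,
      basis = basis
    ),
    class = "cd_decomposition"
  )
}

#' @export
print.cd_decomposition <- function(x, ...) {
  cat(sprintf(
    "<cd_decomposition> non-G4 fraction f = %.4f (grid best %.1f), SSR = %.4g\n",
    x$f_refined, x$f_grid_best, x$ssr_refined
  ))
  invisible(x)
}

#' Composite CD spectrum of a multi-G4-unit structure
#'
#' Per-unit weighted mean of unit spectra: `sum(w_j * S_j) / sum(w_j)`. Used
#' to model beads-on-a-string structures of m stacked or contiguous G4
#' units, e.g. one unit in a parallel/antiparallel equilibrium plus m - 1
#' parallel units. All spectra are assumed recorded at (or normalized to)
#' equal per-G4-unit concentration, which makes per-unit averaging the
#' consistent combination rule.
#'
#' @param unit_spectra List of numeric vectors on a common grid (or
#'   `spectrum` objects on identical grids).
#' @param weights Positive integer unit counts, one per spectrum.
#' @return Numeric vector (or `spectrum` when inputs are spectra) of the
#'   composite.
#' @export
composite_spectrum <- function(unit_spectra, weights) {
  if (!is.list(unit_spectra) || length(unit_spectra) == 0L) {
    .ps_abort("`unit_spectra` must be a nonempty list.", "domain_error")
  }
  if (length(weights) != length(unit_spectra) ||
    any(weights <= 0 | weights != floor(weights))) {
    .ps_abort("`weights` must be positive integers, one per spectrum.",
      "domain_error")
  }
  as_spec <- inherits(unit_spectra[[1]], "spectrum")
  if (as_spec) {
    grid <- unit_spectra[[1]]$wavelength_nm
    ok <- vapply(unit_spectra, function(s) {
      inherits(s, "spectrum") && isTRUE(all.equal(s$wavelength_nm, grid))
    }, logical(1))
    if (!all(ok)) {
      .ps_abort("unit spectra are on different grids; regrid first.",
        "regrid_required_error")
    }
    vals <- map(unit_spectra, ~ .x$value)
  } else {
    len <- length(unit_spectra[[1]])
    if (any(vapply(unit_spectra, length, integer(1)) != len)) {
      .ps_abort("unit spectra are on different grids; regrid first.",
        "regrid_required_error")
    }
    vals <- unit_spectra
  }
  acc <- Reduce(`+`, purrr::map2(vals, weights, ~ .x * .y)) / sum(weights)
  if (as_spec) {
    spectrum(unit_spectra[[1]]$wavelength_nm, acc,
      channel = attr(unit_spectra[[1]], "channel"),
      temperature_C = attr(unit_spectra[[1]], "temperature_C"),
      sample_id = "composite"
    )
  } else {
    acc
  }
}
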