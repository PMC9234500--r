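# Ocular-media transmittance descriptors, oil-droplet means and reflectance
# normalisation.

#' Normalise a transmittance spectrum to its long-wavelength plateau
#'
#' Divides the raw spectrum by its mean over the normalisation window
#' (690–840 nm by default), so the plateau mean of the result is exactly 1.
#' All downstream half-maximum descriptors are therefore invariant to the
#' arbitrary scale of the raw measurement.
#'
#' @param curve A [spectral_curve()] (raw transmittance).
#' @param window Length-2 numeric, lower and upper bound (nm) of the
#'   normalisation window.
#' @return A tibble of class `eyespec_transmittance` (a [spectral_curve()]
#'   with attributes `normalization_window_nm` and `plateau`).
#' @examples
#' ts <- normalize_transmittance(make_media_curve(359, 10))
#' @export
normalize_transmittance <- function(curve, window = c(690, 840)) {
  curve <- as_spectral_curve(curve)
  window <- sort(window)
  if (min(curve$wavelength_nm) > window[1] || max(curve$wavelength_nm) < window[2]) {
    abort("Normalization window lies outside the support of the curve.",
          class = "eyespec_invalid_window")
  }
  in_win <- curve$wavelength_nm >= window[1] & curve$wavelength_nm <= window[2]
  m <- mean(curve$value[in_win])
  if (!is.finite(m) || m <= 0) {
    abort("Window mean must be positive.", class = "eyespec_invalid_window")
  }
  out <- spectral_curve(curve$wavelength_nm, curve$value / m)
  attr(out, "normalization_window_nm") <- window
  class(out) <- c("eyespec_transmittance", class(out))
  out
}

#' Half-maximum (lambda_T0.5) wavelength of a transmittance spectrum
#'
#' Finds the wavelength at which a normalised transmittance spectrum crosses
#' half of its plateau value, the plateau being the mean over the
#' normalisation window (1 after [normalize_transmittance()]). When noise
#' produces several crossings, the longest-wavelength upward crossing is
#' taken, since measured ocular media rise monotonically toward long
#' wavelengths. The crossing is located by linear interpolation between the
#' bracketing samples. Because only the 0.5-plateau ratio enters, the result
#' is invariant to positive rescaling of the raw spectrum.
#'
#' @param ts A normalised transmittance spectrum
#'   ([normalize_transmittance()]); a raw [spectral_curve()] is normalised
#'   first over `window`.
#' @param window Normalisation window used if `ts` is not yet normalised.
#' @return A tibble with columns `lambda_t50_nm`, `crossing_found`,
#'   `direction`.
#' @examples
#' half_max_wavelength(normalize_transmittance(make_media_curve(359, 10)))
#' @export
half_max_wavelength <- function(ts, window = c(690, 840)) {
  if (!inherits(ts, "eyespec_transmittance")) {
    ts <- normalize_transmittance(ts, window)
  }
  window <- attr(ts, "normalization_window_nm")
  in_win <- ts$wavelength_nm >= window[1] & ts$wavelength_nm <= window[2]
  plateau <- mean(ts$value[in_win])
  half <- plateau / 2
  v <- ts$value
  wl <- ts$wavelength_nm
  below <- v < half
  up <- which(below[-length(v)] & !below[-1])
  if (length(up) == 0L) {
    return(tibble(lambda_t50_nm = NA_real_, crossing_found = FALSE,
                  direction = NA_character_))
  }
  i <- max(up) # longest-wavelength upward crossing
  lam <- wl[i] + (half - v[i]) * (wl[i + 1] - wl[i]) / (v[i + 1] - v[i])
  tibble(lambda_t50_nm = lam, crossing_found = TRUE, direction = "rising")
}

#' Combine two ocular media multiplicatively
#'
#' Pointwise product of two transmittance spectra (e.g. cornea and lens),
#' renormalised over the window. Spectra on different grids are resampled by
#' linear interpolation onto the coarser grid over the common support; the
#' supports must overlap and span the window.
#'
#' @param a,b Transmittance spectra ([normalize_transmittance()] output or
#'   raw [spectral_curve()]s).
#' @param window Normalisation window (nm).
#' @return An `eyespec_transmittance` on the common grid.
#' @examples
#' combine_media(make_media_curve(307, 12), make_media_curve(359, 10))
#' @export
combine_media <- function(a, b, window = c(690, 840)) {
  a <- as_spectral_curve(a)
  b <- as_spectral_curve(b)
  lo <- max(min(a$wavelength_nm), min(b$wavelength_nm))
  hi <- min(max(a$wavelength_nm), max(b$wavelength_nm))
  if (lo >= hi) {
    abort("Spectra have disjoint wavelength supports.",
          class = "eyespec_invalid_input")
  }
  # coarser grid = the one with fewer samples on the common support
  ga <- a$wavelength_nm[a$wavelength_nm >= lo & a$wavelength_nm <= hi]
  gb <- b$wavelength_nm[b$wavelength_nm >= lo & b$wavelength_nm <= hi]
  grid <- if (length(ga) <= length(gb)) ga else gb
  va <- resample_spectrum(a, grid)$value
  vb <- resample_spectrum(b, grid)$value
  normalize_transmittance(spectral_curve(grid, va * vb), window)
}

#' Mean of several absorptance traces
#'
#' Pointwise arithmetic mean of individual measurement traces on a common
#' grid (traces on other grids are resampled onto the first trace's grid).
#'
#' @param traces A list of [spectral_curve()]s (at least one).
#' @return A [spectral_curve()].
#' @export
mean_absorptance <- function(traces) {
  if (!is.list(traces) || length(traces) == 0L) {
    abort("`traces` must be a non-empty list of spectral curves.",
          class = "eyespec_invalid_input")
  }
  traces <- lapply(traces, as_spectral_curve)
  grid <- traces[[1]]$wavelength_nm
  vals <- vapply(traces, function(tr) resample_spectrum(tr, grid)$value,
                 numeric(length(grid)))
  spectral_curve(grid, rowMeans(as.matrix(vals)))
}

#' Normalise a spectrum by its integral
#'
#' Divides the curve by its trapezoid-rule integral so the result integrates
#' to 1, the convention used to compare reflectance spectra of different
#' overall brightness. Ratios between any two wavelengths are preserved.
#'
#' @param curve A [spectral_curve()] with positive integral.
#' @return A [spectral_curve()] integrating to 1.
#' @examples
#' normalize_by_integral(spectral_curve(seq(350, 650, 10), rep(2, 31)))
#' @export
normalize_by_integral <- function(curve) {
  curve <- as_spectral_curve(curve)
  z <- trapz(curve$wavelength_nm, curve$value)
  if (!is.finite(z) || z <= 0) {
    abort("Curve integral must be positive.", class = "eyespec_invalid_input")
  }
  spectral_curve(curve$wavelength_nm, curve$value / z)
}
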