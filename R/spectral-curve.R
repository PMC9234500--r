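#' Construct a spectral curve
#'
#' The universal spectrum container used throughout the package: a tibble with
#' a strictly increasing `wavelength_nm` column (restricted to 300–850 nm, the
#' range instruments in this field record) and a finite `value` column holding
#' transmittance, absorptance, reflectance or sensitivity.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nm, strictly
#'   increasing, within \[300, 850\].
#' @param value Numeric vector of the same length; all values finite.
#' @return A tibble of class `eyespec_spectrum` with columns `wavelength_nm`
#'   and `value`.
#' @examples
#' spectral_curve(seq(300, 850, 10), rep(1, 56))
#' @export
spectral_curve <- function(wavelength_nm, value) {
  if (!is.numeric(wavelength_nm) || !is.numeric(value)) {
    abort("`wavelength_nm` and `value` must be numeric.",
          class = "eyespec_invalid_parameter")
  }
  if (length(wavelength_nm) != length(value)) {
    abort("`wavelength_nm` and `value` must have equal length.",
          class = "eyespec_invalid_parameter")
  }
  if (anyNA(wavelength_nm) || any(!is.finite(wavelength_nm))) {
    abort("Wavelengths must be finite.", class = "eyespec_invalid_parameter")
  }
  if (any(!is.finite(value))) {
    abort("Spectrum values must be finite.", class = "eyespec_invalid_parameter")
  }
  if (any(wavelength_nm < 300 | wavelength_nm > 850)) {
    abort("Wavelengths must lie within [300, 850] nm.",
          class = "eyespec_invalid_parameter")
  }
  if (length(wavelength_nm) > 1L && any(diff(wavelength_nm) <= 0)) {
    abort("Wavelengths must be strictly increasing.",
          class = "eyespec_invalid_parameter")
  }
  out <- tibble(wavelength_nm = as.numeric(wavelength_nm),
                value = as.numeric(value))
  class(out) <- c("eyespec_spectrum", class(out))
  out
}

#' Resample a spectral curve onto a new wavelength grid
#'
#' Linear interpolation; the new grid must lie within the support of the
#' curve (no extrapolation).
#'
#' @param curve A [spectral_curve()].
#' @param grid Numeric vector of target wavelengths (nm), strictly increasing.
#' @return A [spectral_curve()] on `grid`.
#' @export
resample_spectrum <- function(curve, grid) {
  curve <- as_spectral_curve(curve)
  if (min(grid) < min(curve$wavelength_nm) || max(grid) > max(curve$wavelength_nm)) {
    abort("Target grid extends beyond the support of the curve.",
          class = "eyespec_invalid_input")
  }
  v <- approx(curve$wavelength_nm, curve$value, xout = grid, ties = "ordered")$y
  spectral_curve(grid, v)
}

# Coerce a two-column data frame (wavelength_nm, value) to a spectral curve.
#' @export
#' @rdname spectral_curve
#' @param x A data frame with columns `wavelength_nm` and `value`.
as_spectral_curve <- function(x) {
  if (inherits(x, "eyespec_spectrum")) return(x)
  if (!is.data.frame(x) || !all(c("wavelength_nm", "value") %in% names(x))) {
    abort("Expected a data frame with columns `wavelength_nm` and `value`.",
          class = "eyespec_invalid_input")
  }
  spectral_curve(x$wavelength_nm, x$value)
}

#' Read / write spectra as two-column CSV
#'
#' The on-disk interchange format for spectra is a headed two-column CSV
#' (`wavelength_nm`, `value`).
#'
#' @param path File path.
#' @return `read_spectrum_csv()` returns a [spectral_curve()];
#'   `write_spectrum_csv()` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  as_spectral_curve(df)
}

#' @rdname read_spectrum_csv
#' @param curve A [spectral_curve()].
#' @export
write_spectrum_csv <- function(curve, path) {
  curve <- as_spectral_curve(curve)
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @method autoplot eyespec_spectrum
#' @export
autoplot.eyespec_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$wavelength_nm, y = .data$value)) +
    ggplot2::geom_line(...) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Value")
}
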