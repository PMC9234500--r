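# Visual-pigment templates and ocular spectral filters.

# Raw Govardovskii et al. (2000) alpha-band template, unnormalised.
# x = lambda_max / lambda.
govardovskii_alpha <- function(lambda_nm, lambda_max_nm, chromophore) {
  x <- lambda_max_nm / lambda_nm
  if (chromophore == "A1") {
    a <- 0.8795 + 0.0459 * exp(-(lambda_max_nm - 300)^2 / 11940)
    1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
           exp(-14.9 * (1.104 - x)) + 0.674)
  } else {
    a <- 0.875 + 0.0268 * exp((lambda_max_nm - 665) / 40.7)
    A <- 62.7 + 1.834 * exp((lambda_max_nm - 625) / 54.2)
    1 / (exp(A * (a - x)) + exp(41.5 * (0.9101 - x)) +
           exp(-10.9 * (1.1123 - x)) + 0.5343)
  }
}

#' Visual-pigment absorbance template
#'
#' Evaluates the standard A1/A2 visual-pigment nomogram (alpha band) of
#' Govardovskii and colleagues for a pigment of given peak wavelength, and
#' peak-normalises it so the maximum absorbance is exactly 1 (the raw template
#' peaks a fraction of a percent above 1). Only the alpha band is modelled;
#' the beta band contributes little above 350 nm for the long-wavelength
#' pigments considered here and is absorbed into the short-wavelength classes'
#' own templates.
#'
#' @param lambda_max_nm Peak absorbance wavelength, in \[330, 620\] nm.
#' @param chromophore `"A1"` (retinal, the usual chromophore of diurnal
#'   lizards) or `"A2"` (3,4-didehydroretinal, red-shifted and broadened).
#' @param grid Wavelength grid (nm) on which to evaluate, within \[300, 850\].
#' @return A [spectral_curve()] of relative absorbance in \[0, 1\], with
#'   maximum 1 at `lambda_max_nm` (within grid resolution).
#' @examples
#' lws <- pigment_absorbance(564)
#' lws$wavelength_nm[which.max(lws$value)]
#' @export
pigment_absorbance <- function(lambda_max_nm, chromophore = c("A1", "A2"),
                               grid = seq(300, 850, by = 1)) {
  chromophore <- match.arg(chromophore)
  if (!is.numeric(lambda_max_nm) || length(lambda_max_nm) != 1L ||
      !is.finite(lambda_max_nm) || lambda_max_nm < 330 || lambda_max_nm > 620) {
    abort("`lambda_max_nm` must lie within the template validity range [330, 620] nm.",
          class = "eyespec_invalid_parameter")
  }
  if (min(grid) < 300 || max(grid) > 850) {
    abort("`grid` must lie within [300, 850] nm.",
          class = "eyespec_invalid_parameter")
  }
  raw <- govardovskii_alpha(grid, lambda_max_nm, chromophore)
  # peak-normalise on a fine internal grid so values never exceed 1
  fine <- seq(max(300, lambda_max_nm - 60), min(850, lambda_max_nm + 60), by = 0.05)
  peak <- max(govardovskii_alpha(fine, lambda_max_nm, chromophore))
  spectral_curve(grid, pmin(raw / peak, 1))
}

#' Sigmoidal ocular-media transmittance curve
#'
#' Logistic transmittance model for a lens or cornea: rises monotonically from
#' 0 to a plateau of 1, crossing 0.5 exactly at `lambda_t50_nm` (the
#' half-peak transmittance wavelength, lambda_T0.5). The plateau is reached,
#' to within a fraction of a percent, above roughly
#' `lambda_t50_nm + 5 * slope_nm`.
#'
#' @param lambda_t50_nm Half-maximum wavelength, in \[300, 500\] nm. The
#'   package defaults elsewhere use 359 nm for the lens and 307 nm for the
#'   cornea, the values measured for *Tiliqua rugosa*.
#' @param slope_nm Width parameter of the logistic rise (nm), > 0.
#' @param grid Wavelength grid (nm).
#' @return A [spectral_curve()] of transmittance in (0, 1).
#' @examples
#' lens <- make_media_curve(359, 10)
#' @export
make_media_curve <- function(lambda_t50_nm, slope_nm,
                             grid = seq(300, 850, by = 1)) {
  check_number(lambda_t50_nm, "lambda_t50_nm", 300, 500)
  if (!is.numeric(slope_nm) || length(slope_nm) != 1L || !is.finite(slope_nm) ||
      slope_nm <= 0) {
    abort("`slope_nm` must be a positive number.",
          class = "eyespec_invalid_parameter")
  }
  spectral_curve(grid, 1 / (1 + exp(-(grid - lambda_t50_nm) / slope_nm)))
}

#' Oil-droplet spectral filter
#'
#' Absorptance profile of a cone oil droplet. Two measured types are
#' supported: `"C2"` (transparent; equal absorptance throughout the spectrum)
#' and `"C1"` (pale yellow; absorptance elevated below a cut-off, by default
#' 430 nm). `"none"` is a zero-absorptance placeholder. Droplet transmittance
#' is `1 - absorptance`.
#'
#' @param label `"C1"`, `"C2"` or `"none"`.
#' @param cutoff_nm Wavelength below which a C1 droplet absorbs more (nm).
#' @param base_absorptance Flat absorptance level of both measured types.
#' @param step_absorptance Additional short-wavelength absorptance of C1.
#' @param width_nm Softness of the C1 transition (nm).
#' @param grid Wavelength grid (nm).
#' @return A list of class `eyespec_droplet` with fields `label`, `cutoff_nm`
#'   and `absorptance` (a [spectral_curve()]).
#' @examples
#' oil_droplet("C1")
#' @export
oil_droplet <- function(label = c("none", "C1", "C2"), cutoff_nm = 430,
                        base_absorptance = 0.08, step_absorptance = 0.25,
                        width_nm = 15, grid = seq(300, 850, by = 1)) {
  label <- match.arg(label)
  absorptance <- switch(label,
    none = rep(0, length(grid)),
    C2 = rep(base_absorptance, length(grid)),
    C1 = base_absorptance +
      step_absorptance / (1 + exp((grid - cutoff_nm) / width_nm))
  )
  if (any(absorptance < 0 | absorptance > 1)) {
    abort("Droplet absorptance must stay within [0, 1].",
          class = "eyespec_invalid_parameter")
  }
  structure(
    list(label = label,
         cutoff_nm = if (label == "C1") cutoff_nm else NA_real_,
         absorptance = spectral_curve(grid, absorptance)),
    class = "eyespec_droplet"
  )
}

#' @rdname oil_droplet
#' @param droplet An `eyespec_droplet`.
#' @return `droplet_transmittance()` returns the complementary transmittance
#'   curve `1 - absorptance`.
#' @export
droplet_transmittance <- function(droplet) {
  stopifnot(inherits(droplet, "eyespec_droplet"))
  spectral_curve(droplet$absorptance$wavelength_nm, 1 - droplet$absorptance$value)
}
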