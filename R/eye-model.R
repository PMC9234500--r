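# Forward eye model: photoreceptor classes, temporal weighting, whole-eye
# spectral sensitivity, and the saturating ERG response nonlinearity.

#' Temporal weighting functions for photoreceptor classes
#'
#' Relative contribution of a photoreceptor class to the flicker ERG as a
#' function of stimulus frequency, on \[0, 1\]. Classes that favour low
#' temporal frequencies (blue-sensitive cones, rod-opsin cones) use the
#' low-pass form; the fast long-wavelength cones use the high-pass form.
#'
#' @param f0_hz Corner frequency (Hz).
#' @param order Steepness exponent.
#' @return A function of frequency (Hz) returning weights in \[0, 1\].
#' @examples
#' temporal_low_pass()(c(3, 10, 30))
#' @export
temporal_low_pass <- function(f0_hz = 8, order = 2) {
  force(f0_hz); force(order)
  function(f) 1 / (1 + (f / f0_hz)^order)
}

#' @rdname temporal_low_pass
#' @export
temporal_high_pass <- function(f0_hz = 5, order = 2) {
  force(f0_hz); force(order)
  function(f) (f / f0_hz)^order / (1 + (f / f0_hz)^order)
}

#' @rdname temporal_low_pass
#' @export
temporal_flat <- function() function(f) rep(1, length(f))

#' Define a photoreceptor class
#'
#' One spectral class of the forward eye model: a visual-pigment template, an
#' oil-droplet filter, a relative abundance/gain weight, and a temporal
#' weighting function.
#'
#' @param name Class label; one of `"SWS1"`, `"SWS2"`, `"RH1-cone"`, `"RH2"`,
#'   `"LWS"`.
#' @param lambda_max_nm Template peak wavelength (nm).
#' @param chromophore `"A1"` or `"A2"`.
#' @param droplet An [oil_droplet()].
#' @param weight Non-negative relative weight.
#' @param temporal A function of frequency (Hz) returning a weight in
#'   \[0, 1\]; see [temporal_low_pass()].
#' @return A list of class `eyespec_photoreceptor_class`.
#' @export
photoreceptor_class <- function(name, lambda_max_nm, chromophore = "A1",
                                droplet = oil_droplet("none"), weight = 1,
                                temporal = temporal_flat()) {
  name <- match.arg(name, c("SWS1", "SWS2", "RH1-cone", "RH2", "LWS"))
  check_number(weight, "weight", 0, Inf)
  stopifnot(is.function(temporal), inherits(droplet, "eyespec_droplet"))
  structure(
    list(name = name, lambda_max_nm = lambda_max_nm, chromophore = chromophore,
         droplet = droplet, weight = weight, temporal = temporal),
    class = "eyespec_photoreceptor_class"
  )
}

#' Forward model of the whole eye
#'
#' Bundles photoreceptor classes with the combined ocular-media transmittance
#' and the saturating response nonlinearity used to simulate ERG amplitudes:
#' a Naka–Rushton form `R(Q) = R_max * Q^n / (Q^n + K^n)` on the effective
#' photon catch `Q`.
#'
#' @param classes List of [photoreceptor_class()] objects (at least one).
#' @param media A [spectral_curve()] of combined cornea+lens transmittance
#'   (values in \[0, 1.1\]), or `NULL` for a spectrally flat eye.
#' @param response_max Saturated response amplitude (arbitrary units).
#' @param response_half_saturation Effective catch `K` at half-saturation
#'   (photons cm^-2 s^-1).
#' @param response_exponent Naka–Rushton exponent `n` (> 0).
#' @param noise_sd Standard deviation of multiplicative log-normal amplitude
#'   noise (log scale); 0 gives deterministic responses.
#' @return A list of class `eyespec_eye_model`.
#' @seealso [default_eye_model()], [eye_sensitivity_spectrum()]
#' @export
eye_model <- function(classes, media = NULL, response_max = 100,
                      response_half_saturation = 1e15,
                      response_exponent = 1, noise_sd = 0.05) {
  if (!is.list(classes) || length(classes) == 0L ||
      !all(vapply(classes, inherits, TRUE, "eyespec_photoreceptor_class"))) {
    abort("`classes` must be a non-empty list of photoreceptor classes.",
          class = "eyespec_invalid_model")
  }
  if (!is.null(media)) {
    media <- as_spectral_curve(media)
    if (any(media$value < 0 | media$value > 1.1)) {
      abort("Media transmittance must lie within [0, 1.1].",
            class = "eyespec_invalid_model")
    }
  }
  check_number(response_max, "response_max", 0, Inf)
  check_number(response_half_saturation, "response_half_saturation", 0, Inf)
  if (response_exponent <= 0) {
    abort("`response_exponent` must be > 0.", class = "eyespec_invalid_model")
  }
  check_number(noise_sd, "noise_sd", 0, Inf)
  structure(
    list(classes = classes, media = media, response_max = response_max,
         response_half_saturation = response_half_saturation,
         response_exponent = response_exponent, noise_sd = noise_sd),
    class = "eyespec_eye_model"
  )
}

#' Default forward eye model
#'
#' The study-condition eye: five photoreceptor classes at anole-like template
#' peaks (SWS1 365, SWS2 456, RH1-cone 491, RH2 494, LWS 564 nm, all A1),
#' pale-yellow C1 droplets on the SWS2 and LWS classes and transparent C2
#' droplets elsewhere, and logistic lens (359 nm) and cornea (307 nm)
#' transmittance combined multiplicatively. SWS2 and RH1-cone classes are
#' low-pass in temporal frequency and LWS is high-pass, so short-wavelength
#' classes dominate slow flicker and long-wavelength classes fast flicker.
#' Class weights are fixed so the 10 Hz whole-eye sensitivity peaks near
#' 560 nm with a broad short-wavelength shoulder.
#'
#' @param noise_sd Multiplicative amplitude noise (log sd) of simulated
#'   responses.
#' @param grid Wavelength grid (nm) for the media curve.
#' @return An [eye_model()].
#' @examples
#' m <- default_eye_model()
#' @export
default_eye_model <- function(noise_sd = 0.05, grid = seq(300, 850, by = 1)) {
  lens <- make_media_curve(359, 10, grid)
  cornea <- make_media_curve(307, 12, grid)
  media <- spectral_curve(grid, lens$value * cornea$value)
  c1 <- oil_droplet("C1", grid = grid)
  c2 <- oil_droplet("C2", grid = grid)
  classes <- list(
    photoreceptor_class("SWS1", 365, droplet = c2, weight = 0.05,
                        temporal = temporal_flat()),
    photoreceptor_class("SWS2", 456, droplet = c1, weight = 0.45,
                        temporal = temporal_low_pass(7, 2)),
    photoreceptor_class("RH1-cone", 491, droplet = c2, weight = 0.12,
                        temporal = temporal_low_pass(7, 2)),
    photoreceptor_class("RH2", 494, droplet = c2, weight = 0.04,
                        temporal = temporal_flat()),
    photoreceptor_class("LWS", 564, droplet = c1, weight = 1.0,
                        temporal = temporal_high_pass(5, 2))
  )
  eye_model(classes, media = media, noise_sd = noise_sd)
}

# Spectral profile of one class on a grid: media * droplet transmittance *
# template absorbance (no temporal or adaptation factors).
class_spectral_profile <- function(class, media, grid) {
  absorb <- pigment_absorbance(class$lambda_max_nm, class$chromophore, grid)$value
  dropt <- resample_spectrum(droplet_transmittance(class$droplet), grid)$value
  med <- if (is.null(media)) rep(1, length(grid)) else
    resample_spectrum(media, grid)$value
  med * dropt * absorb
}

# Weber-style suppression factor per class under a steady monochromatic
# adaptation light: contrast divided by (1 + catch of adaptation light / K).
adaptation_factors <- function(model, adaptation_nm, adaptation_flux) {
  if (is.null(adaptation_nm) || is.na(adaptation_nm) || adaptation_flux <= 0) {
    return(rep(1, length(model$classes)))
  }
  vapply(model$classes, function(cl) {
    prof <- class_spectral_profile(cl, model$media, adaptation_nm)
    1 / (1 + adaptation_flux * prof / model$response_half_saturation)
  }, numeric(1))
}

#' Whole-eye spectral sensitivity of a forward model
#'
#' The model sensitivity at temporal frequency `f` is the weighted sum over
#' classes of media transmittance x droplet transmittance x template
#' absorbance, each class scaled by its weight and its temporal weight at
#' `f`, normalised to a maximum of 1. An optional steady monochromatic
#' adaptation light divides each class's contribution by
#' `1 + catch_of_adaptation_light / K` (Weber-style contrast reduction), which
#' selectively suppresses classes sensitive at the adaptation wavelength.
#'
#' @param model An [eye_model()].
#' @param frequency_hz Stimulus flicker frequency in \[3, 30\] Hz.
#' @param grid Wavelength grid (nm).
#' @param adaptation_nm Wavelength of the adaptation light, or `NULL`/`NA`.
#' @param adaptation_flux Photon flux of the adaptation light
#'   (photons cm^-2 s^-1).
#' @return A [spectral_curve()] normalised to max 1.
#' @examples
#' s <- eye_sensitivity_spectrum(default_eye_model(), 10)
#' @export
eye_sensitivity_spectrum <- function(model, frequency_hz,
                                     grid = seq(350, 650, by = 10),
                                     adaptation_nm = NULL,
                                     adaptation_flux = 3e16) {
  stopifnot(inherits(model, "eyespec_eye_model"))
  check_number(frequency_hz, "frequency_hz", 3, 30)
  supp <- adaptation_factors(model, adaptation_nm, adaptation_flux)
  s <- rep(0, length(grid))
  for (i in seq_along(model$classes)) {
    cl <- model$classes[[i]]
    s <- s + cl$weight * cl$temporal(frequency_hz) * supp[i] *
      class_spectral_profile(cl, model$media, grid)
  }
  if (max(s) <= 0) {
    abort("Model sensitivity is zero everywhere.", class = "eyespec_invalid_model")
  }
  spectral_curve(grid, s / max(s))
}

# Naka-Rushton response to an effective catch Q.
naka_rushton <- function(q, model) {
  n <- model$response_exponent
  k <- model$response_half_saturation
  model$response_max * q^n / (q^n + k^n)
}
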