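# Simulated ERG flicker-photometry trial sets from a forward eye model.

#' Convert irradiance to photon flux
#'
#' `Q = E * lambda / (h * c)` with CODATA constants, for quasi-monochromatic
#' light of wavelength `lambda`.
#'
#' @param irradiance_w_cm2 Irradiance in W cm^-2 (>= 0).
#' @param wavelength_nm Wavelength in \[300, 850\] nm.
#' @return Photon flux in photons cm^-2 s^-1.
#' @examples
#' photon_flux(1, 500) # ~2.517e18
#' @export
photon_flux <- function(irradiance_w_cm2, wavelength_nm) {
  if (any(irradiance_w_cm2 < 0)) {
    abort("Irradiance must be non-negative.", class = "eyespec_invalid_input")
  }
  if (any(wavelength_nm < 300 | wavelength_nm > 850)) {
    abort("Wavelength must lie within [300, 850] nm.",
          class = "eyespec_invalid_input")
  }
  irradiance_w_cm2 * (wavelength_nm * 1e-9) / HC_J_M
}

#' @rdname photon_flux
#' @param flux Photon flux in photons cm^-2 s^-1.
#' @return `irradiance_from_flux()` inverts the conversion.
#' @export
irradiance_from_flux <- function(flux, wavelength_nm) {
  flux * HC_J_M / (wavelength_nm * 1e-9)
}

#' Define an ERG flicker-photometry protocol
#'
#' The measurement schedule replayed by [simulate_erg_trials()]: two
#' interleaved wavelength sweeps (descending 650–350 nm and ascending
#' 340–640 nm, both at 20 nm steps, the splice of which yields a 10 nm grid),
#' the stimulus flicker frequency, an optional steady monochromatic
#' adaptation light, and the white-reference irradiance. At each wavelength a
#' ladder of monochromatic photon fluxes is presented, centred on the flux
#' that matches the white response (emulating online intensity adjustment).
#'
#' @param frequency_hz Flicker frequency in \[3, 30\] Hz.
#' @param adaptation_nm Adaptation-light wavelength (nm), or `NA` for none.
#' @param adaptation_flux Adaptation-light photon flux (photons cm^-2 s^-1).
#' @param white_irradiance_w_cm2 Total white-light irradiance (W cm^-2),
#'   spread uniformly (per nm of energy) over 350–650 nm. The default is the
#'   maximum white output of the stimulator, 3.11e-3 W cm^-2, attenuated by a
#'   1.0 neutral-density filter.
#' @param sweeps List of wavelength sweeps (nm vectors) within \[340, 650\].
#' @param ladder_span_log10,ladder_step_log10 Half-width and step of the
#'   flux ladder, in log10 units around the matching flux.
#' @return A list of class `eyespec_erg_protocol`.
#' @export
erg_protocol <- function(frequency_hz = 10, adaptation_nm = NA_real_,
                         adaptation_flux = 3e16,
                         white_irradiance_w_cm2 = 3.11e-3 * 10^-1,
                         sweeps = list(seq(650, 350, by = -20),
                                       seq(340, 640, by = 20)),
                         ladder_span_log10 = 0.6, ladder_step_log10 = 0.15) {
  check_number(frequency_hz, "frequency_hz", 3, 30)
  if (!is.na(adaptation_nm)) check_number(adaptation_nm, "adaptation_nm", 300, 850)
  if (white_irradiance_w_cm2 <= 0) {
    abort("White irradiance must be positive.", class = "eyespec_invalid_protocol")
  }
  rng <- range(unlist(sweeps))
  if (rng[1] < 340 || rng[2] > 650) {
    abort("Sweep wavelengths must lie within [340, 650] nm.",
          class = "eyespec_invalid_protocol")
  }
  structure(
    list(frequency_hz = frequency_hz, adaptation_nm = adaptation_nm,
         adaptation_flux = adaptation_flux,
         white_irradiance_w_cm2 = white_irradiance_w_cm2, sweeps = sweeps,
         ladder_span_log10 = ladder_span_log10,
         ladder_step_log10 = ladder_step_log10),
    class = "eyespec_erg_protocol"
  )
}

# condition label recorded on trial rows
condition_label <- function(protocol) {
  base <- paste0(protocol$frequency_hz, "Hz")
  if (!is.na(protocol$adaptation_nm)) {
    base <- paste0(base, "+ad", protocol$adaptation_nm)
  }
  base
}

# White-light effective catch for an animal-specific sensitivity spectrum
# evaluated on a 1 nm grid over 350-650.
white_catch <- function(sens_fine, white_irradiance_w_cm2) {
  gl <- sens_fine$wavelength_nm
  e_per_nm <- white_irradiance_w_cm2 / (max(gl) - min(gl))
  q_per_nm <- photon_flux(e_per_nm, gl)
  trapz(gl, sens_fine$value * q_per_nm)
}

#' Simulate ERG flicker-photometry trial sets
#'
#' Generates per-animal, per-wavelength trial records from a forward eye
#' model. Inter-animal variability multiplies each class weight by a
#' log-normal factor (sd `animal_sd`). For each wavelength, a ladder of
#' photon fluxes is presented and the response follows the model's
#' Naka–Rushton nonlinearity on the effective catch
#' `S_animal(lambda) * Q`, with multiplicative log-normal amplitude noise.
#' White-reference responses are simulated per trial row from the animal's
#' integrated white catch. With an adaptation light set in the protocol, each
#' class's catch is divided by `1 + adaptation catch / K` (Weber-style
#' contrast reduction), in both the coloured and white responses.
#'
#' @param model An [eye_model()].
#' @param protocol An [erg_protocol()].
#' @param n_animals Number of animals (>= 1).
#' @param seed Integer seed; identical seeds give identical trial sets. RNG
#'   state is restored afterwards.
#' @param animal_sd Log-sd of per-animal class-weight jitter (0 disables).
#' @return A tibble of class `eyespec_erg_trials` with columns `animal_id`,
#'   `condition`, `frequency_hz`, `adaptation_nm`, `sweep`, `wavelength_nm`,
#'   `irradiance_w_cm2`, `photon_flux`, `response_amplitude`,
#'   `white_response_amplitude`.
#' @examples
#' trials <- simulate_erg_trials(default_eye_model(0), erg_protocol(),
#'                               n_animals = 1, seed = 1)
#' @export
simulate_erg_trials <- function(model, protocol = erg_protocol(),
                                n_animals = 7, seed = 1, animal_sd = 0.15) {
  stopifnot(inherits(model, "eyespec_eye_model"),
            inherits(protocol, "eyespec_erg_protocol"))
  if (n_animals < 1) {
    abort("`n_animals` must be >= 1.", class = "eyespec_invalid_protocol")
  }
  withr::with_seed(seed, {
    fine_grid <- seq(350, 650, by = 1)
    ladder <- seq(-protocol$ladder_span_log10, protocol$ladder_span_log10,
                  by = protocol$ladder_step_log10)
    cond <- condition_label(protocol)
    out <- vector("list", n_animals)
    for (a in seq_len(n_animals)) {
      animal <- model
      if (animal_sd > 0) {
        jit <- exp(rnorm(length(model$classes), 0, animal_sd))
        for (i in seq_along(animal$classes)) {
          animal$classes[[i]]$weight <- animal$classes[[i]]$weight * jit[i]
        }
      }
      sens_fine <- eye_sensitivity_spectrum(
        animal, protocol$frequency_hz, fine_grid,
        adaptation_nm = protocol$adaptation_nm,
        adaptation_flux = protocol$adaptation_flux
      )
      cw <- white_catch(sens_fine, protocol$white_irradiance_w_cm2)
      rows <- vector("list", length(protocol$sweeps))
      for (s in seq_along(protocol$sweeps)) {
        wl <- protocol$sweeps[[s]]
        sens_wl <- approx(sens_fine$wavelength_nm, sens_fine$value,
                          xout = pmin(pmax(wl, 350), 650), ties = "ordered")$y
        q_match <- cw / sens_wl
        for (k in seq_along(wl)) {
          q <- 10^(log10(q_match[k]) + ladder)
          amp <- naka_rushton(sens_wl[k] * q, model)
          wht <- naka_rushton(cw, model)
          if (model$noise_sd > 0) {
            amp <- amp * exp(rnorm(length(amp), 0, model$noise_sd))
            wht <- wht * exp(rnorm(length(amp), 0, model$noise_sd))
          } else {
            wht <- rep(wht, length(amp))
          }
          rows[[s]] <- dplyr::bind_rows(rows[[s]], tibble(
            animal_id = sprintf("animal%02d", a),
            condition = cond,
            frequency_hz = protocol$frequency_hz,
            adaptation_nm = protocol$adaptation_nm,
            sweep = s,
            wavelength_nm = wl[k],
            irradiance_w_cm2 = irradiance_from_flux(q, wl[k]),
            photon_flux = q,
            response_amplitude = amp,
            white_response_amplitude = wht
          ))
        }
      }
      out[[a]] <- dplyr::bind_rows(rows)
    }
    trials <- dplyr::bind_rows(out)
    class(trials) <- c("eyespec_erg_trials", class(trials))
    trials
  })
}

#' Read / write ERG trial sets as CSV
#'
#' Interchange schema: `animal_id, condition, frequency_hz, adaptation_nm`
#' (empty for none), `sweep, wavelength_nm, irradiance_w_cm2, photon_flux,
#' response_amplitude, white_response_amplitude`.
#'
#' @param path File path.
#' @return A tibble of trials (`read_erg_csv`) or `path` invisibly.
#' @export
read_erg_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  class(df) <- c("eyespec_erg_trials", class(df))
  df
}

#' @rdname read_erg_csv
#' @param trials A trial tibble from [simulate_erg_trials()].
#' @export
write_erg_csv <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}
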