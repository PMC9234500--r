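# eyespec

Tools for characterising the spectral sensitivity of the whole eye and the
topography of its photoreceptors, as measured in diurnal lizards by
electroretinogram (ERG) flicker photometry and design-based stereology. The
package is written for visual ecologists and neurophysiologists who need a
tested, reproducible version of this analysis chain:

* **Ocular optics** — plateau-normalised transmittance spectra, the
  half-peak transmittance wavelength λ<sub>T0.5</sub>, multiplicative
  combination of cornea and lens, oil-droplet absorptance means, and
  integral normalisation of reflectance spectra.
* **ERG pipeline** — sensitivity as the reciprocal photon flux producing a
  response equivalent to a white reference, S(λ) = 1/Q<sub>eq</sub>(λ);
  splicing of interleaved 20 nm sweeps onto a 10 nm grid; gain-only
  normalisation of curves to their group mean; peak and FWHM descriptors
  with parabolic peak refinement; the SW:LW statistic
  ∫S(λ)dλ (λ<530 nm) / ∫S(λ)dλ (λ>530 nm); and a mixed-effects comparison
  across temporal frequencies, `1/ratio ~ frequency + (1 | animal)`.
* **Retinal topography** — parsing of a documented stereology-session XML
  dialect, the optical-fractionator estimator N = ΣQ/asf, exact-interpolation
  thin-plate-spline density maps (second-order trend, λ = 0) on a 20 µm
  grid, iso-density contours, and photoreceptor accounting tables.
* **Forward simulator** — a parameterised eye model (visual-pigment
  nomograms, oil-droplet filters, media transmittance, temporal weighting,
  Naka–Rushton response) that generates ERG trial sets and simulated
  wholemount point patterns with known ground truth, so every estimator is
  validated closed-loop.

All user-facing functions take and return tibbles and compose with the pipe;
fitted objects have `tidy()`/`glance()` methods and result types have
`autoplot()` methods.

## Worked example

```r
library(eyespec)
library(dplyr)

# ocular media: combined cornea + lens half-maximum
lens   <- make_media_curve(359, 10)
cornea <- make_media_curve(307, 12)
half_max_wavelength(combine_media(cornea, lens))
#>   lambda_t50_nm crossing_found direction
#> 1          359. TRUE           rising

# simulate an ERG flicker-photometry session and estimate sensitivity
model  <- default_eye_model()
trials <- simulate_erg_trials(model, erg_protocol(frequency_hz = 10),
                              n_animals = 7, seed = 1)
curves <- trials |> estimate_sensitivity() |> normalize_to_group()
curves |>
  group_by(animal_id) |>
  group_modify(~ curve_descriptors(.x)) |>
  ungroup() |>
  summarise(mean_peak_nm = mean(peak_nm), sd_peak_nm = sd(peak_nm),
            mean_fwhm_nm = mean(fwhm_nm))
#>   mean_peak_nm sd_peak_nm mean_fwhm_nm
#> 1         561.       11.7         131.
```

Seven simulated animals give a mean interpolated peak of 561 nm (spread
comparable to the ±17 nm reported for real animals) and a mean bandwidth of
131 nm — the broad curve that distinguishes this species from other diurnal
lizards, produced here by blue-sensitive classes without short-pass oil
droplets.

```r
# SW:LW sensitivity ratios across flicker frequencies, mixed model
ratios <- purrr::map_dfr(c(3, 10, 30), function(f) {
  simulate_erg_trials(model, erg_protocol(frequency_hz = f),
                      n_animals = 7, seed = 1) |>
    estimate_sensitivity() |>
    normalize_to_group() |>
    group_by(animal_id, frequency_hz) |>
    group_modify(~ sw_lw_ratio(.x)) |>
    ungroup()
})
tidy(compare_ratios_across_frequencies(ratios))
#>   term         estimate std.error statistic    df      p.value p.value.wald
#> 1 frequency_hz   0.0516   0.00542      9.53  19.0 0.0000000114     1.59e-21
```

The reciprocal-transformed ratio rises with frequency (p < 0.001, d.f. 19):
short-wavelength classes contribute more at slow flicker, exactly the trend
the temporal weights encode.

```r
# stereology: simulate a wholemount, count it, map it
retina  <- simulate_retina(76000, 25000, outline = retina_outline(2.0, 1.7),
                           sigma_mm = 0.8, seed = 1)
session <- build_fractionator_session(retina, seed = 1)
fractionator_total(session)
#> [1] 468300
map <- interpolate_map(tps_fit(site_densities(session)), retina$outline)
attr(map, "peak_density_mm2")
#> [1] 80042.01
autoplot(map, levels = c(30000, 50000, 70000))
```

The fractionator recovers the simulated population and the spline map's
peak lands within a few percent of the generating 76,000 cells mm⁻²
area-centralis density.

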