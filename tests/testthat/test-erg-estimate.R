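test_that("photon flux conversion matches E*lambda/(h*c)", {
  expect_equal(photon_flux(0, 500), 0)
  expect_equal(photon_flux(1, 500), 2.517e18, tolerance = 1e-3)
  # independent constant-based evaluation at the stimulator's maximum output
  hc <- 6.62607015e-34 * 2.99792458e8
  expect_equal(photon_flux(3.11e-3, 560), 3.11e-3 * 560e-9 / hc, tolerance = 1e-12)
  expect_error(photon_flux(-1, 500), class = "eyespec_invalid_input")
  expect_equal(irradiance_from_flux(photon_flux(0.02, 480), 480), 0.02)
})

test_that("equivalence sensitivity inverts the response at the white match", {
  # amplitudes exactly linear in flux; white matched at Q = 2e14
  expect_equal(equivalence_sensitivity(c(1e14, 2e14, 4e14), c(1, 2, 4), 2), 5e-15,
               tolerance = 1e-9)
  # saturating noise-free trials: matches analytic Naka-Rushton inversion
  m <- single_class_model(564)
  s_lambda <- 0.31
  q_eq_true <- m$response_half_saturation * 0.7 / s_lambda
  white_amp <- eyespec:::naka_rushton(0.7 * m$response_half_saturation, m)
  q <- 10^(log10(q_eq_true) + seq(-0.6, 0.6, 0.15))
  amp <- eyespec:::naka_rushton(s_lambda * q, m)
  got <- equivalence_sensitivity(q, amp, white_amp)
  expect_equal(1 / got, q_eq_true, tolerance = 1e-3)
  # all amplitudes below the reference -> unresolved
  expect_true(is.na(equivalence_sensitivity(c(1e13, 2e13), c(0.1, 0.2), 5)))
  expect_error(equivalence_sensitivity(c(-1, 1), c(1, 2), 1),
               class = "eyespec_invalid_input")
})

test_that("splicing interleaves the two 20 nm sweeps onto the 10 nm grid", {
  f <- function(wl) exp(-(wl - 520)^2 / 5000)
  odd <- tibble::tibble(wavelength_nm = seq(650, 350, -20),
                        sensitivity = f(seq(650, 350, -20)))
  even <- tibble::tibble(wavelength_nm = seq(340, 640, 20),
                         sensitivity = f(seq(340, 640, 20)))
  sp <- splice_sweeps(odd, even)
  expect_equal(sp$wavelength_nm, seq(350, 650, 10))
  expect_equal(nrow(sp), 31)
  expect_equal(sp$value, f(sp$wavelength_nm))
  expect_false(attr(sp, "splice_discontinuity"))
  # constant offset between sweeps is preserved verbatim and flagged
  even_off <- even
  even_off$sensitivity <- even_off$sensitivity * 2
  sp2 <- splice_sweeps(odd, even_off)
  expect_equal(sp2$value[sp2$wavelength_nm %% 20 == 0],
               2 * f(sp2$wavelength_nm[sp2$wavelength_nm %% 20 == 0]))
  expect_true(attr(sp2, "splice_discontinuity"))
  expect_error(splice_sweeps(odd, tibble::tibble(wavelength_nm = seq(355, 655, 20),
                                                 sensitivity = 1)),
               class = "eyespec_invalid_input")
})

test_that("group normalisation scales curves to the mean by gain-only least squares", {
  grid <- seq(350, 650, 10)
  base <- exp(-(grid - 550)^2 / 6000)
  curves <- dplyr::bind_rows(
    tibble::tibble(animal_id = "a", wavelength_nm = grid, sensitivity = base),
    tibble::tibble(animal_id = "b", wavelength_nm = grid, sensitivity = 3 * base)
  )
  norm <- normalize_to_group(curves)
  gains <- norm |> dplyr::distinct(.data$animal_id, .data$normalization_gain)
  expect_equal(sort(gains$normalization_gain), c(2 / 3, 2), tolerance = 1e-12)
  # both scaled curves equal the group mean
  expect_equal(norm$sensitivity[norm$animal_id == "a"], 2 * base, tolerance = 1e-12)
  expect_equal(norm$sensitivity[norm$animal_id == "b"], 2 * base, tolerance = 1e-12)
  # single curve and identical curves: gains 1
  one <- normalize_to_group(curves[curves$animal_id == "a", ])
  expect_equal(unique(one$normalization_gain), 1)
  # scaling invariance of peak and SW:LW ratio
  d0 <- curve_descriptors(curves[curves$animal_id == "b", ])
  d1 <- curve_descriptors(norm[norm$animal_id == "b", ])
  expect_equal(d1$peak_nm, d0$peak_nm)
  expect_equal(d1$fwhm_nm, d0$fwhm_nm)
  expect_equal(sw_lw_ratio(norm[norm$animal_id == "b", ])$ratio,
               sw_lw_ratio(curves[curves$animal_id == "b", ])$ratio,
               tolerance = 1e-12)
})

test_that("curve descriptors recover constructed peaks and bandwidths", {
  # half-max crossings built at 475 and 610 nm
  cur <- make_peak_curve(475, 610)
  d <- curve_descriptors(cur)
  expect_equal(d$peak_nm, 560)
  expect_equal(d$half_max_lo_nm, 475, tolerance = 1e-9)
  expect_equal(d$half_max_hi_nm, 610, tolerance = 1e-9)
  expect_equal(d$fwhm_nm, 135, tolerance = 1e-9)
  # Gaussian: FWHM = 2 sqrt(2 ln 2) sigma
  wl <- seq(400, 700, 1)
  g <- spectral_curve(wl, exp(-(wl - 550)^2 / (2 * 20^2)))
  expect_equal(curve_descriptors(g)$fwhm_nm, 2 * sqrt(2 * log(2)) * 20,
               tolerance = 0.01)
  # symmetric triangle: equidistant crossings
  grid <- seq(350, 650, 10)
  tri <- spectral_curve(grid, pmax(1 - abs(grid - 560) / 150, 0.01))
  dt <- curve_descriptors(tri)
  expect_equal(dt$peak_nm, 560)
  expect_equal(dt$half_max_hi_nm - 560, 560 - dt$half_max_lo_nm, tolerance = 1e-9)
  # monotone curve has no descriptors
  expect_error(curve_descriptors(spectral_curve(grid, seq_along(grid))),
               class = "eyespec_descriptor_undefined")
  # FWHM invariant under positive rescaling
  d2 <- curve_descriptors(spectral_curve(cur$wavelength_nm, 17 * cur$value))
  expect_equal(d2$fwhm_nm, d$fwhm_nm)
})

test_that("SW:LW ratio matches a fine-grid oracle and is monotone in SW mass", {
  grid <- seq(350, 650, 10)
  expect_equal(sw_lw_ratio(spectral_curve(grid, rep(1, 31)))$ratio, 1.5)
  # all mass above the split
  hi_only <- spectral_curve(grid, ifelse(grid > 540, 1, 0))
  expect_equal(sw_lw_ratio(hi_only)$ratio, 0, tolerance = 1e-12)
  # random positive curve vs brute-force Riemann sum at 0.01 nm
  v <- withr::with_seed(8, runif(31, 0.2, 1))
  cur <- spectral_curve(grid, v)
  fine <- seq(350, 650, 0.01)
  fv <- approx(grid, v, xout = fine)$y
  sw <- sum(fv[fine < 530]) * 0.01
  lw <- sum(fv[fine > 530]) * 0.01
  got <- sw_lw_ratio(cur)
  expect_equal(got$ratio, sw / lw, tolerance = 1e-4)
  expect_equal(got$transformed * got$ratio, 1)
  # adding mass strictly below the split increases the ratio
  bumped <- spectral_curve(grid, v + ifelse(grid < 530, 0.3, 0))
  expect_gt(sw_lw_ratio(bumped)$ratio, got$ratio)
  expect_error(sw_lw_ratio(spectral_curve(seq(540, 650, 10), rep(1, 12)), 530),
               class = "eyespec_invalid_input")
})
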