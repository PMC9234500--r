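test_that("plateau normalisation fixes the window mean to 1", {
  grid <- seq(300, 850, 5)
  const <- spectral_curve(grid, rep(0.8, length(grid)))
  norm <- normalize_transmittance(const)
  expect_equal(unique(norm$value), 1)
  # idempotence
  again <- normalize_transmittance(norm)
  expect_equal(again$value, norm$value)
  # window outside support
  short <- spectral_curve(seq(300, 600, 5), rep(1, 61))
  expect_error(normalize_transmittance(short), class = "eyespec_invalid_window")
})

test_that("half-max detection is scale invariant and handles no crossing", {
  cur <- make_media_curve(391, 9)
  base <- half_max_wavelength(normalize_transmittance(cur))
  for (k in c(0.37, 2, 131)) {
    scaled <- spectral_curve(cur$wavelength_nm, k * cur$value)
    hm <- half_max_wavelength(normalize_transmittance(scaled))
    expect_equal(hm$lambda_t50_nm, base$lambda_t50_nm, tolerance = 1e-9)
  }
  flat <- spectral_curve(seq(300, 850, 5), rep(1, 111))
  expect_false(half_max_wavelength(normalize_transmittance(flat))$crossing_found)
})

test_that("noisy sigmoids recover the half-max wavelength within 2 nm", {
  grid <- seq(300, 850, 1)
  true <- 1 / (1 + exp(-(grid - 391) / 9))
  errs <- withr::with_seed(11, vapply(1:100, function(i) {
    noisy <- spectral_curve(grid, pmax(true + rnorm(length(grid), 0, 0.01), 1e-6))
    half_max_wavelength(normalize_transmittance(noisy))$lambda_t50_nm - 391
  }, numeric(1)))
  expect_lt(mean(abs(errs)), 2)
  expect_lt(abs(mean(errs)), 2)
})

test_that("combine_media is an identity with a unit curve, commutative and associative", {
  a <- make_media_curve(359, 10)
  b <- make_media_curve(307, 12)
  unit <- spectral_curve(a$wavelength_nm, rep(1, nrow(a)))
  expect_equal(combine_media(a, unit)$value,
               normalize_transmittance(a)$value, tolerance = 1e-12)
  ab <- combine_media(a, b)
  ba <- combine_media(b, a)
  expect_equal(ab$value, ba$value, tolerance = 1e-12)
  cc <- make_media_curve(330, 6)
  lhs <- combine_media(combine_media(a, b), cc)
  rhs <- combine_media(a, combine_media(b, cc))
  expect_equal(lhs$value, rhs$value, tolerance = 1e-12)
  # disjoint supports
  lo <- spectral_curve(seq(300, 400, 10), rep(1, 11))
  hi <- spectral_curve(seq(500, 600, 10), rep(1, 11))
  expect_error(combine_media(lo, hi), class = "eyespec_invalid_input")
})

test_that("mean absorptance averages traces pointwise", {
  grid <- seq(330, 800, 5)
  one <- spectral_curve(grid, withr::with_seed(4, runif(length(grid))))
  expect_equal(mean_absorptance(list(one))$value, one$value)
  mirrored <- spectral_curve(grid, 1 - one$value)
  expect_equal(mean_absorptance(list(one, mirrored))$value,
               rep(0.5, length(grid)))
  expect_error(mean_absorptance(list()), class = "eyespec_invalid_input")
  # simulated C2 traces: mean within 1 s.e. of the generating profile
  prof <- oil_droplet("C2", grid = grid)$absorptance
  sdv <- 0.02
  traces <- withr::with_seed(5, lapply(1:5, function(i) {
    spectral_curve(grid, prof$value + rnorm(length(grid), 0, sdv))
  }))
  m <- mean_absorptance(traces)
  se <- sdv / sqrt(5)
  expect_gt(mean(abs(m$value - prof$value) <= 2 * se), 0.9)
})

test_that("integral normalisation yields unit mass and preserves shape", {
  grid <- seq(350, 650, 10)
  const <- spectral_curve(grid, rep(2, length(grid)))
  n1 <- normalize_by_integral(const)
  expect_equal(unique(n1$value), 1 / 300)
  expect_equal(normalize_by_integral(n1)$value, n1$value) # idempotent
  # bimodal tongue-like reflectance: integral 1, peak ratio preserved
  wl <- seq(300, 700, 1)
  tongue <- spectral_curve(wl, 0.9 * exp(-(wl - 320)^2 / 800) +
                                 0.5 * exp(-(wl - 460)^2 / 1800) + 0.02)
  nt <- normalize_by_integral(tongue)
  expect_equal(sum(diff(wl) * (head(nt$value, -1) + tail(nt$value, -1)) / 2), 1,
               tolerance = 1e-9)
  r_raw <- tongue$value[wl == 320] / tongue$value[wl == 460]
  r_norm <- nt$value[wl == 320] / nt$value[wl == 460]
  expect_equal(r_norm, r_raw, tolerance = 1e-12)
  expect_error(normalize_by_integral(spectral_curve(grid, rep(0, length(grid)))),
               class = "eyespec_invalid_input")
})
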