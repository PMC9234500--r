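test_that("the fractionator estimate is sum(Q)/asf", {
  outl <- retina_outline(1, 1, 16)
  one <- fractionator_session(
    outl, tibble::tibble(x_mm = 0, y_mm = 0, marker_count = 50),
    grid_cell_area_um2 = 250000, frame_area_um2 = 2500
  )
  expect_equal(fractionator_total(one), 5000)
  # asf = 1: exhaustive count is returned unchanged
  exhaustive <- fractionator_session(
    outl, tibble::tibble(x_mm = c(0, 0.1), y_mm = 0, marker_count = c(7, 3)),
    grid_cell_area_um2 = 2500, frame_area_um2 = 2500
  )
  expect_equal(fractionator_total(exhaustive), 10)
  expect_error(fractionator_session(outl,
                                    tibble::tibble(x_mm = 0, y_mm = 0, marker_count = 1.5),
                                    250000, 2500),
               class = "eyespec_invalid_session")
})

test_that("site densities convert counts with the exact um2 to mm2 factor", {
  s <- fractionator_session(
    retina_outline(1, 1, 16),
    tibble::tibble(x_mm = c(0, 0.2), y_mm = 0, marker_count = c(25, 0)),
    grid_cell_area_um2 = 250000, frame_area_um2 = 2500
  )
  d <- site_densities(s)
  expect_equal(d$density, c(10000, 0))
  # doubling the frame area at fixed count halves the density
  s2 <- s; s2$frame_area_um2 <- 5000
  expect_equal(site_densities(s2)$density, c(5000, 0))
})

test_that("the zero-smoothing spline interpolates exactly and absorbs quadratics", {
  pts <- tidyr::expand_grid(x_mm = seq(-2, 2, 1), y_mm = seq(-2, 2, 1))
  f <- function(x, y) 40 + 3 * x - 2 * y + 1.5 * x^2 - x * y + 0.5 * y^2
  pts$density <- f(pts$x_mm, pts$y_mm)
  fit <- tps_fit(pts)
  # exact at the nodes
  expect_equal(predict(fit, pts), pts$density, tolerance = 1e-8)
  # exact reproduction of the quadratic anywhere
  qry <- withr::with_seed(13, tibble::tibble(x_mm = runif(50, -1.9, 1.9),
                                             y_mm = runif(50, -1.9, 1.9)))
  expect_equal(predict(fit, qry), f(qry$x_mm, qry$y_mm), tolerance = 1e-6)
  # collinear points cannot support the quadratic trend
  line <- tibble::tibble(x_mm = 1:7, y_mm = 2 * (1:7), density = 1:7)
  expect_error(tps_fit(line), class = "eyespec_degenerate_configuration")
  expect_error(tps_fit(pts[1:4, ]), class = "eyespec_degenerate_configuration")
})

test_that("spline predictions match an independently coded dense solve", {
  pts <- withr::with_seed(17, tibble::tibble(
    x_mm = runif(50, -2, 2), y_mm = runif(50, -2, 2),
    density = runif(50, 0, 100)
  ))
  fit <- tps_fit(pts)
  qry <- withr::with_seed(18, tibble::tibble(x_mm = runif(40, -1.5, 1.5),
                                             y_mm = runif(40, -1.5, 1.5)))
  oracle <- tps_oracle(pts$x_mm, pts$y_mm, pts$density, qry$x_mm, qry$y_mm)
  got <- predict(fit, qry)
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("density maps honour masking, clipping and node fidelity", {
  # constant data -> constant map
  pts <- tidyr::expand_grid(x_mm = seq(-1, 1, 0.5), y_mm = seq(-1, 1, 0.5))
  pts$density <- 500
  outl <- retina_outline(1.6, 1.6, 48)
  map <- interpolate_map(tps_fit(pts), outl, spacing_um = 100)
  expect_equal(range(map$density[map$inside]), c(500, 500), tolerance = 1e-6)
  expect_true(all(is.na(map$density[!map$inside])))
  # nodes coinciding with data sites reproduce the site densities
  pts2 <- pts
  pts2$density <- withr::with_seed(3, runif(nrow(pts2), 100, 1000))
  map2 <- interpolate_map(tps_fit(pts2), outl, spacing_um = 100)
  key <- function(d) dplyr::mutate(d, x_mm = round(x_mm, 9), y_mm = round(y_mm, 9))
  hit <- dplyr::inner_join(key(pts2), key(as_tibble(map2)), by = c("x_mm", "y_mm"))
  expect_equal(nrow(hit), nrow(pts2))
  expect_equal(hit$density.y, hit$density.x, tolerance = 1e-6)
  expect_error(interpolate_map(tps_fit(pts), outl, spacing_um = 0),
               class = "eyespec_invalid_parameter")
})

test_that("contours are closed, nested and consistent with Gaussian level sets", {
  # radially symmetric Gaussian field sampled on a grid
  pts <- tidyr::expand_grid(x_mm = seq(-2, 2, 0.25), y_mm = seq(-2, 2, 0.25))
  sig <- 0.8
  pts$density <- 1000 * exp(-(pts$x_mm^2 + pts$y_mm^2) / (2 * sig^2))
  outl <- retina_outline(2.2, 2.2, 64)
  map <- interpolate_map(tps_fit(pts), outl, spacing_um = 50)
  ct <- contour_levels(map, c(250, 500, 750))
  expect_true(all(ct$closed))
  # nested, non-crossing: every vertex radius of a higher level lies inside
  # the innermost radius of the lower level
  radii <- ct |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(rmin = min(sqrt(x_mm^2 + y_mm^2)),
                     rmax = max(sqrt(x_mm^2 + y_mm^2)))
  radii <- radii[order(radii$level), ]
  expect_true(all(diff(radii$rmax) < 0))
  expect_true(all(radii$rmin[-1] < radii$rmax[-nrow(radii)]))
  # the 50%-of-peak contour encloses the analytic disc area
  half_ct <- contour_levels(map, 500)
  area <- abs(sum(half_ct$x_mm * c(half_ct$y_mm[-1], half_ct$y_mm[1]) -
                    c(half_ct$x_mm[-1], half_ct$x_mm[1]) * half_ct$y_mm) / 2)
  analytic <- pi * (sig^2 * 2 * log(2)) # r^2 at half maximum
  expect_equal(area, analytic, tolerance = 0.05)
  # level above the maximum yields no polylines
  expect_equal(nrow(contour_levels(map, 2000)), 0)
})

test_that("map mass matches the fractionator total for a smooth field", {
  r <- small_retina(peak = 20000, background = 8000, seed = 12)
  s <- build_fractionator_session(r, grid_cell_area_um2 = 90000,
                                  frame_area_um2 = 2500, seed = 12)
  fit <- tps_fit(site_densities(s))
  map <- interpolate_map(fit, r$outline, spacing_um = 40)
  expect_equal(map_total(map) / fractionator_total(s), 1, tolerance = 0.1)
})

test_that("accounting reproduces the percentage relationships", {
  sess <- accounting_sessions()
  out <- accounting(sess)
  expect_s3_class(out, "eyespec_count_summary")
  pct <- function(cls, col) out[[col]][out$cell_class == cls]
  expect_equal(pct("single", "pct_of_total") + pct("double", "pct_of_total"), 100,
               tolerance = 0.1)
  expect_equal(round(pct("rh1", "pct_of_single"), 1), 22.8)
  expect_equal(round(pct("rh1", "pct_of_total"), 1), 17.7)
  expect_equal(round(pct("sws1", "pct_of_single"), 1), 8.5)
  expect_equal(round(pct("sws1", "pct_of_total"), 1), 6.6)
  # consistency product equals the direct percentage of total
  expect_equal(out$consistency_pct_of_total[out$cell_class == "rh1"],
               pct("rh1", "pct_of_total"), tolerance = 1e-9)
  # a child class exceeding its parent triggers a warning
  sess$rh1$sites$marker_count <- sess$rh1$sites$marker_count * 10
  expect_warning(accounting(sess), class = "eyespec_consistency_warning")
  expect_error(accounting(sess["total"]), class = "eyespec_invalid_input")
})
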