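# Optical-fractionator estimation, thin-plate-spline density mapping, and
# photoreceptor accounting.

#' Optical-fractionator total cell estimate
#'
#' The unbiased design-based estimator `N = sum(Q) / asf`, where `sum(Q)` is
#' the total marker count over all sampling frames and
#' `asf = frame_area / grid_cell_area` is the area sampling fraction shared
#' by all sites. With `asf = 1` (exhaustive sampling) the estimate equals the
#' raw count.
#'
#' @param session An `eyespec_fractionator_session`.
#' @return Estimated total cell number (a single number).
#' @examples
#' s <- fractionator_session(retina_outline(),
#'   tibble::tibble(x_mm = 0, y_mm = 0, marker_count = 50), 250000, 2500)
#' fractionator_total(s) # 50 / 0.01 = 5000
#' @export
fractionator_total <- function(session) {
  stopifnot(inherits(session, "eyespec_fractionator_session"))
  asf <- session$frame_area_um2 / session$grid_cell_area_um2
  if (asf <= 0 || asf > 1) {
    abort("asf must lie in (0, 1].", class = "eyespec_invalid_session")
  }
  sum(session$sites$marker_count) / asf
}

#' Per-site cell densities
#'
#' Converts frame marker counts to local densities,
#' `density = count / frame_area`, with the exact um^2 to mm^2 conversion
#' (x 1e6). These scattered densities feed the thin-plate-spline map.
#'
#' @param session An `eyespec_fractionator_session`.
#' @return A tibble with `x_mm`, `y_mm`, `density` (cells mm^-2).
#' @export
site_densities <- function(session) {
  stopifnot(inherits(session, "eyespec_fractionator_session"))
  tibble(
    x_mm = session$sites$x_mm,
    y_mm = session$sites$y_mm,
    density = session$sites$marker_count / session$frame_area_um2 * 1e6
  )
}

#' Fit a thin-plate spline to scattered densities
#'
#' Thin-plate spline interpolant with a full second-order polynomial trend
#' (6 coefficients) and radial basis `U(r) = r^2 log r`. With `smoothing = 0`
#' (the default) the spline passes exactly through every input point; any
#' field that is itself a quadratic polynomial is reproduced exactly
#' everywhere, because the trend absorbs it. Coordinates are centred and
#' scaled internally for conditioning.
#'
#' @param points Tibble with columns `x_mm`, `y_mm`, `density` (>= 6
#'   non-collinear points for the quadratic trend).
#' @param smoothing Ridge parameter lambda added to the kernel diagonal
#'   (0 = exact interpolation).
#' @param trend_order 1 (affine) or 2 (full quadratic, default).
#' @return An object of class `eyespec_tps` with a `predict()` method.
#' @examples
#' pts <- tidyr::expand_grid(x_mm = -2:2, y_mm = -2:2)
#' pts$density <- 10 + pts$x_mm^2 - pts$y_mm
#' fit <- tps_fit(pts)
#' predict(fit, tibble::tibble(x_mm = 0.5, y_mm = -0.25))
#' @export
tps_fit <- function(points, smoothing = 0, trend_order = 2) {
  stopifnot(is.data.frame(points),
            all(c("x_mm", "y_mm", "density") %in% names(points)))
  x <- points$x_mm; y <- points$y_mm; v <- points$density
  n <- length(x)
  p <- if (trend_order >= 2) 6L else 3L
  if (n < p) {
    abort(sprintf("Need at least %d points for a trend of order %d.", p, trend_order),
          class = "eyespec_degenerate_configuration")
  }
  ctr <- c(mean(x), mean(y))
  scl <- max(stats::sd(x), stats::sd(y), 1e-12)
  xs <- (x - ctr[1]) / scl
  ys <- (y - ctr[2]) / scl
  P <- tps_trend_matrix(xs, ys, trend_order)
  if (qr(P)$rank < p) {
    abort("Degenerate point configuration: trend system is rank deficient.",
          class = "eyespec_degenerate_configuration")
  }
  K <- tps_kernel_matrix(xs, ys, xs, ys)
  A <- rbind(cbind(K + diag(smoothing, n), P),
             cbind(t(P), matrix(0, p, p)))
  rhs <- c(v, rep(0, p))
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    abort("Degenerate point configuration: interpolation system is singular.",
          class = "eyespec_degenerate_configuration")
  })
  structure(
    list(centers = cbind(xs, ys), coef_rbf = sol[seq_len(n)],
         coef_trend = sol[n + seq_len(p)], trend_order = trend_order,
         centre = ctr, scale = scl, smoothing = smoothing),
    class = "eyespec_tps"
  )
}

tps_trend_matrix <- function(xs, ys, trend_order) {
  if (trend_order >= 2) {
    cbind(1, xs, ys, xs^2, xs * ys, ys^2)
  } else {
    cbind(1, xs, ys)
  }
}

tps_kernel_matrix <- function(qx, qy, cx, cy) {
  r2 <- outer(qx, cx, "-")^2 + outer(qy, cy, "-")^2
  k <- 0.5 * r2 * log(pmax(r2, 1e-300))
  k[r2 == 0] <- 0
  k
}

#' @export
predict.eyespec_tps <- function(object, newdata, ...) {
  stopifnot(all(c("x_mm", "y_mm") %in% names(newdata)))
  xs <- (newdata$x_mm - object$centre[1]) / object$scale
  ys <- (newdata$y_mm - object$centre[2]) / object$scale
  out <- numeric(length(xs))
  # evaluate in chunks to bound the distance-matrix memory
  chunk <- max(1L, floor(4e6 / nrow(object$centers)))
  idx <- split(seq_along(xs), ceiling(seq_along(xs) / chunk))
  for (ii in idx) {
    K <- tps_kernel_matrix(xs[ii], ys[ii], object$centers[, 1], object$centers[, 2])
    P <- tps_trend_matrix(xs[ii], ys[ii], object$trend_order)
    out[ii] <- drop(K %*% object$coef_rbf + P %*% object$coef_trend)
  }
  out
}

#' Interpolate a density map over the retinal outline
#'
#' Evaluates a fitted thin-plate spline on a regular grid (20 um spacing by
#' default) covering the outline bounding box. Nodes outside the outline are
#' masked; negative interpolants are clipped to 0 and their number recorded.
#'
#' @param spline An `eyespec_tps` from [tps_fit()].
#' @param outline Closed polygon tibble (`x_mm`, `y_mm`).
#' @param spacing_um Grid spacing in micrometres (> 0).
#' @return A tibble of class `eyespec_density_map` with columns `x_mm`,
#'   `y_mm`, `inside`, `density` (NA outside the outline) and
#'   `density_unmasked` (the raw spline evaluation, used for contouring);
#'   attributes `spacing_um`, `n_clipped`, `peak_density_mm2`,
#'   `peak_xy_mm`, and `coordinate_note`.
#' @export
interpolate_map <- function(spline, outline, spacing_um = 20) {
  stopifnot(inherits(spline, "eyespec_tps"))
  if (spacing_um <= 0) {
    abort("`spacing_um` must be positive.", class = "eyespec_invalid_parameter")
  }
  sp_mm <- spacing_um * 1e-3
  vx <- outline$x_mm; vy <- outline$y_mm
  gx <- seq(min(vx), max(vx) + sp_mm / 2, by = sp_mm)
  gy <- seq(min(vy), max(vy) + sp_mm / 2, by = sp_mm)
  grid <- expand.grid(x_mm = gx, y_mm = gy)
  inside <- point_in_polygon(grid$x_mm, grid$y_mm, vx, vy, boundary = FALSE)
  vals <- predict(spline, grid)
  n_clip <- sum(vals < 0 & inside)
  clipped <- pmax(vals, 0)
  out <- tibble(
    x_mm = grid$x_mm, y_mm = grid$y_mm, inside = inside,
    density = ifelse(inside, clipped, NA_real_),
    density_unmasked = vals
  )
  class(out) <- c("eyespec_density_map", class(out))
  pk <- which.max(out$density)
  attr(out, "spacing_um") <- spacing_um
  attr(out, "n_clipped") <- n_clip
  attr(out, "peak_density_mm2") <- out$density[pk]
  attr(out, "peak_xy_mm") <- c(out$x_mm[pk], out$y_mm[pk])
  attr(out, "coordinate_note") <-
    "mm; x nasal->temporal, y dorsal->ventral, origin at outline centroid"
  out
}

#' Iso-density contour polylines
#'
#' Extracts marching-squares contour polylines from a density map at the
#' requested levels, clipped to the outline mask (vertices outside the
#' outline are removed and polylines split at the gaps). Levels outside the
#' data range yield no polylines.
#'
#' @param map An `eyespec_density_map`.
#' @param levels Numeric vector of density levels (cells mm^-2).
#' @return A tibble with columns `level`, `contour_id`, `x_mm`, `y_mm`,
#'   `closed`.
#' @export
contour_levels <- function(map, levels) {
  stopifnot(inherits(map, "eyespec_density_map"))
  gx <- sort(unique(map$x_mm))
  gy <- sort(unique(map$y_mm))
  z <- matrix(map$density_unmasked[order(map$y_mm, map$x_mm)],
              nrow = length(gx), ncol = length(gy))
  inside <- matrix(map$inside[order(map$y_mm, map$x_mm)],
                   nrow = length(gx), ncol = length(gy))
  zrange <- range(z[inside])
  levels <- levels[levels >= zrange[1] & levels <= zrange[2]]
  if (length(levels) == 0L) {
    return(tibble(level = numeric(), contour_id = integer(),
                  x_mm = numeric(), y_mm = numeric(), closed = logical()))
  }
  cl <- grDevices::contourLines(gx, gy, z, levels = levels)
  # clip each polyline to the mask, splitting at gaps
  cid <- 0L
  out <- list()
  for (li in cl) {
    ok <- interp_inside(li$x, li$y, gx, gy, inside)
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in seq_along(runs$values)) {
      if (!runs$values[r] || runs$lengths[r] < 2L) next
      cid <- cid + 1L
      sel <- starts[r]:ends[r]
      closed <- runs$lengths[r] == length(li$x) &&
        li$x[1] == li$x[length(li$x)] && li$y[1] == li$y[length(li$y)]
      out[[cid]] <- tibble(level = li$level, contour_id = cid,
                           x_mm = li$x[sel], y_mm = li$y[sel], closed = closed)
    }
  }
  if (length(out) == 0L) {
    return(tibble(level = numeric(), contour_id = integer(),
                  x_mm = numeric(), y_mm = numeric(), closed = logical()))
  }
  dplyr::bind_rows(out)
}

# nearest-node mask lookup for contour vertices
interp_inside <- function(px, py, gx, gy, inside) {
  ix <- pmin(pmax(round((px - gx[1]) / (gx[2] - gx[1])) + 1L, 1L), length(gx))
  iy <- pmin(pmax(round((py - gy[1]) / (gy[2] - gy[1])) + 1L, 1L), length(gy))
  inside[cbind(ix, iy)]
}

#' Integrate a density map over the outline
#'
#' Riemann sum of the masked map (density x node area); for smooth fields it
#' approximates the fractionator total.
#'
#' @param map An `eyespec_density_map`.
#' @return Estimated total cell number.
#' @export
map_total <- function(map) {
  stopifnot(inherits(map, "eyespec_density_map"))
  cell_mm2 <- (attr(map, "spacing_um") * 1e-3)^2
  sum(map$density[map$inside]) * cell_mm2
}

#' Photoreceptor accounting across labelled sessions
#'
#' Computes fractionator totals for a set of sessions (one per cell class)
#' and the percentage relationships reported for photoreceptor wholemounts:
#' single and double cones as percentages of all photoreceptors, opsin-
#' labelled classes as percentages of single cones and of the total, and the
#' consistency product `pct_of_single x single% / 100` which should equal
#' the class's direct percentage of total. A class whose total exceeds its
#' parent total by more than 5% triggers a consistency warning.
#'
#' @param sessions Named list of `eyespec_fractionator_session` objects; must
#'   include `total`, `single` and `double`, plus any opsin-labelled classes
#'   (e.g. `rh1`, `sws1`).
#' @return A tibble of class `eyespec_count_summary` with columns `cell_class`,
#'   `n_estimated`, `pct_of_total`, `pct_of_single`, `consistency_pct_of_total`.
#' @examples
#' # see vignette for a full worked example
#' @export
accounting <- function(sessions) {
  if (!all(c("total", "single", "double") %in% names(sessions))) {
    abort("`sessions` must include 'total', 'single' and 'double' classes.",
          class = "eyespec_invalid_input")
  }
  totals <- vapply(sessions, fractionator_total, numeric(1))
  n_total <- totals[["total"]]
  n_single <- totals[["single"]]
  for (nm in names(totals)) {
    parent <- if (nm %in% c("total")) NA_real_
      else if (nm %in% c("single", "double")) n_total else n_single
    if (!is.na(parent) && totals[[nm]] > 1.05 * parent) {
      warn(sprintf("Class '%s' total exceeds its parent total by more than 5%%.", nm),
           class = "eyespec_consistency_warning")
    }
  }
  opsin <- setdiff(names(totals), c("total", "single", "double"))
  res <- tibble(
    cell_class = names(totals),
    n_estimated = unname(totals),
    pct_of_total = unname(100 * totals / n_total),
    pct_of_single = ifelse(names(totals) %in% opsin,
                           unname(100 * totals / n_single), NA_real_)
  )
  res$consistency_pct_of_total <- ifelse(
    res$cell_class %in% opsin,
    res$pct_of_single * (100 * n_single / n_total) / 100,
    NA_real_
  )
  class(res) <- c("eyespec_count_summary", class(res))
  res
}
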