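# Simulated wholemount retinas: radially decaying density fields and
# inhomogeneous point patterns with known ground truth.

#' Elliptical retinal outline
#'
#' A closed polygon (mm) approximating a flattened wholemount outline,
#' centred at the origin (x = nasal to temporal, y = dorsal to ventral).
#'
#' @param a_mm,b_mm Semi-axes (mm).
#' @param n Number of vertices.
#' @return A tibble with columns `x_mm`, `y_mm` (vertices, not repeated).
#' @export
retina_outline <- function(a_mm = 2.6, b_mm = 2.2, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  tibble(x_mm = a_mm * cos(th), y_mm = b_mm * sin(th))
}

# Density field: isotropic Gaussian bump over a constant background, with an
# optional multiplicative ventral (positive y) linear gradient.
density_field <- function(x, y, centre, peak, background, sigma_mm,
                          ventral_gradient, ymax) {
  r2 <- (x - centre[1])^2 + (y - centre[2])^2
  d <- background + (peak - background) * exp(-r2 / (2 * sigma_mm^2))
  if (ventral_gradient != 0) {
    d <- d * pmax(0, 1 + ventral_gradient * (y - centre[2]) / ymax)
  }
  d
}

#' Simulate a wholemount photoreceptor point pattern
#'
#' Draws an inhomogeneous Poisson point pattern inside a retinal outline,
#' with intensity given by an isotropic Gaussian area-centralis bump over a
#' constant background, peaking at the outline centroid. Points are labelled
#' i.i.d. by the supplied class fractions. An optional multiplicative linear
#' gradient towards ventral (positive y) reproduces the dorsoventral
#' asymmetry of real wholemounts.
#'
#' @param peak_density_mm2 Density at the field centre (cells mm^-2); the
#'   default is the measured central photoreceptor density, 76,000 cells
#'   mm^-2.
#' @param background_density_mm2 Peripheral density (cells mm^-2),
#'   <= peak.
#' @param outline A closed polygon tibble (`x_mm`, `y_mm`).
#' @param class_fractions Named numeric vector of label fractions summing to
#'   1 (default 77.5% single, 22.5% double cones).
#' @param sigma_mm Gaussian radius of the area centralis (mm).
#' @param ventral_gradient Relative ventral density excess (0 disables).
#' @param seed Integer seed; identical seeds give identical patterns.
#' @return A list of class `eyespec_retina` with `points` (tibble `x_mm`,
#'   `y_mm`, `cell_class`), `outline`, the field parameters, and
#'   `true_total` (the analytic intensity integral over the outline).
#' @examples
#' r <- simulate_retina(5000, 2000, seed = 1)
#' nrow(r$points)
#' @export
simulate_retina <- function(peak_density_mm2 = 76000,
                            background_density_mm2 = 25000,
                            outline = retina_outline(),
                            class_fractions = c(single = 0.775, double = 0.225),
                            sigma_mm = 1.1, ventral_gradient = 0, seed = 1) {
  if (background_density_mm2 < 0 || peak_density_mm2 < background_density_mm2) {
    abort("Need peak >= background >= 0.", class = "eyespec_invalid_parameter")
  }
  if (abs(sum(class_fractions) - 1) > 1e-9 || any(class_fractions < 0)) {
    abort("`class_fractions` must be non-negative and sum to 1.",
          class = "eyespec_invalid_parameter")
  }
  vx <- outline$x_mm; vy <- outline$y_mm
  centre <- polygon_centroid(vx, vy)
  ymax <- max(abs(vy - centre[2]))
  dmax <- peak_density_mm2 * (1 + abs(ventral_gradient))
  bbox <- c(min(vx), max(vx), min(vy), max(vy))
  box_area <- (bbox[2] - bbox[1]) * (bbox[4] - bbox[3])
  withr::with_seed(seed, {
    n_prop <- rpois(1, dmax * box_area)
    px <- runif(n_prop, bbox[1], bbox[2])
    py <- runif(n_prop, bbox[3], bbox[4])
    d <- density_field(px, py, centre, peak_density_mm2, background_density_mm2,
                       sigma_mm, ventral_gradient, ymax)
    keep <- runif(n_prop) < d / dmax
    px <- px[keep]; py <- py[keep]
    inside_pt <- point_in_polygon(px, py, vx, vy, boundary = FALSE)
    px <- px[inside_pt]; py <- py[inside_pt]
    labels <- sample(names(class_fractions), length(px), replace = TRUE,
                     prob = class_fractions)
    # analytic intensity integral over the outline (fine-grid quadrature)
    gx <- seq(bbox[1], bbox[2], length.out = 201)
    gy <- seq(bbox[3], bbox[4], length.out = 201)
    gg <- expand.grid(x = gx, y = gy)
    inside <- point_in_polygon(gg$x, gg$y, vx, vy, boundary = FALSE)
    dd <- density_field(gg$x, gg$y, centre, peak_density_mm2,
                        background_density_mm2, sigma_mm, ventral_gradient, ymax)
    cell <- (gx[2] - gx[1]) * (gy[2] - gy[1])
    true_total <- sum(dd[inside]) * cell
    structure(
      list(points = tibble(x_mm = px, y_mm = py, cell_class = labels),
           outline = outline,
           centre = centre,
           peak_density_mm2 = peak_density_mm2,
           background_density_mm2 = background_density_mm2,
           sigma_mm = sigma_mm, ventral_gradient = ventral_gradient,
           class_fractions = class_fractions,
           true_total = true_total),
      class = "eyespec_retina"
    )
  })
}

#' @rdname simulate_retina
#' @param retina An `eyespec_retina`.
#' @param x,y Query coordinates (mm).
#' @return `retina_density()` evaluates the generating intensity field.
#' @export
retina_density <- function(retina, x, y) {
  stopifnot(inherits(retina, "eyespec_retina"))
  ymax <- max(abs(retina$outline$y_mm - retina$centre[2]))
  density_field(x, y, retina$centre, retina$peak_density_mm2,
                retina$background_density_mm2, retina$sigma_mm,
                retina$ventral_gradient, ymax)
}
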