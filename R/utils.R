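# Internal numeric helpers shared across modules.

# Trapezoid-rule integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# Even-odd point-in-polygon test, boundary-inclusive (points on an edge or
# vertex count as inside). Vectorised over query points; the polygon is given
# as vertex vectors and is closed implicitly. The boundary test is skippable
# for bulk Monte-Carlo use where landing exactly on an edge has probability
# zero.
point_in_polygon <- function(px, py, vx, vy, eps = 1e-12, boundary = TRUE) {
  n <- length(vx)
  stopifnot(n >= 3L, length(vy) == n)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    if (boundary) {
      # boundary: point within eps of segment (x1,y1)-(x2,y2)
      dx <- x2 - x1; dy <- y2 - y1
      len2 <- dx * dx + dy * dy
      if (len2 > 0) {
        t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
        d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
        on_edge <- on_edge | d2 <= eps
      } else {
        on_edge <- on_edge | ((px - x1)^2 + (py - y1)^2 <= eps)
      }
    }
    # even-odd ray crossing
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | on_edge
}

polygon_area <- function(vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1L))
  abs(sum(vx[j] * vy - vx * vy[j])) / 2
}

polygon_centroid <- function(vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1L))
  cross <- vx[j] * vy - vx * vy[j]
  a <- sum(cross) / 2
  cx <- sum((vx[j] + vx) * cross) / (6 * a)
  cy <- sum((vy[j] + vy) * cross) / (6 * a)
  c(cx, cy)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a finite number in [%g, %g].", name, lower, upper),
          class = "eyespec_invalid_parameter")
  }
  invisible(x)
}
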