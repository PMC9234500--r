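# Shared fixtures, built in code at test time.

# Piecewise-linear sensitivity curve on the 350-650 nm, 10 nm grid with an
# exactly known peak (refined) and half-maximum crossings: the apex at
# `peak` has symmetric immediate neighbours, so 3-point parabolic refinement
# returns the apex exactly; flanks are linear through (lo, 0.5) and
# (hi, 0.5), so linear interpolation recovers the crossings exactly.
make_peak_curve <- function(lo, hi, peak = 560, grid = seq(350, 650, 10),
                            floor_value = 0.02) {
  stopifnot(peak %in% grid, hi > peak + 10, lo < peak - 10)
  s_left <- 0.5 / (peak - lo)
  v_shoulder <- 1 - (grid[2] - grid[1]) * s_left
  s_right <- (v_shoulder - 0.5) / (hi - (peak + 10))
  v <- ifelse(grid <= peak,
              1 - (peak - grid) * s_left,
              v_shoulder - (grid - (peak + 10)) * s_right)
  v[grid == peak] <- 1
  spectral_curve(grid, pmax(v, floor_value))
}

# Single-class eye model with flat media and no droplet: its sensitivity
# reduces to the pigment template.
single_class_model <- function(lambda_max = 564, droplet = oil_droplet("none"),
                               noise_sd = 0) {
  eye_model(
    list(photoreceptor_class("LWS", lambda_max, droplet = droplet)),
    media = NULL, noise_sd = noise_sd
  )
}

# Small wholemount for fast stereology tests.
small_retina <- function(peak = 4000, background = 2000, seed = 1, ...) {
  simulate_retina(peak, background, outline = retina_outline(1.5, 1.2),
                  sigma_mm = 0.6, seed = seed, ...)
}

# Independent dense radial-basis solve used as the TPS oracle: same maths,
# separately coded (r^2 log r^2 kernel parametrisation, no coordinate
# scaling), predictions must agree with tps_fit().
tps_oracle <- function(x, y, v, qx, qy) {
  n <- length(x)
  U <- function(r2) ifelse(r2 == 0, 0, r2 * log(r2))
  K <- U(outer(x, x, "-")^2 + outer(y, y, "-")^2)
  P <- cbind(1, x, y, x^2, x * y, y^2)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 6, 6)))
  sol <- solve(A, c(v, rep(0, 6)))
  Kq <- U(outer(qx, x, "-")^2 + outer(qy, y, "-")^2)
  Pq <- cbind(1, qx, qy, qx^2, qx * qy, qy^2)
  drop(Kq %*% sol[1:n] + Pq %*% sol[n + 1:6])
}

# Table-style accounting fixture: integer frame counts in the measured
# proportions (asf = 0.01).
accounting_sessions <- function() {
  outl <- retina_outline(1, 1, n = 16)
  mk <- function(counts, cls) {
    n <- length(counts)
    fractionator_session(
      outl,
      tibble::tibble(x_mm = seq(-0.5, 0.5, length.out = n), y_mm = 0,
                     marker_count = counts, cell_class = cls),
      grid_cell_area_um2 = 250000, frame_area_um2 = 2500, cell_class = cls
    )
  }
  list(
    total = mk(c(400, 300, 300), "total"),
    single = mk(c(300, 250, 225), "single"),
    double = mk(c(100, 50, 75), "double"),
    rh1 = mk(c(77, 50, 50), "rh1"),
    sws1 = mk(c(30, 20, 16), "sws1")
  )
}
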