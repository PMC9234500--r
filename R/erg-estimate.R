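# Spectral-sensitivity estimation from ERG flicker-photometry trials.

#' Equivalence sensitivity at one wavelength
#'
#' Sensitivity is the reciprocal of the photon flux at which the
#' monochromatic response matches the white-reference response. The matching
#' flux is found by monotone piecewise-linear interpolation of response
#' amplitude against log10 photon flux; when noise makes the amplitudes
#' non-monotone they are first pooled by isotonic regression. If the white
#' reference amplitude falls outside the amplitude range of the trials the
#' wavelength is unresolved and `NA` is returned (the caller drops it).
#'
#' @param flux Photon fluxes of the trials (photons cm^-2 s^-1, > 0).
#' @param amplitude Response amplitudes at those fluxes.
#' @param white_amplitude White-reference amplitude (scalar; vectors are
#'   averaged).
#' @return Sensitivity `1 / Q_eq` (cm^2 s photon^-1), or `NA_real_` if
#'   unresolved.
#' @examples
#' equivalence_sensitivity(c(1e14, 2e14, 4e14), c(1, 2, 4), 2) # 5e-15
#' @export
equivalence_sensitivity <- function(flux, amplitude, white_amplitude) {
  if (any(flux <= 0)) {
    abort("Photon fluxes must be positive.", class = "eyespec_invalid_input")
  }
  w <- mean(white_amplitude)
  ord <- order(flux)
  lx <- log10(flux[ord])
  y <- amplitude[ord]
  if (length(y) < 2L) {
    abort("Need at least two trials at distinct fluxes.",
          class = "eyespec_invalid_input")
  }
  if (any(diff(y) < 0)) {
    y <- isoreg(lx, y)$yf
  }
  if (w < min(y) || w > max(y)) {
    return(NA_real_) # unresolved wavelength
  }
  # first bracketing interval scanning upward
  i <- which(y[-length(y)] <= w & y[-1] >= w)[1]
  if (is.na(i)) return(NA_real_)
  lq <- if (y[i + 1] == y[i]) (lx[i] + lx[i + 1]) / 2 else
    lx[i] + (w - y[i]) * (lx[i + 1] - lx[i]) / (y[i + 1] - y[i])
  1 / 10^lq
}

#' Splice two 20 nm wavelength sweeps into one 10 nm curve
#'
#' The measurement protocol records a descending sweep on the
#' \{350, 370, ..., 650\} nm grid and an ascending sweep on the
#' \{340, 360, ..., 640\} nm grid. Splicing interleaves them into a single
#' 31-point curve on \{350, 360, ..., 650\} nm; the 340 nm point falls
#' outside the reported range and is dropped. Values are preserved verbatim
#' (no smoothing); a systematic offset between the sweeps of more than 20%
#' (median ratio of each sweep to the interleaved interpolation of the
#' other) is flagged in the `splice_discontinuity` attribute.
#'
#' @param sweep_a,sweep_b Data frames with `wavelength_nm` and a value column
#'   (`sensitivity` or `value`), one per 20 nm grid (either order).
#' @return A [spectral_curve()] on the 350–650 nm, 10 nm grid.
#' @export
splice_sweeps <- function(sweep_a, sweep_b) {
  get_curve <- function(x) {
    x <- as.data.frame(x)
    vcol <- intersect(c("sensitivity", "value"), names(x))[1]
    if (is.na(vcol)) {
      abort("Sweep needs a `sensitivity` or `value` column.",
            class = "eyespec_invalid_input")
    }
    out <- x[order(x$wavelength_nm), c("wavelength_nm", vcol)]
    names(out) <- c("wavelength_nm", "value")
    out[!is.na(out$value), ]
  }
  a <- get_curve(sweep_a)
  b <- get_curve(sweep_b)
  grids <- list(odd = seq(350, 650, 20), even = seq(340, 640, 20))
  id <- function(wl) {
    if (all(wl %in% grids$odd)) "odd" else if (all(wl %in% grids$even)) "even"
    else abort("Sweep wavelengths must lie on the 350-650 or 340-640 20 nm grid.",
               class = "eyespec_invalid_input")
  }
  ia <- id(a$wavelength_nm); ib <- id(b$wavelength_nm)
  if (ia == ib) {
    dup <- intersect(a$wavelength_nm, b$wavelength_nm)
    if (length(dup) > 0) {
      va <- a$value[match(dup, a$wavelength_nm)]
      vb <- b$value[match(dup, b$wavelength_nm)]
      if (any(abs(va - vb) > 1e-9 * pmax(abs(va), abs(vb)))) {
        abort("Sweeps overlap with conflicting values.",
              class = "eyespec_invalid_input")
      }
    }
  }
  comb <- rbind(a, b)
  comb <- comb[comb$wavelength_nm >= 350 & comb$wavelength_nm <= 650, ]
  comb <- comb[!duplicated(comb$wavelength_nm), ]
  comb <- comb[order(comb$wavelength_nm), ]
  out <- spectral_curve(comb$wavelength_nm, comb$value)
  # flag systematic offset between the sweeps
  disc <- FALSE
  if (ia != ib && nrow(a) > 2 && nrow(b) > 2) {
    bi <- approx(b$wavelength_nm, b$value, xout = a$wavelength_nm)$y
    r <- a$value / bi
    r <- r[is.finite(r) & r > 0]
    if (length(r) > 0 && abs(log(stats::median(r))) > log(1.2)) disc <- TRUE
  }
  attr(out, "splice_discontinuity") <- disc
  out
}

#' Estimate per-animal sensitivity curves from an ERG trial set
#'
#' Runs [equivalence_sensitivity()] for every (animal, condition, sweep,
#' wavelength) group and splices the two 20 nm sweeps of each
#' (animal, condition) into a single 10 nm curve over 350–650 nm. Unresolved
#' wavelengths (white reference outside the response range) are dropped.
#'
#' @param trials A trial tibble ([simulate_erg_trials()] or [read_erg_csv()]).
#' @return A tibble with columns `animal_id`, `condition`, `frequency_hz`,
#'   `adaptation_nm`, `wavelength_nm`, `sensitivity`.
#' @examples
#' trials <- simulate_erg_trials(default_eye_model(0), erg_protocol(),
#'                               n_animals = 1, seed = 1)
#' estimate_sensitivity(trials)
#' @export
estimate_sensitivity <- function(trials) {
  per_wl <- trials |>
    dplyr::group_by(.data$animal_id, .data$condition, .data$frequency_hz,
                    .data$adaptation_nm, .data$sweep, .data$wavelength_nm) |>
    dplyr::summarise(
      sensitivity = equivalence_sensitivity(.data$photon_flux,
                                            .data$response_amplitude,
                                            .data$white_response_amplitude),
      .groups = "drop"
    )
  per_wl |>
    dplyr::group_by(.data$animal_id, .data$condition, .data$frequency_hz,
                    .data$adaptation_nm) |>
    dplyr::group_modify(function(df, key) {
      sweeps <- split(df, df$sweep)
      cur <- if (length(sweeps) >= 2L) {
        splice_sweeps(sweeps[[1]], sweeps[[2]])
      } else {
        s <- sweeps[[1]][!is.na(sweeps[[1]]$sensitivity), ]
        spectral_curve(s$wavelength_nm, s$sensitivity)
      }
      tibble(wavelength_nm = cur$wavelength_nm, sensitivity = cur$value)
    }) |>
    dplyr::ungroup()
}

#' Normalise sensitivity curves to their group mean
#'
#' Implements "linearly fitting each curve to the average of all curves being
#' compared": the unweighted mean curve `m` is computed once, then each curve
#' `x` is scaled by the offset-free least-squares gain
#' `a = <x, m> / <x, x>`, which minimises `||a x - m||^2`. Offset-free
#' scaling keeps sensitivities positive and leaves each curve's peak
#' wavelength and SW:LW ratio unchanged. With `offset = TRUE` an intercept is
#' also fitted and subtracted (logged alternative; changes ratio statistics).
#'
#' @param curves Tibble with `animal_id`, `wavelength_nm`, `sensitivity` (one
#'   curve per animal/condition on a common grid), as returned by
#'   [estimate_sensitivity()].
#' @param offset Fit gain + offset instead of gain only.
#' @return The input tibble with `sensitivity` rescaled and a
#'   `normalization_gain` column.
#' @export
normalize_to_group <- function(curves, offset = FALSE) {
  keys <- intersect(c("animal_id", "condition", "frequency_hz", "adaptation_nm"),
                    names(curves))
  curves <- dplyr::arrange(curves, dplyr::across(dplyr::all_of(c(keys, "wavelength_nm"))))
  wide <- curves |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_split()
  grid <- wide[[1]]$wavelength_nm
  common <- Reduce(intersect, lapply(wide, function(d) d$wavelength_nm))
  if (length(common) < 2L) {
    abort("Curves share fewer than two wavelengths.",
          class = "eyespec_invalid_input")
  }
  mat <- vapply(wide, function(d) d$sensitivity[match(common, d$wavelength_nm)],
                numeric(length(common)))
  m <- rowMeans(as.matrix(mat))
  out <- lapply(wide, function(d) {
    x <- d$sensitivity[match(common, d$wavelength_nm)]
    if (all(x == 0)) {
      abort("Cannot normalise an all-zero curve.", class = "eyespec_invalid_input")
    }
    if (offset) {
      fit <- stats::lm(m ~ x)
      d$sensitivity <- coef(fit)[1] + coef(fit)[2] * d$sensitivity
      d$normalization_gain <- unname(coef(fit)[2])
    } else {
      a <- sum(x * m) / sum(x * x)
      d$sensitivity <- a * d$sensitivity
      d$normalization_gain <- a
    }
    d
  })
  dplyr::bind_rows(out)
}

#' Peak and bandwidth descriptors of a sensitivity curve
#'
#' The peak wavelength is the grid argmax refined by a 3-point parabolic fit
#' (a bare 10 nm grid cannot express sub-grid peaks); the refined peak height
#' defines the half-maximum level, whose crossings on each flank are located
#' by linear interpolation scanning outward from the peak. FWHM is the
#' distance between the two crossings; it is invariant under positive
#' rescaling of the curve.
#'
#' @param curve A positive [spectral_curve()] (or data frame with
#'   `wavelength_nm` and `value`/`sensitivity`) with an interior maximum.
#' @return A tibble with `peak_nm`, `peak_value`, `half_max_lo_nm`,
#'   `half_max_hi_nm`, `fwhm_nm`.
#' @examples
#' g <- spectral_curve(seq(350, 650, 10), exp(-(seq(350, 650, 10) - 560)^2 / 800))
#' curve_descriptors(g)
#' @export
curve_descriptors <- function(curve) {
  if (is.data.frame(curve) && "sensitivity" %in% names(curve) &&
      !"value" %in% names(curve)) {
    curve <- spectral_curve(curve$wavelength_nm, curve$sensitivity)
  }
  curve <- as_spectral_curve(curve)
  wl <- curve$wavelength_nm
  v <- curve$value
  i <- which.max(v)
  if (i == 1L || i == length(v)) {
    abort("Curve has no interior maximum; descriptors undefined.",
          class = "eyespec_descriptor_undefined")
  }
  # parabolic refinement over the three points around the grid maximum
  d1 <- v[i - 1] - v[i + 1]
  d2 <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (d2 < 0) {
    h <- wl[i + 1] - wl[i] # assumes locally uniform spacing
    peak <- wl[i] + 0.5 * h * d1 / d2
    peak_value <- v[i] - d1^2 / (8 * d2)
  } else {
    peak <- wl[i]
    peak_value <- v[i]
  }
  half <- peak_value / 2
  # short flank: scan outward from the peak for the first downward crossing
  lo <- NA_real_
  for (k in seq(i - 1L, 1L)) {
    if ((v[k] < half) != (v[k + 1] < half) || v[k] == half) {
      lo <- wl[k] + (half - v[k]) * (wl[k + 1] - wl[k]) / (v[k + 1] - v[k])
      break
    }
  }
  hi <- NA_real_
  for (k in seq(i, length(v) - 1L)) {
    if ((v[k] < half) != (v[k + 1] < half) || v[k + 1] == half) {
      hi <- wl[k] + (half - v[k]) * (wl[k + 1] - wl[k]) / (v[k + 1] - v[k])
      break
    }
  }
  tibble(peak_nm = peak, peak_value = peak_value,
         half_max_lo_nm = lo, half_max_hi_nm = hi, fwhm_nm = hi - lo)
}

#' Short- to long-wavelength sensitivity ratio
#'
#' The ratio of the trapezoid integral of the curve below the split
#' wavelength (530 nm, halfway between the template peaks of the
#' middle- and long-wavelength cone classes) to the integral above it. The
#' value at the split is obtained by linear interpolation when off-grid, so
#' the two integrals meet exactly at the split. The reciprocal transform
#' (used to reduce skewness before modelling) is also returned.
#'
#' @param curve A positive [spectral_curve()] (or data frame with a
#'   `sensitivity` column) spanning the split.
#' @param split_nm Split wavelength (nm).
#' @return A tibble with `ratio` (SW/LW), `transformed` (1/ratio), `split_nm`.
#' @examples
#' sw_lw_ratio(spectral_curve(seq(350, 650, 10), rep(1, 31))) # ratio 1.5
#' @export
sw_lw_ratio <- function(curve, split_nm = 530) {
  if (is.data.frame(curve) && "sensitivity" %in% names(curve) &&
      !"value" %in% names(curve)) {
    curve <- spectral_curve(curve$wavelength_nm, curve$sensitivity)
  }
  curve <- as_spectral_curve(curve)
  wl <- curve$wavelength_nm
  v <- curve$value
  if (min(wl) >= split_nm || max(wl) <= split_nm) {
    abort("Curve must span the split wavelength.", class = "eyespec_invalid_input")
  }
  v_split <- approx(wl, v, xout = split_nm)$y
  lo_sel <- wl < split_nm
  sw <- trapz(c(wl[lo_sel], split_nm), c(v[lo_sel], v_split))
  hi_sel <- wl > split_nm
  lw <- trapz(c(split_nm, wl[hi_sel]), c(v_split, v[hi_sel]))
  if (lw <= 0) {
    abort("Long-wavelength integral is zero; ratio undefined.",
          class = "eyespec_undefined_ratio")
  }
  ratio <- sw / lw
  tibble(ratio = ratio, transformed = 1 / ratio, split_nm = split_nm)
}
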