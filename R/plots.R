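# ggplot2 display methods for result objects.

#' @method autoplot eyespec_density_map
#' @export
autoplot.eyespec_density_map <- function(object, levels = NULL, ...) {
  p <- ggplot2::ggplot(object[object$inside, ],
                       ggplot2::aes(x = .data$x_mm, y = .data$y_mm)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$density / 1000)) +
    ggplot2::scale_fill_viridis_c(name = expression(cells ~ mm^-2 %*% 1000)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm, nasal → temporal)",
                  y = "y (mm, dorsal → ventral)")
  if (!is.null(levels)) {
    cont <- contour_levels(object, levels)
    if (nrow(cont) > 0) {
      p <- p + ggplot2::geom_path(
        data = cont,
        ggplot2::aes(group = .data$contour_id),
        colour = "white", linewidth = 0.3
      )
    }
  }
  p
}

#' Plot estimated sensitivity curves
#'
#' One line per animal plus the group mean, on the estimation grid.
#'
#' @param curves Tibble from [estimate_sensitivity()] /
#'   [normalize_to_group()].
#' @return A ggplot object.
#' @export
plot_sensitivity_curves <- function(curves) {
  mean_curve <- curves |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::summarise(sensitivity = mean(.data$sensitivity), .groups = "drop")
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$wavelength_nm, y = .data$sensitivity)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$animal_id),
                       alpha = 0.4, colour = "grey40") +
    ggplot2::geom_line(data = mean_curve, colour = "blue", linewidth = 1) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Relative sensitivity")
}
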