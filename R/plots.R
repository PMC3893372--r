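# ggplot2 visualisations for the main result types.

#' Plot a solved potential field with its midline
#'
#' Raster of the potential over the ribbon with the phi = 0 midline overlaid,
#' the standard visual check that the solve and the midline extraction agree
#' with the traced geometry.
#'
#' @param field A `potential_field`.
#' @param profile Optional `midline_profile` to overlay.
#' @return A ggplot object.
#' @export
plot_potential_field <- function(field, profile = NULL) {
  phi <- field$phi
  grid <- field$grid
  df <- tibble(
    x = rep(grid$x0 + (seq_len(ncol(phi)) - 1) * grid$grid_spacing,
            each = nrow(phi)),
    y = rep(grid$y0 + (seq_len(nrow(phi)) - 1) * grid$grid_spacing,
            times = ncol(phi)),
    phi = as.vector(phi)
  ) |> filter(is.finite(.data$phi))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$phi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#a50026", limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = expression(phi)) +
    ggplot2::theme_minimal()
  if (!is.null(profile)) {
    p <- p + ggplot2::geom_path(
      data = as_tibble(profile),
      ggplot2::aes(.data$x_px, .data$y_px, group = .data$piece),
      inherit.aes = FALSE, linewidth = 0.4
    )
  }
  p
}

#' @describeIn midline_profile Thickness along the midline arc, coloured by
#'   curvature.
#' @param object A `midline_profile`.
#' @param ... Unused.
#' @export
autoplot.midline_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$arc_s_um / 1000, .data$t_um,
                               colour = .data$kappa_per_mm,
                               group = .data$piece)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_gradient2(low = "#313695", mid = "grey70",
                                    high = "#a50026") +
    ggplot2::labs(x = "midline arc position (mm)",
                  y = expression("cortical thickness" ~ t ~ (mu * m)),
                  colour = expression(kappa ~ (mm^-1))) +
    ggplot2::theme_minimal()
}

#' Mean slide thickness against stereotaxic position
#'
#' One line per group (triangles for cases, circles for controls is the
#' conventional rendering; here shape maps to group), anterior to the right.
#'
#' @param mean_t Output of [mean_thickness_by_slide()] including `y_mm` and
#'   `group` columns.
#' @return A ggplot object.
#' @export
plot_mean_thickness <- function(mean_t) {
  ggplot2::ggplot(as_tibble(mean_t),
                  ggplot2::aes(.data$y_mm, .data$mean_t,
                               colour = .data$group, shape = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_shape_manual(values = c(case = 17, control = 1,
                                           asd = 17)) +
    ggplot2::labs(x = "stereotaxic y (mm, anterior +)",
                  y = expression(bar(t) ~ (mu * m))) +
    ggplot2::theme_minimal()
}

#' @describeIn position_curvature_map Heatmap of the thickness difference by
#'   position and curvature (blue where the case cortex is thinner).
#' @param object A `delta_t_map`.
#' @param ... Unused.
#' @export
autoplot.delta_t_map <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$y_mid, .data$kappa_bin,
                               fill = .data$delta_t)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                  high = "#e08214", na.value = "grey90") +
    ggplot2::labs(x = "stereotaxic y (mm, anterior +)",
                  y = expression(kappa ~ "bin" ~ (mm^-1)),
                  fill = expression(Delta * t ~ (mu * m))) +
    ggplot2::theme_minimal()
}

#' @describeIn granulometry Pattern spectrum bar chart (finite bands).
#' @param object A `pattern_spectrum`.
#' @param ... Unused.
#' @export
autoplot.pattern_spectrum <- function(object, ...) {
  sp <- as_tibble(object) |> filter(is.finite(.data$size_hi))
  ggplot2::ggplot(sp, ggplot2::aes((.data$size_lo + .data$size_hi) / 2,
                                   .data$area_um2)) +
    ggplot2::geom_col(width = min(diff(sp$size_lo)) * 0.9,
                      fill = "steelblue") +
    ggplot2::labs(x = expression("structuring element size" ~ (mu * m)),
                  y = expression("area removed" ~ (mu * m^2))) +
    ggplot2::theme_minimal()
}
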