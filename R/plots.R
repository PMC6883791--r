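#' Plot a force curve with an optional Hertz fit overlay
#'
#' @param object A [force_curve()].
#' @param fit Optional [fit_hertz()] result to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.force_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$displacement_nm, .data$force_pN)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "displacement (nm)", y = "force (pN)")
  if (!is.null(fit)) {
    d <- object$displacement_nm
    dd <- seq(min(d), max(d), length.out = 400)
    delta <- pmax(dd - fit$contact_nm, 0)
    overlay <- tibble(
      displacement_nm = dd,
      force_pN = fit$baseline_pN + fit$a * delta^1.5
    )
    p <- p + ggplot2::geom_line(data = overlay, colour = "firebrick") +
      ggplot2::geom_vline(xintercept = fit$contact_nm, linetype = "dashed") +
      ggplot2::labs(subtitle = sprintf("E = %.3g MPa", fit$E))
  }
  p
}

#' Plot a free-energy surface
#'
#' @param object A [free_energy_surface()] result.
#' @param ... Unused.
#' @return A ggplot raster of the surface in k_bT units; unoccupied bins
#'   are blank.
#' @export
autoplot.fe_surface <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$pc1_center, .data$pc2_center,
                               fill = .data$fe_kbt)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white", name = "FE (kT)") +
    ggplot2::labs(x = "PC1 (nm)", y = "PC2 (nm)")
}

#' Plot per-window minimal-cylinder distributions of an elasticity fit
#'
#' @param object An [estimate_elasticity()] result.
#' @param ... Unused.
#' @return A ggplot with the per-window height and radius distributions.
#' @export
autoplot.elasticity_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$series[, c("window", "h", "r")],
                              c("h", "r"), names_to = "dimension",
                              values_to = "nm")
  ggplot2::ggplot(long, ggplot2::aes(.data$nm)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "grey20") +
    ggplot2::facet_wrap(~dimension, scales = "free") +
    ggplot2::labs(
      x = "cylinder dimension (nm)", y = "windows",
      subtitle = sprintf("E = %.3g +/- %.2g MPa", object$estimate$E,
                         object$estimate$sd)
    )
}

#' Box plots of gaping and sliding distributions
#'
#' @param object A [gape_slide()] series.
#' @param ... Unused.
#' @return A ggplot with one box (whiskers at the extrema) per component.
#' @export
autoplot.gape_slide_series <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object)[, c("frame", "dx_nm", "dy_nm")],
                              c("dx_nm", "dy_nm"), names_to = "component",
                              values_to = "nm")
  ggplot2::ggplot(long, ggplot2::aes(.data$component, .data$nm)) +
    ggplot2::geom_boxplot(coef = Inf) +
    ggplot2::labs(x = NULL, y = "displacement (nm)")
}

#' Plot detected AFM particles
#'
#' @param object A [detect_particles()] table.
#' @param ... Unused.
#' @return A ggplot of particle centroids sized by diameter and coloured by
#'   height.
#' @export
autoplot.particle_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$centroid_x_nm, .data$centroid_y_nm,
                               size = .data$diameter_nm,
                               colour = .data$height_nm)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "height (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", size = "diameter (nm)")
}
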