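#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods for the profile classes and boundary tables. Depth
#' is always on the vertical axis (pia up). Depth x time and depth x
#' frequency images are color-mapped relative to the maximum absolute
#' deviation (MAD) of each profile, a plotting-only normalisation.
#'
#' @param object a profile or `layer_boundaries` object.
#' @param boundaries optional [layer_boundaries()] overlay.
#' @param ... unused.
#' @return a ggplot object.
#' @name laminarid-plots
NULL

boundary_layer <- function(boundaries) {
  if (is.null(boundaries)) return(NULL)
  list(
    ggplot2::geom_hline(data = tidy(boundaries),
                        ggplot2::aes(yintercept = .data$depth_um),
                        linetype = "dashed", linewidth = 0.3,
                        colour = "grey30")
  )
}

#' @rdname laminarid-plots
#' @method autoplot depth_profile
#' @export
autoplot.depth_profile <- function(object, boundaries = NULL, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$depth_um)) +
    ggplot2::geom_path(na.rm = TRUE) +
    boundary_layer(boundaries) +
    ggplot2::labs(x = object$metric[1], y = "depth (µm)") +
    ggplot2::theme_minimal()
}

#' @rdname laminarid-plots
#' @method autoplot depth_time_profile
#' @export
autoplot.depth_time_profile <- function(object, boundaries = NULL, ...) {
  mad <- max(abs(object$value), na.rm = TRUE)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$depth_um,
                                       fill = .data$value / mad)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1), name = "value / MAD") +
    boundary_layer(boundaries) +
    ggplot2::labs(x = "time (ms)", y = "depth (µm)",
                  title = object$metric[1]) +
    ggplot2::theme_minimal()
}

#' @rdname laminarid-plots
#' @method autoplot depth_spectral_profile
#' @export
autoplot.depth_spectral_profile <- function(object, boundaries = NULL, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_hz, y = .data$depth_um,
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$metric[1]) +
    boundary_layer(boundaries) +
    ggplot2::labs(x = "frequency (Hz)", y = "depth (µm)",
                  title = object$metric[1]) +
    ggplot2::theme_minimal()
}

#' @rdname laminarid-plots
#' @method autoplot layer_boundaries
#' @export
autoplot.layer_boundaries <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(y = .data$depth_um)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$depth_um,
                                     colour = .data$provenance)) +
    ggplot2::geom_text(ggplot2::aes(x = 1, label = .data$boundary),
                       hjust = 0, size = 3, nudge_y = 8) +
    ggplot2::scale_x_continuous(limits = c(0.9, 2), breaks = NULL) +
    ggplot2::labs(x = NULL, y = "depth (µm)", colour = "provenance") +
    ggplot2::theme_minimal()
}
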