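#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cumulative DVH
#'
#' @param object A [dvh()] / [dvh_all()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_gy,
                                       y = .data$volume_pct,
                                       colour = .data$structure)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Plot DVH bands (median and 25-75 percentile envelope)
#'
#' @param object A [dvh_bands()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dvh_bands <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose_gy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25_pct,
                                      ymax = .data$q75_pct,
                                      fill = .data$plan), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median_pct,
                                    colour = .data$plan)) +
    ggplot2::facet_wrap(~structure) +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", colour = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fluence map
#'
#' @param object A [fluence_map()].
#' @param ... Unused.
#' @return A ggplot raster of the beamlet intensities.
#' @export
autoplot.fluence_map <- function(object, ...) {
  df <- expand.grid(u = object$grid$u, v = object$grid$v)
  df$fluence <- as.numeric(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   fill = .data$fluence)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u (mm)", y = "v (mm)",
                  title = sprintf("Beam %d fluence", object$beam)) +
    ggplot2::theme_minimal()
}

#' Plot a gamma map
#'
#' @param object A [gamma_index()] result (2D only).
#' @param ... Unused.
#' @return A ggplot raster of gamma values (white where below threshold).
#' @export
autoplot.gamma_result <- function(object, ...) {
  if (length(dim(object$gamma)) != 2L)
    stop("autoplot supports planar gamma maps only")
  df <- expand.grid(i = seq_len(nrow(object$gamma)),
                    j = seq_len(ncol(object$gamma)))
  df$gamma <- as.numeric(object$gamma)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$gamma)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "navy",
                                  mid = "white", high = "red",
                                  na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Gamma %g%%/%g mm, GPR %.1f%%",
                                  object$criteria["dose_pct"],
                                  object$criteria["dist_mm"],
                                  object$gpr_pct)) +
    ggplot2::theme_minimal()
}
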