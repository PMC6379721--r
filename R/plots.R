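# Optional ggplot2 figures echoing the standard presentation of the
# metrics: weave profiles with the two symmetry groups as solid/dotted
# lines, per-junction corrugation curves with their mean, and the
# free-energy landscape as a heat map.

check_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
}

#' Plot a weave profile
#'
#' @param profile a [weave_profile()].
#' @param what `"mean"` or `"sd"`.
#' @return A ggplot object.
#' @export
plot_weave_profile <- function(profile, what = c("mean", "sd")) {
  check_ggplot()
  what <- match.arg(what)
  df <- as.data.frame(profile)
  df$y <- df[[what]]
  aes <- if ("group" %in% names(df))
    ggplot2::aes(x = .data$index, y = .data$y, colour = .data$pair,
                 linetype = factor(.data$group))
  else ggplot2::aes(x = .data$index, y = .data$y, colour = .data$pair)
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "base-pair index",
                  y = if (what == "mean") "inter-helix distance (nm)"
                      else "std. dev. of distance (nm)",
                  linetype = "group") +
    ggplot2::theme_minimal()
}

#' Plot corrugation curves
#'
#' @param profile a [corrugation_profile()].
#' @return A ggplot object.
#' @export
plot_corrugation <- function(profile) {
  check_ggplot()
  ggplot2::ggplot(profile$curves,
                  ggplot2::aes(x = .data$offset, y = .data$angle,
                               group = .data$junction)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_line(data = profile$mean,
                       ggplot2::aes(group = NULL), linewidth = 1) +
    ggplot2::labs(x = "offset from junction midpoint (bp)",
                  y = "inter-helix vector angle (deg)") +
    ggplot2::theme_minimal()
}

#' Plot a free-energy landscape heat map
#'
#' @param landscape a [wham()] result.
#' @param fmax clip free energies above this many kT.
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape, fmax = 8) {
  check_ggplot()
  grid <- expand.grid(phi = landscape$phi_centers,
                      theta = landscape$theta_centers)
  grid$F <- pmin(as.vector(landscape$F), fmax)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$phi, y = .data$theta,
                                     fill = .data$F)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = "F (kT)") +
    ggplot2::labs(x = expression(phi ~ "(deg)"),
                  y = expression(theta ~ "(deg)")) +
    ggplot2::theme_minimal()
}
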