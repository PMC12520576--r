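#' Plot a dispersion curve
#'
#' Dimensionless growth rate versus dimensionless wavenumber, with the
#' fastest-growing mode highlighted.
#'
#' @param object a [dispersion_curve()]
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.dispersion_curve <- function(object, ...) {
  fm <- attr(object, "fastest")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$kr, y = .data$omega_norm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(kR[jet]), y = expression(omega / omega[0]))
  if (!is.null(fm)) {
    om0 <- object$omega_per_s[which.max(object$omega_norm)] /
      max(object$omega_norm)
    p <- p + ggplot2::annotate("point", x = fm$kr_star,
                               y = fm$omega_star_per_s / om0, colour = "red")
  }
  p
}

#' Plot a radius density histogram
#'
#' @param object a [radius_pdf()]
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.radius_pdf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid_um, y = .data$density)) +
    ggplot2::geom_col(width = diff(object$mid_um[1:2]) * 0.95) +
    ggplot2::labs(x = "radius (um)", y = "probability density (1/um)")
}

#' Plot a mixture fit over the sample histogram
#'
#' @param object a [fit_mixture()] result
#' @param bin_width_um histogram bin width (default 5)
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.mixture_fit <- function(object, bin_width_um = 5, ...) {
  grid <- seq(min(object$data), max(object$data), length.out = 400)
  dens <- rowSums(vapply(seq_len(object$n_components), function(i) {
    object$weights[i] * stats::dnorm(grid, object$means[i], object$sds[i])
  }, numeric(length(grid))))
  hist_df <- radius_pdf(object$data, bin_width_um)
  ggplot2::ggplot() +
    ggplot2::geom_col(data = hist_df,
                      ggplot2::aes(x = .data$mid_um, y = .data$density),
                      width = bin_width_um * 0.95, fill = "grey80") +
    ggplot2::geom_line(data = tibble(r = grid, d = dens),
                       ggplot2::aes(x = .data$r, y = .data$d), colour = "red") +
    ggplot2::labs(x = "radius (um)", y = "probability density (1/um)")
}

#' Plot a kymograph
#'
#' @param object a [build_kymograph()] matrix
#' @param ... unused
#' @return a ggplot (time on x in ms, axial position on y in mm)
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.kymograph <- function(object, ...) {
  pitch <- attr(object, "pixel_pitch"); fr <- attr(object, "frame_rate")
  off <- attr(object, "nozzle_offset")
  df <- tidyr::expand_grid(row = seq_len(nrow(object)), col = seq_len(ncol(object)))
  df$grey <- as.vector(object)
  df$t_ms <- (df$col - 1) / fr * 1e3
  df$x_mm <- m_to_mm(off + (df$row - 0.5) * pitch)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$x_mm,
                                   fill = .data$grey)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::labs(x = "time (ms)", y = "axial position (mm)")
}

#' Plot a phase diagram
#'
#' @param object a [phase_diagram()] tibble
#' @param ... unused
#' @return a ggplot of region labels over the (kR, Gamma) plane
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.phase_diagram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$kR, y = .data$Gamma,
                                       fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = expression(kR[jet]), y = expression(Gamma))
}

#' Plot bead tracks aligned on breakup time
#'
#' @param object a [track_beads()] result
#' @param what "v" for velocity, "lambda" for spacing (default "v")
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.bead_tracks <- function(object, what = c("v", "lambda"), ...) {
  what <- match.arg(what)
  ycol <- if (what == "v") "v_m_per_s" else "lambda_m"
  df <- dplyr::filter(object, !is.na(.data[[ycol]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_minus_tb_s * 1e3,
                                   y = .data[[ycol]],
                                   group = .data$track_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "t - T_b (ms)",
                  y = if (what == "v") "bead velocity (m/s)" else "spacing (m)")
}
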