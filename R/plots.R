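#' Plot the fire-size densities of a scenario pair
#'
#' Kernel density curves for the two scenarios on one shared grid, the
#' reference (p0) scenario in blue and the comparison (p1) scenario in
#' orange.
#'
#' @param pair A [scenario_pair()].
#' @param n_points,pad_bandwidths,bandwidth Settings as in
#'   [attribution_curves()].
#' @return A ggplot object.
#' @export
plot_density_pair <- function(pair, n_points = 512, pad_bandwidths = 3,
                              bandwidth = "scott") {
  stopifnot(inherits(pair, "scenario_pair"))
  grid <- make_shared_grid(pair, n_points = n_points,
                           pad_bandwidths = pad_bandwidths,
                           bandwidth_rule = bandwidth)
  dens <- lapply(list(pair$p0_ensemble, pair$p1_ensemble), function(e) {
    d <- estimate_density(e, grid, bandwidth = bandwidth)
    data.frame(size_ha = d$grid, density = d$density, scenario = e$label)
  })
  df <- do.call(rbind, dens)
  df$scenario <- factor(df$scenario,
                        levels = c(pair$p0_ensemble$label,
                                   pair$p1_ensemble$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size_ha, y = .data$density,
                                   colour = .data$scenario)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c("#2166ac", "#e08214")) +
    ggplot2::labs(x = "Final fire size (ha)", y = "Density (per ha)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot p0, p1 and FAR against fire size
#'
#' The two exceedance curves and the FAR curve of an attribution analysis
#' share the probability axis, so all three are drawn in one panel.
#'
#' @param curve An `attribution_curve` from [attribution_curves()].
#' @return A ggplot object.
#' @export
plot_attribution <- function(curve) {
  stopifnot(inherits(curve, "attribution_curve"))
  df <- rbind(
    data.frame(size_ha = curve$grid, value = curve$p0,
               series = paste0("p0 (", curve$labels[["p0"]], ")")),
    data.frame(size_ha = curve$grid, value = curve$p1,
               series = paste0("p1 (", curve$labels[["p1"]], ")")),
    data.frame(size_ha = curve$grid,
               value = ifelse(curve$valid, curve$far, NA_real_),
               series = "FAR")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size_ha, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.8, na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Fire-size threshold (ha)", y = "Probability / FAR",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot relative risk against fire size
#'
#' @param curve An `attribution_curve`.
#' @param threshold Optional fire-size threshold (ha) to mark with a
#'   vertical line.
#' @param log_scale Draw RR on a log axis (useful when RR spans orders of
#'   magnitude, as it does in the upper tail).
#' @return A ggplot object.
#' @export
plot_relative_risk <- function(curve, threshold = NULL, log_scale = FALSE) {
  stopifnot(inherits(curve, "attribution_curve"))
  keep <- curve$valid & is.finite(curve$rr)
  df <- data.frame(size_ha = curve$grid[keep], rr = curve$rr[keep])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$size_ha, y = .data$rr)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#b2182b") +
    ggplot2::labs(x = "Fire-size threshold (ha)", y = "Relative risk") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  if (log_scale) {
    p <- p + ggplot2::scale_y_log10()
  }
  p
}

# Save a ggplot as PNG (always) and SVG (when the device is available).
save_figure <- function(plot, stem, dir, width = 7, height = 4.5) {
  png_path <- file.path(dir, paste0(stem, ".png"))
  ggplot2::ggsave(png_path, plot, width = width, height = height, dpi = 150)
  svg_path <- file.path(dir, paste0(stem, ".svg"))
  ok <- tryCatch({
    ggplot2::ggsave(svg_path, plot, width = width, height = height)
    TRUE
  }, error = function(e) FALSE)
  c(png_path, if (ok) svg_path)
}
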