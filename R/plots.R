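#' @method autoplot raster_grid
#' @export
autoplot.raster_grid <- function(object, ...) {
  df <- raster_to_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = object$layer) +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' @method autoplot sdm_fit
#' @export
autoplot.sdm_fit <- function(object, ...) {
  imp <- tidy(object)
  ggplot2::ggplot(imp, ggplot2::aes(
    x = .data$mean_decrease_accuracy,
    y = stats::reorder(.data$predictor, .data$mean_decrease_accuracy))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Mean decrease in accuracy (OOB)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot patch_report
#' @export
autoplot.patch_report <- function(object, ...) {
  h <- object$size_histogram
  h$bin <- factor(sprintf("%g-%g", h$bin_low, h$bin_high),
                  levels = sprintf("%g-%g", h$bin_low, h$bin_high))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(Patch~size~(km^2)), y = "Patches") +
    ggplot2::theme_minimal()
}

#' Plot scenario summaries across periods
#'
#' Mean +/- 1 SE across GCMs of a chosen metric, one line per RCP.
#'
#' @param summary tibble from [scenario_summary()].
#' @param metric one of `"rc"`, `"area"`, `"n_patches"`, `"patch_size"`,
#'   `"elevation"`.
#' @return A ggplot.
#' @export
plot_scenario_summary <- function(summary, metric = c("rc", "area",
                                                      "n_patches",
                                                      "patch_size",
                                                      "elevation")) {
  metric <- match.arg(metric)
  cols <- switch(metric,
    rc = c("rc_mean", "rc_se", "Range change (%)"),
    area = c("area_mean_km2", "area_se_km2", "Habitat area (km²)"),
    n_patches = c("n_patches_mean", "n_patches_se", "Number of patches"),
    patch_size = c("patch_size_mean_km2", "patch_size_se_km2",
                   "Mean patch size (km²)"),
    elevation = c("elevation_mean_m", "elevation_sd_m",
                  "Mean patch elevation (m)"))
  df <- summary
  df$m <- df[[cols[1]]]; df$e <- df[[cols[2]]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data$m,
                                   colour = .data$rcp,
                                   group = .data$rcp)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$m - .data$e,
                                          ymax = .data$m + .data$e)) +
    ggplot2::labs(x = "Period", y = cols[3], colour = "RCP") +
    ggplot2::theme_minimal()
}
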