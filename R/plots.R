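#' Map of the seasonal MDA8 difference
#'
#' Tile map of the per-cell seasonal `UG - Base` MDA8 difference, with the
#' urban mask outlined when present.
#'
#' @param object A `go_exposure` from [delta_mda8()].
#' @param value Column to map (default `delta`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot go_exposure
#' @export
autoplot.go_exposure <- function(object, value = "delta", ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$x, y = .data$y, fill = .data[[value]])) +
    geom_raster() +
    scale_fill_viridis_c(name = switch(value,
                                       delta = expression(Delta * "MDA8 (ppb)"),
                                       rel_pct = "rel. change (%)", value)) +
    coord_equal() +
    labs(x = "x (km)", y = "y (km)",
         title = "Urban-greening MDA8 ozone enhancement") +
    theme_minimal()
  if ("urban" %in% names(df)) {
    p <- p + geom_tile(data = filter(df, .data$urban), fill = NA,
                       colour = "grey30", linewidth = 0.05)
  }
  p
}

#' Map of attributable deaths
#'
#' @param object A `go_attribution` from [attribute_to_urban_greening()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot go_attribution
#' @export
autoplot.go_attribution <- function(object, ...) {
  ggplot(object$grid,
         aes(x = .data$x, y = .data$y, fill = .data$deaths_attributed)) +
    geom_raster() +
    scale_fill_viridis_c(name = "deaths", option = "magma") +
    coord_equal() +
    labs(x = "x (km)", y = "y (km)",
         title = "Mortality attributed to urban-greening ozone") +
    theme_minimal()
}

#' Boxplot-style view of the temperature relationship
#'
#' Per-temperature-bin summaries of the daily urban-mean MDA8 difference
#' (box: 25th/50th/75th percentiles; whiskers: min/max; point: mean), with
#' the Pearson correlation annotated.
#'
#' @param trel A `go_temprel` from [temperature_relationship()].
#' @return A ggplot object.
#' @export
plot_temperature_relationship <- function(trel) {
  ggplot(as_tibble(trel), aes(x = .data$bin_mid)) +
    geom_errorbar(aes(ymin = .data$min, ymax = .data$max), width = 0.1) +
    geom_crossbar(aes(y = .data$p50, ymin = .data$p25, ymax = .data$p75),
                  fill = "lightsteelblue", width = 0.5) +
    geom_point(aes(y = .data$mean), shape = 18, size = 2) +
    labs(x = "daily-mean 2 m temperature (°C)",
         y = expression(Delta * "MDA8 (ppb)"),
         subtitle = sprintf("Pearson r = %.2f, p = %.2g",
                            attr(trel, "r"), attr(trel, "p_value"))) +
    theme_minimal()
}
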