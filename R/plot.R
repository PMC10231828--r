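# Basic raster displays for gridded outputs. Publication cartography is
# out of scope; these are quick-look maps on the native grid.

raster_image <- function(lat, lon, values, main, ...) {
  graphics::image(lon, lat, t(values), xlab = "Longitude", ylab = "Latitude",
                  main = main, col = grDevices::hcl.colors(64, "viridis"),
                  ...)
}

#' @export
plot.isoscape <- function(x, ...) {
  raster_image(x$lat, x$lon, x$values,
               sprintf("Otolith d18O isoscape, %s %d", x$contingent,
                       x$year), ...)
  invisible(x)
}

#' @export
plot.probability_surface <- function(x, scaled = TRUE, ...) {
  v <- if (scaled) x$scaled else x$posterior
  raster_image(x$lat, x$lon, v,
               sprintf("Probability of origin, fish %s", x$fish_id), ...)
  invisible(x)
}

#' @export
plot.summary_map <- function(x, ...) {
  raster_image(x$lat, x$lon, x$values,
               sprintf("Nursery summary, %s year-class %s", x$contingent,
                       x$year_class), ...)
  invisible(x)
}

#' @export
plot.validation_curve <- function(x, ...) {
  graphics::plot(x$curve$q, x$curve$accuracy, type = "b", ylim = c(0, 1),
                 xlab = "Binarization quantile (precision)",
                 ylab = "Validation accuracy", ...)
  if (!is.na(x$chosen)) graphics::abline(v = x$chosen, lty = 2)
  graphics::abline(h = x$accuracy_floor, lty = 3)
  invisible(x)
}
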