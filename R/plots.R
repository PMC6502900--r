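#' Mirror plot of two conditions
#'
#' Plots selected timepoints of `series_a` upright and of `series_b`
#' vertically inverted on a shared, reversed ppm axis (high field right),
#' the standard display for direct comparison of two conditions by peak
#' height and position. The figure is a static export (PNG or SVG by file
#' extension).
#'
#' @param series_a,series_b preprocessed [spectrum_series] on compatible
#'   (overlapping) ppm ranges.
#' @param times integer indices of the timepoints to draw, per series
#'   (recycled to both); must be non-empty and in range for both series.
#' @param path output image path ending in `.png` or `.svg`.
#' @param ppm_window optional closed ppm interval to restrict the display.
#' @param width,height device size in pixels (png) or inches (svg).
#' @return `path`, invisibly.
#' @export
mirror_plot <- function(series_a, series_b, times, path,
                        ppm_window = NULL, width = 1600, height = 900) {
  assert_that(length(times) >= 1, "empty timepoint selection",
              "civmtrace_empty_error")
  assert_that(all(times >= 1 & times <= n_times(series_a)) &&
                all(times >= 1 & times <= n_times(series_b)),
              "timepoint selection out of range", "civmtrace_range_error")
  lo <- max(min(series_a$ppm), min(series_b$ppm))
  hi <- min(max(series_a$ppm), max(series_b$ppm))
  if (lo >= hi)
    stop_civm("series have incompatible (non-overlapping) ppm ranges",
              "civmtrace_axis_mismatch_error")
  if (!is.null(ppm_window)) {
    ppm_window <- as_interval(ppm_window)
    lo <- max(lo, ppm_window[1]); hi <- min(hi, ppm_window[2])
    assert_that(lo < hi, "ppm_window excludes the shared range")
  }
  ca <- ppm_columns(series_a, c(lo, hi))
  cb <- ppm_columns(series_b, c(lo, hi))
  ymax <- max(series_a$intensities[times, ca], 0)
  ymin <- -max(series_b$intensities[times, cb], 0)

  open_device(path, width, height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 2, 1))
  plot.new()
  plot.window(xlim = c(hi, lo), ylim = c(ymin, ymax) * 1.04)
  graphics::axis(1); graphics::axis(2)
  graphics::title(xlab = "chemical shift (ppm)",
                  ylab = "relative intensity (DSS = 1)")
  cols <- grDevices::hcl.colors(max(length(times), 2), "Zissou 1")
  for (k in seq_along(times)) {
    t <- times[k]
    graphics::lines(series_a$ppm[ca], series_a$intensities[t, ca],
                    col = cols[k], lwd = 0.8)
    graphics::lines(series_b$ppm[cb], -series_b$intensities[t, cb],
                    col = cols[k], lwd = 0.8)
  }
  graphics::abline(h = 0, col = "grey40")
  graphics::mtext(sprintf("mirror plot: %d timepoints", length(times)),
                  side = 3, line = 0.5)
  invisible(path)
}

#' Stacked-spectra plot with ridge overlays
#'
#' Draws the series as a waterfall (each spectrum offset proportionally to
#' its time) with the traced ridge polylines overlaid, the standard view
#' for visual QC of tracing.
#'
#' @param series a [spectrum_series].
#' @param ridges list of ridges traced on `series` (may be empty).
#' @param path output image path ending in `.png` or `.svg`.
#' @param ppm_window optional closed ppm interval to restrict the display.
#' @param offset_frac vertical offset between consecutive spectra as a
#'   fraction of the display maximum.
#' @param width,height device size.
#' @return `path`, invisibly.
#' @export
ridge_overlay_plot <- function(series, ridges = list(), path,
                               ppm_window = NULL, offset_frac = 0.04,
                               width = 1600, height = 1000) {
  cols_keep <- if (!is.null(ppm_window)) ppm_columns(series, ppm_window)
               else seq_len(n_points(series))
  assert_that(length(cols_keep) > 0, "ppm_window misses the axis",
              "civmtrace_empty_error")
  for (r in ridges) {
    p <- r$points
    if (any(p$time_index < 1 | p$time_index > n_times(series)) ||
        any(!is.na(p$ppm_index) &
              (p$ppm_index < 1 | p$ppm_index > n_points(series))))
      stop_civm(sprintf("ridge %s references indices outside the series",
                        r$id), "civmtrace_range_error")
  }
  T_n <- n_times(series)
  base <- max(series$intensities[, cols_keep])
  step <- offset_frac * base
  open_device(path, width, height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 2, 1))
  plot.new()
  plot.window(xlim = rev(range(series$ppm[cols_keep])),
              ylim = c(0, base + step * T_n))
  graphics::axis(1)
  graphics::title(xlab = "chemical shift (ppm)",
                  ylab = "relative intensity + time offset")
  for (t in seq_len(T_n))
    graphics::lines(series$ppm[cols_keep],
                    series$intensities[t, cols_keep] + step * (t - 1),
                    col = "grey55", lwd = 0.5)
  rc <- grDevices::hcl.colors(max(length(ridges), 2), "Dark 3")
  for (i in seq_along(ridges)) {
    p <- ridges[[i]]$points
    graphics::lines(p$ppm, p$raw_intensity + step * (p$time_index - 1),
                    col = rc[i], lwd = 2)
  }
  if (length(ridges))
    graphics::legend("topright",
                     legend = vapply(ridges, `[[`, character(1), "id"),
                     col = rc[seq_along(ridges)], lwd = 2, cex = 0.7,
                     bty = "n")
  invisible(path)
}

open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    grDevices::svg(path, width = width / 160, height = height / 160)
  } else {
    grDevices::png(path, width = width, height = height, res = 150)
  }
}
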