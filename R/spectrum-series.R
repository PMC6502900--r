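#' Spectral time-series container
#'
#' A `spectrum_series` holds a T x P matrix of real frequency-domain
#' intensities (one row per timepoint), the shared chemical-shift axis and
#' the acquisition times. The ppm axis is always stored in descending order
#' (standard NMR display orientation, high field right); every constructor
#' and reader canonicalises to that orientation so windowed searches never
#' have to branch on axis direction.
#'
#' @param intensities numeric matrix, T timepoints x P ppm points.
#' @param ppm numeric length-P chemical-shift axis (ppm), strictly monotone.
#' @param times_h numeric length-T acquisition times in hours since the
#'   experiment origin, strictly increasing.
#' @param records optional list of T [acquisition_record] objects.
#' @param meta list of free-form metadata (`sample_id`, `condition`, ...).
#'   A `history` character vector records one entry per transform applied.
#'
#' @return An object of class `spectrum_series`.
#' @seealso [assemble_series()] to build one from per-timepoint spectra,
#'   [preprocess_pipeline()] for the processing chain.
#' @export
spectrum_series <- function(intensities, ppm, times_h, records = NULL,
                            meta = list()) {
  intensities <- as.matrix(intensities)
  ppm <- as.numeric(ppm)
  times_h <- as.numeric(times_h)
  assert_that(nrow(intensities) == length(times_h),
              "number of spectra must match length of times_h",
              "civmtrace_dim_error")
  assert_that(ncol(intensities) == length(ppm),
              "number of columns must match length of ppm axis",
              "civmtrace_dim_error")
  d <- diff(ppm)
  assert_that(length(ppm) < 2 || all(d > 0) || all(d < 0),
              "ppm axis must be strictly monotone", "civmtrace_axis_error")
  if (length(ppm) >= 2 && d[1] > 0) {       # canonicalise to descending
    ppm <- rev(ppm)
    intensities <- intensities[, rev(seq_along(ppm)), drop = FALSE]
  }
  assert_that(length(times_h) < 2 || all(diff(times_h) > 0),
              "times_h must be strictly increasing", "civmtrace_time_error")
  if (!is.null(records)) {
    assert_that(length(records) == length(times_h),
                "records must align with timepoints", "civmtrace_dim_error")
  }
  meta$history <- meta$history %||% character()
  structure(
    list(intensities = unname(intensities), ppm = ppm, times_h = times_h,
         records = records, meta = meta),
    class = "spectrum_series"
  )
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf(
    "<spectrum_series> %d spectra x %d points | ppm [%.3f, %.3f] | t [%.2f, %.2f] h\n",
    nrow(x$intensities), ncol(x$intensities),
    min(x$ppm), max(x$ppm), min(x$times_h), max(x$times_h)))
  if (length(x$meta$history))
    cat("history:", paste(x$meta$history, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.spectrum_series <- function(x) dim(x$intensities)

n_times <- function(series) nrow(series$intensities)
n_points <- function(series) ncol(series$intensities)

add_history <- function(series, entry) {
  series$meta$history <- c(series$meta$history, entry)
  series
}

# column indices whose ppm lies in the closed interval
ppm_columns <- function(series, interval) {
  interval <- as_interval(interval)
  which(series$ppm >= interval[1] & series$ppm <= interval[2])
}

#' Assemble per-timepoint spectra into a series
#'
#' Orders spectra by their acquisition start clock, converts absolute start
#' times to hours relative to `origin`, and stacks the intensity vectors into
#' the canonical matrix form. All spectra must share one ppm axis (after
#' orientation canonicalisation, equality is exact).
#'
#' @param spectra list; each element a list with components `ppm` and
#'   `intensity` (equal-length numeric vectors).
#' @param records list of [acquisition_record] objects, one per spectrum, in
#'   the same order as `spectra`. Their `start_clock` fields (seconds since
#'   epoch) define the time axis and the ordering.
#' @param origin absolute timestamp (seconds since epoch) taken as time zero,
#'   e.g. the inoculation time; per-sample offsets between inoculation and
#'   first acquisition are expressed through this argument.
#' @param meta optional metadata list passed to [spectrum_series()].
#'
#' @return A [spectrum_series] with `times_h[i] = (start_clock[i] - origin)/3600`.
#' @export
assemble_series <- function(spectra, records, origin, meta = list()) {
  assert_that(length(spectra) >= 1L, "need at least one spectrum")
  assert_that(length(records) == length(spectra),
              "one acquisition record per spectrum is required",
              "civmtrace_dim_error")
  assert_that(is_number(origin), "origin must be a single finite timestamp")

  canon <- lapply(spectra, function(s) {
    ppm <- as.numeric(s$ppm); y <- as.numeric(s$intensity)
    assert_that(length(ppm) == length(y),
                "ppm and intensity lengths differ", "civmtrace_dim_error")
    if (length(ppm) >= 2 && diff(ppm)[1] > 0) { ppm <- rev(ppm); y <- rev(y) }
    list(ppm = ppm, intensity = y)
  })
  axis0 <- canon[[1]]$ppm
  for (s in canon) {
    if (!identical(length(s$ppm), length(axis0)) || !all(s$ppm == axis0))
      stop_civm("spectra do not share a common ppm axis",
                "civmtrace_axis_mismatch_error")
  }

  clocks <- vapply(records, function(r) r$start_clock, numeric(1))
  if (anyDuplicated(clocks))
    stop_civm("duplicate acquisition start times", "civmtrace_duplicate_time_error")
  ord <- order(clocks)
  mat <- do.call(rbind, lapply(canon[ord], `[[`, "intensity"))
  spectrum_series(mat, axis0, (clocks[ord] - origin) / 3600,
                  records = records[ord], meta = meta)
}
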