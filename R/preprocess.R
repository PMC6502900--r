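#' Preprocessing configuration
#'
#' Bundles the parameters of the post-acquisition processing chain applied by
#' [preprocess_pipeline()]. Defaults follow standard CIVM-NMR practice:
#' keep \[-0.5, 10\] ppm, zero the residual water signal in \[4.7, 5.0\] ppm,
#' drop timepoints beyond 11 h, search for the DSS reference peak within
#' 0.25 ppm of 0 ppm, and sum every 3 consecutive spectra.
#'
#' @param keep_ppm closed ppm interval retained by trimming.
#' @param water_ppm closed ppm interval zeroed out (residual water).
#' @param max_time_h latest retained acquisition time, hours.
#' @param dss_search_ppm half-width around 0 ppm of the DSS search window.
#' @param block number of consecutive spectra summed (>= 1).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(keep_ppm = c(-0.5, 10), water_ppm = c(4.7, 5.0),
                              max_time_h = 11, dss_search_ppm = 0.25,
                              block = 3L) {
  keep_ppm <- as_interval(keep_ppm)
  water_ppm <- as_interval(water_ppm)
  assert_that(is_number(max_time_h) && max_time_h > 0, "max_time_h must be > 0")
  assert_that(is_number(dss_search_ppm) && dss_search_ppm > 0,
              "dss_search_ppm must be > 0")
  assert_that(is_number(block) && block >= 1 && block == as.integer(block),
              "block must be a positive integer")
  structure(list(keep_ppm = keep_ppm, water_ppm = water_ppm,
                 max_time_h = max_time_h, dss_search_ppm = dss_search_ppm,
                 block = as.integer(block)),
            class = "preprocess_config")
}

# DSS window columns and detectability floor (5x the median absolute
# intensity inside the window); returns the window max index or errors.
find_reference_peak <- function(y, cols, t_index) {
  w <- y[cols]
  floor_t <- 5 * stats::median(abs(w))
  j <- which.max(w)
  if (!is.finite(w[j]) || w[j] <= floor_t)
    stop_civm(sprintf("reference peak not found at timepoint %d", t_index),
              "civmtrace_reference_error")
  cols[j]
}

#' Reference each spectrum to the DSS peak at 0 ppm
#'
#' Locates the maximum within `search_halfwidth` ppm of 0 in every spectrum
#' and shifts that spectrum by whole axis indices so the maximum sits on the
#' axis point nearest 0 ppm. Intensities are never re-interpolated, so raw
#' peak heights are preserved for downstream maximum-based quantification;
#' positions vacated at the spectrum ends are zero-filled. An optional
#' per-spectrum override replaces the automatic shift (the manual half of
#' "semi-automatic" referencing).
#'
#' @param series a [spectrum_series].
#' @param search_halfwidth half-width of the search window around 0 ppm.
#' @param shift_override optional integer vector (length T) of index shifts;
#'   `NA` entries fall back to the automatic shift.
#' @return The referenced [spectrum_series]; per-spectrum shifts are appended
#'   to the processing history.
#' @export
reference_to_dss <- function(series, search_halfwidth = 0.25,
                             shift_override = NULL) {
  cols <- ppm_columns(series, c(-search_halfwidth, search_halfwidth))
  assert_that(length(cols) > 0, "DSS search window misses the ppm axis",
              "civmtrace_axis_error")
  target <- which.min(abs(series$ppm))
  P <- n_points(series)
  shifts <- integer(n_times(series))
  for (t in seq_len(n_times(series))) {
    if (!is.null(shift_override) && !is.na(shift_override[t])) {
      shifts[t] <- as.integer(shift_override[t])
    } else {
      j <- find_reference_peak(series$intensities[t, ], cols, t)
      shifts[t] <- target - j
    }
    s <- shifts[t]
    if (s != 0) {
      y <- series$intensities[t, ]
      shifted <- numeric(P)
      src <- seq_len(P) - s
      ok <- src >= 1 & src <= P
      shifted[ok] <- y[src[ok]]
      series$intensities[t, ] <- shifted
    }
  }
  add_history(series, sprintf("reference_to_dss(hw=%g; shifts=[%s])",
                              search_halfwidth,
                              paste(shifts, collapse = ",")))
}

#' Trim the spectral ends
#'
#' Retains only the columns whose ppm lies in the closed interval `keep`.
#'
#' @param series a [spectrum_series].
#' @param keep closed ppm interval, default `c(-0.5, 10)`.
#' @return The trimmed [spectrum_series].
#' @export
trim_ppm <- function(series, keep = c(-0.5, 10)) {
  cols <- ppm_columns(series, keep)
  if (length(cols) == 0)
    stop_civm("keep interval does not overlap the ppm axis",
              "civmtrace_empty_error")
  series$intensities <- series$intensities[, cols, drop = FALSE]
  series$ppm <- series$ppm[cols]
  add_history(series, sprintf("trim_ppm([%g, %g])", min(keep), max(keep)))
}

#' Zero a spectral region
#'
#' Replaces all intensities whose ppm lies in the closed `region` (typically
#' the residual water signal) by exact zeros, in every spectrum. A region
#' outside the axis is a no-op.
#'
#' @param series a [spectrum_series].
#' @param region closed ppm interval, default `c(4.7, 5.0)`.
#' @return The modified [spectrum_series].
#' @export
zero_region <- function(series, region = c(4.7, 5.0)) {
  cols <- ppm_columns(series, region)
  if (length(cols)) series$intensities[, cols] <- 0
  add_history(series, sprintf("zero_region([%g, %g])", min(region), max(region)))
}

#' Drop late timepoints
#'
#' Retains timepoints with `times_h <= max_h` (closed bound).
#'
#' @param series a [spectrum_series].
#' @param max_h latest retained time, hours; default 11.
#' @return The truncated [spectrum_series].
#' @export
truncate_time <- function(series, max_h = 11) {
  keep <- which(series$times_h <= max_h)
  if (length(keep) == 0)
    stop_civm("no timepoints at or before max_h", "civmtrace_empty_error")
  series$intensities <- series$intensities[keep, , drop = FALSE]
  series$times_h <- series$times_h[keep]
  if (!is.null(series$records)) series$records <- series$records[keep]
  add_history(series, sprintf("truncate_time(%g)", max_h))
}

#' Normalise each spectrum to its DSS peak height
#'
#' Divides every spectrum by its own maximum intensity within
#' `ref_halfwidth` ppm of 0, so the reference peak height becomes exactly 1
#' in each spectrum and intensities are comparable across timepoints and
#' samples (relative quantification).
#'
#' @param series a [spectrum_series].
#' @param ref_halfwidth half-width of the DSS window, ppm.
#' @return The normalised [spectrum_series].
#' @export
normalize_to_reference <- function(series, ref_halfwidth = 0.25) {
  cols <- ppm_columns(series, c(-ref_halfwidth, ref_halfwidth))
  assert_that(length(cols) > 0, "DSS window misses the ppm axis",
              "civmtrace_axis_error")
  for (t in seq_len(n_times(series))) {
    j <- find_reference_peak(series$intensities[t, ], cols, t)
    series$intensities[t, ] <- series$intensities[t, ] /
      series$intensities[t, j]
  }
  add_history(series, sprintf("normalize_to_reference(hw=%g)", ref_halfwidth))
}

#' Sum consecutive blocks of spectra
#'
#' Sums each consecutive non-overlapping block of `block` spectra
#' elementwise, starting from the first timepoint, to improve
#' signal-to-noise. A trailing incomplete block is dropped. The time of a
#' summed spectrum is the arithmetic mean of its constituents' times; the
#' acquisition records are replaced by per-block summaries.
#'
#' @param series a [spectrum_series].
#' @param block block size (>= 1); `block = 1` is the identity.
#' @return The block-summed [spectrum_series] with `floor(T / block)` rows.
#' @export
block_sum <- function(series, block = 3L) {
  assert_that(is_number(block) && block >= 1 && block == as.integer(block),
              "block must be a positive integer")
  block <- as.integer(block)
  T_in <- n_times(series)
  if (T_in < block)
    stop_civm(sprintf("need at least %d spectra, have %d", block, T_in),
              "civmtrace_insufficient_data_error")
  if (block == 1L) return(add_history(series, "block_sum(1)"))
  nb <- T_in %/% block
  groups <- split(seq_len(nb * block), rep(seq_len(nb), each = block))
  mat <- do.call(rbind, lapply(groups, function(g)
    colSums(series$intensities[g, , drop = FALSE])))
  times <- vapply(groups, function(g) mean(series$times_h[g]), numeric(1))
  recs <- if (!is.null(series$records)) {
    lapply(groups, function(g)
      structure(list(members = g,
                     n_scans = sum(vapply(series$records[g],
                                          function(r) r$n_scans, numeric(1)))),
                class = "block_record"))
  }
  out <- spectrum_series(mat, series$ppm, unname(times), records = recs,
                         meta = series$meta)
  add_history(out, sprintf("block_sum(%d)", block))
}

#' Maximum-intensity trajectory of a spectral region
#'
#' Targeted quantification: at each timepoint, takes the raw maximum
#' intensity within the closed ppm `region` together with its location.
#' This is the region-based readout used e.g. to follow an isotope-labelled
#' substrate/product pair against baseline noise.
#'
#' @param series a [spectrum_series].
#' @param region closed ppm interval to search.
#' @return A data.frame with columns `time_h`, `intensity` (the region
#'   maximum) and `ppm` (its location).
#' @export
region_max_trajectory <- function(series, region) {
  cols <- ppm_columns(series, region)
  if (length(cols) == 0)
    stop_civm("region does not overlap the ppm axis", "civmtrace_empty_error")
  sub <- series$intensities[, cols, drop = FALSE]
  j <- apply(sub, 1L, which.max)
  data.frame(time_h = series$times_h,
             intensity = sub[cbind(seq_len(nrow(sub)), j)],
             ppm = series$ppm[cols][j])
}

#' Run the full preprocessing chain
#'
#' Applies, in this order: DSS referencing, spectral-end trimming,
#' water-region zeroing, time truncation, DSS normalisation, and block
#' summation. The order matters: normalisation must follow referencing and
#' water zeroing (so the reference height is found on the final axis), and
#' summation comes last so each summed spectrum is a sum of individually
#' normalised spectra.
#'
#' @param series a [spectrum_series].
#' @param cfg a [preprocess_config].
#' @return The processed [spectrum_series]; the history records every stage.
#' @export
preprocess_pipeline <- function(series, cfg = preprocess_config()) {
  assert_that(inherits(cfg, "preprocess_config"),
              "cfg must be a preprocess_config")
  series <- reference_to_dss(series, cfg$dss_search_ppm)
  series <- trim_ppm(series, cfg$keep_ppm)
  series <- zero_region(series, cfg$water_ppm)
  series <- truncate_time(series, cfg$max_time_h)
  series <- normalize_to_reference(series, cfg$dss_search_ppm)
  block_sum(series, cfg$block)
}
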