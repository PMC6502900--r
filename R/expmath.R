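#' Experiment planning arithmetic
#'
#' Small closed-form utilities for the arithmetic behind a CIVM-NMR
#' acquisition plan: how long one experiment takes, the effective temporal
#' resolution after block summation, the centrifugal load on a spinning
#' HR-MAS rotor, media molarity from a mass/volume percentage, and the cell
#' density after inoculating a culture. All return full precision; rounding
#' for display is the caller's concern.
#'
#' @name expmath
NULL

#' @describeIn expmath Duration of one experiment in minutes:
#'   `n_scans * seconds_per_scan / 60`. With the standard 64-scan noesypr1d
#'   experiment at ~3.97 s per scan this is ~4.23 min.
#' @param n_scans number of scans summed per saved FID (>= 1).
#' @param seconds_per_scan wall time per scan, seconds (> 0).
#' @export
experiment_duration_minutes <- function(n_scans, seconds_per_scan) {
  assert_that(is_number(n_scans) && n_scans >= 1, "n_scans must be >= 1")
  assert_that(is_number(seconds_per_scan) && seconds_per_scan > 0,
              "seconds_per_scan must be > 0")
  n_scans * seconds_per_scan / 60
}

#' @describeIn expmath Temporal resolution after summing `block` consecutive
#'   spectra: `block * experiment_minutes` (e.g. 3 x 4.23 min ~ 12.7 min).
#' @param experiment_minutes duration of a single experiment, minutes.
#' @param block number of consecutive spectra summed (>= 1).
#' @export
block_resolution_minutes <- function(experiment_minutes, block) {
  assert_that(is_number(block) && block >= 1, "block must be >= 1")
  assert_that(is_number(experiment_minutes) && experiment_minutes > 0,
              "experiment_minutes must be > 0")
  block * experiment_minutes
}

#' @describeIn expmath Centrifugal acceleration at the rotor wall in
#'   multiples of standard gravity: `(2 * pi * spin_hz)^2 * radius_mm / 1000
#'   / 9.81`. A 1.4 mm radius rotor at 6000 Hz experiences ~2e5 g.
#' @param radius_mm rotor internal radius, millimetres (>= 0).
#' @param spin_hz magic-angle spinning rate, Hz (>= 0).
#' @export
centrifugal_g <- function(radius_mm, spin_hz) {
  assert_that(is_number(radius_mm) && radius_mm >= 0, "radius_mm must be >= 0")
  assert_that(is_number(spin_hz) && spin_hz >= 0, "spin_hz must be >= 0")
  (2 * pi * spin_hz)^2 * radius_mm * 1e-3 / 9.81
}

#' @describeIn expmath Convert a mass/volume percentage (g per 100 mL) to
#'   molarity: `10 * percent_wv / molar_mass` mol/L. 1.5% w/v D-glucose
#'   (180.16 g/mol) is 83 mM.
#' @param percent_wv concentration in g / 100 mL (>= 0).
#' @param molar_mass molar mass, g/mol (> 0).
#' @export
mass_percent_to_molar <- function(percent_wv, molar_mass) {
  assert_that(is_number(percent_wv) && percent_wv >= 0,
              "percent_wv must be >= 0")
  assert_that(is_number(molar_mass) && molar_mass > 0,
              "molar_mass must be > 0")
  10 * percent_wv / molar_mass
}

#' @describeIn expmath Cell density after adding a volume of stock suspension
#'   to a culture: `(vol_added_uL * 1e-3 * stock_cells_per_mL) /
#'   (culture_vol_mL + vol_added_uL * 1e-3)` cells/mL.
#' @param vol_added_uL inoculum volume, microlitres (> 0).
#' @param stock_cells_per_mL stock suspension density, cells/mL (> 0).
#' @param culture_vol_mL culture volume before inoculation, mL (> 0).
#' @export
inoculum_concentration <- function(vol_added_uL, stock_cells_per_mL,
                                   culture_vol_mL) {
  assert_that(is_number(vol_added_uL) && vol_added_uL > 0,
              "vol_added_uL must be > 0")
  assert_that(is_number(stock_cells_per_mL) && stock_cells_per_mL > 0,
              "stock_cells_per_mL must be > 0")
  assert_that(is_number(culture_vol_mL) && culture_vol_mL > 0,
              "culture_vol_mL must be > 0")
  (vol_added_uL * 1e-3 * stock_cells_per_mL) /
    (culture_vol_mL + vol_added_uL * 1e-3)
}

#' @describeIn expmath Width in ppm of a search window expressed in axis
#'   indices: `window_indices * ppm_per_index`. The default 10-index mapping
#'   window at ~2.9e-4 ppm/index is ~2.9e-3 ppm wide.
#' @param window_indices window width in axis points (> 0).
#' @param ppm_per_index axis resolution, ppm per point (> 0).
#' @export
index_window_to_ppm <- function(window_indices, ppm_per_index) {
  assert_that(is_number(window_indices) && window_indices > 0,
              "window_indices must be > 0")
  assert_that(is_number(ppm_per_index) && ppm_per_index > 0,
              "ppm_per_index must be > 0")
  window_indices * ppm_per_index
}
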