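#' Fit a cubic chemical-shift-versus-pH titration curve
#'
#' Fits `ppm = a0 + a1*pH + a2*pH^2 + a3*pH^3` by least squares to a
#' titration table of a standard (typically the most upfield citrate peak
#' position at each measured pH). The fitted polynomial must be strictly
#' monotone over the calibrated pH range — that is what makes the numeric
#' inversion in [ppm_to_ph()] well defined; a non-monotone fit is a
#' calibration error, not a warning.
#'
#' @param ph numeric vector of measured pH values (>= 4 distinct).
#' @param ppm numeric vector of peak positions, one per pH.
#' @return A `titration_curve`: list with `ph`, `ppm`, `coeffs`
#'   (a0..a3), `r_squared` and `ph_range`.
#' @export
fit_titration <- function(ph, ppm) {
  assert_that(is.numeric(ph) && is.numeric(ppm) && length(ph) == length(ppm),
              "ph and ppm must be equal-length numeric vectors")
  assert_that(length(unique(ph)) >= 4,
              "need at least 4 distinct pH points for a cubic fit")
  fit <- stats::lm(ppm ~ stats::poly(ph, 3, raw = TRUE))
  coeffs <- unname(stats::coef(fit))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ppm - mean(ppm))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  rng <- range(ph)
  # derivative sign over a fine grid of the calibrated range
  grid <- seq(rng[1], rng[2], length.out = 512)
  deriv <- coeffs[2] + 2 * coeffs[3] * grid + 3 * coeffs[4] * grid^2
  if (!(all(deriv > 0) || all(deriv < 0)))
    stop_civm("fitted cubic is not strictly monotone over the pH range",
              "civmtrace_calibration_error")
  structure(list(ph = ph, ppm = ppm, coeffs = coeffs, r_squared = r2,
                 ph_range = rng),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("<titration_curve> pH [%.2f, %.2f], R^2 = %.5f\n",
              x$ph_range[1], x$ph_range[2], x$r_squared))
  cat("ppm =", paste(sprintf("%+.5g pH^%d", x$coeffs, 0:3), collapse = " "),
      "\n")
  invisible(x)
}

#' Evaluate a titration curve at given pH values
#'
#' @param curve a `titration_curve` from [fit_titration()].
#' @param ph pH values.
#' @return Predicted peak positions, ppm.
#' @export
titration_ppm <- function(curve, ph) {
  a <- curve$coeffs
  a[1] + a[2] * ph + a[3] * ph^2 + a[4] * ph^3
}

#' Estimate pH from a peak-position trajectory
#'
#' Inverts the calibrated cubic for each observed peak position by bisection
#' on the calibrated pH range (the curve's monotonicity guarantees a unique
#' root) to a tolerance of 1e-6 pH. Positions outside the ppm span the curve
#' covers are an error — no extrapolation beyond the titrated range.
#'
#' @param curve a `titration_curve` from [fit_titration()].
#' @param ppm_trajectory numeric vector of per-timepoint peak positions
#'   (e.g. the `ppm` column of a traced ridge).
#' @param tol bisection tolerance in pH units, default 1e-6.
#' @return Numeric vector of pH estimates, one per input position.
#' @export
ppm_to_ph <- function(curve, ppm_trajectory, tol = 1e-6) {
  assert_that(inherits(curve, "titration_curve"),
              "curve must be a titration_curve")
  lo <- curve$ph_range[1]; hi <- curve$ph_range[2]
  f_lo <- titration_ppm(curve, lo); f_hi <- titration_ppm(curve, hi)
  span <- sort(c(f_lo, f_hi))
  vapply(seq_along(ppm_trajectory), function(i) {
    target <- ppm_trajectory[i]
    if (is.na(target) || target < span[1] || target > span[2])
      stop_civm(sprintf(
        "ppm %.5f at timepoint %d is outside the calibrated span [%.5f, %.5f]",
        target, i, span[1], span[2]), "civmtrace_range_error")
    a <- lo; b <- hi
    fa <- f_lo - target
    if (fa == 0) return(a)
    if (f_hi - target == 0) return(b)
    while (b - a > tol) {
      m <- (a + b) / 2
      fm <- titration_ppm(curve, m) - target
      if (fm == 0) return(m)
      if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else b <- m
    }
    (a + b) / 2
  }, numeric(1))
}

#' Read a two-column titration table
#'
#' @param path CSV file with columns `ph` and `ppm` (header required).
#' @return data.frame with numeric `ph` and `ppm`.
#' @export
read_titration <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path),
              "civmtrace_io_error")
  d <- utils::read.csv(path)
  assert_that(all(c("ph", "ppm") %in% names(d)),
              "titration table needs columns 'ph' and 'ppm'",
              "civmtrace_io_error")
  d[, c("ph", "ppm")]
}
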