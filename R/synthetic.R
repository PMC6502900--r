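#' Synthetic peak specification
#'
#' Declares one simulated resonance: its lineshape, width, how its centre
#' drifts and how its height evolves. Heights are specified as peak height
#' (not area), matching the maximum-based quantification used downstream.
#' Several peaks may share a `compound` and an amplitude trajectory while
#' differing in `response_factor`, emulating a multiplet whose components
#' report the same concentration with different sensitivities.
#'
#' @param name peak name (unique within a spec).
#' @param center centre trajectory: one of
#'   `list(type = "constant", ppm =)`,
#'   `list(type = "linear", start =, end =)`,
#'   `list(type = "sigmoid", start =, end =, midpoint_h =, steepness =)`
#'   (a pH-like sigmoidal drift), or
#'   `list(type = "ph_schedule", ph_start =, ph_end =, midpoint_h =,
#'   steepness =, coeffs =)` where `coeffs` are cubic ppm-vs-pH
#'   coefficients: the centre follows a sigmoidal pH schedule mapped through
#'   the titration cubic.
#' @param amplitude height trajectory: one of
#'   `list(type = "constant", value =)`,
#'   `list(type = "logistic_growth", L =, k =, t0 =, floor = 0)`,
#'   `list(type = "logistic_depletion", L =, k =, t0 =, floor = 0)`
#'   (e.g. glucose falling to ~0 around its midpoint), or
#'   `list(type = "exp_decay", A0 =, rate =, floor = 0)`.
#' @param fwhm full width at half maximum, ppm (> 0).
#' @param lineshape `"lorentzian"` (default), `"gaussian"` or
#'   `"pseudo_voigt"`.
#' @param eta Lorentzian fraction for the pseudo-Voigt mixture, in \[0, 1\].
#' @param compound compound this peak reports on; defaults to `name`.
#' @param response_factor multiplier relating the compound concentration
#'   trajectory to this peak's height (> 0, default 1).
#' @return A list of class `synthetic_peak`.
#' @export
synthetic_peak <- function(name, center, amplitude, fwhm = 0.005,
                           lineshape = c("lorentzian", "gaussian",
                                         "pseudo_voigt"),
                           eta = 0.5, compound = name, response_factor = 1) {
  lineshape <- match.arg(lineshape)
  assert_that(is_number(fwhm) && fwhm > 0, "fwhm must be > 0")
  assert_that(is_number(response_factor) && response_factor > 0,
              "response_factor must be > 0")
  assert_that(is.list(center) && !is.null(center$type),
              "center must be a trajectory list with a 'type'")
  assert_that(is.list(amplitude) && !is.null(amplitude$type),
              "amplitude must be a trajectory list with a 'type'")
  structure(list(name = name, center = center, amplitude = amplitude,
                 fwhm = fwhm, lineshape = lineshape, eta = eta,
                 compound = compound, response_factor = response_factor),
            class = "synthetic_peak")
}

sigmoid01 <- function(t, midpoint, steepness) {
  1 / (1 + exp(-steepness * (t - midpoint)))
}

eval_center <- function(center, t, duration_h) {
  switch(center$type,
    constant = rep(center$ppm, length(t)),
    linear = center$start + (center$end - center$start) * t / duration_h,
    sigmoid = center$start + (center$end - center$start) *
      sigmoid01(t, center$midpoint_h, center$steepness),
    ph_schedule = {
      ph <- center$ph_start + (center$ph_end - center$ph_start) *
        sigmoid01(t, center$midpoint_h, center$steepness)
      a <- center$coeffs
      a[1] + a[2] * ph + a[3] * ph^2 + a[4] * ph^3
    },
    stop_civm(paste("unknown center trajectory type:", center$type),
              "civmtrace_spec_error")
  )
}

eval_amplitude <- function(amplitude, t) {
  fl <- amplitude$floor %||% 0
  a <- switch(amplitude$type,
    constant = rep(amplitude$value, length(t)),
    logistic_growth = fl + amplitude$L /
      (1 + exp(-amplitude$k * (t - amplitude$t0))),
    logistic_depletion = fl + amplitude$L /
      (1 + exp(amplitude$k * (t - amplitude$t0))),
    exp_decay = fl + amplitude$A0 * exp(-amplitude$rate * t),
    stop_civm(paste("unknown amplitude trajectory type:", amplitude$type),
              "civmtrace_spec_error")
  )
  assert_that(all(a >= 0), "amplitudes must be >= 0 at all times")
  a
}

#' Evaluate a height-normalised lineshape on a ppm axis
#'
#' Lorentzian, Gaussian and pseudo-Voigt profiles parameterised by height:
#' the value at the centre equals `amplitude` and the value one half-width
#' from the centre equals `amplitude / 2`.
#'
#' @param lineshape `"lorentzian"`, `"gaussian"` or `"pseudo_voigt"`.
#' @param center centre position, ppm.
#' @param fwhm full width at half maximum, ppm (> 0).
#' @param amplitude peak height.
#' @param axis ppm axis to evaluate on.
#' @param eta Lorentzian fraction for pseudo-Voigt.
#' @return Intensity vector along `axis`.
#' @export
peak_profile <- function(lineshape, center, fwhm, amplitude, axis,
                         eta = 0.5) {
  assert_that(is_number(fwhm) && fwhm > 0, "fwhm must be > 0")
  hw <- fwhm / 2
  d <- axis - center
  lor <- function() hw^2 / (d^2 + hw^2)
  gau <- function() exp(-log(2) * (d / hw)^2)
  shape <- switch(lineshape,
    lorentzian = lor(),
    gaussian = gau(),
    pseudo_voigt = eta * lor() + (1 - eta) * gau(),
    stop_civm(paste("unknown lineshape:", lineshape), "civmtrace_spec_error"))
  amplitude * shape
}

#' Synthetic spectral-series specification
#'
#' Declares a full simulated CIVM-NMR series: the peaks, the axis geometry,
#' the acquisition cadence, the constant DSS reference peak at 0 ppm, an
#' optional polynomial baseline and the additive noise level. Defaults
#' mirror a typical acquisition: 4.23-min spacing over 11 h at ~2.9e-4
#' ppm/point resolution.
#'
#' @param peaks list of [synthetic_peak] objects.
#' @param ppm_range closed ppm interval of the axis.
#' @param n_points axis points (>= 64); default from `ppm_range` at
#'   2.9e-4 ppm/point.
#' @param duration_h experiment length, hours.
#' @param spacing_min time between spectra, minutes (default 4.23).
#' @param dss_amplitude height of the constant DSS peak at 0 ppm.
#' @param dss_fwhm width of the DSS peak, ppm.
#' @param noise_sd additive Gaussian noise standard deviation (relative
#'   units; 0 for noiseless simulations).
#' @param baseline optional numeric polynomial coefficients (b0, b1, ...)
#'   evaluated in ppm and added to every spectrum.
#' @param seed default RNG seed used by [simulate_series()].
#' @return A list of class `synthetic_series_spec`.
#' @export
synthetic_series_spec <- function(peaks, ppm_range = c(-0.5, 10),
                                  n_points = NULL, duration_h = 11,
                                  spacing_min = 4.23, dss_amplitude = 1,
                                  dss_fwhm = 0.002, noise_sd = 0,
                                  baseline = NULL, seed = 1L) {
  ppm_range <- as_interval(ppm_range)
  if (is.null(n_points))
    n_points <- as.integer(round(diff(ppm_range) / 2.9e-4)) + 1L
  problems <- character()
  if (!(is_number(n_points) && n_points >= 64))
    problems <- c(problems, "n_points must be >= 64")
  if (!(is_number(duration_h) && duration_h > 0))
    problems <- c(problems, "duration_h must be > 0")
  if (!(is_number(spacing_min) && spacing_min > 0))
    problems <- c(problems, "spacing_min must be > 0")
  if (!(is_number(dss_amplitude) && dss_amplitude > 0))
    problems <- c(problems, "dss_amplitude must be > 0")
  if (!(is_number(noise_sd) && noise_sd >= 0))
    problems <- c(problems, "noise_sd must be >= 0")
  if (!all(vapply(peaks, inherits, logical(1), "synthetic_peak")))
    problems <- c(problems, "peaks must be synthetic_peak objects")
  if (length(problems))
    stop_civm(paste("invalid synthetic series spec:",
                    paste(problems, collapse = "; ")),
              "civmtrace_spec_error")
  structure(list(peaks = peaks, ppm_range = ppm_range,
                 n_points = as.integer(n_points), duration_h = duration_h,
                 spacing_min = spacing_min, dss_amplitude = dss_amplitude,
                 dss_fwhm = dss_fwhm, noise_sd = noise_sd,
                 baseline = baseline, seed = seed),
            class = "synthetic_series_spec")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate a spectral time series with ground truth
#'
#' Generates `floor(duration_h * 60 / spacing_min) + 1` spectra at the
#' specified cadence. Each spectrum is the sum of the peak profiles at that
#' time's true centres and heights, a constant DSS reference peak at 0 ppm,
#' the optional baseline, and seeded i.i.d. Gaussian noise. The same seed
#' always yields a bitwise-identical series.
#'
#' @param spec a [synthetic_series_spec].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return List with `series` (a [spectrum_series]) and `truth`: a list of
#'   `peaks` (per peak per timepoint: true centre and height) and
#'   `concentrations` (per compound per timepoint: the underlying
#'   concentration trajectory, before response factors).
#' @export
simulate_series <- function(spec, seed = spec$seed) {
  assert_that(inherits(spec, "synthetic_series_spec"),
              "spec must be a synthetic_series_spec")
  T_n <- as.integer(floor(spec$duration_h * 60 / spec$spacing_min)) + 1L
  times <- (seq_len(T_n) - 1L) * spec$spacing_min / 60
  axis <- seq(spec$ppm_range[1], spec$ppm_range[2],
              length.out = spec$n_points)

  truth_peaks <- vector("list", length(spec$peaks))
  mat <- matrix(0, T_n, spec$n_points)
  for (k in seq_along(spec$peaks)) {
    pk <- spec$peaks[[k]]
    centers <- eval_center(pk$center, times, spec$duration_h)
    conc <- eval_amplitude(pk$amplitude, times)
    heights <- pk$response_factor * conc
    for (t in seq_len(T_n)) {
      mat[t, ] <- mat[t, ] + peak_profile(pk$lineshape, centers[t], pk$fwhm,
                                          heights[t], axis, pk$eta)
    }
    truth_peaks[[k]] <- data.frame(
      name = pk$name, compound = pk$compound, time_index = seq_len(T_n),
      time_h = times, center_ppm = centers, amplitude = heights,
      concentration = conc)
  }
  # constant DSS anchor at 0 ppm
  dss <- peak_profile("lorentzian", 0, spec$dss_fwhm, spec$dss_amplitude,
                      axis)
  mat <- mat + matrix(dss, T_n, spec$n_points, byrow = TRUE)
  if (!is.null(spec$baseline)) {
    b <- Reduce(`+`, lapply(seq_along(spec$baseline),
                            function(i) spec$baseline[i] * axis^(i - 1)))
    mat <- mat + matrix(b, T_n, spec$n_points, byrow = TRUE)
  }
  if (spec$noise_sd > 0) {
    mat <- mat + with_seed(seed,
      matrix(stats::rnorm(T_n * spec$n_points, sd = spec$noise_sd),
             T_n, spec$n_points))
  }
  tp <- do.call(rbind, truth_peaks)
  conc <- unique(tp[, c("compound", "time_index", "time_h", "concentration")])
  series <- spectrum_series(mat, axis, times,
                            meta = list(sample_id = "synthetic",
                                        history = "simulate_series"))
  list(series = series,
       truth = list(peaks = tp, concentrations = conc))
}

# cubic ppm-vs-pH coefficients of the synthetic citrate titration fixture
# (monotone decreasing in ppm over pH 4-8)
fixture_citrate_coeffs <- function() c(2.9, -0.05, -0.004, 2e-4)

#' Synthetic citrate titration table
#'
#' A noiseless (pH, ppm) table generated from a fixed monotone cubic,
#' standing in for an in-house citrate titration (which is
#' instrument-specific). Used by the `"ph_drift_citrate"` fixture, whose
#' peak drift follows the same cubic, so fitting this table and inverting
#' the traced ridge recovers the declared pH schedule.
#'
#' @param ph pH grid, default `seq(4, 8, by = 0.25)`.
#' @return data.frame with columns `ph` and `ppm`.
#' @export
fixture_citrate_titration <- function(ph = seq(4, 8, by = 0.25)) {
  a <- fixture_citrate_coeffs()
  data.frame(ph = ph, ppm = a[1] + a[2] * ph + a[3] * ph^2 + a[4] * ph^3)
}

#' Standard synthetic fixtures
#'
#' Named [synthetic_series_spec] presets covering the scenarios the pipeline
#' must handle:
#' \describe{
#'   \item{two_drifting_peaks}{two well-separated peaks with small sigmoidal
#'     drifts (<= 0.03 ppm over 11 h) and smooth height trajectories; the
#'     reference case for ridge-tracing recovery.}
#'   \item{glucose_ethanol}{a glucose-like compound (two peaks, differing
#'     response factors) depleting logistically around 6 h and an
#'     ethanol-like compound (two peaks) rising inversely; the compositing
#'     and end-to-end case.}
#'   \item{ph_drift_citrate}{a citrate-like peak whose centre follows a
#'     sigmoidal pH schedule (6.3 to 5.3, midpoint 3 h) mapped through the
#'     fixture titration cubic; the pH-estimation case.}
#'   \item{crowded_region}{two heavily overlapped peaks closer than their
#'     linewidth; the documented failure mode of maximum-based tracing.}
#' }
#'
#' @return Named list of [synthetic_series_spec] objects.
#' @export
standard_fixtures <- function() {
  list(
    two_drifting_peaks = synthetic_series_spec(
      peaks = list(
        synthetic_peak("peakA",
          center = list(type = "sigmoid", start = 3.00, end = 2.975,
                        midpoint_h = 4, steepness = 0.8),
          amplitude = list(type = "logistic_depletion", L = 3, k = 0.8,
                          t0 = 6, floor = 2),
          fwhm = 0.006),
        synthetic_peak("peakB",
          center = list(type = "sigmoid", start = 2.80, end = 2.78,
                        midpoint_h = 5, steepness = 1.0),
          amplitude = list(type = "logistic_growth", L = 4, k = 1.2,
                          t0 = 5, floor = 1),
          fwhm = 0.006)),
      ppm_range = c(-0.5, 4), noise_sd = 0.02, seed = 101L),
    glucose_ethanol = synthetic_series_spec(
      peaks = list(
        synthetic_peak("glc_5.22", compound = "glucose",
          center = list(type = "constant", ppm = 5.22),
          amplitude = list(type = "logistic_depletion", L = 8, k = 1.2,
                          t0 = 6),
          fwhm = 0.005, response_factor = 1),
        synthetic_peak("glc_3.45", compound = "glucose",
          center = list(type = "constant", ppm = 3.45),
          amplitude = list(type = "logistic_depletion", L = 8, k = 1.2,
                          t0 = 6),
          fwhm = 0.005, response_factor = 0.6),
        synthetic_peak("etoh_1.19", compound = "ethanol",
          center = list(type = "constant", ppm = 1.19),
          amplitude = list(type = "logistic_growth", L = 6, k = 1.2,
                          t0 = 6),
          fwhm = 0.005, response_factor = 1),
        synthetic_peak("etoh_3.66", compound = "ethanol",
          center = list(type = "constant", ppm = 3.66),
          amplitude = list(type = "logistic_growth", L = 6, k = 1.2,
                          t0 = 6),
          fwhm = 0.005, response_factor = 0.4)),
      ppm_range = c(-0.5, 6), noise_sd = 0.01, seed = 102L),
    ph_drift_citrate = synthetic_series_spec(
      peaks = list(
        synthetic_peak("citrate_upfield", compound = "citrate",
          center = list(type = "ph_schedule", ph_start = 6.3, ph_end = 5.3,
                        midpoint_h = 3, steepness = 1.2,
                        coeffs = fixture_citrate_coeffs()),
          amplitude = list(type = "constant", value = 4),
          fwhm = 0.005)),
      ppm_range = c(-0.5, 4), noise_sd = 0.005, seed = 103L),
    crowded_region = synthetic_series_spec(
      peaks = list(
        synthetic_peak("overlapA",
          center = list(type = "constant", ppm = 1.500),
          amplitude = list(type = "constant", value = 3),
          fwhm = 0.010),
        synthetic_peak("overlapB",
          center = list(type = "sigmoid", start = 1.504, end = 1.496,
                        midpoint_h = 5, steepness = 1),
          amplitude = list(type = "constant", value = 2.5),
          fwhm = 0.010)),
      ppm_range = c(-0.5, 3), noise_sd = 0.02, seed = 104L)
  )
}

#' Read a synthetic series spec from YAML
#'
#' YAML mirror of [synthetic_series_spec()]: top-level keys are the
#' constructor arguments; `peaks` is a list of mappings mirroring
#' [synthetic_peak()].
#'
#' @param path YAML file path.
#' @return A [synthetic_series_spec].
#' @export
read_series_spec_yaml <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path),
              "civmtrace_io_error")
  y <- yaml::read_yaml(path)
  peaks <- lapply(y$peaks, function(p) do.call(synthetic_peak, p))
  y$peaks <- peaks
  if (!is.null(y$ppm_range)) y$ppm_range <- as.numeric(y$ppm_range)
  do.call(synthetic_series_spec, y)
}
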