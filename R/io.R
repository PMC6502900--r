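#' Write a spectrum series to a delimited text file
#'
#' Plain interchange layout: one header row (`time_h` followed by the ppm
#' axis), then one row per timepoint (`time_h` followed by the intensities).
#' Numbers are written with 17 significant digits so the round trip through
#' [read_series_delim()] is bitwise exact.
#'
#' @param series a [spectrum_series].
#' @param path output file path.
#' @param sep field separator, default tab.
#' @return `path`, invisibly.
#' @export
write_series_delim <- function(series, path, sep = "\t") {
  assert_that(inherits(series, "spectrum_series"), "series must be a spectrum_series")
  fmt <- function(x) sprintf("%.17g", x)
  header <- paste(c("time_h", fmt(series$ppm)), collapse = sep)
  rows <- vapply(seq_len(n_times(series)), function(i) {
    paste(c(fmt(series$times_h[i]), fmt(series$intensities[i, ])),
          collapse = sep)
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read a spectrum series from a delimited text file
#'
#' Counterpart of [write_series_delim()]. The axis is canonicalised to
#' descending ppm on load.
#'
#' @param path file path.
#' @param sep field separator, default tab (use "," for CSV).
#' @return A [spectrum_series].
#' @export
read_series_delim <- function(path, sep = "\t") {
  assert_that(file.exists(path), paste("no such file:", path), "civmtrace_io_error")
  dt <- data.table::fread(path, sep = sep, header = FALSE,
                          colClasses = "character", data.table = FALSE)
  assert_that(nrow(dt) >= 2 && ncol(dt) >= 2,
              "series file must have a ppm header row and >= 1 spectrum row",
              "civmtrace_io_error")
  ppm <- as.numeric(dt[1, -1])
  times <- as.numeric(dt[-1, 1])
  mat <- matrix(as.numeric(as.matrix(dt[-1, -1, drop = FALSE])),
                nrow = nrow(dt) - 1L)
  spectrum_series(mat, ppm, times)
}

trajectory_columns <- c("id", "type", "annotation", "time_index", "time_h",
                        "ppm_index", "ppm", "intensity", "smoothed_intensity",
                        "interpolated", "n_contributing")

#' Write ridges and compound trajectories to a long-format TSV
#'
#' One row per (trajectory, timepoint). Ridges carry their raw (mapped)
#' intensity in the `intensity` column plus smoothed intensity and axis
#' indices; composite compound trajectories carry the composite value and the
#' per-time contributing-ridge count. [read_trajectories()] reconstructs the
#' objects losslessly.
#'
#' @param trajectories non-empty list of [ridge] and/or
#'   [compound_trajectory] objects (a single object is accepted).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  if (inherits(trajectories, c("ridge", "compound_trajectory")))
    trajectories <- list(trajectories)
  assert_that(length(trajectories) >= 1L, "no trajectories to write",
              "civmtrace_empty_error")
  rows <- lapply(trajectories, function(tr) {
    if (inherits(tr, "ridge")) {
      p <- tr$points
      data.frame(id = tr$id, type = "ridge",
                 annotation = tr$annotation %||% "unknown",
                 time_index = p$time_index, time_h = p$time_h,
                 ppm_index = p$ppm_index, ppm = p$ppm,
                 intensity = p$raw_intensity,
                 smoothed_intensity = p$smoothed_intensity,
                 interpolated = p$interpolated,
                 n_contributing = NA_integer_)
    } else if (inherits(tr, "compound_trajectory")) {
      data.frame(id = tr$compound, type = "compound",
                 annotation = tr$compound,
                 time_index = NA_integer_, time_h = tr$times_h,
                 ppm_index = NA_integer_, ppm = NA_real_,
                 intensity = tr$value, smoothed_intensity = NA_real_,
                 interpolated = FALSE, n_contributing = tr$n_contributing)
    } else {
      stop_civm("trajectories must be ridge or compound_trajectory objects",
                "civmtrace_type_error")
    }
  })
  out <- do.call(rbind, rows)
  for (col in c("time_h", "ppm", "intensity", "smoothed_intensity"))
    out[[col]] <- sprintf("%.17g", out[[col]])
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read ridges / compound trajectories written by [write_trajectories()]
#'
#' @param path TSV path.
#' @return A list of [ridge] and [compound_trajectory] objects, in file order.
#' @export
read_trajectories <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path), "civmtrace_io_error")
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE, na.strings = "NA")
  assert_that(all(trajectory_columns %in% names(dt)),
              "not a civmtrace trajectory table", "civmtrace_io_error")
  lapply(split(dt, factor(dt$id, levels = unique(dt$id))), function(g) {
    if (g$type[1] == "ridge") {
      new_ridge(
        id = g$id[1],
        points = data.frame(
          time_index = as.integer(g$time_index), time_h = as.numeric(g$time_h),
          ppm_index = as.integer(g$ppm_index), ppm = as.numeric(g$ppm),
          smoothed_intensity = as.numeric(g$smoothed_intensity),
          raw_intensity = as.numeric(g$intensity),
          interpolated = as.logical(g$interpolated)),
        annotation = g$annotation[1])
    } else {
      new_compound_trajectory(
        compound = g$annotation[1], ridge_ids = character(),
        scale_factors = numeric(), support = numeric(),
        times_h = as.numeric(g$time_h), value = as.numeric(g$intensity),
        n_contributing = as.integer(g$n_contributing))
    }
  })
}

# ---- NMRPipe 1D frequency-domain files -------------------------------------

# Header word offsets (0-based) in the 512-float NMRPipe header.
FD <- list(MAGIC = 0L, FLTFORMAT = 2L, FLTORDER = 3L, DIMCOUNT = 9L,
           QUADFLAG = 106L, SIZE = 99L, F2SW = 100L, F2ORIG = 101L,
           F2OBS = 119L, F2FTFLAG = 220L, F2QUADFLAG = 56L)

#' Read a 1D NMRPipe frequency-domain spectrum
#'
#' Minimal reader for single-file 1D real spectra: a 512-float32 header
#' followed by the data points. The ppm axis is reconstructed from the
#' spectral width, observe frequency and origin words
#' (`ppm[i] = (ORIG + (N - i) * SW / N) / OBS` for 1-based `i`), giving the
#' conventional descending axis. Time-domain files (FT flag unset) are
#' rejected: this package consumes transformed spectra only.
#'
#' @param path path to a `.ft`-style file.
#' @return List with `ppm`, `intensity` and `header` (named numeric vector).
#' @export
read_nmrpipe_1d <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path), "civmtrace_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "numeric", n = 512L, size = 4L, endian = "little")
  if (!isTRUE(abs(hdr[FD$FLTORDER + 1L] - 2.345) < 1e-4))
    stop_civm("not an NMRPipe file in native byte order", "civmtrace_parse_error")
  if (hdr[FD$F2FTFLAG + 1L] != 1)
    stop_civm("time-domain (FID) data: only frequency-domain input is supported",
              "civmtrace_fid_error")
  n <- as.integer(hdr[FD$SIZE + 1L])
  assert_that(n >= 1, "empty spectrum", "civmtrace_parse_error")
  y <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  sw <- hdr[FD$F2SW + 1L]; obs <- hdr[FD$F2OBS + 1L]; orig <- hdr[FD$F2ORIG + 1L]
  assert_that(obs > 0, "observe frequency missing from header",
              "civmtrace_parse_error")
  ppm <- (orig + (n - seq_len(n)) * sw / n) / obs
  list(ppm = ppm, intensity = y,
       header = stats::setNames(hdr[unlist(FD) + 1L], names(FD)))
}

#' Write a 1D spectrum as an NMRPipe frequency-domain file
#'
#' Inverse of [read_nmrpipe_1d()] for a uniformly spaced descending ppm axis.
#' Intensities are stored as float32, so round trips are exact only to
#' single precision.
#'
#' @param ppm descending, uniformly spaced chemical-shift axis.
#' @param intensity intensity vector, same length as `ppm`.
#' @param path output path.
#' @param obs_mhz observe (spectrometer) frequency in MHz used to convert
#'   ppm to Hz; default 600.
#' @return `path`, invisibly.
#' @export
write_nmrpipe_1d <- function(ppm, intensity, path, obs_mhz = 600) {
  assert_that(length(ppm) == length(intensity) && length(ppm) >= 2,
              "ppm and intensity must be equal-length vectors (>= 2 points)")
  step <- diff(ppm)
  assert_that(all(step < 0) && diff(range(step)) < 1e-9 * max(abs(step)),
              "ppm axis must be descending and uniformly spaced")
  n <- length(ppm)
  sw_hz <- (ppm[1] - ppm[n]) * obs_mhz * n / (n - 1)  # SW spans N steps
  orig <- ppm[n] * obs_mhz
  hdr <- numeric(512L)
  hdr[FD$FLTFORMAT + 1L] <- 4008636160
  hdr[FD$FLTORDER + 1L] <- 2.345
  hdr[FD$DIMCOUNT + 1L] <- 1
  hdr[FD$QUADFLAG + 1L] <- 1
  hdr[FD$F2QUADFLAG + 1L] <- 1
  hdr[FD$SIZE + 1L] <- n
  hdr[FD$F2SW + 1L] <- sw_hz
  hdr[FD$F2ORIG + 1L] <- orig
  hdr[FD$F2OBS + 1L] <- obs_mhz
  hdr[FD$F2FTFLAG + 1L] <- 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con, size = 4L, endian = "little")
  writeBin(as.numeric(intensity), con, size = 4L, endian = "little")
  invisible(path)
}
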