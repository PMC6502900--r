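#' Acquisition metadata record
#'
#' Per-spectrum acquisition metadata, typically harvested from a Bruker
#' `acqus` parameter file. Only `start_clock` and `n_scans` are mandatory;
#' fields that the source file does not carry are `NA`, never guessed.
#'
#' @param start_clock absolute acquisition start time, seconds since epoch.
#' @param n_scans number of summed scans (>= 1).
#' @param n_dummy_scans dummy (steady-state) scans, not recorded.
#' @param acquisition_time_s FID acquisition time per scan, seconds.
#' @param recycle_delay_s relaxation delay per scan, seconds.
#' @param pulse_width_us excitation pulse width, microseconds.
#' @param offset_ppm transmitter (water) offset, ppm.
#' @param spin_rate_hz MAS spinning rate, Hz.
#' @param label free-text label (e.g. pulse program name).
#' @return An object of class `acquisition_record`.
#' @export
acquisition_record <- function(start_clock, n_scans, n_dummy_scans = NA_real_,
                               acquisition_time_s = NA_real_,
                               recycle_delay_s = NA_real_,
                               pulse_width_us = NA_real_,
                               offset_ppm = NA_real_, spin_rate_hz = NA_real_,
                               label = NA_character_) {
  assert_that(is_number(start_clock), "start_clock must be a finite timestamp")
  assert_that(is_number(n_scans) && n_scans >= 1, "n_scans must be >= 1")
  for (d in list(n_dummy_scans, acquisition_time_s, recycle_delay_s,
                 pulse_width_us)) {
    assert_that(is.na(d) || (is_number(d) && d >= 0),
                "durations and counts must be >= 0")
  }
  structure(
    list(start_clock = start_clock, n_scans = n_scans,
         n_dummy_scans = n_dummy_scans, acquisition_time_s = acquisition_time_s,
         recycle_delay_s = recycle_delay_s, pulse_width_us = pulse_width_us,
         offset_ppm = offset_ppm, spin_rate_hz = spin_rate_hz, label = label),
    class = "acquisition_record"
  )
}

#' @export
print.acquisition_record <- function(x, ...) {
  cat(sprintf("<acquisition_record> start=%.0f s, NS=%g, P1=%g us\n",
              x$start_clock, x$n_scans, x$pulse_width_us))
  invisible(x)
}

# Parse the JCAMP-like `##$KEY= value` dialect of Bruker parameter files
# into a named list. Array parameters ("##$P= (0..63)" followed by value
# lines) become numeric vectors.
parse_bruker_params <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[[i]]
    m <- regmatches(ln, regexec("^##\\$?([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      key <- m[2]; val <- trimws(m[3])
      if (startsWith(val, "(")) {            # array: values on following lines
        vals <- character()
        j <- i + 1L
        while (j <= length(lines) && !startsWith(lines[[j]], "##")) {
          vals <- c(vals, lines[[j]]); j <- j + 1L
        }
        out[[key]] <- suppressWarnings(
          as.numeric(unlist(strsplit(trimws(paste(vals, collapse = " ")),
                                     "\\s+"))))
        i <- j
        next
      }
      num <- suppressWarnings(as.numeric(val))
      out[[key]] <- if (is.na(num)) gsub("^<|>$", "", val) else num
    }
    i <- i + 1L
  }
  out
}

#' Parse a Bruker acqus parameter file
#'
#' Reads the `##$KEY= value` parameter dialect and extracts the acquisition
#' metadata needed to time-stamp and document each spectrum of a series.
#' `DATE` (epoch seconds) and `NS` are required; everything else is optional
#' and left `NA` when absent. The acquisition time is derived as
#' `TD / (2 * SW_h)` when both the point count and the spectral width in Hz
#' are present, and the transmitter offset as `O1 / SFO1`.
#'
#' @param text character: either the file contents (single string or vector
#'   of lines) or a path to an acqus file.
#' @return An [acquisition_record].
#' @examples
#' rec <- parse_acqus(c("##$DATE= 1500000000", "##$NS= 64", "##$DS= 8"))
#' rec$n_scans
#' @export
parse_acqus <- function(text) {
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  p <- parse_bruker_params(text)
  if (is.null(p$DATE))
    stop_civm("acqus is missing DATE: cannot set start_clock",
              "civmtrace_parse_error")
  if (is.null(p$NS))
    stop_civm("acqus is missing NS: cannot set n_scans",
              "civmtrace_parse_error")
  aq <- if (!is.null(p$TD) && !is.null(p$SW_h) && p$SW_h > 0)
    p$TD / (2 * p$SW_h) else NA_real_
  acquisition_record(
    start_clock = p$DATE,
    n_scans = p$NS,
    n_dummy_scans = p$DS %||% NA_real_,
    acquisition_time_s = aq,
    recycle_delay_s = if (!is.null(p$D) && length(p$D) >= 2) p$D[2] else NA_real_,
    pulse_width_us = if (!is.null(p$P) && length(p$P) >= 2) p$P[2] else NA_real_,
    offset_ppm = if (!is.null(p$O1) && !is.null(p$SFO1) && p$SFO1 > 0)
      p$O1 / p$SFO1 else NA_real_,
    spin_rate_hz = p$MASR %||% NA_real_,
    label = if (!is.null(p$PULPROG)) as.character(p$PULPROG) else NA_character_
  )
}
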