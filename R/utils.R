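`%||%` <- function(x, y) if (is.null(x)) y else x

stop_civm <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "civmtrace_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_that <- function(cond, msg, class = "civmtrace_domain_error") {
  if (!isTRUE(cond)) stop_civm(msg, class)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# closed interval c(lo, hi); tolerant of reversed input from CLI strings
as_interval <- function(x) {
  assert_that(is.numeric(x) && length(x) == 2L && all(is.finite(x)),
              "interval must be two finite numbers")
  sort(x)
}
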