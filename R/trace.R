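#' Uniformly sampled time series
#'
#' A `trace` is the basic unit of electrophysiology I/O: a uniformly
#' sampled series of current (pA) or voltage (mV) values with a start
#' time and a sampling interval.
#'
#' @param values numeric vector of samples; must be finite.
#' @param dt sampling interval in seconds (default 1/20000, i.e. 20 kHz).
#' @param t0 time of the first sample in seconds.
#' @param units unit label, e.g. `"pA"` or `"mV"`.
#'
#' @return An object of class `trace` with fields `t0`, `dt`, `values`,
#'   `units`.
#' @examples
#' tr <- trace(sin(seq(0, 1, length.out = 100)), dt = 1e-3, units = "mV")
#' length(trace_times(tr))
#' @export
trace <- function(values, dt = 1 / 20000, t0 = 0, units = "pA") {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  values <- as.numeric(values)
  if (!all(is.finite(values))) {
    stop("trace values must be finite", call. = FALSE)
  }
  structure(
    list(t0 = as.numeric(t0), dt = dt, values = values, units = units),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf(
    "<trace> %d samples @ %.6g s (%.4g kHz), t0 = %.6g s, units = %s\n",
    length(x$values), x$dt, 1e-3 / x$dt, x$t0, x$units
  ))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param tr a [trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(tr) {
  stopifnot(inherits(tr, "trace"))
  tr$t0 + tr$dt * (seq_along(tr$values) - 1L)
}

#' Read / write traces as two-column delimited text
#'
#' The on-disk format is a header line naming the units
#' (`time_s,value_<units>`) followed by comma-separated `time, value`
#' rows. Time must be uniformly sampled.
#'
#' @param tr a [trace()].
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [trace()].
#' @export
write_trace <- function(tr, path) {
  stopifnot(inherits(tr, "trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("time_s,value_%s", tr$units), con)
  tt <- trace_times(tr)
  writeLines(sprintf("%.9g,%.9g", tt, tr$values), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  header <- readLines(path, n = 1L)
  units <- sub("^time_s,value_", "", header)
  d <- utils::read.csv(path, header = TRUE,
                       col.names = c("time_s", "value"))
  if (nrow(d) < 2L) stop("trace file needs at least two samples", call. = FALSE)
  dts <- diff(d$time_s)
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 1e-6 * dt + 1e-12) {
    stop("trace file is not uniformly sampled", call. = FALSE)
  }
  trace(d$value, dt = dt, t0 = d$time_s[1L], units = units)
}

# Internal: index of the sample nearest to time `t` (s), ties toward zero.
time_to_index <- function(tr, t) {
  i <- (t - tr$t0) / tr$dt
  # round half toward zero so onset snapping is reproducible across platforms
  1L + as.integer(sign(i) * floor(abs(i) + 0.5 - 1e-12))
}
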