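#' Construct a time course
#'
#' A sampled single-channel trace: strictly increasing times (seconds) and
#' one value per time. The channel label records what the values are:
#' `"F488"` (pyruvate-sensitive fluorescence, a.u.), `"F435"` (isosbestic
#' channel, a.u.), `"concentration"` (uM) or `"percent_max"`.
#'
#' @param times numeric, seconds, strictly increasing.
#' @param values numeric, same length as `times`.
#' @param channel channel label.
#' @return data.frame of class `time_course` with columns `time`, `value`
#'   and attribute `channel`.
#' @export
time_course <- function(times, values,
                        channel = c("F488", "F435", "concentration",
                                    "percent_max")) {
  channel <- match.arg(channel)
  if (length(times) != length(values))
    stop("time_course: 'times' and 'values' must have equal length",
         call. = FALSE)
  if (length(times) < 1L || any(!is.finite(times)) || any(diff(times) <= 0))
    stop("time_course: 'times' must be finite and strictly increasing",
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("time_course: 'values' must be finite", call. = FALSE)
  structure(data.frame(time = as.numeric(times), value = as.numeric(values)),
            channel = channel, class = c("time_course", "data.frame"))
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("Time course [%s]: %d samples, t = %g..%g s, value range %.4g..%.4g\n",
              attr(x, "channel"), nrow(x), min(x$time), max(x$time),
              min(x$value), max(x$value)))
  invisible(x)
}

# Indices of samples falling inside a closed [start, end] window.
.window_idx <- function(tc, window, what = "window", min_n = 1L) {
  if (length(window) != 2L || window[1] >= window[2])
    stop(what, " must be an increasing (start, end) pair", call. = FALSE)
  idx <- which(tc$time >= window[1] & tc$time <= window[2])
  if (length(idx) < min_n)
    stop(what, " contains ", length(idx), " samples; need >= ", min_n,
         call. = FALSE)
  idx
}

#' Read or write trace CSV files
#'
#' Trace files are plain CSV with a `time_s` column followed by one column
#' per region of interest.
#'
#' @param path CSV path.
#' @param channel channel label applied to all traces.
#' @return `read_trace_csv()`: named list of [time_course()] objects, one
#'   per non-time column. `write_trace_csv()` returns `path` invisibly.
#' @export
read_trace_csv <- function(path, channel = "F488") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop("read_trace_csv: file must have a 'time_s' column", call. = FALSE)
  roi <- setdiff(names(df), "time_s")
  stats::setNames(lapply(roi, function(nm)
    time_course(df$time_s, df[[nm]], channel = channel)), roi)
}

#' @rdname read_trace_csv
#' @param traces named list of [time_course()] objects on one common grid.
#' @export
write_trace_csv <- function(traces, path) {
  if (is.null(names(traces)) || any(names(traces) == ""))
    stop("write_trace_csv: 'traces' must be a named list", call. = FALSE)
  times <- traces[[1]]$time
  for (tc in traces) if (!isTRUE(all.equal(tc$time, times)))
    stop("write_trace_csv: all traces must share one time grid", call. = FALSE)
  df <- data.frame(time_s = times)
  for (nm in names(traces)) df[[nm]] <- traces[[nm]]$value
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
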