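# Plain-text I/O for signals and event series.

#' Read and write signals as CSV
#'
#' Signals are exchanged as two-column CSV files (`time_s`, `value`) with a
#' uniform time grid; the sampling interval is inferred from the time
#' column on reading.
#'
#' @param path CSV file path.
#' @param label Label for the returned signal (default: file name).
#' @return `read_signal_csv()` returns a [pc_signal];
#'   `write_signal_csv()` returns `path` invisibly.
#' @export
read_signal_csv <- function(path, label = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), value = readr::col_double()
  ))
  if (nrow(df) < 1) stop("empty signal file: ", path, call. = FALSE)
  dt <- if (nrow(df) > 1) stats::median(diff(df$time_s)) else 1
  pc_signal(df$value, dt = dt,
            label = label %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_signal_csv
#' @param x A [pc_signal].
#' @export
write_signal_csv <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Read event times (one value per line, seconds)
#'
#' @param path Text file with one strictly increasing event time per line.
#' @return Numeric vector of event times.
#' @export
read_event_times <- function(path) {
  ev <- scan(path, what = numeric(), quiet = TRUE)
  if (length(ev) < 2) stop("need at least 2 events in ", path, call. = FALSE)
  ev
}
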