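# Preprocessing of raw physiological inputs into 1 Hz node series.

#' Instantaneous rate series from event times
#'
#' Converts a strictly increasing sequence of event times (heart beats,
#' breath extrema) into a 1 Hz instantaneous-rate series: each
#' inter-event interval contributes the rate `1/interval`, placed at the
#' interval midpoint, and the step sequence is interpolated onto the
#' integer-second grid spanned by the events.
#'
#' @param events Numeric vector of event times in seconds, strictly
#'   increasing, length >= 2.
#' @param interp `"linear"` (default) or `"constant"`
#'   (previous-interval value).
#' @param label Label of the returned signal.
#' @return A [pc_signal] at 1 Hz covering
#'   `ceiling(first event) .. floor(last event)` seconds.
#' @examples
#' rate_from_events(0:60)          # constant 1 Hz heart rate
#' @export
rate_from_events <- function(events, interp = c("linear", "constant"),
                             label = "rate") {
  interp <- match.arg(interp)
  events <- as.numeric(events)
  if (length(events) < 2) stop("need at least 2 events", call. = FALSE)
  if (any(diff(events) <= 0)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  iv <- diff(events)
  rates <- 1 / iv
  mid <- events[-length(events)] + iv / 2
  grid <- seq(ceiling(events[1]), floor(events[length(events)]), by = 1)
  if (length(grid) < 1) {
    stop("events span less than one second of the integer grid",
         call. = FALSE)
  }
  vals <- if (length(rates) == 1) {
    rep(rates, length(grid))
  } else {
    stats::approx(mid, rates, xout = grid, method = interp, rule = 2,
                  f = 0)$y
  }
  pc_signal(vals, dt = 1, label = label)
}

# Analytic signal (FFT Hilbert transform): x + i * H[x]. The input is
# mirror-padded to a composite length to keep the FFT fast; the pad is
# dropped again before returning.
analytic_signal <- function(x) {
  n0 <- length(x)
  nf <- stats::nextn(n0, c(2L, 3L, 5L))
  if (nf > n0) {
    npad <- nf - n0
    pad <- x[seq(n0 - 1, by = -1, length.out = min(npad, n0 - 1))]
    if (length(pad) < npad) pad <- rep_len(c(pad, rev(pad)), npad)
    x <- c(x, pad)
  }
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  (stats::fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

#' EEG alpha-band amplitude at 1 Hz
#'
#' Band-passes a raw EEG trace in the alpha band (default 7.8-15.6 Hz) with
#' a zero-phase (forward-backward) 4th-order Butterworth filter, takes the
#' instantaneous amplitude, and averages it over non-overlapping one-second
#' windows.
#'
#' @param raw A [pc_signal] sampled at `fs = 1/dt`, or a numeric vector with
#'   `fs` given explicitly.
#' @param fs Sampling frequency in Hz; must exceed twice the upper band
#'   edge. Defaults to `1/dt` of `raw`.
#' @param band Length-2 pass band in Hz.
#' @param envelope `"analytic"` (default; magnitude of the analytic signal,
#'   which recovers the amplitude of an in-band sinusoid) or `"rectified"`
#'   (absolute value of the filtered trace; note its window mean is
#'   `2/pi` of the amplitude for a sinusoid).
#' @return A [pc_signal] at 1 Hz (one value per complete second). The first
#'   and last seconds carry filter edge effects.
#' @examples
#' fs <- 128
#' eeg <- pc_signal(2 * sin(2 * pi * 10 * (0:(10 * fs - 1)) / fs), dt = 1 / fs)
#' eeg_alpha_amplitude(eeg)$values
#' @export
eeg_alpha_amplitude <- function(raw, fs = NULL, band = c(7.8, 15.6),
                                envelope = c("analytic", "rectified")) {
  envelope <- match.arg(envelope)
  v <- sig_values(raw)
  if (is.null(fs)) fs <- 1 / sig_dt(raw)
  if (fs <= 2 * band[2]) {
    stop("sampling frequency too low for the requested band", call. = FALSE)
  }
  if (length(v) < 2 * fs) stop("need at least 2 s of data", call. = FALSE)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, v)
  env <- switch(envelope,
                analytic = Mod(analytic_signal(xf)),
                rectified = abs(xf))
  sec <- floor((seq_along(env) - 1) / fs)
  n_sec <- floor(length(env) / fs)
  keep <- sec < n_sec
  vals <- as.numeric(tapply(env[keep], sec[keep], mean))
  pc_signal(vals, dt = 1, label = "eeg_alpha")
}

#' Coarse-grain a series by non-overlapping block averaging
#'
#' @param x A [pc_signal] or numeric vector.
#' @param factor Block length in samples (>= 1); the output has
#'   `floor(n / factor)` samples (a trailing partial block is dropped) and
#'   sampling interval `dt * factor`.
#' @return A [pc_signal].
#' @examples
#' coarse_grain(c(1, 2, 3, 4), 2)$values  # 1.5, 3.5
#' @export
coarse_grain <- function(x, factor) {
  v <- sig_values(x)
  factor <- as.integer(factor)
  if (factor < 1) stop("`factor` must be >= 1", call. = FALSE)
  nb <- floor(length(v) / factor)
  if (nb < 1) stop("series shorter than one block", call. = FALSE)
  vals <- colMeans(matrix(v[seq_len(nb * factor)], nrow = factor))
  pc_signal(vals, dt = sig_dt(x) * factor, label = sig_label(x))
}

#' Read and map a hypnogram
#'
#' Reads one sleep-stage code per line (one 30 s epoch per line). Numeric
#' Rechtschaffen-Kales codes can be mapped: 0 -> W, 1-2 -> LS, 3-4 -> DS,
#' 5 (or R/REM) -> REM.
#'
#' @param path File with one code per epoch.
#' @param map_rk Map numeric R&K stage codes onto W/LS/DS/REM.
#' @return Character vector of stage codes.
#' @export
read_hypnogram <- function(path, map_rk = TRUE) {
  codes <- trimws(readLines(path, warn = FALSE))
  codes <- codes[codes != ""]
  if (map_rk) {
    rk <- c("0" = "W", "1" = "LS", "2" = "LS", "3" = "DS", "4" = "DS",
            "5" = "REM", "R" = "REM", "W" = "W", "LS" = "LS", "DS" = "DS",
            "REM" = "REM")
    unknown <- setdiff(unique(codes), names(rk))
    if (length(unknown)) {
      stop("unknown stage codes: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    codes <- unname(rk[codes])
  }
  codes
}

#' Partition a signal triple into standardized same-stage patches
#'
#' Cuts the aligned triple into maximal runs of identical sleep stage (30 s
#' epochs), drops wake runs, and standardizes each channel of each patch to
#' zero mean and unit variance. A patch is dropped (with a warning) when any
#' channel has zero variance or fewer than two samples fall inside the run.
#'
#' @param signals Named list of three equal-length [pc_signal]s or numeric
#'   vectors, all sampled at `resolution` seconds per sample.
#' @param hypnogram Character vector of stage codes, one per 30 s epoch,
#'   covering the signals.
#' @param resolution Seconds per sample; defaults to `dt` of the first
#'   signal. A sample is assigned to a run when its whole `[t, t +
#'   resolution)` interval lies inside the run.
#' @param exclude Stage codes to drop (default `"W"`).
#' @return A tibble with one row per surviving patch: `stage`, `start`,
#'   `end` (1-based inclusive sample indices), `start_s`, `end_s` (seconds,
#'   half-open), `n`, and a list-column `signals` holding the named list of
#'   standardized sample vectors.
#' @export
partition_by_stage <- function(signals, hypnogram, resolution = NULL,
                               exclude = "W") {
  vs <- lapply(signals, sig_values)
  n <- length(vs[[1]])
  if (any(vapply(vs, length, 1L) != n)) {
    stop("all series must have equal length", call. = FALSE)
  }
  if (is.null(resolution)) resolution <- sig_dt(signals[[1]])
  if (n * resolution > length(hypnogram) * 30 + 1e-9) {
    stop("hypnogram does not cover the signals", call. = FALSE)
  }
  runs <- rle(as.character(hypnogram))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  rows <- list()
  for (r in seq_along(runs$values)) {
    if (runs$values[r] %in% exclude) next
    t0 <- (starts[r] - 1) * 30
    t1 <- ends[r] * 30
    i0 <- floor(t0 / resolution) + 1
    i1 <- floor(t1 / resolution + 1e-9)
    i1 <- min(i1, n)
    if (i1 - i0 + 1 < 2) next
    seg <- lapply(vs, function(v) v[i0:i1])
    sds <- vapply(seg, stats::sd, numeric(1))
    if (any(sds == 0)) {
      warning(sprintf("dropping zero-variance %s patch at %g s",
                      runs$values[r], t0), call. = FALSE)
      next
    }
    seg <- lapply(seg, function(v) (v - mean(v)) / stats::sd(v))
    rows[[length(rows) + 1]] <- tibble::tibble(
      stage = runs$values[r], start = as.integer(i0), end = as.integer(i1),
      start_s = t0, end_s = t1, n = as.integer(i1 - i0 + 1),
      signals = list(seg)
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(stage = character(), start = integer(),
                          end = integer(), start_s = numeric(),
                          end_s = numeric(), n = integer(),
                          signals = list()))
  }
  dplyr::bind_rows(rows)
}
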