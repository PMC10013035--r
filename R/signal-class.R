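#' Uniformly sampled signal
#'
#' Light container for a uniformly sampled time series: a numeric vector of
#' values, the sampling interval `dt` in seconds, and a label. All analysis
#' functions in the package accept either a `pc_signal` or a bare numeric
#' vector (in which case `dt = 1` is assumed).
#'
#' @param values Numeric vector of finite samples (length >= 1).
#' @param dt Sampling interval in seconds (> 0).
#' @param label Character label naming the signal.
#' @return An object of class `pc_signal`.
#' @examples
#' s <- pc_signal(sin(1:100 / 5), dt = 1, label = "demo")
#' s
#' @export
pc_signal <- function(values, dt = 1, label = "signal") {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("`values` must have length >= 1", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("`values` must be finite", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values, dt = as.numeric(dt), label = as.character(label)[1]),
    class = "pc_signal"
  )
}

#' @export
print.pc_signal <- function(x, ...) {
  cat(sprintf(
    "<pc_signal> %s: %d samples @ dt = %g s (%.1f s)\n",
    x$label, length(x$values), x$dt, length(x$values) * x$dt
  ))
  invisible(x)
}

#' @export
length.pc_signal <- function(x) length(x$values)

#' @importFrom tibble as_tibble
#' @export
as_tibble.pc_signal <- function(x, ...) {
  tibble::tibble(
    time_s = (seq_along(x$values) - 1) * x$dt,
    value = x$values
  )
}

# Coerce a pc_signal or numeric vector to its sample vector.
sig_values <- function(x) {
  if (inherits(x, "pc_signal")) x$values else as.numeric(x)
}

sig_dt <- function(x, default = 1) {
  if (inherits(x, "pc_signal")) x$dt else default
}

sig_label <- function(x, default = "signal") {
  if (inherits(x, "pc_signal")) x$label else default
}

# Deterministic child seeds: a small multiplicative hash over integer keys,
# kept below 2^31 so the result is a valid R seed. Character keys are folded
# into integers by code point.
child_seed <- function(seed, ...) {
  keys <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (k in keys) {
    if (is.character(k)) {
      k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    }
    for (ki in as.numeric(k)) {
      h <- (h * 48271 + (ki %% 2147483647) * 7919 + 1) %% 2147483647
    }
  }
  as.integer(h)
}

# Run `expr` under a locally set seed when `seed` is non-NULL.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
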