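# ADF stationarity testing and recursive patch splitting.

# Dickey-Fuller tau quantiles for the regression with constant, no trend
# (published large-sample simulation tables; interpolated over both the
# effective sample size and the probability).
df_tau_probs <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
df_tau_n <- c(25, 50, 100, 250, 500, 1e9)
df_tau_table <- matrix(c(
  -3.75, -3.33, -3.00, -2.63, -0.37,  0.00,  0.34,  0.72,
  -3.58, -3.22, -2.93, -2.60, -0.40, -0.03,  0.29,  0.66,
  -3.51, -3.17, -2.89, -2.58, -0.42, -0.05,  0.26,  0.63,
  -3.46, -3.14, -2.88, -2.57, -0.42, -0.06,  0.24,  0.62,
  -3.44, -3.13, -2.87, -2.57, -0.43, -0.07,  0.24,  0.61,
  -3.43, -3.12, -2.86, -2.57, -0.44, -0.07,  0.23,  0.60
), nrow = 6, byrow = TRUE)

df_tau_pvalue <- function(stat, n_eff) {
  n_eff <- min(max(n_eff, df_tau_n[1]), df_tau_n[length(df_tau_n)])
  crit <- vapply(seq_along(df_tau_probs), function(i) {
    stats::approx(df_tau_n, df_tau_table[, i], xout = n_eff, rule = 2)$y
  }, numeric(1))
  stats::approx(crit, df_tau_probs, xout = stat, rule = 2)$y
}

#' Augmented Dickey-Fuller stationarity decision
#'
#' Tests the unit-root null with the ADF regression
#' `diff(x)_t = a + rho * x_{t-1} + sum_{i=1..order} b_i diff(x)_{t-i} + e_t`
#' (constant included, no trend term). The t-statistic of `rho` is compared
#' with the Dickey-Fuller tau distribution; rejection of the unit root
#' (p-value below `alpha`) is taken as evidence of stationarity.
#'
#' @param x A [pc_signal] or numeric vector with length > `order + 2`.
#' @param order Number of lagged differences in the regression.
#' @param alpha Significance level of the stationarity decision.
#' @return A list with `stationary` (logical), `p_value`, `statistic`,
#'   `order`, and `degenerate` (TRUE for zero-variance input or a
#'   regression with too few rows, both reported as non-stationary with
#'   `p_value = 1`).
#' @details The tau p-value is interpolated from the published quantile
#'   table for the constant-only case and clamped to `[0.01, 0.99]`, which
#'   is ample for decisions at conventional levels.
#' @examples
#' x <- stats::arima.sim(list(ar = 0.5), 500)
#' adf_stationary(as.numeric(x), order = 5)$stationary
#' @export
adf_stationary <- function(x, order = 5, alpha = 0.05) {
  v <- sig_values(x)
  order <- as.integer(order)
  if (order < 0) stop("`order` must be >= 0", call. = FALSE)
  n <- length(v)
  if (n <= order + 2) {
    stop("series too short for the requested ADF order", call. = FALSE)
  }
  degen <- function() list(stationary = FALSE, p_value = 1,
                           statistic = NA_real_, order = order,
                           degenerate = TRUE)
  if (stats::sd(v) == 0) return(degen())
  dv <- diff(v)
  rows <- (order + 1):(n - 1)          # index into dv
  yy <- dv[rows]
  X <- cbind(1, v[rows])               # constant + lagged level
  if (order > 0) {
    for (i in seq_len(order)) X <- cbind(X, dv[rows - i])
  }
  k <- ncol(X)
  if (length(yy) < k + 1) return(degen())
  qx <- qr(X)
  if (qx$rank < k) return(degen())
  beta <- qr.coef(qx, yy)
  res <- qr.resid(qx, yy)
  s2 <- sum(res^2) / (length(yy) - k)
  xtx_inv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
  if (is.null(xtx_inv)) return(degen())
  se_rho <- sqrt(s2 * xtx_inv[2, 2])
  stat <- beta[2] / se_rho
  p <- df_tau_pvalue(unname(stat), length(yy))
  list(stationary = p < alpha, p_value = p, statistic = unname(stat),
       order = order, degenerate = FALSE)
}

#' Recursive stationarity splitting of a signal triple
#'
#' Implements the patch-splitting algorithm used ahead of Granger analysis
#' on non-stationary recordings. A patch is accepted when all three channels
#' pass the ADF stationarity test at a common model order, trying orders in
#' the sequence given by `orders` (default 5, then 4, then 3). If no order
#' succeeds, the patch is split in half (the left half receiving the extra
#' sample for odd lengths) and the procedure recurses on both halves.
#' Patches shorter than `min_len` samples (default 6, i.e. six times the
#' sampling resolution) are considered non-stationary and discarded.
#'
#' @param signals Named list of three equal-length [pc_signal]s or numeric
#'   vectors.
#' @param resolution Seconds per sample (recorded in the output; defaults to
#'   the `dt` of the first signal).
#' @param orders Decreasing sequence of model orders to try.
#' @param alpha ADF significance level.
#' @param min_len Minimum patch length in samples; shorter patches are
#'   discarded.
#' @return A tibble of accepted patches with columns `start`, `end`
#'   (1-based, inclusive sample indices), `n` (length in samples), `order`
#'   (the accepted model order, also the order to use for subsequent AR
#'   fits) and `resolution`. Patches are disjoint and in temporal order; an
#'   empty tibble is a valid result.
#' @examples
#' set.seed(1)
#' tri <- replicate(3, as.numeric(stats::arima.sim(list(ar = 0.4), 256)),
#'                  simplify = FALSE)
#' names(tri) <- c("H", "B", "E")
#' split_patches(tri)
#' @export
split_patches <- function(signals, resolution = NULL, orders = c(5, 4, 3),
                          alpha = 0.05, min_len = 6) {
  if (length(signals) != 3) {
    stop("`signals` must contain exactly three series", call. = FALSE)
  }
  vs <- lapply(signals, sig_values)
  n <- length(vs[[1]])
  if (any(vapply(vs, length, 1L) != n)) {
    stop("all three series must have equal length", call. = FALSE)
  }
  if (is.null(resolution)) resolution <- sig_dt(signals[[1]])

  empty <- tibble::tibble(start = integer(), end = integer(), n = integer(),
                          order = integer(), resolution = numeric())
  test_order <- function(seg, ord) {
    if (length(seg[[1]]) <= ord + 2) return(FALSE)
    all(vapply(seg, function(v) {
      adf_stationary(v, order = ord, alpha = alpha)$stationary
    }, logical(1)))
  }
  recurse <- function(start, end) {
    len <- end - start + 1
    if (len < min_len) return(empty)
    seg <- lapply(vs, function(v) v[start:end])
    for (ord in orders) {
      if (test_order(seg, ord)) {
        return(tibble::tibble(start = start, end = end, n = len,
                              order = as.integer(ord),
                              resolution = resolution))
      }
    }
    mid <- start + ceiling(len / 2) - 1  # left half gets the extra sample
    dplyr::bind_rows(recurse(start, mid), recurse(mid + 1, end))
  }
  recurse(1L, n)
}

#' Fraction of samples covered by accepted stationary patches
#'
#' @param patches A patch tibble from [split_patches()].
#' @param total_length Total number of samples of the underlying series.
#' @return The covered fraction in `[0, 1]`.
#' @export
stationary_fraction <- function(patches, total_length) {
  if (total_length <= 0) stop("`total_length` must be positive", call. = FALSE)
  if (nrow(patches) == 0) return(0)
  sum(patches$n) / total_length
}
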