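# Nested autoregressive Granger-causality.
#
# All models are least-squares lagged regressions without intercept (inputs
# are assumed standardized to zero mean). Both models of a nested pair are
# fitted on the identical observation rows t = p+1 .. n, so their residual
# sums of squares are directly comparable and the F-test is valid.

# Lagged design block: column i holds v_{t-i} for t = p+1 .. n.
lag_block <- function(v, p) {
  n <- length(v)
  m <- matrix(0, n - p, p)
  for (i in seq_len(p)) m[, i] <- v[(p + 1 - i):(n - i)]
  m
}

#' Fit a lagged autoregressive model
#'
#' Least-squares fit of `target_t = sum_i phi_i target_{t-i} + sum_blocks
#' sum_i psi_i reg_{t-i} + w_t` over lags `1..order`, without intercept. The
#' target's own past is always included as the first regressor block.
#'
#' @param target A [pc_signal] or numeric vector to be modelled.
#' @param regressors Named list of additional signals whose lags enter the
#'   model (may be empty).
#' @param order Model order `p` (>= 1): number of lags per block.
#' @return An object of class `ar_fit` with elements `order`, `coef` (named
#'   list of length-`p` coefficient vectors per block), `sigma`
#'   (`sqrt(rss / n_obs)`), `rss`, `n_obs` (`length - order`), `collinear`
#'   (TRUE when the design was rank deficient) and `residuals`.
#' @details `sigma` uses the `1/n_obs` normalization. In the G-value only the
#'   ratio of two sigmas computed on identical rows enters, so the
#'   normalization convention cancels.
#' @examples
#' x <- fourier_filtered_noise(512, 0, seed = 1)
#' fit_ar(x, order = 2)
#' @export
fit_ar <- function(target, regressors = list(), order) {
  y_full <- sig_values(target)
  p <- as.integer(order)
  if (p < 1) stop("`order` must be >= 1", call. = FALSE)
  regs <- lapply(regressors, sig_values)
  n <- length(y_full)
  if (any(vapply(regs, length, 1L) != n)) {
    stop("all series must have equal length", call. = FALSE)
  }
  if (n < 2 * p + 2) {
    stop("series too short for the requested order", call. = FALSE)
  }
  labels <- c(sig_label(target, "target"),
              if (length(regs)) {
                nm <- names(regs)
                if (is.null(nm)) nm <- rep("", length(regs))
                ifelse(nm == "",
                       vapply(regressors, sig_label, "", "reg"),
                       nm)
              })
  blocks <- c(list(y_full), regs)
  X <- do.call(cbind, lapply(blocks, lag_block, p = p))
  y <- y_full[(p + 1):n]
  qx <- qr(X)
  collinear <- qx$rank < ncol(X)
  beta <- qr.coef(qx, y)
  beta[is.na(beta)] <- 0
  res <- qr.resid(qx, y)
  rss <- sum(res^2)
  n_obs <- length(y)
  coef_list <- split(beta, rep(seq_along(blocks), each = p))
  names(coef_list) <- make.unique(labels)
  structure(
    list(order = p, coef = coef_list, sigma = sqrt(rss / n_obs), rss = rss,
         n_obs = n_obs, n_coef = ncol(X), collinear = collinear,
         residuals = res, labels = names(coef_list)),
    class = "ar_fit"
  )
}

#' @export
print.ar_fit <- function(x, ...) {
  cat(sprintf("<ar_fit> order %d, blocks: %s | sigma = %.5g, n_obs = %d%s\n",
              x$order, paste(x$labels, collapse = ", "), x$sigma, x$n_obs,
              if (x$collinear) " [collinear]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_ar
#' @param x An `ar_fit` object.
#' @param ... Unused.
#' @export
tidy.ar_fit <- function(x, ...) {
  tibble::tibble(
    block = rep(x$labels, each = x$order),
    lag = rep(seq_len(x$order), times = length(x$labels)),
    estimate = unlist(x$coef, use.names = FALSE)
  )
}

#' @rdname fit_ar
#' @export
glance.ar_fit <- function(x, ...) {
  tibble::tibble(order = x$order, sigma = x$sigma, rss = x$rss,
                 n_obs = x$n_obs, n_coef = x$n_coef, collinear = x$collinear)
}

# Lightweight ar_fit from a shared QR decomposition (see g_nested).
ar_fit_from_qr <- function(beta, rss, p, n_obs, labels) {
  coef_list <- split(beta, rep(seq_along(labels), each = p))
  names(coef_list) <- make.unique(labels)
  structure(
    list(order = p, coef = coef_list, sigma = sqrt(rss / n_obs), rss = rss,
         n_obs = n_obs, n_coef = length(beta), collinear = FALSE,
         residuals = NULL, labels = names(coef_list)),
    class = "ar_fit"
  )
}

# Shared core of the pairwise and conditional tests. Both nested models are
# solved from a single QR decomposition of the unrestricted design (the
# restricted design is its leading column block, so its RSS follows from
# the transformed response); if the design is rank deficient the slower
# two-fit route of fit_ar() is used instead.
g_nested <- function(x, source, cond = list(), order, test = c("f", "chi2")) {
  test <- match.arg(test)
  p <- as.integer(order)
  fits <- g_nested_fits(x, source, cond, p)
  restricted <- fits$restricted
  unrestricted <- fits$unrestricted
  n_obs <- restricted$n_obs
  df2 <- n_obs - unrestricted$n_coef
  if (df2 < 1) {
    stop("series too short: no residual degrees of freedom for the F-test",
         call. = FALSE)
  }
  if (n_obs != unrestricted$n_obs) {
    stop("internal error: nested fits on different rows", call. = FALSE)
  }
  rss1 <- restricted$rss
  rss2 <- unrestricted$rss
  collinear <- restricted$collinear || unrestricted$collinear
  tiny <- .Machine$double.eps^0.75 * max(rss1, n_obs)
  # a perfect fit counts as such only when the restricted model left
  # something to explain (deterministic dependence on the source); if both
  # models are exact the input was degenerate
  perfect <- rss2 <= tiny && rss1 > tiny
  if (perfect) {
    g <- Inf
    stat <- Inf
    p_value <- 0
  } else if (rss1 <= tiny && rss2 <= tiny) {
    # degenerate: nothing left to explain in either model
    g <- 0
    stat <- NaN
    p_value <- 1
  } else {
    g <- 0.5 * log(rss1 / rss2)
    f_stat <- ((rss1 - rss2) / p) / (rss2 / df2)
    if (test == "f") {
      stat <- f_stat
      p_value <- stats::pf(f_stat, p, df2, lower.tail = FALSE)
    } else {
      stat <- p * f_stat
      p_value <- stats::pchisq(stat, p, lower.tail = FALSE)
    }
  }
  if (collinear && !perfect) p_value <- 1
  structure(
    list(
      g_value = g, statistic = stat, p_value = p_value, test = test,
      order = p, n_obs = n_obs, df = c(p, df2),
      conditional = length(cond) > 0,
      cond_labels = vapply(cond, sig_label, "", "cond"),
      source_label = sig_label(source, "source"),
      target_label = sig_label(x, "target"),
      collinear = collinear,
      restricted = restricted, unrestricted = unrestricted
    ),
    class = "g_result"
  )
}

# Fit the two nested models, preferring the shared-QR fast path.
g_nested_fits <- function(x, source, cond, p) {
  y_full <- sig_values(x)
  n <- length(y_full)
  cond_v <- lapply(cond, sig_values)
  src_v <- sig_values(source)
  lens <- c(vapply(cond_v, length, 1L), length(src_v))
  if (n >= 2 * p + 2 && all(lens == n)) {
    cond_labels <- if (length(cond) == 0) character(0) else {
      nms <- names(cond) %||% rep("", length(cond))
      vapply(seq_along(cond), function(i) {
        if (nzchar(nms[i])) nms[i] else sig_label(cond[[i]], "cond")
      }, character(1))
    }
    labels_r <- c(sig_label(x, "target"), cond_labels)
    labels_u <- c(labels_r, sig_label(source, "source"))
    blocks <- c(list(y_full), cond_v, list(src_v))
    X <- do.call(cbind, lapply(blocks, lag_block, p = p))
    y <- y_full[(p + 1):n]
    k_u <- ncol(X)
    k_r <- k_u - p
    qx <- qr(X)
    if (qx$rank == k_u && identical(qx$pivot, seq_len(k_u)) &&
        length(y) > k_u) {
      qty <- qr.qty(qx, y)
      n_obs <- length(y)
      rss_u <- sum(qty[(k_u + 1):n_obs]^2)
      rss_r <- rss_u + sum(qty[(k_r + 1):k_u]^2)
      beta_u <- qr.coef(qx, y)
      R <- qr.R(qx)
      beta_r <- backsolve(R[seq_len(k_r), seq_len(k_r), drop = FALSE],
                          qty[seq_len(k_r)])
      return(list(
        restricted = ar_fit_from_qr(beta_r, rss_r, p, n_obs, labels_r),
        unrestricted = ar_fit_from_qr(beta_u, rss_u, p, n_obs, labels_u)
      ))
    }
  }
  list(restricted = fit_ar(x, cond, p),
       unrestricted = fit_ar(x, c(cond, list(source)), p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise Granger causality test
#'
#' Quantifies how much the past of `source` improves the least-squares
#' forecast of `target` beyond the target's own past. Two nested AR models
#' are fitted on identical rows — the restricted one on the target's own
#' `order` lags, the unrestricted one adding the source's lags — and the
#' G-value `G = ln(sigma_restricted / sigma_unrestricted) >= 0` measures the
#' improvement. Significance of the source block is assessed with an F-test
#' (`order` numerator degrees of freedom) or the chi-squared variant
#' (`order * F` with `order` df).
#'
#' @param target,source [pc_signal]s or numeric vectors of equal length.
#' @param order Model order (lags per block).
#' @param test `"f"` (default) or `"chi2"`.
#' @return A `g_result` object; see [glance.g_result()].
#' @details A numerically perfect unrestricted fit (deterministic
#'   dependence) is reported as `g_value = Inf` with `p_value = 0`. A rank
#'   deficient design is flagged via `collinear` and the p-value set to 1.
#' @examples
#' sys <- pairwise_system(2048, q = 0.5, seed = 1)
#' g_pairwise(sys$x, sys$z, order = 5)
#' @export
g_pairwise <- function(target, source, order = 5, test = c("f", "chi2")) {
  g_nested(target, source, list(), order, test)
}

#' Conditional Granger causality test
#'
#' Like [g_pairwise()], but the past of every conditioning signal is
#' included in both nested models, so the G-value counts only information in
#' `source` that the conditioning signals do not already provide. This
#' separates direct links from indirect or common-driver links.
#'
#' @inheritParams g_pairwise
#' @param cond A signal or (possibly named) list of signals to condition on.
#' @return A `g_result` object with `conditional = TRUE`.
#' @examples
#' sys <- common_driver_system(4096, 0.5, 0.5, seed = 1)
#' g_conditional(sys$x, sys$z, cond = sys$y, order = 5)
#' @export
g_conditional <- function(target, source, cond, order = 5,
                          test = c("f", "chi2")) {
  if (inherits(cond, "pc_signal") || is.numeric(cond)) cond <- list(cond)
  if (length(cond) < 1) stop("`cond` must be non-empty", call. = FALSE)
  g_nested(target, source, cond, order, test)
}

#' @export
print.g_result <- function(x, ...) {
  kind <- if (x$conditional) {
    sprintf("conditional on %s", paste(x$cond_labels, collapse = ", "))
  } else "pairwise"
  cat(sprintf(
    "<g_result> G(%s -> %s%s) = %.5g | %s-test stat = %.4g, p = %.4g (order %d, n_obs %d)%s\n",
    x$source_label, x$target_label,
    if (x$conditional) paste0(" | ", paste(x$cond_labels, collapse = ",")) else "",
    x$g_value, toupper(x$test), x$statistic, x$p_value, x$order, x$n_obs,
    if (x$collinear) " [collinear]" else ""
  ))
  invisible(x)
}

#' Summaries of a Granger test result
#'
#' `glance()` returns a one-row tibble with the G-value, test statistic and
#' p-value; `tidy()` returns the coefficients of both nested fits in long
#' format.
#'
#' @param x A `g_result` object.
#' @param ... Unused.
#' @export
glance.g_result <- function(x, ...) {
  tibble::tibble(
    source = x$source_label, target = x$target_label,
    conditional = x$conditional,
    g_value = x$g_value, statistic = x$statistic, p_value = x$p_value,
    test = x$test, order = x$order, n_obs = x$n_obs,
    collinear = x$collinear
  )
}

#' @rdname glance.g_result
#' @export
tidy.g_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$restricted), model = "restricted"),
    dplyr::mutate(tidy(x$unrestricted), model = "unrestricted")
  )[, c("model", "block", "lag", "estimate")]
}
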