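#' Generate 1/f^alpha noise by Fourier filtering
#'
#' Starts from Gaussian white noise, rescales the discrete Fourier amplitudes
#' so that the power spectrum follows `1/f^alpha`, transforms back, and
#' standardizes the result to zero mean and unit sample variance. The
#' zero-frequency (DC) component is set to zero before the inverse transform.
#'
#' @param n Number of samples (>= 2).
#' @param alpha Spectral exponent (>= 0); `alpha = 0` gives white noise,
#'   `alpha = 0.5` the weakly long-range correlated noise used by the
#'   benchmark systems.
#' @param seed Optional integer seed; the global RNG state is not disturbed.
#' @param dt Sampling interval for the returned signal.
#' @param label Label for the returned signal.
#' @return A [pc_signal] with mean 0 and sample variance 1.
#' @examples
#' x <- fourier_filtered_noise(1024, alpha = 0.5, seed = 1)
#' var(x$values)
#' @export
fourier_filtered_noise <- function(n, alpha = 0.5, seed = NULL, dt = 1,
                                   label = sprintf("noise_1f%g", alpha)) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("`n` must be a single number >= 2", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.numeric(alpha) || alpha < 0) {
    stop("`alpha` must be >= 0", call. = FALSE)
  }
  # Work on a highly composite grid >= n (mixed-radix FFTs degrade to
  # O(n^2) on awkward lengths), then keep the first n samples.
  nf <- stats::nextn(n, c(2L, 3L, 5L))
  w <- with_seed_if(seed, stats::rnorm(nf))
  k <- 0:(nf - 1)
  f <- pmin(k, nf - k) / nf        # two-sided frequency magnitude
  amp <- numeric(nf)
  nz <- f > 0
  amp[nz] <- f[nz]^(-alpha / 2)    # power ~ f^-alpha => amplitude ~ f^-alpha/2
  x <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE))[seq_len(n)] / nf
  x <- x - mean(x)
  x <- x / stats::sd(x)
  pc_signal(x, dt = dt, label = label)
}

#' Two-node benchmark system with a direct lagged coupling
#'
#' Builds the pair of series used for detection-limit experiments: the source
#' `z` is unit-variance `1/f^alpha` noise, and the target is a mixture
#' `x_t = q * z_{t-lag} + (1 - q) * o2_t` with an independent noise `o2`.
#' `q` in `[0, 1]` sets the coupling strength (`q = 0`: independent,
#' `q = 1`: a pure delayed copy). Internally the noises are generated with
#' `lag` extra samples so both returned series have length `n` after the
#' initial lag window is dropped.
#'
#' @param n Number of returned samples per series (must exceed `lag`).
#' @param q Coupling strength in `[0, 1]`.
#' @param lag Integer delay of the coupling, in samples (>= 0).
#' @param alpha Spectral exponent of both noise sources.
#' @param seed Optional master seed; the two noise sources get independent
#'   child seeds derived from it.
#' @param dt Sampling interval.
#' @return A list with elements `z` and `x`, both [pc_signal]s of length `n`.
#' @examples
#' sys <- pairwise_system(4096, q = 0.5, seed = 1)
#' cor(sys$x$values[-(1:3)], sys$z$values[1:4093])
#' @export
pairwise_system <- function(n, q, lag = 3, alpha = 0.5, seed = NULL, dt = 1) {
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q > 1) {
    stop("`q` must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(lag) || lag < 0 || lag != round(lag)) {
    stop("`lag` must be a non-negative integer", call. = FALSE)
  }
  lag <- as.integer(lag)
  if (!is.numeric(n) || n <= lag) {
    stop("`n` must exceed `lag`", call. = FALSE)
  }
  n <- as.integer(n)
  ntot <- n + lag
  s1 <- if (is.null(seed)) NULL else child_seed(seed, "o1")
  s2 <- if (is.null(seed)) NULL else child_seed(seed, "o2")
  o1 <- fourier_filtered_noise(ntot, alpha, seed = s1)$values
  o2 <- fourier_filtered_noise(ntot, alpha, seed = s2)$values
  z <- o1
  tt <- (lag + 1):ntot
  x <- q * z[tt - lag] + (1 - q) * o2[tt]
  list(
    z = pc_signal(z[tt], dt = dt, label = "z"),
    x = pc_signal(x, dt = dt, label = "x")
  )
}

#' Three-node benchmark system with a common driver
#'
#' Builds the triple used for the direct-versus-indirect classification
#' experiments. A hidden-in-pairwise-analysis driver `y` influences both `z`
#' (at `lag_yz`) and `x` (at `lag_yx`):
#' `y = o2`, `z_t = q_yz * y_{t-lag_yz} + (1 - q_yz) * o1_t`,
#' `x_t = q_yx * y_{t-lag_yx} + (1 - q_yx) * o3_t`.
#' With `lag_yx > lag_yz`, `z` leads `x` and a pairwise test sees a spurious
#' `z -> x` link; no direct `z -> x` term exists by construction.
#'
#' @param n Returned length of each series.
#' @param q_yz,q_yx Coupling strengths in `[0, 1]`.
#' @param lag_yz,lag_yx Integer lags of the two couplings (samples).
#' @param alpha Spectral exponent of the three independent noises.
#' @param seed Optional master seed.
#' @param dt Sampling interval.
#' @return A list with elements `x`, `y`, `z` ([pc_signal]s of length `n`).
#' @export
common_driver_system <- function(n, q_yz, q_yx, lag_yz = 2, lag_yx = 4,
                                 alpha = 0.5, seed = NULL, dt = 1) {
  for (q in c(q_yz, q_yx)) {
    if (!is.numeric(q) || length(q) != 1L || q < 0 || q > 1) {
      stop("coupling strengths must lie in [0, 1]", call. = FALSE)
    }
  }
  if (lag_yz < 0 || lag_yx < 0 ||
      lag_yz != round(lag_yz) || lag_yx != round(lag_yx)) {
    stop("lags must be non-negative integers", call. = FALSE)
  }
  maxlag <- as.integer(max(lag_yz, lag_yx))
  if (!is.numeric(n) || n <= maxlag) {
    stop("`n` must exceed the largest lag", call. = FALSE)
  }
  n <- as.integer(n)
  ntot <- n + maxlag
  sd1 <- if (is.null(seed)) NULL else child_seed(seed, "o1")
  sd2 <- if (is.null(seed)) NULL else child_seed(seed, "o2")
  sd3 <- if (is.null(seed)) NULL else child_seed(seed, "o3")
  o1 <- fourier_filtered_noise(ntot, alpha, seed = sd1)$values
  o2 <- fourier_filtered_noise(ntot, alpha, seed = sd2)$values
  o3 <- fourier_filtered_noise(ntot, alpha, seed = sd3)$values
  y <- o2
  tt <- (maxlag + 1):ntot
  z <- q_yz * y[tt - lag_yz] + (1 - q_yz) * o1[tt]
  x <- q_yx * y[tt - lag_yx] + (1 - q_yx) * o3[tt]
  list(
    x = pc_signal(x, dt = dt, label = "x"),
    y = pc_signal(y[tt], dt = dt, label = "y"),
    z = pc_signal(z, dt = dt, label = "z")
  )
}

#' Synthetic sleeper: three 1 Hz physiological-like series with a hypnogram
#'
#' Generates a triple of 1 Hz series emulating heart rate (`H`), breathing
#' rate (`B`) and EEG alpha-band amplitude (`E`) over a sequence of 30 s
#' sleep-stage epochs, together with the matching hypnogram. Within each
#' maximal run of one stage, every channel is `1/f^alpha` noise, and directed
#' couplings are planted with the same lagged mixture used by
#' [pairwise_system]: the target channel is
#' `sum(q_i * source_noise_{t-lag_i}) + (1 - sum(q_i)) * own_noise_t`,
#' where the source contribution is the source channel's own base noise.
#' Segment boundaries introduce mean and variance shifts (drawn per segment
#' and channel), and an optional slow random-walk trend can be added to make
#' individual segments non-stationary.
#'
#' @param stages Either a character vector of stage codes (one per 30 s
#'   epoch) or a data frame with columns `stage` and `epochs`. Codes must be
#'   among `"W"`, `"LS"`, `"DS"`, `"REM"`.
#' @param couplings Optional data frame with columns `stage`, `from`, `to`,
#'   `q`, `lag` describing directed couplings active within epochs of
#'   `stage` (`stage = NA` applies to every stage). `from`/`to` are channel
#'   names among `"H"`, `"B"`, `"E"`; `q` in `[0, 1]`; `lag` a positive
#'   integer in samples (seconds). The `q` entering one target within one
#'   stage must sum to at most 1.
#' @param alpha Spectral exponent of each channel's base noise.
#' @param shift_sd Standard deviation of the per-segment mean shift.
#' @param scale_range Length-2 range of the per-segment multiplicative
#'   scale, drawn uniformly.
#' @param trend_amp Amplitude of a slow standardized random-walk trend added
#'   per segment (0 disables it; positive values make long segments fail
#'   stationarity tests, exercising the patch splitter).
#' @param seed Optional master seed.
#' @return A list with [pc_signal]s `H`, `B`, `E` (1 Hz) and `hypnogram`, a
#'   character vector with one stage code per 30 s epoch.
#' @examples
#' coup <- tibble::tibble(stage = "LS", from = "B", to = "H", q = 0.5, lag = 2)
#' s <- synthetic_sleeper(rep(c("LS", "DS"), each = 20), coup, seed = 1)
#' table(s$hypnogram)
#' @export
synthetic_sleeper <- function(stages, couplings = NULL, alpha = 0.5,
                              shift_sd = 0.5, scale_range = c(0.7, 1.4),
                              trend_amp = 0, seed = NULL) {
  epoch_s <- 30L
  if (is.data.frame(stages)) {
    if (!all(c("stage", "epochs") %in% names(stages))) {
      stop("`stages` data frame needs columns `stage` and `epochs`",
           call. = FALSE)
    }
    stages <- rep(as.character(stages$stage), times = stages$epochs)
  }
  stages <- as.character(stages)
  valid <- c("W", "LS", "DS", "REM")
  if (length(stages) < 1L || !all(stages %in% valid)) {
    stop("stage codes must be among W, LS, DS, REM", call. = FALSE)
  }
  channels <- c("H", "B", "E")
  if (!is.null(couplings)) {
    couplings <- as.data.frame(couplings)
    need <- c("from", "to", "q")
    if (!all(need %in% names(couplings))) {
      stop("`couplings` needs columns from, to, q (and optionally stage, lag)",
           call. = FALSE)
    }
    if (is.null(couplings$lag)) couplings$lag <- 2L
    if (is.null(couplings$stage)) couplings$stage <- NA_character_
    if (!all(couplings$from %in% channels) ||
        !all(couplings$to %in% channels)) {
      stop("coupling channels must be among H, B, E", call. = FALSE)
    }
    if (any(couplings$q < 0 | couplings$q > 1)) {
      stop("coupling strengths must lie in [0, 1]", call. = FALSE)
    }
    if (any(couplings$from == couplings$to)) {
      stop("self-couplings are not supported", call. = FALSE)
    }
  }

  runs <- rle(stages)
  out <- stats::setNames(vector("list", 3), channels)
  for (ch in channels) out[[ch]] <- numeric(0)

  for (s in seq_along(runs$lengths)) {
    stage <- runs$values[s]
    nseg <- runs$lengths[s] * epoch_s
    active <- if (is.null(couplings)) NULL else
      couplings[is.na(couplings$stage) | couplings$stage == stage, ,
                drop = FALSE]
    maxlag <- if (is.null(active) || nrow(active) == 0) 0L else
      as.integer(max(active$lag))
    ntot <- nseg + maxlag
    base <- list()
    for (ch in channels) {
      sd_ch <- if (is.null(seed)) NULL else child_seed(seed, "noise", s, ch)
      base[[ch]] <- fourier_filtered_noise(ntot, alpha, seed = sd_ch)$values
    }
    tt <- (maxlag + 1):ntot
    for (ch in channels) {
      rows <- if (is.null(active)) active else
        active[active$to == ch, , drop = FALSE]
      if (!is.null(rows) && nrow(rows) > 0) {
        qtot <- sum(rows$q)
        if (qtot > 1) {
          stop(sprintf("couplings into %s exceed total strength 1 in stage %s",
                       ch, stage), call. = FALSE)
        }
        v <- (1 - qtot) * base[[ch]][tt]
        for (r in seq_len(nrow(rows))) {
          v <- v + rows$q[r] * base[[rows$from[r]]][tt - rows$lag[r]]
        }
      } else {
        v <- base[[ch]][tt]
      }
      # per-segment affine disturbance + optional slow trend
      sd_seg <- if (is.null(seed)) NULL else child_seed(seed, "seg", s, ch)
      v <- with_seed_if(sd_seg, {
        sc <- stats::runif(1, scale_range[1], scale_range[2])
        sh <- stats::rnorm(1, 0, shift_sd)
        vv <- v * sc + sh
        if (trend_amp > 0 && nseg >= 4) {
          tr <- cumsum(stats::rnorm(nseg))
          tr <- (tr - mean(tr)) / max(stats::sd(tr), .Machine$double.eps)
          vv <- vv + trend_amp * tr
        }
        vv
      })
      out[[ch]] <- c(out[[ch]], v)
    }
  }

  list(
    H = pc_signal(out$H, dt = 1, label = "H"),
    B = pc_signal(out$B, dt = 1, label = "B"),
    E = pc_signal(out$E, dt = 1, label = "E"),
    hypnogram = stages
  )
}
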