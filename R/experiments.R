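# Benchmark experiments: detection-limit isolines and the
# pairwise/conditional region-classification map.

#' Single-cell detector p-value on the two-node benchmark
#'
#' Generates one realization of the lagged-coupling benchmark system
#' ([pairwise_system]) and returns the p-value of the chosen causality
#' detector for the (true) `z -> x` link.
#'
#' @param detector One of `"granger_f"`, `"bprsa_ks1"`, `"bprsa_ks2"`,
#'   `"bprsa_ad"`, `"bprsa_sw"`.
#' @param n Series length.
#' @param q Coupling strength.
#' @param order AR order for the Granger detector.
#' @param L BPRSA half-width.
#' @param lag Coupling lag of the benchmark system.
#' @param alpha Spectral exponent of the noise sources.
#' @param seed Seed for the realization (also drives the `ks2` surrogate).
#' @return A single p-value (NA when the BPRSA curve cannot be formed).
#' @export
detector_pvalue <- function(detector = c("granger_f", "bprsa_ks1",
                                         "bprsa_ks2", "bprsa_ad",
                                         "bprsa_sw"),
                            n, q, order = 5, L = 15, lag = 3, alpha = 0.5,
                            seed = NULL) {
  detector <- match.arg(detector)
  sys <- pairwise_system(n, q, lag = lag, alpha = alpha, seed = seed)
  if (detector == "granger_f") {
    return(g_pairwise(sys$x, sys$z, order = order)$p_value)
  }
  trig <- find_triggers(sys$z)
  cv <- tryCatch(bprsa_curve(sys$x, trig, L = L), error = function(e) NULL)
  if (is.null(cv)) return(NA_real_)
  tt <- sub("^bprsa_", "", detector)
  s2 <- if (is.null(seed)) NULL else child_seed(seed, "ks2")
  bprsa_test(cv, tt, seed = s2)$p_value
}

# Smallest grid q whose aggregated p-value drops below `level`,
# log-interpolated between the bracketing grid points. NA when the detector
# never rejects on the grid.
crossing_q <- function(q_grid, agg_p, level) {
  below <- which(agg_p < level)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  if (i == 1) return(q_grid[1])
  # linear in (log q, p) between the bracketing points
  p0 <- agg_p[i - 1]; p1 <- agg_p[i]
  w <- (p0 - level) / (p0 - p1)
  exp(log(q_grid[i - 1]) + w * (log(q_grid[i]) - log(q_grid[i - 1])))
}

#' Detection-limit isoline of a causality detector
#'
#' For each series length, benchmark systems are simulated over a grid of
#' coupling strengths `q` with `n_real` independent realizations per cell;
#' the detector's p-values are aggregated per `q` (mean p-value by default)
#' and the critical coupling is the smallest `q` at which the aggregate
#' drops below `level`, log-interpolated between grid points. A bootstrap
#' over the realizations (resampling `n_real` out of `n_real` with
#' replacement, `n_boot` times) gives the 5th/95th percentile band.
#'
#' @inheritParams detector_pvalue
#' @param lengths Series lengths to scan.
#' @param q_grid Increasing grid of coupling strengths in (0, 1).
#' @param n_real Realizations per (length, q) cell.
#' @param n_boot Bootstrap resamples for the confidence band (0 disables).
#' @param level Rejection level defining the isoline.
#' @param aggregate `"mean_p"` (default) or `"reject_frac"` (critical q is
#'   then where the rejection fraction first exceeds 1/2).
#' @param seed Master seed; each (length, q, realization) cell gets an
#'   independent reproducible child seed.
#' @return A tibble of class `isoline_result` with columns `detector`, `n`,
#'   `q_crit` (NA when never detected), `lo`, `hi` (bootstrap percentiles)
#'   and `n_real`.
#' @examples
#' \donttest{
#' iso <- critical_isoline("granger_f", lengths = 2^(8:10), n_real = 5,
#'                         n_boot = 20, seed = 1)
#' iso
#' }
#' @export
critical_isoline <- function(detector, lengths = 2^(6:16),
                             q_grid = exp(seq(log(0.005), log(0.95),
                                              length.out = 24)),
                             n_real = 20, n_boot = 100, level = 0.05,
                             aggregate = c("mean_p", "reject_frac"),
                             order = 5, L = 15, lag = 3, alpha = 0.5,
                             seed = 1) {
  aggregate <- match.arg(aggregate)
  agg_fun <- function(pm) {
    if (aggregate == "mean_p") {
      colMeans(pm, na.rm = TRUE)
    } else {
      # step function: 0 where the majority of realizations rejects, else 1,
      # so the crossing falls between the bracketing grid points
      ifelse(colMeans(pm < level, na.rm = TRUE) >= 0.5, 0, 1)
    }
  }
  rows <- lapply(lengths, function(N) {
    pm <- matrix(NA_real_, n_real, length(q_grid))
    for (qi in seq_along(q_grid)) {
      for (r in seq_len(n_real)) {
        s <- child_seed(seed, detector, log2(N), qi, r)
        pm[r, qi] <- detector_pvalue(detector, n = N, q = q_grid[qi],
                                     order = order, L = L, lag = lag,
                                     alpha = alpha, seed = s)
      }
    }
    q_crit <- crossing_q(q_grid, agg_fun(pm), level)
    lo <- hi <- NA_real_
    if (n_boot > 0) {
      qb <- with_seed_if(child_seed(seed, "boot", log2(N)), {
        vapply(seq_len(n_boot), function(b) {
          ii <- sample.int(n_real, n_real, replace = TRUE)
          crossing_q(q_grid, agg_fun(pm[ii, , drop = FALSE]), level)
        }, numeric(1))
      })
      if (any(!is.na(qb))) {
        qq <- stats::quantile(qb, c(0.05, 0.95), na.rm = TRUE)
        lo <- qq[[1]]; hi <- qq[[2]]
      }
    }
    tibble::tibble(detector = detector, n = N, q_crit = q_crit,
                   lo = lo, hi = hi, n_real = n_real)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("isoline_result", class(out))
  out
}

#' Region classification of the common-driver benchmark
#'
#' For each cell of a coupling-strength grid, `n_real` realizations of the
#' common-driver system ([common_driver_system]) are generated and the
#' pairwise and conditional (given `y`) Granger F-tests for `z -> x` are
#' run. Each realization is classified and the cell takes the majority
#' class:
#' * Region 1 — neither test rejects (couplings too weak; false negative);
#' * Region 2 — pairwise rejects, conditional does not (the correct call:
#'   an indirect link is detected and recognised as indirect);
#' * Region 3 — both reject (couplings so strong that a direct link is
#'   mistakenly claimed);
#' * inconsistent — conditional rejects only.
#'
#' @param q_yz,q_yx Grids of coupling strengths (a full grid is formed).
#' @param n Series length.
#' @param n_real Realizations per cell.
#' @param level Test level.
#' @param order AR order.
#' @param lag_yz,lag_yx Lags of the two couplings.
#' @param alpha Noise spectral exponent.
#' @param seed Master seed (per-cell child seeds).
#' @return A tibble of class `region_map` with columns `q_yz`, `q_yx`,
#'   `product`, `region` (factor: `"1"`, `"2"`, `"3"`, `"inconsistent"`)
#'   and `n_real`.
#' @export
region_map <- function(q_yz, q_yx, n = 2^15, n_real = 20, level = 0.05,
                       order = 5, lag_yz = 2, lag_yx = 4, alpha = 0.5,
                       seed = 1) {
  grid <- tidyr::expand_grid(q_yz = q_yz, q_yx = q_yx)
  classify <- function(pair_rej, cond_rej) {
    if (pair_rej && !cond_rej) "2"
    else if (pair_rej && cond_rej) "3"
    else if (!pair_rej && !cond_rej) "1"
    else "inconsistent"
  }
  res <- purrr::pmap(grid, function(q_yz, q_yx) {
    cls <- vapply(seq_len(n_real), function(r) {
      s <- child_seed(seed, "region", round(q_yz * 1e6),
                      round(q_yx * 1e6), r)
      sys <- common_driver_system(n, q_yz, q_yx, lag_yz = lag_yz,
                                  lag_yx = lag_yx, alpha = alpha, seed = s)
      pp <- g_pairwise(sys$x, sys$z, order = order)$p_value
      pc <- g_conditional(sys$x, sys$z, cond = sys$y,
                          order = order)$p_value
      classify(pp < level, pc < level)
    }, character(1))
    tab <- table(cls)
    names(tab)[which.max(tab)]
  })
  out <- dplyr::mutate(
    grid,
    product = .data$q_yz * .data$q_yx,
    region = factor(unlist(res), levels = c("1", "2", "3", "inconsistent")),
    n_real = n_real
  )
  class(out) <- c("region_map", class(out))
  out
}

#' Smallest Region-2 coupling product of a region map
#'
#' Convenience accessor for the detection boundary: the smallest
#' `q_yz * q_yx` product among cells whose majority classification is
#' Region 2.
#'
#' @param map A [region_map()] result.
#' @return The smallest Region-2 product (NA if Region 2 never occurs).
#' @export
region2_boundary <- function(map) {
  r2 <- map$product[map$region == "2"]
  if (length(r2) == 0) return(NA_real_)
  min(r2)
}
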