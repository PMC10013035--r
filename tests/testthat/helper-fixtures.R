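# Shared helpers for the test suite. All fixtures are generated in code.

# Three independent stationary AR(1) series as a named channel triple.
ar1_triple <- function(n = 256, phi = 0.5, seed = 1) {
  withr::with_seed(seed, {
    tri <- lapply(1:3, function(i) {
      as.numeric(stats::arima.sim(list(ar = phi), n))
    })
    names(tri) <- c("H", "B", "E")
    tri
  })
}

# Brute-force normal-equations solver for the nested AR comparison: an
# independent oracle for G and F (no QR, no shared code with the package).
oracle_g <- function(y, blocks_restricted, blocks_unrestricted, p) {
  design <- function(blocks) {
    n <- length(y)
    X <- NULL
    for (b in blocks) {
      for (i in 1:p) X <- cbind(X, b[(p + 1 - i):(n - i)])
    }
    X
  }
  rss_of <- function(blocks) {
    X <- design(blocks)
    yy <- y[(p + 1):length(y)]
    beta <- solve(t(X) %*% X, t(X) %*% yy)
    sum((yy - X %*% beta)^2)
  }
  rss1 <- rss_of(blocks_restricted)
  rss2 <- rss_of(blocks_unrestricted)
  n_obs <- length(y) - p
  k_u <- p * length(blocks_unrestricted)
  f <- ((rss1 - rss2) / p) / (rss2 / (n_obs - k_u))
  list(
    g = 0.5 * log(rss1 / rss2),
    f = f,
    p_value = stats::pf(f, p, n_obs - k_u, lower.tail = FALSE)
  )
}

# Small synthetic-sleeper cohort with one planted directed coupling.
planted_cohort <- function(seed, n_subjects = 3, q = 0.5,
                           stages = rep(c("LS", "DS"), each = 70)) {
  coup <- tibble::tibble(stage = NA_character_, from = "B", to = "H",
                         q = q, lag = 2)
  lapply(seq_len(n_subjects), function(i) {
    synthetic_sleeper(stages, coup, seed = seed * 100 + i)
  })
}
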