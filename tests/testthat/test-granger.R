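test_that("fit_ar recovers AR coefficients and residual scale", {
  withr::with_seed(10, {
    x <- as.numeric(stats::arima.sim(list(ar = 0.5), 1e5))
    fit <- fit_ar(x, order = 1)
    expect_equal(unname(fit$coef[[1]]), 0.5, tolerance = 0.02)
    # white noise: nothing to explain, sigma ~ sample SD
    w <- rnorm(5000)
    fw <- fit_ar(w, order = 1)
    expect_equal(fw$sigma, sd(w), tolerance = 0.02 * sd(w))
  })
  expect_error(fit_ar(rnorm(5), order = 2), "too short")
})

test_that("fit_ar matches the normal-equations oracle on a tiny series", {
  y <- c(1, 2, 1, 2, 1, 2, 1, 2)
  fit <- fit_ar(y, order = 1)
  # oracle: minimise sum (y_t - phi y_{t-1})^2 => phi = sum y_t y_{t-1} / sum y_{t-1}^2
  num <- sum(y[2:8] * y[1:7])
  den <- sum(y[1:7]^2)
  expect_equal(unname(fit$coef[[1]]), num / den, tolerance = 1e-12)
  expect_equal(fit$rss, sum((y[2:8] - (num / den) * y[1:7])^2),
               tolerance = 1e-12)
  expect_equal(fit$n_obs, 7)
})

test_that("G and F agree with a brute-force normal-equations solver", {
  withr::with_seed(77, {
    for (case in 1:8) {
      n <- sample(20:50, 1)
      p <- sample(1:2, 1)
      sys <- pairwise_system(n, q = runif(1, 0, 0.8),
                             seed = 1000 + case)
      x <- sys$x$values
      z <- sys$z$values
      g <- g_pairwise(x, z, order = p)
      orc <- oracle_g(x, list(x), list(x, z), p)
      expect_equal(g$g_value, orc$g, tolerance = 1e-8)
      expect_equal(g$statistic, orc$f, tolerance = 1e-8)
      expect_equal(g$p_value, orc$p_value, tolerance = 1e-8)
      # conditional against the oracle as well
      y <- fourier_filtered_noise(n, 0.5, seed = 2000 + case)$values
      gc <- g_conditional(x, z, cond = y, order = p)
      orc2 <- oracle_g(x, list(x, y), list(x, y, z), p)
      expect_equal(gc$g_value, orc2$g, tolerance = 1e-8)
      expect_equal(gc$statistic, orc2$f, tolerance = 1e-8)
    }
  })
})

test_that("pairwise G agrees with lmtest::grangertest as external oracle", {
  skip_if_not_installed("lmtest")
  sys <- pairwise_system(2048, q = 0.4, seed = 31)
  g <- g_pairwise(sys$x, sys$z, order = 3)
  gt <- lmtest::grangertest(sys$x$values ~ sys$z$values, order = 3)
  # lmtest fits with intercept on the same rows; our inputs are zero-mean
  # by construction so statistics agree closely, not to machine precision
  expect_equal(g$statistic, gt$F[2], tolerance = 0.02 * gt$F[2])
  expect_lt(g$p_value, 1e-6)
  expect_lt(gt$`Pr(>F)`[2], 1e-6)
})

test_that("nesting and monotone-RSS invariants hold exactly", {
  withr::with_seed(5, {
    for (case in 1:10) {
      n <- 64 + case
      x <- rnorm(n)
      z <- rnorm(n)
      y <- rnorm(n)
      g <- g_pairwise(x, z, order = 3)
      expect_gte(g$g_value, 0)
      # adding a regressor block never increases the RSS
      f0 <- fit_ar(x, order = 3)
      f1 <- fit_ar(x, list(z), order = 3)
      f2 <- fit_ar(x, list(z, y), order = 3)
      expect_lte(f1$rss, f0$rss + 1e-12)
      expect_lte(f2$rss, f1$rss + 1e-12)
      gc <- g_conditional(x, z, cond = y, order = 3)
      expect_gte(gc$g_value, 0)
    }
  })
})

test_that("deterministic dependence hits the perfect-fit sentinel", {
  sys <- pairwise_system(400, q = 1, seed = 13)
  g <- g_pairwise(sys$x, sys$z, order = 5)
  expect_identical(g$g_value, Inf)
  expect_identical(g$p_value, 0)
})

test_that("degenerate inputs are flagged collinear with p-value 1", {
  x <- rep(1, 50)
  z <- rep(2, 50)
  g <- g_pairwise(x, z, order = 2)
  expect_true(g$collinear)
  expect_identical(g$p_value, 1)
})

test_that("chi-squared variant equals order times F with matching tails", {
  sys <- pairwise_system(1024, q = 0.2, seed = 21)
  gf <- g_pairwise(sys$x, sys$z, order = 4, test = "f")
  gc <- g_pairwise(sys$x, sys$z, order = 4, test = "chi2")
  expect_equal(gc$statistic, 4 * gf$statistic, tolerance = 1e-12)
  expect_equal(gc$g_value, gf$g_value, tolerance = 1e-12)
  expect_equal(gc$p_value,
               pchisq(4 * gf$statistic, 4, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("irrelevant conditioning leaves the G-value unchanged", {
  ratios <- sapply(1:20, function(s) {
    sys <- pairwise_system(2^12, q = 0.5, seed = 500 + s)
    y <- fourier_filtered_noise(2^12, 0.5, seed = 900 + s)
    gp <- g_pairwise(sys$x, sys$z, order = 5)$g_value
    gc <- g_conditional(sys$x, sys$z, cond = y, order = 5)$g_value
    gc / gp
  })
  expect_true(all(ratios > 0.8 & ratios < 1.2))
})

test_that("common driver: pairwise detects the indirect link, conditional does not", {
  # coupling product 0.04 sits inside the indirect-detection window:
  # strong enough for the pairwise test, weak enough that conditioning on
  # the driver removes the evidence
  pair_rej <- cond_rej <- logical(5)
  for (s in 1:5) {
    sys <- common_driver_system(2^15, 0.2, 0.2, seed = 700 + s)
    pair_rej[s] <- g_pairwise(sys$x, sys$z, order = 5)$p_value < 0.05
    cond_rej[s] <- g_conditional(sys$x, sys$z, cond = sys$y,
                                 order = 5)$p_value < 0.05
  }
  expect_gte(sum(pair_rej), 4)
  expect_lte(sum(cond_rej), 1)
})

test_that("tidy and glance return well-formed tibbles", {
  sys <- pairwise_system(512, 0.5, seed = 3)
  g <- g_pairwise(sys$x, sys$z, order = 2)
  gl <- glance(g)
  expect_s3_class(gl, "tbl_df")
  expect_equal(nrow(gl), 1)
  expect_named(gl, c("source", "target", "conditional", "g_value",
                     "statistic", "p_value", "test", "order", "n_obs",
                     "collinear"))
  td <- tidy(g)
  expect_s3_class(td, "tbl_df")
  # restricted: 1 block * 2 lags; unrestricted: 2 blocks * 2 lags
  expect_equal(nrow(td), 2 + 4)
  fit <- fit_ar(sys$x, list(z = sys$z), order = 2)
  expect_equal(nrow(tidy(fit)), 4)
  expect_equal(glance(fit)$n_obs, 510)
})
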