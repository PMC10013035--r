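test_that("fourier-filtered noise is standardized exactly and validates input", {
  x <- fourier_filtered_noise(4096, alpha = 0.5, seed = 11)
  expect_s3_class(x, "pc_signal")
  expect_equal(mean(x$values), 0, tolerance = 1e-12)
  expect_equal(var(x$values), 1, tolerance = 1e-12)
  expect_error(fourier_filtered_noise(1), "n")
  expect_error(fourier_filtered_noise(100, alpha = -1), "alpha")
})

test_that("alpha = 0 gives white noise (negligible lag-1 autocorrelation)", {
  x <- fourier_filtered_noise(1024, alpha = 0, seed = 3)$values
  r1 <- stats::acf(x, plot = FALSE, lag.max = 1)$acf[2]
  expect_lt(abs(r1), 0.1)
})

test_that("ensemble log-periodogram slope matches -alpha", {
  n <- 4096
  P <- 0
  for (s in 1:50) {
    x <- fourier_filtered_noise(n, alpha = 0.5, seed = s)$values
    P <- P + Mod(stats::fft(x)[2:(n / 2)])^2
  }
  f <- (1:(n / 2 - 1)) / n
  slope <- unname(coef(lm(log(P / 50) ~ log(f)))[2])
  expect_equal(slope, -0.5, tolerance = 0.05)
})

test_that("pairwise system honours the coupling mixture", {
  # q = 1: pure delayed copy
  s1 <- pairwise_system(200, q = 1, seed = 5)
  expect_equal(s1$x$values[4:200], s1$z$values[1:197])
  # q = 0.5: cross-correlation at the lag follows the closed form
  # q / sqrt(q^2 + (1-q)^2) for independent unit-variance components
  s2 <- pairwise_system(2^14, q = 0.5, seed = 7)
  r <- cor(s2$x$values[-(1:3)], s2$z$values[1:(2^14 - 3)])
  expect_equal(r, 0.5 / sqrt(0.5), tolerance = 0.05)
  expect_length(s2$x$values, 2^14)
  expect_error(pairwise_system(100, q = 1.2), "q")
  expect_error(pairwise_system(2, q = 0.5, lag = 3), "lag")
})

test_that("common-driver system couples both ends to the driver only", {
  # deterministic chain at full coupling: x_t = z_{t-2}
  s1 <- common_driver_system(300, 1, 1, seed = 2)
  expect_equal(s1$x$values[3:300], s1$z$values[1:298])
  # closed-form lagged cross-correlation at q = 0.5 / 0.5
  s2 <- common_driver_system(2^15, 0.5, 0.5, seed = 9)
  r <- cor(s2$z$values[1:(2^15 - 2)], s2$x$values[3:2^15])
  expect_equal(r, 0.25 / 0.5, tolerance = 0.05)
  # zero coupling: three mutually (nearly) uncorrelated series
  s3 <- common_driver_system(2^13, 0, 0, seed = 4)
  cc <- abs(c(cor(s3$x$values, s3$y$values),
              cor(s3$x$values, s3$z$values),
              cor(s3$y$values, s3$z$values)))
  expect_true(all(cc < 0.1))
})

test_that("generators are bit-identical under identical seeds", {
  a <- pairwise_system(512, 0.3, seed = 42)
  b <- pairwise_system(512, 0.3, seed = 42)
  expect_identical(a$x$values, b$x$values)
  expect_identical(a$z$values, b$z$values)
  c1 <- common_driver_system(512, 0.2, 0.4, seed = 42)
  c2 <- common_driver_system(512, 0.2, 0.4, seed = 42)
  expect_identical(c1$z$values, c2$z$values)
  s1 <- synthetic_sleeper(rep("LS", 4), seed = 1)
  s2 <- synthetic_sleeper(rep("LS", 4), seed = 1)
  expect_identical(s1$H$values, s2$H$values)
})

test_that("synthetic sleeper produces aligned 1 Hz channels and hypnogram", {
  st <- rep(c("LS", "DS", "REM"), times = c(4, 3, 2))
  s <- synthetic_sleeper(st, seed = 8)
  expect_identical(s$hypnogram, st)
  expect_length(s$H$values, 9 * 30)
  expect_length(s$B$values, 9 * 30)
  expect_equal(s$E$dt, 1)
  # stage-table input form
  s2 <- synthetic_sleeper(data.frame(stage = "LS", epochs = 4), seed = 1)
  expect_identical(s2$hypnogram, rep("LS", 4))
  expect_error(synthetic_sleeper(c("LS", "XX")), "stage codes")
  bad <- tibble::tibble(from = "B", to = "B", q = 0.5)
  expect_error(synthetic_sleeper(rep("LS", 2), bad), "self-couplings")
  over <- tibble::tibble(from = c("B", "E"), to = "H", q = c(0.7, 0.6))
  expect_error(synthetic_sleeper(rep("LS", 2), over), "exceed")
})

test_that("planted stage-dependent coupling shows up in conditional G", {
  # coupling B -> H present in LS, absent in DS: the LS patches must carry
  # the larger conditional G for that edge in most seeds
  coup <- tibble::tibble(stage = "LS", from = "B", to = "H", q = 0.6,
                         lag = 2)
  wins <- 0
  for (s in 1:10) {
    sl <- synthetic_sleeper(rep(c("LS", "DS"), each = 40), coup,
                            seed = 300 + s)
    net <- reconstruct_network(sl, resolutions = 1, n_boot = 0)
    e <- net$edges
    g_ls <- e$g_mean[e$source == "B" & e$target == "H" & e$stage == "LS"]
    g_ds <- e$g_mean[e$source == "B" & e$target == "H" & e$stage == "DS"]
    if (length(g_ls) == 1 && length(g_ds) == 1 && g_ls > g_ds) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 8)
})
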