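test_that("firing efficiency implements the SR-corrected count", {
  trains <- c(rep(list(c(1e-3)), 50), rep(list(numeric(0)), 50))
  expect_equal(firing_efficiency(trains, 0, 3.5e-3, sr = 0), 0.5)
  expect_equal(firing_efficiency(rep(list(numeric(0)), 10), 0, 3.5e-3), 0)
  # direct evaluation: N = 85, SR = 100/s, T = 3.5 ms, M = 100
  trains85 <- c(rep(list(2e-3), 85), rep(list(numeric(0)), 15))
  expect_equal(firing_efficiency(trains85, 0, 3.5e-3, sr = 100, M = 100),
               (85 - 0.35 * 100) / 100)
})

test_that("integrated-Gaussian fit recovers known parameters", {
  set.seed(1)
  L <- seq(0.8, 1.2, length.out = 10)
  fe <- rbinom(10, 100, pnorm((L - 1.0) / 0.06)) / 100
  fit <- fit_fe_curve(fe_curve(L, fe, 100))
  expect_lt(abs(fit$mu - 1.0), 0.01)
  expect_lt(abs(fit$rs - 0.06), 0.01)
  expect_error(fit_fe_curve(fe_curve(1, 0.5, 100)))
  expect_error(fit_fe_curve(fe_curve(seq(0.9, 1.1, length.out = 5),
                                     rep(0.5, 5), 100)),
               "widen")
})

test_that("dynamic range follows the 10-90 % definition", {
  mkfit <- function(mu, sigma) {
    structure(list(mu = mu, sigma = sigma, rs = sigma / mu), class = "threshold_fit")
  }
  expect_equal(dynamic_range(mkfit(1, 0)), 0)
  # closed form at RS = 4.04 %
  z <- qnorm(0.9)
  expect_equal(dynamic_range(mkfit(1, 0.0404)),
               20 * log10((1 + z * 0.0404) / (1 - z * 0.0404)))
  expect_equal(round(dynamic_range(mkfit(1, 0.0404)), 2), 0.90)
  drs <- sapply(c(0.02, 0.04, 0.08), function(s) dynamic_range(mkfit(1, s)))
  expect_true(all(diff(drs) > 0))
  expect_warning(dd <- dynamic_range(mkfit(1, 1)), "undefined")
  expect_true(is.na(dd))
})

test_that("latency and jitter pool all spikes in post-onset windows", {
  tr <- list(c(1.3e-3), c(5.3e-3, 6e-3))
  lj <- latency_jitter(tr, c(1e-3, 5e-3), T = 3.5e-3)
  expect_equal(lj$n, 3L)
  expect_equal(lj$latency, mean(c(0.3e-3, 0.3e-3, 1e-3)))
  lj0 <- latency_jitter(list(c(0.3e-3, 4.3e-3)), c(0, 4e-3), T = 3.5e-3)
  expect_equal(lj0$latency, 0.3e-3)
  expect_equal(lj0$jitter, 0)
  expect_warning(latency_jitter(list(numeric(0)), 0), "undefined")
  expect_error(latency_jitter(tr, c(0, 1e-3), T = 3.5e-3), "exceeds")
})

test_that("uniform spike latencies tend to T/2 and T/sqrt(12)", {
  set.seed(2)
  sp <- sort(runif(20000, 0, 3.5e-3))
  lj <- latency_jitter(list(sp), 0, T = 3.5e-3)
  expect_lt(abs(lj$latency - 1.75e-3), 0.03e-3)
  expect_lt(abs(lj$jitter - 1.01e-3), 0.03e-3)
})

test_that("vector strength has the exact constructed values", {
  expect_equal(vector_strength((0:9) * 4e-3, 250), 1)
  expect_equal(vector_strength(c(0, 1e-3, 2e-3, 3e-3), 250), 0,
               tolerance = 1e-12)
  expect_warning(v <- vector_strength(numeric(0), 250))
  expect_true(is.na(v))
  set.seed(3)
  vs <- vector_strength(runif(1000, 0, 4e-3), 250)
  expect_lt(vs, 0.1)  # Rayleigh scale 1/sqrt(N)
})

test_that("analytic latency and jitter reduce exactly in both limits", {
  T <- 3.5e-3
  expect_equal(analytic_latency(70, T, 0, 0), T / 2)
  expect_equal(analytic_jitter(70, T, 0, 0, 0), T / sqrt(12))
  expect_equal(analytic_latency(0, T, 0.5, 0.11e-3), 0.11e-3)
  expect_equal(analytic_jitter(0, T, 0.5, 0.11e-3, 0.06e-3), 0.06e-3)
  # direct evaluation of the mixture mean
  expect_equal(analytic_latency(100, T, 0.5, 0.11e-3),
               (0.35 * 1.75e-3 + 0.5 * 0.11e-3) / 0.85)
})

test_that("analytic jitter matches a brute-force mixture simulation", {
  set.seed(4)
  T <- 3.5e-3; N_S <- 70 * T; N_E <- 0.5
  L_E <- 0.11e-3; J_E <- 0.06e-3
  n <- 1e6
  evoked <- runif(n) < N_E / (N_S + N_E)
  lat <- ifelse(evoked, rnorm(n, L_E, J_E), runif(n, 0, T))
  expect_lt(abs(sd(lat) - analytic_jitter(70, T, N_E, L_E, J_E)) /
              sd(lat), 0.01)
})

test_that("interval statistics apply the SR correction", {
  set.seed(5)
  sp <- sort(runif(1000, 0, 10))  # homogeneous 100/s over 10 s
  ivs <- list(A = c(1, 3), B = c(5, 9))
  st <- interval_stats(list(sp), ivs, sr = 100, pulse_rate = 250,
                       pulse_onsets = seq(0, 9.996, by = 4e-3))
  expect_equal(st$interval_id, c("A", "B"))
  expect_lt(max(abs(st$rate)), 3 * sqrt(100 / 2))
  expect_true(all(st$vs < 0.2))
})
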