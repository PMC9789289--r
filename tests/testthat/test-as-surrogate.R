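test_that("spontaneous-rate calibration has the exact limiting behavior", {
  expect_identical(calibrate_spontaneous_rate(0, 450e-6, 512.5e-6), 0)
  expect_identical(calibrate_spontaneous_rate(70, 0, 0), 70)
  expect_error(calibrate_spontaneous_rate(1200, 450e-6, 512.5e-6),
               "unreachable")
})

test_that("calibration closes the loop through the spike generator", {
  set.seed(1)
  r0 <- calibrate_spontaneous_rate(70, 450e-6, 512.5e-6)
  rel <- generate_releases(r0, c(0, 100))
  sp <- releases_to_spikes(rel, 450e-6, 512.5e-6)
  expect_lt(abs(length(sp) / 100 - 70), 2)
})

test_that("release-rate profile has the stated piecewise behavior", {
  f <- mean_fiber(sr = 70)
  p <- rate_profile_params()
  r0 <- calibrate_spontaneous_rate(70, f$t_abs, f$t_rel)
  expect_equal(release_rate_profile(c(0, 1, 2), NULL, f, p), rep(r0, 3))
  spec <- acoustic_stimulus(90, onset = 0.1, duration = 0.2)
  # recovery limit after offset
  expect_equal(release_rate_profile(10, spec, f, p), r0, tolerance = 1e-6)
  # full suppression right at offset
  p1 <- rate_profile_params(suppression_depth = 1)
  expect_equal(release_rate_profile(0.3, spec, f, p1), 0)
  # onset enhancement: rate at onset exceeds the sustained driven rate
  on <- release_rate_profile(0.1, spec, f, p)
  sus <- release_rate_profile(0.29, spec, f, p)
  expect_gt(on, sus)
})

test_that("release generation matches Poisson statistics on the 10 us grid", {
  set.seed(2)
  expect_length(generate_releases(0, c(0, 1)), 0)
  ev <- generate_releases(100, c(0, 100))
  expect_lt(abs(length(ev) - 1e4), 300)
  expect_true(all(diff(ev) >= 10e-6 - 1e-12))
  expect_true(all(round(ev / 10e-6) * 10e-6 - ev < 1e-12))
})

test_that("event counts in disjoint windows are independent", {
  set.seed(3)
  n1 <- n2 <- integer(200)
  for (i in 1:200) {
    ev <- generate_releases(80, c(0, 1))
    n1[i] <- sum(ev < 0.5); n2[i] <- sum(ev >= 0.5)
  }
  a <- n1 > median(n1); b <- n2 > median(n2)
  expect_gt(suppressWarnings(chisq.test(table(a, b))$p.value), 0.01)
})

test_that("the refractory spike generator discards as specified", {
  set.seed(4)
  expect_equal(releases_to_spikes(c(0.1, 0.2, 0.3), 0, 0),
               c(0.1, 0.2, 0.3))
  expect_length(releases_to_spikes(c(1e-3, 1.1e-3), 450e-6, 0), 1)
  # property: output ISIs never fall below t_abs, output is a thinning
  rel <- generate_releases(400, c(0, 5))
  sp <- releases_to_spikes(rel, 450e-6, 512.5e-6)
  expect_true(all(diff(sp) >= 450e-6 - 1e-12))
  expect_true(all(sp %in% as.numeric(rel)))
  expect_lte(length(sp), length(rel))
})

test_that("spontaneous output of the acoustic pathway matches SR", {
  set.seed(5)
  f <- mean_fiber(sr = 70)
  s <- run_as_alone(f, NULL, c(0, 10))
  expect_lt(abs(length(s$times) - 700), 3 * sqrt(700))
})

test_that("spontaneous latency and jitter follow the uniform-window law", {
  set.seed(6)
  f <- mean_fiber(sr = 70)
  s <- run_as_alone(f, NULL, c(0, 10))
  onsets <- seq(0, 10 - 4e-3, by = 4e-3)
  lj <- latency_jitter(list(s), onsets, T = 3.5e-3)
  expect_lt(abs(lj$latency - 1.75e-3), 0.12e-3)
  expect_lt(abs(lj$jitter - 1.01e-3), 0.08e-3)
})

test_that("refractoriness regularizes spontaneous counts (Fano < 1)", {
  set.seed(7)
  f <- mean_fiber(sr = 70)
  counts <- sapply(1:600, function(i) length(run_as_alone(f, NULL,
                                                          c(0, 1))$times))
  expect_lt(var(counts) / mean(counts), 1)
})

test_that("a plug-in release generator replaces the surrogate", {
  f <- mean_fiber(sr = 10)
  fixed <- function(fiber, spec, window) c(0.1, 0.2, 0.5)
  s <- run_as_alone(f, NULL, c(0, 1), release_fun = fixed)
  expect_equal(s$times, c(0.1, 0.2, 0.5))
})
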