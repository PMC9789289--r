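test_that("release currents are rectangular, cathodic and summing", {
  w <- release_current(numeric(0), 1e-6, 100)
  expect_true(all(w$samples == 0))
  w1 <- release_current(1e-3, 1e-6, 2000)
  expect_identical(sum(w1$samples != 0), 40L)
  expect_equal(min(w1$samples), -3.0)
  # overlapping injections sum
  w2 <- release_current(c(1e-3, 1.02e-3), 1e-6, 2000)
  expect_equal(min(w2$samples), -6.0)
})

test_that("one release fires the peripheral neuron of any fiber", {
  set.seed(1)
  for (i in 1:8) {
    f <- sample_fiber(sample(c("LSR", "MSR", "HSR"), 1))
    n <- 3000
    dp <- anfeas:::.release_drive(1e-3, 1e-6, n)
    r <- integrate_fiber(f, dp, numeric(n))
    in_win <- r$times[r$times > 1e-3 & r$times < 2e-3]
    expect_identical(length(in_win), 1L)
    expect_identical(r$neuron[which(r$times %in% in_win)], 1L)
  }
})

test_that("a release inside the dead time is suppressed", {
  f <- mean_fiber()
  n <- 3000
  z <- numeric(n)
  dp <- anfeas:::.release_drive(c(1e-3, 1.1e-3), 1e-6, n)
  r <- integrate_fiber(f, dp, z, noise_per = z, noise_cen = z)
  expect_identical(length(r$times), 1L)
})

test_that("uncoupled output is the plain union of both pathways", {
  set.seed(2)
  f <- mean_fiber(sr = 70)
  w <- monophasic_pulse(0.05, 26e-6, "cathodic", total_duration = 0.2)
  u <- run_uncoupled(f, w, NULL)
  # subthreshold electric: all spikes are acoustic-pathway spontaneous ones
  expect_gt(length(u$times), 0)
  expect_identical(u$times, sort(u$times))
  f0 <- mean_fiber(sr = 0)
  u0 <- run_uncoupled(f0, w, NULL)
  expect_length(u0$times, 0)
})

test_that("coupled model with electric input off reproduces the SR", {
  set.seed(3)
  f <- mean_fiber(sr = 70)
  tot <- 0
  for (i in 1:8) {
    s <- run_coupled(f, NULL, NULL, window = c(0, 2))
    tot <- tot + length(s$times)
  }
  rate <- tot / 16
  expect_lt(abs(rate - 70) / 70, 0.05)
})

test_that("coupled and uncoupled coincide for silent fibers", {
  set.seed(4)
  f <- mean_fiber(sr = 0)
  w <- monophasic_pulse(4, 26e-6, "cathodic", total_duration = 3e-3)
  cp <- run_coupled(f, w, NULL)
  un <- run_uncoupled(f, w, NULL)
  expect_identical(length(cp$times), 1L)
  expect_identical(length(un$times), 1L)
  expect_lt(abs(cp$times[1] - un$times[1]), 3e-4)
})

test_that("alternative coupling honors mutual refractoriness", {
  set.seed(5)
  f <- mean_fiber(sr = 90)
  w <- biphasic_pulse_train(3, 40e-6, 250, 0.2)
  s <- run_alternative(f, w, NULL)
  expect_gt(length(s$times), 10)
  expect_true(all(diff(s$times) >= f$t_abs - 1e-9))
  f0 <- mean_fiber(sr = 0)
  w0 <- monophasic_pulse(0.05, 26e-6, "cathodic", total_duration = 50e-3)
  expect_length(run_alternative(f0, w0, NULL)$times, 0)
})

test_that("combined stimulation adds sublinearly in the coupled model", {
  set.seed(6)
  f <- mean_fiber(sr = 90)
  spec <- acoustic_stimulus(100, onset = 0, duration = 0.5)
  w <- biphasic_pulse_train(2, 40e-6, 250, 0.5)
  n_ea <- n_e <- n_a <- 0
  for (i in 1:3) {
    n_ea <- n_ea + length(run_coupled(f, w, spec)$times)
    n_e <- n_e + length(run_coupled(f, w, NULL)$times)
    n_a <- n_a + length(run_coupled(f, NULL, spec, window = c(0, 0.5))$times)
  }
  expect_lt(n_ea, n_e + n_a)
})
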