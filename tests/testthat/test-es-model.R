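test_that("without noise or drive the membrane rests near E_L", {
  f <- mean_fiber()
  n <- 20000
  z <- numeric(n)
  r <- integrate_fiber(f, z, z, noise_per = z, noise_cen = z)
  expect_length(r$times, 0)
  # the adaptive-exponential rest point sits within 1 mV of E_L (the
  # exponential term is small but nonzero at E_L)
  expect_lt(abs(r$state[1] - (-80)), 1)
  expect_lt(abs(r$state[2] - (-80)), 0.1)
})

test_that("a strongly suprathreshold pulse yields exactly one spike", {
  set.seed(1)
  f <- mean_fiber()
  w <- monophasic_pulse(5, 26e-6, "cathodic", total_duration = 3.5e-3)
  for (tr in run_es_alone(f, w, n_reps = 10)) {
    expect_identical(sum(tr$times >= 0 & tr$times < 3.5e-3), 1L)
  }
})

test_that("subthreshold drive without noise never spikes", {
  f <- mean_fiber()
  w <- monophasic_pulse(0.2, 26e-6, "cathodic", total_duration = 2e-3)
  d <- stimulus_drives(w)
  z <- numeric(length(d$drive_per))
  for (rep in 1:5) {
    r <- integrate_fiber(f, d$drive_per, d$drive_cen,
                         noise_per = z, noise_cen = z)
    expect_length(r$times, 0)
  }
})

test_that("no two spikes fall closer than the dead time", {
  set.seed(2)
  f <- mean_fiber()
  w <- biphasic_pulse_train(4, 40e-6, 250, 60e-3)
  for (tr in run_es_alone(f, w, n_reps = 4)) {
    expect_gt(length(tr$times), 5)
    expect_true(all(diff(tr$times) >= f$t_dead - 1e-9))
  }
})

test_that("pulse polarity selects the spiking neuron", {
  set.seed(3)
  f <- mean_fiber()
  wc <- monophasic_pulse(4, 26e-6, "cathodic", total_duration = 1.5e-3)
  wa <- monophasic_pulse(4, 26e-6, "anodic", total_duration = 1.5e-3)
  tc <- run_es_alone(f, wc, n_reps = 5)
  ta <- run_es_alone(f, wa, n_reps = 5)
  # neuron attribution: 1 = peripheral, 2 = central
  expect_true(all(vapply(tc, function(s) s$neuron[1], 0L) == 1L))
  expect_true(all(vapply(ta, function(s) s$neuron[1], 0L) == 2L))
})

test_that("burn-in without noise decays to rest and differs across streams", {
  f <- mean_fiber()
  k <- es_neuron_constants()
  k0 <- k
  k0$peripheral$sigma_noise <- 0
  k0$central$sigma_noise <- 0
  s <- burn_in(f, duration = 20e-3, consts = k0)
  expect_lt(abs(s[1] - (-80)), 1)
  expect_lt(abs(s[3]), 3)  # subthreshold adaptation current near rest level
  set.seed(4); s1 <- burn_in(f)
  set.seed(5); s2 <- burn_in(f)
  expect_gt(abs(s1[1] - s2[1]), 0)
})

test_that("membrane state is stationary after 20 ms of burn-in", {
  set.seed(6)
  f <- mean_fiber()
  v20 <- replicate(60, burn_in(f, duration = 20e-3)[1])
  v40 <- replicate(60, burn_in(f, duration = 40e-3)[1])
  ks <- suppressWarnings(stats::ks.test(v20, v40))
  expect_gt(ks$p.value, 0.01)
})

test_that("refractory suppression is monotone in the adaptation offset b", {
  set.seed(7)
  f <- mean_fiber()
  k <- es_neuron_constants()
  w <- biphasic_pulse_train(1.3, 40e-6, 250, 100e-3)
  count_at_b <- function(b) {
    kb <- k; kb$b <- b
    mean(sapply(run_es_alone(f, w, n_reps = 4, consts = kb),
                function(s) length(s$times)))
  }
  counts <- sapply(c(90, 900, 9000), count_at_b)
  expect_true(all(diff(counts) < 0))
  # with an enormous increment no two spikes occur within five of the
  # faster (central) suprathreshold adaptation time constants
  kx <- k; kx$b <- 1e5
  for (s in run_es_alone(f, w, n_reps = 4, consts = kx)) {
    if (length(s$times) > 1) {
      expect_true(all(diff(s$times) >= 5 * f$tau_supra_cen))
    }
  }
})

test_that("mean-parameter fiber threshold sits in the published band", {
  set.seed(8)
  f <- mean_fiber()
  bank <- state_bank(f, "es", n_states = 60)
  fit <- fiber_threshold(f, "es-alone", "monophasic", 26e-6, "cathodic",
                         bank = bank, n_final = 60)
  thr_db <- 20 * log10(fit$mu)
  # population band for 26 us cathodic pulses: -1.06 +/- 2 x 3.92 dB
  expect_gt(thr_db, -1.06 - 2 * 3.92)
  expect_lt(thr_db, -1.06 + 2 * 3.92)
})

test_that("threshold at threshold level gives ~50 % firing efficiency", {
  set.seed(9)
  f <- mean_fiber()
  bank <- state_bank(f, "es", n_states = 60)
  fit <- fiber_threshold(f, "es-alone", "monophasic", 26e-6, "cathodic",
                         bank = bank, n_final = 60)
  bld <- anfeas:::.window_stim("monophasic", 26e-6, "cathodic", 3.5e-3)
  fe <- measure_fe(fit$mu, 300, f, "es-alone", bld, bank)
  # binomial 99 % interval around 0.5 at n = 300
  expect_lt(abs(fe - 0.5), 2.58 * sqrt(0.25 / 300) + 0.03)
})
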