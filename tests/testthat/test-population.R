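# Closed-form oracle for the capacitance distribution: C = 10^x F - alpha
# with x ~ N(mu, sigma^2) truncated at mu +/- 2 sigma, alpha in nF.
cap_closed_form <- function(x, mu_row) 10^x * 1e9 - mu_row$cap_alpha

test_that("capacitance transform matches the closed form at the mean", {
  k <- es_neuron_constants()
  expect_equal(cap_closed_form(-6.1514, k$peripheral), 869.5, tolerance = 1e-3)
  expect_equal(cap_closed_form(-5.7547, k$central), 1791.7, tolerance = 1e-3)
})

test_that("capacitance draws respect the truncation bounds", {
  set.seed(1)
  k <- es_neuron_constants()
  for (which in c("peripheral", "central")) {
    p <- k[[which]]
    cc <- sample_capacitance(which, n = 2000)
    lo <- 10^(p$cap_mu - 2 * p$cap_sigma) * 1e9 - p$cap_alpha
    hi <- 10^(p$cap_mu + 2 * p$cap_sigma) * 1e9 - p$cap_alpha
    expect_true(all(cc >= lo & cc <= hi))
  }
})

test_that("capacitance quantiles match the truncated-lognormal-minus-offset law", {
  set.seed(2)
  k <- es_neuron_constants()
  p <- k$peripheral
  cc <- sample_capacitance("peripheral", n = 1e4)
  pfun <- function(C) {
    x <- log10((C + p$cap_alpha) / 1e9)
    z <- (pnorm(x, p$cap_mu, p$cap_sigma) - pnorm(-2)) / (pnorm(2) - pnorm(-2))
    pmin(pmax(z, 0), 1)
  }
  ks <- suppressWarnings(stats::ks.test(cc, pfun))
  expect_gt(ks$p.value, 0.01)
})

test_that("fiber parameters obey the cross-model ties and ranges", {
  set.seed(3)
  for (g in c("LSR", "MSR", "HSR")) {
    f <- sample_fiber(g)
    expect_identical(f$t_dead, f$t_abs)
    # tau_supra scaled by t_rel normalized to its 512.5 us expectation
    expect_equal(f$tau_supra_per / 4500e-6, f$t_rel / 512.5e-6,
                 tolerance = 1e-12)
    expect_equal(f$tau_supra_cen / 2500e-6, f$t_rel / 512.5e-6,
                 tolerance = 1e-12)
    expect_true(f$t_abs >= 208.5e-6 && f$t_abs <= 691.5e-6)
    expect_true(f$t_rel >= 131.0e-6 && f$t_rel <= 894.0e-6)
  }
  expect_error(sample_fiber("XSR"))
})

test_that("spontaneous rates stay inside their group truncation limits", {
  set.seed(4)
  lims <- list(LSR = c(1e-3, 0.2), MSR = c(0.2, 18), HSR = c(18, 180))
  for (g in names(lims)) {
    srs <- replicate(400, sample_fiber(g)$sr)
    expect_true(all(srs >= lims[[g]][1] & srs <= lims[[g]][2]))
  }
})

test_that("HSR spontaneous-rate mean matches the truncated-normal oracle", {
  set.seed(5)
  srs <- replicate(8000, sample_fiber("HSR")$sr)
  # oracle: mean of N(70, 30^2) truncated to [18, 180] by numerical integration
  z <- integrate(function(x) dnorm(x, 70, 30), 18, 180)$value
  m <- integrate(function(x) x * dnorm(x, 70, 30), 18, 180)$value / z
  v <- integrate(function(x) (x - m)^2 * dnorm(x, 70, 30), 18, 180)$value / z
  expect_lt(abs(mean(srs) - m), 3 * sqrt(v / length(srs)))
})

test_that("dead-time mean matches the uniform-distribution mean", {
  set.seed(6)
  td <- replicate(1e4, sample_fiber("HSR")$t_dead)
  se <- (691.5e-6 - 208.5e-6) / sqrt(12) / sqrt(length(td))
  expect_lt(abs(mean(td) - 450e-6), 3 * se)
})

test_that("population sampling is sized, ordered and reproducible", {
  set.seed(7)
  pop <- sample_population(30, 30, 90)
  expect_length(pop, 150)
  expect_equal(sum(vapply(pop, `[[`, "", "sr_group") == "HSR"), 90)
  expect_length(sample_population(0, 0, 0), 0)
  set.seed(8); a <- sample_population(3, 3, 3)
  set.seed(8); b <- sample_population(3, 3, 3)
  expect_identical(a, b)
})

test_that("population round-trips through CSV and JSON", {
  set.seed(9)
  pop <- sample_population(1, 1, 2)
  for (ext in c("csv", "json")) {
    path <- file.path(tempdir(), paste0("pop.", ext))
    write_population(pop, path)
    back <- read_population(path)
    expect_equal(length(back), 4)
    expect_equal(back[[3]]$C_per, pop[[3]]$C_per, tolerance = 1e-8)
    expect_identical(back[[4]]$sr_group, pop[[4]]$sr_group)
  }
})
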