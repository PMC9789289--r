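test_that("analysis intervals sit where the protocol places them", {
  for (dur in c(0.1, 0.2, 0.3)) {
    iv <- eas_intervals(50e-3, dur)
    off <- 50e-3 + dur
    expect_equal(iv$I1, c(0, 50e-3))
    expect_equal(iv$I2, c(50e-3, 70e-3))
    expect_equal(iv$I3, c(off - 30e-3, off))
    expect_equal(iv$I4, c(off, off + 20e-3))
    expect_equal(iv$I5, c(off + 50e-3, off + 150e-3))
    expect_equal(iv$I6, c(off + 150e-3, off + 250e-3))
    durs <- sapply(iv, diff)
    expect_equal(unname(durs), c(50, 20, 30, 20, 100, 100) * 1e-3)
  }
})

test_that("acoustic level selection honors the 250 % criterion and cap", {
  f_low <- mean_fiber(sr = 0.1)
  expect_equal(select_as_level(f_low), 70)
  # saturated driven rate (~150/s) cannot exceed 2.5 x SR for high-SR fibers
  f_high <- mean_fiber(sr = 120)
  expect_equal(select_as_level(f_high), 100)
  f_mid <- mean_fiber(sr = 30)
  expect_true(select_as_level(f_mid) %in% 70:100)
})

test_that("experiment 1 produces the per-condition table deterministically", {
  run_once <- function() {
    set.seed(10)
    pop <- sample_population(1, 0, 1)
    run_experiment1(pop, n_final = 30, n_latency = 30)
  }
  r <- run_once()
  expect_identical(nrow(r$per_fiber), 8L)   # 2 fibers x 2 widths x 2 polarities
  expect_identical(nrow(r$summary), 4L)
  expect_true(all(r$per_fiber$threshold_mA > 0))
  expect_true(all(is.finite(r$per_fiber$latency_s)))
  r2 <- run_once()
  expect_identical(r$per_fiber, r2$per_fiber)
})

test_that("experiment 2 emits tests and analytic-deviation comparisons", {
  set.seed(11)
  pop <- sample_population(0, 0, 5)
  r <- run_experiment2(pop, n_final = 30, n_pres = 3, train_duration = 0.06)
  expect_identical(nrow(r$per_fiber), 15L)  # 5 fibers x 3 variants
  expect_identical(nrow(r$tests), 3L)
  expect_true(all(c("U_threshold", "p_threshold") %in% names(r$tests)))
  expect_true(!is.null(r$deviation_tests))
  expect_true(all(r$deviation_tests$variant %in% c("uncoupled", "coupled")))
})

test_that("experiment 3 reports per-interval differences and I3 ratios", {
  set.seed(12)
  pop <- sample_population(0, 0, 1)
  r <- run_experiment3(pop, n_levels = 2, durations = 0.1, n_final = 30)
  expect_identical(nrow(r$per_run), 2L * 2L * 6L)  # levels x variants x I1-I6
  expect_true(all(r$per_run$interval %in% paste0("I", 1:6)))
  expect_identical(nrow(r$i3), 4L)
  expect_true(all(is.finite(r$i3$rate_ea)))
})

test_that("the command-line interface runs end to end", {
  cli <- system.file("cli", "anfeas", package = "anfeas")
  skip_if(cli == "", "CLI script not installed")
  rscript <- file.path(R.home("bin"), "Rscript")
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  td <- tempdir()
  pop_csv <- file.path(td, "pop.csv")
  out1 <- system2(rscript, c(cli, "population", "--n-fibers", "6",
                             "--seed", "1", "--out", pop_csv),
                  stdout = TRUE, stderr = TRUE,
                  env = paste0("R_LIBS=", libs))
  expect_true(file.exists(pop_csv))
  expect_identical(nrow(read.csv(pop_csv)), 6L)
  # subthreshold electric-only simulation: empty spike table
  sp_csv <- file.path(td, "spikes.csv")
  system2(rscript, c(cli, "simulate", "--coupling", "es-alone",
                     "--amplitude", "0.01", "--train-duration", "0.05",
                     "--seed", "2", "--out", sp_csv),
          stdout = TRUE, stderr = TRUE, env = paste0("R_LIBS=", libs))
  expect_true(file.exists(sp_csv))
  expect_identical(nrow(read.csv(sp_csv)), 0L)
  # determinism: the same seed yields byte-identical outputs
  sp2 <- file.path(td, "spikes2.csv")
  system2(rscript, c(cli, "simulate", "--coupling", "uncoupled",
                     "--amplitude", "1.5", "--train-duration", "0.05",
                     "--seed", "3", "--out", sp_csv),
          stdout = TRUE, stderr = TRUE, env = paste0("R_LIBS=", libs))
  system2(rscript, c(cli, "simulate", "--coupling", "uncoupled",
                     "--amplitude", "1.5", "--train-duration", "0.05",
                     "--seed", "3", "--out", sp2),
          stdout = TRUE, stderr = TRUE, env = paste0("R_LIBS=", libs))
  expect_identical(readLines(sp_csv), readLines(sp2))
})
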