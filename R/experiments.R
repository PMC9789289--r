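#' Latency/jitter and rate statistics for pulse-train stimulation
#'
#' Simulates repeated presentations of a biphasic pulse train for one
#' fiber and model variant and pools the latencies of all spikes falling
#' in the analysis window after each pulse onset.
#'
#' @param fiber a \code{fiber_params} object.
#' @param level phase current (mA).
#' @param variant \code{"es-alone"}, \code{"uncoupled"} or
#'   \code{"coupled"}.
#' @param n_pres number of train presentations (the single-fiber
#'   literature uses at least 15).
#' @param phase_width,rate,train_duration train parameters.
#' @param T post-pulse analysis window (s).
#' @param params surrogate parameters.
#' @param consts constants.
#' @return list(latency, jitter, n, trains, onsets).
#' @export
fiber_train_stats <- function(fiber, level, variant = "es-alone",
                              n_pres = 20, phase_width = 40e-6, rate = 250,
                              train_duration = 0.3, T = 3.5e-3,
                              params = rate_profile_params(),
                              consts = es_neuron_constants()) {
  w <- biphasic_pulse_train(level, phase_width, rate, train_duration)
  d <- stimulus_drives(w, consts$beta)
  dt <- w$dt
  burn <- 20e-3
  nb <- round(burn / dt)
  n <- nb + length(w$samples)
  extra <- NULL
  if (variant == "coupled" && fiber$sr > 0) {
    r0 <- calibrate_spontaneous_rate(fiber$sr, fiber$t_abs, fiber$t_rel)
    extra <- matrix(0, n, n_pres)
    for (k in seq_len(n_pres)) {
      rel <- generate_releases(r0, c(0, n * dt))
      extra[, k] <- .release_drive(rel, dt, n)
    }
  }
  r <- .es_run_trials(fiber, d$drive_per, d$drive_cen, n_pres, dt = dt,
                      burn_in_dur = burn, extra_per = extra, consts = consts)
  trains <- lapply(r$times, function(tt) tt[tt >= 0])
  if (variant == "uncoupled") {
    trains <- lapply(trains, function(tt) {
      as_sp <- run_as_alone(fiber, NULL, c(-50e-3, train_duration),
                            params)$times
      sort(c(tt, as_sp[as_sp >= 0]))
    })
  }
  lj <- suppressWarnings(latency_jitter(trains, w$onsets, T))
  lj$spikes_per_window <- lj$n / (length(w$onsets) * n_pres)
  c(lj, list(trains = trains, onsets = w$onsets))
}

#' Experiment 1: single monophasic pulses in acoustically insensitive fibers
#'
#' For every fiber and every combination of phase width (26, 39 us) and
#' polarity (cathodic, anodic): fits the firing-efficiency curve of a
#' single monophasic pulse, then measures latency and jitter at the fitted
#' threshold (3.5 ms window, 100 presentations).
#'
#' @param pop fiber population (list of \code{fiber_params}); sampled
#'   with the given counts when \code{NULL}.
#' @param n_lsr,n_msr,n_hsr population counts used if \code{pop} is NULL.
#' @param widths phase widths (s).
#' @param polarities pulse polarities.
#' @param n_final trials per final FE level.
#' @param n_latency presentations for the latency estimate.
#' @param progress print one line per fiber.
#' @return list with \code{per_fiber} (data.frame) and \code{summary}
#'   (mean and SD per condition, the population-table layout).
#' @export
run_experiment1 <- function(pop = NULL, n_lsr = 30, n_msr = 30, n_hsr = 90,
                            widths = c(26e-6, 39e-6),
                            polarities = c("cathodic", "anodic"),
                            n_final = 100, n_latency = 100,
                            progress = FALSE) {
  if (is.null(pop)) pop <- sample_population(n_lsr, n_msr, n_hsr)
  rows <- list()
  for (f in pop) {
    bank <- state_bank(f, "es")
    for (wd in widths) for (pol in polarities) {
      fit <- fiber_threshold(f, "es-alone", "monophasic", wd, pol,
                             bank = bank, n_final = n_final)
      lj <- fiber_latency(f, fit$mu, "es-alone", "monophasic", wd, pol,
                          bank = bank, n_reps = n_latency)
      rows[[length(rows) + 1]] <- data.frame(
        fiber_id = f$fiber_id, sr_group = f$sr_group,
        width_us = wd * 1e6, polarity = pol,
        threshold_mA = fit$mu, threshold_db = 20 * log10(fit$mu),
        rs = fit$rs, dr_db = fit$dr_db,
        latency_s = lj$latency, jitter_s = lj$jitter)
    }
    if (progress) cat(sprintf("fiber %d done\n", f$fiber_id))
  }
  per_fiber <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(
    per_fiber, list(per_fiber$width_us, per_fiber$polarity)), function(d) {
      data.frame(width_us = d$width_us[1], polarity = d$polarity[1],
                 threshold_db_mean = mean(d$threshold_db),
                 threshold_db_sd = sd(d$threshold_db),
                 latency_us_mean = mean(d$latency_s, na.rm = TRUE) * 1e6,
                 latency_us_sd = sd(d$latency_s, na.rm = TRUE) * 1e6,
                 jitter_us_mean = mean(d$jitter_s, na.rm = TRUE) * 1e6,
                 jitter_us_sd = sd(d$jitter_s, na.rm = TRUE) * 1e6,
                 rs_pct_mean = mean(d$rs) * 100, rs_pct_sd = sd(d$rs) * 100)
    }))
  rownames(summary) <- NULL
  list(per_fiber = per_fiber, summary = summary)
}

#' Experiment 2: biphasic pulse trains in acoustically sensitive fibers
#'
#' First-pulse thresholds and dynamic ranges of 250 pps biphasic
#' (cathodic-leading, 40 us/phase) pulse trains for the ES-alone,
#' uncoupled and coupled model variants, with nonparametric comparisons;
#' optionally latency/jitter at threshold from full-train runs, compared
#' per fiber against the analytic non-interacting estimates.
#'
#' @param pop fiber population; sampled if NULL.
#' @param n_lsr,n_msr,n_hsr population counts used if \code{pop} is NULL.
#' @param variants model variants to fit.
#' @param n_final trials per final FE level.
#' @param do_latency variants for which full-train latency/jitter at
#'   threshold are computed (character vector, possibly empty).
#' @param n_pres train presentations for the latency runs.
#' @param train_duration train length (s).
#' @param progress print one line per fiber.
#' @return list with \code{per_fiber}, \code{tests} (Mann-Whitney U
#'   results on thresholds and DRs), \code{deviation_tests} (Wilcoxon
#'   signed-rank of latency/jitter deviations from the analytic
#'   estimates, split at SR = 50), and \code{regressions}.
#' @export
run_experiment2 <- function(pop = NULL, n_lsr = 30, n_msr = 30, n_hsr = 90,
                            variants = c("es-alone", "uncoupled", "coupled"),
                            n_final = 100,
                            do_latency = c("es-alone", "uncoupled",
                                           "coupled"),
                            n_pres = 20, train_duration = 0.3,
                            progress = FALSE) {
  if (is.null(pop)) pop <- sample_population(n_lsr, n_msr, n_hsr)
  rows <- list()
  for (f in pop) {
    be <- state_bank(f, "es")
    bc <- if (any(c("coupled", "alternative") %in% variants)) {
      state_bank(f, "coupled")
    } else NULL
    for (v in variants) {
      bank <- if (v %in% c("coupled", "alternative")) bc else be
      fit <- fiber_threshold(f, v, "biphasic", 40e-6, bank = bank,
                             n_final = n_final)
      lat <- jit <- spw <- NA_real_
      if (v %in% do_latency) {
        ts <- fiber_train_stats(f, fit$mu, v, n_pres = n_pres,
                                train_duration = train_duration)
        lat <- ts$latency; jit <- ts$jitter
        spw <- ts$spikes_per_window
      }
      rows[[length(rows) + 1]] <- data.frame(
        fiber_id = f$fiber_id, sr_group = f$sr_group, sr = f$sr,
        t_abs = f$t_abs, variant = v,
        threshold_mA = fit$mu, rs = fit$rs, dr_db = fit$dr_db,
        latency_s = lat, jitter_s = jit, spikes_per_window = spw)
    }
    if (progress) cat(sprintf("fiber %d done\n", f$fiber_id))
  }
  per_fiber <- do.call(rbind, rows)
  wide <- function(col) {
    sapply(variants, function(v)
      per_fiber[per_fiber$variant == v, col], simplify = FALSE)
  }
  thr <- wide("threshold_mA"); dr <- wide("dr_db")
  pairs <- utils::combn(variants, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(p) {
    wt <- stats::wilcox.test(thr[[p[1]]], thr[[p[2]]], exact = FALSE)
    wd <- stats::wilcox.test(dr[[p[1]]], dr[[p[2]]], exact = FALSE)
    data.frame(comparison = paste(p, collapse = " vs "),
               U_threshold = unname(wt$statistic), p_threshold = wt$p.value,
               U_dr = unname(wd$statistic), p_dr = wd$p.value)
  }))
  # deviations from the analytic non-interacting estimates.  N_E is each
  # fiber's measured evoked count per analysis window from its ES-alone
  # run (the definition entering the estimates; per-pulse firing
  # efficiency declines across the train, so the nominal first-pulse 0.5
  # would mis-state the mixture weights); L_E and J_E are the per-fiber
  # ES-alone latency and jitter.
  deviation_tests <- NULL
  if (all(c("es-alone") %in% do_latency)) {
    base <- per_fiber[per_fiber$variant == "es-alone", ]
    devs <- list()
    for (v in setdiff(do_latency, "es-alone")) {
      d <- per_fiber[per_fiber$variant == v, ]
      L_pred <- mapply(analytic_latency, base$sr, 3.5e-3,
                       base$spikes_per_window, base$latency_s)
      J_pred <- mapply(analytic_jitter, base$sr, 3.5e-3,
                       base$spikes_per_window, base$latency_s,
                       base$jitter_s)
      for (grp in c("SR<=50", "SR>50")) {
        sel <- if (grp == "SR<=50") base$sr <= 50 else base$sr > 50
        if (sum(sel, na.rm = TRUE) < 3) next
        dl <- d$latency_s[sel] - L_pred[sel]
        dj <- d$jitter_s[sel] - J_pred[sel]
        wl <- stats::wilcox.test(dl, exact = FALSE)
        wj <- stats::wilcox.test(dj, exact = FALSE)
        devs[[length(devs) + 1]] <- data.frame(
          variant = v, group = grp, n = sum(sel),
          latency_dev_s = mean(dl, na.rm = TRUE), p_latency = wl$p.value,
          jitter_dev_s = mean(dj, na.rm = TRUE), p_jitter = wj$p.value)
      }
    }
    deviation_tests <- do.call(rbind, devs)
  }
  regressions <- NULL
  if (all(c("es-alone", "coupled") %in% variants)) {
    e <- per_fiber[per_fiber$variant == "es-alone", ]
    cc <- per_fiber[per_fiber$variant == "coupled", ]
    dthr <- cc$threshold_mA - e$threshold_mA
    ddr <- cc$dr_db - e$dr_db
    regressions <- list(
      dthr_vs_sr = stats::lm(dthr ~ e$sr),
      ddr_vs_sr = stats::lm(ddr ~ e$sr),
      dthr_vs_arp = stats::lm(dthr ~ e$t_abs),
      ddr_vs_arp = stats::lm(ddr ~ e$t_abs))
  }
  list(per_fiber = per_fiber, tests = tests,
       deviation_tests = deviation_tests, regressions = regressions)
}

#' Analysis intervals for combined electric-acoustic stimulation
#'
#' Six intervals defined relative to the acoustic onset and offset:
#' I1 the 50 ms before onset, I2 the 20 ms after onset, I3 the 30 ms
#' before offset, I4 the 20 ms after offset, I5 a 100 ms window starting
#' 50 ms after offset, and I6 the following 100 ms.
#'
#' @param as_onset acoustic stimulus onset (s).
#' @param as_duration acoustic stimulus duration (s).
#' @return Named list of c(start, end) pairs.
#' @export
eas_intervals <- function(as_onset, as_duration) {
  off <- as_onset + as_duration
  list(I1 = c(as_onset - 50e-3, as_onset),
       I2 = c(as_onset, as_onset + 20e-3),
       I3 = c(off - 30e-3, off),
       I4 = c(off, off + 20e-3),
       I5 = c(off + 50e-3, off + 150e-3),
       I6 = c(off + 150e-3, off + 250e-3))
}

#' Experiment 3: combined electric-acoustic stimulation
#'
#' For each fiber: four current levels drawn uniformly across the fiber's
#' dynamic range (the 10-90 % FE span of its coupled-model first-pulse
#' fit), a broadband-noise burst of 100/200/300 ms (one third of the
#' population each) at the lowest level in [70, 100] dB SPL whose
#' predicted driven rate exceeds the spontaneous rate by at least 250 %
#' (100 dB if none), and an electric pulse train starting 50 ms before
#' the acoustic onset and ending 250 ms after its offset.  The
#' electric+acoustic (EA), electric-only (E), and acoustic-only (A)
#' conditions are simulated with the uncoupled and the coupled model
#' (E and EA with matched noise seeds), and per-interval differences and
#' rate ratios are reported.
#'
#' @param pop fiber population; sampled if NULL.
#' @param n_lsr,n_msr,n_hsr population counts used if \code{pop} is NULL.
#' @param n_levels current levels per fiber.
#' @param durations acoustic durations to cycle through (s).
#' @param n_final trials per final FE level in the DR fit.
#' @param params surrogate parameters.
#' @param progress print one line per fiber.
#' @return list with \code{per_run} (one row per fiber x level x variant
#'   x interval: EA-E differences in rate, jitter, VS) and \code{i3}
#'   (interval-I3 EA/E and EA/A rate ratios).
#' @export
run_experiment3 <- function(pop = NULL, n_lsr = 10, n_msr = 10, n_hsr = 30,
                            n_levels = 4, durations = c(0.1, 0.2, 0.3),
                            n_final = 100, params = rate_profile_params(),
                            progress = FALSE) {
  if (is.null(pop)) pop <- sample_population(n_lsr, n_msr, n_hsr)
  as_onset <- 50e-3
  rate <- 250
  per_run <- list(); i3 <- list()
  for (fi in seq_along(pop)) {
    f <- pop[[fi]]
    bc <- state_bank(f, "coupled", params = params)
    fit <- fiber_threshold(f, "coupled", "biphasic", 40e-6, bank = bc,
                           n_final = n_final, params = params)
    z90 <- stats::qnorm(0.9)
    l10 <- max(fit$mu - z90 * fit$sigma, 0.05 * fit$mu)
    l90 <- fit$mu + z90 * fit$sigma
    levels <- stats::runif(n_levels, l10, l90)
    dur <- durations[(fi - 1) %% length(durations) + 1]
    as_level <- select_as_level(f, params)
    spec <- acoustic_stimulus(as_level, as_onset, dur)
    train_dur <- as_onset + dur + 250e-3
    ivs <- eas_intervals(as_onset, dur)
    onsets <- (seq_len(floor(rate * train_dur)) - 1) / rate
    for (lv in levels) {
      elec <- biphasic_pulse_train(lv, 40e-6, rate, train_dur)
      for (v in c("uncoupled", "coupled")) {
        runner <- if (v == "uncoupled") run_uncoupled else run_coupled
        seed <- sample.int(.Machine$integer.max, 1)
        set.seed(seed)
        ea <- runner(f, elec, spec, params = params)
        set.seed(seed)
        e <- runner(f, elec, NULL, params = params)
        a <- runner(f, NULL, spec, window = c(0, train_dur),
                    params = params)
        st_ea <- interval_stats(ea, ivs, f$sr, rate, onsets)
        st_e <- interval_stats(e, ivs, f$sr, rate, onsets)
        st_a <- interval_stats(a, ivs, f$sr, rate, onsets)
        per_run[[length(per_run) + 1]] <- data.frame(
          fiber_id = f$fiber_id, sr = f$sr, level_mA = lv, variant = v,
          interval = st_ea$interval_id,
          rate_diff = st_ea$rate - st_e$rate,
          jitter_diff = st_ea$jitter - st_e$jitter,
          vs_diff = st_ea$vs - st_e$vs)
        r_ea <- st_ea$rate[st_ea$interval_id == "I3"]
        r_e <- st_e$rate[st_e$interval_id == "I3"]
        r_a <- st_a$rate[st_a$interval_id == "I3"]
        i3[[length(i3) + 1]] <- data.frame(
          fiber_id = f$fiber_id, sr = f$sr, level_mA = lv, variant = v,
          rate_ea = r_ea, rate_e = r_e, rate_a = r_a)
      }
    }
    if (progress) cat(sprintf("fiber %d done\n", f$fiber_id))
  }
  list(per_run = do.call(rbind, per_run), i3 = do.call(rbind, i3))
}

#' Acoustic level selection for combined-stimulation runs
#'
#' Lowest level in [70, 100] dB SPL whose predicted sustained driven
#' spike rate exceeds the fiber's spontaneous rate by at least 250 %;
#' 100 dB SPL if no level qualifies.
#'
#' @param fiber a \code{fiber_params} object.
#' @param params surrogate parameters.
#' @param candidates candidate levels (dB SPL).
#' @return Selected level in dB SPL.
#' @export
select_as_level <- function(fiber, params = rate_profile_params(),
                            candidates = 70:100) {
  r0 <- calibrate_spontaneous_rate(fiber$sr, fiber$t_abs, fiber$t_rel)
  tot <- fiber$t_abs + fiber$t_rel
  for (L in sort(candidates)) {
    eff <- L - fiber$hearing_loss
    r_driven <- params$r_max / (1 + exp(-(eff - params$L50) / params$slope))
    r_tot <- r0 + r_driven
    driven_spikes <- r_tot / (1 + r_tot * tot) - fiber$sr
    if (driven_spikes >= 2.5 * fiber$sr) return(L)
  }
  max(candidates)
}
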