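#' Stationary ensemble of pre-stimulus states for one fiber
#'
#' In the absence of stimulation the membrane is in a random state
#' produced by its intrinsic noise (and, for an acoustically sensitive
#' fiber in the coupled model, by its ongoing spontaneous synaptic input).
#' This function evolves one long unstimulated run and snapshots the state
#' every \code{spacing} seconds (several suprathreshold-adaptation time
#' constants, so successive snapshots are effectively independent draws
#' from the stationary distribution).  Trial batches then start from these
#' states instead of repeating a burn-in integration for every trial.
#'
#' @param fiber a \code{fiber_params} object.
#' @param variant \code{"es"} (membrane noise only) or \code{"coupled"}
#'   (spontaneous release currents injected into the peripheral neuron).
#' @param n_states number of snapshots.
#' @param spacing snapshot spacing in s.
#' @param warmup initial span discarded before the first snapshot (s).
#' @param dt integration step (s).
#' @param params surrogate parameters (used for \code{"coupled"}).
#' @param consts constants from [es_neuron_constants()].
#' @return A list: \code{states} (7 x n_states matrix), \code{variant},
#'   \code{spont_rate} (release rate used, events/s).
#' @export
state_bank <- function(fiber, variant = c("es", "coupled"), n_states = 100,
                       spacing = 20e-3, warmup = 50e-3, dt = 1e-6,
                       params = rate_profile_params(),
                       consts = es_neuron_constants()) {
  variant <- match.arg(variant)
  n <- round((warmup + n_states * spacing) / dt)
  pr <- .noise_pairs(n, 1L, consts$alpha_noise)
  dp <- numeric(n)
  r0 <- 0
  if (variant == "coupled" && fiber$sr > 0) {
    r0 <- calibrate_spontaneous_rate(fiber$sr, fiber$t_abs, fiber$t_rel)
    rel <- generate_releases(r0, c(0, n * dt))
    dp <- .release_drive(rel, dt, n)
  }
  at <- round((warmup + seq_len(n_states) * spacing) / dt)
  r <- es_collect_states_cpp(dp, numeric(n),
                             pr$A[, 1] * consts$peripheral$sigma_noise,
                             pr$B[, 1] * consts$central$sigma_noise,
                             dt * 1e6, .es_par(fiber, consts),
                             .es_rest_state(consts), as.integer(at))
  list(states = r$states, variant = variant, spont_rate = r0)
}

# spike-time lists for a batch of window trials of one model variant.
# drive traces cover the analysis window only (t = 0 at window start);
# initial states are drawn from the bank.  Returns a list of numeric
# spike-time vectors (s).
.window_trials <- function(fiber, drive_per, drive_cen, n_trials, bank,
                           variant, dt = 1e-6,
                           params = rate_profile_params(),
                           consts = es_neuron_constants(), pre = 3e-3) {
  nw <- length(drive_per)
  npre <- round(pre / dt)
  n <- npre + nw
  dp <- c(numeric(npre), drive_per)
  dc <- c(numeric(npre), drive_cen)
  pr <- .noise_pairs(n, n_trials, consts$alpha_noise)
  # Each trial carries its own noise over a short pre-stimulus span so the
  # initial state and the in-window noise share one continuous slow-noise
  # history, as in a full-length (burn-in + window) trial.  The remaining
  # band -- components slower than this span but faster than a full trial
  # -- acts as a quasi-constant per-trial current offset and is restored
  # explicitly on each neuron.
  so <- .slow_offset_share(n, dt, consts$alpha_noise,
                           burn_in_dur = max(0, 20e-3 - pre))
  if (so > 0) {
    pr$A <- sweep(pr$A, 2, stats::rnorm(n_trials, 0, sqrt(so)), "+")
    pr$B <- sweep(pr$B, 2, stats::rnorm(n_trials, 0, sqrt(so)), "+")
  }
  ns <- ncol(bank$states)
  pick <- sample.int(ns, n_trials, replace = n_trials > ns)
  states <- bank$states[, pick, drop = FALSE]
  if (variant %in% c("coupled", "alternative") && bank$spont_rate > 0) {
    rel <- lapply(seq_len(n_trials), function(k) {
      as.numeric(generate_releases(bank$spont_rate, c(0, n * dt)))
    })
  } else rel <- NULL
  shift <- function(ix) (ix - npre) * dt
  if (variant == "alternative") {
    rel_idx <- lapply(rel %||% rep(list(numeric(0)), n_trials), function(tt) {
      ii <- as.integer(round(tt / dt))
      ii[ii >= 1 & ii <= n]
    })
    r <- eas_alt_integrate_cpp(dp, dc,
                               pr$A * consts$peripheral$sigma_noise,
                               pr$B * consts$central$sigma_noise,
                               integer(0), rel_idx, dt * 1e6,
                               fiber$t_abs * 1e6, fiber$t_rel * 1e6,
                               .es_par(fiber, consts), states)
    return(lapply(r$spike_idx, shift))
  }
  extra <- NULL
  if (!is.null(rel)) {
    extra <- matrix(0, n, n_trials)
    for (k in seq_len(n_trials)) {
      extra[, k] <- .release_drive(rel[[k]], dt, n)
    }
  }
  r <- es_integrate_batch_cpp(dp, dc,
                              pr$A * consts$peripheral$sigma_noise,
                              pr$B * consts$central$sigma_noise,
                              dt * 1e6, .es_par(fiber, consts), states, extra)
  out <- lapply(r$spike_idx, shift)
  if (variant == "uncoupled") {
    # merge independent spontaneous acoustic-pathway spikes (no interaction)
    out <- lapply(out, function(tt) {
      as_sp <- run_as_alone(fiber, NULL, c(-50e-3, nw * dt))$times
      sort(c(tt, as_sp[as_sp >= 0]))
    })
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measure one firing-efficiency point
#'
#' Simulates \code{n_trials} presentations of the stimulus at one level
#' and returns the spontaneous-rate-corrected firing efficiency in the
#' first \code{T} seconds of the window.
#'
#' @param level stimulus level in mA.
#' @param n_trials number of presentations.
#' @param fiber a \code{fiber_params} object.
#' @param variant \code{"es-alone"}, \code{"uncoupled"}, \code{"coupled"}
#'   or \code{"alternative"}.
#' @param stim_builder function(level) returning an
#'   \code{electric_waveform} whose span covers the analysis window.
#' @param bank a [state_bank()] matching the variant.
#' @param T analysis window duration (s).
#' @param params surrogate parameters.
#' @param consts constants.
#' @return Firing efficiency (numeric scalar).
#' @export
measure_fe <- function(level, n_trials, fiber, variant, stim_builder, bank,
                       T = 3.5e-3, params = rate_profile_params(),
                       consts = es_neuron_constants()) {
  w <- stim_builder(level)
  d <- stimulus_drives(w, consts$beta)
  v <- if (variant == "es-alone") "es" else variant
  trains <- .window_trials(fiber, d$drive_per, d$drive_cen, n_trials, bank,
                           v, dt = w$dt, params = params, consts = consts)
  sr_eff <- if (variant == "es-alone") 0 else fiber$sr
  firing_efficiency(trains, 0, T, sr = sr_eff, M = n_trials)
}

#' Adaptive threshold measurement for one fiber
#'
#' Staged protocol: (1) a factor-2 bracketing search for levels with FE
#' below 0.1 and above 0.9; (2) a coarse scan of the bracket to localize
#' the crossings; (3) \code{n_levels} equally spaced levels across the
#' refined bracket (extended by 25 % on each side) at \code{n_final}
#' trials per level.  The final integrated-Gaussian fit uses all
#' collected points with binomial weights.
#'
#' @param sim_fe function(level, n_trials) returning a firing efficiency.
#' @param guess starting level (mA).
#' @param n_probe trials per bracketing probe.
#' @param n_stage2 trials per coarse-scan level.
#' @param n_final trials per final level.
#' @param n_levels number of final levels.
#' @return A \code{threshold_fit} (see [fit_fe_curve()]).
#' @export
fit_threshold <- function(sim_fe, guess = 1.0, n_probe = 30, n_stage2 = 30,
                          n_final = 100, n_levels = 10) {
  lv <- c(); fe <- c(); nn <- c()
  add <- function(L, n) {
    f <- sim_fe(L, n)
    lv <<- c(lv, L); fe <<- c(fe, f); nn <<- c(nn, n)
    f
  }
  f0 <- add(guess, n_probe)
  L_hi <- L_lo <- guess
  f_hi <- f_lo <- f0
  it <- 0
  while (f_hi < 0.9 && it < 14) { L_hi <- L_hi * 2; f_hi <- add(L_hi, n_probe); it <- it + 1 }
  it <- 0
  while (f_lo > 0.1 && it < 14) { L_lo <- L_lo / 2; f_lo <- add(L_lo, n_probe); it <- it + 1 }
  # firing efficiency can saturate below 0.9 (a pulse falling in the dead
  # time never fires, capping FE near 1 - SR * t_abs), so the upper
  # bracket only requires the fit's own 0.8 reachability
  if (max(fe) < 0.8 || min(fe) > 0.2) {
    stop("bracketing failed: FE does not span 0.2-0.8; widen the level sweep")
  }
  # stage 2: scan the bracket to localize the 0.1 / 0.9 crossings
  s2 <- seq(L_lo, L_hi, length.out = 8)[2:7]
  for (L in s2) add(L, n_stage2)
  below <- lv[fe <= 0.1]
  above <- lv[fe >= 0.9]
  lo2 <- if (length(below)) max(below) else min(lv)
  hi2 <- if (length(above)) min(above) else lv[which.max(fe)]
  if (lo2 >= hi2) { lo2 <- L_lo; hi2 <- L_hi }
  # stage 3: 10 equally spaced levels across the refined bracket (a 25 %
  # margin keeps the fit anchored outside the transition)
  ext <- 0.25 * (hi2 - lo2)
  lo <- max(lo2 - ext, 0.05 * lo2)
  hi <- hi2 + ext
  for (L in seq(lo, hi, length.out = n_levels)) add(L, n_final)
  keep <- !duplicated(lv)
  o <- order(lv[keep])
  fit_fe_curve(fe_curve(lv[keep][o], fe[keep][o], nn[keep][o]))
}

#' Threshold, RS and DR of one fiber for a standard stimulus
#'
#' Convenience wrapper binding [fit_threshold()] to a fiber, a model
#' variant, and one of the package's standard stimuli: a single monophasic
#' pulse (analysis window 3.5 ms) or the first pulse of a biphasic pulse
#' train (first-pulse firing efficiency).
#'
#' @param fiber a \code{fiber_params} object.
#' @param variant model variant (see [measure_fe()]).
#' @param stim \code{"monophasic"} or \code{"biphasic"}.
#' @param phase_width phase duration in s.
#' @param polarity pulse polarity (monophasic) or leading-phase polarity
#'   (biphasic).
#' @param T analysis window (s).
#' @param bank optional precomputed [state_bank()].
#' @param guess starting level (mA).
#' @param n_final trials per final level.
#' @param params surrogate parameters.
#' @param consts constants.
#' @return A \code{threshold_fit} with the bank attached as
#'   \code{attr(, "bank")}.
#' @export
fiber_threshold <- function(fiber, variant = "es-alone",
                            stim = c("monophasic", "biphasic"),
                            phase_width = 26e-6, polarity = "cathodic",
                            T = 3.5e-3, bank = NULL, guess = 1.0,
                            n_final = 100, params = rate_profile_params(),
                            consts = es_neuron_constants()) {
  stim <- match.arg(stim)
  if (is.null(bank)) {
    bank <- state_bank(fiber,
                       if (variant %in% c("coupled", "alternative"))
                         "coupled" else "es",
                       params = params, consts = consts)
  }
  builder <- .window_stim(stim, phase_width, polarity, T)
  fit <- fit_threshold(function(L, n) {
    measure_fe(L, n, fiber, variant, builder, bank, T = T, params = params,
               consts = consts)
  }, guess = guess, n_final = n_final)
  attr(fit, "bank") <- bank
  fit
}

#' Latency and jitter at a given level for a single-pulse stimulus
#'
#' @param fiber a \code{fiber_params} object.
#' @param level stimulus level (mA).
#' @param variant model variant.
#' @param stim,phase_width,polarity,T,bank,params,consts as in
#'   [fiber_threshold()].
#' @param n_reps presentations to pool.
#' @return list(latency, jitter, n) as in [latency_jitter()].
#' @export
fiber_latency <- function(fiber, level, variant = "es-alone",
                          stim = c("monophasic", "biphasic"),
                          phase_width = 26e-6, polarity = "cathodic",
                          T = 3.5e-3, bank = NULL, n_reps = 100,
                          params = rate_profile_params(),
                          consts = es_neuron_constants()) {
  stim <- match.arg(stim)
  if (is.null(bank)) {
    bank <- state_bank(fiber,
                       if (variant %in% c("coupled", "alternative"))
                         "coupled" else "es",
                       params = params, consts = consts)
  }
  w <- .window_stim(stim, phase_width, polarity, T)(level)
  d <- stimulus_drives(w, consts$beta)
  v <- if (variant == "es-alone") "es" else variant
  trains <- .window_trials(fiber, d$drive_per, d$drive_cen, n_reps, bank, v,
                           dt = w$dt, params = params, consts = consts)
  latency_jitter(trains, 0, T)
}

# single-pulse stimulus covering exactly the analysis window [0, T)
.window_stim <- function(stim, phase_width, polarity, T, dt = 1e-6) {
  n <- round(T / dt)
  if (stim == "monophasic") {
    function(level) monophasic_pulse(level, phase_width, polarity,
                                     dt = dt, total_duration = T)
  } else {
    function(level) {
      b <- biphasic_pulse_train(level, phase_width, 250, 1 / 250,
                                leading = polarity, dt = dt)
      s <- b$samples
      s <- if (length(s) >= n) s[seq_len(n)] else c(s, numeric(n - length(s)))
      electric_waveform(s, dt, onsets = 0)
    }
  }
}

# share of unit noise variance carried by frequencies below the analysis
# window's fundamental, for a reference trial of burn-in + window length
.slow_offset_share <- function(n_win, dt, alpha, burn_in_dur = 20e-3) {
  m_ref <- n_win + round(burn_in_dur / dt)
  if (m_ref <= n_win) return(0)
  k <- seq_len(floor(m_ref / 2))
  p <- k^(-alpha)
  sum(p[k < m_ref / n_win]) / sum(p)
}
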