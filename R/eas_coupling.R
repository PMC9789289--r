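#' Convert release events into a synaptic current waveform
#'
#' Every neurotransmitter release event triggers a rectangular cathodic
#' (excitatory for the peripheral neuron) current injection of duration
#' \code{t_neuro} and amplitude \code{I_neuro}; the amplitude is strongly
#' suprathreshold, so each release fires the peripheral neuron unless it
#' is refractory.  Overlapping injections sum.
#'
#' @param releases release times in s (relative to the waveform start).
#' @param dt sample step in s.
#' @param n_samples length of the returned trace.
#' @param t0 time of the first sample in s.
#' @param t_neuro injection duration in s (default 40 us).
#' @param I_neuro injection amplitude in mA (default 3.0).
#' @return An \code{electric_waveform} (cathodic, i.e. negative, samples).
#' @export
#' @examples
#' w <- release_current(c(1e-3), 1e-6, 2000)
#' range(w$samples)  # -3 mA during the 40 us injection
release_current <- function(releases, dt, n_samples, t0 = 0,
                            t_neuro = 40e-6, I_neuro = 3.0) {
  s <- numeric(n_samples)
  np <- max(1L, as.integer(round(t_neuro / dt)))
  for (tr in as.numeric(releases)) {
    i0 <- as.integer(round((tr - t0) / dt))
    ii <- i0 + seq_len(np)
    ii <- ii[ii >= 1 & ii <= n_samples]
    s[ii] <- s[ii] - I_neuro  # cathodic sign convention: negative
  }
  electric_waveform(s, dt, t0 = t0)
}

# peripheral drive (uA, depolarizing positive) from release events
.release_drive <- function(releases, dt, n_samples, t0 = 0,
                           t_neuro = 40e-6, I_neuro = 3.0) {
  -release_current(releases, dt, n_samples, t0, t_neuro, I_neuro)$samples * 1e3
}

# releases for one coupled/alternative trial: spontaneous during the
# pre-stimulus span, profile-driven inside the window
.eas_releases <- function(fiber, spec, t_lo, t_hi, params) {
  generate_releases(function(t) release_rate_profile(t, spec, fiber, params),
                    c(t_lo, t_hi))
}

#' Uncoupled electric-acoustic model: merged, non-interacting spike trains
#'
#' Runs the electric-stimulation membrane model and the acoustic-pathway
#' model independently and merges their spike times.  No deduplication and
#' no refractory interaction across sources: this is the non-interacting
#' reference against which coupling effects are judged.
#'
#' @param fiber a \code{fiber_params} object.
#' @param elec an \code{electric_waveform} or \code{NULL}.
#' @param spec an [acoustic_stimulus()] or \code{NULL}.
#' @param window analysis window c(start, end) in s; defaults to the
#'   electric waveform span.
#' @param params surrogate parameters ([rate_profile_params()]).
#' @param burn_in_dur pre-stimulus burn-in for the membrane model (s).
#' @param trial trial index recorded in the output.
#' @return A \code{spike_train} with source \code{"EAS-uncoupled"}.
#' @export
run_uncoupled <- function(fiber, elec = NULL, spec = NULL, window = NULL,
                          params = rate_profile_params(),
                          burn_in_dur = 20e-3, trial = NA_integer_) {
  if (is.null(window)) window <- c(0, length(elec$samples) * elec$dt)
  es_times <- if (!is.null(elec)) {
    run_es_alone(fiber, elec, n_reps = 1, burn_in_dur = burn_in_dur)[[1]]$times
  } else numeric(0)
  as_times <- run_as_alone(fiber, spec, window, params)$times
  spike_train(sort(c(es_times, as_times)),
              fiber_id = if (is.null(fiber$fiber_id)) NA_integer_
                         else fiber$fiber_id,
              trial = trial, source = "EAS-uncoupled")
}

#' Coupled electric-acoustic model: releases drive the peripheral neuron
#'
#' The acoustic pathway's spike generator is replaced by the peripheral
#' neuron of the membrane model: every neurotransmitter release event
#' injects a suprathreshold rectangular current ([release_current()]) into
#' the peripheral neuron, on top of the polarity-weighted electric drive.
#' All output spikes come from the membrane model, so refractoriness after
#' a spike of either origin suppresses subsequent excitation by either
#' modality.  Releases also run during the burn-in span, so the fiber
#' enters the analysis window in a state consistent with its ongoing
#' spontaneous activity.
#'
#' @inheritParams run_uncoupled
#' @return A \code{spike_train} with source \code{"EAS-coupled"}.
#' @export
run_coupled <- function(fiber, elec = NULL, spec = NULL, window = NULL,
                        params = rate_profile_params(),
                        burn_in_dur = 20e-3, trial = NA_integer_) {
  dt <- if (!is.null(elec)) elec$dt else 1e-6
  if (is.null(window)) window <- c(0, length(elec$samples) * elec$dt)
  nb <- round(burn_in_dur / dt)
  nw <- round((window[2] - window[1]) / dt)
  n <- nb + nw
  if (!is.null(elec)) {
    d <- stimulus_drives(elec)
    dp <- c(numeric(nb), d$drive_per[seq_len(nw)])
    dc <- c(numeric(nb), d$drive_cen[seq_len(nw)])
  } else {
    dp <- dc <- numeric(n)
  }
  rel <- .eas_releases(fiber, spec, window[1] - burn_in_dur, window[2], params)
  dp <- dp + .release_drive(rel, dt, n, t0 = window[1] - burn_in_dur)
  r <- integrate_fiber(fiber, dp, dc, dt = dt)
  tt <- r$times + window[1] - burn_in_dur
  keep <- tt >= window[1]
  spike_train(tt[keep],
              fiber_id = if (is.null(fiber$fiber_id)) NA_integer_
                         else fiber$fiber_id,
              trial = trial, source = "EAS-coupled", neuron = r$neuron[keep])
}

#' Alternative coupling: runtime spike exchange between the two models
#'
#' Both models run in full -- the acoustic pathway keeps its own
#' release-driven spike generator -- and exchange spike occurrences at
#' runtime: a spike in either model triggers the refractory processes of
#' both (membrane reset, suprathreshold adaptation increment and dead time
#' on the electric side; a fresh stochastic refractory span on the
#' acoustic side).  The output is the time-sorted union, with a release
#' and a membrane crossing in the same integration step collapsed into a
#' single spike.
#'
#' @inheritParams run_uncoupled
#' @param dt integration step in s.
#' @return A \code{spike_train} with source \code{"EAS-alt"}.
#' @export
run_alternative <- function(fiber, elec = NULL, spec = NULL, window = NULL,
                            params = rate_profile_params(),
                            burn_in_dur = 20e-3, dt = 1e-6,
                            trial = NA_integer_) {
  if (!is.null(elec)) dt <- elec$dt
  if (is.null(window)) window <- c(0, length(elec$samples) * elec$dt)
  nb <- round(burn_in_dur / dt)
  nw <- round((window[2] - window[1]) / dt)
  n <- nb + nw
  if (!is.null(elec)) {
    d <- stimulus_drives(elec)
    dp <- c(numeric(nb), d$drive_per[seq_len(nw)])
    dc <- c(numeric(nb), d$drive_cen[seq_len(nw)])
  } else {
    dp <- dc <- numeric(n)
  }
  t0 <- window[1] - burn_in_dur
  rel <- .eas_releases(fiber, spec, t0, window[2], params)
  rel_idx <- as.integer(round((as.numeric(rel) - t0) / dt))
  rel_idx <- rel_idx[rel_idx >= 1 & rel_idx <= n]
  consts <- es_neuron_constants()
  pr <- .noise_pairs(n, 1L, consts$alpha_noise)
  r <- eas_alt_integrate_cpp(dp, dc,
                             pr$A * consts$peripheral$sigma_noise,
                             pr$B * consts$central$sigma_noise,
                             rel_idx, list(), dt * 1e6,
                             fiber$t_abs * 1e6, fiber$t_rel * 1e6,
                             .es_par(fiber, consts),
                             matrix(.es_rest_state(consts), ncol = 1))
  tt <- r$spike_idx[[1]] * dt + t0
  keep <- tt >= window[1]
  spike_train(tt[keep],
              fiber_id = if (is.null(fiber$fiber_id)) NA_integer_
                         else fiber$fiber_id,
              trial = trial, source = "EAS-alt")
}
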