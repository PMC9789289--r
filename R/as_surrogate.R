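#' Acoustic stimulus descriptor
#'
#' The acoustic pathway consumes a stimulus descriptor rather than a
#' sampled sound waveform: the surrogate front end maps (level, onset,
#' duration) of a broadband noise burst onto an instantaneous
#' neurotransmitter-release rate.
#'
#' @param level sound level in dB SPL.
#' @param onset stimulus onset in s.
#' @param duration stimulus duration in s (>= 0).
#' @param kind stimulus kind; only \code{"broadband-noise"} is supported.
#' @return A list of class \code{"acoustic_stimulus"}.
#' @export
acoustic_stimulus <- function(level, onset = 0, duration = 0,
                              kind = "broadband-noise") {
  stopifnot(duration >= 0, kind == "broadband-noise")
  structure(list(level = level, onset = onset, duration = duration,
                 kind = kind), class = "acoustic_stimulus")
}

#' Surrogate rate-profile parameters
#'
#' Parameters of the phenomenological release-rate profile that stands in
#' for a full auditory-periphery model: a logistic rate-level function for
#' the sustained driven rate, exponential onset adaptation, and transient
#' suppression of spontaneous releases after stimulus offset.
#'
#' @param r_max saturated sustained driven release rate (events/s).
#' @param L50 level of half-maximal driven rate (dB SPL), before the
#'   hearing-loss shift.
#' @param slope rate-level sigmoid slope (dB).
#' @param onset_factor peak/sustained ratio of the onset response.
#' @param tau_adapt onset adaptation time constant (s).
#' @param tau_rec recovery time constant after offset (s).
#' @param suppression_depth fraction of spontaneous releases suppressed at
#'   offset, in [0, 1].
#' @return A list of class \code{"rate_profile_params"}.
#' @export
rate_profile_params <- function(r_max = 185, L50 = 55, slope = 6,
                                onset_factor = 2.5, tau_adapt = 10e-3,
                                tau_rec = 80e-3, suppression_depth = 1.0) {
  stopifnot(r_max > 0, tau_adapt > 0, tau_rec > 0,
            suppression_depth >= 0, suppression_depth <= 1)
  structure(list(r_max = r_max, L50 = L50, slope = slope,
                 onset_factor = onset_factor, tau_adapt = tau_adapt,
                 tau_rec = tau_rec, suppression_depth = suppression_depth),
            class = "rate_profile_params")
}

#' Spontaneous release rate matching a target spike rate
#'
#' The refractory spike generator discards every release that falls within
#' \code{t_abs + X} of the previous spike, with \code{X} exponential with
#' mean \code{t_rel}.  For a homogeneous Poisson release process this
#' thinning has mean inter-spike interval \code{t_abs + t_rel + 1/r0}
#' (memorylessness of the release process), so the release rate that
#' yields an output spike rate \code{sr} is exactly
#' \deqn{r_0 = sr / (1 - sr (t_{abs} + t_{rel})).}
#'
#' @param sr target spontaneous spike rate (spikes/s, >= 0).
#' @param t_abs absolute refractory period (s).
#' @param t_rel mean relative refractory duration (s).
#' @return Release rate r0 in events/s.
#' @export
#' @examples
#' calibrate_spontaneous_rate(70, 450e-6, 512.5e-6)
calibrate_spontaneous_rate <- function(sr, t_abs, t_rel) {
  stopifnot(sr >= 0)
  loss <- sr * (t_abs + t_rel)
  if (loss >= 1) {
    stop("target rate unreachable: sr * (t_abs + t_rel) >= 1")
  }
  sr / (1 - loss)
}

#' Instantaneous release rate of the surrogate front end
#'
#' Piecewise profile: spontaneous rate \code{r0} before the stimulus;
#' during the stimulus the driven rate (logistic in level, after the
#' fiber's flat hearing-loss shift) rides on the spontaneous rate with an
#' exponentially decaying onset enhancement; after the offset, spontaneous
#' releases are transiently suppressed and recover exponentially.
#'
#' @param t time(s) at which to evaluate the rate (s); vectorized.
#' @param spec an [acoustic_stimulus()] or \code{NULL} (spontaneous only).
#' @param fiber a \code{fiber_params} object (uses \code{sr}, \code{t_abs},
#'   \code{t_rel}, \code{hearing_loss}).
#' @param params a [rate_profile_params()] object.
#' @return Release rate(s) in events/s.
#' @export
release_rate_profile <- function(t, spec, fiber,
                                 params = rate_profile_params()) {
  r0 <- calibrate_spontaneous_rate(fiber$sr, fiber$t_abs, fiber$t_rel)
  if (is.null(spec) || spec$duration <= 0) return(rep(r0, length(t)))
  eff <- spec$level - fiber$hearing_loss
  r_driven <- params$r_max / (1 + exp(-(eff - params$L50) / params$slope))
  off <- spec$onset + spec$duration
  out <- rep(r0, length(t))
  during <- t >= spec$onset & t < off - 1e-12
  out[during] <- r0 + r_driven *
    (1 + (params$onset_factor - 1) *
       exp(-(t[during] - spec$onset) / params$tau_adapt))
  after <- t >= off - 1e-12
  out[after] <- r0 * (1 - params$suppression_depth *
                        exp(-(t[after] - off) / params$tau_rec))
  out
}

#' Generate neurotransmitter release events
#'
#' Inhomogeneous Poisson process sampled by thinning against the profile's
#' maximum, with events snapped to a 10 us grid (at most one event per
#' grid cell).
#'
#' @param rate_fun function of time (s) returning events/s, or a single
#'   number for a homogeneous process.
#' @param window numeric length-2, start and end time (s).
#' @param grid release-time resolution (s).
#' @param rate_max optional upper bound on \code{rate_fun} over the window
#'   (computed from a dense evaluation by default).
#' @return Sorted release event times (s), class \code{"release_train"}.
#' @export
#' @examples
#' set.seed(1)
#' r <- generate_releases(100, c(0, 1))
generate_releases <- function(rate_fun, window, grid = 10e-6,
                              rate_max = NULL) {
  if (is.numeric(rate_fun)) {
    r0 <- rate_fun
    rate_fun <- function(t) rep(r0, length(t))
    if (is.null(rate_max)) rate_max <- r0
  }
  if (is.null(rate_max)) {
    tt <- seq(window[1], window[2], length.out = 2048)
    rate_max <- max(rate_fun(tt)) * 1.001
  }
  span <- window[2] - window[1]
  if (rate_max <= 0 || span <= 0) {
    return(structure(numeric(0), class = "release_train"))
  }
  n_cand <- stats::rpois(1, rate_max * span)
  if (n_cand == 0) return(structure(numeric(0), class = "release_train"))
  tc <- sort(stats::runif(n_cand, window[1], window[2]))
  keep <- stats::runif(n_cand) < rate_fun(tc) / rate_max
  ev <- tc[keep]
  ev <- unique(round(ev / grid) * grid)  # snap; one event per grid cell
  ev <- ev[ev >= window[1] & ev <= window[2]]
  structure(sort(ev), class = "release_train")
}

#' Convert release events to spikes with stochastic refractoriness
#'
#' Sequential scan: every release becomes a spike unless it falls within
#' the current refractory span of the previous spike; after each spike a
#' new refractory duration \code{t_abs + Exp(mean = t_rel)} is drawn.
#'
#' @param releases sorted release times (s).
#' @param t_abs absolute refractory period (s).
#' @param t_rel mean of the exponential relative refractory duration (s).
#' @return Sorted spike times (s).
#' @export
releases_to_spikes <- function(releases, t_abs, t_rel) {
  ev <- as.numeric(releases)
  if (!length(ev)) return(numeric(0))
  spikes <- numeric(length(ev))
  ns <- 0L
  block_until <- -Inf
  for (t in ev) {
    if (t >= block_until) {
      ns <- ns + 1L
      spikes[ns] <- t
      rr <- if (t_rel > 0) stats::rexp(1, 1 / t_rel) else 0
      block_until <- t + t_abs + rr
    }
  }
  spikes[seq_len(ns)]
}

#' Simulate the acoustic-pathway model alone
#'
#' Composes the surrogate front end: spontaneous-rate calibration, the
#' release-rate profile, inhomogeneous-Poisson release generation, and the
#' refractory spike generator.  This is the activity of an acoustically
#' sensitive fiber in the absence of electric stimulation.
#'
#' To plug in a full auditory-periphery model instead of the surrogate,
#' supply \code{release_fun(fiber, spec, window)} returning release times;
#' the refractory spike generator is applied unchanged.
#'
#' @param fiber a \code{fiber_params} object.
#' @param spec an [acoustic_stimulus()] or \code{NULL}.
#' @param window simulation window c(start, end) in s.
#' @param params surrogate parameters from [rate_profile_params()].
#' @param release_fun optional adapter replacing the surrogate release
#'   generator.
#' @param trial trial index recorded in the output.
#' @return A \code{spike_train} with source label \code{"AS"}.
#' @export
#' @examples
#' set.seed(1)
#' f <- sample_fiber("HSR")
#' s <- run_as_alone(f, NULL, c(0, 1))
run_as_alone <- function(fiber, spec = NULL, window = c(0, 1),
                         params = rate_profile_params(),
                         release_fun = NULL, trial = NA_integer_) {
  rel <- if (is.null(release_fun)) {
    generate_releases(function(t) release_rate_profile(t, spec, fiber, params),
                      window)
  } else {
    release_fun(fiber, spec, window)
  }
  spike_train(releases_to_spikes(rel, fiber$t_abs, fiber$t_rel),
              fiber_id = if (is.null(fiber$fiber_id)) NA_integer_
                         else fiber$fiber_id,
              trial = trial, source = "AS")
}
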