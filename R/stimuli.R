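#' Electric stimulus waveforms
#'
#' An \code{electric_waveform} is a regularly sampled current trace in mA.
#' Cathodic (negative-electrode) current is represented by negative sample
#' values; anodic current by positive values.  Pulse onset times are kept
#' as an attribute for latency analysis.
#'
#' @param samples current samples in mA.
#' @param dt sample step in s.
#' @param t0 time of the first sample in s.
#' @param onsets pulse onset times in s (optional bookkeeping).
#' @return An object of class \code{"electric_waveform"}.
#' @export
electric_waveform <- function(samples, dt, t0 = 0, onsets = numeric(0)) {
  stopifnot(dt > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), dt = dt, t0 = t0,
                 onsets = onsets),
            class = "electric_waveform")
}

#' @export
print.electric_waveform <- function(x, ...) {
  cat(sprintf(
    "<electric_waveform> %d samples @ %.2f us (%.3f ms), %d pulse onset(s)\n",
    length(x$samples), x$dt * 1e6, length(x$samples) * x$dt * 1e3,
    length(x$onsets)))
  invisible(x)
}

# round a duration to samples, warning if not an integer multiple of dt
.dur_to_samples <- function(width, dt, what = "duration") {
  n <- width / dt
  if (abs(n - round(n)) > 1e-9) {
    warning(sprintf("%s (%g s) rounded to %d samples of dt = %g s",
                    what, width, round(n), dt))
  }
  as.integer(round(n))
}

#' Single monophasic rectangular pulse
#'
#' @param amplitude pulse current in mA (> 0; the sign is set by
#'   \code{polarity}).
#' @param phase_width pulse duration in s.
#' @param polarity \code{"cathodic"} (negative samples) or \code{"anodic"}.
#' @param dt sample step in s (default 1 us).
#' @param total_duration length of the returned trace in s.
#' @return An \code{electric_waveform} with the pulse at t = 0.
#' @export
#' @examples
#' w <- monophasic_pulse(1.0, 26e-6, "cathodic", total_duration = 3.5e-3)
#' sum(w$samples != 0)  # 26 samples
monophasic_pulse <- function(amplitude, phase_width,
                             polarity = c("cathodic", "anodic"),
                             dt = 1e-6, total_duration = 3.5e-3) {
  polarity <- match.arg(polarity)
  stopifnot(amplitude > 0)
  if (phase_width <= 0) stop("phase_width must be positive")
  np <- .dur_to_samples(phase_width, dt, "phase_width")
  n <- max(.dur_to_samples(total_duration, dt), np)
  s <- numeric(n)
  s[seq_len(np)] <- if (polarity == "cathodic") -amplitude else amplitude
  electric_waveform(s, dt, onsets = 0)
}

#' Charge-balanced biphasic pulse train
#'
#' Symmetric biphasic pulses (no interphase gap) repeated at a fixed rate.
#'
#' @param amplitude phase current in mA (> 0).
#' @param phase_width duration of each phase in s.
#' @param rate pulse rate in pulses/s.
#' @param train_duration train length in s; the number of pulses is
#'   \code{floor(rate * train_duration)} with the first pulse at t = 0.
#' @param leading polarity of the first phase (default cathodic).
#' @param dt sample step in s.
#' @return An \code{electric_waveform}; pulse onsets in \code{$onsets}.
#' @export
#' @examples
#' w <- biphasic_pulse_train(1, 40e-6, 250, 0.3)
#' length(w$onsets)        # 75 pulses
#' sum(w$samples) * w$dt   # net charge 0
biphasic_pulse_train <- function(amplitude, phase_width, rate,
                                 train_duration,
                                 leading = c("cathodic", "anodic"),
                                 dt = 1e-6) {
  leading <- match.arg(leading)
  stopifnot(amplitude > 0, phase_width > 0, rate > 0)
  n_pulses <- floor(rate * train_duration)
  if (n_pulses < 1) stop("train_duration too short for one pulse")
  if (2 * phase_width > 1 / rate) stop("pulses overlap: 2*phase_width > 1/rate")
  np <- .dur_to_samples(phase_width, dt, "phase_width")
  n <- .dur_to_samples(train_duration, dt)
  s <- numeric(n)
  sgn <- if (leading == "cathodic") -1 else 1
  onsets <- (seq_len(n_pulses) - 1) / rate
  for (t_on in onsets) {
    i0 <- as.integer(round(t_on / dt))
    s[i0 + seq_len(np)] <- sgn * amplitude
    s[i0 + np + seq_len(np)] <- -sgn * amplitude
  }
  electric_waveform(s, dt, onsets = onsets)
}

#' Per-sample polarity decomposition of a waveform
#'
#' Splits a current trace into its cathodic (negative) and anodic
#' (positive) contributions; the two parts reconstruct the input exactly.
#' These feed the polarity-dependent weighting of the two point neurons:
#' cathodic current depolarizes the peripheral neuron and hyperpolarizes
#' the central one (scaled by the compression factor beta), and vice versa.
#'
#' @param w an \code{electric_waveform}.
#' @return A list with components \code{I_minus} and \code{I_plus}
#'   (numeric vectors, mA).
#' @export
split_polarity <- function(w) {
  s <- w$samples
  list(I_minus = pmin(s, 0), I_plus = pmax(s, 0))
}

#' Polarity-weighted stimulus drives for the two point neurons
#'
#' Applies the weighting
#' \eqn{I^{per}_{stim} = -(I^- + \beta I^+)} and
#' \eqn{I^{cen}_{stim} = \beta I^- + I^+}
#' so that a cathodic pulse yields a positive (depolarizing) peripheral
#' drive and a negative (hyperpolarizing) central drive.
#'
#' @param w an \code{electric_waveform} (mA).
#' @param beta inhibitory compression factor in (0, 1].
#' @return list of \code{drive_per}, \code{drive_cen} in uA.
#' @export
stimulus_drives <- function(w, beta = es_neuron_constants()$beta) {
  p <- split_polarity(w)
  list(drive_per = -(p$I_minus + beta * p$I_plus) * 1e3,
       drive_cen = (beta * p$I_minus + p$I_plus) * 1e3)
}

#' Write a waveform as two-column CSV (time_s, current_mA)
#'
#' @param w an \code{electric_waveform}.
#' @param path output path.
#' @export
write_waveform <- function(w, path) {
  t <- w$t0 + (seq_along(w$samples) - 1) * w$dt
  utils::write.csv(data.frame(time_s = t, current_mA = w$samples), path,
                   row.names = FALSE)
  invisible(path)
}
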