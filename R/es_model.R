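#' Spike trains
#'
#' Light container for the spike times of one fiber and one trial.
#'
#' @param times sorted spike times in s.
#' @param fiber_id integer fiber identifier.
#' @param trial trial index.
#' @param source generating model label: \code{"ES"}, \code{"AS"},
#'   \code{"EAS-uncoupled"}, \code{"EAS-coupled"} or \code{"EAS-alt"}.
#' @param neuron optional per-spike attribution (1 = peripheral,
#'   2 = central, 3 = both) for membrane-generated spikes.
#' @return An object of class \code{"spike_train"}.
#' @export
spike_train <- function(times, fiber_id = NA_integer_, trial = NA_integer_,
                        source = "ES", neuron = NULL) {
  structure(list(times = as.numeric(times), fiber_id = fiber_id,
                 trial = trial, source = source, neuron = neuron),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s fiber %s trial %s: %d spike(s)\n",
              x$source, x$fiber_id, x$trial, length(x$times)))
  invisible(x)
}

#' Write spike trains as CSV
#'
#' @param trains a list of \code{spike_train} objects.
#' @param path output path (\code{.csv} or \code{.json}).
#' @export
write_spike_trains <- function(trains, path) {
  tab <- do.call(rbind, lapply(trains, function(s) {
    if (!length(s$times)) return(NULL)
    data.frame(fiber_id = s$fiber_id, trial = s$trial,
               spike_time_s = s$times, source_label = s$source)
  }))
  if (is.null(tab)) {
    tab <- data.frame(fiber_id = integer(0), trial = integer(0),
                      spike_time_s = numeric(0), source_label = character(0))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tab, path, digits = NA)
  } else {
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

# parameter list handed to the C++ integrator (times converted to us here:
# this is the package's single conversion layer between the second-based
# user surface and the microsecond-based integrator)
.es_par <- function(fiber, consts = es_neuron_constants()) {
  list(C_per = fiber$C_per, C_cen = fiber$C_cen,
       gL_per = consts$peripheral$g_L, gL_cen = consts$central$g_L,
       dT_per = consts$peripheral$Delta_T, dT_cen = consts$central$Delta_T,
       EL = consts$E_L, vthr = consts$v_thr,
       vpeak = consts$v_peak, vreset = consts$v_reset,
       tau_sub = consts$tau_sub * 1e6, a_sub = consts$a_sub,
       tau_supra_per = fiber$tau_supra_per * 1e6,
       tau_supra_cen = fiber$tau_supra_cen * 1e6,
       a_supra = consts$a_supra, b = consts$b,
       t_dead = fiber$t_dead * 1e6)
}

# resting state vector: V at E_L, adaptation currents zero, no dead time
.es_rest_state <- function(consts = es_neuron_constants()) {
  c(consts$E_L, consts$E_L, 0, 0, 0, 0, 0)
}

#' Integrate one fiber over arbitrary drive traces
#'
#' Forward-Euler integration of both point neurons on a shared time grid.
#' A spike is recorded at the first sample where either membrane reaches
#' the peak potential; both neurons are then reset, the suprathreshold
#' adaptation currents are incremented, and all external drive (electric
#' and synaptic alike) is suppressed for the fiber's dead time while the
#' intrinsic dynamics and the noise continue to evolve.
#'
#' @param fiber a \code{fiber_params} object.
#' @param drive_per,drive_cen stimulus drives for the peripheral/central
#'   neuron in uA (same length).
#' @param dt sample step in s.
#' @param state initial state vector (from [burn_in()]); defaults to rest.
#' @param noise_per,noise_cen optional noise traces (uA); freshly
#'   synthesized 1/f^alpha noise by default.
#' @param consts constants from [es_neuron_constants()].
#' @return A list: \code{times} (spike times in s, relative to the first
#'   sample), \code{neuron} (1 peripheral, 2 central, 3 both), and
#'   \code{state} (final state vector).
#' @export
integrate_fiber <- function(fiber, drive_per, drive_cen, dt = 1e-6,
                            state = NULL, noise_per = NULL, noise_cen = NULL,
                            consts = es_neuron_constants()) {
  n <- length(drive_per)
  stopifnot(length(drive_cen) == n)
  if (is.null(state)) state <- .es_rest_state(consts)
  if (is.null(noise_per)) {
    noise_per <- make_noise_current(n, dt, consts$peripheral$sigma_noise,
                                    consts$alpha_noise)
  }
  if (is.null(noise_cen)) {
    noise_cen <- make_noise_current(n, dt, consts$central$sigma_noise,
                                    consts$alpha_noise)
  }
  r <- es_integrate_cpp(drive_per, drive_cen, noise_per, noise_cen,
                        dt * 1e6, .es_par(fiber, consts), state)
  list(times = r$spike_idx * dt, neuron = r$neuron, state = r$state)
}

#' Evolve a fiber to a stationary pre-stimulus state
#'
#' Before each trial the membrane is evolved with the intrinsic noise
#' current only, so stimulation starts from a random stationary state
#' rather than from deterministic rest.
#'
#' @param fiber a \code{fiber_params} object.
#' @param duration burn-in duration in s (default 20 ms).
#' @param dt sample step in s.
#' @param consts constants from [es_neuron_constants()].
#' @return Final state vector, usable as \code{state} in
#'   [integrate_fiber()].
#' @export
burn_in <- function(fiber, duration = 20e-3, dt = 1e-6,
                    consts = es_neuron_constants()) {
  stopifnot(duration > 0)
  n <- round(duration / dt)
  z <- numeric(n)
  integrate_fiber(fiber, z, z, dt = dt, consts = consts)$state
}

# Batched trial engine shared by the ES-alone and coupled models.
# drive_per/drive_cen cover the stimulus span only; a burn-in span of
# zeros is prepended internally (fresh noise everywhere, every trial).
# extra_per: optional n_total x n_reps matrix of additional peripheral
# drive (uA), e.g. synaptic release currents, covering burn-in + stimulus.
# Returns a list with per-trial spike times (s, relative to stimulus
# onset; burn-in spikes have negative times) and per-spike neuron codes.
.es_run_trials <- function(fiber, drive_per, drive_cen, n_reps, dt = 1e-6,
                           burn_in_dur = 20e-3, extra_per = NULL,
                           states = NULL, consts = es_neuron_constants()) {
  nb <- round(burn_in_dur / dt)
  n <- nb + length(drive_per)
  dp <- c(numeric(nb), drive_per)
  dc <- c(numeric(nb), drive_cen)
  pr <- .noise_pairs(n, n_reps, consts$alpha_noise)
  if (is.null(states)) states <- matrix(.es_rest_state(consts), ncol = 1)
  r <- es_integrate_batch_cpp(dp, dc,
                              pr$A * consts$peripheral$sigma_noise,
                              pr$B * consts$central$sigma_noise,
                              dt * 1e6, .es_par(fiber, consts), states,
                              extra_per)
  list(times = lapply(r$spike_idx, function(ix) (ix - nb) * dt),
       neuron = r$neuron)
}

#' Simulate repeated trials of electric-only stimulation
#'
#' Runs the electric-stimulation model for an acoustically insensitive
#' fiber (no synaptic input): the waveform is split into cathodic and
#' anodic parts, weighted onto the peripheral and central neurons, and
#' integrated with a fresh noise realization and a fresh noise-driven
#' burn-in for every repetition.
#'
#' @param fiber a \code{fiber_params} object.
#' @param waveform an \code{electric_waveform} (mA).
#' @param n_reps number of repetitions.
#' @param burn_in_dur pre-stimulus burn-in duration in s.
#' @param keep_burnin if TRUE, spikes occurring during the burn-in are
#'   retained (with negative times); dropped by default.
#' @param consts constants from [es_neuron_constants()].
#' @return A list of \code{spike_train} objects (times relative to the
#'   waveform start).
#' @export
#' @examples
#' set.seed(1)
#' f <- sample_fiber("HSR")
#' w <- monophasic_pulse(3, 26e-6, "cathodic")
#' tr <- run_es_alone(f, w, n_reps = 3)
run_es_alone <- function(fiber, waveform, n_reps = 1, burn_in_dur = 20e-3,
                         keep_burnin = FALSE,
                         consts = es_neuron_constants()) {
  d <- stimulus_drives(waveform, consts$beta)
  r <- .es_run_trials(fiber, d$drive_per, d$drive_cen, n_reps,
                      dt = waveform$dt, burn_in_dur = burn_in_dur,
                      consts = consts)
  lapply(seq_len(n_reps), function(k) {
    tt <- r$times[[k]]
    keep <- if (keep_burnin) rep(TRUE, length(tt)) else tt >= 0
    spike_train(tt[keep],
                fiber_id = if (is.null(fiber$fiber_id)) NA_integer_
                           else fiber$fiber_id,
                trial = k, source = "ES", neuron = r$neuron[[k]][keep])
  })
}
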