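#' Firing efficiency of a set of trials
#'
#' Spontaneous-rate-corrected spike probability per stimulus presentation:
#' \deqn{FE = (N - SR \cdot T \cdot M) / M,}
#' where \eqn{N} is the total number of spikes falling in the analysis
#' window \eqn{[start, start+T)} summed over all presentations, \eqn{SR}
#' the spontaneous rate, and \eqn{M} the number of presentations (one
#' analysis window per presentation).
#'
#' @param spike_trains list of \code{spike_train} objects (or numeric
#'   vectors of spike times), one per presentation.
#' @param window_start analysis window start (s).
#' @param T window duration (s).
#' @param sr spontaneous rate (spikes/s).
#' @param M number of presentations; defaults to
#'   \code{length(spike_trains)}.
#' @return Firing efficiency (dimensionless; can exceed [0, 1] slightly
#'   through the SR correction).
#' @export
#' @examples
#' trains <- list(c(1e-3), numeric(0))
#' firing_efficiency(trains, 0, 3.5e-3, sr = 0)  # 0.5
firing_efficiency <- function(spike_trains, window_start, T, sr = 0,
                              M = length(spike_trains)) {
  stopifnot(M >= 1, T > 0)
  N <- sum(vapply(spike_trains, function(s) {
    tt <- if (inherits(s, "spike_train")) s$times else as.numeric(s)
    sum(tt >= window_start & tt < window_start + T)
  }, numeric(1)))
  (N - sr * T * length(spike_trains)) / M
}

#' Firing-efficiency-versus-level curve
#'
#' @param levels stimulus amplitudes (mA), strictly increasing.
#' @param fe firing efficiencies at each level.
#' @param n_trials trials per level (recycled).
#' @param T analysis window duration (s).
#' @return A list of class \code{"fe_curve"}.
#' @export
fe_curve <- function(levels, fe, n_trials, T = 3.5e-3) {
  stopifnot(length(levels) == length(fe), all(diff(levels) > 0),
            all(is.finite(fe)))
  structure(list(levels = levels, fe = fe,
                 n_trials = rep_len(n_trials, length(levels)), T = T),
            class = "fe_curve")
}

#' Fit an integrated Gaussian to an FE-level curve
#'
#' Weighted least squares fit of \eqn{FE(L) = \Phi((L - \mu)/\sigma)} with
#' binomial weights \eqn{n / (p(1-p))} (predicted probabilities, clamped;
#' two reweighting passes).  The threshold is \eqn{\mu} (level at 50 % FE),
#' the relative spread \eqn{RS = \sigma/\mu}, and the dynamic range is the
#' dB span between the 10 % and 90 % FE levels of the fitted curve.
#'
#' @param curve an \code{fe_curve} object.
#' @return A list of class \code{"threshold_fit"}: \code{mu}, \code{sigma}
#'   (mA), \code{rs}, \code{dr_db}, and the fitted \code{curve}.
#' @export
#' @examples
#' set.seed(1)
#' L <- seq(0.8, 1.2, length.out = 10)
#' fe <- pnorm((L - 1) / 0.06)
#' fit_fe_curve(fe_curve(L, fe, 100))
fit_fe_curve <- function(curve) {
  stopifnot(inherits(curve, "fe_curve"))
  L <- curve$levels; fe <- curve$fe; n <- curve$n_trials
  if (length(L) < 4 || min(fe) > 0.2 || max(fe) < 0.8) {
    stop("FE data must span below 0.2 and above 0.8 over >= 4 levels; ",
         "widen the level sweep")
  }
  # initial values from linear interpolation of the 20/50/80 % crossings
  xing <- function(p) {
    i <- which(fe >= p)[1]
    if (i == 1) return(L[1])
    L[i - 1] + (p - fe[i - 1]) / (fe[i] - fe[i - 1]) * (L[i] - L[i - 1])
  }
  mu0 <- xing(0.5)
  sg0 <- max((xing(0.8) - xing(0.2)) / 1.683, 1e-4 * mu0)
  # optimized in (log mu, log sigma): the threshold is a current and must
  # stay positive even for degenerate plateau-shaped curves
  obj <- function(par, w) {
    p <- stats::pnorm((L - exp(par[1])) / exp(par[2]))
    sum(w * (fe - p)^2)
  }
  par <- c(log(mu0), log(sg0))
  for (pass in 1:2) {
    p_hat <- stats::pnorm((L - exp(par[1])) / exp(par[2]))
    w <- n / pmax(p_hat * (1 - p_hat), 0.02)
    par <- stats::optim(par, obj, w = w)$par
  }
  mu <- exp(par[1]); sigma <- exp(par[2])
  fit <- structure(list(mu = mu, sigma = sigma, rs = sigma / mu,
                        dr_db = NA_real_, curve = curve),
                   class = "threshold_fit")
  fit$dr_db <- dynamic_range(fit)
  fit
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf(
    "<threshold_fit> mu %.4f mA (%.2f dB re 1 mA), RS %.2f %%, DR %.2f dB\n",
    x$mu, 20 * log10(x$mu), 100 * x$rs, x$dr_db))
  invisible(x)
}

#' Dynamic range of a fitted FE-level curve
#'
#' dB span between the 10 % and 90 % FE levels of the fitted integrated
#' Gaussian: \eqn{DR = 20 \log_{10}(L_{90}/L_{10})} with
#' \eqn{L_{10,90} = \mu \mp 1.2816\,\sigma}.
#'
#' @param fit a \code{threshold_fit}.
#' @return Dynamic range in dB; \code{NA} (with a warning) if the 10 %
#'   level is not positive.
#' @export
dynamic_range <- function(fit) {
  z90 <- stats::qnorm(0.9)
  l10 <- fit$mu - z90 * fit$sigma
  l90 <- fit$mu + z90 * fit$sigma
  if (l10 <= 0) {
    warning("10 % FE level not positive; dynamic range undefined")
    return(NA_real_)
  }
  20 * log10(l90 / l10)
}

#' Latency and jitter of spikes in post-pulse analysis windows
#'
#' Pools the latencies of all spikes (not only the first) falling within
#' \code{T} of each pulse onset, across all trains; latency is the mean
#' and jitter the standard deviation of the pooled latencies.
#'
#' @param spike_trains list of \code{spike_train} objects or numeric
#'   vectors.
#' @param pulse_onsets pulse onset times (s).
#' @param T analysis window duration (s); must not exceed the inter-pulse
#'   interval.
#' @return list with \code{latency}, \code{jitter} (s) and \code{n}
#'   (pooled spike count); latency/jitter are \code{NA} with a warning if
#'   no spikes fall in any window.
#' @export
latency_jitter <- function(spike_trains, pulse_onsets, T = 3.5e-3) {
  if (length(pulse_onsets) > 1 && T > min(diff(sort(pulse_onsets))) + 1e-12) {
    stop("analysis window exceeds the inter-pulse interval")
  }
  lat <- unlist(lapply(spike_trains, function(s) {
    tt <- if (inherits(s, "spike_train")) s$times else as.numeric(s)
    unlist(lapply(pulse_onsets, function(o) {
      d <- tt - o
      d[d >= 0 & d < T]
    }))
  }))
  if (!length(lat)) {
    warning("no spikes in any analysis window; latency undefined")
    return(list(latency = NA_real_, jitter = NA_real_, n = 0L))
  }
  list(latency = mean(lat),
       jitter = if (length(lat) > 1) stats::sd(lat) else 0,
       n = length(lat))
}

#' Vector strength of spike times relative to a pulse rate
#'
#' \deqn{VS = \frac{1}{N}\sqrt{(\sum_i \sin 2\pi\nu t_i)^2 +
#'   (\sum_i \cos 2\pi\nu t_i)^2}}
#'
#' @param spike_times spike times in s (>= 1 spike).
#' @param pulse_rate stimulus pulse rate nu in pulses/s.
#' @return Vector strength in [0, 1]; \code{NA} with a warning for an
#'   empty spike set.
#' @export
#' @examples
#' vector_strength(c(0, 4e-3, 8e-3), 250)  # 1
vector_strength <- function(spike_times, pulse_rate) {
  tt <- if (inherits(spike_times, "spike_train")) spike_times$times
        else as.numeric(spike_times)
  if (!length(tt)) {
    warning("no spikes; vector strength undefined")
    return(NA_real_)
  }
  ph <- 2 * pi * pulse_rate * tt
  min(1, sqrt(sum(sin(ph))^2 + sum(cos(ph))^2) / length(tt))
}

#' Analytic latency estimate for mixed spontaneous and evoked spiking
#'
#' Under the assumption that spontaneous spikes (uniform over the analysis
#' window of duration T) and electrically evoked spikes do not interact,
#' the expected latency is the mixture mean
#' \deqn{L = \frac{N_S}{N_S+N_E}\,\frac{T}{2} +
#'   \frac{N_E}{N_S+N_E}\,L_E,}
#' with \eqn{N_S = SR \cdot T} the expected spontaneous count and
#' \eqn{N_E} the expected evoked count per window.
#'
#' @param sr spontaneous rate (spikes/s).
#' @param T analysis window duration (s).
#' @param N_E expected evoked spikes per window.
#' @param L_E mean latency of the evoked spikes alone (s).
#' @return Expected latency (s).
#' @export
#' @examples
#' analytic_latency(70, 3.5e-3, 0, 0)  # T/2 = 1.75 ms
analytic_latency <- function(sr, T, N_E, L_E) {
  N_S <- sr * T
  if (N_S + N_E <= 0) {
    warning("no spontaneous and no evoked spikes; latency undefined")
    return(NA_real_)
  }
  (N_S * T / 2 + N_E * L_E) / (N_S + N_E)
}

#' Analytic jitter estimate for mixed spontaneous and evoked spiking
#'
#' Mixture standard deviation of uniform spontaneous latencies (variance
#' \eqn{T^2/12}) and evoked latencies (mean \eqn{L_E}, SD \eqn{J_E}):
#' \deqn{J = \Big(\frac{N_S}{N_S+N_E}\frac{T^2}{12} +
#'   \frac{N_E}{N_S+N_E} J_E^2 +
#'   \frac{N_S N_E}{(N_S+N_E)^2}\big(\frac{T}{2}-L_E\big)^2\Big)^{1/2}.}
#'
#' @inheritParams analytic_latency
#' @param J_E jitter of the evoked spikes alone (s).
#' @return Expected jitter (s).
#' @export
#' @examples
#' analytic_jitter(70, 3.5e-3, 0, 0, 0)  # T/sqrt(12) = 1.01 ms
analytic_jitter <- function(sr, T, N_E, L_E, J_E) {
  N_S <- sr * T
  if (N_S + N_E <= 0) {
    warning("no spontaneous and no evoked spikes; jitter undefined")
    return(NA_real_)
  }
  f_s <- N_S / (N_S + N_E)
  f_e <- N_E / (N_S + N_E)
  sqrt(f_s * T^2 / 12 + f_e * J_E^2 + f_s * f_e * (T / 2 - L_E)^2)
}

#' Per-interval response statistics
#'
#' For each analysis interval: the SR-corrected spike rate
#' (spikes/duration − SR), the latency and jitter from post-pulse windows
#' restricted to the interval, and the vector strength of the in-interval
#' spikes.
#'
#' @param spike_trains list of \code{spike_train} objects or numeric
#'   vectors (trials pooled).
#' @param intervals named list of c(start, end) pairs (s).
#' @param sr spontaneous rate (spikes/s).
#' @param pulse_rate electric pulse rate (pulses/s).
#' @param pulse_onsets pulse onset times (s).
#' @param T post-pulse analysis window (s).
#' @return data.frame with one row per interval: \code{interval_id},
#'   \code{rate}, \code{latency}, \code{jitter}, \code{vs}, \code{n}.
#' @export
interval_stats <- function(spike_trains, intervals, sr, pulse_rate,
                           pulse_onsets, T = 3.5e-3) {
  if (inherits(spike_trains, "spike_train")) spike_trains <- list(spike_trains)
  m <- length(spike_trains)
  do.call(rbind, lapply(names(intervals), function(id) {
    iv <- intervals[[id]]
    dur <- iv[2] - iv[1]
    tt <- unlist(lapply(spike_trains, function(s) {
      x <- if (inherits(s, "spike_train")) s$times else as.numeric(s)
      x[x >= iv[1] & x < iv[2]]
    }))
    onsets_in <- pulse_onsets[pulse_onsets >= iv[1] &
                                pulse_onsets + T <= iv[2] + T]
    lj <- if (length(onsets_in)) {
      suppressWarnings(latency_jitter(spike_trains, onsets_in, T))
    } else list(latency = NA_real_, jitter = NA_real_, n = 0L)
    data.frame(interval_id = id,
               rate = length(tt) / (dur * m) - sr,
               latency = lj$latency, jitter = lj$jitter,
               vs = if (length(tt)) {
                 suppressWarnings(vector_strength(tt, pulse_rate))
               } else NA_real_,
               n = length(tt))
  }))
}
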