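#' Draw one membrane capacitance from the fitted population distribution
#'
#' Capacitances follow \eqn{C = 10^x - \alpha} in farads, with
#' \eqn{x \sim N(\mu, \sigma^2)} truncated at \eqn{\mu \pm 2\sigma} and
#' \eqn{\alpha} an additive offset in nF (negative for both neurons, so the
#' offset increases C).  Truncation is implemented by rejection so the
#' interior shape of the normal is preserved.
#'
#' @param which \code{"peripheral"} or \code{"central"}.
#' @param n number of draws.
#' @param consts constants from [es_neuron_constants()].
#' @return Capacitance(s) in nF.
#' @export
#' @examples
#' set.seed(1)
#' sample_capacitance("peripheral")
sample_capacitance <- function(which = c("peripheral", "central"), n = 1,
                               consts = es_neuron_constants()) {
  which <- match.arg(which)
  p <- consts[[which]]
  x <- .rnorm_trunc(n, p$cap_mu, p$cap_sigma, p$cap_mu - 2 * p$cap_sigma,
                    p$cap_mu + 2 * p$cap_sigma)
  10^x * 1e9 - p$cap_alpha  # farads -> nF, minus (negative) offset in nF
}

# truncated normal by rejection (no atoms at the limits)
.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# spontaneous-rate group definitions: truncated normal (spikes/s)
.sr_groups <- list(
  LSR = list(mean = 0.1,  sd = 0.1,  lo = 1e-3, hi = 0.2),
  MSR = list(mean = 4.0,  sd = 4.0,  lo = 0.2,  hi = 18.0),
  HSR = list(mean = 70.0, sd = 30.0, lo = 18.0, hi = 180.0)
)

#' Sample one fiber parameter set
#'
#' Draws the randomized per-fiber parameters of the population model:
#' characteristic frequency (log-uniform on 0.125--40 kHz), spontaneous rate
#' (truncated normal of the chosen group), absolute and baseline relative
#' refractory periods (uniform), and membrane capacitances of the
#' peripheral and central neurons.  The electric-model refractory
#' parameters are tied to the acoustic ones: the dead time equals
#' \code{t_abs}, and the suprathreshold adaptation time constants are the
#' baseline values scaled by \code{t_rel} normalized to its expectation
#' (512.5 us).
#'
#' @param sr_group \code{"LSR"}, \code{"MSR"} or \code{"HSR"}.
#' @param consts constants from [es_neuron_constants()].
#' @param hearing_loss flat threshold shift in dB applied to acoustic input.
#' @return A list of class \code{"fiber_params"} with fields \code{cf}
#'   (kHz), \code{sr} (spikes/s), \code{sr_group}, \code{t_abs},
#'   \code{t_rel}, \code{t_dead}, \code{tau_supra_per}, \code{tau_supra_cen}
#'   (all times in s), \code{C_per}, \code{C_cen} (nF), and
#'   \code{hearing_loss} (dB).
#' @export
#' @examples
#' set.seed(7)
#' f <- sample_fiber("HSR")
#' f$t_dead == f$t_abs
sample_fiber <- function(sr_group = c("LSR", "MSR", "HSR"),
                         consts = es_neuron_constants(),
                         hearing_loss = 26) {
  sr_group <- match.arg(sr_group)
  g <- .sr_groups[[sr_group]]
  cf <- exp(stats::runif(1, log(0.125), log(40)))
  sr <- .rnorm_trunc(1, g$mean, g$sd, g$lo, g$hi)
  t_abs <- stats::runif(1, 208.5e-6, 691.5e-6)
  t_rel <- stats::runif(1, 131.0e-6, 894.0e-6)
  scale <- t_rel / .t_rel_mean()
  out <- list(
    cf = cf, sr = sr, sr_group = sr_group,
    t_abs = t_abs, t_rel = t_rel,
    t_dead = t_abs,
    tau_supra_per = consts$peripheral$tau_supra0 * scale,
    tau_supra_cen = consts$central$tau_supra0 * scale,
    C_per = sample_capacitance("peripheral", consts = consts),
    C_cen = sample_capacitance("central", consts = consts),
    hearing_loss = hearing_loss
  )
  class(out) <- "fiber_params"
  out
}

#' Sample a fiber population
#'
#' @param n_lsr,n_msr,n_hsr fiber counts per spontaneous-rate group.
#' @param consts constants from [es_neuron_constants()].
#' @param hearing_loss flat threshold shift in dB, shared by all fibers.
#' @return A list of \code{fiber_params}, LSR first, then MSR, then HSR.
#' @export
#' @examples
#' set.seed(1)
#' pop <- sample_population(2, 2, 6)
#' length(pop)
sample_population <- function(n_lsr = 30, n_msr = 30, n_hsr = 90,
                              consts = es_neuron_constants(),
                              hearing_loss = 26) {
  stopifnot(n_lsr >= 0, n_msr >= 0, n_hsr >= 0)
  groups <- rep(c("LSR", "MSR", "HSR"), times = c(n_lsr, n_msr, n_hsr))
  pop <- lapply(groups, sample_fiber, consts = consts,
                hearing_loss = hearing_loss)
  if (length(pop)) {
    for (i in seq_along(pop)) pop[[i]]$fiber_id <- i
  }
  pop
}

#' Convert a fiber population to a data frame
#'
#' @param pop list of \code{fiber_params} from [sample_population()].
#' @return A data frame with one row per fiber.
#' @export
population_table <- function(pop) {
  do.call(rbind, lapply(pop, function(f) {
    data.frame(fiber_id = if (is.null(f$fiber_id)) NA_integer_ else f$fiber_id,
               cf = f$cf, sr = f$sr, sr_group = f$sr_group,
               t_abs = f$t_abs, t_rel = f$t_rel, t_dead = f$t_dead,
               tau_supra_per = f$tau_supra_per,
               tau_supra_cen = f$tau_supra_cen,
               C_per = f$C_per, C_cen = f$C_cen,
               hearing_loss = f$hearing_loss)
  }))
}

#' Write / read a fiber population
#'
#' Serializes the population either as CSV (one row per fiber) or JSON.
#' The format is chosen from the file extension.
#'
#' @param pop list of \code{fiber_params}.
#' @param path output path ending in \code{.csv} or \code{.json}.
#' @export
write_population <- function(pop, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(population_table(pop), path, digits = NA)
  } else {
    utils::write.csv(population_table(pop), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_population
#' @return \code{read_population} returns a list of \code{fiber_params}.
#' @export
read_population <- function(path) {
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  pop <- lapply(seq_len(nrow(tab)), function(i) {
    f <- as.list(tab[i, ])
    f$sr_group <- as.character(f$sr_group)
    class(f) <- "fiber_params"
    f
  })
  pop
}

#' @export
print.fiber_params <- function(x, ...) {
  cat(sprintf("<fiber_params> %s fiber: CF %.3f kHz, SR %.2f /s\n",
              x$sr_group, x$cf, x$sr))
  cat(sprintf("  t_abs %.1f us, t_rel %.1f us, C_per %.1f nF, C_cen %.1f nF\n",
              x$t_abs * 1e6, x$t_rel * 1e6, x$C_per, x$C_cen))
  invisible(x)
}
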