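#' Point-neuron constants for the electric-stimulation (ES) model
#'
#' Returns the fixed parameter set of the two adaptive exponential
#' integrate-and-fire point neurons representing the peripheral and central
#' axonal processes of an auditory nerve fiber under extracellular electric
#' stimulation.  Units follow the package's canonical system: potentials in
#' mV, conductances in mS, currents in uA, capacitances in nF, and times in
#' seconds at the user surface (converted to microseconds inside the
#' integrator, the single documented conversion layer).
#'
#' The capacitance of each neuron is not fixed but drawn per fiber from a
#' truncated log-normal-minus-offset distribution,
#' \eqn{C = 10^x - \alpha} (farads) with
#' \eqn{x \sim N(\mu, \sigma^2)} truncated at \eqn{\mu \pm 2\sigma};
#' the (\code{cap_mu}, \code{cap_sigma}, \code{cap_alpha}) entries hold the
#' distribution parameters (\code{cap_alpha} in nF, negative by convention,
#' so the offset is effectively added).
#'
#' @return A list with class \code{"es_neuron_constants"} and elements
#'   \code{peripheral} and \code{central} (per-neuron parameters
#'   \code{g_L}, \code{Delta_T}, \code{cap_mu}, \code{cap_sigma},
#'   \code{cap_alpha}, \code{sigma_noise}, \code{tau_supra0}) plus shared
#'   parameters \code{E_L}, \code{v_thr}, \code{v_peak}, \code{v_reset},
#'   \code{alpha_noise}, \code{beta}, \code{tau_sub}, \code{a_sub},
#'   \code{a_supra}, \code{b}.
#' @export
#' @examples
#' k <- es_neuron_constants()
#' k$peripheral$g_L   # 1.1 mS
#' k$beta             # 0.75
es_neuron_constants <- function() {
  out <- list(
    peripheral = list(
      g_L        = 1.1,      # mS
      Delta_T    = 10.0,     # mV
      cap_mu     = -6.1514,  # log10 farads
      cap_sigma  = 0.1947,
      cap_alpha  = -164.0,   # nF
      sigma_noise = 8.70,    # uA
      tau_supra0 = 4500e-6   # s
    ),
    central = list(
      g_L        = 2.7,
      Delta_T    = 3.0,
      cap_mu     = -5.7547,
      cap_sigma  = 0.2010,
      cap_alpha  = -32.7,
      sigma_noise = 11.89,
      tau_supra0 = 2500e-6
    ),
    E_L        = -80.0,   # mV
    v_thr      = -70.0,   # mV (threshold potential V_T of the exponential term)
    v_peak     = 24.0,    # mV (spike detection)
    v_reset    = -84.0,   # mV
    alpha_noise = 0.80,   # 1/f^alpha noise shaping exponent
    beta       = 0.75,    # inhibitory compression of the opposite polarity
    tau_sub    = 250e-6,  # s
    a_sub      = 2.0,     # mS
    a_supra    = 3.0,     # mS
    b          = 90.0     # uA, spike-triggered suprathreshold adaptation offset
  )
  class(out) <- "es_neuron_constants"
  out
}

# Mean of the baseline relative-refractory-period distribution (uniform on
# [131, 894] us); used to normalize tau_supra per fiber.
.t_rel_mean <- function() (131.0e-6 + 894.0e-6) / 2
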