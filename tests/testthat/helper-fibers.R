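# fiber with every randomized parameter at its distribution mean
mean_fiber <- function(sr = 0, sr_group = "HSR") {
  f <- list(
    cf = 1.0, sr = sr, sr_group = sr_group,
    t_abs = 450e-6, t_rel = 512.5e-6, t_dead = 450e-6,
    tau_supra_per = 4500e-6, tau_supra_cen = 2500e-6,
    C_per = 10^(-6.1514) * 1e9 + 164.0,
    C_cen = 10^(-5.7547) * 1e9 + 32.7,
    hearing_loss = 26, fiber_id = 1L)
  class(f) <- "fiber_params"
  f
}

# firing efficiency of a batch of spike-time vectors in [0, T)
fe_of <- function(trains, T = 3.5e-3, sr = 0) {
  firing_efficiency(trains, 0, T, sr = sr)
}
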