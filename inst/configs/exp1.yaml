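# Single monophasic pulses (26 / 39 us, cathodic / anodic) in acoustically
# insensitive fibers; thresholds, RS, latency, jitter per fiber.
population: {n_lsr: 30, n_msr: 30, n_hsr: 90, seed: 1}
n_final: 100          # trials per final FE level
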