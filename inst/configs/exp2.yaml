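# 250 pps biphasic (cathodic-leading, 40 us/phase) pulse trains, 300 ms;
# first-pulse thresholds and DRs for ES-alone / uncoupled / coupled models.
population: {n_lsr: 30, n_msr: 30, n_hsr: 90, seed: 1}
n_final: 100
n_pres: 20            # train presentations for latency/jitter at threshold
do_latency: [es-alone, uncoupled, coupled]
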