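# Combined EAS: pulse train starts 50 ms before the acoustic broadband
# noise (100/200/300 ms, one third each) and ends 250 ms after its offset;
# four current levels per fiber across its DR; intervals I1-I6.
population: {n_lsr: 30, n_msr: 30, n_hsr: 90, seed: 1}
n_final: 100
durations_s: [0.1, 0.2, 0.3]
n_levels: 4
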