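Package: anfeas
Title: Single Auditory-Nerve-Fiber Spiking Under Electric, Acoustic, and
    Combined Electric-Acoustic Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates spike times of single auditory nerve fibers driven by
    cochlear-implant current pulses, by acoustic stimulation, or by combined
    electric-acoustic stimulation (EAS).  The electric pathway is a pair of
    adaptive exponential integrate-and-fire point neurons (peripheral and
    central axonal processes) with polarity-dependent stimulus weighting,
    1/f-shaped membrane noise, spike-triggered adaptation, and an absolute
    dead time.  The acoustic pathway is a surrogate synaptic-release model:
    an inhomogeneous Poisson process of neurotransmitter release events with
    onset adaptation and offset suppression, converted to spikes by a
    stochastic refractory spike generator.  Three EAS coupling variants
    (uncoupled merge, release-to-current coupling, and runtime spike
    exchange) allow probing refractoriness-mediated interaction between the
    two modalities.  Population sampling, firing-efficiency curve fitting
    (threshold, relative spread, dynamic range), latency/jitter and
    vector-strength statistics, and experiment protocols for single-pulse,
    pulse-train, and combined-stimulation paradigms are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
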