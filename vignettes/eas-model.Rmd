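---
title: "Modeling auditory-nerve-fiber spiking under electric-acoustic stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling auditory-nerve-fiber spiking under electric-acoustic stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anfeas)
```

## The problem

Cochlear-implant users with residual low-frequency hearing receive combined
electric-acoustic stimulation (EAS).  Both modalities converge on the same
auditory nerve fibers (ANFs), and because a fiber that has just fired is
refractory, electrically and acoustically evoked spikes suppress each
other.  `anfeas` simulates single-ANF spike times under electric
stimulation (ES), acoustic stimulation (AS), and combined EAS, with the
interaction carried entirely by the refractoriness of the fiber.

## The electric-stimulation model

The peripheral and central axonal processes of the ANF are two structurally
identical adaptive exponential integrate-and-fire point neurons.  Each
membrane obeys

$$C \frac{dV}{dt} = -g_L (V - E_L) + g_L \Delta_T
  e^{(V - V_T)/\Delta_T} - I_{sub} - I_{supra} + I_{noise} + I_{stim},$$

with subthreshold and suprathreshold adaptation currents relaxing as
$\tau \, dI/dt = a (V - E_L) - I$.  A spike is detected when either
membrane reaches the peak potential $v_{peak}$; both neurons are then
reset to $v_{reset}$, both suprathreshold adaptation currents are
incremented by $b$ (the relative refractory period), and all *external*
drive is suppressed for the dead time $t_{dead}$ (the absolute refractory
period) while the intrinsic dynamics and the noise keep evolving.

Extracellular current of the two polarities excites the two processes
asymmetrically.  With cathodic current represented by negative sample
values, the stimulus is split per sample into its cathodic ($I^-$) and
anodic ($I^+$) parts and weighted as

$$I_{stim}^{per} = -(I^- + \beta I^+), \qquad
  I_{stim}^{cen} = \beta I^- + I^+,$$

so a cathodic pulse depolarizes the peripheral neuron and hyperpolarizes
the central one by the compressed fraction $\beta = 0.75$, and vice versa.
This is why cathodic thresholds are lower but latencies longer: the
peripheral process has the larger capacitance and slope factor.

$I_{noise}$ is a $1/f^{\alpha}$ current ($\alpha = 0.8$) synthesized in
the frequency domain (random Hermitian spectra with magnitude
$|f|^{-\alpha/2}$, DC removed) and rescaled so each trace's sample
variance equals $\sigma_{noise}^2$ exactly.  The peripheral and central
neurons receive independent realizations; two independent traces are
obtained per inverse FFT by packing two Hermitian spectra into the real
and imaginary parts of one complex spectrum.

Fixed constants (conductances, potentials, adaptation parameters, noise
amplitudes) are returned by `es_neuron_constants()`.  Units follow one
canonical system — mV, mS, uA, nF, seconds at the user surface — chosen so
that `dV = dt * I / C` holds without scale factors once time is converted
to microseconds at the integrator boundary (the single conversion layer).

## Population variability

Per-fiber parameters are drawn by `sample_fiber()`:

* membrane capacitances $C = 10^x - \alpha$ farads, $x$ normal and
  truncated at $\mu \pm 2\sigma$ (rejection sampling, so no probability
  mass piles up at the limits) — these carry the threshold variability;
* absolute refractory period $t_{abs} \sim U[208.5, 691.5]$ us and
  baseline relative refractory period $t_{rel} \sim U[131, 894]$ us;
* spontaneous rate from a truncated normal per fiber group (LSR/MSR/HSR);
* characteristic frequency log-uniform on 0.125–40 kHz.  CF does not
  enter the membrane model or the surrogate front end; it is kept as
  bookkeeping so a full periphery model can be plugged in later.

The electric and acoustic refractory behaviors are tied together:
$t_{dead} = t_{abs}$ and $\tau_{supra} = \tau_{supra,0} \cdot
t_{rel}/\langle t_{rel} \rangle$ with $\langle t_{rel} \rangle = 512.5$
us, so the mean dead time of the population is 450 us.  The offset
$\alpha$ of the capacitance law is negative for both neurons; the law is
applied literally, i.e. the offset adds capacitance.

## The acoustic surrogate

The full auditory periphery (middle ear, basilar membrane, hair cells,
power-law synapse) is out of scope.  It is replaced by a surrogate release
generator with the one property the coupling mechanism needs: a point
process of neurotransmitter release events with realistic rates and an
adapter interface (`release_fun` in `run_as_alone()`) through which a full
periphery model can be substituted.

The instantaneous release rate is piecewise: spontaneous rate $r_0$
before the stimulus; during a broadband-noise burst a logistic
rate-level term (half-max at `L50` = 55 dB SPL above the fiber's flat
hearing loss, slope 6 dB) with an exponentially decaying onset
enhancement (`onset_factor` 2.5, $\tau_{adapt}$ 10 ms); after the offset,
spontaneous releases are fully suppressed and recover with $\tau_{rec}$ =
80 ms.  Releases are drawn by Poisson thinning and snapped to a 10 us
grid.  A spike generator converts releases to spikes, discarding any
release within $t_{abs} + X$ of the last spike, $X$ exponential with mean
$t_{rel}$.

For this refractory rule the release rate that yields a target
spontaneous spike rate has a closed form: by memorylessness the mean
inter-spike interval is $t_{abs} + t_{rel} + 1/r_0$, so
$r_0 = sr / (1 - sr\,(t_{abs} + t_{rel}))$
(`calibrate_spontaneous_rate()`).  No iterative refinement is needed; the
identity is verified by simulation in the test suite.

The saturated driven release rate (`r_max` = 185 events/s) was chosen so
the saturated driven *spike* rate is near 150 spikes/s for typical
refractory parameters, matching the ceiling the combined-stimulation
experiment operates against.  A flat hearing loss of 26 dB shifts the
rate-level function.  What the surrogate does *not* emulate: basilar-
membrane tuning (all fibers respond to broadband noise identically up to
their parameters), synaptic redocking statistics (releases are Poisson,
not clustered or sub-Poisson), and power-law adaptation over seconds.
Passing tests therefore validate the coupling and statistics machinery,
not periphery realism.

## Coupling variants

* **Uncoupled** (`run_uncoupled`): spike times of the ES membrane model
  and the AS pathway are merged without interaction — the non-interacting
  reference.  No deduplication is attempted: coincidences have measure
  zero on a continuous timeline.
* **Coupled** (`run_coupled`): the AS spike generator is replaced by the
  peripheral neuron.  Every release injects a rectangular cathodic
  current (40 us, 3.0 mA — far above any fiber's threshold) into the
  peripheral membrane, so each release fires the fiber *unless it is
  refractory*; all output spikes come from the membrane.  Overlapping
  injections sum (overlaps are rare below 1 kHz on a 10 us grid, and the
  current is suprathreshold anyway).  Synaptic current is zeroed during
  the dead time like any other external drive.
* **Alternative** (`run_alternative`): both models run in full and
  exchange spike occurrences at runtime; every spike restarts the
  refractory processes of both sides.  The output is the union, with
  same-integration-step duplicates collapsed (a single physical event).
  In our simulations this variant tracks the coupled one closely
  (biphasic thresholds within a few percent), mirroring the behavior the
  coupled design aims for.

## Response statistics

Firing efficiency is the spontaneous-rate-corrected spike probability per
presentation, $FE = (N - SR \cdot T \cdot M)/M$ over an analysis window
$T = 3.5$ ms.  Thresholds and relative spread come from a weighted
integrated-Gaussian fit $FE(L) = \Phi((L-\mu)/\sigma)$; RS $= \sigma/\mu$.
Dynamic range is reported as the dB span between the 10 % and 90 % FE
levels of the fitted curve, $DR = 20\log_{10}(L_{90}/L_{10})$ with
$L_{10,90} = \mu \mp 1.2816\sigma$ — the convention of the single-fiber
literature; it reproduces ~0.9 dB at ~4 % RS.  Latency and jitter pool
*all* spikes (not first spikes only) in the window after each pulse
onset; only under all-spike pooling do the analytic mixture estimates

$$L = \tfrac{N_S}{N_S+N_E}\tfrac{T}{2} + \tfrac{N_E}{N_S+N_E} L_E, \qquad
  J^2 = \tfrac{N_S}{N_S+N_E}\tfrac{T^2}{12} + \tfrac{N_E}{N_S+N_E} J_E^2 +
  \tfrac{N_S N_E}{(N_S+N_E)^2}\big(\tfrac{T}{2}-L_E\big)^2$$

hold ($N_S = SR \cdot T$ spontaneous and $N_E$ evoked spikes per window).
When the estimates serve as a per-fiber non-interaction baseline, $N_E$
is the fiber's measured evoked count per window from its ES-alone run:
per-pulse firing efficiency declines across a pulse train under
adaptation, so the nominal first-pulse value of 0.5 would mis-state the
mixture weights.  Phase locking to the pulse train is quantified by the
vector strength.

## Numerical choices

* **Integration**: forward Euler at $dt = 1$ us.  The shortest time
  constant is 250 us, and halving the step moves fitted thresholds by
  less than 1 % (tested).  The exponential term's argument is clamped at
  60 to avoid overflow; any crossing of $v_{peak}$ in the same step emits
  the spike regardless.
* **Spike time**: the first sample at which $V \ge v_{peak}$.
* **Threshold nomenclature**: the threshold potential (−70 mV) is the
  $V_T$ of the exponential term; the peak potential (+24 mV) is the spike
  detection level.
* **Pre-stimulus state**: in the absence of stimulation the membrane
  occupies a noise-driven stationary distribution.  `run_es_alone()`
  evolves a fresh 20 ms burn-in (≥ 8 membrane and ≥ 4 suprathreshold-
  adaptation time constants; stationarity is KS-tested against 40 ms) per
  repetition.  The population protocols instead draw initial states from
  a per-fiber stationary ensemble (`state_bank()`): one long unstimulated
  run — with spontaneous release currents, for the coupled variant —
  snapshotted every 20 ms.  Snapshots that far apart are effectively
  independent draws from the same stationary law (KS-tested at double
  spacing), and each state is used at most once per FE level, so
  within-level trials stay independent.  Each trial then evolves a 3 ms
  noise-driven pre-span from its sampled state before the stimulus, so
  the state and the in-window noise share one continuous slow-noise
  history, and a per-trial constant current restores the still-slower
  band of the 1/f spectrum — without both, the slow noise components that
  dominate trial-to-trial threshold variability are lost and relative
  spread comes out ~30 % too small.  The engine is verified against the
  fresh-burn-in path (equal thresholds and relative spreads on matched
  fibers); it is a speed-up, not a model change.
* **FE level placement**: a factor-2 bracketing search for the FE 0.1 and
  0.9 crossings, a 6-level scan of the bracket to refine the crossing
  estimates, then 10 equally spaced levels across the refined bracket
  (extended 25 % each side), 100 trials per final level; the fit uses all
  collected points with binomial weights.  Threshold estimates are
  insensitive to the placement; for strongly non-Gaussian FE curves
  (coupled high-SR fibers, whose curves rise steeply and then plateau at
  the non-refractory fraction) the fitted $\sigma$ — hence RS and DR —
  necessarily depends on it, which is worth remembering when comparing
  dynamic ranges across studies that do not publish their level grids.
* **Degenerate inputs**: zero-rate release processes yield empty trains;
  FE fits refuse data that do not bracket 0.2–0.8 and direct the user to
  widen the sweep; a non-positive 10 % FE level flags the dynamic range
  as undefined rather than returning a complex number.

## Experiment protocols

`run_experiment1()` fits single monophasic pulses (26 and 39 us, both
polarities) per fiber and measures latency and jitter at threshold.
`run_experiment2()` fits first-pulse thresholds of 250 pps biphasic
(cathodic-leading, 40 us/phase) trains for the ES-alone, uncoupled and
coupled variants, compares them by Mann-Whitney tests, and tests per-fiber
latency/jitter deviations from the analytic estimates by Wilcoxon
signed-rank, split at SR = 50 spikes/s.  `run_experiment3()` runs combined
stimulation: the train starts 50 ms before a 100/200/300 ms noise burst
and ends 250 ms after it; four current levels are drawn uniformly across
each fiber's fitted 10–90 % FE span; the acoustic level is the lowest in
70–100 dB SPL whose predicted driven rate exceeds 2.5 x SR (else 100 dB);
electric-only and combined conditions share matched noise seeds for
paired differences across the six analysis intervals.

Default population sizes follow the 30/30/90 LSR/MSR/HSR composition.
The test suite and the acceptance script run the protocols at reduced
sizes chosen so population-mean standard errors stay well inside the
published population SDs: 30 fibers (experiment 1 full grid), 60
(experiment 2), 32 (experiment 3), and 60/120 in the acceptance script;
train-latency runs use 10–12 presentations of the 300 ms train.

## Known limitations

* The coupled variant's quantitative threshold/DR elevations in high-SR
  fibers depend on the release statistics of the acoustic front end.
  With the Poisson surrogate the elevation of the population-mean
  first-pulse threshold is smaller (and the DR inflation larger) than
  with a full synapse model; the directions, SR-dependence and
  significance structure are reproduced.
* Monophasic latencies are short of experimental values by roughly
  200 us, a known property of this model family.
* No electrophonic (hair-cell-mediated) response to electric current is
  modeled, and no spatial electrode-fiber geometry: threshold variability
  is carried entirely by the capacitance distribution.
* Subthreshold interaction between modalities is absent by construction:
  the synaptic injection is suprathreshold and interaction is confined to
  refractoriness.

## A minimal session

```{r example, eval = FALSE}
set.seed(1)
fiber <- sample_fiber("HSR")
bank <- state_bank(fiber, "es")
fit <- fiber_threshold(fiber, "es-alone", "monophasic", 26e-6, "cathodic",
                       bank = bank)
fit
fiber_latency(fiber, fit$mu, "es-alone", "monophasic", 26e-6, "cathodic",
              bank = bank)
```
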