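---
title: "Modelling eyeblink conditioning in a two-micromodule olivocerebellar network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling eyeblink conditioning in a two-micromodule olivocerebellar network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Classical eyeblink conditioning (CEBC) pairs a neutral conditioned stimulus
(CS, e.g. a LED) with an aversive unconditioned stimulus (US, an air puff)
at a fixed inter-stimulus interval (ISI, 250 ms by default). The cerebellum
learns to produce an anticipatory eyelid closure — the conditioned response
(CR) — timed just before the US. `olivosim` simulates this process in a
spiking network of the olivocerebellar circuit organized into two
micromodules: a *downbound* module (70% of Purkinje, nuclear and olivary
cells; high-rate, zebrin-negative-like Purkinje cells that mainly undergo
simple-spike suppression during learning) and an *upbound* module (30%;
low-rate, zebrin-positive-like cells that mainly undergo facilitation). The
CS is carried by mossy fibres into a sparse granular-layer code; the US is
carried by climbing fibres from the downbound inferior olive; the deep
nuclear projection cells of both modules are decoded into an analog eyelid
signal.

Learning is driven by two climbing-fibre-supervised plasticity rules on the
parallel-fibre synapses: cf-gated long-term depression at pf–Purkinje-cell
synapses (with potentiation for unsupervised parallel-fibre activity) and
the mirror-image rule at pf–molecular-layer-interneuron synapses (cf-gated
potentiation, unsupervised depression). Knock-out configurations emulate
mutant-mouse phenotypes: `ltd_ko` silences pf-PC LTD, `mli_ko` disconnects
the interneurons from the Purkinje cells, and `double_ko` applies both.

## Neuron and synapse models

All integrated neurons are extended generalized leaky integrate-and-fire
(E-GLIF) point neurons with three state variables: the membrane potential,
a voltage-coupled adaptation current and a fast spike-triggered
depolarizing current. This minimal set reproduces the salient cerebellar
electroresponsive signatures — tonic autorhythmic firing, an approximately
linear frequency–current curve, burst–pause responses to strong input
(the complex-spike correlate in Purkinje cells) and post-inhibitory rebound
(deep nuclei). Mossy fibres and glomeruli are relay units that forward the
spike trains they receive.

The update runs on a fixed 1-ms grid (the protocol's resolution), with a
documented operation order (`step_neuron()`); the compiled network engine
applies exactly the same sequence, so the two paths are replayable against
each other. Synapses are alpha-shaped conductances
`g(t) = w (t/tau) exp(1 - t/tau)` with per-connection-type time constants,
implemented as an exactly integrated two-state linear filter per
(neuron, time constant, reversal class) channel.

The supplementary parameter tables of the source model are not distributed
with this package, so every neuron parameter set is a documented fallback,
fitted with `tonic_rate()` so that each population reproduces its target
discharge. Two printed anchors pin the Purkinje cell: an endogenous current
of 176.3 pA must produce 39 ± 1 Hz (upbound/zebrin-positive) and 742.54 pA
must produce 86 ± 1 Hz (downbound/zebrin-negative); the remaining PC
constants were fitted so that both anchors lie on the cell's f–I curve,
which stays close to the straight line through them. Low-rate populations
(Golgi, interneurons, olive, nuclear GABAergic cells) are implemented as
subthreshold pacemakers — threshold slightly below rest, with the interspike
interval stretched by slow spike-triggered adaptation — because a plain
integrate-and-fire neuron cannot fire stably at 1–25 Hz without a firing
floor discontinuity.

Membrane noise is an explicit free parameter (the reference protocol
specifies noise seeds but no noise model): each noisy neuron receives a
zero-mean current refreshed every 5 ms (approximately normal, sd
`noise_sd`).

## Network construction

Construction is statistical rather than morphological: each cell receives a
mediolateral coordinate in [0, 1); the downbound module occupies the first
70%. Micromodule-confined connection types (everything touching PC, DCN or
IO) never cross modules. Spatially local types (glomerular rosettes,
ascending axons, molecular-layer and Golgi axons) draw presynaptic partners
from a sliding window along the coordinate; parallel fibres, which run
across the modules, draw uniformly. Climbing-fibre spillover onto the
molecular-layer interneurons follows a linear parasagittal ramp that
favours downbound olivary sources near the downbound zone; each interneuron
is then labelled downbound- or upbound-preferring by the majority of the
Purkinje cells it inhibits (ties: spillover origin, then id parity).

The 24 connection types (15 cortical, 9 involving the deep nuclei and
olive) carry fallback convergences, weights, delays and receptor time
constants refined against the target baseline discharges
(`calibrate_weights()` performs the bisection refinement; the shipped
defaults already satisfy the targets, so the calibration verifies and
returns unit multipliers). Two types use module-differentiated weights
(`weight_upbound`), mirroring the downbound;upbound weight convention of
the source tables: PC→DCN coupling is weaker in the upbound module, with
the baseline balance carried by module-specific nuclear endogenous
currents.

### Down-scaling

`scale_factor` controls the simulated size. Granule cells — the bulk of the
computational cost — scale linearly; the sparser readout-chain populations
(GoC, PC, SC, BC) scale as `sqrt(scale)`; the deep populations (already at
a mesoscale minimum, and the motor readout) and the mossy-fibre/glomerulus
input battery are held at full size by default. The rationale is the
decoded output: the conditioned response is detected per trial against a
threshold of 2.5 baseline standard deviations, and the baseline SD of a
population-averaged signal grows as the inverse square root of the cell
count. Linear scaling of all populations at cortical scale 0.1 leaves ~7
downbound Purkinje cells, whose per-capita rate fluctuations are as large
as the learned signal, making the threshold rule unattainable for reasons
that have nothing to do with the model's physiology. Square-root scaling
degrades readout signal-to-noise only as the fourth root of the scale.
In-degrees are held at their full-scale values until the presynaptic pool
caps them. At `scale_factor = 1` the rule has no effect and the cortical
population counts reproduce the canonical 29,230-neuron cortex.

## The protocol

Each 1260-ms trial is a 500-ms baseline, the CS (10-Hz Poisson on the
central 45 of 117 mossy fibres, duration ISI + 10 ms), the US (500-Hz,
10-ms burst co-terminating with the CS, delivered to every downbound
olivary cell) and a 500-ms post window; 1-Hz background runs on all mossy
fibres throughout. The conditioned olivary response (CIO) — a 400-Hz burst
to a fixed half of the downbound olive at 88 ms after CS onset — occurs
with probability rising linearly over trials to 0.43. US and CIO are
delivered as strong conductance inputs to the olivary cells rather than
forced spikes, so the nucleo-olivary feedback (DCN_GABA→IO) can damp the
conditioned response of the olive, as observed. A session is 10 blocks of
100 trials, repeated for 3 seeds; one master seed derives independent
streams for construction, initial conditions, stimuli and noise, so a
lesion never perturbs the construction randomness.

Within the engine, trials are contiguous: membrane state, adaptation and
conductances carry across trial boundaries (only the trial-local
plasticity bookkeeping restarts), and the motor decoding filters each
100-trial block as one continuous stream before slicing it into trials —
per-trial filtering of a 1260-ms snippet would otherwise manufacture edge
artifacts in the baseline statistics.

## Plasticity implementation

The eligibility kernel is the unit-peak alpha function
`K(t) = (t/tau) exp(1 - t/tau)` with tau = 50 ms (the pf-PC site reuses the
same form with its own rise time as a documented fallback for the original
rule's kernel). At each teaching (climbing-fibre) spike arriving at a
target, every plastic synapse onto that target changes by the rate times
`sum_k K(t_cf - s_k)` over all of its preceding parallel-fibre spikes; a
parallel-fibre spike with no coincident (same 1-ms step) teaching spike
triggers the fixed unsupervised change. The kernel sum is evaluated
*exactly* — not truncated — via a pair of recursively decayed exponential
traces per synapse (`P`, `Q` with `sum K = (e/tau)(t P - Q)`), which is
O(1) per event and agrees with the brute-force double loop over spike
pairs to floating-point precision. Weights are clipped to [0, 4x initial].

The four learning rates are free parameters. The shipped defaults were
tuned at the full 10x100-trial protocol against the reference
end-of-learning firing modulation and the learning-curve shape (see
`scripts/calibrate_rates.R`). The short-sequence shortcut — tune on ~20
trials, then divide by 50 — was evaluated and rejected: with bounded
weights, rates strong enough to express end-of-learning modulation within
20 trials drive the active synapses to their bounds almost immediately,
and the linear extrapolation then badly overshoots (the 1000-trial curve
peaks early and decays).

## Motor decoding and CR detection

Per-capita instantaneous rates of the downbound and upbound nuclear
projection cells are filtered (20-ms moving average, then a Gaussian window
whose stated 25-ms width is interpreted as its standard deviation — the
same convention as all analysis kernels), subtracted (downbound minus
upbound, per-capita so the 70/30 split does not trivially bias the
amplitude), baseline-subtracted per trial, and normalized by the maximum
amplitude of the control simulations (knock-out runs must be normalized by
the control constant; the decoder raises an explicit error otherwise). A CR
is scored when the normalized signal reaches
`max(0.2, mean + 2.5 SD of the trial's baseline)` within the last 200 ms of
the ISI; the first crossing is the onset latency, the maximum from onset to
trial end is the peak.

## Analysis formulas

Spike density functions are Gaussian-kernel convolutions (kernel width =
standard deviation; 41 ms for Purkinje simple spikes and interneurons,
10 ms for nuclear cells, 5 ms for complex spikes and the olive). Purkinje
complex spikes are maximal runs of at least two spikes whose inter-spike
intervals all exceed twice the cell's baseline rate in instantaneous
frequency; each run is replaced by a single spike in the simple-spike
series. Suppression (facilitation) in the CR window — which excludes the
first 50 ms of the ISI, where only fast non-associative responses occur —
is the mean percentage deviation from the baseline SDF over the instants
strictly below (above) baseline; instants exactly at baseline belong to
neither set. A trace is significantly modulated when its dominant
CR-window deviation strictly exceeds the same quantity computed over the
whole baseline window (the choice of the whole 500-ms baseline rather than
a window-length sub-segment is ours). Traces with near-zero baseline SDF
(complex spikes in the downbound module) are flagged undefined rather than
divided by zero. Plasticity curves report, per block and site, the mean
percentage weight change of the synapses moving in each direction
multiplied by the fraction of synapses moving that way.

## Design choices and degenerate cases

* "Coincident" pf and cf activity means the same 1-ms step; the kernel
  vanishes at zero lag, so the branch order at a shared step is immaterial.
* The CIO burst duration is 10 ms (four spikes at 400 Hz), matched to the
  US duration; its target half of the downbound olive is drawn once per
  experiment, giving a stable conditioned pathway.
* The CIO probability ramp is per-trial linear (not per-block).
* Golgi gap junctions are approximated by a fast spike-mediated
  depolarization of the other Golgi cells (0.2 mV per spike); they are not
  counted among the 24 chemical connection types.
* Peak latency is searched from the CR onset to the end of the trial, not
  only within the CR window.
* Ties in interneuron preference fall back to climbing-fibre in-degree and
  then id parity; interneurons with no Purkinje target are labelled from
  their climbing-fibre afferent alone, with a warning.
* Empty populations at extreme down-scaling raise errors naming the
  population (or the emptied micromodule).
* The explicit 1-ms membrane update can overshoot the inhibitory reversal
  under extreme conductance (e.g. during weight-calibration sweeps); the
  engine floors the potential at -95 mV, which is inert in the normal
  operating regime.

## What the simulations do and do not show

The generator emulates the study conditions — population ratios, the 70/30
module split, stimulus statistics, trial structure, lesion configurations —
at a reduced scale (the package's standard conditions are cortical scale
0.1: ~2,900 granule cells, 31 Purkinje cells, 141 interneurons, full-size
deep nuclei; run sizes chosen so a full four-condition, three-seed study
completes on a single CPU in well under an hour). It does not reproduce
full-scale granular-layer combinatorics, morphological connectivity, or
the variance structure of in vivo recordings; passing tests demonstrate
that the implemented mechanisms produce the right directions and
magnitudes of modulation under these synthetic conditions, not that the
parameters are a fit to any particular animal. Conditioned-response
percentages at this scale are more step-like across blocks than the
gradual experimental curves: with tens rather than thousands of cells per
readout population, the decoded signal crosses the detection threshold
more deterministically once learning consolidates. The lesion ordering and
the modulation statistics are the robust quantities.
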