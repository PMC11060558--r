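# olivosim

Mesoscale spiking simulation of the olivocerebellar circuit during
classical eyeblink conditioning (CEBC).

## What it is for

In CEBC, a neutral conditioned stimulus (CS) is paired with an aversive
unconditioned stimulus (US) at a fixed inter-stimulus interval (ISI); the
cerebellum learns an anticipatory eyelid closure — the conditioned response
(CR) — timed just before the US. `olivosim` is for computational
neuroscientists who want to simulate this process mechanistically in a
spiking network organized as two olivo-cortico-nuclear micromodules: a
*downbound* module (70% of Purkinje/nuclear/olivary cells; high-rate
Purkinje cells that mainly undergo simple-spike suppression during
learning, and the only module receiving the US) and an *upbound* module
(30%; low-rate cells that mainly undergo facilitation).

The network contains granule, Golgi, Purkinje, stellate and basket cells,
two deep-nuclear populations (glutamatergic projection cells DCN_p and
GABAergic nucleo-olivary cells) and the inferior olive, wired through 24
connection types (29,230 cortical neurons at full scale; a `scale_factor`
shrinks the network for desk-scale studies). Neurons are E-GLIF point
models (tonic firing, near-linear f-I, burst-pause, rebound); synapses are
alpha-shaped conductances.

Learning is carried by two climbing-fibre-supervised spike-driven rules on
parallel-fibre synapses. With the alpha eligibility kernel
`K(t) = (t/tau) e^(1 - t/tau)` (tau = 50 ms), a teaching (climbing-fibre)
spike at time `t_cf` changes each synapse by the learning rate times
`sum_k K(t_cf - s_k)` over its preceding parallel-fibre spikes `s_k`, while
a parallel-fibre spike without coincident teaching triggers the opposite
fixed-size change:

* pf-PC: cf-gated **LTD**, unsupervised LTP;
* pf-MLI: cf-gated **LTP**, unsupervised LTD (signs reversed).

Knock-out configurations emulate mutant mice: `ltd_ko` (pf-PC LTD off),
`mli_ko` (molecular-layer interneurons disconnected from Purkinje cells),
`double_ko` (both).

The DCN_p output of both modules is decoded (20-ms moving average plus a
25-ms Gaussian, downbound minus upbound per-capita rate, normalized by the
control simulations' maximum) and a CR is scored when the signal exceeds
`max(0.2, mean + 2.5 SD of the trial baseline)` in the last 200 ms of the
ISI. Analysis tools implement spike density functions, simple/complex-spike
separation, suppression/facilitation quantification with a significance
rule, neuronal recruitment, plasticity curves and SDF-minimum timing
distributions.

## A worked example

```r
library(olivosim)

cfg <- network_config(scale_factor = 0.05, seed = 1)
net <- generate_connectivity(build_network(cfg))
net
#> <cereb_network> scale 0.05
#>
#>       BC DCN_GABA    DCN_p     glom      GoC      GrC       IO       mf
#>       33       32       96     2336       16     1431       14      117
#>       PC       SC
#>       22       67
#> 91576 synapses across 24 connection types

pr <- protocol_config()                 # 500 ms baseline, CS 260 ms,
pr$us_onset_ms                          #   US at 750 ms, trial 1260 ms
#> [1] 750

# a short control experiment: 2 blocks of 100 CS-US trials, one seed
pr$n_blocks <- 2
ex <- run_experiment(net, pr, lesion = "control", n_seeds = 1)
learning_curve(ex$cr)
#>    block pct_cr sd_cr n_trials
#> 1:     1     78    NA      100
#> 2:     2    100    NA      100
```

The learning curve gives the percentage of trials per 100-trial block in
which the decoded eyelid signal crossed the CR threshold inside the CR
window; it rises over blocks as pf-PC LTD and pf-MLI LTP reshape the
Purkinje simple-spike output. `analyse_modulation(ex, "PC", "downbound")`
returns per-trace suppression/facilitation statistics of the retained
blocks, and `plasticity_curves()` summarizes the per-block weight
development at each plastic site.

A thin command-line front end is installed at `inst/cli/olivosim`
(`build`, `run --lesion ... --isi ... --scale ... --seeds ...`,
`analyze`).

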