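# compinhib

Spiking-network simulation and gradient-based optimization of interneuron
circuits for **compartment-specific feedback inhibition**.

## What problem does this solve?

Cortical pyramidal cells (PCs) receive distinct excitatory input streams at
the soma and at the apical dendrite, and integrate them nonlinearly
(dendritic calcium plateaus, bursts). For feedback inhibition to stabilize
each stream separately, the surrounding interneuron (IN) circuit has to
*invert* that nonlinear integration: recover the somatic and the dendritic
input from PC spike trains alone, and return matching inhibition to the
right compartment. `compinhib` treats this as an optimization problem — and
asks what circuit structure falls out.

The model is a recurrent spiking network of two-compartment PCs (leaky
integrate-and-fire soma with spike-triggered adaptation; dendrite with a
sigmoidal regenerative current `f(v) = 1/(1+exp(-(v-E_d)/D_d))`, plateau-
terminating adaptation, and back-propagating-AP coincidence detection) plus
integrate-and-fire INs. PC→IN synapses carry Tsodyks–Markram short-term
plasticity: release scale `mu = u R`, with utilization `u` relaxing to the
initial release probability `U` and facilitating at spikes, and resources
`R` depleting at spikes. The objective, for each compartment `x` of each PC,

```
L = sum_t sum_i ( E_i^x(t) - alpha*mu_x + I_i^x(t) )^2
```

asks inhibition `I <= 0` to track excitation `E` above the mean background
`mu_x`, and is minimized by backpropagation through the simulation with a
surrogate spike derivative `1/(1+beta|v-theta|)^2` and Adam (gradient clip
[-1, 1], `U` clipped to [0, 1]). During optimization the INs diversify into
a depressing-input, soma-targeting class and a facilitating-input,
dendrite-targeting class — model analogues of PV and SST interneurons —
because depressing synapses read out PC *events* (somatic drive) while
facilitating synapses read out *bursts* (dendritic drive). A companion
linear PV/SST/PC rate model makes the wiring requirement exact: without
perfectly facilitating PC→SST synapses, disynaptic PC→PV→SST inhibition
must cancel the event drive (`beta*W_SST<-PC = alpha*W_SST<-PV*W_PV<-PC`),
which is why knocking out PV→SST connections selectively destroys the
dendritic balance.

The analysis suite implements the accompanying measurements: paired-pulse
ratios (PPR), event/burst demultiplexing of spike trains, Gaussian-mixture
clustering of INs, excitation–inhibition correlations, specialization, and
class-resolved IN→IN connectivity.

## Worked example

Train a reduced self-organized network and look at what emerged:

```r
library(compinhib)

net <- build_network(network_config(N_E = 60, N_I = 16), default_params(), seed = 1)
round(evaluate_network(net, "pulses300", seed = 5)$r, 3)   # untrained balance
#>  soma  dend
#> 0.444 0.059

tr  <- train_network(net, train_config(n_updates = 150, patience = Inf), seed = 2)
ev  <- evaluate_network(tr$net, "pulses300", seed = 5)
round(ev$r, 3)                                             # trained balance
#>  soma  dend
#> 0.656 0.256

feats <- in_features(tr$net, ev$record)
round(cor(feats$ppr, feats$w_dend - feats$w_soma), 2)      # facilitation -> dendrite
#> [1] 0.51
round(range(network_ppr(tr$net)), 2)                       # depressing ... facilitating
#> [1] 0.87 1.22
```

The untrained network tracks somatic excitation loosely (r ≈ 0.44, generic
recurrent feedback) and dendritic excitation barely (r ≈ 0.06). Even this
very small, briefly trained network improves both (soma 0.66, dendrite
0.26; the larger networks trained by the acceptance script reach ≈0.72 and
≈0.4–0.5), and the interneurons spread from a paired-pulse-neutral
population (PPR ≈ 1) into depressing (PPR < 1) cells that target somata and
facilitating (PPR > 1) cells that target dendrites — the correlation
between PPR and the dendrite-vs-soma weight difference is clearly positive.

`pulse_probe()` exposes the underlying code: somatic current pulses move
the event rate, dendritic pulses move the burst probability.
`measure_ppr()`, `detect_events()`, `cluster_interneurons()`,
`specialization()` and `cluster_connectivity()` implement the measurement
pipeline; `rate_params()` / `rate_sensitivities()` /
`dendritic_specificity_residual()` give the algebraic picture. The methods
vignette (`vignettes/compartment-specific-inhibition.Rmd`) documents the
model, every default parameter, and the design decisions.

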