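---
title: "Modeling bilateral spinal locomotor circuits with spinalcpg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bilateral spinal locomotor circuits with spinalcpg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`spinalcpg` simulates a bilateral spinal central pattern generator (CPG):
two rhythm generators (RGs), one per side of the cord, each made of a
flexor (F) and an extensor (E) half-center, coupled through commissural
interneuron pathways (V0D, V0V, V3, and a descending excitatory CIN
population, CINe) and shaped by ipsilaterally projecting inhibitory
interneurons (V1, V1-1, V2b, Ini, Ini1) and the excitatory V2a relay.

Every neuron is a single-compartment Hodgkin–Huxley model with fast sodium,
delayed-rectifier potassium and leak currents. Neurons of the F and E
half-centers additionally carry a persistent (slowly inactivating) sodium
current INaP whose inactivation time constant reaches 18 s at its
half-inactivation voltage; this current makes them conditional bursters.
As a neuron's excitability grows, its state passes from silence through
rhythmic bursting to sustained tonic firing, and within the bursting range
the burst frequency grows with excitability. The half-centers are
asymmetric by construction: F operates in the bursting regime and paces the
rhythm, while an isolated E population is tonic and is made rhythmic by
phasic inhibition tied to the flexor phase.

Membrane dynamics follow

$$C\,\dot V = -I_{Na} - I_{NaP} - I_K - I_L - I_{SynE} - I_{SynI}
  \;(-\,I_{Ar} - I_{Ch}\ \text{in V1-class neurons}),$$

with gate kinetics $\tau_x(V)\,\dot x = x_\infty(V) - x$; sodium activation
(both fast and persistent) is instantaneous. Synapses are conductance
based: a presynaptic spike with signed weight $w$ increments the target's
excitatory ($w>0$, by $\bar g_E w$) or inhibitory ($w<0$, by
$\bar g_I |w|$) conductance, which then decays exponentially
($\tau = 5$ ms). Reversal potentials are $-10$ mV (excitatory) and
$-70$ mV (inhibitory).

Two ways of inducing the rhythm are built in:

* **drug variant** — a dimensionless excitation parameter $\alpha$ rescales
  every population's mean leak reversal, $\bar E_{L} = \bar E_{L0}(1-\alpha)$,
  emulating bath-applied neuroactive drugs (all $\bar E_{L0} < 0$, so
  increasing $\alpha$ depolarises);
* **brainstem variant** — baseline excitability ($\alpha = 0$) plus a tonic
  excitatory drive conductance $\bar g_{Ed}\,\lfloor w_d\,d\rfloor_+$ to the
  F, E, CINe and Ini populations on both sides (default weights 0.4, 0.48,
  0.75 and 2).

Optogenetic manipulation of the two V1-class populations is modelled by
switching on an archaerhodopsin conductance (gAr, reversal $-80$ mV,
hyperpolarising) or a channelrhodopsin conductance (gCh, reversal $-10$ mV,
depolarising) during timed epochs; both are zero in control conditions.

A midsagittal hemisection (`apply_hemisection()`) removes one side's
populations and every crossing connection, emulating the isolated
hemicord.

## Stochastic structure and reproducibility

Heterogeneity enters in three places, all seeded explicitly: per-neuron
leak reversals (normal, tabulated SD, resampled beyond 6 SD), per-neuron
INaP conductances in the half-centers, and the connectome — each ordered
neuron pair of a connected population pair receives a synapse independently
with the tabulated probability, with weights drawn at 5% (excitatory) or
10% (inhibitory) relative SD, sign preserved by resampling. Structural
randomness (build seed) and dynamical randomness (run seed; initial
membrane potentials uniform within ±5 mV of each neuron's leak reversal)
are independent streams, so either can be varied alone. Identical seeds
give bit-identical rasters; the test suite asserts this at the metrics
layer.

## Numerics

The integrator is exponential Euler with a 0.1 ms step: within a step the
total conductance and effective reversal are frozen and the membrane decays
exactly toward the frozen equilibrium; dynamic gates relax exactly toward
their steady states with their voltage-dependent time constants evaluated
at the pre-step voltage. Spikes are upward crossings of $-10$ mV
(edge-triggered, no refractory period beyond what the currents provide) and
are delivered to postsynaptic conductances at the next step (0.1 ms
latency, no axonal delays). The update order per step is fixed: synaptic
decay, delivery of the previous step's spikes, photostimulation evaluation,
membrane/gate update, spike detection.

For speed the engine evaluates gate steady states and per-step relaxation
factors from a voltage-indexed lookup table (0.01 mV grid, linear
interpolation); the table error is orders of magnitude below the
integration error (a 10 s single-neuron trajectory stays within ~1e-4 mV of
exact-formula stepping, and within-band burst counts match a classical RK4
reference at a 0.01 ms step to ±1 spike in the bursting regime). In the
fast tonic regime (> 50 Hz) the 0.1 ms exponential-Euler step
underestimates firing rate by a few percent relative to RK4 — a known
property of coarse-step integration of stiff spike upstrokes; halving the
step changes network burst frequency by under 2%.

## Analysis layer

Population activity is summarised as average rate histograms in
spikes/(N·s) with 100 ms bins. Burst segmentation takes maximal runs of
bins above 0.3 of the robust (95th percentile) peak rate, merges gaps
shorter than 200 ms and drops runs shorter than 300 ms; the threshold is
relative, so segmentation is invariant to rate rescaling. Oscillation
frequency is the burst count divided by the window; windows with fewer than
three bursts are flagged non-oscillatory rather than given a spurious
frequency. Phase relations are circular means of one train's burst-onset
latencies within the other's cycles: alternation is a phase in
[0.4, 0.6], synchrony in [0, 0.1] ∪ [0.9, 1), and a mean resultant length
below 0.6 is labelled irregular. These segmentation conventions (and the
three-burst rule) are package conventions, chosen on synthetic square-wave
trains where ground truth is known; all are exposed as arguments.

## Problem sizes and default conditions

The full bilateral model has 2100 neurons (two sides of 1050). Tests and
the acceptance script use the quarter-scale model: population sizes ÷ 4
with connection probabilities × 4 (capped at 1), which preserves each
neuron's expected in-degree and therefore the mean synaptic conductance
budget. Settling periods of 10–15 s and recording windows of 30–60 s are
the defaults for quarter-scale work; they leave ≥ 10 rhythm cycles for
phase estimation at the observed frequencies (~0.2–0.5 Hz). The named
protocols carry the canonical condition parameters: drug controls at
α = 0.17 (intact) and 0.2 (hemicord); photostimulation at gAr = 7 or
gCh = 0.7 mS/cm² with per-protocol α of 0.15–0.2; brainstem runs at drive
level d = 1.

## Design choices where the architecture was open

* The printed membrane equations for half-center and interneuron
  populations are identical; INaP is included only where a persistent
  sodium conductance is tabulated (F and E).
* CINe axons cross the midline (left CINe excites right V1/V1-1). Only the
  crossing interpretation lets hemisection silence V1 by removing its
  contralateral excitation, which is the mechanism the hemicord phenotype
  rests on; with ipsilateral CINe the phenotype is unreachable.
* The brainstem variant keeps baseline excitability and expresses
  stimulation strength purely through the drive level d; rescaling leak
  reversals to zero would be unphysical.
* The drug variant has no external drive; CINe (one of the two most
  excitable populations, mean leak reversal −60 mV) is the sole carrier of
  contralateral tonic excitation to V1. An explicit contralateral drive
  conductance onto V1 was prototyped and rejected: any value large enough
  to recruit V1 makes it fire tonically (its rhythmic inhibitor V0D
  carries too little signal to sculpt it), which degrades flexor–extensor
  coordination and flips left–right coordination to synchrony.
* Ini1 receives no synaptic input in the connection table; it is driven by
  its excitability alone.

## What passes, and known limitations

The single-neuron layer reproduces its targets exactly: the
silence/bursting/tonic ladder with monotone burst frequency, integrator
agreement with an independent RK4 reference, event-driven synapses equal to
the explicit exponential sums to 1e-12, and connectome statistics matching
their binomial and dispersion specifications. Hemisection silences V1
completely and leaves Ini tonically active, and the two-cell half-center
fixture alternates in anti-phase.

The network-level phenotypes that depend on V1-mediated frequency control
do **not** emerge from the tabulated parameter set under the standard
conductance-synapse semantics implemented here, and the corresponding
acceptance tests are left failing rather than tuned into agreement. The
quantitative obstructions, verified by direct arithmetic and simulation:

* **V1 recruitment.** A V1 neuron (leak reversal −90 mV baseline, leak
  conductance 0.1 mS/cm²) needs roughly 0.05–0.13 mS/cm² of excitatory
  conductance to reach threshold. The CINe→V1 pathway (weight 0.14,
  expected in-degree 10, CINe firing ~40 Hz) supplies ~0.014 mS/cm². V1 is
  therefore silent even in the intact drug model, so hyperpolarising it
  changes nothing.
* **Channelrhodopsin block.** With the tabulated sodium inactivation
  (half-voltage −55 mV), a V1-class neuron sustains firing only for
  gCh ≈ 0.09–0.2 mS/cm²; at the protocol values 0.7–1.0 the membrane
  settles at a stable depolarised fixed point near −28 mV after a single
  spike (confirmed by RK4). "Activation" of V1-1 by gCh, the mechanism
  behind the depolarisation phenotypes, is therefore unreachable.
* **Relay saturation.** The strong excitatory weights onto V2b and V0D
  (0.5–0.6) deliver ~0.4 mS/cm² during flexor bursts, putting these relays
  into the same depolarisation block; V2a (leak conductance 0.8 mS/cm²)
  can never be driven to threshold by its tabulated input. Flexor–extensor
  and left–right coupling consequently rely on residual, fluctuation-driven
  relay spikes: the extensor entrains 2:1 to the flexor instead of 1:1.
* **Inert micro-weights.** The inhibitory weights onto the half-centers
  (Ini→F −0.005, Ini1→F −0.0025, V0D→F −0.02) translate to ≤ 0.3 mV of
  equivalent hyperpolarisation at plausible source rates, while the
  measured frequency sensitivity of the flexor population is
  ~0.085 Hz/mV; deleting the Ini→F pathway entirely changes the hemicord
  frequency by < 0.01 Hz. The tonic-Ini mechanism for the hemicord slowdown
  is therefore numerically inert, and the hemicord actually runs slightly
  faster than the intact cord at equal α (hemisection removes the V0D
  commissural inhibition of F).

No single rescaling reconciles these (the shortfalls span factors of ~0.5×
to ~60× in different pathways), and the connection table is part of the
model's published identity, so it is preserved as printed. The simulator,
fixtures and analysis layer are validated independently of these
network-level outcomes; the failing phenotype tests document precisely
which published behaviours would require additional, unpublished
calibration of the original simulation environment.

Beyond this, the usual scope limits apply: no motoneurons, sensory
afferents, reflex or pattern-formation circuits; single-compartment
neurons without channel noise, calcium dynamics or temperature dependence;
no synaptic plasticity or axonal conduction delays; and the synthetic
networks emulate population-level statistics only — none of the
anatomical rostrocaudal structure of a real cord.

## Reproducing the analyses

```r
library(spinalcpg)

# intact drug-induced rhythm, quarter scale
net <- default_model("drug", "intact", alpha = 0.17, scale = 0.25, seed = 42)
rec <- run_simulation(net, config = sim_config(settle_s = 15, record_s = 60),
                      seed = 7)
rhythm_metrics(rec)
coordination_summary(rec)
autoplot(population_histogram(rec, "F", "left"))

# frequency versus excitation
sw <- alpha_sweep(alphas = seq(0.14, 0.23, by = 0.03), replicates = 3,
                  seed = 101, scale = 0.25,
                  config = sim_config(settle_s = 10, record_s = 30))
glance(sw)
autoplot(sw)

# the full condition matrix
experiment_matrix(scale = 0.25, seed = 55, control_s = 40, stim_s = 40,
                  config = sim_config(settle_s = 15))
```
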