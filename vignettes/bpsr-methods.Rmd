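---
title: "Methods: sparse spiking network training with bpsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse spiking network training with bpsr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpsr)
```

This vignette documents the model implemented by `bpsr`, the tunable
parameters and their defaults, the numerical design decisions, what the
synthetic tasks emulate, and the known limitations. It states no empirical
result beyond what the package's test suite and `scripts/acceptance.R`
themselves compute.

## Neuron model and forward dynamics

A layer holds `N` heterogeneous leaky integrate-and-fire neurons updated
synchronously in discrete time from the initial state `u⁰ = s⁰ = 0`:

$$u_i^t = u_i^{t-1}\,\tau_i\,(1 - s_i^{t-1}) + \sum_j w_{ij} x_j^t +
  \sum_k w_{ik} s_k^{t-1} + b_i, \qquad s_i^t = [u_i^t \ge U_{th}]$$

Design points worth making explicit:

* **Reset semantics.** A spike at `t−1` multiplicatively gates the leak
  term to zero — reset to the rest potential 0, not reset by subtraction.
* **Threshold comparison is `>=`**, so a potential exactly at threshold
  spikes.
* **Recurrent input uses `s^{t−1}`**, never the same-step spikes; all
  neurons of a layer update from the `t−1` state simultaneously.
* **Self-synapses are off by default** (the diagonal of the intra-layer
  weight matrix is masked): the bias already provides self-excitation or
  self-suppression. `self_synapse = TRUE` restores them.
* **Heterogeneous leaks.** Each neuron's `τ_i ∈ [0,1]` is learnable,
  which is what lets a recurrent layer act as a bank of temporal filters;
  `tau_shared = TRUE` instead sums the `τ` gradient across the layer and
  keeps one shared value.
* **Event-driven accumulation.** `lif_step` adds synaptic weight columns
  only for channels that spiked, in channel order. Besides mirroring
  spike-driven hardware, this keeps the forward pass bit-reproducible:
  its result does not depend on the vector width or the BLAS in use, and
  the test suite checks it bit-for-bit against an independent scalar
  simulator. The batched training path uses matrix products and agrees
  with the per-sample path to numerical tolerance rather than bitwise.

Potentials are protected by the parameter clamp (below): upward
excursions are capped by the spike reset at one step above threshold,
while downward drift is only bounded through the leak — a layer driven
with strongly negative input and `τ` near 1 can accumulate a potential of
magnitude `drive/(1−τ)`.

## Surrogate gradient and the O(T) backward recursion

The Heaviside derivative is replaced in the backward pass by the
unit-mass Gaussian

$$g'(x) = \frac{\alpha}{\sqrt{\pi}} e^{-\alpha^2 x^2},$$

with `alpha = 0.7` by default. Two conventions coexist in the literature
for the normalization (`α/√π` versus `α/π`); the package uses `α/√π`
because the surrogate then integrates to exactly 1, i.e. it is a proper
Dirac approximation (the constant is an argument, so the other convention
is one edit away). The constant only rescales gradients uniformly.

The loss gradient with respect to potentials is computed by a single
backward sweep per layer: at `t = T`, `d_u = d_s·g'(u−U_th)`; at `t < T`
the next step's potential gradient flows back through the leak gate
`τ(1−s^t)`, and in recurrent layers the bracket additionally collects
`W_rec' d_u^{t+1}`. Two deliberate exclusions:

* The gating dependency of `u^t` on `s^{t-1}` is **not** differentiated:
  the previous spike only gates information flow, it contributes none
  itself. The full-unroll oracle used in the tests shares this
  convention.
* The output-layer spike gradient is `p − y` exactly. The exact chain
  rule through the `k = 10/T`-scaled readout would carry an extra factor
  `k`; this is a positive constant rescaling of the whole gradient,
  absorbed by the learning rate, and the plain `p − y` form is used.

Parameter gradients accumulate over the window (`sign(0) = 0`, so pruned
weights feel no l1 push), and gradients of masked synapses are zeroed
after the rewiring momentum has seen them. There is no gradient clipping;
instead the *parameters* are clamped after every update: weights and
biases to `[−U_th, U_th]` (potential changes far beyond threshold are
meaningless), leaks to `[0, 1]`.

A note on the loss landscape: the readout depends on parameters only
through spike counts, so the loss is piecewise constant — a gradient step
that flips no spike leaves it exactly unchanged. Descent is therefore a
property of short runs of surrogate-gradient steps, not of a single
infinitesimal step, and that is how the test suite asserts it.

## Loss, regularization, and batch reduction

$$L = -\textstyle\sum_c y_c \log p_c + \frac{\lambda_s}{2}
  \sum_{\text{hidden}} \|s\|_2^2 + \lambda_w \sum_{\text{layers}} \|w\|_1$$

The spiking penalty covers every layer except the readout (protecting
classification accuracy); since spikes are boolean, it equals
`λ_s/2 ×` hidden spike count. The synaptic penalty covers all inter- and
intra-layer weights. Cross-entropy and the spiking penalty are averaged
over the mini-batch; the weight penalty, which does not depend on data,
enters once per batch.

**Decoupled l1 application.** The l1 term is applied in the optimizer as
`lr·λ_w·sign(w)`, outside Adam's moment normalization (for SGD this is
identical to folding it into the gradient). Folding a constant-sign
`λ_w·sign(w)` into Adam instead renormalizes it to a full-learning-rate
decay on every weight whose data gradient is smaller than `λ_w`, which at
the default `λ_w = 10⁻²` is the majority — the network's weights then
collapse to zero faster than learning can counteract. Decoupling keeps
the intended gentle, constant-rate decay that the rewiring mechanism
assumes, analogous to AdamW's treatment of l2 weight decay. The gradient
*reported* by `parameter_grads` and fed to the rewiring momentum still
contains the `λ_w·sign(w)` term.

Defaults (changeable per fit): `U_th = 1`, `α = 0.7`, `lr = 10⁻²`,
AdamW, batch 32, `λ_s = 10⁻⁷`, `λ_w = 10⁻²` when rewiring is enabled and
0 otherwise, `τ` initialized at 0.5. Weights initialize from N(0, 1)
clamped to the threshold range, biases from U(0, 1), coordinates uniform
in the unit cube. The N(0, 1) initialization deliberately starts the
network in a high-firing regime; training then *reduces* the firing rate
as it learns, and the spiking penalty accentuates that.

## Rewiring

Every `interval` update steps (default: every step), per layer:

1. **Prune**: existing synapses with `|w| < Θ_w` (default `10⁻²`,
   strict inequality) are removed — mask cleared, weight zeroed.
2. **Grow**: absent synapses whose gradient momentum satisfies
   `|m| > Θ_m (1 + μ_m · d^{p})` are created at weight exactly 0, where
   `d` is the Euclidean distance between the two neurons' coordinates
   (`Θ_m = 10⁻⁴`, `μ_m = 5`, exponent `p = 1` by default, `p = 0.5`
   selectable — either choice preserves the "longer range costs more"
   semantics).
3. The mask is superimposed on weights and gradients; the optimizer then
   updates, and the mask is re-applied so that optimizer momentum cannot
   revive a pruned synapse.

The momentum is the standard exponential moving average
`m ← β_m m + (1−β_m)∇w` (`β_m = 0.99`). A literal accumulation variant
`m ← m + (1−β_m)∇w` is available behind `ema = FALSE` for comparison; it
is unbounded under a constant gradient and is not the default. Momentum
keeps tracking masked positions (their data gradients are still defined),
which is what allows regrowth; it is not reset when a synapse grows.
Growth candidates default to every absent position, including never-wired
ones (`grow_candidates = "pruned_only"` restricts to previously existing
positions). Pruning acts on existing and growth on absent synapses, so
the two sets are disjoint by construction, and full disconnection of a
layer is legal (the fit records it in the rewiring log).

## Spike encoders

* **Rate**: channel intensity in [0, 1] is a per-step Bernoulli spike
  probability; seeded and bit-reproducible.
* **Rank order**: at most one spike per channel, larger values earlier,
  via the linear latency map `t(v) = round((1 − v/v_max)(T−1)) + 1`;
  `v = 0` stays silent. Ties share a timestep; a strict-rank variant
  (unique times, index tiebreak) is available. The map is the standard
  linear realization of rank-order coding; its quantization onto the T
  grid and tie handling are package decisions, documented here because
  no canonical convention exists.
* **Level crossing**: bipolar UP/DOWN spikes when the signal crosses
  absolute amplitude boundaries `k·δ`. Absolute levels (rather than
  relative to the last sample) avoid drift, so the running spike count
  reconstructs the signal to within `δ` wherever no bin holds two
  same-sign crossings. Samples map onto the T-step window by uniform
  binning with OR-reduction, which can merge same-sign crossings if the
  sampling is coarse relative to the slope.

## Quantization and energy accounting

Post-training quantization rounds weights and biases to
`n`-bit fixed point (1 sign bit, `n−1` fraction bits, round-half-to-even,
saturation at `±(1 − 2^{-(n-1)})`) and leaks to powers of two
(`τ ≈ 2^{-m}`, `τ = 0` maps to an immediate-reset sentinel), so inference
needs only fixed-point adds and bit shifts. Weights stored at exactly the
clamp boundary `|w| = 1` are not representable and saturate with a
full-step error `2^{-(n-1)}`; `quantization_error` reports the
non-saturated maximum separately. Quantized inference accumulates in
doubles, which is exact for these grids (wide fixed-point accumulation,
no intermediate rounding). Rounding `τ` to a power of two is a large
perturbation when `τ` is far from the grid — spike trains may change for
that reason alone, which is legitimate PTQ behaviour, not a numerical
defect.

Energy is counted event-wise: one accumulate per spike per existing
outgoing synapse (recurrent spikes at the final step are never consumed
and are not counted), one bias add and one leak multiply per
neuron-timestep, converted with the normalized cost model FL-ADD 1,
FL-MUL 4, FI-ADD 0.2, BIT-OP 0.

## Motif significance profiles

The learned graph (existing synapses of selected layers) is summarized by
the census of the 13 connected directed 3-node motifs, counted as induced
subgraph classes over all node triples (the package enumerates triples
against a canonicalized 64-code lookup; the test suite cross-checks
against an independent 16-class census implementation). Z-scores against
a degree-preserving edge-swap ensemble (default 100 samples, 10×edges
swaps each) are scaled to unit Euclidean norm. Motif classes with zero
ensemble variance get `z = 0` — keeping the profile finite and
comparable; an all-zero profile is signalled as an error rather than
returned. Reference graphs (e.g. connectomes) load from two-column edge
lists via `read_edgelist`.

## Synthetic tasks: what they emulate, and what they do not

`make_synthetic_task` generates the three study conditions used
throughout the tests (defaults: 2 classes, T = 20, 400 train / 200 test):

* `rate_clusters` (20 channels): per-class intensity templates drawn
  uniformly, Gaussian noise (sd 0.1), rate-encoded. Information lives in
  spike counts — a stand-in for rate-coded image classification.
* `temporal_order` (20 channels): class-specific channel orderings of an
  evenly spaced intensity ladder (ascending vs descending for two
  classes), 5% multiplicative jitter, rank-order encoded against a fixed
  scale. Every channel fires exactly once, so spike counts are identical
  across classes and *only timing* is informative; `collapse_time`
  produces the matched T = 1 ablation, which is at chance by
  construction. Solving the intact task requires the temporal credit
  assignment of the backward recursion.
* `lc_waveforms` (2 signal → 4 spike channels): class-specific
  quasi-periodic waveforms (distinct fundamental frequency and harmonic
  mix, random phase, amplitude jitter, additive noise), level-crossing
  encoded with δ = 0.1 — emulating multichannel biosignals such as ECG.

The noise level, jitter and waveform family were chosen once as
representative of clearly separable laboratory-scale problems. Passing
these tasks demonstrates that the machinery works — temporal information
is actually used, sparsity penalties actually bite, rewiring preserves
what matters. It does not demonstrate performance on real, long-tailed,
high-dimensional data: the tasks are low-dimensional, class-balanced and
noise-limited rather than structure-limited.

## Problem sizes and runtimes

The test-suite and acceptance runs use the "r20-fc10-fc2" architecture on
the task sizes above: 50 epochs for plain fits, a {0, 10⁻⁷, 10⁻⁶, 10⁻⁵}
spiking-regularization sweep with five common-seeded replicates per
level, and a 600-epoch rewiring run on the waveform task (the synaptic
decay proceeds at `lr·λ_w = 10⁻⁴` per step, so halving the synapse count
takes a few thousand updates). Common random numbers across the sweep —
identical initialization, data and batch order per seed — isolate the
effect of `λ_s` from run-to-run noise. All runs are single-CPU, minutes
in total.

## Known limitations

* No convolutional, pooling or residual layers; no weight sharing beyond
  the optional shared leak.
* Synchronous discrete time only — no event-driven (asynchronous)
  simulation and no continuous-time LIF.
* The divergence detector (non-finite loss aborts; firing rate ≥ 0.99
  sustained for three epochs flags the fit) identifies runaway regimes,
  e.g. an inappropriately high threshold, but does not attempt recovery.
* Rank-order encoding assumes non-negative intensities; signed signals
  should use level-crossing encoding.
* The triad census enumerates all `C(n,3)` node triples; it is intended
  for network graphs up to a few hundred nodes, not for large connectome
  meshes.
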