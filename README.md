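# bpsr: sparsity-regularized backpropagation for spiking neural networks

Spiking neural networks (SNNs) exchange information through binary spikes
and only compute when a spike arrives, which makes them attractive for
low-power inference — but only if both the **spikes** and the **synapses**
are actually sparse. `bpsr` is an R package for training and analysing such
sparse spiking classifiers. It is aimed at researchers in computational
neuroscience and neuromorphic engineering who want a self-contained,
inspectable implementation of surrogate-gradient training with explicit
sparsity control: no deep-learning framework, plain matrices, every
gradient recursion written out.

## The model

Each layer is a population of heterogeneous leaky integrate-and-fire (LIF)
neurons in discrete time. For neuron *i* of a layer receiving input spikes
`x_j^t` and (for recurrent layers) intra-layer spikes `s_k^{t-1}`:

    u_i^t = u_i^{t-1} · τ_i · (1 − s_i^{t-1}) + Σ_j w_ij x_j^t + Σ_k w_ik s_k^{t-1} + b_i
    s_i^t = H(u_i^t − U_th)

A spike at `t−1` gates the leak term to zero (reset to rest), `τ_i ∈ [0,1]`
is a per-neuron learnable leak, and `H` is the Heaviside step with
threshold `U_th = 1`. The readout sums output spikes over the window,
scales by `k = 10/T` and applies softmax. Training minimizes

    L = cross-entropy + (λ_s/2) Σ_hidden ‖s‖² + λ_w Σ ‖w‖₁

where the `λ_s` term penalizes the hidden firing rate and the `λ_w` term
drives synaptic weights toward zero. Because the Heaviside derivative is a
Dirac impulse, the backward pass substitutes the unit-mass Gaussian
surrogate `g'(x) = (α/√π)·exp(−α²x²)` (α = 0.7) and runs an O(T) backward
recursion per layer — no unrolled graph is materialized. Gradients flow
through the leak chain and, in recurrent layers, through the transposed
intra-layer weights from the next timestep.

On top of gradient training the package provides:

* **Synaptic rewiring** — every existing synapse with `|w| < Θ_w` is
  pruned; an absent synapse grows back when the exponential moving average
  *m* of its weight gradient satisfies `|m| > Θ_m (1 + μ_m‖c_i − c_j‖₂)`,
  so long-range connections (neurons carry coordinates in the unit cube)
  need a stronger trend. Grown synapses re-enter at weight 0.
* **Spike encoders** — Bernoulli rate coding, rank-order (intensity →
  latency) coding, and bipolar level-crossing sampling for continuous
  multichannel signals (2 signal channels → 4 spike channels).
* **Post-training quantization** — weights/biases to n-bit fixed point
  (1 sign bit, n−1 fraction bits), leaks to powers of two so the leak
  multiply becomes a bit shift, plus event-driven operation counting and a
  normalized energy model (FL-ADD 1, FL-MUL 4, FI-ADD 0.2, BIT-OP ≈ 0).
* **Motif analysis** — 13-class connected directed triad census, a
  degree-preserving edge-swap null model, and unit-norm significance
  profiles for comparing a learned topology against reference graphs such
  as connectome edge lists.

## Worked example

```r
library(bpsr)

# a seeded synthetic task: 2 intensity templates on 20 channels,
# Bernoulli rate-encoded over T = 20 steps, 400 train / 200 test samples
task <- make_synthetic_task("rate_clusters", seed = 42)

fit <- bpsr(task, arch = "r20-fc10-fc2", epochs = 20, seed = 42)
print(fit)
#> Sparse spiking network classifier (LIF, surrogate-gradient BPTT)
#>   architecture: r20-fc10-fc2   T = 20   classes: 1, 2
#>   epochs: 20   final loss 0.0003   train accuracy 1.000
#>   validation accuracy 1.000
#>   firing rate 0.360   synapses 1000/1000
```

The architecture string is the field's compact notation: a 20-neuron
recurrent layer, a 10-neuron fully connected layer, a 2-class readout.
The fit reaches 100% held-out accuracy while the mean firing rate drops
from its post-initialization level to 0.36 spikes per neuron per timestep
— training itself is a firing-rate-reduction process, and `λ_s` pushes it
further down at no accuracy cost.

```r
summary(fit)            # per-layer synapse counts, densities, mean leaks
predict(fit, task$x_test[, , 1:8])
#> [1] 1 2 1 2 1 2 1 2
evaluate_network(fit, task$x_test, task$y_test)
#> $accuracy 1   $fr 0.361   $fr_hidden 0.354
#> $synapse_count 1000   $spikes_per_sample 231   $energy 11522
```

`evaluate_network` reports the event-driven energy of an average
inference (normalized to floating-point adds); after
`quantize_network(fit, n_bits = 8)` the same inference runs on fixed-point
adds and bit shifts at roughly 16% of the float energy with no accuracy
loss. `plot(fit)` shows the loss, accuracy, firing-rate and synapse-count
trajectories; `coef`, `residuals` and `simulate` behave as for any fitted
R model.

Enable structural plasticity with `rewire = TRUE` (defaults `Θ_w = 1e-2`,
`Θ_m = 1e-4`, `μ_m = 5`, `β_m = 0.99`, `λ_w = 1e-2`): on the level-crossing
waveform task a 600-epoch run prunes over half of all synapses with no
loss in accuracy, and `significance_profile(network_to_graph(fit))`
summarizes the learned wiring as a motif z-score profile comparable to
biological connectivity graphs.

## Scope

Flat (fully connected) and recurrent layers only — no convolutional or
residual layers, no event-camera ingestion, no GPU path. The methods
vignette (`vignettes/bpsr-methods.Rmd`) documents the model assumptions,
the numerical design choices and the limits of what the synthetic tasks
can show.
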