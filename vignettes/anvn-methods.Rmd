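---
title: "Artificial neurovascular networks: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artificial neurovascular networks: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(anvn)
```

## The model

An artificial neurovascular network couples two structures:

* a **perceptron** with one hidden layer of `N` neurons, logistic
  activations, and the quadratic cost `C = ½ Σ ‖d − y‖²`;
* a **vascular tree**: a k-ary tree whose root receives energy `E_s` and
  whose `N` leaves deliver energy to the hidden neurons one-to-one.

Each branch weight is the fraction of the parent's energy routed down
that branch; sibling weights are absolute-normalized to sum to one, so
energy is conserved exactly at every junction and `Σ_j E_j = E_s`. The
input-to-hidden weight rows of the perceptron are normalized the same
way, which bounds every hidden net input to `|W x − b| ≤ 1 + max|b|`.

Energy acts on the network solely through the **bias-energy law**
`b = 1 − E` on `0 ≤ E ≤ 2`, saturating at `−1` beyond 2 units: energy
lowers the firing threshold, and 2 units buy the lowest threshold a
neuron can have. The coupling runs both ways: during backpropagation the
hidden-bias gradient is converted to an energy-demand gradient
(`ΔE_j = η δ_j^f` on the linear branch, 0 above it, since the law's
slope is −1 there and 0 beyond), each internal node takes the *mean* of
its children's gradients, every branch weight moves by `η_v` times the
gradient of the node it feeds, and sibling groups are renormalized.
Weights are clamped at zero before renormalization so energies stay
nonnegative; a sibling group driven entirely to zero is an error, not a
silent repair, because the model gives no rule for reviving a dead
subtree.

Four training regimes are provided:

1. **untrained** (`run_untrained()`): a perceptron trained with free
   biases is evaluated under an equal split `E_s / N`;
2. **sequential** (`run_sequential()`): the perceptron is frozen and
   only the tree learns, driven by the gap between trained and
   energy-derived biases, `ΔE = η (b^E − b^T)` on the linear branch;
3. **simultaneous** (`run_simultaneous()`): both learn each epoch;
4. **reservoir** (`run_reservoir()`, the ANVN_R): a constant 5000-unit
   source feeds the tree root through a trainable weight `U_0` and a
   reservoir through `1 − U_0`; leaves holding more than 2 units return
   energy at a fixed slope `γ = 0.005`, and the root-level gradient
   also trains `U_0`, so the network draws only what it demands.
   Leaf energy plus reservoir energy equals 5000 at all times.

## Tunable parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `N`, `k` | — | `k ≥ 2`, `k ≤ N` | leaves = hidden neurons; branching factor |
| `E_s` | — | energy units | root supply (plain ANVN) |
| `per_capita0` | — | 0.2–1 probed | initial mean leaf energy (ANVN_R) |
| `eta` (η) | 0.05 | — | neural learning rate |
| `eta_v` (η_v) | 0.5 | — | vascular learning rate |
| `gamma` (γ) | 0.005 | — | excess-return slope (ANVN_R) |
| `slope1` / `slope2` | 5 / 1 | — | hidden / output logistic steepness |
| `lambda_w`, `lambda_E` | 0 | — | L2 weight / L1 energy penalties |
| `source_energy` | 5000 | units | ANVN_R source |
| `noise_sd` | 1.0 | feature units | generator noise |

Updates are full-batch: gradients are averaged over the training set and
applied once per epoch, the natural reading of a per-epoch update rule
(the internal-node rule is itself an average). Output-layer biases are
ordinary trainable parameters; only hidden biases are energy-coupled.
Input-weight rows are renormalized after every update, mirroring the
vascular normalization (a flag disables this for ablation studies).

## Why the hidden activation is steep

With row-normalized input weights and features in `[0, 1]`, the hidden
net input lives in roughly `[−1.5, 1.5]`. A unit-slope logistic is
nearly linear there, and a near-linear hidden layer lets the trainable
output layer compensate *any* bias shift — accuracy would then be
independent of energy, and no accuracy–energy trade-off could exist in
the model at all. For the bias to act as a genuine firing threshold, the
activation must be sharp on the scale of the bias range `[−1, 1]`. The
package therefore uses a slope-5 hidden logistic (transition width
≈ 0.8, well inside the threshold range) in the training regimes, keeping
the standard unit-slope logistic as the low-level default
(`init_mlp()`) and for the output layer. With this choice an
energy-starved network is genuinely impaired (near-chance accuracy at a
few hundredths of a unit per neuron) and a well-fed one is not, which is
the regime in which all of the package's phenomena live. At slope 5 a
learning rate of 0.1 destabilizes full-batch training; `eta = 0.05` is
the default.

Two scale notes. First, the probed root energies should keep per-capita
energy at or below ~1: beyond 2 units per neuron every bias saturates at
−1 and a steep activation pins the hidden layer, so accuracy degrades —
the reservoir variant exists precisely to shed such excess. Second,
`eta_v = 0.5` is chosen so that vascular allocation reaches steady state
within the scaled-down schedules used here (≈ 2000 epochs); the energy
gradients already carry the factor η, so the effective vascular step per
unit bias-gap is `η_v · η ≈ 0.025`. The sequential regime's demand
gradient includes the same η factor for exactly this commensurability.

## The synthetic data generator

`make_synthetic()` draws one uniform prototype per class in
`[0,1]^784` and forms samples as prototype + Gaussian noise
(`noise_sd = 1.0`), clipped to `[0,1]`, 500 training and 200 test
points, ten classes. The noise level is calibrated so that a
small-sample perceptron lands in the mid-80s/90s accuracy range typical
of flat-vector digit benchmarks while a nearest-prototype classifier
still exceeds 95% — i.e., the task is hard for a capacity- and
energy-limited network but not intrinsically ambiguous.
`make_transfer_variant()` mixes the prototypes 50/50 with a fresh draw,
emulating retraining on a similar-but-different dataset.

What the generator does **not** emulate: the low effective
dimensionality, pixel sparsity, and within-class style variation of real
handwritten digits. Samples are isotropic around a single prototype, so
class structure is unimodal and every feature is equally informative.
Passing tests therefore show that the energy-allocation machinery
behaves as designed under controlled conditions; they do not certify
quantitative accuracy values on real image data, and the published
figures obtained on real digit datasets are reproduced here only as
qualitative orderings.

## Numerical choices and degenerate inputs

* Tree arithmetic is exact-integer (ceil-log by repeated
  multiplication), avoiding floating-point `ceiling(log/log)` artifacts
  at exact powers of `k`.
* When `N` is not a power of `k`, each level's first `⌊c/k⌋` parents
  take `k` children and the remainder attaches to the last parent in
  breadth-first order; nodes are numbered breadth-first with the root
  at 1 and leaf `j` feeding neuron `j`.
* `N = 1` yields a single node that is both root and leaf (`L = 1`).
* Argmax ties in classification break toward the lowest class index.
* Pearson correlations with a zero-variance input raise an explicit
  error rather than returning `NA` or 0 (an EECC of 0 means something;
  an undefined one must not masquerade as it).
* The ablation error (`ablate_and_score()`) implements the printed
  mean-squared form without a root; `rooted = TRUE` gives the literally
  rooted variant. Likewise the per-level transfer drift is a plain sum
  of squared weight differences per originating level (root = level 1);
  the source→root edge of a reservoir model is reported separately.
* Checkpoints (topology, weights, energies, biases) serialize to JSON
  with 17 significant digits, which round-trips doubles exactly.
* With the L1 energy penalty active, the penalty term of the update is
  applied wherever the cost carries it, so analytic updates match
  finite differences of the penalized cost on both branches of the
  bias-energy law.

## Problem sizes used in the shipped analyses

The test-suite and `scripts/acceptance.R` run every experiment at sizes
a single CPU handles in minutes, chosen as the smallest scales at which
each phenomenon is stably expressed: regime comparison at `N = 32`,
`k = 4`, 2000 epochs, five seeds, root energies `{1, 8, 16, 32}`
(per-capita 0.03–1, matching the probed per-capita range of the
reference setting); the deficit sweep on the same network over
`E_s ∈ {2, …, 32}`; attractor spreads at `N = 24` vs `N = 128` from
initial per-capita energies `{0.2, 0.6, 1.0}` (steady state = mean of
the final 5% of epochs); transfer drift on a 4-level tree (`N = 27`,
`k = 3`); and the EECC contrast at `N = 16` vs `N = 128` after 1000
epochs. Stochastic conclusions are reported as seed-averages or
majority votes across seeds.

## Known limitations

* One hidden layer only; the model says nothing about depth.
* Plain gradient steps; no momentum or adaptive optimizers, by design.
* The vascular tree is purely combinatorial — no geometry, no flow
  dynamics, no delays.
* The sequential regime needs no data once the target biases are known;
  its trace therefore evaluates accuracy only when a dataset is passed.
* Very small energy budgets with aggressive vascular rates can drive a
  sibling group to zero; the package stops with a degenerate-weights
  error rather than renormalizing an all-zero group.
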