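---
title: "Quantum-inspired feature-map fusion: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-inspired feature-map fusion: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qfuse)
```

## The model

`qfuse` implements a hybrid classifier for multi-class medical image
classification built around a *quantum-inspired feature map* (QFM). Two frozen
backbone networks produce embeddings $z_A \in \mathbb{R}^{d_A}$ and
$z_B \in \mathbb{R}^{d_B}$ for each image. The model then proceeds in four
stages.

**Hadamard interaction.** Both embeddings are truncated to the common
dimension $d_H = \min(d_A, d_B)$ (first $d_H$ components, no learned
projection) and multiplied elementwise:
$z_H = \hat z_A \odot \hat z_B$. This multiplicative token carries
*joint* statistics of the two views that neither embedding carries alone.

**Quantum feature map.** Each of the three vectors $z \in \{z_A, z_B, z_H\}$
is mapped through its own parameter set:

$$\theta = W z + b \in \mathbb{R}^P, \qquad c = \cos\theta, \quad s = \sin\theta,$$
$$h_1 = U^\top \cos\theta \in \mathbb{R}^r, \qquad h_2 = \sin(V^\top z) \in \mathbb{R}^r,
\qquad h = h_1 \odot h_2,$$
$$f = W_0\,[c;\, s;\, h] + b_0 \in \mathbb{R}^P, \qquad
\psi = \frac{f}{\lVert f \rVert_2 + \varepsilon}.$$

The phase projection plus trigonometric embedding gives a periodic,
bounded representation; the rank-$r$ term $h$ injects multiplicative
cross-structure at low parameter cost; the final scaling keeps
$\lVert\psi\rVert_2 = \lVert f\rVert_2 / (\lVert f\rVert_2 + \varepsilon)$
strictly inside the unit sphere, by analogy with unit-norm quantum states.
The norm is monotone in $\lVert f \rVert_2$ and within $10^{-4}$ of 1 once
$\lVert f\rVert_2 \ge 10^4\,\varepsilon$; both properties are tested.

**Attention fusion.** The three tokens are stacked into
$T = [t_A; t_B; t_H] \in \mathbb{R}^{3\times P}$ and passed through one
multi-head self-attention layer,
$\mathrm{softmax}(Q K^\top / \sqrt{d_k})\,V$ per head with
$d_k = P / h$, heads concatenated and projected by $W^O$. There is no
residual connection and no layer norm — none is part of the design this
package implements, and the choice is deliberate and documented rather than
implicit.

**Classification.** The attended tokens are mean-pooled (a `flatten`
option exists), passed through one hidden layer with ReLU, dropout (inactive
at inference), and a softmax over the $K$ classes. Training minimises average
cross-entropy $L = -\tfrac{1}{N_b}\sum_n \log p_{n,y_n}$.

## Ambiguities resolved in the low-rank term

The defining expressions for $h_1$ and $h_2$ admit two parenthesisations.
This package defaults to reading $h_1$ as the $U$-projection of the
elementwise cosine of $\theta$ (the phase vector is defined first, so
$\cos\theta$ is the natural operand) and $h_2$ as the elementwise sine
*after* projecting $z$ by $V$, honouring the explicit parenthesisation of
$\sin(z^\top V)$. The alternative — trig after projection on both sides —
is available as `h1_reading = "project_then_cos"` in `qfm_params()`; both
readings give length-$r$ vectors and both are covered by the scalar-loop
oracle tests.

Two further choices where the design was genuinely open:

* **Separate QFM parameter sets per branch.** The three QFM modules do not
  share weights: the branch inputs can have different dimensions, and the
  plural "modules" is taken at face value.
* **Token pooling.** Mean over the three attended tokens before the MLP;
  `flatten` (concatenation to $3P$) is the config alternative.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `P` | 256 | phase embedding dimension (token width) |
| `r` | 32 | low-rank interaction dimension |
| `n_heads` | 4 | attention heads; `P` must be divisible by it |
| `hidden_dim` | 256 | MLP hidden width (unstated in the source design; configurable) |
| `dropout_rate` | 0.3 | MLP dropout (unstated; configurable) |
| `eps` | 1e-6 | QFM norm-scaling constant (unstated; must be > 0) |
| `epochs` | 10 | training epochs |
| `batch_size` | 32 | mini-batch size |
| `lr` | 1e-4 | initial learning rate, cosine-annealed per step to 0 |
| `weight_decay` | 1e-2 | decoupled weight decay on weight matrices (not biases) |
| `patience` | 3 | early-stopping patience on validation macro F1 |

Initialisation is variance-scaled uniform for every projection matrix and
zero for biases, under a fixed seed; one global seed hierarchically spawns
per-stage seeds (`spawn_seed()`), so changing one stage's randomness never
perturbs another's.

## Preprocessing protocol

Channel statistics use the *population* divisor $NHW$ and are computed from
**all** data by default, matching the normalization protocol the model was
described with. That protocol leaks test-set pixel moments into
preprocessing; `stats_from = "train"` in the run config computes them from
the training subset instead, and the documentation flags the difference.
A zero-variance channel is divided by $\sigma_c + 10^{-8}$.

Splitting is stratified by default (the rare class is small enough that an
unstratified draw can miss it): the test share is `ceiling(0.20 * n_k)` per
class, and the validation share is 10% of the remaining pool, sized by
round-half-up and apportioned across classes by largest remainder. Under
these rules a 5-class cohort of 3176 images yields a 636-image test set, and
100 samples split 72/8/20. Backbone selection is scored on the validation
split (scoring on test is possible via `eval_on = "test"` but not the
default, to keep selection independent of the final evaluation).

Metric conventions: one-vs-rest precision/recall/F1 per class; macro =
unweighted mean (drives early stopping); weighted = support-weighted mean
(drives model comparison). Support-weighted recall telescopes to
trace/total, i.e. it *is* accuracy — the package computes it that way so the
identity is exact in floating point. A class with zero support or zero
predictions gets metric 0 with a warning. Reports print percentages at two
decimals (round-half-up).

## What the synthetic generator emulates — and what it does not

The reference task is five-way classification of single abdominal CT slices
(normal, simple, localized complicated, advanced complicated, rare). That
dataset is private, so the generator emulates *controllable class structure*,
not anatomy:

* classes differ by grating frequency, bright-blob count, and (in the
  interaction regime) block-wise sign patterns, all scaled by
  `signal_strength`; at `signal_strength = 0` the class-conditional
  distributions are identical by construction;
* `interaction_only = TRUE` produces **two views per image**: view A carries
  a random block-brightness field $g$, view B carries $g$ multiplied by a
  class-specific sign pattern. Each view is marginally class-free (a sign
  flip of a symmetric field is distribution-preserving), while the
  elementwise product of the views has class-dependent mean — precisely the
  regime in which the Hadamard token is the only route to the label. The
  feature-level analogue (`generate_feature_fixture(interaction_only =
  TRUE)`) sets view B to $c \cdot \mathrm{sign}_k \odot g$ plus noise with
  $c = \mathrm{separation}/(1 + \mathrm{separation})$, so separation 0
  removes the signal entirely.

The generator does **not** simulate CT physics, Hounsfield calibration,
anatomical shape, scanner artefacts, or patient-level correlation. Passing
tests therefore demonstrate that the implementation is faithful and that the
architecture can exploit interaction-only signal — they say nothing about
clinical performance on real CT.

## Study sizes and numerical choices

The tests and the acceptance script run two scaled-down studies whose
conditions were fixed once, by pre-build calibration, and are not tuned per
run:

* **Separable study:** 4000 samples (800/class), $d_A = d_B = 16$,
  separation 10, model $P=32, r=8$, 4 heads, hidden 64. Under the standard
  recipe (10 epochs, batch 32, lr $10^{-4}$) validation accuracy exceeds
  95% robustly across seeds; 2000 samples was marginal at this learning
  rate, which is why the study uses 4000 — the same order as the reference
  cohort (3176 images).
* **Interaction study:** 5000 samples (1000/class), $d=16$, separation 10,
  model $P=64, r=16$, 4 heads, hidden 128, same recipe. The fused model's
  test accuracy exceeds the best single-view baseline by 50–65 points
  (single views are at the 20% chance level by construction; a linear probe
  on the elementwise product exceeds 90%).

Numerical guards: cross-entropy clamps the true-class probability at
$10^{-12}$; the QFM norm guard $\varepsilon$ must be strictly positive
(validated); candidate-selection ties break by higher accuracy, then
lexicographic name; gradients of the full composition are verified against
central finite differences at $10^{-4}$ relative tolerance, and every stage
against an independently written scalar-loop oracle at $10^{-6}$.

## Known limitations

* The six published pretrained backbones are represented by tiny
  deterministic stubs (block pooling, gradient pooling, frequency energies,
  pixel subsampling behind fixed seeded projections). The selection
  machinery is still exercised on the published candidate scores, and the
  stub contract (fixed dimension, frozen, deterministic) matches what a real
  backbone plugin must provide.
* Training is single-threaded CPU R; it is meant for desk-scale studies,
  not 224×224×thousands workloads. All heavy linear algebra is BLAS-backed
  matrix code.
* The synthetic block-field signal is deliberately matched to what pooling
  stubs can extract; a backbone that destroys coarse block structure would
  need a different generator regime.
* One attention layer, no residual/layer-norm: at these depths that is
  harmless, but the class imbalance and calibration behaviour of the real
  clinical task are outside what the synthetic studies can show.
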