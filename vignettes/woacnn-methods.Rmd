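---
title: "Whale-optimized CNN training for skin lesion detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whale-optimized CNN training for skin lesion detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woacnn)
```

## The problem

Early melanoma detection from dermoscopy images is a two-class decision —
healthy skin versus a cancerous lesion — plus, for clinical use, a per-pixel
delineation of the lesion region. Convolutional neural networks handle both
tasks well, but gradient-descent training (backpropagation) can stall in
local minima of the cross-entropy surface. This package trains the CNN with
the *whale optimization algorithm* (WOA), a population metaheuristic, either
directly on the network's weights and biases or on its integer
hyperparameters, and turns the resulting two-class patch classifier into a
binary lesion mask by a sliding-window sweep.

## The whale optimization algorithm

WOA maintains a swarm of candidate solutions ("search agents"). Writing
$X^{*}$ for the best solution found so far, each agent $X$ moves at every
generation by one of three rules:

* **Encircling** (exploitation): $D' = |C \circ X^{*} - X|$,
  $X \leftarrow X^{*} - A \circ D'$, with $A = 2ar - a$ and $C = 2r'$,
  $r, r' \sim \mathrm{Uniform}(0,1)$ drawn per component.
* **Spiral bubble-net attack**: $D' = |X^{*} - X|$,
  $X \leftarrow D' \, e^{bl} \cos(2\pi l) + X^{*}$, where $b > 0$ fixes the
  logarithmic spiral's shape and $l \sim \mathrm{Uniform}(-1,1)$.
* **Exploration**: the encircling move aimed at a *random* agent
  $X_{\mathrm{rand}}$ instead of $X^{*}$, used when $|A| \ge 1$.

The scalar $a$ decays linearly from 2 to 0 over the run
(`woa_decay(t, t_max) = 2(1 - t/t_max)`), so the swarm explores early and
exploits late. Each agent flips a fair coin between the spiral move and the
$A$-dependent encircle/explore pair. The implementation is elitist: $X^{*}$
is the best-ever evaluated position, which makes the best-fitness history
monotone non-increasing by construction.

Several details of this scheme are genuinely open; the package fixes them as
follows and treats them as part of its definition:

* the spiral's cosine argument is the random $l$, not the iteration counter —
  a deterministic spiral would leave $l$ unused and make every agent's
  bubble-net move identical within a generation;
* the exploration switch tests $|A|$ per agent, on the first component of
  the freshly drawn $A$ vector; $p$, $l$, $A$, $C$ are redrawn per agent per
  generation;
* positions leaving the search box are clamped to the bounds;
* ties in best-fitness selection keep the incumbent;
* $b = 1$ by default;
* all randomness flows from a single seeded generator, so identical seeds
  give bit-identical runs.

## The network and its losses

The CNN is deliberately minimal: valid (unpadded) cross-correlation
convolutions with stride 1, ReLU activations, non-overlapping max pooling
(window at least 2; trailing rows/columns that do not fill a window are
dropped), flattening, dense layers, and a terminal softmax
$z_j = e^{f_j} / \sum_i e^{f_i}$ (computed with max-subtraction). Training
minimises the penalised cross-entropy

$$L = \sum_{j=1}^{N} \sum_{i=1}^{M} -d_j(i)\, \log z_j(i)
      \;+\; \tfrac{\gamma}{2} \sum_{k,l} W_{k,l}^2,$$

with $N$ samples, $M$ classes, one-hot targets $d$, and the penalty running
over every connection weight of every layer (biases are not penalised);
$\gamma = 0$ recovers the plain cross-entropy. The alternative fitness is the
per-sample mean squared error
$E = \tfrac{1}{T} \sum_{i=1}^{T} \sum_{j=1}^{k} (d_{ji} - o_{ji})^2$.
Logarithms are natural throughout; a predicted probability of zero at the
target class is clipped to the machine epsilon rather than letting the loss
diverge.

The backpropagation baseline computes analytic gradients (verified against
central finite differences in the test suite at $10^{-5}$ relative error)
and takes full-batch descent steps. Two numerical choices matter here:

* the step is the stated learning rate times the *per-sample* gradient
  (i.e. the summed-loss gradient divided by $T$) — a rate like the default
  0.9 is only meaningful on that scale, since the summed gradient grows
  linearly with the batch;
* a step that would increase the loss is retried with a halved step length
  (resetting after every accepted step), so the final training loss provably
  never exceeds the initial one.

## Coupling the WOA to the CNN

**Weight mode** (the default). All weights and biases are flattened —
layer-major, weights before biases, arrays in column-major order — into one
position vector, so a whole network is a single search agent; the codec is an
exact bijection. The swarm of such vectors is searched in a box
$[-h, +h]^{P}$ (default $h = 1$) and scored by the training-view loss above;
no gradients, and hence no backward pass, are ever computed in this mode.
Fitness is evaluated on the training split only; the validation split is
reserved for model selection, the test split for reporting. The im2col patch
matrix of the first convolution depends only on the images, so it is built
once per problem and reused by every fitness evaluation.

**Hyperparameter mode.** An agent is 10 integers, each at least 2 (the
smallest legal pooling window): two kernel sizes, two kernel counts, two
pooling windows, a hidden dense-width multiplier, and three reserved genes.
The WOA runs on the continuous relaxation; positions are decoded by
round-then-clamp (idempotent on integer genes). Each decoded architecture is
trained briefly by backpropagation and scored by its validation *error rate*
(1 − accuracy) — used as the selection cost because plain error is the
quantity the validation split can estimate directly. Architectures whose
kernels or windows outgrow the running feature map receive an effectively
infinite penalty, so they can never be returned while any valid architecture
exists; the fitness of a gene vector is deterministic (the inner weight
initialisation is seeded from the trainer config), and evaluations are
memoized. The best architecture is refitted with a full backpropagation run.

**Split protocol.** Datasets are partitioned 70/10/20
(train/validation/test) by a seeded random permutation; validation and test
sizes are floors of their ratios with the remainder assigned to training, so
100 samples split exactly 70/10/20.

## From classifier to mask

A full image is swept by patches of the network's input size (default stride:
half a patch). Each patch's lesion-class probability is accumulated over the
patch's footprint and overlaps are averaged; pixels beyond the last scored
footprint (when the stride does not tile the image exactly) copy the nearest
covered row/column. The binary mask is exactly the probability map
thresholded at 0.5 (configurable), so raising the threshold can only shrink
the flagged region. A per-pixel classifier was considered and rejected: a
single RGB pixel cannot feed a convolutional stack, so patch classification
with footprint broadcasting is the consistent reading of per-pixel output.

## Performance metrics

From the confusion counts over held-out images: sensitivity
$tp/(tp+fn)$, specificity $tn/(tn+fp)$, PPV $tp/(tp+fp)$, NPV $tn/(tn+fn)$,
accuracy $(tp+tn)/n$. A zero denominator yields `NA` rather than an error.
Reports render the five metrics in that order, rounded to two decimals.

## The synthetic data generator

Real dermoscopy archives cannot ship with a package, so the generator
emulates their two-class structure: a warm skin-tone background
(RGB ≈ (0.87, 0.72, 0.60), jittered per image) with Gaussian texture noise,
and — for positives — a darker, brown-tinted ellipse whose outline is
perturbed by a few smooth random harmonics, placed fully inside the frame,
with the ground-truth mask marking exactly its pixels. Defaults: 16×16
images (small enough that the default architecture's 506 parameters remain a
tractable WOA search space; a larger size is used only for mask demos),
semi-axes 0.15–0.3 of the image side, darkening offset 0.5, boundary
irregularity 0.3, noise SD 0.05, balanced classes. These defaults define the
package's "easy benchmark": the lesion/background contrast (0.5) is ten
noise standard deviations, so the labels are recoverable from the pixels —
which the test suite verifies by training to ≥ 90–95 % test accuracy.

What the generator does *not* emulate: hair, rulers, air bubbles, vignetting,
multi-lesion images, colour variation across skin types, or class overlap.
Passing tests therefore show that the optimizer and network behave correctly
and can extract a strong, genuinely present signal — not that the method
reaches any particular accuracy on clinical images.

## Problem sizes and run settings

The package's benchmark conditions, used by the test suite and the
acceptance script, are desk-scale by design: 200 images of 16×16, the
default conv(3,4)/pool(2)/dense(2) architecture, WOA population 30 with 150
generations (seed 42 as the fixed benchmark seed), sphere benchmarks in 5
dimensions with 500 generations, and a 64×64 image for mask recovery. The
command-line tool's `--paper-scale` preset switches to population 150, 1500
inner BP iterations and 30 000 WOA generations for full-scale experiments.

## Known limitations

* WOA weight training scales poorly with parameter count; beyond a few
  thousand parameters the swarm degenerates to local search around its best
  member.
* The mask stage inherits the patch grid's resolution; lesion borders are
  blocky at large strides, and no morphological post-processing is applied.
* The hyperparameter gene mapping is one fixed convention (two conv blocks
  plus one hidden dense layer); the reserved genes allow extensions without
  changing the agent width.
* Dataset PNG round trips quantise pixels to 8 bits; in-memory pipelines are
  exact.
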