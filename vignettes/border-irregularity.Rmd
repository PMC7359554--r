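---
title: "Border irregularity with a fuzzy multilayer perceptron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Border irregularity with a fuzzy multilayer perceptron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmlp)
```

Border irregularity — the B of the clinical ABCD rule — is one of the
strongest visual signs of melanoma, and one of the most subjective to judge.
This package implements an objective pipeline: detect the lesion border with
a histogram-driven fuzzy edge filter, summarise its irregularity as a
two-value measure (box-counting fractal dimension, convexity), and classify
lesions as regular or irregular with a fuzzy multilayer perceptron (F-MLP).
This vignette explains the models, the tunable parameters, and the design
choices made where the method description left the design open.

## The F-MLP

The classifier is an ordinary fully-connected feedforward network (reference
architecture 2–4–2–1: two features in, hidden layers of 4 and 2 neurons, one
output probability) with two modifications.

**Type-II fuzzy sigmoid pair.** A type-II fuzzy set can be built from a
type-I membership function $\mu(x)$ by taking the exponent pair
$\mu^\alpha$ and $\mu^{1/\alpha}$, $\alpha \in (1,\infty)$; the band between
them is the footprint of uncertainty. Applied to the logistic sigmoid this
gives the activation pair

$$\varphi_L(x) = \mathrm{sig}(x)^\alpha, \qquad
  \varphi_U(x) = \mathrm{sig}(x)^{1/\alpha},$$

which bracket the ordinary sigmoid for $\alpha > 1$ (a power of a value in
$(0,1)$). Training the same network once with $\varphi_L$ and once with
$\varphi_U$ yields two classifiers whose accuracies delimit the range of
performance attainable under the input uncertainty; the better of the two is
reported (`select_variant()`, ties resolving to the lower variant). The
default $\alpha = 2$ follows the convention that much larger exponents are
not meaningful for image-derived memberships. $\alpha = 1$ collapses both
variants onto the plain sigmoid, which is exploited by the reduction test
below.

**Fuzzy gradient descent.** Each weight update is scaled by an *ambiguity
factor*

$$a = \operatorname{mean}_j\,(u_{1j} - u_{2j})^2,$$

where $u_{1j}, u_{2j}$ are fuzzy c-means memberships of object $j$ to two
clusters (the two classes of interest). Crisp memberships give $a = 1$ and
plain gradient descent; maximally ambiguous memberships ($u_1 = u_2 = 0.5$)
give $a = 0$ and leave the weights untouched. The update is

$$w \leftarrow w - a\,\eta\,\frac{\partial E}{\partial w},$$

with the squared-error-style delta $(y - p)\,\varphi'(z)$ backpropagated
through the chain rule using the active variant's derivative
($\varphi_L' = \alpha s^{\alpha-1} s(1-s)$ with $s = \mathrm{sig}(z)$, and
analogously for $\varphi_U$).

**Where the ambiguity factors attach.** Memberships are computed by
clustering the activation table (training samples × neurons) of the input
layer and of each hidden layer — never the output layer — once per epoch.
That yields one scalar per non-output layer, and exactly one weight matrix
originates at each of those layers; the scalar from layer $l$'s activations
therefore scales the updates of the weights leaving layer $l$. This is the
only mapping consistent with clustering input + hidden layers while every
weight matrix receives a factor. Two alternatives are exposed as options
because the method description admits both readings: `ambiguity_scope =
"global"` averages the per-layer scalars into a single network-wide factor,
and `orientation = "neurons"` clusters the transposed activation table
(neurons as objects) instead of samples. Per-layer, per-sample is the
default: with samples as objects, the two clusters correspond naturally to
the two classes of interest.

Three exact properties pin the implementation down and are asserted in the
test suite:

* *Reduction*: fuzzy training with the ambiguity forced to 1 and
  $\alpha = 1$ reproduces the standard backpropagation trajectory to
  `1e-12`.
* *Freeze*: ambiguity 0 on all layers leaves the weights bit-identical to
  their initialisation.
* *Envelope*: lower-variant activations never exceed the standard sigmoid,
  which never exceeds the upper variant, at equal pre-activations.

**Decision rule.** Predictions are thresholded at the arithmetic mean of
the batch's probabilities; a lesion is called regular only when its
probability strictly exceeds the threshold (boundary cases are irregular,
and a single sample is therefore always irregular). The mean is taken over
the *test* probabilities, i.e. the rule is transductive, matching how the
protocol is described; `decide(probs, threshold =)` accepts a fixed,
train-derived threshold as the deployment-safe alternative.

**Initialisation and defaults.** Weights start seeded-uniform on
$(-0.5, 0.5)$, biases at 0 (biases are kept although the reference
architecture diagram omits them; without them nothing off-centre can be
fit). The constructor defaults are the reference settings: $\eta = 0.001$
and a single full-batch epoch. Those values are kept for fidelity, but they
barely move the weights from a random start; the synthetic demonstrations
in this package train with $\eta = 2$ for 300 full-batch epochs, a schedule
chosen once as the smallest round numbers that converged from every tested
initialisation seed on the synthetic features. Squared-error gradients
through saturating sigmoids vanish near the plateaus, so under-training can
leave the network at a sign-inverted random map — visible as accuracies far
below chance in a thresholded read-out.

## Fuzzy c-means

`fcm_cluster()` minimises
$J = \sum_j \sum_i u_{ij}^m \lVert x_j - v_i \rVert^2$ (Euclidean distance,
fuzzifier $m = 2$) by alternating the closed-form centroid and membership
updates from `c` distinct seeded data points. Numerical choices: when an
object coincides with a centroid the membership update is undefined and the
crisp limit is used (this also keeps rows stochastic); convergence is
declared when the largest centroid displacement falls below `tol` (default
`1e-6`, cap 300 iterations) — literal centroid equality, the textbook
criterion, never triggers in floating point. The objective is non-increasing
across iterations and the tests check the fixed point against direct
numerical minimisation of the reduced objective $J(v)$.

## Border detection

`create_concepts()` partitions the gray axis $[0, L-1]$ into Dark, Median
and Bright bands (band edges at $\lfloor (L-1)/N_f \rfloor$ multiples, zero
overlap by default), snaps the outer band ends to the first and last
occupied levels, and places each concept's triangular membership apex at the
histogram mode inside its band, with the triangle feet at the band ends. A
triangle is the shape determined by exactly a centre and two spreads, which
is what the concept-construction procedure stores; an empty band falls back
to its midpoint with a warning.

`fuzzedge_filter()` runs, for every pixel, a standard-deviation process over
the 3×3 neighbourhood under each concept: each neighbour's value is taken
through the concept membership (value × membership) and the population
standard deviation of the nine transformed values is recorded. A reference
deviation — the *fuzzy estimator* — uses the interval membership equal to 1
over the whole occupied range, i.e. it is the plain neighbourhood standard
deviation. The output is the concept deviation nearest to the estimator
(ties resolve Dark < Median < Bright). The value-transform reading was
chosen over weighted variance because the latter makes every concept
deviation vanish on two-level images — a binary mask would produce no border
at all — while under the value transform flat neighbourhoods give exactly 0
and borders are exactly the pixels with non-zero response. On binary masks
the responding pixels provably lie within one pixel of the morphological
boundary; the tests assert this against a dilation/erosion oracle. Frame
pixels are handled by edge replication.

`extract_border()` binarises the response (`> 0` by default, configurable),
keeps the largest 8-connected component and traces its outer boundary by
Moore-neighbour tracing with Jacob's stopping criterion, starting at the
topmost-then-leftmost pixel and walking clockwise — deterministic by
construction.

## The irregularity measures

**Fractal dimension** is the least-squares slope of $\log N(e)$ against
$\log(1/e)$, where $N(e)$ counts occupied cells of an $e \times e$ lattice
anchored at the image origin (single offset, no offset search; all ladder
points enter the fit). The default ladder is powers of 2 from 2 up to a
quarter of the image side. Two practical caveats, both visible in the test
suite: boxes comparable to the object size only quantise its bounding box
(an axis-aligned square ring at $e$ = half its side occupies exactly 4
cells, inflating the slope), so the mask pipeline uses the ladder
$\{2,4,8,16\}$, well below the default lesion diameter of ~128 px; and
self-similar test curves are best probed at their own scale ratio — the
level-4 Koch curve rasterised at side 729 measures 1.23 on the powers-of-3
ladder $\{3,9,27,81\}$ against the analytic $\log 4 / \log 3 \approx 1.262$.

**Convexity** is the convex-hull perimeter divided by the lesion boundary
perimeter. The boundary perimeter is the traced 8-connected contour with
unit steps for axial moves and $\sqrt 2$ for diagonal moves; the hull
(computed over the contour pixel coordinates) is measured as exact polygon
arc length. An axis-aligned rectangle scores exactly 1. For smooth oblique
curves the $(1, \sqrt 2)$ chain length overestimates true arc length by up
to the factor $\cos\theta + (\sqrt2 - 1)\sin\theta \le 1.0824$ (about 5% on
average around a closed smooth curve), so even a discretised disk scores
about 0.95, not 1. This digitisation bias is inherent to the pixel-grid
perimeter definition adopted here; it cancels in the regular-vs-irregular
*comparison*, which is what the classifier consumes, but absolute values
are not comparable to sub-pixel perimeter estimators.

Per the measurement flow, the fractal dimension is computed on the border
image and the convexity on the segmentation mask (`extract_features()`).

## The synthetic generator

Real dermoscopic studies use segmented lesions labelled by a dermatologist;
none of that is distributable here, so `make_dataset()` generates the study
conditions synthetically: 157 regular and 153 irregular masks (the balanced
post-augmentation composition), regular = 1 / irregular = 0. Regular
lesions are filled ellipses (seeded aspect ratio 0.7–1 and orientation).
Irregular lesions are star-convex regions

$$r(\theta) = R\,\bigl(1 + \rho \sum_k a_k \sin(k\theta + \phi_k)\bigr)$$

with 16 integer frequencies log-spaced from 2 to $\approx 0.75 R$,
amplitudes $a_k \propto k^{-0.3}$ normalised to $\sum a_k = 1$ (so the
perturbation is bounded by the roughness $\rho$ and the radius stays
positive for $\rho < 1$), and seeded uniform phases. The slow amplitude
decay is deliberate: coarse components form lobes and indentations that
lower convexity, while fine components add serrations that raise the
box-counting dimension — a steeper (e.g. $1/k$) spectrum leaves every
sub-coarse component under one pixel of radial amplitude and produces no
fractal-dimension signal at all. Defaults: image side 256, base radius 64,
roughness 0.4.

What the generator does *not* emulate: hair, colour, illumination,
segmentation errors, or the subtlety of real dermatologist-labelled borders
(real regular/irregular classes overlap; the synthetic classes separate
cleanly at roughness 0.4). Passing the end-to-end test therefore shows the
pipeline is internally correct and the classes it defines are learnable —
it does not certify clinical accuracy, and the published real-data
accuracies are reproduced here only through their printed confusion-matrix
worked examples.

`augment()` provides the isometries used to balance such datasets (90°
rotations and flips; area-preserving by construction). Arbitrary-angle
rotation is deliberately excluded from the defaults to avoid interpolation
artefacts on binary masks.

## Evaluation protocol

`split_dataset()` draws a stratified, seeded split; the train size is
`round(frac * n)` allocated across classes by largest remainder, which
reproduces the published 310-sample tables exactly (248/62, 217/93,
186/124, 155/155). `metrics()` reports accuracy, sensitivity and
specificity as half-up one-decimal percentages with *regular as the
positive class* (the convention the published confusion matrices imply —
dermatological usage might pick irregular; undefined ratios are `NA`,
never 0). `roc_curve()` delegates the threshold sweep and trapezoid area to
pROC. `compare_networks()` trains the standard network and both type-II
variants on an identical split and initialisation (features z-scored with
training-set statistics) and applies the max-accuracy selection.

## Problem sizes and limitations

The test suite and the acceptance script run the full synthetic pipeline at
310 masks of side 256 and the property checks at 50 seeds per class —
sizes chosen so the whole suite completes in about a minute while keeping
every box-counting scale meaningful. Known limitations: the FuzzEdge
standard-deviation process is one defensible reading of a description that
does not fully specify the weighting; box-counting uses a single lattice
offset; convexity carries the digital-perimeter bias discussed above; and
the 1-epoch, $\eta = 0.001$ reference training settings are faithful but
under-trained — use the demo schedule (or your own) for anything beyond
reproducing the reference configuration.
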