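---
title: "Methods: a lightweight multi-scale attention network for lesion image classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lightweight multi-scale attention network for lesion image classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enetcaem)
```

## The problem

Field images of diseased leaves and fruit are hard to classify with compact
networks: lesions appear at very different scales, their colours and
textures can resemble the background, several diseases look alike, and the
datasets collected under real conditions are small and imbalanced. This
package implements a classifier designed for exactly that regime: a reduced
EfficientNetB0 backbone whose channel attention, context modelling, head
pooling and regularisation are all replaced or extended so the model stays
deployable (about 6.5 M parameters, under half a GMAC per image) while
gaining multi-scale sensitivity.

Because no deep-learning framework is assumed, the package carries its own
dense tensor machinery: grouped/dilated 2-D convolution (im2col + GEMM in
compiled code) with hand-derived backward passes for every layer, verified
against nested-loop oracles and finite-difference gradient checks in the
test suite.

## The architecture

The baseline is the standard EfficientNetB0: a 3x3 stride-2 stem of 32
channels, seven stages of inverted-bottleneck (MBConv) blocks with
squeeze-and-excitation (repeats 1,2,2,3,3,4,1; widths
16,24,40,80,112,192,320), and a head of a 1x1 convolution to 1280 channels,
global average pooling and a fully connected classifier. With an 8-class
head this build has 4,017,796 trainable parameters (4.02 M) and 0.385 G
multiply-accumulates (MACs) at 224x224.

The modified network keeps the stem and MBConv skeleton and changes five
things.

**Multi-scale efficient channel attention.** Inside every block, the SE
module is replaced by a channel attention that global-average-pools the
feature map to one descriptor per channel, runs three parallel 1-D
convolutions (kernel sizes 3, 5, 7) along the channel sequence, fuses the
branches by an arithmetic mean, and squashes the result with a sigmoid:

$$ w_c = \sigma\!\Big(\tfrac{1}{n}\sum_{k\in\{3,5,7\}}
  \mathrm{Conv1D}_k(\mathrm{GAP}(X))\Big), \qquad X' = X \cdot w_c . $$

A light spatial stage follows: channel-wise average and max maps are
concatenated into a two-channel map, a 7x7 convolution reduces them to one
channel, and a sigmoid yields a spatial weight map multiplied back onto
$X'$. Two conventions are fixed here deliberately: the fusion is the plain
mean over the $n = 3$ branches (a per-branch learnable softmax fusion is
available via `block_config(eca_learnable_fusion = TRUE)` but is off by
default), and the spatial map has one channel, the only shape that can
broadcast-multiply the feature map. Both gates lie in $(0,1)$, so the block
can only shrink activations — a contraction property the tests assert on
random inputs.

**Channel context module (CCM).** In the 40/80/112-channel stages
(Stages 4–6 in the stage numbering where Stage 1 is the stem), a
bottleneck gate is inserted after the depthwise convolution: GAP, 1x1
compression to $\max(\lfloor C/r\rfloor, 1)$ channels with batch norm and
ReLU, 1x1 restoration with batch norm, sigmoid, channel-wise rescaling.
The reduction ratio is not pinned down by the architecture description;
`r = 16`, the usual squeeze-and-excitation convention, is the default.

**Reduced depth.** The backbone drops from 16 to 13 MBConv blocks. Which
three repeats are removed is not specified by the architecture's
description; see *Calibration* below for how the package fixes this.

**Light atrous spatial pyramid pooling head.** The top feature map passes
through three parallel 3x3 dilated convolutions (rates 3, 6, 9, padding
equal to the rate, each followed by batch norm + ReLU) plus a
global-average-pooling branch compressed to 128 channels by a 1x1
convolution and bilinearly upsampled back (the upsampling of a 1x1 map is a
spatial constant). The four branch outputs are concatenated directly,
without a fusing 1x1 convolution. The small, medium and large rates are
aimed at early, typical and diffuse lesions respectively.

**Mixed pooling, learnable stochastic depth, label smoothing.** The head
pools globally with $y = \lambda\,\max + (1-\lambda)\,\mathrm{avg}$, where
$\lambda$ is a single trainable scalar stored as a logit and squashed by a
sigmoid so it stays in $[0,1]$; it is initialised at $0.5$. Residual
connections are gated by stochastic depth whose drop probability is
learnable per block: $p = \sigma(\theta)\,p_{\max}$ with $p_{\max} = 0.2$
and initial probabilities ramping linearly from 0 to 0.1 with depth. During
training a per-sample Bernoulli gate keeps the branch with probability
$1-p$ and rescales by $1/(1-p)$, so the expectation equals the identity;
the gradient reaches $\theta$ through the rescaling factor. This
gate-with-learned-scale relaxation is the simplest differentiable scheme
consistent with an individually learnable drop probability; the
Monte-Carlo unbiasedness is asserted in the tests. The classifier is
trained with label-smoothed cross-entropy, mixture convention
$q = (1-\varepsilon)\,\mathrm{onehot} + \varepsilon/K$ (the dominant
convention; the $\varepsilon/(K-1)$ variant differs only in how the off-mass
is spread), $\varepsilon = 0.1$ by default.

## Calibration of the unstated structure

Three structural choices are not derivable from the architecture
description: which 3 of the 16 blocks are removed, the width of the dilated
pyramid branches (only the global branch's 128 is stated), and whether the
1x1 expansion to 1280 channels survives in front of the pyramid head. The
only hard constraint available is the model's published complexity budget:
6.55 M parameters and 0.461 GMACs.

The package fixes these by a one-time grid calibration: all repeat-removal
profiles summing to 13, branch widths 96–256, and both head variants. The
head variant is decided immediately — without the retained 1280-channel
expansion the model cannot exceed 4.63 M parameters, so the expansion must
stay. Three combinations round to 6.55 M; the one whose MAC count lands
nearest the 0.461 G budget is the default, and is what
`enet_caem_config()` encodes:

* repeats (1,2,2,2,1,4,1) — one block removed from the 80-channel stage,
  two from the 112-channel stage;
* `aspp_branch_channels = 97`, `aspp_gap_channels = 128`;
* `retain_1x1_expand = TRUE`.

This build has 6,548,855 parameters (6.55 M) and 0.469 GMACs.

**MAC convention.** `count_flops()` counts multiply-accumulates of
convolution, depthwise and linear layers only, at batch 1; normalisation,
activations and pooling are excluded. This is the convention under which
the baseline's canonical complexity is quoted as roughly 0.39 G. Counters
that also bill normalisation and element-wise operations report numbers
around 0.41 G for the same baseline; the package deliberately reports the
pure MAC count and documents the difference rather than mixing
conventions.

## Data pipeline

Images are 8-bit RGB held as numeric arrays in `[0, 255]`. The
augmentation policy implements eight transforms with these ranges: rotation
in [-45, 45] degrees (black corner fill), horizontal flip (probability
0.5), random 200x200 crop resized back to 224x224 (crop position uniform
over valid offsets), Gaussian blur with sigma in [0.5, 1.5], additive
Gaussian noise with sigma = 10 intensity units, and brightness [0.7, 1.3],
contrast [0.8, 1.2], saturation [0.6, 1.4] scalings. Each augmentation
cycle samples 2–3 distinct transforms (without replacement) and produces
two augmented versions per source image. Class imbalance is addressed by
resampling — drawing with replacement up to the target for small classes,
without replacement down to it for large ones; the convenience default
target is the median class size. Splitting is stratified 8:1:1 per class
with largest-remainder rounding (ties resolved toward the earlier split),
so every class's proportions are exact to within one item. All three
operations are pure functions of their inputs and a seed. Split-then-
augment is the recommended order; the command-line `augment` warns if its
input tree looks already split, since augmenting first can leak
near-duplicates across the train/test boundary.

## Synthetic data: what it does and does not show

The generator emulates eight visually distinct classes named after the
usual strawberry roster (four leaf states, four fruit states). Each class
is a background shade (greenish for leaves, reddish for fruit) with
low-frequency mottling, plus lesions from one of three shape families —
circular spots, angular (rotated-diamond) patches, or dense powdery
speckles — with class-specific colour, count and radius ranges; the two
healthy classes have none. Classes are deliberately separable by colour
statistics alone at zero noise (a nearest-centroid classifier on mean RGB
reaches accuracy 1.0, asserted in the tests), which makes the learnability
checks diagnostic: if the network fails here, the implementation is wrong,
not the data ambiguous. The flip side is equally important: passing on this
data says nothing about accuracy on real field imagery — there is no
photorealism, no background clutter, no class overlap, and no claim of
biological fidelity. `generate_scale_series()` regenerates the same scenes
with scaled lesion radii, exercising the multi-scale claim.

## Training recipe and problem sizes

Training uses Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$), batch size 32,
and a cosine-annealed learning rate
$\mathrm{lr}(t) = \mathrm{lr}_{\min} + \tfrac12(\mathrm{lr}_{\max} -
\mathrm{lr}_{\min})(1 + \cos(\pi t/T))$ over $T$ epochs; the reference
recipe runs $T = 200$. The initial rate is not pinned down by the recipe's
description; the default is $\mathrm{lr}_{\max} = 10^{-3}$,
$\mathrm{lr}_{\min} = 0$, standard for Adam with cosine annealing, and
weight decay defaults to 0. There is no early stopping; the checkpoint with
the best validation accuracy is retained, ties resolved toward the earlier
epoch. Every stochastic element — initialisation, shuffling, dropout,
stochastic depth — keys off the configured seed, and identical seeds give
bit-identical loss trajectories.

The package's own test and example runs are sized for a single CPU: the
learnability check trains `enet_caem_mini_config()` — a three-stage
miniature with the identical block inventory (multi-scale ECA in every
block, CCM in the middle stage, learnable stochastic depth, pyramid +
mixed-pooling head) — on 8 x 50 synthetic images at 48x48 for 30 epochs,
which reaches perfect validation accuracy around epoch 6 and takes a few
minutes. The full 6.55 M configuration trains with exactly the same code
path; it is simply not exercised at 224x224 in the tests.

## Evaluation

`confusion_matrix()` stores truth in rows and predictions in columns.
Per-class precision, recall and F1 are one-vs-rest ratios; any ratio with a
zero denominator is reported as 0 and flagged, never NaN. Aggregates are
unweighted class means (macro) by default — on a near-balanced test set
macro recall essentially coincides with accuracy, which is how the
reference results read — with micro averaging available.
`kfold_cv()` builds stratified folds, trains from scratch on each
complement and reports each metric's mean and sample (n-1) standard
deviation. Fold assignment and per-fold seeds derive from one seed.

## Numerical choices

* Batch norm: momentum 0.1, eps 1e-5; running variance stored unbiased;
  evaluation mode uses running moments (fresh layers are identity up to the
  variance floor). Swish is $x\,\sigma(x)$.
* Convolutions feeding a batch norm carry no bias; the SE/CCM 1x1 stages
  and the 1-D channel convolutions do.
* Channel-max operations (spatial attention, global mixed pooling) resolve
  ties by first index, and their backward passes route gradient only to the
  argmax entry; the average path spreads gradient uniformly.
* The sigmoid reparameterisations of $\lambda$ and of the drop
  probabilities keep both constrained without clipping; initial values are
  clamped away from the boundaries by 1e-6 so the logits stay finite.
* Weight initialisation is He-normal with fan-in; all draws come from the
  session RNG so builds are reproducible under `set.seed()`.
* Degenerate inputs: 1x1 spatial maps, single-channel maps and batch size 1
  are all legal (batch norm at batch 1 falls back to a zero-variance
  normalisation guarded by eps); empty prediction vectors give an all-zero
  confusion matrix.

## Known limitations

* Training at the full 224x224 scale is CPU-bound in this implementation
  (a full forward pass costs a few seconds per image); the code is written
  for correctness and auditability first, with compiled kernels only where
  they pay off most.
* The three structural unknowns are fixed by complexity calibration, not by
  ground truth; other combinations rounding to the same budget exist and
  can be selected through `architecture_config()`.
* The pure-MAC complexity convention understates tool-reported "FLOPs" that
  include normalisation and element-wise work (see *Calibration*).
* Synthetic data is a correctness instrument, not a benchmark; no accuracy
  claim on real disease imagery follows from it.
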