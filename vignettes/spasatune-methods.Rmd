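---
title: "Methods: sparrow-search hyperparameter optimization for image classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparrow-search hyperparameter optimization for image classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spasatune)
```

## The problem

Fine-tuning a pretrained image classifier involves a dozen coupled choices
— loss, batch size, dropout, how much of the backbone to unfreeze, which
optimizer, how to scale intensities, whether and how to augment. This
package treats that choice as a black-box optimization over the unit
hypercube: each hyperparameter occupies one coordinate of a vector in
$[0,1]^D$, and a swarm optimizer searches the cube using only fitness
evaluations (validation accuracy of a short training run). The motivating
application is a two-stage kidney diagnosis: CT scans classified into
Cyst/Normal/Stone/Tumor, with tumor cases routed to a second model that
grades histopathology slides (Grade 0–4).

## The optimizer

The Sparrow Search Algorithm maintains $N$ solutions ranked by fitness.
Each round:

1. **Discoverers** (the best $PD = \max(1, \lceil r_p N \rfloor)$
   solutions) either contract, $X \leftarrow X \cdot e^{-t/(\alpha T)}$
   with per-solution $\alpha \sim U(0,1)$, while the alarm draw
   $R_2 \sim U(0,1)$ stays below the safety threshold $ST$, or take a
   coordinate-wise normal step $X + Q$ when the alarm trips.
2. **Followers** (the rest) either collapse to
   $Q \cdot e^{(X_{worst}-X)/i^2}$ when their rank $i$ is in the worse
   half, or move to the best producer position plus the scalar projection
   $\sum_d |X_d - X_{P,d}| A_d / D$ (Rademacher $A$) added to every
   coordinate.
3. **Scouts** ($SD$ solutions sampled without replacement) jump toward the
   best position with a normal step size, or — if already at the best
   score — take a $K \cdot |X - X_{worst}| / ((f_i - f_w) + \epsilon)$
   escape step, $K \sim U(-1,1)$.

Every update is followed by a hard clamp into $[0,1]$, which the decoding
layer requires. The best-ever solution and score are tracked across
rounds, so the reported history is monotone.

Defaults: $N = 10$, $T = 10$, producer and scout ratios 0.20, $ST = 0.8$,
$\epsilon = 10^{-50}$. The alarm value is drawn once per discoverer round;
$Q$ is a fresh normal vector per solution (the all-ones matrix $L$ in the
update rules implies element-wise action); $A^+ = A^T/(A A^T) = A^T/D$ is
implemented in closed form.

### Known behavioral limitations

Two quirks follow from implementing the published update rules literally,
and are kept deliberately:

- The follower collapse $Q \cdot e^{(X_{worst}-X)/i^2}$ ignores the
  follower's current position almost entirely, acting as a random restart
  near the origin.
- The discoverer contraction multiplies positions toward $0$, which in
  $[0,1]^D$ is a *corner*, not the domain center.

On the sphere and Rastrigin benchmarks (minimization, optimum at the cube
center) the optimizer still dominates equal-budget uniform random search
(median over 20 seeds, tested). On the very smooth "distance to a hidden
target" objective it only *ties* with random search at equal budget
(median paired margin ≈ −0.003 over 10 seeds); the coordinate-recovery
bound (median max-coordinate error ≤ 0.15 at $N{=}20$, $T{=}50$, $D{=}5$)
holds. Users optimizing smooth objectives on the cube should treat the
algorithm as a competitive-but-not-superior searcher; its value here is
the discrete, conditional hyperparameter landscape.

## The encoding

The search space is an ordered list of 15 dimension specs. Discrete
dimensions decode by `floor(value * n_choices)` clamped at the top (so
value 1.0 is valid), matching the published worked example in which 0.85
against the 12 batch sizes yields index 11 (1-based), i.e. batch size 44.
Continuous dimensions interpolate linearly; booleans switch at 0.5.

Three interpretation choices were genuinely open and are fixed as follows:

- **Brightness (element 15)** is a single scalar, but reported best
  configurations show two-ended brightness intervals of varying width.
  The scalar is decoded as an interval *center* $c \in [0.5, 2.0]$ and
  expanded to $[\max(0.5, c-0.3), \min(2.0, c+0.3)]$; the half-width is a
  `search_space()` argument.
- **TL learn ratio** is read as the percentage of backbone layer groups,
  counted from the output end, left trainable during fine-tuning —
  consistent with its 1–100 range and transfer-learning usage. Whether the
  source meant layers, blocks, or a learning-rate multiplier is not
  recoverable from the text.
- The optimizer always works on the **fixed 15-dimension cube**; when the
  augmentation flag decodes to off, elements 8–15 are carried but ignored.
  The 7-dimension variant is available as `search_space(FALSE)` and never
  augments.

## The data pipeline

Images are real-valued H×W×3 arrays on the $[0,255]$ scale until a scaler
is applied. Resizing is separable bicubic (Catmull–Rom kernel,
$a = -0.5$, pixel-center alignment); edge windows drop out-of-range taps
and renormalize, which matches the Pillow reference resampler to ~1e-5 on
a frozen fixture. The four intensity scalers — $X/\max(X)$,
$(X-\mu)/\sigma$, min–max, max–abs — use per-image statistics; a flat
image cannot be scaled and falls back to zeros with a warning.

Augmentation samples a rotation, shifts, shear, zoom (uniform in
$[-m, +m]$), optional flips (probability 0.5 each when enabled), and a
brightness multiplier, applies the combined affine warp about the image
center with reflect padding and bilinear sampling, and clips to
$[0, 255]$. Class balancing up-samples every class to the largest class
size with augmented copies of uniformly resampled members (the fixed
balancing settings: rotation 30°, 20 % shifts/shear/zoom, both flips,
brightness [0.8, 1.2]). The balancing target is the maximum because the
published before/after tables raise every class and reduce none. Applying
the rule to the 4-class study counts {3709, 5077, 1377, 2283} gives
5077 per class (20 308 total); applying it to the 5-class counts
{45, 45, 60, 67, 60} gives 67 per class, i.e. a total of 335 — one
published total (355) disagrees with its own per-class figure, and the
rule is what is implemented.

Splitting is stratified per class (default 85 % train+validation / 15 %
test, validation = 15 % of the training share; the validation fraction is
not fixed by the source and is configurable). Because balancing runs
before splitting, an augmented copy and its source image are assigned to
the same partition (whole source groups move together); otherwise copies
of a training image leak into validation or test and inflate scores.
`group_by_source = FALSE` restores the plain per-image split.

## The fitness engine

No deep-learning framework exists in the target environment, so the
classifier is written in base R: three 3×3 convolution blocks (8/16/32
filters, ReLU, 2×2 mean pooling) implemented as im2col matrix products,
global average pooling, one dropout layer, and a softmax head. The six
losses and eleven optimizers of the search vocabulary are implemented
from their standard (Keras-convention) formulas with analytic gradients;
hinge-family losses act on the softmax outputs through the softmax
Jacobian. Freezing: `ceiling(ratio/100 * 3)` blocks from the output end
stay trainable; the head always trains, so the trainable-parameter count
is non-decreasing in the ratio.

The surrogate is the *tested* backbone: it runs a fitness evaluation in
well under a second on one CPU at 32×32, which is what makes the whole
search loop testable. The eight named pretrained backbones are accepted
for interface compatibility but construct the same surrogate architecture
with deterministic synthetic weights (a warning says so): true ImageNet
weights cannot be obtained offline, and results under these names carry no
transfer-learning meaning.

Fitness is total by design: any decodable configuration returns a result,
with training failures and non-finite losses mapped to score 0 plus a
diagnostic, so the optimizer survives pathological loss/optimizer
pairings. Two evaluation modes exist because the source is ambiguous
about its own: `holdout` (default) scores the validation partition only;
`paper-faithful` scores the union of the provided sets, which mixes
training data into the fitness and inflates it — the mode is recorded in
every result.

## Metrics

Multiclass results are pooled one-vs-rest: each (sample, class) pair
contributes one binary outcome, so $TP+TN+FP+FN = nC$ under argmax
prediction and pooled FP always equals pooled FN. Published confusion
tables with $FP \neq FN$ imply per-class threshold counting, so a
`threshold` mode (predict class $c$ iff $p_c > 0.5$) is provided and the
mode is always recorded. Closed forms: accuracy $(TP+TN)/(TP+TN+FP+FN)$,
precision $TP/(TP+FP)$, sensitivity $TP/(TP+FN)$, specificity
$TN/(TN+FP)$, $F1 = 2TP/(2TP+FP+FN)$; a zero denominator yields an absent
metric, never 0. AUC is the macro one-vs-rest rank statistic with
mid-ranks for ties; IoU is $TP/(TP+FP+FN)$ from argmax counts; cosine
similarity is the mean per-sample cosine between the one-hot truth and
the probability row. AUC/IoU/cosine are *chosen* definitions (the source
names but never defines them) and are not treated as comparison surfaces.
Percentages are displayed at two decimals with half-up rounding, matching
the apparent table convention; full precision is kept internally.

## Synthetic fixtures

The generator renders each class as a distinct parametric texture —
a bright ring on a dark disk (cyst-like), a smooth gradient (unremarkable
parenchyma), bright speckles (stone-like), a soft central mass
(tumor-like), and, for the 5-class problem, sinusoidal granularity whose
spatial frequency grows with the grade. An image is
`background + signal_strength * texture + Gaussian noise`, clipped to
$[0,255]$, with sub-pixel per-image jitter. Defaults state the emulated
world: the 4-class preset uses the study's class imbalance at 1 % scale
(37/51/14/23), the 5-class preset uses the study's actual desk-scale
counts (45/45/60/67/60), 32×32 pixels (the real pipeline's 128×128 is
used only in integration tests), noise SD 8.

What a green test establishes: the machinery — decoding, preprocessing,
training, scoring, search — behaves correctly on separable, low-variance
images. What it does not establish: any claim about real CT or
histopathology performance; the textures share none of the statistics of
medical images, and the surrogate is not a pretrained network.

## Numerical and reproducibility choices

- One master seed per run is split into component seeds (data, balancing,
  splitting, evaluation, optimizer); fitness evaluations run under a
  saved-and-restored RNG state so the optimizer stream is independent of
  training randomness, making fitness a deterministic function of the
  solution and the whole run bitwise reproducible.
- The optimizer can checkpoint its full state (population, scores,
  best-ever, RNG state) to JSON after every iteration; resuming from a
  mid-run checkpoint reproduces the uninterrupted result exactly
  (tested).
- Sorting ties are broken stably by index. Out-of-bounds positions are
  clamped, not reflected. $\epsilon = 10^{-50}$ guards the scout
  division.
- Images travel as plain-text portable pixmaps (ASCII PPM/PGM) in
  class-per-subdirectory trees; no binary image reader is assumed.

## Limitations

- The optimizer quirks above; the literal update rules are kept because
  they are the published executable form.
- The surrogate backbone (~7k parameters) bounds attainable accuracy on
  hard fixtures; headline-scale results require real backbones and GPUs,
  which are out of scope.
- Named pretrained backbones are synthetic stand-ins.
- `paper-faithful` evaluation deliberately reproduces a
  train-on-test-adjacent protocol; use `holdout` for honest scores.
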