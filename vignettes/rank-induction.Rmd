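---
title: "Rank induction: injecting partial expert annotations into attention MIL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank induction: injecting partial expert annotations into attention MIL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whole-slide images (WSIs) are classified under multiple instance learning
(MIL): a slide is a bag of patch feature vectors $z_1, \dots, z_K$, a slide is
positive iff at least one patch contains a lesion, and only the slide label is
guaranteed to exist. Attention-based MIL (AB-MIL) learns a per-patch raw score
$s_k$, softmax weights $a_k$, pools $M = \sum_k a_k z_k$, and classifies $M$.
With weak supervision alone the attention is free to latch onto anything
correlated with the label, which makes small-data training unstable and the
attention maps unreliable as localization evidence.

Pathologists often *do* annotate some lesions, at least on some slides, as
polygons. `rankmil` implements **rank induction**: those partial annotations
enter the objective not as patch-level classification targets but as *pairwise
ranking constraints on the raw attention scores* — every annotated (lesion)
patch should outrank every unannotated patch in the same slide.

## The objective

For a slide with patch labels $y_k \in \{0, 1\}$ the valid pair set is
$P = \{(i, j) : y_i = 1, y_j = 0\}$; same-class pairs are excluded. For a pair
the preference that $i$ outranks $j$ is the RankNet-style sigmoid

$$P_{ij} = \sigma\!\big(\texttt{scale} \cdot (s_i - s_j - m)\big),$$

so the margin $m$ is the score gap at which the preference is exactly 0.5.
Because the ground-truth preference is 1 for every valid pair, the rank loss
reduces to $L_{\text{rank}} = -\tfrac{1}{|P|}\sum_{(i,j) \in P} \log P_{ij}$
(implemented as the general two-term cross-entropy; the reduction is verified
by a test, not assumed). The loss consumes *raw* scores, not softmax weights:
the softmax normalization couples all patches, whereas raw-score ranking
constrains only relative order. The total objective is

$$L = L_{\text{BCE}} + \lambda\, L_{\text{rank}},$$

with the ranking term omitted for negative slides and for positive slides
whose annotations are absent or hidden — an unannotated positive slide
contributes exactly what it would in plain AB-MIL. This distinction is why
bags store "no annotation" (`patch_labels = NULL, annotated = FALSE`) apart
from "annotated, all normal" (all-zero labels).

For very large bags the pair set is capped by sampling up to 1024 annotated
and 1024 unannotated patches per slide and taking their full Cartesian
product (the sets are sampled, not the pairs, so the estimator stays a mean
over a complete bipartite graph). When class counts are within the caps the
sampled loss is exactly the exhaustive one.

### Attention thresholding

With thousands of patches, even near-zero attention weights sum to a
non-trivial fraction of the pooled representation and dilute the lesion
signal. After the softmax we therefore zero every weight below $T/K$ ($T$
times the uniform weight) and renormalize the survivors:

$$\bar a_k = \frac{a_k \,\mathbf 1[a_k \ge T/K]}{\sum_j a_j \,\mathbf 1[a_j \ge T/K]}.$$

Choices worth stating explicitly:

* the cutoff is *relative* ($T/K$): $T = 1$ means "suppress below-uniform
  weights", which keeps the operation meaningful across bag sizes;
* the boundary uses $\ge$, so a uniform attention vector survives $T = 1$
  unchanged and $T = 0$ is the exact identity;
* if no weight survives (large $T$ on a flat distribution) the single argmax
  weight is kept with $\bar a = 1$ — training must never divide by zero;
* in differentiation the indicator is treated as a constant
  (straight-through): gradient flows through surviving weights only;
* thresholding is applied during training and, by default, also at inference
  (`apply_threshold_at_inference`), keeping the train/test pooling
  consistent; localization rankings use the pre-threshold $a$, which
  preserves the order among survivors while keeping top-$\alpha$ sweeps
  well-defined when $T$ zeroes many patches.

### The network

The scorer is the standard two-layer tanh attention,
$s_k = w^\top \tanh(V z_k + b)$, with an optional gated variant
($\odot\, \text{sigmoid}(U z_k + c)$) behind a flag; the classifier is a
logistic head on the pooled embedding. Defaults: hidden width 256, ungated,
$T = 1$, $m = 1$, scale $1$, $\lambda = 1$. Training uses Adam
(learning rate $2 \times 10^{-4}$, weight decay $10^{-5}$), one slide per
step, up to 200 epochs with early stopping on the validation total loss
(patience 7 after a 20-epoch warmup; epochs inside the warmup never advance
the patience counter, so a last improvement at epoch 21 stops training at
epoch 28). All randomness — initialization, epoch shuffling, pair sampling,
splits — derives from one integer seed, and two runs with the same
configuration and seed are bit-identical. Gradients for the whole network
are hand-derived and checked against finite differences in the test suite.

## Preprocessing rasters into bags

The optional tiling module turns an image plus polygon annotations into a
bag: multilevel Otsu tissue masking, tessellation into non-overlapping
224 px tiles (half-open $[x_0, x_0 + 224)$, 0-based), discarding tiles with
less than 5% tissue (kept iff coverage $\ge 0.05$), labeling a tile positive
iff its rectangle intersects the union of polygons with strictly positive
area, and a pluggable `feature_fn` per tile.

Two numerical choices deserve comment.

* **Foreground rule.** With $L = 3$ Otsu classes the textbook rule
  "foreground = every class below the brightest" breaks on bimodal images:
  the dynamic program gains more between-class variance by splitting the
  heavier mode (usually the white background) than by cutting an empty
  histogram region, so the "brightest class" can be just the upper half of
  the background. The default rule (`best_split`) instead takes, among the
  multilevel thresholds, the one maximizing the two-class between-class
  variance; on tissue-on-glass histograms this picks the tissue/background
  gap, and on bimodal images it degrades to plain Otsu behaviour. The
  literal `below_top` rule stays available as an option.
* **Annotation coarsening.** `pad_annotation` buffers polygons outward
  (Minkowski dilation with round joins), emulating coarse expert outlines;
  patch labels are monotone non-decreasing in the padding. The module is
  magnification-agnostic: a 448 px padding drawn at 40x corresponds to one
  224 px patch-width at 20x, a factor the caller applies. On the synthetic
  grid the analogue is `coarsen_labels`, a Chebyshev-ball dilation in units
  of whole patches.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` draws bags of $D$-dimensional standard-normal instances;
positive bags contain a spatially contiguous lesion blob (grown on a virtual
$\sqrt K \times \sqrt K$ grid, so coarsening is meaningful) whose instances
are shifted by $\delta$ along one random unit direction fixed per dataset.
This is the simplest family in which the Bayes-optimal attention is known
(project onto the direction), giving analytic oracles for localization
tests, and it reproduces the study's three stress axes: training-set size,
annotation granularity (`coarsening_pad`), and the fraction of annotated
positive slides (`annotated_fraction`, hiding labels on exactly
$\mathrm{round}(f \cdot n_{\text{pos}})$ positives).

Defaults are sized for minutes-level single-CPU runs: 60/20/40
train/val/test slides balanced across classes, $K \in [100, 300]$, $D = 32$,
$\delta = 2$, lesion fraction 2–10%. What the generator deliberately does
*not* model: correlated patch features (stain, texture, scanner effects),
feature distributions of a pretrained CNN, label noise inside expert
polygons, and class imbalance beyond the lesion fraction. Passing the
mechanism tests therefore shows that the *objective* behaves as designed —
annotations steer attention, thresholding controls dilution, partial
annotation saturates early — not that any particular clinical AUROC is
attainable.

## Evaluation protocol

Slide-level metrics: AUROC by the Mann–Whitney rank statistic (ties
half-counted), AUPRC by step interpolation, accuracy at 0.5. Localization on
positive slides ranks all patches by attention and selects the top
$\max(1, \mathrm{round}(\alpha/100 \cdot n_{\text{tumor}}))$ patches
(round-half-even; ties to the lower index), then scores IoU, Dice, and the
pointing game (a hit iff any selected patch is annotated) for
$\alpha \in \{1, 5, 10, 20, 50, 75, 100\}$; at $\alpha = 100$ perfect
attention reaches IoU = Dice = 1. The pointing game shares the top-$\alpha$
selection: its candidates are ranked over all patches, and for
$\alpha \le 100$ the selection size never exceeds $n_{\text{tumor}}$, so the
two readings of the protocol coincide on this grid. Monte Carlo
cross-validation resplits only train/validation; the test split stays fixed.

In the threshold ablation the readout besides AUROC is the cumulative
attention mass $\sum_k \bar a_k \mathbf 1[y_k = 0]$ on non-lesion patches of
positive test slides — the quantity thresholding is designed to suppress.

## Experiment harnesses and problem sizes

`run_experiment()` wraps the four stress studies (`low_data`, `granularity`,
`subset_annotation`, `threshold_ablation`) plus `localization`; each grid
point is trained per fold on Monte Carlo resplits with fold-derived seeds.
The subset-annotation fraction applies to the development positives as a
whole (train *and* validation): hiding only training annotations would leave
ranking terms in the validation loss at $f = 0$, and the equivalence
"$f = 0$ is exactly the BCE-only baseline" would silently break. Low-data
subsampling is stratified by slide label so small fractions cannot become
all-negative.

The package's own mechanism checks run rank induction against the AB-MIL
baseline ($\lambda = 0$) over five seeds of the default synthetic
conditions, with the annotation-fraction sweep ($f \in \{0, 0.2, 1\}$) and
coarsening pads 1–3; `scripts/acceptance.R` recomputes the same grid from
scratch. These sizes — five seeds, 120 slides per dataset — were chosen as
the smallest grid on which across-seed SDs are meaningful.

## Known limitations

* Thresholding uses a straight-through subgradient; the loss is therefore
  not the exact gradient target when survivor sets change between steps.
* The empty-survivor fallback makes $\bar a$ one-hot and locally constant,
  so a bag stuck in the fallback receives no attention gradient from the
  pooling path (the rank loss still updates its scores).
* `batch_size` is fixed at one slide; pair averaging is per slide, then
  across slides.
* The generator's Gaussian mean-shift instances are linearly separable in
  one direction; conclusions about representation learning do not transfer.
* Bag containers are HDF5; features are stored as float64 because R has no
  native float32, trading file size for bit-exact round trips.
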