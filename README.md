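# rankmil

Rank-induction multiple instance learning (MIL) for slide-level
classification with partial expert annotations.

## The problem

Digital-pathology slides are classified as bags of patch feature vectors
under MIL: a slide is positive iff at least one patch contains a lesion, and
usually only the slide label is available. Attention-based MIL (AB-MIL)
pools patches with learned softmax attention, but with weak supervision
alone the attention is unconstrained, so small-data training is unstable and
attention maps are unreliable for localization. Yet pathologists often
annotate *some* lesions on *some* slides as polygons — supervision that
plain MIL discards.

`rankmil` turns those partial annotations into pairwise ranking constraints
on the raw attention scores (rank induction): for every annotated patch
`i` and unannotated patch `j` in the same slide,

    P_ij = sigmoid( scale * (s_i - s_j - m) )
    L    = L_BCE + lambda * mean over pairs of [ -log P_ij ]

so annotated patches are pushed to outrank unannotated ones, with margin `m`.
Slides without (trusted) annotations contribute the slide-level
cross-entropy only. A second ingredient, attention thresholding, zeroes
softmax weights below `T/K` (T times the uniform weight) and renormalizes,
preventing thousands of near-zero weights from diluting the pooled slide
representation:

    abar_k = a_k * 1[a_k >= T/K] / sum_j a_j * 1[a_j >= T/K]

The package ships the full surrounding toolchain: HDF5 feature-bag storage
with CSV manifests, an optional raster preprocessing pipeline (multilevel
Otsu tissue masking, 224-px tessellation, <5%-tissue filtering,
polygon-overlap patch labeling, polygon padding), a synthetic bag generator
with controllable difficulty, a deterministic single-CPU training loop
(Adam, early stopping), classification metrics (AUROC/AUPRC/accuracy),
attention-localization metrics (IoU, Dice, pointing game at top-alpha%),
Monte Carlo cross-validation, and experiment harnesses for low-data,
annotation-granularity, subset-annotation, and threshold-ablation studies.

## Worked example

Train rank induction and the AB-MIL baseline (`lambda = 0`) on one synthetic
dataset and compare:

```r
library(rankmil)

ds <- generate_dataset(synthetic_spec(seed = 11))   # 60/20/40 slides, D = 32
m  <- ds$manifest
tr <- ds$bags[m$slide_id[m$split == "train"]]
va <- ds$bags[m$slide_id[m$split == "val"]]
te <- ds$bags[m$slide_id[m$split == "test"]]

fit  <- train_model(tr, va, train_config(seed = 5))   # rank induction
fit0 <- train_model(tr, va, train_config(seed = 5,
                    loss = rank_loss_config(weight = 0)))  # AB-MIL

ev  <- evaluate_model(fit,  te)
ev0 <- evaluate_model(fit0, te)
ev$metrics$auroc
#> [1] 0.9275
ev0$metrics$auroc
#> [1] 0.8075
ev$localization$aggregate
#>   alpha   mean_iou mean_dice pointing_accuracy
#> 1     1 0.08021825 0.1438875              0.85
#> 2     5 0.08021825 0.1438875              0.85
#> 3    10 0.09757937 0.1732546              0.85
#> 4    20 0.15007908 0.2530584              0.85
#> 5    50 0.28686661 0.4342135              1.00
#> 6    75 0.34837052 0.4968468              1.00
#> 7   100 0.32230948 0.4718452              1.00
```

Both models see identical bags; only the ranking term differs. Rank
induction's test AUROC (0.93 vs 0.81 here) and its localization quality
improve because annotated lesion patches are forced to the top of the
attention ranking: at `alpha = 100` (select as many top patches as there are
tumor patches) every positive test slide has at least one selected patch
inside the annotation (pointing accuracy 1.00), and roughly a third of the
selected set is exactly right (IoU 0.32).

Stress harnesses run the same comparison over a grid, e.g. the fraction of
annotated positive slides:

```r
run_experiment("subset_annotation", grid = c(0, 0.2, 1), dataset = ds,
               config = train_config(seed = 5), n_folds = 5)
```

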