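Package: rankmil
Title: Rank-Induction Multiple Instance Learning for Slide-Level Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Attention-based multiple instance learning (MIL) for whole-slide
    image classification with rank induction: partial expert annotations are
    injected as pairwise ranking constraints that push raw attention scores of
    annotated (lesion) patches above those of unannotated patches, and an
    attention-thresholding step suppresses the dilution of the slide
    representation by many near-zero attention weights. Includes HDF5 feature-bag
    storage with CSV manifests, an optional raster preprocessing pipeline
    (multilevel Otsu tissue masking, patch tessellation, polygon-based patch
    labeling and annotation coarsening), a synthetic bag generator with
    controllable difficulty, a deterministic CPU training loop, slide-level
    classification metrics (AUROC, AUPRC, accuracy), attention localization
    metrics (IoU, Dice, pointing game), Monte Carlo cross-validation, and
    experiment harnesses for low-data, annotation-granularity,
    subset-annotation, and attention-threshold studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rhdf5,
    polyclip,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    EBImage,
    sp,
    png,
    yaml
Config/testthat/edition: 3
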