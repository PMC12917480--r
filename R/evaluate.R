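#' Select the top-attention patches relative to the tumor burden
#'
#' Ranks all patches by attention and selects the
#' `max(1, round(alpha/100 * n_tumor))` highest (round half to even, R's
#' `round()`); `alpha = 100` selects exactly `n_tumor` patches, so perfect
#' attention can reach IoU = Dice = 1. Ties are broken toward the lower patch
#' index so the selection is deterministic.
#'
#' @param attention attention vector (softmax weights `a` by default in
#'   [localization_report()]; thresholded weights only reorder nothing).
#' @param n_tumor number of tumor-annotated patches in the slide (>= 1).
#' @param alpha selection percentage relative to `n_tumor`.
#' @return integer vector of selected patch indices.
#' @export
select_top_patches <- function(attention, n_tumor, alpha) {
  if (n_tumor < 1) stop("n_tumor must be >= 1; slides without tumor patches ",
                        "are excluded from localization")
  n_sel <- max(1L, round(alpha / 100 * n_tumor))
  order(-attention, seq_along(attention))[seq_len(min(n_sel, length(attention)))]
}

#' Overlap scores between selected and tumor patch sets
#'
#' `IoU = |S intersect T| / |S union T|`,
#' `Dice = 2 |S intersect T| / (|S| + |T|)`, and a pointing-game hit when the
#' intersection is non-empty.
#'
#' @param selected integer indices of the selected high-attention patches.
#' @param tumor integer indices of tumor-annotated patches (non-empty).
#' @return list `(iou, dice, hit)`.
#' @export
localization_scores <- function(selected, tumor) {
  if (length(tumor) == 0) stop("empty tumor set: slide excluded")
  inter <- length(intersect(selected, tumor))
  uni <- length(union(selected, tumor))
  list(iou = inter / uni,
       dice = 2 * inter / (length(selected) + length(tumor)),
       hit = inter >= 1L)
}

#' Attention localization report over positive slides
#'
#' For every slide with at least one tumor-annotated patch, and every alpha in
#' the grid, selects the top patches with [select_top_patches()] and scores
#' them against the annotation. Slides without tumor patches are excluded with
#' a warning. The pointing game shares the top-alpha selection: candidates are
#' ranked over all patches of the slide, and for alpha <= 100 the selection
#' size never exceeds `n_tumor`, so the two protocol readings coincide
#' (`pointing_from_all` flag retained for explicitness).
#'
#' @param attention_list named list of per-slide attention vectors.
#' @param label_list named list of per-slide binary patch-label vectors
#'   (ground truth).
#' @param alphas percentage grid (default `c(1, 5, 10, 20, 50, 75, 100)`).
#' @param pointing_from_all rank pointing-game candidates over all patches
#'   (default TRUE; identical selection for alpha <= 100).
#' @return list of class `localization_report`: `per_slide` data.frame
#'   (slide, alpha, n_tumor, iou, dice, hit) and `aggregate` data.frame
#'   (alpha, mean_iou, mean_dice, pointing_accuracy).
#' @export
localization_report <- function(attention_list, label_list,
                                alphas = c(1, 5, 10, 20, 50, 75, 100),
                                pointing_from_all = TRUE) {
  slides <- names(attention_list)
  rows <- list()
  for (id in slides) {
    y <- label_list[[id]]
    tumor <- which(y == 1L)
    if (length(tumor) == 0L) {
      warning("slide ", id, " has no tumor-annotated patches; excluded")
      next
    }
    a <- attention_list[[id]]
    for (alpha in alphas) {
      sel <- select_top_patches(a, length(tumor), alpha)
      sc <- localization_scores(sel, tumor)
      rows[[length(rows) + 1L]] <- data.frame(
        slide = id, alpha = alpha, n_tumor = length(tumor),
        iou = sc$iou, dice = sc$dice, hit = sc$hit)
    }
  }
  per_slide <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_slide, per_slide$alpha), function(d) {
    data.frame(alpha = d$alpha[1], mean_iou = mean(d$iou),
               mean_dice = mean(d$dice),
               pointing_accuracy = mean(d$hit))
  }))
  agg <- agg[order(agg$alpha), ]
  rownames(agg) <- NULL
  structure(list(per_slide = per_slide, aggregate = agg),
            class = "localization_report")
}

#' Slide-level classification metrics
#'
#' AUROC by the rank statistic (Mann-Whitney formulation; tied scores are
#' half-counted via midranks), AUPRC by step interpolation of the
#' precision-recall curve, and accuracy at the 0.5 threshold.
#'
#' @param scores predicted probabilities or scores.
#' @param labels binary labels.
#' @return list `(auroc, auprc, accuracy)`.
#' @export
classification_metrics <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores)                       # midranks half-count ties
  auroc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  auprc <- average_precision(scores, labels)
  accuracy <- mean((scores >= 0.5) == (labels == 1L))
  list(auroc = auroc, auprc = auprc, accuracy = accuracy)
}

# Step-interpolated area under the precision-recall curve (average
# precision). Tied scores are processed as one threshold group.
average_precision <- function(scores, labels) {
  ord <- order(-scores)
  labels <- labels[ord]
  scores <- scores[ord]
  n_pos <- sum(labels == 1L)
  grp <- cumsum(!duplicated(scores))
  tp <- cumsum(labels == 1L)
  n <- seq_along(labels)
  last <- !duplicated(grp, fromLast = TRUE)  # last element of each tie group
  tp <- tp[last]; n <- n[last]
  recall <- tp / n_pos
  precision <- tp / n
  prev_recall <- c(0, recall[-length(recall)])
  sum((recall - prev_recall) * precision)
}

#' Monte Carlo cross-validation
#'
#' Performs `n_folds` independent random train/validation resplits of the
#' development slides (the test set stays fixed), trains from scratch on each
#' with a fold-derived seed, and aggregates metrics as mean and SD.
#'
#' @param dataset a `synthetic_dataset` (or compatible list with `bags` and
#'   `manifest`).
#' @param trainer function `(train_bags, val_bags, test_bags, seed) ->`
#'   named numeric vector of metrics.
#' @param n_folds number of resplits (default 10).
#' @param val_fraction fraction of development slides used for validation in
#'   each resplit (default 0.25).
#' @param seed master seed; fold seeds are derived from it.
#' @return list `(per_fold` data.frame, `mean`, `sd)`.
#' @export
monte_carlo_cv <- function(dataset, trainer, n_folds = 10L,
                           val_fraction = 0.25, seed = 1L) {
  m <- dataset$manifest
  dev_ids <- m$slide_id[m$split %in% c("train", "val")]
  dev_labels <- m$label[match(dev_ids, m$slide_id)]
  test_ids <- m$slide_id[m$split == "test"]
  test_bags <- dataset$bags[test_ids]
  rows <- list()
  for (fold in seq_len(n_folds)) {
    fold_seed <- derive_seed(seed, "fold", fold)
    val_ids <- with_seed(fold_seed, {
      unlist(lapply(split(dev_ids, dev_labels), function(ids) {
        ids[sample.int(length(ids), max(1L, round(val_fraction * length(ids))))]
      }), use.names = FALSE)
    })
    train_ids <- setdiff(dev_ids, val_ids)
    metrics <- trainer(dataset$bags[train_ids], dataset$bags[val_ids],
                       test_bags, fold_seed)
    rows[[fold]] <- data.frame(fold = fold, t(metrics))
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_fold), "fold")
  list(per_fold = per_fold,
       mean = colMeans(per_fold[, metric_cols, drop = FALSE]),
       sd = if (n_folds > 1) apply(per_fold[, metric_cols, drop = FALSE], 2,
                                   stats::sd)
            else stats::setNames(rep(0, length(metric_cols)), metric_cols))
}
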