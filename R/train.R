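#' Training configuration
#'
#' Defaults follow the study protocol: Adam with learning rate 2e-4 and
#' weight decay 1e-5, up to 200 epochs, early stopping when the validation
#' loss has not improved for 7 consecutive epochs after an initial 20-epoch
#' warmup, one slide per optimization step.
#'
#' @param learning_rate Adam learning rate (default 2e-4).
#' @param weight_decay L2 weight decay (default 1e-5).
#' @param max_epochs epoch cap (default 200).
#' @param patience early-stopping patience in epochs (default 7).
#' @param warmup epochs before early stopping may trigger (default 20).
#' @param batch_size slides per optimizer step; variable bag sizes make one
#'   slide the natural unit (default 1; the only supported value).
#' @param seed master seed: initialization, shuffling and pair sampling are
#'   all derived from it, so a run is fully reproducible.
#' @param model a [model_config()]; `feature_dim` may be NA to infer from
#'   the data.
#' @param loss a [rank_loss_config()].
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 2e-4, weight_decay = 1e-5,
                         max_epochs = 200L, patience = 7L, warmup = 20L,
                         batch_size = 1L, seed = 1L,
                         model = NULL, loss = rank_loss_config()) {
  if (patience < 1) stop("patience must be >= 1")
  if (warmup >= max_epochs) stop("warmup must be smaller than max_epochs")
  if (batch_size != 1L) stop("only batch_size = 1 (one slide per step) is supported")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), warmup = as.integer(warmup),
                 batch_size = 1L, seed = as.integer(seed),
                 model = model, loss = loss),
            class = "train_config")
}

# Early-stopping state machine. Epochs <= warmup never increment the patience
# counter; any improvement resets it; training stops once `counter` reaches
# `patience`. With the last improvement at epoch `warmup + 1`, training stops
# at epoch warmup + 1 + patience.
early_stop_update <- function(state, val_loss, epoch, patience, warmup) {
  if (is.null(state)) state <- list(best = Inf, best_epoch = 0L,
                                    counter = 0L, stop = FALSE)
  if (val_loss < state$best) {
    state$best <- val_loss
    state$best_epoch <- epoch
    state$counter <- 0L
    state$improved <- TRUE
  } else {
    state$improved <- FALSE
    if (epoch > warmup) {
      state$counter <- state$counter + 1L
      if (state$counter >= patience) state$stop <- TRUE
    }
  }
  state
}

# Loss (and gradient step) bookkeeping for one bag. Returns updated model /
# optimizer and the loss components.
train_step <- function(model, opt, bag, config) {
  fwd <- bag_forward_train(model, bag$features)
  bce <- slide_bce(fwd$p, bag$slide_label)
  use_rank <- isTRUE(bag$annotated) && !is.null(bag$patch_labels) &&
    any(bag$patch_labels == 1L) && config$loss$weight > 0
  rank_component <- 0
  rank_grad <- NULL
  if (use_rank) {
    rl <- rank_loss(fwd$s, bag$patch_labels, config$loss)
    rank_component <- rl$loss
    rank_grad <- rank_loss_grad(fwd$s, rl, config$loss)
  }
  grads <- bag_backward(model, bag$features, bag$slide_label, fwd,
                        rank_grad = rank_grad,
                        rank_weight = config$loss$weight)
  step <- adam_step(model$pars, grads, opt,
                    lr = config$learning_rate,
                    weight_decay = config$weight_decay)
  model$pars <- step$pars
  list(model = model, opt = step$state,
       total = bce + config$loss$weight * rank_component,
       bce = bce, rank = rank_component)
}

# Mean loss components over a list of bags without updating parameters.
eval_loss <- function(model, bags, config) {
  comp <- vapply(bags, function(bag) {
    fwd <- bag_forward_train(model, bag$features)
    bce <- slide_bce(fwd$p, bag$slide_label)
    rank <- 0
    if (isTRUE(bag$annotated) && !is.null(bag$patch_labels) &&
        any(bag$patch_labels == 1L) && config$loss$weight > 0) {
      rank <- rank_loss(fwd$s, bag$patch_labels, config$loss)$loss
    }
    c(total = bce + config$loss$weight * rank, bce = bce, rank = rank)
  }, numeric(3))
  rowMeans(comp)
}

#' Train a rank-induction (or AB-MIL) model on bag lists
#'
#' Runs the full training protocol on in-memory bags: per-slide Adam steps,
#' rank loss on annotated positive slides (skipped automatically when
#' `loss$weight = 0`, giving the AB-MIL baseline), validation after every
#' epoch, and early stopping on the validation total loss. Returns the
#' checkpoint with the best validation loss.
#'
#' @param train_bags,val_bags named lists of [mil_bag()].
#' @param config a [train_config()].
#' @param verbose print per-epoch losses (default FALSE).
#' @return a `rank_mil_fit`: `model` (best checkpoint), `history`
#'   (per-epoch loss data.frame), `best_epoch`, `stopped_epoch`, `config`.
#' @export
train_model <- function(train_bags, val_bags, config = train_config(),
                        verbose = FALSE) {
  if (length(train_bags) == 0L) stop("empty training split")
  if (length(val_bags) == 0L) stop("empty validation split")
  D <- ncol(train_bags[[1]]$features)
  mcfg <- config$model %||% model_config(feature_dim = D)
  if (is.na(mcfg$feature_dim)) mcfg$feature_dim <- D
  model <- init_model(mcfg, seed = config$seed)
  opt <- adam_init(model$pars)
  history <- list()
  es <- NULL
  best_pars <- model$pars
  with_seed(derive_seed(config$seed, "loop"), {
    for (epoch in seq_len(config$max_epochs)) {
      order_idx <- sample.int(length(train_bags))
      tr <- c(total = 0, bce = 0, rank = 0)
      for (i in order_idx) {
        step <- train_step(model, opt, train_bags[[i]], config)
        model <- step$model
        opt <- step$opt
        tr <- tr + c(step$total, step$bce, step$rank)
      }
      tr <- tr / length(train_bags)
      if (!all(is.finite(tr)))
        stop("divergent training loss (non-finite) at epoch ", epoch)
      va <- eval_loss(model, val_bags, config)
      history[[epoch]] <- data.frame(
        epoch = epoch, train_total = tr[["total"]], train_bce = tr[["bce"]],
        train_rank = tr[["rank"]], val_total = va[["total"]],
        val_bce = va[["bce"]], val_rank = va[["rank"]])
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        tr[["total"]], va[["total"]]))
      es <- early_stop_update(es, va[["total"]], epoch,
                              config$patience, config$warmup)
      if (es$improved) best_pars <- model$pars
      if (es$stop) break
    }
  })
  model$pars <- best_pars
  structure(list(model = model,
                 history = do.call(rbind, history),
                 best_epoch = es$best_epoch,
                 stopped_epoch = nrow(do.call(rbind, history)),
                 config = config),
            class = "rank_mil_fit")
}

#' Train from a manifest of bag files
#'
#' Loads the `train` and `val` splits referenced by the manifest and calls
#' [train_model()].
#'
#' @param manifest an `mil_manifest` (or path to a manifest CSV).
#' @param config a [train_config()].
#' @param ... passed to [train_model()].
#' @return a `rank_mil_fit`.
#' @export
train <- function(manifest, config = train_config(), ...) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  m <- as.data.frame(manifest)
  if (!all(c("train", "val") %in% m$split))
    stop("manifest must contain train and val splits")
  train_model(load_bags(manifest, "train"), load_bags(manifest, "val"),
              config, ...)
}

#' Predict slide probabilities (and attention) for a set of bags
#'
#' @param model a `rank_mil_model` or `rank_mil_fit`.
#' @param bags named list of [mil_bag()] (or an `mil_manifest` plus `split`).
#' @param split optional split filter when `bags` is a manifest.
#' @return data.frame `(slide_id, prob, label)` with the per-slide softmax
#'   attention vectors `a` and thresholded vectors `abar` in
#'   `attr(, "attention")`.
#' @export
predict_bags <- function(model, bags, split = NULL) {
  if (inherits(model, "rank_mil_fit")) model <- model$model
  if (inherits(bags, "mil_manifest")) bags <- load_bags(bags, split)
  if (length(bags) == 0L) stop("no bags to predict")
  att <- list()
  rows <- lapply(names(bags), function(id) {
    bag <- bags[[id]]
    if (ncol(bag$features) != model$config$feature_dim)
      stop("feature dimension mismatch between bag and checkpoint")
    out <- forward(model, bag, training = FALSE)
    att[[id]] <<- list(a = out$state$a, abar = out$state$abar)
    data.frame(slide_id = id, prob = out$p, label = bag$slide_label)
  })
  res <- do.call(rbind, rows)
  attr(res, "attention") <- att
  res
}

#' Evaluate a trained model on a set of bags
#'
#' @param model a `rank_mil_model` or `rank_mil_fit`.
#' @param bags named list of [mil_bag()].
#' @param alphas localization alpha grid (positive annotated bags only);
#'   NULL skips localization.
#' @return list `(metrics, predictions, localization)`.
#' @export
evaluate_model <- function(model, bags, alphas = c(1, 5, 10, 20, 50, 75, 100)) {
  preds <- predict_bags(model, bags)
  metrics <- classification_metrics(preds$prob, preds$label)
  loc <- NULL
  if (!is.null(alphas)) {
    att <- attr(preds, "attention")
    pos <- Filter(function(id) {
      bag <- bags[[id]]
      bag$slide_label == 1L && !is.null(bag$patch_labels) &&
        any(bag$patch_labels == 1L)
    }, names(bags))
    if (length(pos)) {
      loc <- localization_report(
        lapply(stats::setNames(pos, pos), function(id) att[[id]]$a),
        lapply(stats::setNames(pos, pos), function(id) bags[[id]]$patch_labels),
        alphas = alphas)
    }
  }
  list(metrics = metrics, predictions = preds, localization = loc)
}

# Mean attention mass assigned to non-lesion patches on positive test
# slides, using the thresholded weights abar (T-ablation readout).
nonlesion_attention_mass <- function(model, bags) {
  if (inherits(model, "rank_mil_fit")) model <- model$model
  pos <- Filter(function(b) b$slide_label == 1L && !is.null(b$patch_labels),
                bags)
  if (length(pos) == 0L) return(NA_real_)
  mean(vapply(pos, function(bag) {
    out <- forward(model, bag, training = FALSE)
    sum(out$state$abar[bag$patch_labels == 0L])
  }, numeric(1)))
}

# Stratified subsample of a named bag list by slide label (low-data regime).
subsample_bags <- function(bags, fraction, seed) {
  labels <- vapply(bags, function(b) b$slide_label, integer(1))
  keep <- with_seed(derive_seed(seed, "lowdata"), {
    unlist(lapply(split(names(bags), labels), function(ids) {
      ids[sample.int(length(ids), max(1L, round(fraction * length(ids))))]
    }), use.names = FALSE)
  })
  bags[keep]
}

#' Run one of the study's experiment harnesses
#'
#' Each harness trains one model per grid point and fold on a (possibly
#' modified) copy of the dataset and evaluates it on the fixed test split.
#' Folds are Monte Carlo resplits of the development (train + validation)
#' slides with fold-derived seeds.
#'
#' * `low_data` — grid of training fractions; the training split is
#'   subsampled stratified by slide label.
#' * `granularity` — grid of label-dilation pads (patch widths) applied to
#'   annotated training positives via [coarsen_labels()].
#' * `subset_annotation` — grid of annotated fractions f applied via
#'   [subset_annotation()].
#' * `threshold_ablation` — grid of attention thresholds T; also reports the
#'   cumulative attention weight on non-lesion patches of positive test
#'   slides.
#' * `localization` — no grid; reports IoU/Dice/pointing aggregates per fold.
#'
#' @param kind experiment kind (see above).
#' @param grid numeric grid (ignored for `localization`).
#' @param dataset a `synthetic_dataset` (test split fixed).
#' @param config base [train_config()].
#' @param n_folds Monte Carlo folds per grid point (default 5).
#' @param out optional directory: writes `<kind>.csv` and the resolved
#'   configuration.
#' @return data.frame, one row per grid point and fold.
#' @export
run_experiment <- function(kind = c("low_data", "granularity",
                                    "subset_annotation", "threshold_ablation",
                                    "localization"),
                           grid, dataset, config = train_config(),
                           n_folds = 5L, out = NULL) {
  kind <- match.arg(kind)
  if (kind == "localization") grid <- NA_real_
  if (kind == "low_data" && any(grid <= 0 | grid > 1))
    stop("low_data fractions must lie in (0, 1]")
  if (kind == "subset_annotation" && any(grid < 0 | grid > 1))
    stop("annotated fractions must lie in [0, 1]")
  if (kind == "threshold_ablation" && any(grid < 0))
    stop("thresholds must be >= 0")
  if (kind == "granularity" && any(grid < 0))
    stop("pads must be >= 0")
  m <- dataset$manifest
  dev_ids <- m$slide_id[m$split %in% c("train", "val")]
  dev_labels <- m$label[match(dev_ids, m$slide_id)]
  test_bags <- dataset$bags[m$slide_id[m$split == "test"]]
  rows <- list()
  for (g in grid) {
    for (fold in seq_len(n_folds)) {
      fold_seed <- derive_seed(config$seed, kind, g, fold)
      val_ids <- with_seed(fold_seed, {
        unlist(lapply(split(dev_ids, dev_labels), function(ids) {
          ids[sample.int(length(ids), max(1L, round(0.25 * length(ids))))]
        }), use.names = FALSE)
      })
      train_ids <- setdiff(dev_ids, val_ids)
      train_bags <- dataset$bags[train_ids]
      val_bags <- dataset$bags[val_ids]
      cfg <- config
      cfg$seed <- fold_seed
      if (kind == "low_data" && g < 1)
        train_bags <- subsample_bags(train_bags, g, fold_seed)
      if (kind == "granularity" && g > 0) {
        train_bags <- lapply(train_bags, function(bag) {
          if (bag$slide_label == 1L && isTRUE(bag$annotated) &&
              !is.null(bag$patch_labels)) coarsen_labels(bag, g) else bag
        })
      }
      if (kind == "subset_annotation") {
        # the annotated fraction refers to the development positives as a
        # whole, so hiding spans both train and val slides
        sub <- subset_annotation(list(bags = dataset$bags, manifest = m),
                                 g, seed = fold_seed,
                                 splits = c("train", "val"))
        train_bags <- sub$bags[train_ids]
        val_bags <- sub$bags[val_ids]
      }
      if (kind == "threshold_ablation") {
        mc <- cfg$model %||% model_config(ncol(test_bags[[1]]$features))
        mc$threshold <- g
        cfg$model <- mc
      }
      fit <- train_model(train_bags, val_bags, cfg)
      ev <- evaluate_model(fit, test_bags,
                           alphas = if (kind == "localization")
                             c(1, 5, 10, 20, 50, 75, 100) else 100)
      row <- data.frame(kind = kind, grid = g, fold = fold,
                        auroc = ev$metrics$auroc, auprc = ev$metrics$auprc,
                        accuracy = ev$metrics$accuracy,
                        best_epoch = fit$best_epoch,
                        stopped_epoch = fit$stopped_epoch)
      if (!is.null(ev$localization)) {
        agg <- ev$localization$aggregate
        row$pointing_100 <- agg$pointing_accuracy[agg$alpha == 100]
        row$mean_iou_100 <- agg$mean_iou[agg$alpha == 100]
        row$mean_dice_100 <- agg$mean_dice[agg$alpha == 100]
      }
      if (kind == "threshold_ablation")
        row$nonlesion_attention <- nonlesion_attention_mass(fit, test_bags)
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res, file.path(out, paste0(kind, ".csv")),
                     row.names = FALSE)
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                                pretty = TRUE),
               file.path(out, paste0(kind, "_config.json")))
  }
  res
}
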