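#' Rank-loss configuration
#'
#' @param margin m, the score separation enforced between annotated and
#'   unannotated patches; `P_ij = 0.5` exactly when `s_i - s_j = m`
#'   (default 1).
#' @param scale sigma > 0, slope of the pairwise sigmoid (default 1).
#' @param weight lambda >= 0, weight of the rank loss in the total objective
#'   (default 1); `lambda = 0` reduces training to plain AB-MIL.
#' @param max_pos_samples,max_neg_samples per-slide caps on sampled annotated
#'   / unannotated patches (default 1024 each); pairs are the full Cartesian
#'   product of the two sampled sets.
#' @return a `rank_loss_config` list.
#' @export
rank_loss_config <- function(margin = 1, scale = 1, weight = 1,
                             max_pos_samples = 1024L, max_neg_samples = 1024L) {
  if (scale <= 0) stop("scale sigma must be > 0")
  if (weight < 0) stop("weight lambda must be >= 0")
  if (max_pos_samples < 1 || max_neg_samples < 1) stop("sampling caps must be >= 1")
  structure(list(margin = margin, scale = scale, weight = weight,
                 max_pos_samples = as.integer(max_pos_samples),
                 max_neg_samples = as.integer(max_neg_samples)),
            class = "rank_loss_config")
}

#' Pairwise ranking preference
#'
#' RankNet-style preference that patch i outranks patch j:
#' `P_ij = 1 / (1 + exp(-sigma * (s_i - s_j - m)))`. Strictly increasing in
#' `s_i - s_j`, equal to 0.5 exactly at `s_i - s_j = m`, and approaching a
#' step function at the margin as sigma grows.
#'
#' @param s_i,s_j raw attention scores (vectors recycle as usual).
#' @param margin m.
#' @param scale sigma.
#' @return probability in (0, 1).
#' @export
pairwise_preference <- function(s_i, s_j, margin = 1, scale = 1) {
  sigmoid(scale * (s_i - s_j - margin))
}

# Sample up to `cap` indices from idx without replacement (deterministic
# under the current RNG state); returns idx unchanged when within the cap.
sample_capped <- function(idx, cap) {
  if (length(idx) <= cap) idx else idx[sample.int(length(idx), cap)]
}

#' Pairwise rank loss over annotated / unannotated patches
#'
#' Builds the valid pair set `P = {(i, j) : y_i = 1, y_j = 0}` (same-class
#' pairs excluded) from up to `max_pos_samples` annotated and
#' `max_neg_samples` unannotated patches sampled without replacement, then
#' averages the binary cross-entropy of [pairwise_preference()] against the
#' ground-truth preference `P_bar_ij = 1`:
#' `L_rank = -(1/|P|) sum log P_ij`, computed stably as
#' `mean(softplus(-sigma (s_i - s_j - m)))`. The general two-term BCE is
#' implemented; the reduction to `-log P_ij` for `P_bar = 1` is exercised by
#' tests rather than assumed. Operates on raw (pre-softmax) scores.
#'
#' Bags whose labels are all one class yield no valid pairs; the loss is 0
#' with `skipped = TRUE`, mirroring the omission of the ranking term for
#' slides without annotated lesions.
#'
#' @param s raw attention scores, length K.
#' @param y binary patch labels, length K.
#' @param config a [rank_loss_config()].
#' @param target ground-truth preference `P_bar` for valid pairs (default 1).
#' @return list `(loss, pairs_used, skipped, pos_idx, neg_idx)`.
#' @export
rank_loss <- function(s, y, config = rank_loss_config(), target = 1) {
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  if (length(pos) == 0L || length(neg) == 0L)
    return(list(loss = 0, pairs_used = 0L, skipped = TRUE,
                pos_idx = integer(), neg_idx = integer()))
  pos <- sample_capped(pos, config$max_pos_samples)
  neg <- sample_capped(neg, config$max_neg_samples)
  # x[i, j] = sigma * (s_i - s_j - m) over the Cartesian pair set
  x <- config$scale * (outer(s[pos], s[neg], "-") - config$margin)
  # BCE against P_bar: -P_bar log P_ij - (1 - P_bar) log(1 - P_ij)
  loss <- mean(target * softplus(-x) + (1 - target) * softplus(x))
  list(loss = loss, pairs_used = length(pos) * length(neg), skipped = FALSE,
       pos_idx = pos, neg_idx = neg)
}

# Gradient of the (lambda-weighted) rank loss w.r.t. the raw scores, reusing
# the sampled index sets returned by rank_loss(). dL/ds_i = -sigma/|P| *
# sum_j sigmoid(-x_ij); dL/ds_j is the mirrored column sum.
rank_loss_grad <- function(s, rl, config) {
  g <- numeric(length(s))
  if (rl$skipped) return(g)
  pos <- rl$pos_idx; neg <- rl$neg_idx
  x <- config$scale * (outer(s[pos], s[neg], "-") - config$margin)
  sig <- sigmoid(-x)
  scale <- config$scale / (length(pos) * length(neg))
  g[pos] <- g[pos] - scale * rowSums(sig)
  g[neg] <- g[neg] + scale * colSums(sig)
  g
}

#' Slide-level binary cross-entropy
#'
#' `-(label log p + (1 - label) log(1 - p))` with p clamped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param p predicted slide probability.
#' @param label binary slide label.
#' @return non-negative loss.
#' @export
slide_bce <- function(p, label) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -(label * log(p) + (1 - label) * log(1 - p))
}

#' Total training objective for one bag
#'
#' `L = L_BCE + lambda L_rank`. The rank term is included only when the bag
#' is annotated and carries at least one positive patch label; negative
#' slides and unannotated positive slides contribute the slide-level BCE
#' only.
#'
#' @param bag an [mil_bag()].
#' @param model_output result of [forward()] (carries `p` and raw scores).
#' @param config a [rank_loss_config()].
#' @return list `(total, bce, rank, pairs_used, rank_skipped)`.
#' @export
total_loss <- function(bag, model_output, config = rank_loss_config()) {
  bce <- slide_bce(model_output$p, bag$slide_label)
  use_rank <- isTRUE(bag$annotated) && !is.null(bag$patch_labels) &&
    any(bag$patch_labels == 1L)
  if (use_rank && config$weight > 0) {
    rl <- rank_loss(model_output$state$s, bag$patch_labels, config)
    list(total = bce + config$weight * rl$loss, bce = bce, rank = rl$loss,
         pairs_used = rl$pairs_used, rank_skipped = rl$skipped)
  } else {
    list(total = bce, bce = bce, rank = 0, pairs_used = 0L,
         rank_skipped = TRUE)
  }
}
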