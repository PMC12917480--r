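#' Model configuration for the attention-MIL network
#'
#' @param feature_dim D, dimension of the per-patch feature vectors.
#' @param attention_hidden_dim width of the attention hidden layer (default 256).
#' @param gated use the gated tanh/sigmoid attention variant (default FALSE).
#' @param threshold attention threshold T (default 1). Softmax weights below
#'   `T / K` are zeroed and the survivors renormalized; `T = 0` disables
#'   thresholding. `T = 1` suppresses below-uniform weights.
#' @param apply_threshold_at_inference also threshold at inference time
#'   (default TRUE), keeping train and test pooling consistent.
#' @return a `model_config` list.
#' @export
model_config <- function(feature_dim,
                         attention_hidden_dim = 256L,
                         gated = FALSE,
                         threshold = 1,
                         apply_threshold_at_inference = TRUE) {
  stopifnot(feature_dim >= 1, attention_hidden_dim >= 1)
  if (threshold < 0) stop("threshold T must be >= 0")
  structure(list(feature_dim = as.integer(feature_dim),
                 attention_hidden_dim = as.integer(attention_hidden_dim),
                 gated = isTRUE(gated),
                 threshold = threshold,
                 apply_threshold_at_inference = isTRUE(apply_threshold_at_inference)),
            class = "model_config")
}

#' Initialize model parameters deterministically from a seed
#'
#' Attention scorer: `s_k = w' tanh(V z_k + b)` (optionally gated by
#' `sigmoid(U z_k + c)`); classifier: logistic regression on the attention-
#' pooled slide embedding. Weights use scaled Gaussian (Glorot-style)
#' initialization; biases start at zero.
#'
#' @param config a [model_config()].
#' @param seed integer seed.
#' @return a `rank_mil_model` with parameter matrices and the config.
#' @export
init_model <- function(config, seed = 1L) {
  D <- config$feature_dim
  H <- config$attention_hidden_dim
  with_seed(derive_seed(seed, "init"), {
    pars <- list(
      V = matrix(stats::rnorm(H * D, sd = sqrt(2 / (D + H))), H, D),
      b = numeric(H),
      w = stats::rnorm(H, sd = sqrt(1 / H)),
      cls_w = stats::rnorm(D, sd = sqrt(1 / D)) * 0.1,
      cls_b = 0
    )
    if (config$gated) {
      pars$U <- matrix(stats::rnorm(H * D, sd = sqrt(2 / (D + H))), H, D)
      pars$cg <- numeric(H)
    }
    structure(list(pars = pars, config = config), class = "rank_mil_model")
  })
}

#' @export
print.rank_mil_model <- function(x, ...) {
  cat(sprintf("<rank_mil_model> D=%d, hidden=%d, gated=%s, T=%g\n",
              x$config$feature_dim, x$config$attention_hidden_dim,
              x$config$gated, x$config$threshold))
  invisible(x)
}

# Hidden activations of the attention scorer; returns list(H, G) with G NULL
# when ungated. Kept internal so forward and backward share one definition.
attention_hidden <- function(features, pars, gated) {
  K <- nrow(features)
  # column-major recycling adds the bias per hidden unit without sweep()
  Hm <- tanh(tcrossprod(features, pars$V) + rep(pars$b, each = K))
  G <- NULL
  if (gated)
    G <- sigmoid(tcrossprod(features, pars$U) + rep(pars$cg, each = K))
  list(H = Hm, G = G)
}

#' Raw attention scores
#'
#' Computes `s_k = w' tanh(V z_k + b)` for every patch (two-layer tanh
#' attention; the gated variant multiplies in `sigmoid(U z_k + c)`).
#'
#' @param features K x D feature matrix.
#' @param model a `rank_mil_model` (or a bare parameter list plus `gated`).
#' @param gated override the gating flag (defaults to the model config).
#' @return numeric vector s of length K.
#' @export
attention_scores <- function(features, model, gated = NULL) {
  pars <- if (inherits(model, "rank_mil_model")) model$pars else model
  gated <- gated %||%
    (if (inherits(model, "rank_mil_model")) model$config$gated else FALSE)
  features <- as.matrix(features)
  if (ncol(features) != ncol(pars$V))
    stop("feature dimension mismatch: features have D=", ncol(features),
         ", model expects D=", ncol(pars$V))
  hid <- attention_hidden(features, pars, gated)
  Heff <- if (gated) hid$H * hid$G else hid$H
  drop(Heff %*% pars$w)
}

#' Softmax attention weights
#'
#' Max-stabilized softmax: `a_k = exp(s_k - max s) / sum_j exp(s_j - max s)`.
#'
#' @param s numeric vector of raw attention scores.
#' @return probability vector a with `sum(a) == 1`.
#' @export
softmax_weights <- function(s) {
  if (!all(is.finite(s))) stop("raw scores must be finite")
  e <- exp(s - max(s))
  e / sum(e)
}

#' Threshold and renormalize attention weights
#'
#' Zeroes softmax weights below `T / K` (T times the uniform weight) and
#' renormalizes the survivors:
#' `a_bar_k = a_k 1[a_k >= T/K] / sum_j a_j 1[a_j >= T/K]`.
#' `T = 0` is the identity. If no weight survives (large T on a flat
#' distribution), the single argmax weight is retained with weight 1, so the
#' result is never an all-zero vector. The boundary uses `>=`: a weight at
#' exactly `T/K` survives. The operation is idempotent.
#'
#' @param a probability vector (softmax weights).
#' @param threshold non-negative attention threshold T.
#' @return probability vector a_bar of the same length.
#' @export
threshold_renormalize <- function(a, threshold) {
  if (threshold < 0) stop("threshold T must be >= 0")
  if (threshold == 0) return(a)
  K <- length(a)
  keep <- a >= threshold / K
  if (!any(keep)) {
    abar <- numeric(K)
    abar[which.max(a)] <- 1
    return(abar)
  }
  abar <- a * keep
  abar / sum(abar)
}

#' Attention-weighted pooling and slide classification
#'
#' Slide embedding `M = sum_k a_bar_k z_k`, slide probability
#' `p = logistic(cls_w' M + cls_b)`.
#'
#' @param features K x D feature matrix.
#' @param abar probability vector of attention weights (length K).
#' @param model a `rank_mil_model` (or bare parameter list with cls_w, cls_b).
#' @return list with `p` (probability), `logit`, and `embedding` (length D).
#' @export
pool_and_classify <- function(features, abar, model) {
  pars <- if (inherits(model, "rank_mil_model")) model$pars else model
  features <- as.matrix(features)
  if (nrow(features) != length(abar))
    stop("length of attention weights must equal the number of patches")
  if (ncol(features) != length(pars$cls_w))
    stop("feature dimension mismatch with classifier weights")
  M <- drop(crossprod(features, abar))
  logit <- sum(pars$cls_w * M) + pars$cls_b
  list(p = sigmoid(logit), logit = logit, embedding = M)
}

#' Forward pass over one bag
#'
#' Deterministic composition: raw scores -> softmax -> threshold-renormalize
#' -> attention pooling -> slide probability. Returns the full attention state
#' so losses and localization metrics can consume raw scores `s`, softmax
#' weights `a`, and thresholded weights `abar`.
#'
#' @param model a `rank_mil_model`.
#' @param bag an [mil_bag()] (or a bare K x D feature matrix).
#' @param training logical; when FALSE and
#'   `config$apply_threshold_at_inference` is FALSE, thresholding is skipped.
#' @return list `(p, logit, state)` where `state` has class `attention_state`
#'   with fields `s`, `a`, `abar`, `threshold`.
#' @export
forward <- function(model, bag, training = TRUE) {
  features <- if (inherits(bag, "mil_bag")) bag$features else as.matrix(bag)
  s <- attention_scores(features, model)
  a <- softmax_weights(s)
  T_eff <- if (training || model$config$apply_threshold_at_inference)
    model$config$threshold else 0
  abar <- threshold_renormalize(a, T_eff)
  out <- pool_and_classify(features, abar, model)
  state <- structure(list(s = s, a = a, abar = abar, threshold = T_eff),
                     class = "attention_state")
  list(p = out$p, logit = out$logit, embedding = out$embedding, state = state)
}

#' Save / load a model checkpoint
#'
#' Single-file serialized parameter tree plus the model config.
#' @param model a `rank_mil_model`.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rank_mil_model")) stop("not a rank_mil_model checkpoint")
  model
}
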