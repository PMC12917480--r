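# Internal reverse-mode gradients for the attention-MIL network and a plain
# Adam optimizer. The forward used in training caches the hidden activations
# so backward never recomputes them.

# Forward pass that also returns hidden activations and the survivor set of
# the thresholding step (needed for the straight-through backward).
bag_forward_train <- function(model, features) {
  pars <- model$pars
  gated <- model$config$gated
  hid <- attention_hidden(features, pars, gated)
  Heff <- if (gated) hid$H * hid$G else hid$H
  s <- drop(Heff %*% pars$w)
  a <- softmax_weights(s)
  T_eff <- model$config$threshold
  K <- length(a)
  fallback <- FALSE
  if (T_eff > 0) {
    keep <- a >= T_eff / K
    if (!any(keep)) {
      keep <- seq_along(a) == which.max(a)
      fallback <- TRUE
    }
    abar <- a * keep
    abar <- abar / sum(abar)
  } else {
    keep <- rep(TRUE, K)
    abar <- a
  }
  M <- drop(crossprod(features, abar))
  logit <- sum(pars$cls_w * M) + pars$cls_b
  list(p = sigmoid(logit), logit = logit, s = s, a = a, abar = abar,
       keep = keep, fallback = fallback, H = hid$H, G = hid$G, M = M,
       threshold = T_eff)
}

# Gradient of L = BCE(p, label) + lambda * L_rank(s, y) w.r.t. all
# parameters, for one bag. `fwd` is the output of bag_forward_train();
# `rank_grad` is the (already lambda-weighted or raw) d L_rank / d s, or NULL.
# The thresholding indicator is treated as constant (straight-through):
# gradient flows through surviving weights only.
bag_backward <- function(model, features, label, fwd, rank_grad = NULL,
                         rank_weight = 1) {
  pars <- model$pars
  gated <- model$config$gated
  K <- nrow(features)

  dlogit <- fwd$p - label
  dcls_w <- dlogit * fwd$M
  dcls_b <- dlogit
  dM <- dlogit * pars$cls_w
  dabar <- drop(features %*% dM)

  if (fwd$threshold > 0) {
    if (fwd$fallback) {
      da <- numeric(K)                       # abar one-hot, locally constant
    } else {
      A <- sum(fwd$a[fwd$keep])
      da <- numeric(K)
      inner <- sum(dabar[fwd$keep] * fwd$abar[fwd$keep])
      da[fwd$keep] <- (dabar[fwd$keep] - inner) / A
    }
  } else {
    da <- dabar
  }
  # softmax Jacobian
  ds <- fwd$a * (da - sum(fwd$a * da))
  if (!is.null(rank_grad)) ds <- ds + rank_weight * rank_grad

  Heff <- if (gated) fwd$H * fwd$G else fwd$H
  dw <- drop(crossprod(Heff, ds))
  dsw <- outer(ds, pars$w)                   # K x H
  grads <- list(cls_w = dcls_w, cls_b = dcls_b, w = dw)
  if (gated) {
    dPreH <- dsw * fwd$G * (1 - fwd$H^2)
    dPreG <- dsw * fwd$H * fwd$G * (1 - fwd$G)
    grads$V <- crossprod(dPreH, features)
    grads$b <- colSums(dPreH)
    grads$U <- crossprod(dPreG, features)
    grads$cg <- colSums(dPreG)
  } else {
    dPre <- dsw * (1 - fwd$H^2)
    grads$V <- crossprod(dPre, features)
    grads$b <- colSums(dPre)
  }
  grads
}

adam_init <- function(pars) {
  list(m = lapply(pars, function(p) p * 0),
       v = lapply(pars, function(p) p * 0),
       t = 0L)
}

# One Adam step with L2 weight decay folded into the gradient.
adam_step <- function(pars, grads, state, lr = 2e-4, weight_decay = 1e-5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]] + weight_decay * pars[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    pars[[nm]] <- pars[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(pars = pars, state = state)
}
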