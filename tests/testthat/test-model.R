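test_that("attention scores follow the two-layer tanh form", {
  pars <- list(V = matrix(0, 3, 2), b = numeric(3), w = c(1, -2, 3),
               cls_w = numeric(2), cls_b = 0)
  Z <- matrix(rnorm(10), 5, 2)
  # zero map
  expect_equal(attention_scores(Z, pars), rep(0, 5))

  # closed form in one dimension: s = tanh(z)
  pars1 <- list(V = matrix(1, 1, 1), b = 0, w = 1, cls_w = 0, cls_b = 0)
  expect_equal(attention_scores(matrix(0, 1, 1), pars1), 0)
  expect_equal(attention_scores(matrix(50, 1, 1), pars1), 1, tolerance = 1e-12)

  # random instance against direct matrix arithmetic
  set.seed(11)
  V <- matrix(rnorm(12), 4, 3); b <- rnorm(4); w <- rnorm(4)
  Z <- matrix(rnorm(18), 6, 3)
  pars2 <- list(V = V, b = b, w = w, cls_w = numeric(3), cls_b = 0)
  manual <- vapply(1:6, function(k) sum(w * tanh(V %*% Z[k, ] + b)),
                   numeric(1))
  expect_equal(attention_scores(Z, pars2), manual, tolerance = 1e-6)

  expect_error(attention_scores(matrix(1, 2, 5), pars2), "dimension mismatch")
})

test_that("softmax weights are stable, normalized, and shift invariant", {
  expect_equal(softmax_weights(rep(0, 4)), rep(0.25, 4))
  a <- softmax_weights(c(1000, 0))
  expect_true(all(is.finite(a)))
  expect_equal(a[1], 1, tolerance = 1e-12)
  set.seed(21)
  for (i in 1:20) {
    s <- rnorm(sample(2:30, 1), sd = 5)
    expect_equal(sum(softmax_weights(s)), 1, tolerance = 1e-9)
    expect_equal(softmax_weights(s + runif(1, -100, 100)),
                 softmax_weights(s), tolerance = 1e-9)
  }
  expect_error(softmax_weights(c(1, NA)), "finite")
})

test_that("threshold-renormalize matches the hand-worked examples", {
  # uniform weights sit exactly at T/K and survive (>= boundary)
  expect_equal(threshold_renormalize(rep(0.25, 4), 1), rep(0.25, 4))
  # cutoff T/K = 0.25 removes the two smallest, survivors renormalized
  expect_equal(threshold_renormalize(c(0.4, 0.3, 0.2, 0.1), 1),
               c(4 / 7, 3 / 7, 0, 0))
  # cutoff 5/4 kills everything; fallback keeps the argmax patch
  expect_equal(threshold_renormalize(c(0.7, 0.1, 0.1, 0.1), 5),
               c(1, 0, 0, 0))
  # T = 0 is the exact identity
  a <- softmax_weights(rnorm(10))
  expect_identical(threshold_renormalize(a, 0), a)
  expect_error(threshold_renormalize(a, -1), "T must be >= 0")
})

test_that("thresholding is idempotent with shrinking survivor sets in T", {
  set.seed(31)
  for (i in 1:200) {
    a <- softmax_weights(rnorm(sample(2:50, 1), sd = 2))
    prev_surv <- Inf
    for (T in c(0, 0.25, 0.5, 1, 2, 5)) {
      ab <- threshold_renormalize(a, T)
      expect_gte(min(ab), 0)
      expect_equal(sum(ab), 1, tolerance = 1e-9)
      surv <- sum(ab > 0)
      expect_lte(surv, prev_surv)
      prev_surv <- surv
      expect_equal(threshold_renormalize(ab, T), ab, tolerance = 1e-12)
      if (T > 0 && surv > 1)
        expect_true(all(a[ab > 0] >= T / length(a)))
    }
  }
})

test_that("attention pooling selects, averages, and classifies as specified", {
  set.seed(41)
  Z <- matrix(rnorm(15), 5, 3)
  pars <- list(cls_w = rnorm(3), cls_b = 0.3)
  onehot <- c(0, 0, 1, 0, 0)
  out <- pool_and_classify(Z, onehot, pars)
  expect_equal(out$embedding, Z[3, ])

  # identical instances: embedding independent of the weights
  Zc <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  w1 <- c(0.7, 0.1, 0.1, 0.1); w2 <- rep(0.25, 4)
  expect_equal(pool_and_classify(Zc, w1, pars)$embedding,
               pool_and_classify(Zc, w2, pars)$embedding)

  # zero classifier gives p = 0.5
  expect_equal(pool_and_classify(Z, rep(0.2, 5), list(cls_w = numeric(3),
                                                      cls_b = 0))$p, 0.5)
  expect_error(pool_and_classify(Z, c(0.5, 0.5), pars), "number of patches")
})

test_that("forward is permutation invariant in p and equivariant in attention", {
  set.seed(51)
  for (i in 1:100) {
    K <- sample(2:25, 1); D <- sample(2:6, 1)
    model <- init_model(model_config(D, attention_hidden_dim = 16,
                                     threshold = sample(c(0, 1, 2), 1)),
                        seed = i)
    Z <- matrix(rnorm(K * D), K, D)
    perm <- sample.int(K)
    f1 <- forward(model, Z)
    f2 <- forward(model, Z[perm, , drop = FALSE])
    expect_equal(f2$p, f1$p, tolerance = 1e-10)
    expect_equal(f2$state$s, f1$state$s[perm], tolerance = 1e-10)
    expect_equal(f2$state$a, f1$state$a[perm], tolerance = 1e-10)
    expect_equal(f2$state$abar, f1$state$abar[perm], tolerance = 1e-10)
  }
})

test_that("forward handles K = 1 and differs between T = 0 and T > 0 only via abar", {
  model <- init_model(model_config(3, attention_hidden_dim = 8), seed = 1)
  z <- matrix(rnorm(3), 1, 3)
  f <- forward(model, z)
  expect_equal(f$state$abar, 1)
  expect_equal(f$p, pool_and_classify(z, 1, model$pars)$p)

  model0 <- model; model0$config$threshold <- 0
  Z <- matrix(rnorm(24), 8, 3)
  fT <- forward(model, Z); f0 <- forward(model0, Z)
  expect_equal(fT$state$s, f0$state$s)
  expect_equal(fT$state$a, f0$state$a)
  expect_false(isTRUE(all.equal(fT$state$abar, f0$state$abar)))
})

test_that("analytic gradients match finite differences on a 5-instance bag", {
  for (gated in c(FALSE, TRUE)) {
    set.seed(61 + gated)
    bag <- random_bag(K = 5, D = 4, label = 1)
    cfg <- model_config(4, attention_hidden_dim = 6, gated = gated,
                        threshold = 1)
    model <- init_model(cfg, seed = 3)
    lcfg <- rank_loss_config()
    loss_at <- function(pars) {
      m2 <- model; m2$pars <- pars
      fwd <- rankmil:::bag_forward_train(m2, bag$features)
      slide_bce(fwd$p, bag$slide_label) +
        lcfg$weight * rank_loss(fwd$s, bag$patch_labels, lcfg)$loss
    }
    fwd <- rankmil:::bag_forward_train(model, bag$features)
    rl <- rank_loss(fwd$s, bag$patch_labels, lcfg)
    rg <- rankmil:::rank_loss_grad(fwd$s, rl, lcfg)
    gr <- rankmil:::bag_backward(model, bag$features, bag$slide_label, fwd,
                                 rank_grad = rg, rank_weight = lcfg$weight)
    eps <- 1e-6
    for (nm in names(gr)) {
      num <- model$pars[[nm]]
      for (i in seq_along(num)) {
        pp <- model$pars; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- model$pars; pm[[nm]][i] <- pm[[nm]][i] - eps
        num[i] <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      }
      expect_equal(as.vector(gr[[nm]]), as.vector(num), tolerance = 1e-4,
                   info = paste("parameter", nm, "gated =", gated))
    }
  }
})

test_that("checkpoints round-trip through disk", {
  dir <- withr::local_tempdir()
  model <- init_model(model_config(5), seed = 9)
  p <- file.path(dir, "ckpt.rds")
  save_checkpoint(model, p)
  expect_identical(load_checkpoint(p), model)
  saveRDS(list(), p)
  expect_error(load_checkpoint(p), "not a rank_mil_model")
})
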