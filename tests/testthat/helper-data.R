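# Shared fixture builders: everything is generated in code at test time.

random_bag <- function(K = NULL, D = NULL, label = NULL, with_coords = TRUE) {
  K <- K %||% sample(1:20, 1)
  D <- D %||% sample(1:8, 1)
  label <- label %||% sample(0:1, 1)
  y <- if (label == 1L) {
    v <- integer(K)
    v[sample.int(K, max(1, rbinom(1, K - 1, 0.2)))] <- 1L
    v
  } else integer(K)
  side <- ceiling(sqrt(K))
  coords <- cbind(rep(seq_len(side), each = side)[seq_len(K)],
                  rep(seq_len(side), times = side)[seq_len(K)])
  mil_bag(slide_id = paste0("s", sample.int(1e6, 1)),
          features = matrix(rnorm(K * D), K, D),
          slide_label = label,
          patch_labels = y,
          patch_coords = if (with_coords) coords,
          annotated = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_spec <- function(seed = 1L, ...) {
  synthetic_spec(n_train = 14L, n_val = 6L, n_test = 20L,
                 k_range = c(20L, 40L), feature_dim = 8L,
                 separation = 3.0, seed = seed, ...)
}

tiny_train_config <- function(seed = 1L, lambda = 1, ...) {
  train_config(max_epochs = 12L, warmup = 3L, patience = 3L, seed = seed,
               model = model_config(feature_dim = 8L,
                                    attention_hidden_dim = 32L),
               loss = rank_loss_config(weight = lambda), ...)
}

split_bags <- function(ds) {
  m <- ds$manifest
  list(train = ds$bags[m$slide_id[m$split == "train"]],
       val = ds$bags[m$slide_id[m$split == "val"]],
       test = ds$bags[m$slide_id[m$split == "test"]])
}
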