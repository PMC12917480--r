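# Numerically stable log(1 + exp(x)).
softplus <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

sigmoid <- function(x) plogis(x)

# Derive a reproducible child seed (< 2^31) from a master seed and a tag.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) {
    for (ch in utf8ToInt(paste0(p))) h <- (h * 31 + ch) %% 2147483563
  }
  as.integer(h + 1L)
}

# Run code with a local RNG state derived from `seed`, restoring the caller's.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
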