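#' Specification for synthetic MIL bag generation
#'
#' The generator draws bags of Gaussian instances: every patch feature vector
#' is standard normal in D dimensions; in positive bags a spatially contiguous
#' blob of lesion patches receives an additional mean shift of `separation`
#' along a random unit direction fixed per dataset. Patch labels mark the
#' lesion instances; patches live on a virtual square grid so annotation
#' coarsening (label dilation) is meaningful. This emulates feature bags from
#' tessellated whole-slide images at a difficulty controlled by
#' `separation` and the lesion fraction.
#'
#' @param n_train,n_val,n_test slides per split (balanced across classes);
#'   defaults 60/20/40.
#' @param k_range bag-size range, patches per slide (default 100..300).
#' @param lesion_frac_range range of the lesion fraction for positive bags
#'   (default 0.02..0.10).
#' @param feature_dim D (default 32).
#' @param separation delta >= 0, mean shift of lesion instances (default 2).
#' @param noise_sd instance noise standard deviation (default 1).
#' @param annotated_fraction f in `[0, 1]`: fraction of positive slides whose
#'   patch labels are exposed to the trainer (default 1).
#' @param coarsening_pad label dilation radius in patch widths applied to
#'   annotated bags (default 0 = exact annotations).
#' @param seed integer master seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_train = 60L, n_val = 20L, n_test = 40L,
                           k_range = c(100L, 300L),
                           lesion_frac_range = c(0.02, 0.10),
                           feature_dim = 32L,
                           separation = 2.0,
                           noise_sd = 1.0,
                           annotated_fraction = 1.0,
                           coarsening_pad = 0L,
                           seed = 1L) {
  stopifnot(length(k_range) == 2, k_range[1] >= 1, k_range[2] >= k_range[1],
            length(lesion_frac_range) == 2)
  if (any(lesion_frac_range <= 0) || any(lesion_frac_range >= 1))
    stop("lesion fraction must lie strictly inside (0, 1)")
  if (separation < 0) stop("separation delta must be >= 0")
  if (annotated_fraction < 0 || annotated_fraction > 1)
    stop("annotated_fraction must lie in [0, 1]")
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test),
                 k_range = as.integer(k_range),
                 lesion_frac_range = lesion_frac_range,
                 feature_dim = as.integer(feature_dim),
                 separation = separation, noise_sd = noise_sd,
                 annotated_fraction = annotated_fraction,
                 coarsening_pad = as.integer(coarsening_pad),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Grow a contiguous blob of `n` cells on the set of occupied grid cells
# (4-neighborhood breadth-first growth from a random start, with randomized
# frontier order). `coords` is a K x 2 matrix of (row, col).
grow_blob <- function(coords, n) {
  K <- nrow(coords)
  key <- paste(coords[, 1], coords[, 2])
  index <- seq_len(K)
  names(index) <- key
  start <- sample.int(K, 1L)
  chosen <- logical(K)
  chosen[start] <- TRUE
  frontier <- start
  while (sum(chosen) < n && length(frontier) > 0) {
    cur <- frontier[1L]
    frontier <- frontier[-1L]
    nb <- cbind(coords[cur, 1] + c(-1L, 1L, 0L, 0L),
                coords[cur, 2] + c(0L, 0L, -1L, 1L))
    nb_idx <- index[paste(nb[, 1], nb[, 2])]
    nb_idx <- nb_idx[!is.na(nb_idx)]
    nb_idx <- nb_idx[!chosen[nb_idx]]
    if (length(nb_idx)) {
      nb_idx <- nb_idx[sample.int(length(nb_idx))]
      take <- utils::head(nb_idx, n - sum(chosen))
      chosen[take] <- TRUE
      frontier <- c(frontier, take)
    }
  }
  # isolated pockets can exhaust the frontier early; top up arbitrarily
  if (sum(chosen) < n) {
    rest <- which(!chosen)
    chosen[rest[sample.int(length(rest), n - sum(chosen))]] <- TRUE
  }
  which(chosen)
}

#' Generate one synthetic bag
#'
#' Uses the current RNG state; wrap in a seeded context (or use
#' [generate_dataset()]) for reproducibility. Positive bags always contain at
#' least one lesion patch.
#'
#' @param spec a [synthetic_spec()].
#' @param label slide label 0/1.
#' @param direction unit vector of length D giving the lesion mean-shift
#'   direction (fixed per dataset; drawn if NULL).
#' @param slide_id identifier for the bag.
#' @return an [mil_bag()] with grid coords and patch labels.
#' @export
generate_bag <- function(spec, label, direction = NULL, slide_id = "synthetic") {
  D <- spec$feature_dim
  if (is.null(direction)) {
    direction <- stats::rnorm(D)
    direction <- direction / sqrt(sum(direction^2))
  }
  K <- spec$k_range[1] + sample.int(spec$k_range[2] - spec$k_range[1] + 1L, 1L) - 1L
  side <- ceiling(sqrt(K))
  coords <- cbind(row = rep(seq_len(side), each = side)[seq_len(K)],
                  col = rep(seq_len(side), times = side)[seq_len(K)])
  features <- matrix(stats::rnorm(K * D, sd = spec$noise_sd), K, D)
  y <- integer(K)
  if (label == 1L) {
    frac <- stats::runif(1, spec$lesion_frac_range[1], spec$lesion_frac_range[2])
    n_lesion <- max(1L, round(frac * K))
    lesion <- grow_blob(coords, n_lesion)
    y[lesion] <- 1L
    features[lesion, ] <- features[lesion, , drop = FALSE] +
      rep(spec$separation * direction, each = length(lesion))
  }
  mil_bag(slide_id = slide_id, features = features, slide_label = label,
          patch_labels = y, patch_coords = coords, annotated = TRUE)
}

#' Generate a full synthetic dataset
#'
#' Splits are balanced across classes (odd counts give the extra slide to the
#' negative class). The lesion direction `u` is drawn once per dataset.
#' Annotation hiding (`annotated_fraction`) and label coarsening
#' (`coarsening_pad`) are applied to training-split positives only; validation
#' and test bags keep exact labels for evaluation.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `bags` (named list of `mil_bag`), `manifest`
#'   (split/label table without file paths), `direction`, and `spec`.
#' @export
generate_dataset <- function(spec) {
  with_seed(derive_seed(spec$seed, "dataset"), {
    direction <- stats::rnorm(spec$feature_dim)
    direction <- direction / sqrt(sum(direction^2))
    counts <- c(train = spec$n_train, val = spec$n_val, test = spec$n_test)
    bags <- list()
    rows <- list()
    for (split in names(counts)) {
      n <- counts[[split]]
      n_pos <- n %/% 2L
      labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
      for (i in seq_len(n)) {
        id <- sprintf("%s_%03d", split, i)
        bags[[id]] <- generate_bag(spec, labels[i], direction, slide_id = id)
        rows[[id]] <- data.frame(slide_id = id, label = labels[i],
                                 split = split, stringsAsFactors = FALSE)
      }
    }
    manifest <- do.call(rbind, rows)
    rownames(manifest) <- NULL
    ds <- list(bags = bags, manifest = manifest, direction = direction,
               spec = spec)
    class(ds) <- "synthetic_dataset"
    if (spec$coarsening_pad > 0) {
      for (id in manifest$slide_id[manifest$split == "train"])
        ds$bags[[id]] <- coarsen_labels(ds$bags[[id]], spec$coarsening_pad)
    }
    if (spec$annotated_fraction < 1) {
      ds <- subset_annotation(ds, spec$annotated_fraction,
                              seed = derive_seed(spec$seed, "subset"),
                              splits = "train")
    }
    ds
  })
}

#' Dilate patch labels on the virtual grid
#'
#' Marks as positive every patch within Chebyshev distance `pad_patches` of an
#' originally positive patch, emulating coarse (padded) expert annotations.
#' Original positives always remain positive, so the positive set is
#' non-decreasing in the pad.
#'
#' @param bag an [mil_bag()] with grid coords and patch labels.
#' @param pad_patches dilation radius in patch widths (>= 0).
#' @return the bag with dilated `patch_labels`.
#' @export
coarsen_labels <- function(bag, pad_patches) {
  if (pad_patches < 0) stop("pad_patches must be >= 0")
  if (is.null(bag$patch_coords)) stop("bag has no grid coords")
  if (is.null(bag$patch_labels)) stop("bag has no patch labels")
  if (pad_patches == 0 || !any(bag$patch_labels == 1L)) return(bag)
  pos <- bag$patch_coords[bag$patch_labels == 1L, , drop = FALSE]
  cheb <- function(i) {
    min(pmax(abs(pos[, 1] - bag$patch_coords[i, 1]),
             abs(pos[, 2] - bag$patch_coords[i, 2])))
  }
  d <- vapply(seq_len(nrow(bag$patch_coords)), cheb, numeric(1))
  bag$patch_labels <- as.integer(d <= pad_patches)
  bag
}

#' Hide patch annotations on a fraction of positive slides
#'
#' Exactly `round(f * n_pos)` positive slides (within the chosen splits) keep
#' `annotated = TRUE`; the rest have their patch labels hidden
#' (`patch_labels = NULL`, `annotated = FALSE`), contributing slide-level
#' supervision only. Negative slides are untouched.
#'
#' @param dataset a `synthetic_dataset` from [generate_dataset()].
#' @param fraction f in `[0, 1]`.
#' @param seed integer seed selecting which slides stay annotated.
#' @param splits which splits to affect (default `"train"`).
#' @return the modified dataset.
#' @export
subset_annotation <- function(dataset, fraction, seed = 1L, splits = "train") {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  m <- dataset$manifest
  pos_ids <- m$slide_id[m$label == 1L & m$split %in% splits]
  n_keep <- round(fraction * length(pos_ids))
  keep <- with_seed(derive_seed(seed, "subset_annotation"), {
    pos_ids[sample.int(length(pos_ids), n_keep)]
  })
  for (id in pos_ids) {
    if (!(id %in% keep)) {
      # keep the field present-but-NULL so bags stay structurally identical
      # across an HDF5 round trip
      dataset$bags[[id]]["patch_labels"] <- list(NULL)
      dataset$bags[[id]]$annotated <- FALSE
    }
  }
  dataset
}

#' Write a synthetic dataset to bag files plus a manifest CSV
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- dataset$manifest
  m$path <- paste0(m$slide_id, ".h5")
  m$annotated <- vapply(dataset$bags[m$slide_id], function(b) b$annotated,
                        logical(1))
  for (id in m$slide_id)
    write_bag(dataset$bags[[id]], file.path(dir, paste0(id, ".h5")))
  manifest_path <- file.path(dir, "manifest.csv")
  write_manifest(as_manifest(m), manifest_path)
  manifest_path
}

#' Load all bags referenced by a manifest
#'
#' @param manifest an `mil_manifest` (with resolvable paths).
#' @param split optional split tag filter.
#' @return named list of `mil_bag`.
#' @export
load_bags <- function(manifest, split = NULL) {
  m <- as.data.frame(manifest)
  if (!is.null(split)) m <- m[m$split %in% split, , drop = FALSE]
  bags <- lapply(m$path, read_bag)
  names(bags) <- m$slide_id
  bags
}
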