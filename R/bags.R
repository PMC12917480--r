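#' Construct a feature bag for one slide
#'
#' A bag holds the per-patch feature matrix of one whole-slide image together
#' with its slide-level label and, when available, per-patch annotation labels.
#' A slide is positive iff at least one patch contains a lesion; patch labels
#' `y_k = 1` mark patches overlapping an expert-annotated region.
#'
#' @param slide_id character scalar identifying the slide.
#' @param features numeric matrix, K patches by D feature dimensions.
#' @param slide_label 0 (normal) or 1 (abnormal).
#' @param patch_labels optional binary vector of length K. For a negative
#'   slide every entry must be 0.
#' @param patch_coords optional integer matrix K x 2 of (row, col) grid
#'   positions of each patch.
#' @param annotated logical: are `patch_labels` trusted expert annotations for
#'   this slide? Unannotated positive slides carry `patch_labels = NULL` and
#'   `annotated = FALSE`, which is distinct from an all-zero label vector.
#' @return an object of class `mil_bag`.
#' @export
mil_bag <- function(slide_id, features, slide_label,
                    patch_labels = NULL, patch_coords = NULL,
                    annotated = !is.null(patch_labels)) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  dimnames(features) <- NULL
  bag <- structure(list(
    slide_id = as.character(slide_id),
    features = features,
    slide_label = as.integer(slide_label),
    patch_labels = if (!is.null(patch_labels)) as.integer(patch_labels),
    patch_coords = if (!is.null(patch_coords)) {
      pc <- as.matrix(patch_coords); storage.mode(pc) <- "integer"
      dimnames(pc) <- NULL; pc
    },
    annotated = isTRUE(annotated)
  ), class = "mil_bag")
  validate_bag(bag)
  bag
}

#' Validate bag invariants
#'
#' Checks K >= 1, finite features, label/shape consistency, and that a
#' negative slide carries no positive patch labels. Errors name the offending
#' field rather than silently repairing.
#'
#' @param bag an `mil_bag`.
#' @return the bag, invisibly.
#' @export
validate_bag <- function(bag) {
  if (!inherits(bag, "mil_bag")) stop("not an 'mil_bag' object")
  K <- nrow(bag$features)
  if (is.null(K) || K < 1L) stop("features: bag must contain at least one patch (K >= 1)")
  if (!all(is.finite(bag$features)))
    stop("features: non-finite values are not allowed")
  if (!bag$slide_label %in% c(0L, 1L))
    stop("slide_label: must be 0 or 1")
  if (!is.null(bag$patch_labels)) {
    if (length(bag$patch_labels) != K)
      stop("patch_labels: length (", length(bag$patch_labels),
           ") must equal the number of patches K (", K, ")")
    if (!all(bag$patch_labels %in% c(0L, 1L)))
      stop("patch_labels: entries must be 0 or 1")
    if (bag$slide_label == 0L && any(bag$patch_labels == 1L))
      stop("patch_labels: a negative slide (slide_label = 0) cannot contain ",
           "positive patch labels")
  }
  if (!is.null(bag$patch_coords)) {
    if (nrow(bag$patch_coords) != K || ncol(bag$patch_coords) != 2L)
      stop("patch_coords: must be a K x 2 integer matrix")
  }
  invisible(bag)
}

#' @export
print.mil_bag <- function(x, ...) {
  cat(sprintf("<mil_bag> %s: K=%d patches, D=%d, slide_label=%d, annotated=%s",
              x$slide_id, nrow(x$features), ncol(x$features),
              x$slide_label, x$annotated))
  if (!is.null(x$patch_labels))
    cat(sprintf(", %d positive patches", sum(x$patch_labels)))
  cat("\n")
  invisible(x)
}

#' Write a bag to an HDF5 container file
#'
#' Layout: datasets `/features` (K x D, float64), optional `/patch_labels`
#' and `/coords`, plus root attributes `slide_id`, `slide_label`, `annotated`.
#' `read_bag()` reproduces the bag bit-exactly.
#'
#' @param bag an `mil_bag`.
#' @param path output file path (created or overwritten).
#' @return `path`, invisibly.
#' @export
write_bag <- function(bag, path) {
  validate_bag(bag)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist: ", dir)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(bag$features, path, "features")
  if (!is.null(bag$patch_labels))
    rhdf5::h5write(bag$patch_labels, path, "patch_labels")
  if (!is.null(bag$patch_coords))
    rhdf5::h5write(bag$patch_coords, path, "coords")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(bag$slide_id, fid, "slide_id")
  rhdf5::h5writeAttribute(bag$slide_label, fid, "slide_label")
  rhdf5::h5writeAttribute(as.integer(bag$annotated), fid, "annotated")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a bag from an HDF5 container file
#'
#' Inverse of [write_bag()]. All bag invariants are re-validated on load;
#' inconsistent files (e.g. a negative slide with a positive patch label, or
#' non-finite features) raise an error instead of being silently repaired.
#'
#' @param path file written by [write_bag()] or conforming to its layout.
#' @return an `mil_bag`.
#' @export
read_bag <- function(path) {
  if (!file.exists(path)) stop("missing bag file: ", path)
  contents <- tryCatch(rhdf5::h5ls(path, recursive = FALSE),
                       error = function(e) stop("corrupt bag file: ", path))
  names_present <- contents$name
  if (!"features" %in% names_present)
    stop("corrupt bag layout: no /features dataset in ", path)
  features <- rhdf5::h5read(path, "features")
  patch_labels <- if ("patch_labels" %in% names_present)
    as.integer(rhdf5::h5read(path, "patch_labels"))
  coords <- if ("coords" %in% names_present) {
    m <- rhdf5::h5read(path, "coords"); storage.mode(m) <- "integer"; m
  }
  fid <- rhdf5::H5Fopen(path)
  slide_id <- as.character(rhdf5::h5readAttributes(fid, "/")$slide_id)
  attrs <- rhdf5::h5readAttributes(fid, "/")
  rhdf5::H5Fclose(fid)
  mil_bag(slide_id = slide_id,
          features = features,
          slide_label = as.integer(attrs$slide_label),
          patch_labels = patch_labels,
          patch_coords = coords,
          annotated = as.integer(attrs$annotated) == 1L)
}

#' Load a slide manifest
#'
#' A manifest is a CSV with header `slide_id,path,label,annotated,split`
#' listing one row per slide. Relative bag paths are resolved against the
#' manifest's directory.
#'
#' @param path manifest CSV path.
#' @param check_paths verify every referenced bag file exists (default TRUE).
#' @return a data.frame of class `mil_manifest`.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("missing manifest: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("slide_id", "path", "label", "annotated", "split")
  if (!all(required %in% names(m)))
    stop("manifest must have columns ", paste(required, collapse = ","))
  m$slide_id <- as.character(m$slide_id)
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  as_manifest(m, check_paths = check_paths)
}

#' @rdname load_manifest
#' @param m a data.frame with the manifest columns.
#' @export
as_manifest <- function(m, check_paths = FALSE) {
  if (anyDuplicated(m$slide_id))
    stop("duplicate slide_id in manifest: ",
         paste(unique(m$slide_id[duplicated(m$slide_id)]), collapse = ", "))
  if (!all(m$label %in% c(0L, 1L))) stop("manifest labels must be 0/1")
  if (check_paths) {
    missing <- m$path[!file.exists(m$path)]
    if (length(missing))
      stop("manifest references missing bag files: ",
           paste(utils::head(missing, 3), collapse = ", "))
  }
  class(m) <- c("mil_manifest", "data.frame")
  m
}

#' Write a manifest CSV
#' @param manifest an `mil_manifest` (or compatible data.frame).
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest)[, c("slide_id", "path", "label",
                                               "annotated", "split")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Split a manifest into named fractions, stratified by slide label
#'
#' Assigns every slide to one of the named splits. The split is stratified by
#' `label`: within each class, slides are shuffled with `seed` and fractions
#' are realized by largest-remainder rounding, so class proportions are
#' preserved to within one slide per class. Deterministic given `seed`.
#'
#' @param manifest an `mil_manifest`.
#' @param fractions named numeric vector summing to 1, e.g.
#'   `c(train = 0.8, val = 0.2)`.
#' @param seed integer seed.
#' @return the manifest with its `split` column reassigned.
#' @export
split_manifest <- function(manifest, fractions, seed) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1 (got ", sum(fractions), ")")
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("fractions must be named by split")
  out <- as.data.frame(manifest)
  out$split <- NA_character_
  with_seed(derive_seed(seed, "split"), {
    for (cls in sort(unique(out$label))) {
      idx <- which(out$label == cls)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      base <- floor(fractions * n)
      rem <- n - sum(base)
      if (rem > 0) {
        extra <- order(-(fractions * n - base))[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      at <- 1L
      for (s in seq_along(fractions)) {
        take <- base[s]
        if (take > 0) {
          out$split[idx[at:(at + take - 1L)]] <- names(fractions)[s]
          at <- at + take
        }
      }
    }
  })
  as_manifest(out)
}
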