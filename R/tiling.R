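#' Polygon annotation container
#'
#' Expert lesion annotations for one slide: a list of polygons in pixel
#' coordinates (one coordinate frame / magnification per annotation object;
#' callers working across magnifications apply the scale factor themselves,
#' e.g. a factor of 2 between 40x polygon coordinates and 20x patch
#' coordinates).
#'
#' @param slide_id character scalar.
#' @param polygons list of polygons, each a list with numeric `x` and `y`
#'   vertex vectors (>= 3 vertices, non-negative coordinates).
#' @param class_tag annotation class label (default "lesion").
#' @return a `polygon_annotation`.
#' @export
polygon_annotation <- function(slide_id, polygons, class_tag = "lesion") {
  polygons <- lapply(polygons, function(p) {
    if (is.matrix(p)) p <- list(x = p[, 1], y = p[, 2])
    if (length(p$x) < 3 || length(p$y) != length(p$x))
      stop("each polygon needs >= 3 (x, y) vertices")
    if (any(p$x < 0) || any(p$y < 0))
      stop("polygon coordinates must be non-negative")
    list(x = as.numeric(p$x), y = as.numeric(p$y))
  })
  structure(list(slide_id = as.character(slide_id), polygons = polygons,
                 class_tag = class_tag),
            class = "polygon_annotation")
}

#' Read / write polygon annotations as JSON
#'
#' Format: `{"slide_id": ..., "polygons": [[[x, y], ...], ...], "class": ...}`.
#'
#' @param path JSON file path.
#' @export
read_annotation <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  polys <- lapply(j$polygons, function(p) list(x = p[, 1], y = p[, 2]))
  polygon_annotation(j$slide_id, polys, j$class %||% "lesion")
}

#' @rdname read_annotation
#' @param annotation a `polygon_annotation`.
#' @export
write_annotation <- function(annotation, path) {
  jsonlite::write_json(
    list(slide_id = annotation$slide_id,
         polygons = lapply(annotation$polygons, function(p) cbind(p$x, p$y)),
         class = annotation$class_tag),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Multilevel Otsu thresholds on a 256-bin histogram by dynamic programming:
# maximize the between-class variance sum_c w_c mu_c^2 over L-1 cut points.
# Returns the bin-value thresholds (upper bound of each class but the last).
multilevel_otsu_thresholds <- function(gray255, levels = 3L) {
  h <- tabulate(pmin(pmax(floor(gray255), 0), 255) + 1L, nbins = 256L)
  p <- h / sum(h)
  cw <- cumsum(p)
  cm <- cumsum(p * (0:255))
  class_score <- function(i, j) {            # bins i..j (1-based)
    w <- cw[j] - if (i > 1) cw[i - 1] else 0
    if (w <= 0) return(0)
    m <- cm[j] - if (i > 1) cm[i - 1] else 0
    m^2 / w
  }
  # S[[k]][j]: best score splitting bins 1..j into k classes; arg tracks cuts
  S <- matrix(-Inf, levels, 256L)
  arg <- matrix(0L, levels, 256L)
  for (j in 1:256) S[1, j] <- class_score(1, j)
  for (k in 2:levels) {
    for (j in k:256) {
      best <- -Inf; bt <- 0L
      for (t in (k - 1):(j - 1)) {
        v <- S[k - 1, t] + class_score(t + 1, j)
        if (v > best) { best <- v; bt <- t }
      }
      S[k, j] <- best
      arg[k, j] <- bt
    }
  }
  cuts <- integer(levels - 1)
  j <- 256L
  for (k in levels:2) {
    cuts[k - 1] <- arg[k, j]
    j <- arg[k, j]
  }
  cuts - 1L                                  # bin upper bounds as 0..255 values
}

#' Tissue-background segmentation by multilevel Otsu thresholding
#'
#' Converts the image to grayscale if needed, computes `levels - 1` Otsu
#' thresholds on the 256-bin histogram, and labels as tissue (foreground)
#' every pixel at or below the tissue/background boundary threshold — i.e.
#' darker than the white glass background. A constant image has no
#' background class and yields an empty mask with a warning.
#'
#' Two rules choose the boundary among the multilevel thresholds:
#' `"best_split"` (default) takes the candidate with maximal two-class
#' between-class variance, which picks the gap between tissue and background
#' on H&E-like trimodal histograms and degrades to plain Otsu behaviour on
#' bimodal images; `"below_top"` always takes the last threshold, so
#' foreground is every class below the brightest one (this over-segments
#' when the background mode itself gets split).
#'
#' @param image numeric matrix (grayscale) or H x W x 3 array (RGB, converted
#'   with luma weights); values in `[0, 1]` or `[0, 255]`.
#' @param levels number of Otsu classes L (default 3).
#' @param foreground_rule `"best_split"` or `"below_top"` (see above).
#' @return logical matrix, TRUE = tissue.
#' @export
tissue_mask <- function(image, levels = 3L,
                        foreground_rule = c("best_split", "below_top")) {
  foreground_rule <- match.arg(foreground_rule)
  if (length(dim(image)) == 3L)
    image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  gray <- as.matrix(image)
  if (max(gray) <= 1) gray <- gray * 255
  if (diff(range(gray)) < .Machine$double.eps * 255) {
    warning("constant image: no background class, returning empty mask")
    return(matrix(FALSE, nrow(gray), ncol(gray)))
  }
  cuts <- multilevel_otsu_thresholds(gray, levels = levels)
  cut <- if (foreground_rule == "below_top") {
    cuts[length(cuts)]
  } else {
    h <- tabulate(pmin(pmax(floor(gray), 0), 255) + 1L, nbins = 256L)
    p <- h / sum(h)
    cw <- cumsum(p); cm <- cumsum(p * (0:255))
    two_class <- vapply(cuts, function(t) {
      w0 <- cw[t + 1L]
      if (w0 <= 0 || w0 >= 1) return(-Inf)
      (cm[256] * w0 - cm[t + 1L])^2 / (w0 * (1 - w0))
    }, numeric(1))
    cuts[which.max(two_class)]
  }
  gray <= cut
}

#' Tessellate an image into patches and filter by tissue coverage
#'
#' Lays a regular grid of `patch_size` tiles (half-open `[x0, x0 + patch_size)`
#' in 0-based pixel coordinates; only tiles fully inside the image) and
#' retains exactly the tiles whose mask coverage is `>= min_tissue_fraction`
#' ("less than 5% tissue" is discarded). Tiles are emitted in row-major
#' raster order.
#'
#' @param mask logical matrix from [tissue_mask()] (rows = y, cols = x).
#' @param patch_size tile side in pixels (default 224).
#' @param stride tile stride (default `patch_size`, nonoverlapping).
#' @param min_tissue_fraction coverage cutoff in `[0, 1]` (default 0.05).
#' @return a `tile_grid`: list with `patch_size`, `stride`, and `tiles`, a
#'   data.frame `(row, col, x0, y0, coverage)` of retained tiles.
#' @export
tessellate_and_filter <- function(mask, patch_size = 224L, stride = patch_size,
                                  min_tissue_fraction = 0.05) {
  stopifnot(stride >= 1)
  if (min_tissue_fraction < 0 || min_tissue_fraction > 1)
    stop("min_tissue_fraction must lie in [0, 1]")
  H <- nrow(mask); W <- ncol(mask)
  empty <- data.frame(row = integer(), col = integer(), x0 = integer(),
                      y0 = integer(), coverage = numeric())
  if (patch_size > H || patch_size > W) {
    warning("patch_size exceeds image dimensions: zero tiles")
    return(structure(list(patch_size = patch_size, stride = stride,
                          tiles = empty), class = "tile_grid"))
  }
  ys <- seq(0L, H - patch_size, by = stride)
  xs <- seq(0L, W - patch_size, by = stride)
  rows <- list()
  for (r in seq_along(ys)) {
    for (cc in seq_along(xs)) {
      y0 <- ys[r]; x0 <- xs[cc]
      cov <- mean(mask[(y0 + 1):(y0 + patch_size), (x0 + 1):(x0 + patch_size)])
      if (cov >= min_tissue_fraction)
        rows[[length(rows) + 1L]] <- data.frame(row = r, col = cc,
                                                x0 = x0, y0 = y0,
                                                coverage = cov)
    }
  }
  tiles <- if (length(rows)) do.call(rbind, rows) else empty
  structure(list(patch_size = patch_size, stride = stride, tiles = tiles),
            class = "tile_grid")
}

# Shoelace area of one polygon path.
path_area <- function(p) {
  x <- p$x; y <- p$y
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Area of (tile rectangle) intersect (union of polygons).
rect_polys_overlap_area <- function(x0, y0, size, polygons) {
  rect <- list(x = c(x0, x0 + size, x0 + size, x0),
               y = c(y0, y0, y0 + size, y0 + size))
  inter <- polyclip::polyclip(list(rect), polygons, op = "intersection",
                              fillA = "nonzero", fillB = "nonzero")
  if (length(inter) == 0) 0 else sum(vapply(inter, path_area, numeric(1)))
}

#' Label tiles by overlap with annotated polygons
#'
#' `y_k = 1` iff the tile rectangle and the union of annotation polygons
#' intersect with strictly positive area (a polygon merely touching a tile
#' edge does not label it). A configurable minimum overlap fraction of the
#' tile area is exposed; the default 0 keeps the any-positive-area rule.
#' Grid and polygons must share one coordinate frame; if every polygon's
#' bounding box falls wholly outside the tiled region a coordinate-frame
#' mismatch warning is raised.
#'
#' @param grid a `tile_grid`.
#' @param annotation a [polygon_annotation()] (or NULL for all-zero labels).
#' @param min_overlap_frac minimum overlap as a fraction of tile area
#'   (default 0 = any positive area).
#' @return integer 0/1 vector, one entry per retained tile.
#' @export
label_patches <- function(grid, annotation, min_overlap_frac = 0) {
  n <- nrow(grid$tiles)
  if (is.null(annotation) || length(annotation$polygons) == 0L)
    return(integer(n))
  if (n > 0L) {
    ps <- grid$patch_size
    xmax <- max(grid$tiles$x0) + ps; ymax <- max(grid$tiles$y0) + ps
    inside <- vapply(annotation$polygons, function(p) {
      max(p$x) > min(grid$tiles$x0) && min(p$x) < xmax &&
        max(p$y) > min(grid$tiles$y0) && min(p$y) < ymax
    }, logical(1))
    if (!any(inside))
      warning("possible coordinate-frame mismatch: every polygon lies ",
              "outside the tiled region")
  }
  tol <- 1e-9
  vapply(seq_len(n), function(k) {
    area <- rect_polys_overlap_area(grid$tiles$x0[k], grid$tiles$y0[k],
                                    grid$patch_size, annotation$polygons)
    cutoff <- max(tol, min_overlap_frac * grid$patch_size^2)
    as.integer(area >= cutoff && area > tol)
  }, integer(1))
}

#' Pad polygon annotations outward
#'
#' Replaces every polygon by its outward Euclidean buffer (Minkowski dilation
#' with a disc of radius `padding_px`, round joins). Padding 0 is the exact
#' identity. Dilation never shrinks the annotated region, so downstream patch
#' labels are monotone non-decreasing in the padding.
#'
#' @param annotation a [polygon_annotation()].
#' @param padding_px buffer radius in pixels (>= 0).
#' @return a `polygon_annotation` with buffered polygons.
#' @export
pad_annotation <- function(annotation, padding_px) {
  if (padding_px < 0) stop("padding must be >= 0")
  if (padding_px == 0) return(annotation)
  buffered <- polyclip::polyoffset(annotation$polygons, padding_px,
                                   jointype = "round")
  buffered <- lapply(buffered, function(p) {
    list(x = pmax(p$x, 0), y = pmax(p$y, 0))   # stay in the image quadrant
  })
  structure(list(slide_id = annotation$slide_id, polygons = buffered,
                 class_tag = annotation$class_tag),
            class = "polygon_annotation")
}

#' Build a feature bag from a raster image
#'
#' Composition of the preprocessing pipeline: tissue masking, tessellation
#' with coverage filtering, polygon-based patch labeling, and per-patch
#' feature extraction via a pluggable `feature_fn` (e.g. a CNN embedding;
#' tests use synthetic feature functions).
#'
#' @param image grayscale matrix or RGB array.
#' @param feature_fn function mapping a patch pixel matrix to a fixed-length
#'   finite numeric vector.
#' @param annotation optional [polygon_annotation()]; when supplied, patch
#'   labels come from [label_patches()] and the slide is positive iff any
#'   patch is.
#' @param slide_label slide label when `annotation` is NULL.
#' @param slide_id identifier (default "image").
#' @param patch_size,stride,min_tissue_fraction,otsu_levels see
#'   [tessellate_and_filter()] and [tissue_mask()].
#' @param min_overlap_frac see [label_patches()].
#' @return an [mil_bag()].
#' @export
build_bag_from_image <- function(image, feature_fn, annotation = NULL,
                                 slide_label = NULL, slide_id = "image",
                                 patch_size = 224L, stride = patch_size,
                                 min_tissue_fraction = 0.05,
                                 otsu_levels = 3L, min_overlap_frac = 0) {
  mask <- tissue_mask(image, levels = otsu_levels)
  grid <- tessellate_and_filter(mask, patch_size = patch_size,
                                stride = stride,
                                min_tissue_fraction = min_tissue_fraction)
  if (nrow(grid$tiles) == 0L) stop("empty bag: no tiles passed tissue filtering")
  if (length(dim(image)) == 3L)
    image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  feats <- lapply(seq_len(nrow(grid$tiles)), function(k) {
    x0 <- grid$tiles$x0[k]; y0 <- grid$tiles$y0[k]
    v <- feature_fn(image[(y0 + 1):(y0 + patch_size),
                          (x0 + 1):(x0 + patch_size), drop = FALSE])
    if (!all(is.finite(v))) stop("feature_fn returned non-finite values")
    v
  })
  dlen <- unique(lengths(feats))
  if (length(dlen) != 1L) stop("feature_fn must return fixed-length vectors")
  features <- do.call(rbind, feats)
  y <- if (!is.null(annotation))
    label_patches(grid, annotation, min_overlap_frac) else NULL
  label <- if (!is.null(y) && any(y == 1L)) 1L
           else if (!is.null(slide_label)) as.integer(slide_label)
           else if (!is.null(y)) 0L
           else stop("supply either an annotation or a slide_label")
  mil_bag(slide_id = slide_id, features = features, slide_label = label,
          patch_labels = if (!is.null(annotation)) y,
          patch_coords = cbind(grid$tiles$row, grid$tiles$col),
          annotated = !is.null(annotation))
}
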