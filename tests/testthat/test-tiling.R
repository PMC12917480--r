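test_that("multilevel Otsu recovers a dark disc on a white background", {
  # synthetic bimodal image: disc of value 80 on background 250
  H <- 120; W <- 120
  img <- matrix(250, H, W)
  cx <- 60; cy <- 60; r <- 30
  for (y in 1:H) for (x in 1:W)
    if ((x - cx)^2 + (y - cy)^2 <= r^2) img[y, x] <- 80
  img <- img + matrix(rnorm(H * W, sd = 3), H, W)
  mask <- tissue_mask(img, levels = 3)

  # oracle: direct 2-class Otsu threshold on the bimodal histogram
  ref <- if (requireNamespace("EBImage", quietly = TRUE)) {
    img01 <- pmin(pmax(img / 255, 0), 1)
    img01 < EBImage::otsu(EBImage::Image(t(img01)), range = c(0, 1))
  } else {
    img < 165   # midpoint threshold: modes are far apart
  }
  agreement <- mean(mask == ref)
  expect_gt(agreement, 0.98)
})

test_that("degenerate images yield empty masks", {
  expect_warning(m1 <- tissue_mask(matrix(1, 10, 10)), "constant")
  expect_false(any(m1))
  expect_warning(m2 <- tissue_mask(matrix(0, 10, 10)), "constant")
  expect_false(any(m2))
  # RGB input converts to grayscale first
  rgb <- array(runif(5 * 5 * 3), c(5, 5, 3))
  expect_silent(tissue_mask(rgb))
})

test_that("tessellation keeps tiles at the >= coverage boundary", {
  # fully-tissue 448x448 image tiles into exactly 4 nonoverlapping 224 tiles
  grid <- tessellate_and_filter(matrix(TRUE, 448, 448))
  expect_identical(nrow(grid$tiles), 4L)
  expect_identical(grid$tiles$x0, c(0L, 224L, 0L, 224L))
  expect_identical(grid$tiles$y0, c(0L, 0L, 224L, 224L))

  # coverage exactly at the cutoff survives; just below is dropped
  ps <- 20L
  n_px <- ps * ps
  mk <- function(n_true) {
    m <- matrix(FALSE, ps, ps); if (n_true > 0) m[seq_len(n_true)] <- TRUE; m
  }
  at <- tessellate_and_filter(mk(ceiling(0.05 * n_px)), patch_size = ps)
  expect_identical(nrow(at$tiles), 1L)
  below <- tessellate_and_filter(mk(ceiling(0.05 * n_px) - 1L),
                                 patch_size = ps)
  expect_identical(nrow(below$tiles), 0L)

  # empty mask and oversized patches give zero tiles
  expect_identical(nrow(tessellate_and_filter(matrix(FALSE, 300, 300))$tiles),
                   0L)
  expect_warning(
    g <- tessellate_and_filter(matrix(TRUE, 100, 100), patch_size = 224),
    "exceeds")
  expect_identical(nrow(g$tiles), 0L)
})

test_that("tessellation agrees with brute-force pixel counting (fuzz)", {
  set.seed(301)
  for (i in 1:50) {
    H <- sample(30:70, 1); W <- sample(30:70, 1); ps <- sample(c(8L, 12L), 1)
    cutoff <- runif(1, 0.01, 0.5)
    mask <- matrix(runif(H * W) < runif(1, 0.05, 0.6), H, W)
    grid <- tessellate_and_filter(mask, patch_size = ps,
                                  min_tissue_fraction = cutoff)
    # oracle: double loop over all tile positions, counting mask pixels
    expected <- 0L
    for (y0 in seq(0L, H - ps, by = ps)) for (x0 in seq(0L, W - ps, by = ps)) {
      cnt <- 0L
      for (yy in (y0 + 1):(y0 + ps)) for (xx in (x0 + 1):(x0 + ps))
        cnt <- cnt + mask[yy, xx]
      if (cnt / ps^2 >= cutoff) expected <- expected + 1L
    }
    expect_identical(nrow(grid$tiles), expected)
    expect_lte(nrow(grid$tiles), floor(W / ps) * floor(H / ps))
  }
})

test_that("patch labeling uses the strictly-positive-area overlap rule", {
  grid <- tessellate_and_filter(matrix(TRUE, 20, 20), patch_size = 10)
  expect_identical(nrow(grid$tiles), 4L)
  sq <- function(x0, y0, x1, y1)
    list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))

  # polygon inside tile 1 only
  ann <- polygon_annotation("s", list(sq(2, 2, 8, 8)))
  expect_identical(label_patches(grid, ann), c(1L, 0L, 0L, 0L))

  # polygon sharing only an edge with tile 2: zero area, no label
  edge <- polygon_annotation("s", list(sq(10, 12, 10, 18)))
  expect_error(polygon_annotation("s", list(list(x = c(10, 10), y = c(12, 18)))),
               ">= 3")
  touching <- polygon_annotation("s", list(sq(5, 12, 10, 18)))
  expect_identical(label_patches(grid, touching), c(0L, 0L, 1L, 0L))

  # polygon covering the whole image labels every tile
  full <- polygon_annotation("s", list(sq(0, 0, 20, 20)))
  expect_identical(label_patches(grid, full), rep(1L, 4L))

  # absent annotation: all-zero labels
  expect_identical(label_patches(grid, NULL), rep(0L, 4L))

  # polygons wholly outside the tiled region: frame-mismatch warning
  far <- polygon_annotation("s", list(sq(500, 500, 600, 600)))
  expect_warning(y <- label_patches(grid, far), "mismatch")
  expect_identical(y, rep(0L, 4L))
})

test_that("patch labeling agrees with exact rectangle arithmetic (fuzz)", {
  set.seed(311)
  for (i in 1:50) {
    ps <- 10L
    side <- sample(3:5, 1)
    grid <- tessellate_and_filter(matrix(TRUE, side * ps, side * ps),
                                  patch_size = ps)
    # random axis-aligned rectangle with continuous coordinates
    x0 <- runif(1, 0, side * ps - 1); y0 <- runif(1, 0, side * ps - 1)
    x1 <- x0 + runif(1, 0.5, 20); y1 <- y0 + runif(1, 0.5, 20)
    ann <- polygon_annotation("r", list(
      list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))))
    got <- label_patches(grid, ann)
    # oracle: closed-form rectangle-rectangle intersection area
    expected <- vapply(seq_len(nrow(grid$tiles)), function(k) {
      tx0 <- grid$tiles$x0[k]; ty0 <- grid$tiles$y0[k]
      w <- min(x1, tx0 + ps) - max(x0, tx0)
      h <- min(y1, ty0 + ps) - max(y0, ty0)
      as.integer(w > 1e-9 && h > 1e-9)
    }, integer(1))
    expect_identical(got, expected)
  }
})

test_that("patch labeling agrees with point-in-polygon rasterization on triangles", {
  skip_if_not_installed("sp")
  set.seed(321)
  for (i in 1:20) {
    ps <- 10L
    grid <- tessellate_and_filter(matrix(TRUE, 40, 40), patch_size = ps)
    tri <- list(x = runif(3, 0, 40), y = runif(3, 0, 40))
    ann <- polygon_annotation("t", list(tri))
    got <- label_patches(grid, ann)
    for (k in seq_len(nrow(grid$tiles))) {
      # subpixel raster of the tile: fraction of points inside the triangle
      gx <- seq(grid$tiles$x0[k] + 0.125, grid$tiles$x0[k] + ps - 0.125,
                by = 0.25)
      gy <- seq(grid$tiles$y0[k] + 0.125, grid$tiles$y0[k] + ps - 0.125,
                by = 0.25)
      pts <- expand.grid(x = gx, y = gy)
      inside <- sp::point.in.polygon(pts$x, pts$y, tri$x, tri$y) > 0
      raster_area <- sum(inside) * 0.25^2
      # the two routes may only disagree on sub-raster slivers
      if (raster_area > 0.5) expect_identical(got[k], 1L)
      if (got[k] == 0L) expect_lt(raster_area, 0.5)
    }
  }
})

test_that("annotation padding buffers outward and is monotone", {
  sq <- polygon_annotation("s", list(
    list(x = c(100, 200, 200, 100), y = c(100, 100, 200, 200))))
  # padding 0 is the identity
  expect_identical(pad_annotation(sq, 0), sq)
  expect_error(pad_annotation(sq, -3), ">= 0")

  pad <- pad_annotation(sq, 448)
  area0 <- rankmil:::path_area(sq$polygons[[1]])
  area1 <- sum(vapply(pad$polygons, rankmil:::path_area, numeric(1)))
  expect_gt(area1, area0)
  # the buffered square of side 100 with radius 448 contains the square
  # grown by 448 on each side except the rounded corners; check the
  # axis-extremes reach 100 - 448 (clipped to 0) and 200 + 448
  xs <- unlist(lapply(pad$polygons, `[[`, "x"))
  ys <- unlist(lapply(pad$polygons, `[[`, "y"))
  expect_equal(max(xs), 648, tolerance = 1)
  expect_equal(max(ys), 648, tolerance = 1)
  expect_equal(min(xs), 0, tolerance = 1)

  # area oracle: rounded-corner buffer of a convex polygon
  small <- polygon_annotation("s", list(
    list(x = c(50, 150, 150, 50), y = c(50, 50, 150, 150))))
  r <- 20
  buf <- pad_annotation(small, r)
  buf_area <- sum(vapply(buf$polygons, rankmil:::path_area, numeric(1)))
  exact <- 100^2 + 4 * 100 * r + pi * r^2
  expect_equal(buf_area, exact, tolerance = 0.01 * exact)

  # monotonicity of downstream labels in the padding
  grid <- tessellate_and_filter(matrix(TRUE, 40, 40), patch_size = 10)
  set.seed(331)
  for (i in 1:10) {
    tri <- polygon_annotation("t", list(list(x = runif(3, 0, 40),
                                             y = runif(3, 0, 40))))
    prev <- which(label_patches(grid, tri) == 1L)
    for (padding in c(2, 5, 10, 40)) {
      cur <- which(label_patches(grid, pad_annotation(tri, padding)) == 1L)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
    # saturation: a huge buffer covers every tile
    expect_identical(label_patches(grid, pad_annotation(tri, 100)),
                     rep(1L, nrow(grid$tiles)))
  }
})

test_that("bags compose from images, polygons, and a feature function", {
  # checkerboard-ish tissue: dark tissue block occupying the top-left 30x30
  img <- matrix(250, 40, 40)
  img[1:30, 1:30] <- 80
  img <- img + matrix(rnorm(1600, sd = 2), 40, 40)
  feat <- function(patch) c(mean(patch), sd(patch), min(patch), max(patch))
  ann <- polygon_annotation("im", list(
    list(x = c(1, 9, 9, 1), y = c(1, 1, 9, 9))))
  bag <- build_bag_from_image(img, feat, annotation = ann, slide_id = "im",
                              patch_size = 10L)
  # 3x3 tiles of tissue survive the 5% filter; only tile (1,1) is annotated
  expect_s3_class(bag, "mil_bag")
  expect_identical(nrow(bag$features), 9L)
  expect_identical(ncol(bag$features), 4L)
  expect_identical(bag$slide_label, 1L)
  expect_identical(sum(bag$patch_labels), 1L)
  expect_identical(bag$patch_labels[1], 1L)
  expect_true(bag$annotated)

  # no tissue at all: empty bag error
  expect_error(
    suppressWarnings(build_bag_from_image(matrix(200, 40, 40), feat,
                                          slide_label = 0)),
    "empty bag")

  # no annotation, caller-supplied negative label
  bag0 <- build_bag_from_image(img, feat, slide_label = 0, patch_size = 10L)
  expect_identical(bag0$slide_label, 0L)
  expect_null(bag0$patch_labels)
  expect_false(bag0$annotated)
})

test_that("polygon annotations round-trip through JSON", {
  dir <- withr::local_tempdir()
  ann <- polygon_annotation("s9", list(
    list(x = c(0, 10, 5.5), y = c(0, 0, 8.25)),
    list(x = c(20, 30, 30, 20), y = c(20, 20, 30, 30))), "tumor")
  p <- file.path(dir, "ann.json")
  write_annotation(ann, p)
  back <- read_annotation(p)
  expect_equal(back$polygons, ann$polygons)
  expect_identical(back$slide_id, "s9")
  expect_identical(back$class_tag, "tumor")
})
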