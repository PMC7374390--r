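test_that("hue rotation maps red to 90 degrees and is invertible", {
  red <- flat_rgb(1, 0, 0)
  expect_true(all(abs(rotate_hue(red)$h - 90) < 1e-9))
  green <- flat_rgb(0, 1, 0) # hue 120
  expect_true(all(abs(rotate_hue(green)$h - 210) < 1e-9))

  pep <- test_pepper(0.5, seed = 17)
  rv <- render_viewpoint(pep, "side1", "robotic", small_opts())
  rot <- rotate_hue(rv$rgb, 90)
  back <- (rot$h - 90) %% 360
  expect_equal(back, rgb_to_hsv_raster(rv$rgb)$h, tolerance = 1e-12)
  # saturation/value untouched
  plain <- rgb_to_hsv_raster(rv$rgb)
  expect_identical(rot$s, plain$s)
  expect_identical(rot$v, plain$v)
})

test_that("rotated fruit hues sit in one interval away from the wrap point", {
  pep <- test_pepper(0.5, seed = 17)
  for (vp in c("side1", "side3")) {
    rv <- render_viewpoint(pep, vp, "robotic", small_opts())
    h <- rotate_hue(rv$rgb)$h[rv$truth_mask]
    expect_true(all(h > 5 & h < 355)) # nothing within 5 degrees of 0/360
  }
})

test_that("depth holes are filled from the Euclidean-nearest valid pixel", {
  d <- matrix(500, 10, 10)
  expect_identical(fill_depth_holes(d), d) # hole-free identity

  d1 <- matrix(0, 3, 3); d1[2, 3] <- 500
  expect_equal(fill_depth_holes(d1)[2, 2], 500)

  expect_error(fill_depth_holes(matrix(0, 4, 4)), "no valid")

  # brute-force oracle on a random small raster with 2% holes
  set.seed(31)
  d <- matrix(as.numeric(sample(100:900, 30 * 40, replace = TRUE)), 30, 40)
  holes <- matrix(runif(30 * 40) < 0.02, 30, 40)
  dh <- d; dh[holes] <- 0
  got <- fill_depth_holes(dh)
  valid <- which(!holes, arr.ind = TRUE)
  for (idx in which(holes)) {
    i <- (idx - 1) %% 30 + 1; j <- (idx - 1) %/% 30 + 1
    d2 <- (valid[, 1] - i)^2 + (valid[, 2] - j)^2
    key <- (valid[, 1] - 1) * 40 + (valid[, 2] - 1) # row-major tie-break
    best <- order(d2, key)[1]
    expect_identical(got[i, j], d[valid[best, 1], valid[best, 2]])
  }
  expect_identical(got[!holes], d[!holes]) # valid pixels unchanged
})

test_that("photocell segmentation recovers the fruit and rejects empty scenes", {
  pep <- test_pepper(0.55, seed = 23)
  rv <- render_viewpoint(pep, "side2", "photocell", small_opts())
  sm <- segment_photocell(rv$rgb)
  expect_s3_class(sm, "segmentation_mask")
  expect_identical(sm$area, sum(sm$mask))
  expect_gte(mask_iou(sm$mask, rv$truth_mask), 0.90)

  expect_error(segment_photocell(flat_rgb(0, 0, 0, 50, 50)),
               class = "pepperview_no_pepper")

  # a bright disk on black is recovered almost entirely
  disk <- disk_mask(96, 128, 48, 64, 25)
  img <- array(0.02, dim = c(96, 128, 3))
  for (ch in 1:3) { p <- img[, , ch]; p[disk] <- 0.8; img[, , ch] <- p }
  got <- segment_photocell(img)$mask
  expect_gte(sum(got & disk) / sum(disk), 0.95)
})

test_that("the color+depth window keeps vegetation in range and drops the rest", {
  pep <- test_pepper(0.5, seed = 29)
  opts <- small_opts()
  rv <- render_viewpoint(pep, "side1", "robotic", opts)
  cfg <- seg_config("robotic")
  hsv <- rotate_hue(rv$rgb)
  df <- fill_depth_holes(rv$depth)
  fg <- foreground_mask(hsv, df, cfg)

  # clutter beyond the far limit never survives (the closing step may bleed
  # one pixel across a boundary with in-range vegetation, so test its core)
  in_range <- df >= cfg$depth_range[1] & df <= cfg$depth_range[2]
  near_in_range <- pepperview:::from_ebimage(EBImage::dilate(
    pepperview:::as_ebimage(in_range), EBImage::makeBrush(3, "box")))
  far_core <- df > cfg$depth_range[2] & !near_in_range
  expect_identical(sum(fg & far_core), 0L)

  # covers nearly all of fruit + in-range plant pixels
  want <- rv$truth_mask | rv$plant_mask
  expect_gte(sum(fg & want) / sum(want), 0.95)

  # a single isolated pixel is removed by the opening
  lone <- matrix(FALSE, 20, 20); lone[10, 10] <- TRUE
  h_iso <- list(h = ifelse(lone, 100, 300), s = lone * 0 + 1, v = lone * 0 + 1)
  got <- foreground_mask(h_iso, matrix(500, 20, 20), cfg)
  expect_false(any(got))
})

test_that("morphological refinement never increases the component count", {
  cfg <- seg_config("robotic")
  count_components <- function(m)
    max(EBImage::bwlabel(EBImage::Image(t(m) * 1)))
  set.seed(41)
  for (rep in 1:5) {
    m <- matrix(runif(60 * 80) < 0.3, 60, 80)
    h <- list(h = ifelse(m, 100, 300))
    before <- count_components(m)
    after <- count_components(
      foreground_mask(list(h = h$h), matrix(500, 60, 80), cfg))
    expect_lte(after, before)
  }
})

test_that("robotic segmentation is accurate, convex and deterministic", {
  # fruit large enough that the fixed-width edge halo is small relative to it
  opts <- render_options(width = 400, height = 300,
                         fruit_shape = c(69, 69, 106))
  for (front in list(c(1, 0, 0), c(0, 1, 0))) {
    pep <- generate_pepper(pepper_spec("p", "red", 0.65, front,
                                       shape = c(69, 69, 106), seed = 9))
    rv <- render_viewpoint(pep, "side1", "robotic", opts)
    sm <- segment_robotic(rv$rgb, rv$depth)
    expect_gte(mask_iou(sm$mask, rv$truth_mask), 0.85)
    expect_identical(sm$mask, convex_hull_mask(sm$mask)) # convex
    sm2 <- segment_robotic(rv$rgb, rv$depth)
    expect_identical(sm$mask, sm2$mask)                  # deterministic
  }
})

test_that("at the default scale the robotic mask is a convex superset of the fruit", {
  pep <- generate_pepper(pepper_spec("p", "yellow", 0.6, c(0, 1, 0), seed = 19))
  rv <- render_viewpoint(pep, "side2", "robotic", render_options())
  sm <- segment_robotic(rv$rgb, rv$depth)
  expect_gte(sum(sm$mask & rv$truth_mask) / sum(rv$truth_mask), 0.80)
  expect_gte(mask_iou(sm$mask, rv$truth_mask), 0.80)
  expect_identical(sm$mask, convex_hull_mask(sm$mask))
})

test_that("lowest-mean-hue selection picks the pepper over green foliage", {
  # analytic two-object scene: a fruit disk with a ripe wedge + a green disk,
  # far enough apart that the dilated edge rings (+10 px each) cannot merge
  h <- 120; w <- 220
  fruit <- disk_mask(h, w, 60, 50, 28)
  ripe <- fruit & disk_mask(h, w, 60, 35, 20)   # part of the fruit is red
  leaf <- disk_mask(h, w, 60, 170, 26)
  img <- array(0, dim = c(h, w, 3))
  hue <- matrix(30, h, w); sat <- matrix(0.05, h, w); val <- matrix(0.2, h, w)
  hue[fruit] <- 110; sat[fruit] <- 0.9; val[fruit] <- 0.8
  hue[ripe] <- 5; val[ripe] <- 0.85
  hue[leaf] <- 110; sat[leaf] <- 0.9; val[leaf] <- 0.8
  img <- array(c(pepperview:::hsv_to_rgb_raster(hue, sat, val)), dim = c(h, w, 3))
  depth <- matrix(1200, h, w); depth[fruit | leaf] <- 500

  sm <- segment_robotic(img, depth)
  expect_gte(sum(sm$mask & fruit) / sum(fruit), 0.9)
  expect_identical(sum(sm$mask & leaf), 0L)

  # with an impossibly high size filter nothing survives
  expect_error(segment_robotic(img, depth,
                               seg_config("robotic", min_object_area_frac = 0.9)),
               class = "pepperview_no_pepper")

  # plant-only scene: only the green disk present, high size filter
  hue[ripe] <- 110; val[ripe] <- 0.8
  hue[fruit] <- 30; sat[fruit] <- 0.05; val[fruit] <- 0.2
  img2 <- array(c(pepperview:::hsv_to_rgb_raster(hue, sat, val)),
                dim = c(h, w, 3))
  depth2 <- matrix(1200, h, w); depth2[leaf] <- 500
  expect_error(segment_robotic(img2, depth2,
                               seg_config("robotic", min_object_area_frac = 0.2)),
               class = "pepperview_no_pepper")
})

test_that("the convex hull raster is tight on analytic shapes", {
  m <- disk_mask(50, 60, 25, 30, 15)
  expect_identical(convex_hull_mask(m), m | convex_hull_mask(m))
  # an L-shape fills to its hull: the bounding triangle corner gets covered
  L <- matrix(FALSE, 40, 40)
  L[10:30, 10:12] <- TRUE; L[28:30, 10:30] <- TRUE
  hull <- convex_hull_mask(L)
  expect_true(all(hull[L]))
  expect_true(hull[20, 18]) # inside the hull, outside the L
})
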