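#' Segmentation configuration
#'
#' One configuration object drives both segmentation algorithms. Photocell
#' images (uniform dark background) are segmented by intensity thresholding
#' refined with Chan-Vese active contours. Robotic RGB-D scenes go through a
#' depth/color/edge pipeline: hue rotation, depth hole filling, a combined
#' color+depth foreground window refined by morphological opening/closing,
#' Canny edges on the value channel dilated then eroded, ripe-color add-back,
#' size filtering, lowest-mean-hue object selection, and a final convex hull.
#'
#' Hue convention: hues are on a 0-360 degree circle and the robotic pipeline
#' rotates them by `hue_rotation_deg` (default +90) so that red (0) maps to
#' 90 and the red-to-green range becomes one contiguous interval away from
#' the 0/360 wrap point. `color_range` and `ripe_range` are intervals on the
#' rotated circle.
#'
#' @param mode `"photocell"` or `"robotic"`.
#' @param intensity_threshold 0-255; photocell initial mask keeps pixels whose
#'   max RGB channel exceeds this.
#' @param chanvese_iters,chanvese_mu Chan-Vese iterations and contour-length
#'   weight.
#' @param hue_rotation_deg rotation applied to the hue channel, degrees.
#' @param color_range rotated-hue interval \[lo, hi\] retained as vegetation
#'   (pepper + plant) by the foreground window.
#' @param ripe_range rotated-hue interval of the ripe (red/yellow) colors,
#'   used for the add-back step.
#' @param depth_range \[near, far\] millimetres retained by the foreground
#'   window.
#' @param canny_low,canny_high hysteresis thresholds on the 8-bit Sobel
#'   magnitude scale.
#' @param canny_sigma Gaussian smoothing before edge detection, pixels.
#' @param dilate_iters,erode_iters edge dilation / erosion passes
#'   (`dilate_iters >= erode_iters`).
#' @param min_object_area_frac components smaller than this fraction of the
#'   image are discarded.
#' @param struct_elem odd side length of the square structuring element.
#' @return list of class `seg_config`.
#' @export
seg_config <- function(mode = c("photocell", "robotic"),
                       intensity_threshold = 40,
                       chanvese_iters = 100, chanvese_mu = 0.25,
                       hue_rotation_deg = 90,
                       color_range = c(75, 230),
                       ripe_range = c(75, 170),
                       depth_range = c(300, 700),
                       canny_low = 50, canny_high = 150, canny_sigma = 1.4,
                       dilate_iters = 10, erode_iters = 5,
                       min_object_area_frac = 0.005,
                       struct_elem = 3) {
  mode <- match.arg(mode)
  if (erode_iters < 0 || dilate_iters < erode_iters)
    stop("need dilate_iters >= erode_iters >= 0")
  if (depth_range[1] >= depth_range[2]) stop("need near < far in depth_range")
  if (canny_low >= canny_high) stop("need canny_low < canny_high")
  if (struct_elem %% 2 != 1) stop("struct_elem must be odd")
  structure(as.list(environment()), class = "seg_config")
}

new_segmentation_mask <- function(mask, config) {
  structure(list(mask = mask, area = sum(mask),
                 provenance = rlang::hash(unclass(config))),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %dx%d, area %d px, config %s\n",
              nrow(x$mask), ncol(x$mask), x$area,
              substr(x$provenance, 1, 8)))
  invisible(x)
}

#' Segment a pepper from a dark photocell background
#'
#' Keeps pixels whose brightest RGB channel exceeds `intensity_threshold`,
#' refines the blob with two-phase Chan-Vese active-contour evolution
#' initialised from that blob, and returns the largest connected component.
#'
#' @param rgb H x W x 3 array in \[0,1\] (8-bit image).
#' @param config a [seg_config()].
#' @return a `segmentation_mask` (fields `mask`, `area`, `provenance`).
#' @export
segment_photocell <- function(rgb, config = seg_config("photocell")) {
  intensity <- pmax(rgb[, , 1], rgb[, , 2], rgb[, , 3]) * 255
  init <- intensity > config$intensity_threshold
  if (!any(init))
    stop_no_pepper("no pixel above the intensity threshold")
  gray <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  phi <- .chanvese_cpp(gray, init, as.integer(config$chanvese_iters),
                       config$chanvese_mu, 0.5, 1, 1, 1)
  mask <- phi >= 0
  if (!any(mask)) stop_no_pepper("active contour collapsed to empty")
  new_segmentation_mask(largest_component(mask), config)
}

#' Rotate the hue channel of an RGB image
#'
#' Converts to HSV and rotates the hue circle so that the red-to-green color
#' range becomes contiguous (red 0 degrees maps to `degrees`). Saturation and
#' value are untouched.
#'
#' @param rgb H x W x 3 array in \[0,1\].
#' @param degrees rotation, default +90.
#' @return list of H x W matrices `h` (rotated, degrees in \[0,360)), `s`, `v`.
#' @export
rotate_hue <- function(rgb, degrees = 90) {
  hsv <- rgb_to_hsv_raster(rgb)
  hsv$h <- (hsv$h + degrees) %% 360
  hsv
}

#' Fill missing depth pixels from the nearest valid pixel
#'
#' Missing depth (sensor dropout) is encoded as 0. Every hole takes the value
#' of its Euclidean-nearest valid pixel; ties are broken by row-major scan
#' order so the result is deterministic. Valid pixels are unchanged.
#'
#' @param depth H x W numeric matrix, millimetres, holes = 0.
#' @return filled H x W matrix.
#' @export
fill_depth_holes <- function(depth) {
  stopifnot(is.matrix(depth))
  .nnfill_cpp(depth)
}

morph_square <- function(mask, op, size, times = 1) {
  brush <- EBImage::makeBrush(size, shape = "box")
  img <- as_ebimage(mask)
  for (i in seq_len(times)) img <- op(img, brush)
  from_ebimage(img)
}

#' Color + depth foreground window
#'
#' Retains pixels whose rotated hue lies in `color_range` and whose depth lies
#' in `depth_range` (vegetation in front of the background), then applies a
#' morphological opening followed by a closing with a square structuring
#' element to remove speckle and close small gaps.
#'
#' @param hsv_rotated output of [rotate_hue()].
#' @param depth_filled output of [fill_depth_holes()], same shape.
#' @param config a [seg_config()].
#' @return logical H x W mask (possibly empty).
#' @export
foreground_mask <- function(hsv_rotated, depth_filled,
                            config = seg_config("robotic")) {
  stopifnot(identical(dim(hsv_rotated$h), dim(depth_filled)))
  m <- hsv_rotated$h >= config$color_range[1] &
       hsv_rotated$h <= config$color_range[2] &
       depth_filled >= config$depth_range[1] &
       depth_filled <= config$depth_range[2]
  m <- morph_square(m, EBImage::erode, config$struct_elem)   # opening
  m <- morph_square(m, EBImage::dilate, config$struct_elem)
  m <- morph_square(m, EBImage::dilate, config$struct_elem)  # closing
  m <- morph_square(m, EBImage::erode, config$struct_elem)
  m
}

#' Canny edges of a value channel
#'
#' @param value H x W matrix in \[0,1\].
#' @param config a [seg_config()] supplying the hysteresis thresholds.
#' @return logical edge mask.
#' @export
canny_edges <- function(value, config = seg_config("robotic")) {
  .canny_cpp(value, config$canny_sigma, config$canny_low, config$canny_high)
}

#' Filled convex hull of a binary mask
#'
#' @param mask logical matrix.
#' @return logical matrix covering the filled convex hull of the true pixels.
#' @export
convex_hull_mask <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0) return(mask)
  h <- grDevices::chull(pts[, 2], pts[, 1])      # x = col, y = row
  hx <- pts[h, 2]; hy <- pts[h, 1]
  n <- length(hx)
  if (n <= 2) {
    out <- matrix(FALSE, nrow(mask), ncol(mask))
    out[pts] <- TRUE
    return(out)
  }
  # the interior of a convex polygon is where every edge cross product has
  # one sign; the sign follows from the vertex orientation (shoelace area)
  k2s <- c(seq_len(n)[-1], 1L)
  orient <- sign(sum(hx * hy[k2s] - hx[k2s] * hy))
  rows <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  cols <- matrix(seq_len(ncol(mask)), nrow(mask), ncol(mask), byrow = TRUE)
  inside <- matrix(TRUE, nrow(mask), ncol(mask))
  for (k in seq_len(n)) {
    k2 <- k2s[k]
    cross <- (hx[k2] - hx[k]) * (rows - hy[k]) -
             (hy[k2] - hy[k]) * (cols - hx[k])
    inside <- inside & (orient * cross >= 0)
  }
  inside
}

#' Segment a pepper from a cluttered RGB-D scene
#'
#' Full robotic-mode pipeline: rotate the hue circle, fill depth holes, apply
#' the color+depth foreground window ([foreground_mask()]), detect Canny
#' edges on the value channel within the foreground, dilate the edges
#' `dilate_iters` times and erode `erode_iters` times (square kernel) to
#' close the fruit outline, add the ripe-colored foreground pixels back (the
#' red/green transition on the fruit itself produces no value edge), label
#' connected components, drop those below the size filter, pick the component
#' with the lowest mean rotated hue (ripe reds/yellows sit below foliage
#' green under the rotation), and return its filled convex hull.
#'
#' @param rgb H x W x 3 array in \[0,1\].
#' @param depth H x W matrix, millimetres, holes = 0.
#' @param config a [seg_config()].
#' @return a `segmentation_mask`; the mask is convex by construction.
#' @export
segment_robotic <- function(rgb, depth, config = seg_config("robotic")) {
  stopifnot(identical(dim(rgb)[1:2], dim(depth)))
  hsv <- rotate_hue(rgb, config$hue_rotation_deg)
  depth_f <- fill_depth_holes(depth)
  fg <- foreground_mask(hsv, depth_f, config)

  # Canny restricted to the foreground: masking V before edge detection keeps
  # the silhouette edge (its gradient peak can fall one pixel outside the
  # foreground window and would be lost if masking after)
  edges <- canny_edges(hsv$v * fg, config)
  m <- morph_square(edges, EBImage::dilate, config$struct_elem,
                    config$dilate_iters)
  m <- morph_square(m, EBImage::erode, config$struct_elem, config$erode_iters)

  ripe <- fg & hsv$h >= config$ripe_range[1] & hsv$h <= config$ripe_range[2]
  m <- m | ripe

  lab <- t(EBImage::imageData(EBImage::bwlabel(as_ebimage(m))))
  n_obj <- max(lab)
  if (n_obj == 0) stop_no_pepper("no connected component in the mask")
  sizes <- tabulate(lab[lab > 0], nbins = n_obj)
  min_area <- config$min_object_area_frac * length(depth)
  keep <- which(sizes >= min_area)
  if (length(keep) == 0)
    stop_no_pepper("no component passes the size filter")

  mean_hue <- vapply(keep, function(k) mean(hsv$h[lab == k]), numeric(1))
  sel <- keep[which.min(mean_hue)]
  new_segmentation_mask(convex_hull_mask(lab == sel), config)
}
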