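#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded rendering/splitting helpers
#' do not disturb the caller's random number stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Derive a child seed from a parent seed
#'
#' Deterministic, keeps the result in the 32-bit signed integer range.
#' @keywords internal
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2654435.0 + as.numeric(k) * 97003.0) %%
               2147483587 + 1)
}

# pmin/pmax take attributes from their first argument, so x goes first to
# preserve dims
clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- raster helpers -------------------------------------------------------

#' Convert a [0,1] RGB array to 8-bit integers and back
#' @keywords internal
quantize8 <- function(rgb01) round(clamp01(rgb01) * 255) / 255

#' Hue/saturation/value of an RGB raster
#'
#' @param rgb H x W x 3 numeric array in \[0,1\].
#' @return list of H x W matrices `h` (degrees, 0-360), `s`, `v`.
#' @keywords internal
rgb_to_hsv_raster <- function(rgb) {
  d <- dim(rgb)
  m <- rbind(as.vector(rgb[, , 1]), as.vector(rgb[, , 2]),
             as.vector(rgb[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

#' HSV (degrees) to an RGB [0,1] array
#' @keywords internal
hsv_to_rgb_raster <- function(h_deg, s, v) {
  hh <- (as.vector(h_deg) %% 360) / 360
  cols <- grDevices::col2rgb(grDevices::hsv(hh, as.vector(s), as.vector(v)))
  H <- nrow(h_deg); W <- ncol(h_deg)
  array(c(cols[1, ], cols[2, ], cols[3, ]) / 255, dim = c(H, W, 3))
}

# EBImage stores images x-by-y; this package stores rasters row-by-column with
# the origin at the top-left, so every hand-off transposes.
as_ebimage <- function(mask) EBImage::Image(t(mask) * 1)
from_ebimage <- function(img) t(EBImage::imageData(img)) > 0.5

#' Largest connected component of a binary mask
#' @keywords internal
largest_component <- function(mask) {
  lab <- t(EBImage::imageData(EBImage::bwlabel(as_ebimage(mask))))
  if (max(lab) == 0) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b logical matrices of the same shape.
#' @return IoU in \[0,1\]; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# ---- image file I/O -------------------------------------------------------

DEPTH_SCALE_MM <- 10000 # 16-bit TIFF stores depth_mm / DEPTH_SCALE_MM

#' Read / write the package's raster formats
#'
#' RGB images are 8-bit PNG. Depth rasters are 16-bit grayscale TIFF holding
#' millimetres divided by 10000 (resolution about 0.15 mm, range 0-10 m);
#' missing depth is 0. Masks are 8-bit grayscale PNG with foreground 255.
#'
#' @param path file path.
#' @param rgb H x W x 3 array in \[0,1\].
#' @param depth H x W matrix of millimetres.
#' @param mask logical H x W matrix.
#' @name raster_io
NULL

#' @rdname raster_io
#' @export
write_rgb_png <- function(rgb, path) png::writePNG(clamp01(rgb), path)

#' @rdname raster_io
#' @export
read_rgb_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3 && dim(x)[3] >= 3) x[, , 1:3, drop = FALSE] else
    array(rep(x, 3), dim = c(dim(x), 3))
}

#' @rdname raster_io
#' @export
write_depth_tiff <- function(depth, path) {
  tiff::writeTIFF(clamp01(depth / DEPTH_SCALE_MM), path,
                  bits.per.sample = 16)
}

#' @rdname raster_io
#' @export
read_depth_tiff <- function(path) {
  round(tiff::readTIFF(path) * DEPTH_SCALE_MM)
}

#' @rdname raster_io
#' @export
write_mask_png <- function(mask, path) png::writePNG(mask * 1, path)

#' @rdname raster_io
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x > 0.5
}
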