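#' Collect the color channels of the segmented pixels
#'
#' Extracts, for every pixel under the mask, the three color channels the
#' maturity features are built on: hue (degrees), the red channel (0-255)
#' and the red-minus-green difference (-255..255). Hue can be taken on the
#' plain circle (photocell chain) or after the +90 degree rotation of the
#' robotic chain, which keeps the red-to-green range contiguous; the choice
#' is recorded on the sample.
#'
#' @param rgb H x W x 3 array in \[0,1\].
#' @param mask logical H x W matrix; must select at least one pixel.
#' @param hue `"unrotated"` or `"rotated"`.
#' @param hue_rotation_deg rotation used when `hue = "rotated"`.
#' @return object of class `pixel_sample`: list with numeric vectors `hue`,
#'   `red`, `red_minus_green`, count `n`, and the hue convention used.
#' @export
collect_pixels <- function(rgb, mask, hue = c("unrotated", "rotated"),
                           hue_rotation_deg = 90) {
  hue <- match.arg(hue)
  stopifnot(identical(dim(rgb)[1:2], dim(mask)))
  if (!any(mask)) stop("empty mask: no pixels to collect")
  hsv <- rgb_to_hsv_raster(rgb)
  h <- if (hue == "rotated") (hsv$h + hue_rotation_deg) %% 360 else hsv$h
  r <- rgb[, , 1][mask] * 255
  g <- rgb[, , 2][mask] * 255
  structure(list(hue = h[mask], red = r, red_minus_green = r - g,
                 n = sum(mask), hue_convention = hue),
            class = "pixel_sample")
}

#' Trimmed mean with floor-per-side trimming
#'
#' The mean after discarding the lower and upper `trim_fraction` of the data:
#' `k = floor(trim_fraction * n)` observations are dropped from each end of
#' the sorted sample, so samples with `n < 1/trim_fraction` are not trimmed
#' at all.
#'
#' @param values numeric vector, length >= 1.
#' @param trim_fraction fraction in \[0, 0.5).
#' @return the trimmed mean.
#' @export
#' @examples
#' trimmed_mean(c(1:19, 1000), 0.05)  # drops 1 and 1000 -> 10.5
trimmed_mean <- function(values, trim_fraction = 0.05) {
  n <- length(values)
  if (n < 1) stop("empty input")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("trim_fraction must be in [0, 0.5)")
  k <- floor(trim_fraction * n)
  if (k == 0) return(mean(values))
  mean(sort(values)[(k + 1):(n - k)])
}

FEATURE_CHANNELS <- c("hue", "red", "red_minus_green")
FEATURE_STATS <- c("mean", "sd", "min", "max", "median", "trimmed_mean5")

#' Canonical names of the 18 color features
#'
#' Three channels (hue, red, red minus green) times six statistics (mean,
#' sample standard deviation, minimum, maximum, median, 5% trimmed mean), in
#' fixed order.
#'
#' @return character vector of length 18.
#' @export
feature_names <- function() {
  as.vector(t(outer(FEATURE_CHANNELS, FEATURE_STATS, paste, sep = "_")))
}

#' Compute the 18 color statistics of a pixel sample
#'
#' For each of the three channels: mean, sample standard deviation (n-1
#' denominator; 0 for a single pixel), minimum, maximum, median (mean of the
#' two central order statistics for even n), and 5% trimmed mean
#' ([trimmed_mean()]).
#'
#' @param sample a [collect_pixels()] result (or any list with `hue`, `red`,
#'   `red_minus_green` vectors).
#' @return named numeric vector of length 18, names per [feature_names()].
#' @export
compute_features <- function(sample) {
  one <- function(x) c(
    mean(x),
    if (length(x) > 1) stats::sd(x) else 0,
    min(x), max(x), stats::median(x), trimmed_mean(x, 0.05))
  out <- unlist(lapply(FEATURE_CHANNELS, function(ch) one(sample[[ch]])))
  names(out) <- feature_names()
  out
}

#' Pool pixel samples across viewpoints
#'
#' Concatenates the per-channel pixel vectors of several viewpoints into one
#' sample, the multi-viewpoint fusion used throughout the analysis: features
#' of a viewpoint combination are computed over the union of its segmented
#' pixels, not by fusing per-view predictions.
#'
#' @param samples list of `pixel_sample` objects (at least one non-empty).
#' @return a pooled `pixel_sample`.
#' @export
pool_pixels <- function(samples) {
  samples <- Filter(function(s) (s$n %||% 0) > 0, samples)
  if (length(samples) == 0) stop("all samples are empty")
  conv <- unique(vapply(samples, function(s) s$hue_convention %||% "unrotated",
                        character(1)))
  if (length(conv) > 1) stop("cannot pool samples with mixed hue conventions")
  structure(list(
    hue = unlist(lapply(samples, `[[`, "hue"), use.names = FALSE),
    red = unlist(lapply(samples, `[[`, "red"), use.names = FALSE),
    red_minus_green = unlist(lapply(samples, `[[`, "red_minus_green"),
                             use.names = FALSE),
    n = sum(vapply(samples, `[[`, numeric(1), "n")),
    hue_convention = conv), class = "pixel_sample")
}

#' Features of a viewpoint combination by pixel pooling
#'
#' @param samples list of `pixel_sample` objects.
#' @return named numeric vector of length 18 over the pooled pixels.
#' @export
pool_and_extract <- function(samples) compute_features(pool_pixels(samples))
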