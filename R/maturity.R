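#' Maturity class of a whole pepper from its colored surface fraction
#'
#' Sweet-pepper maturity is graded on an ordinal 1-4 scale from the fraction
#' of the fruit surface that has turned from green to the ripe color
#' (red or yellow):
#' class 1 = fully green, class 2 = majority green with some ripe color,
#' class 3 = majority ripe color with some green, class 4 = fully colored.
#' A fraction of exactly 0.5 is graded class 3 (the ripe color wins ties).
#'
#' @param colored_fraction numeric vector in \[0,1\]: fraction of the fruit
#'   surface bearing the ripe color.
#' @param has_mixture optional logical; whether the fruit shows both colors.
#'   Defaults to `colored_fraction` strictly inside (0,1). Supplying a value
#'   inconsistent with a fraction of exactly 0 or 1 is an error.
#' @return integer vector of classes in 1..4.
#' @seealso [classify_viewpoint()] for the per-viewpoint grading rules.
#' @export
#' @examples
#' classify_whole(c(0, 0.3, 0.7, 1))
classify_whole <- function(colored_fraction, has_mixture = NULL) {
  f <- colored_fraction
  stopifnot(is.numeric(f), all(f >= 0 & f <= 1))
  mix <- has_mixture %||% (f > 0 & f < 1)
  if (any(mix & (f == 0 | f == 1)))
    stop("has_mixture = TRUE is inconsistent with a fraction of exactly 0 or 1")
  out <- ifelse(f == 0, 1L, ifelse(f == 1, 4L, ifelse(f < 0.5, 2L, 3L)))
  as.integer(out)
}

#' Maturity class apparent from a single viewpoint
#'
#' Grades what a human rater would assign from one viewpoint alone, using the
#' visible colored fraction:
#' class 1 if the view is more than 95% green, class 4 if more than 95%
#' ripe-colored, class 2 if more than 50% green, class 3 if at least 50%
#' ripe-colored. "More than" is strict, so exactly 95% colored is class 3 and
#' exactly 50% colored is class 3 (ripe color wins the tie).
#'
#' Because peppers ripen nonuniformly, the viewpoint class can differ from the
#' whole-pepper class of the same fruit.
#'
#' @param visible_colored_fraction numeric vector in \[0,1\]: fraction of the
#'   visible fruit surface bearing the ripe color.
#' @return integer vector of classes in 1..4, monotone non-decreasing in the
#'   colored fraction.
#' @export
#' @examples
#' classify_viewpoint(c(0.03, 0.40, 0.60, 0.97))
classify_viewpoint <- function(visible_colored_fraction) {
  f <- visible_colored_fraction
  stopifnot(is.numeric(f), all(f >= 0 & f <= 1))
  green <- 1 - f
  out <- ifelse(f > 0.95, 4L,
         ifelse(green > 0.95, 1L,
         ifelse(f >= 0.5, 3L, 2L)))
  as.integer(out)
}
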