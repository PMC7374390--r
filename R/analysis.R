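#' Classification accuracy
#'
#' Fraction of peppers classified into the actual whole-pepper class.
#'
#' @param preds,truths equal-length class vectors.
#' @return accuracy in \[0,1\].
#' @export
classification_accuracy <- function(preds, truths) {
  stopifnot(length(preds) == length(truths), length(preds) >= 1)
  mean(preds == truths)
}

#' Viewpoint classification accuracy (VCA)
#'
#' Fraction of single-viewpoint images classified into the same class as the
#' *viewpoint* ground truth (what a human would grade from that view alone).
#' A prediction that matches the whole-pepper class but not the viewpoint
#' ground truth counts as wrong here.
#'
#' @param preds,viewpoint_truths equal-length class vectors, one element per
#'   viewpoint image.
#' @return accuracy in \[0,1\].
#' @export
viewpoint_classification_accuracy <- function(preds, viewpoint_truths) {
  classification_accuracy(preds, viewpoint_truths)
}

#' Enumerate the viewpoint combinations under test
#'
#' Photocell protocol (three sides plus bottom): every single viewpoint, the
#' three side pairs, the side triple, bottom plus one side, bottom plus two
#' sides, and all four. Robotic protocol (three sides): singles, pairs, and
#' the triple.
#'
#' @param mode `"photocell"` or `"robotic"`, or `NULL` when supplying
#'   `viewpoints` directly (then all subsets of size >= 1 are returned).
#' @param viewpoints optional viewpoint ids overriding the mode's default.
#' @return data.frame with `combo_id` (viewpoints joined by `+`),
#'   `viewpoints` (list column) and `n_viewpoints`, in canonical order.
#' @export
enumerate_combinations <- function(mode = c("photocell", "robotic"),
                                   viewpoints = NULL) {
  if (!is.null(viewpoints)) {
    if (anyDuplicated(viewpoints)) stop("duplicate viewpoint id")
    sets <- unlist(lapply(seq_along(viewpoints), function(k)
      combn(viewpoints, k, simplify = FALSE)), recursive = FALSE)
  } else {
    mode <- match.arg(mode)
    sides <- c("side1", "side2", "side3")
    sets <- if (mode == "robotic") {
      c(as.list(sides), combn(sides, 2, simplify = FALSE), list(sides))
    } else {
      c(as.list(c(sides, "bottom")),
        combn(sides, 2, simplify = FALSE),
        list(sides),
        lapply(sides, function(s) c("bottom", s)),
        lapply(combn(sides, 2, simplify = FALSE),
               function(p) c("bottom", p)),
        list(c(sides, "bottom")))
    }
  }
  data.frame(
    combo_id = vapply(sets, paste, character(1), collapse = "+"),
    viewpoints = I(sets),
    n_viewpoints = vapply(sets, length, integer(1)),
    stringsAsFactors = FALSE)
}

#' Correctness matrix of peppers by viewpoint combinations
#'
#' @param preds data.frame with columns `pepper_id`, `combo_id`, `pred`.
#' @param truths data.frame with columns `pepper_id`, `class`
#'   (whole-pepper truth).
#' @return logical matrix, rows = peppers, columns = combinations; cell is
#'   `TRUE` when that combination classified that pepper correctly.
#' @export
correctness_matrix <- function(preds, truths) {
  truths <- unique(truths[, c("pepper_id", "class")])
  key <- setNames(truths$class, truths$pepper_id)
  ids <- sort(unique(preds$pepper_id))
  combos <- unique(preds$combo_id)
  m <- matrix(NA, length(ids), length(combos),
              dimnames = list(ids, combos))
  m[cbind(match(preds$pepper_id, ids), match(preds$combo_id, combos))] <-
    preds$pred == key[preds$pepper_id]
  if (anyNA(m)) stop("correctness matrix has missing cells")
  m
}

#' Optimistic and pessimistic scenario bounds
#'
#' In a real harvesting run the viewpoint that happens to face the camera is
#' unknown, so per-combination accuracies are bracketed by two scenarios:
#' optimistic — a pepper counts as correct if *any* of the considered
#' combinations classified it correctly (OR across columns); pessimistic — it
#' counts as correct only if *every* considered combination did (AND).
#'
#' @param matrix logical correctness matrix
#'   (peppers x combinations, see [correctness_matrix()]).
#' @param combinations character vector of column names to consider
#'   (default: all).
#' @return list of class `scenario_result`: `per_combination_ca` (named),
#'   `optimistic_ca`, `pessimistic_ca`.
#' @export
scenario_bounds <- function(matrix, combinations = colnames(matrix)) {
  if (length(combinations) == 0) stop("empty combination subset")
  stopifnot(all(combinations %in% colnames(matrix)), nrow(matrix) >= 1)
  m <- matrix[, combinations, drop = FALSE]
  structure(list(
    per_combination_ca = colMeans(m),
    optimistic_ca = mean(apply(m, 1, any)),
    pessimistic_ca = mean(apply(m, 1, all))
  ), class = "scenario_result")
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (Pa - Pe) / (1 - Pe)` with `Pa` the
#' observed agreement and `Pe` the chance agreement from the raters' marginal
#' class frequencies. The degenerate case `Pe = 1` (both raters constant with
#' identical marginals) is defined as 1 under perfect agreement and is an
#' error otherwise.
#'
#' @param r1,r2 equal-length categorical vectors.
#' @return kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(r1, r2) {
  stopifnot(length(r1) == length(r2), length(r1) >= 1)
  pa <- mean(r1 == r2)
  lev <- sort(unique(c(as.character(r1), as.character(r2))))
  p1 <- table(factor(as.character(r1), lev)) / length(r1)
  p2 <- table(factor(as.character(r2), lev)) / length(r2)
  pe <- sum(as.numeric(p1) * as.numeric(p2))
  if (isTRUE(all.equal(pe, 1))) {
    if (isTRUE(all.equal(pa, 1))) return(1)
    stop("chance agreement is 1 but observed agreement is not perfect")
  }
  (pa - pe) / (1 - pe)
}

#' Light's kappa for several raters
#'
#' Arithmetic mean of [cohens_kappa()] over all unordered rater pairs. When
#' the raters are viewpoints grading the same fruit, fully green (class 1)
#' and fully colored (class 4) peppers agree across viewpoints by definition,
#' so rows can be restricted to whole-pepper classes 2 and 3 via
#' `whole_class`.
#'
#' @param table matrix or data.frame, rows = peppers, columns = raters
#'   (viewpoints), cells = maturity classes.
#' @param whole_class optional vector of whole-pepper classes (one per row);
#'   when given, only rows with class 2 or 3 enter the calculation.
#' @return mean pairwise kappa.
#' @export
light_kappa <- function(table, whole_class = NULL) {
  m <- as.matrix(table)
  if (!is.null(whole_class)) {
    stopifnot(length(whole_class) == nrow(m))
    m <- m[whole_class %in% c(2, 3), , drop = FALSE]
  }
  if (ncol(m) < 2) stop("need at least two raters")
  if (nrow(m) == 0) stop("no peppers left after the class-1/4 exclusion")
  pairs <- combn(ncol(m), 2)
  mean(apply(pairs, 2, function(p) cohens_kappa(m[, p[1]], m[, p[2]])))
}
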