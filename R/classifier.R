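#' Train/test split specification
#'
#' The evaluation protocol holds out a fixed number of whole peppers per
#' (maturity class, color) stratum; all viewpoints of a held-out pepper are
#' test data, so no pixel of a test fruit is ever seen in training.
#'
#' @param n_test_per_class_per_color held-out peppers per stratum (default 5).
#' @param seed integer seed for the random draw.
#' @return list of class `split_spec`.
#' @export
split_spec <- function(n_test_per_class_per_color = 5, seed = 1L) {
  stopifnot(n_test_per_class_per_color >= 1)
  structure(list(n_test_per_class_per_color = n_test_per_class_per_color,
                 seed = as.integer(seed)), class = "split_spec")
}

#' Split peppers into training and test sets
#'
#' Draws `n_test_per_class_per_color` peppers uniformly at random without
#' replacement from every (class, color) stratum.
#'
#' @param records data.frame with one row per pepper: columns `pepper_id`,
#'   `color`, `class` (duplicated rows per viewpoint are tolerated and
#'   deduplicated).
#' @param spec a [split_spec()].
#' @return list with character vectors `train_ids` and `test_ids` (disjoint,
#'   covering all peppers).
#' @export
split_dataset <- function(records, spec = split_spec()) {
  peppers <- unique(records[, c("pepper_id", "color", "class")])
  peppers <- peppers[order(peppers$pepper_id), ]
  n <- spec$n_test_per_class_per_color
  test_ids <- with_seed(spec$seed, {
    unlist(lapply(split(peppers$pepper_id,
                        interaction(peppers$class, peppers$color,
                                    drop = TRUE)),
                  function(ids) {
                    if (length(ids) < n)
                      stop("stratum with only ", length(ids),
                           " peppers; cannot hold out ", n)
                    sample(ids, n)
                  }), use.names = FALSE)
  })
  list(train_ids = sort(setdiff(peppers$pepper_id, test_ids)),
       test_ids = sort(test_ids))
}

#' Random-forest specification
#'
#' @param n_trees number of trees (default 500).
#' @param features_per_split candidate features at each split
#'   (default 5 of the 18).
#' @param seed integer seed.
#' @return list of class `forest_spec`.
#' @export
forest_spec <- function(n_trees = 500, features_per_split = 5, seed = 1L) {
  stopifnot(features_per_split >= 1, features_per_split <= 18, n_trees >= 1)
  structure(list(n_trees = n_trees, features_per_split = features_per_split,
                 seed = as.integer(seed)), class = "forest_spec")
}

#' Fit a maturity random forest
#'
#' Standard classification random forest (Gini impurity, bootstrap sampling,
#' unlimited depth) on the 18 color features, predicting the whole-pepper
#' maturity class. One model is fit per dataset and pepper color. Training
#' rows are sorted by `ids` before fitting so that the seeded bootstrap draws
#' do not depend on the caller's row order. A single-class training set is
#' permitted and yields a degenerate model that always predicts that class.
#'
#' @param features data.frame or matrix of feature columns
#'   (see [feature_names()]).
#' @param labels vector of maturity classes (1..4), one per row.
#' @param spec a [forest_spec()].
#' @param ids optional stable row identifiers used for canonical ordering;
#'   defaults to row names or row index.
#' @return object of class `maturity_forest`.
#' @export
train_maturity_forest <- function(features, labels, spec = forest_spec(),
                                  ids = NULL) {
  x <- as.data.frame(features)[, feature_names(), drop = FALSE]
  y <- factor(as.integer(labels), levels = 1:4)
  stopifnot(nrow(x) == length(y))
  ids <- ids %||% rownames(x) %||% as.character(seq_len(nrow(x)))
  ord <- order(as.character(ids))
  x <- x[ord, , drop = FALSE]; y <- y[ord]

  if (length(unique(y)) < 2) {
    return(structure(list(constant = as.integer(as.character(y[1])),
                          spec = spec), class = "maturity_forest"))
  }
  fit <- with_seed(spec$seed, randomForest::randomForest(
    x = x, y = droplevels(y), ntree = spec$n_trees,
    mtry = min(spec$features_per_split, ncol(x))))
  structure(list(forest = fit, spec = spec), class = "maturity_forest")
}

#' Predict maturity classes
#'
#' @param model a [train_maturity_forest()] model.
#' @param features feature rows to classify.
#' @return integer vector of predicted classes (1..4).
#' @export
predict_maturity <- function(model, features) {
  stopifnot(inherits(model, "maturity_forest"))
  x <- as.data.frame(features)[, feature_names(), drop = FALSE]
  if (!is.null(model$constant)) return(rep(model$constant, nrow(x)))
  as.integer(as.character(predict(model$forest, newdata = x)))
}
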