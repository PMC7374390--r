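# the 4-pepper x 3-viewpoint worked example of correct/incorrect single-view
# classifications used throughout these tests
worked_example <- function() {
  m <- rbind(pepper1 = c(TRUE, TRUE, TRUE),
             pepper2 = c(TRUE, FALSE, TRUE),
             pepper3 = c(FALSE, TRUE, FALSE),
             pepper4 = c(FALSE, FALSE, FALSE))
  colnames(m) <- c("VP1", "VP2", "VP3")
  m
}

test_that("classification accuracy is the fraction of correct peppers", {
  expect_identical(classification_accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(classification_accuracy(c(1, 1), c(2, 3)), 0)
  expect_identical(classification_accuracy(c(1, 2, 3, 4), c(1, 2, 4, 3)), 0.5)
  expect_error(classification_accuracy(integer(0), integer(0)))
})

test_that("VCA scores against the viewpoint truth, not the whole-pepper truth", {
  # the prediction matches the whole-pepper class (2) but the rater graded
  # this viewpoint as class 3 -> counted wrong for the VCA
  preds <- c(2, 3, 1)
  viewpoint_truth <- c(3, 3, 1)
  expect_equal(viewpoint_classification_accuracy(preds, viewpoint_truth),
               2 / 3)
  expect_identical(viewpoint_classification_accuracy(c(1, 2), c(3, 4)), 0)
})

test_that("scenario bounds reproduce the worked single-viewpoint example", {
  sb <- scenario_bounds(worked_example())
  expect_equal(unname(sb$per_combination_ca), c(0.5, 0.5, 0.5))
  expect_equal(sb$optimistic_ca, 0.75)
  expect_equal(sb$pessimistic_ca, 0.25)

  # a singleton subset collapses both bounds onto that column's CA
  s1 <- scenario_bounds(worked_example(), "VP2")
  expect_equal(s1$optimistic_ca, 0.5)
  expect_equal(s1$pessimistic_ca, 0.5)

  expect_error(scenario_bounds(worked_example(), character(0)), "empty")
})

test_that("bounds bracket every per-combination accuracy and are subset-monotone", {
  set.seed(19)
  subsets <- unlist(lapply(1:3, function(k)
    combn(c("VP1", "VP2", "VP3"), k, simplify = FALSE)), recursive = FALSE)
  for (rep in 1:20) {
    m <- matrix(sample(c(TRUE, FALSE), 18, replace = TRUE), 6, 3,
                dimnames = list(paste0("p", 1:6), c("VP1", "VP2", "VP3")))
    for (s in subsets) {
      sb <- scenario_bounds(m, s)
      expect_gte(sb$optimistic_ca, max(sb$per_combination_ca))
      expect_lte(sb$pessimistic_ca, min(sb$per_combination_ca))
    }
    for (s in subsets) for (t in subsets) {
      if (all(s %in% t)) {
        expect_gte(scenario_bounds(m, t)$optimistic_ca,
                   scenario_bounds(m, s)$optimistic_ca)
        expect_lte(scenario_bounds(m, t)$pessimistic_ca,
                   scenario_bounds(m, s)$pessimistic_ca)
      }
    }
  }
})

test_that("the viewpoint-combination protocols enumerate completely", {
  rb <- enumerate_combinations("robotic")
  expect_identical(nrow(rb), 7L)                 # 3 singles + 3 pairs + triple
  expect_identical(sum(rb$n_viewpoints == 1), 3L)
  expect_identical(sum(rb$n_viewpoints == 2), 3L)
  expect_identical(sum(rb$n_viewpoints == 3), 1L)

  pc <- enumerate_combinations("photocell")
  expect_identical(nrow(pc), 15L)
  expect_identical(as.vector(table(pc$n_viewpoints)), c(4L, 6L, 4L, 1L))
  # bottom appears in: its single, 3 bottom+side, 3 bottom+2sides, all four
  has_bottom <- vapply(pc$viewpoints, function(v) "bottom" %in% v, logical(1))
  expect_identical(sum(has_bottom), 8L)
  expect_true("side1+side2+side3+bottom" %in% pc$combo_id)

  expect_error(enumerate_combinations(viewpoints = c("a", "a")), "duplicate")
})

test_that("correctness matrices are complete and keyed to the whole truth", {
  truths <- data.frame(pepper_id = c("a", "b"), class = c(2, 3))
  preds <- expand.grid(pepper_id = c("a", "b"), combo_id = c("x", "y"),
                       stringsAsFactors = FALSE)
  preds$pred <- c(2, 4, 3, 3)
  m <- correctness_matrix(preds, truths)
  expect_identical(m["a", "x"], TRUE)
  expect_identical(m["b", "x"], FALSE)
  expect_identical(m["b", "y"], TRUE)
  expect_error(correctness_matrix(preds[-1, ], truths), "missing")
})

test_that("Cohen's kappa matches hand-computed and reference values", {
  expect_identical(cohens_kappa(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  # complete reversal: Pa = 0, Pe = 0.5 -> kappa = -1
  expect_identical(cohens_kappa(c(2, 2, 3, 3), c(3, 3, 2, 2)), -1)
  # degenerate: both raters constant and identical (Pe = 1, perfect agreement)
  expect_identical(cohens_kappa(c(2, 2), c(2, 2)), 1)
  # constant raters on different classes: Pa = Pe = 0 -> kappa = 0
  expect_identical(cohens_kappa(c(2, 2, 2), c(3, 3, 3)), 0)

  skip_if_not_installed("e1071")
  set.seed(42)
  for (i in 1:10) {
    r1 <- sample(1:4, 50, replace = TRUE)
    r2 <- ifelse(runif(50) < 0.6, r1, sample(1:4, 50, replace = TRUE))
    tab <- table(factor(r1, 1:4), factor(r2, 1:4))
    expect_equal(cohens_kappa(r1, r2), e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-12)
  }
})

test_that("independent raters have kappa near zero", {
  set.seed(7)
  r1 <- sample(1:4, 1e4, replace = TRUE, prob = c(0.1, 0.4, 0.3, 0.2))
  r2 <- sample(1:4, 1e4, replace = TRUE, prob = c(0.25, 0.25, 0.3, 0.2))
  expect_lt(abs(cohens_kappa(r1, r2)), 0.1)
})

test_that("Light's kappa is the mean over rater pairs with class-1/4 rows excluded", {
  tab <- matrix(c(2, 2, 3, 3,
                  2, 3, 3, 2,
                  2, 2, 3, 3), 4, 3)
  direct <- mean(c(cohens_kappa(tab[, 1], tab[, 2]),
                   cohens_kappa(tab[, 1], tab[, 3]),
                   cohens_kappa(tab[, 2], tab[, 3])))
  expect_equal(light_kappa(tab), direct)

  # identical raters agree perfectly
  same <- cbind(c(2, 3, 2), c(2, 3, 2), c(2, 3, 2))
  expect_identical(light_kappa(same), 1)

  # brute-force pairwise mean on random tables
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(sample(1:4, 80, replace = TRUE), 20, 4)
    pairs <- combn(4, 2)
    oracle <- mean(apply(pairs, 2, function(p)
      cohens_kappa(m[, p[1]], m[, p[2]])))
    expect_equal(light_kappa(m), oracle)
  }

  # exclusion by whole-pepper class: rows of class 1/4 peppers are dropped
  m <- rbind(c(1, 1, 1), c(4, 4, 4), c(2, 3, 2), c(3, 3, 2),
             c(2, 2, 3), c(4, 4, 4))
  whole <- c(1, 4, 2, 3, 2, 4)
  expect_equal(light_kappa(m, whole),
               light_kappa(m[whole %in% c(2, 3), , drop = FALSE]))
  expect_false(isTRUE(all.equal(light_kappa(m), light_kappa(m, whole))))
  expect_error(light_kappa(m[1:2, , drop = FALSE], c(1, 4)), "no peppers")
  expect_error(light_kappa(m[, 1, drop = FALSE]), "two raters")

  # invariance under rater relabeling and row permutation
  set.seed(13)
  m2 <- matrix(sample(1:4, 60, replace = TRUE), 15, 4)
  expect_equal(light_kappa(m2[sample(15), c(3, 1, 4, 2)]), light_kappa(m2))
})
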