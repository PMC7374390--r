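test_that("collect_pixels extracts the three channels over the mask", {
  red <- flat_rgb(1, 0, 0, 10, 10)
  mask <- matrix(TRUE, 10, 10)
  s <- collect_pixels(red, mask, hue = "rotated")
  expect_identical(s$n, 100L)
  expect_true(all(s$hue == 90))        # red rotates to 90 degrees
  expect_true(all(s$red == 255))
  expect_true(all(s$red_minus_green == 255))

  s0 <- collect_pixels(red, mask, hue = "unrotated")
  expect_true(all(s0$hue == 0))

  one <- mask & FALSE; one[5, 5] <- TRUE
  s1 <- collect_pixels(red, one)
  expect_identical(s1$n, 1L)
  expect_identical(unname(compute_features(s1)["red_sd"]), 0)

  expect_error(collect_pixels(red, mask & FALSE), "empty mask")

  # 50/50 red/green checkerboard balances R-G exactly
  chk <- flat_rgb(1, 0, 0, 10, 10)
  alt <- outer(1:10, 1:10, "+") %% 2 == 0
  for (ch in 1:2) {
    p <- chk[, , ch]
    p[alt] <- 1 - p[alt]
    chk[, , ch] <- p
  }
  expect_equal(mean(collect_pixels(chk, mask)$red_minus_green), 0)
})

test_that("trimmed mean drops floor(trim*n) observations per side", {
  expect_identical(trimmed_mean(c(7, 7, 7, 7)), 7)
  x <- c(3, 9, 1, 4)
  expect_identical(trimmed_mean(x, 0), mean(x))
  # n=20, trim 5% -> k=1: the outliers 1 and 1000 are dropped
  expect_identical(trimmed_mean(c(1:19, 1000), 0.05), mean(2:19))
  # n<20 at 5%: no trimming at all
  expect_identical(trimmed_mean(c(1, 2, 1000), 0.05), mean(c(1, 2, 1000)))
  expect_error(trimmed_mean(numeric(0)))
  expect_error(trimmed_mean(1:5, 0.5))
})

test_that("the 18 statistics obey their defining identities", {
  # constant sample: every location statistic collapses, spread is 0
  s <- manual_sample(rep(40, 9), rep(200, 9), rep(120, 9))
  f <- compute_features(s)
  expect_identical(unname(f["hue_mean"]), 40)
  expect_identical(unname(f["hue_sd"]), 0)
  expect_true(all(f[c("red_mean", "red_min", "red_max", "red_median",
                      "red_trimmed_mean5")] == 200))

  # two-point sample in red
  s2 <- manual_sample(c(0, 0), c(0, 255), c(0, 0))
  f2 <- compute_features(s2)
  expect_identical(unname(f2["red_mean"]), 127.5)
  expect_identical(unname(f2["red_sd"]), stats::sd(c(0, 255)))
  expect_identical(unname(f2["red_min"]), 0)
  expect_identical(unname(f2["red_max"]), 255)
  expect_identical(unname(f2["red_median"]), 127.5) # mean of central pair

  # schema is frozen
  expect_identical(feature_names(), c(
    "hue_mean", "hue_sd", "hue_min", "hue_max", "hue_median",
    "hue_trimmed_mean5",
    "red_mean", "red_sd", "red_min", "red_max", "red_median",
    "red_trimmed_mean5",
    "red_minus_green_mean", "red_minus_green_sd", "red_minus_green_min",
    "red_minus_green_max", "red_minus_green_median",
    "red_minus_green_trimmed_mean5"))
  expect_identical(names(f), feature_names())
})

test_that("order statistics stay ordered on random samples", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(1:200, 1)
    s <- manual_sample(runif(n, 0, 360), runif(n, 0, 255), runif(n, -255, 255))
    f <- compute_features(s)
    for (ch in c("hue", "red", "red_minus_green")) {
      v <- function(st) unname(f[paste(ch, st, sep = "_")])
      expect_lte(v("min"), v("median"))
      expect_lte(v("median"), v("max"))
      expect_lte(v("min"), v("trimmed_mean5"))
      expect_lte(v("trimmed_mean5"), v("max"))
      expect_gte(v("sd"), 0)
    }
  }
})

test_that("pixel pooling obeys the union identities", {
  set.seed(123)
  mk <- function(n) manual_sample(runif(n, 0, 360), runif(n, 0, 255),
                                  runif(n, -255, 255))
  a <- mk(40); b <- mk(25); c <- mk(60)

  # pooling a sample with itself only duplicates pixels
  f1 <- compute_features(a)
  f2 <- pool_and_extract(list(a, a))
  # location statistics are exactly duplication-invariant; the sample sd
  # (n-1 denominator) only asymptotically so
  for (st in c("mean", "min", "max", "median", "sd"))
    expect_equal(unname(f2[paste0("hue_", st)]),
                 unname(f1[paste0("hue_", st)]),
                 tolerance = if (st == "sd") 0.02 else 1e-12)

  pooled <- pool_and_extract(list(a, b, c))
  ns <- c(a$n, b$n, c$n)
  for (ch in c("hue", "red", "red_minus_green")) {
    means <- vapply(list(a, b, c),
                    function(s) mean(s[[ch]]), numeric(1))
    expect_equal(unname(pooled[paste0(ch, "_mean")]),
                 sum(ns * means) / sum(ns), tolerance = 1e-9)
    expect_identical(unname(pooled[paste0(ch, "_min")]),
                     min(vapply(list(a, b, c), function(s) min(s[[ch]]),
                                numeric(1))))
    expect_identical(unname(pooled[paste0(ch, "_max")]),
                     max(vapply(list(a, b, c), function(s) max(s[[ch]]),
                                numeric(1))))
  }

  # permutation invariance of the argument list (up to float summation order)
  expect_equal(pooled, pool_and_extract(list(c, a, b)), tolerance = 1e-12)

  # empty samples are skipped; all-empty is an error
  e <- manual_sample(numeric(0), numeric(0), numeric(0))
  expect_identical(pool_and_extract(list(a, e)), compute_features(a))
  expect_error(pool_and_extract(list(e, e)), "empty")
})
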