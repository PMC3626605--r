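test_that("chi-squared statistics match the published segregation tests", {
  # (observed, ratio, printed chi2)
  cases <- list(
    list(c(25, 24), c(1, 1), 0.020),                            # Pa alleles, cross 1
    list(c(14, 10), c(1, 1), 0.667),                            # Pa alleles, cross 2
    list(c(2, 4, 8, 5, 10, 5, 0, 0, 0, 0, 5, 10), rep(1, 12), 38.918),
    list(c(2, 4, 5, 1, 5, 1, 0, 0, 0, 1, 2, 3), rep(1, 12), 19.000),
    list(c(34, 6, 28, 30), c(1, 1, 1, 1), 19.388),
    list(c(34, 6, 28, 30), c(5, 1, 5, 5), 0.612),
    list(c(18, 7, 11, 12), c(1, 1, 1, 1), 5.167),
    list(c(18, 7, 11, 12), c(2, 1, 2, 2), 2.094),
    list(c(6, 13, 15, 15, 0, 0), rep(1, 6), 31.204),
    list(c(6, 13, 15, 15, 0, 0), c(1, 2, 2, 2, 0, 0), 0.357),
    list(c(6, 6, 6, 0, 1, 5), rep(1, 6), 9.500),
    list(c(6, 6, 6, 0, 1, 5), c(6, 6, 6, 0, 1, 6), 0.132),
    list(c(385, 80, 428, 334), c(1, 1, 1, 1), 237.923),
    list(c(385, 80, 428, 334), c(5, 1, 5, 4), 2.472),
    list(c(80, 375, 281, 74, 66, 324), rep(1, 6), 503.970),
    list(c(264, 425, 282, 254, 143, 263), rep(1, 6), 149.426),
    list(c(264, 425, 282, 254, 143, 263), c(2, 3, 2, 2, 1, 2), 3.162)
  )
  for (cs in cases)
    expect_chi2(chi2_gof(cs[[1]], cs[[2]])$chi2, cs[[3]])
  # large distorted-pair statistic, printed with coarser rounding
  expect_chi2(chi2_gof(c(80, 375, 281, 74, 66, 324),
                        c(3, 16, 12, 3, 3, 16))$chi2, 7.556, 5e-3)
})

test_that("zero-ratio cells contribute nothing when empty and are impossible when occupied", {
  r <- chi2_gof(c(6, 13, 15, 15, 0, 0), c(1, 2, 2, 2, 0, 0))
  expect_identical(r$df, 5L)                      # zero-ratio cells keep their df
  expect_equal(r$contributions[5:6], c(0, 0))
  expect_false(r$impossible)
  expect_true(r$fits)

  r2 <- chi2_gof(c(6, 13, 15, 15, 3, 0), c(1, 2, 2, 2, 0, 0))
  expect_true(r2$impossible)
  expect_identical(r2$chi2, Inf)
  expect_false(r2$fits)
  expect_equal(r2$p_value, 0)
})

test_that("the statistic obeys its algebraic invariances", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    obs <- stats::rpois(k, 20) + 1L
    ratio <- sample(1:6, k, replace = TRUE)
    base <- chi2_gof(obs, ratio)
    # ratio scale invariance
    expect_equal(chi2_gof(obs, ratio * 7)$chi2, base$chi2, tolerance = 1e-9)
    # simultaneous permutation invariance
    perm <- sample(k)
    expect_equal(chi2_gof(obs[perm], ratio[perm])$chi2, base$chi2,
                 tolerance = 1e-9)
    # perfect fit
    expect_equal(chi2_gof(obs * 3L, obs)$chi2, 0)
    # statistic is the sum of its per-class contributions
    expect_equal(sum(base$contributions), base$chi2, tolerance = 1e-9)
    expect_identical(base$fits, base$chi2 <= base$critical)
  }
  expect_error(chi2_gof(c(1, 2), c(1, 1, 1)), "same length")
  expect_error(chi2_gof(c(0, 0), c(1, 1)), "positive")
  expect_error(chi2_gof(c(1, 2), c(0, 0)), "positive")
})

test_that("upper-tail critical values reproduce the usable published entries", {
  expect_equal(critical_value(1), 3.84, tolerance = 5e-3)
  expect_equal(critical_value(3), 7.815, tolerance = 5e-4)
  expect_equal(critical_value(5), 11.07, tolerance = 5e-3)
  expect_equal(critical_value(11), 19.68, tolerance = 5e-3)
  expect_error(critical_value(0), "df")
})

test_that("exhaustive ratio search recovers the published small-integer approximations", {
  top <- find_candidate_ratios(c(34, 6, 28, 30), max_term = 5, top_k = 25)
  hit <- top[top$ratio == "5:1:5:5", ]
  expect_equal(nrow(hit), 1L)
  expect_chi2(hit$chi2, 0.612, 5e-3)

  top2 <- find_candidate_ratios(c(18, 7, 11, 12), max_term = 3, top_k = 25)
  hit2 <- top2[top2$ratio == "2:1:2:2", ]
  expect_chi2(hit2$chi2, 2.094, 5e-3)

  best <- find_candidate_ratios(c(1, 1), max_term = 1, top_k = 3)
  expect_equal(best$ratio[1], "1:1")
  expect_equal(best$chi2[1], 0)
  # candidates are de-duplicated up to common scaling
  expect_false("2:2" %in% best$ratio)
  # ranking is ascending with deterministic ties
  expect_false(is.unsorted(top$chi2))

  expect_error(find_candidate_ratios(rep(1, 9), max_term = 2), "8 classes")
  expect_error(find_candidate_ratios(rep(1, 8), max_term = 9), "too large")
})

test_that("fruit-set classification uses an inclusive 2% threshold", {
  expect_equal(as.character(classify_fruit_set(105, 5212)), "compatible")
  expect_equal(as.character(classify_fruit_set(1, 100)), "incompatible")
  expect_equal(as.character(classify_fruit_set(2, 100)), "compatible")
  expect_equal(attr(classify_fruit_set(105, 5212), "percent"),
               100 * 105 / 5212)
  expect_error(classify_fruit_set(0, 0), "positive")
})
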