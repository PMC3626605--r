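test_that("unfiltered self cross of a tetrasomic tetraploid gives the 1:1:1:1:1:1:6:6:6:6:6 class distribution", {
  d <- expected_phenotype_distribution(cherry_cross("Dabai", "Dabai",
                                                    si = FALSE))
  expect_equal(nrow(d), 11L)
  two <- lengths(strsplit(d$class, "+", fixed = TRUE)) == 2L
  expect_equal(sum(two), 6L)
  expect_equal(d$prob, c(rep(1, 6), rep(6, 5))[order_phenotype_classes(d$class)] / 36,
               tolerance = 1e-12)
  expect_equal(unname(expected_ratio(d)), c(rep(1L, 6), rep(6L, 5)))
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  # dosage-blind classes: none of size 1; size masses 6/36, 24/36, 6/36
  sizes <- lengths(strsplit(d$class, "+", fixed = TRUE))
  expect_false(any(sizes == 1L))
  expect_equal(as.vector(tapply(d$prob, sizes, sum)),
               c(6, 24, 6) / 36, tolerance = 1e-12)
})

test_that("the interspecific cross gives 12 equiprobable classes", {
  d <- expected_phenotype_distribution(cherry_cross("Summit", "Dabai",
                                                    si = FALSE))
  expect_equal(nrow(d), 12L)
  expect_equal(d$prob, rep(1 / 12, 12), tolerance = 1e-12)
  expect_equal(unname(expected_ratio(d)), rep(1L, 12))
  expect_true(all(grepl("^Pa-S[12]\\+Pps-", d$class)))
})

test_that("the pollen-part-mutant + competitive-interaction self model zeroes the S2 pair classes", {
  cr <- cherry_cross("Dabai", "Dabai", s2_dead = TRUE)
  d <- expected_phenotype_distribution(cr)
  acc <- attr(d, "pollen")
  expect_setequal(acc$alleles[acc$accepted],
                  c("Pps-S1+Pps-S5", "Pps-S1+Pps-S8", "Pps-S5+Pps-S8"))
  # the S2-containing pair classes are unreachable
  expect_false(any(c("Pps-S1+Pps-S2", "Pps-S2+Pps-S5", "Pps-S2+Pps-S8")
                   %in% d$class))
  # 6 egg classes x 3 accepted pollen classes, each cell 1/18
  oracle <- oracle_cross_dist(enumerate_gametes(cr$seed_parent),
                              enumerate_gametes(cr$pollen_parent),
                              accept = acc$accepted)
  expect_dist_equal(d, oracle)
})

test_that("expected distributions equal the explicit gamete-pair double loop on all configured crosses", {
  crosses <- list(
    cherry_cross("Dabai", "Dabai", si = FALSE),
    cherry_cross("Taishanganying", "Taishanganying", si = FALSE),
    cherry_cross("Summit", "Dabai", si = FALSE),
    cherry_cross("Summit", "Taishanganying", si = FALSE),
    cherry_cross("Dabai", "Dabai", s2_dead = TRUE),
    cherry_cross("Dabai", "Dabai", si = FALSE, alpha = 0.15),
    cherry_cross("Summit", "Dabai", si = FALSE,
                 weights = c("Pps-S1+Pps-S5" = 2, "Pps-S2+Pps-S5" = 0.5))
  )
  for (cr in crosses) {
    d <- expected_phenotype_distribution(cr)
    acc <- attr(d, "pollen")
    oracle <- oracle_cross_dist(enumerate_gametes(cr$seed_parent, cr$alpha),
                                enumerate_gametes(cr$pollen_parent, cr$alpha),
                                accept = acc$accepted, weights = acc$weight)
    expect_dist_equal(d, oracle)
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  }
})

test_that("transmission weights are scale-invariant and can silence classes", {
  gam <- enumerate_gametes(cherry_parents()$Dabai)$alleles
  w1 <- stats::setNames(c(3, 16, 12, 3, 3, 16), gam)
  d1 <- expected_phenotype_distribution(cherry_cross("Dabai", "Dabai",
                                                     si = FALSE, weights = w1))
  d2 <- expected_phenotype_distribution(cherry_cross("Dabai", "Dabai",
                                                     si = FALSE,
                                                     weights = w1 * 10))
  expect_equal(d1$class, d2$class)
  expect_equal(d1$prob, d2$prob, tolerance = 1e-12)

  # uniform weights leave the distribution at its unweighted value
  u <- stats::setNames(rep(4, 6),
                       enumerate_gametes(cherry_parents()$Dabai)$alleles)
  du <- expected_phenotype_distribution(cherry_cross("Dabai", "Dabai",
                                                     si = FALSE, weights = u))
  d0 <- expected_phenotype_distribution(cherry_cross("Dabai", "Dabai",
                                                     si = FALSE))
  expect_equal(du$prob, d0$prob, tolerance = 1e-12)

  # zero weight on every accepted class is a fully incompatible cross
  z <- stats::setNames(rep(0, 6), names(u))
  expect_error(expected_phenotype_distribution(
    cherry_cross("Dabai", "Dabai", si = FALSE, weights = z)),
    "fully incompatible")
  # as is a self cross with competition switched off and all alleles live
  expect_error(expected_phenotype_distribution(
    cherry_cross("Dabai", "Dabai", competitive = FALSE)),
    "fully incompatible")
})

test_that("allele marginals reproduce the published per-allele totals", {
  m <- allele_marginals(cherry_counts("dabai_self"))
  expect_equal(m, c("Pps-S1" = 385, "Pps-S2" = 80, "Pps-S5" = 428,
                    "Pps-S8" = 334))
  m2 <- allele_marginals(collapse_over_parent(cherry_counts("summit_x_dabai"),
                                              "Pa"))
  expect_equal(m2, c("Pps-S1" = 34, "Pps-S2" = 6, "Pps-S5" = 28,
                     "Pps-S8" = 30))
  expect_length(allele_marginals(stats::setNames(integer(0), character(0))), 0L)
  # each individual contributes once per allele it carries
  ct <- cherry_counts("taishanganying_self")
  sizes <- lengths(strsplit(ct$class, "+", fixed = TRUE))
  expect_equal(sum(allele_marginals(ct)), sum(ct$count * sizes))
})

test_that("collapsing classes over one parent reproduces the published pair-class rows", {
  v <- collapse_over_parent(cherry_counts("summit_x_dabai"), "Pa")
  expect_equal(v, c("Pps-S1+Pps-S2" = 6, "Pps-S1+Pps-S5" = 13,
                    "Pps-S1+Pps-S8" = 15, "Pps-S2+Pps-S5" = 0,
                    "Pps-S2+Pps-S8" = 0, "Pps-S5+Pps-S8" = 15))
  w <- collapse_over_parent(cherry_counts("summit_x_taishanganying"), "Pa")
  expect_equal(w, c("Pps-S1+Pps-S2" = 6, "Pps-S1+Pps-S4" = 6,
                    "Pps-S1+Pps-S6" = 6, "Pps-S2+Pps-S4" = 0,
                    "Pps-S2+Pps-S6" = 1, "Pps-S4+Pps-S6" = 5))
  # totals conserved; collapsing over an absent species is the identity
  expect_equal(sum(v), sum(cherry_counts("summit_x_dabai")$count))
  ct <- cherry_counts("dabai_self")
  expect_equal(collapse_over_parent(ct, "Pa"),
               stats::setNames(as.numeric(ct$count), ct$class))
})
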