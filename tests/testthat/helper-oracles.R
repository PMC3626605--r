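# Independent brute-force oracles used to cross-check the closed-form
# model code.  These deliberately take a different computational route
# (ordered chromosome enumeration, expand.grid + tapply aggregation)
# from the implementation.

# all ordered pairs of distinct homologues of a tetrasomic parent
# (4 x 3 = 12 equally likely cases), collapsed to unordered gametes
oracle_tetrasomic_gametes <- function(keys) {
  grid <- expand.grid(i = 1:4, j = 1:4)
  grid <- grid[grid$i != grid$j, , drop = FALSE]
  ids <- mapply(function(i, j) paste(sort(keys[c(i, j)]), collapse = "+"),
                grid$i, grid$j)
  tab <- table(ids)
  data.frame(alleles = names(tab), prob = as.vector(tab) / 12,
             stringsAsFactors = FALSE)
}

# explicit double loop over all egg x pollen gamete pairs; acceptance and
# weights supplied as vectors aligned with the pollen table
oracle_cross_dist <- function(eggs, pollen, accept = NULL, weights = NULL) {
  if (is.null(accept)) accept <- rep(TRUE, nrow(pollen))
  if (is.null(weights)) weights <- rep(1, nrow(pollen))
  p <- pollen$prob * weights * ifelse(accept, 1, 0)
  stopifnot(sum(p) > 0)
  p <- p / sum(p)
  grid <- expand.grid(i = seq_len(nrow(eggs)), j = seq_len(nrow(pollen)))
  cls <- mapply(function(i, j) {
    paste(sort(unique(c(strsplit(eggs$alleles[i], "+", fixed = TRUE)[[1]],
                        strsplit(pollen$alleles[j], "+", fixed = TRUE)[[1]]))),
          collapse = "+")
  }, grid$i, grid$j)
  pr <- eggs$prob[grid$i] * p[grid$j]
  agg <- tapply(pr, cls, sum)
  out <- data.frame(class = names(agg), prob = as.vector(agg),
                    stringsAsFactors = FALSE)
  out[out$prob > 0, , drop = FALSE]
}

# chromosome-level simulation of tetraploid gamete formation with forced
# double reduction at rate alpha
oracle_simulate_gametes <- function(keys, alpha, n, seed) {
  set.seed(seed)
  first <- sample.int(4L, n, replace = TRUE)
  dr <- stats::runif(n) < alpha
  shift <- sample.int(3L, n, replace = TRUE)
  second <- ifelse(dr, first, (first + shift - 1L) %% 4L + 1L)
  ids <- mapply(function(a, b) paste(sort(keys[c(a, b)]), collapse = "+"),
                first, second)
  table(ids) / n
}

# compare a phenotype_distribution (or gamete_distribution) with an oracle
# table on the same identifiers
expect_dist_equal <- function(dist, oracle, tol = 1e-12) {
  ids <- if ("class" %in% names(dist)) dist$class else dist$alleles
  oids <- if ("class" %in% names(oracle)) oracle$class else oracle$alleles
  expect_setequal(ids, oids)
  m <- match(ids, oids)
  expect_equal(dist$prob, oracle$prob[m], tolerance = tol)
}

# printed chi-squared values compare at the precision they were printed
# with, i.e. an absolute band
expect_chi2 <- function(actual, printed, tol = 5e-3) {
  expect_lt(abs(actual - printed), tol)
}

cherry_cross <- function(seed, pollen, si = TRUE, competitive = TRUE,
                         s2_dead = FALSE, alpha = 0, weights = NULL) {
  p <- cherry_parents(s2_pollen_dead = s2_dead)
  cross_spec(p[[seed]], p[[pollen]],
             rules = compatibility_rules(competitive_interaction = competitive,
                                         si_enabled = si),
             alpha = alpha, pollen_weights = weights)
}
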