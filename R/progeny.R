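#' Specify a cross
#'
#' Bundles the seed (style) parent, the pollen parent, the SI rule set, the
#' double-reduction rate and optional per-pollen-class transmission weights
#' into one object consumed by [expected_phenotype_distribution()] and the
#' simulator.
#'
#' Transmission weights model distortion attributed to differential
#' pollen-tube performance: they multiply the probability of each *accepted*
#' pollen gamete class before renormalisation.  Weights attach to pollen
#' gamete identifiers (e.g. `"Pps-S1+Pps-S5"`); classes not named keep
#' weight 1.
#'
#' @param seed_parent,pollen_parent [parent_genotype()] objects.  A self
#'   pollination passes the same cultivar twice.
#' @param rules A [compatibility_rules()] object.
#' @param alpha Double-reduction rate for both parents (default 0).
#' @param pollen_weights Optional named non-negative numeric vector of
#'   transmission weights keyed by pollen gamete identifier.
#' @return An object of class `cross_spec`.
#' @examples
#' dabai <- parent_genotype("Dabai", lapply(c("S1","S2","S5","S8"), s_haplotype))
#' cross_spec(dabai, dabai, compatibility_rules(si_enabled = FALSE))
#' @export
cross_spec <- function(seed_parent, pollen_parent,
                       rules = compatibility_rules(), alpha = 0,
                       pollen_weights = NULL) {
  stopifnot(inherits(seed_parent, "parent_genotype"),
            inherits(pollen_parent, "parent_genotype"),
            inherits(rules, "si_rules"))
  if (!is.null(pollen_weights)) {
    if (is.null(names(pollen_weights)) || any(!nzchar(names(pollen_weights))))
      stop("'pollen_weights' must be a named vector keyed by gamete identifier")
    if (any(pollen_weights < 0) || any(!is.finite(pollen_weights)))
      stop("'pollen_weights' must be finite and non-negative")
    # canonicalise key order within each identifier
    names(pollen_weights) <- vapply(names(pollen_weights),
                                    function(k) gamete_id(split_alleles(k)),
                                    character(1))
  }
  structure(
    list(seed_parent = seed_parent, pollen_parent = pollen_parent,
         rules = rules, alpha = alpha, pollen_weights = pollen_weights),
    class = "cross_spec"
  )
}

#' @export
print.cross_spec <- function(x, ...) {
  cat(sprintf("<cross %s x %s%s%s>\n", x$seed_parent$name,
              x$pollen_parent$name,
              if (!x$rules$si_enabled) ", SI off" else "",
              if (x$alpha > 0) sprintf(", alpha=%g", x$alpha) else ""))
  invisible(x)
}

#' Expected progeny S-phenotype class distribution
#'
#' Combines the egg and pollen gamete distributions of a cross into the
#' expected distribution over progeny S-phenotype classes.  Eggs are never
#' filtered (GSI acts on pollen only).  Pollen gamete classes are filtered
#' by [is_pollen_accepted()] against the seed parent's style, re-weighted by
#' the cross's transmission weights and renormalised.  A zygote's phenotype
#' class is the *set* of distinct allele keys contributed by the two
#' gametes: presence/absence genotyping is dosage-blind, so an egg and a
#' pollen grain sharing an allele yield a smaller class.
#'
#' @param cross A [cross_spec()].
#' @return A `phenotype_distribution`: data frame with columns `class`
#'   ("+"-joined sorted allele keys) and `prob`, ordered by class size then
#'   lexically; probabilities sum to 1.  The pollen acceptance table used is
#'   attached as attribute `"pollen"`.
#' @examples
#' dabai <- parent_genotype("Dabai", lapply(c("S1","S2","S5","S8"), s_haplotype))
#' d <- expected_phenotype_distribution(
#'   cross_spec(dabai, dabai, compatibility_rules(si_enabled = FALSE)))
#' expected_ratio(d)   # 1:1:1:1:1:1:6:6:6:6:6
#' @export
expected_phenotype_distribution <- function(cross) {
  stopifnot(inherits(cross, "cross_spec"))
  eggs <- enumerate_gametes(cross$seed_parent, cross$alpha)
  pollen <- enumerate_gametes(cross$pollen_parent, cross$alpha)
  style <- style_context(cross$seed_parent)

  acc <- pollen_acceptance_table(pollen, style, cross$rules)
  w <- rep(1, nrow(acc))
  if (!is.null(cross$pollen_weights)) {
    hit <- match(acc$alleles, names(cross$pollen_weights))
    w[!is.na(hit)] <- cross$pollen_weights[hit[!is.na(hit)]]
  }
  acc$weight <- ifelse(acc$accepted, w, 0)
  total <- sum(acc$prob * acc$weight)
  if (total <= 0)
    stop("cross fully incompatible: no pollen gamete class is both accepted ",
         "and positively weighted")
  pprob <- acc$prob * acc$weight / total

  cls <- character(0)
  prob <- numeric(0)
  env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(eggs))) {
    ek <- split_alleles(eggs$alleles[i])
    for (j in seq_len(nrow(acc))) {
      if (pprob[j] == 0) next
      id <- gamete_id(unique(c(ek, split_alleles(acc$alleles[j]))))
      p <- eggs$prob[i] * pprob[j]
      assign(id, p + (if (exists(id, envir = env)) get(id, envir = env) else 0),
             envir = env)
    }
  }
  ids <- ls(env)
  out <- data.frame(class = ids,
                    prob = vapply(ids, get, numeric(1), envir = env),
                    stringsAsFactors = FALSE)
  out <- out[order_phenotype_classes(out$class), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("phenotype_distribution", "data.frame"),
            cross = cross, pollen = acc)
}

#' @export
print.phenotype_distribution <- function(x, digits = 4, ...) {
  cr <- attr(x, "cross")
  cat(sprintf("Expected S-phenotype classes, %s x %s (%d classes)\n",
              cr$seed_parent$name, cr$pollen_parent$name, nrow(x)))
  print(data.frame(class = x$class, prob = round(x$prob, digits)),
        row.names = FALSE)
  invisible(x)
}

#' Canonical ordering of phenotype classes
#'
#' Classes are reported with smaller allele sets first (2-allele, then
#' 3-allele, ...) and lexically within a size — the convention used for all
#' package output so tables diff cleanly.
#'
#' @param classes Character vector of "+"-joined class identifiers.
#' @return Integer permutation ordering `classes`.
#' @export
order_phenotype_classes <- function(classes) {
  sizes <- lengths(strsplit(as.character(classes), "+", fixed = TRUE))
  order(sizes, classes)
}

#' Smallest-integer expected ratio of a phenotype distribution
#'
#' Converts class probabilities to the smallest vector of integers with the
#' same proportions (e.g. the 1:1:1:1:1:1:6:6:6:6:6 expectation of a
#' tetrasomic self cross), using exact rational reconstruction of the
#' floating-point probabilities.
#'
#' @param dist A `phenotype_distribution` (or bare numeric probability
#'   vector).
#' @param max_denominator Largest denominator considered when recovering
#'   rationals (default 1e6).
#' @return Named integer vector aligned with the distribution's classes.
#' @export
expected_ratio <- function(dist, max_denominator = 1e6) {
  p <- if (is.data.frame(dist)) dist$prob else as.numeric(dist)
  fr <- MASS::fractions(p, cycles = 12, max.denominator = max_denominator)
  txt <- strsplit(attr(fr, "fracs"), "/", fixed = TRUE)
  num <- vapply(txt, function(z) as.numeric(z[1L]), numeric(1))
  den <- vapply(txt, function(z) if (length(z) > 1L) as.numeric(z[2L]) else 1,
                numeric(1))
  l <- Reduce(lcm2, den)
  ints <- round(num * (l / den))
  g <- Reduce(gcd2, ints[ints > 0])
  ratio <- as.integer(ints / g)
  names(ratio) <- if (is.data.frame(dist)) dist$class else NULL
  ratio
}

gcd2 <- function(a, b) { while (b != 0) { t <- b; b <- a %% b; a <- t }; a }
lcm2 <- function(a, b) a / gcd2(a, b) * b

#' Allele marginals of a progeny count table
#'
#' For each allele key, the number of progeny individuals carrying it; an
#' individual contributes to every allele in its class (so marginals sum to
#' total individuals times mean alleles per individual).
#'
#' @param counts Named integer vector (names are class identifiers) or a
#'   `count_table` data frame with columns `class` and `count`.
#' @return Named integer vector of per-allele counts, names sorted.
#' @examples
#' allele_marginals(c("Pps-S1+Pps-S5" = 90, "Pps-S1+Pps-S2+Pps-S5" = 14))
#' @export
allele_marginals <- function(counts) {
  counts <- as_count_vector(counts)
  out <- new.env(parent = emptyenv())
  for (i in seq_along(counts)) {
    for (k in split_alleles(names(counts)[i])) {
      assign(k, counts[[i]] +
               (if (exists(k, envir = out)) get(k, envir = out) else 0),
             envir = out)
    }
  }
  ks <- sort(ls(out))
  stats::setNames(vapply(ks, get, numeric(1), envir = out), ks)
}

#' Collapse progeny classes over one parent's alleles
#'
#' Removes every allele belonging to `parent_species` from each class and
#' sums counts of classes that coincide afterwards.  Used to reduce the 12
#' interspecific cross classes (P. pseudocerasus pair x P. avium allele) to
#' the 6 pollen-pair classes.
#'
#' @param counts Named integer vector or `count_table`.
#' @param parent_species Species tag to strip (e.g. `"Pa"`).
#' @return Named integer vector over the collapsed classes, in canonical
#'   order.  Total count is preserved.
#' @export
collapse_over_parent <- function(counts, parent_species) {
  counts <- as_count_vector(counts)
  stripped <- vapply(names(counts), function(id) {
    ks <- split_alleles(id)
    keep <- ks[species_of(ks) != parent_species]
    if (!length(keep))
      stop("class '", id, "' is empty after removing species '",
           parent_species, "'")
    gamete_id(keep)
  }, character(1))
  agg <- tapply(counts, stripped, sum)
  out <- stats::setNames(as.vector(agg), names(agg))
  out[order_phenotype_classes(names(out))]
}

species_of <- function(keys) sub("-.*$", "", keys)

as_count_vector <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("class", "count") %in% names(counts)))
    counts <- stats::setNames(counts$count, counts$class)
  }
  if (is.null(names(counts)) && length(counts) > 0L)
    stop("counts must be named by phenotype class identifier")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  # canonicalise identifiers, reject duplicate alleles within a class
  nm <- vapply(names(counts), function(id) {
    ks <- split_alleles(id)
    if (anyDuplicated(ks))
      stop("duplicate allele within class '", id, "' (classes are sets)")
    gamete_id(ks)
  }, character(1))
  if (anyDuplicated(nm))
    stop("duplicate phenotype class: ", paste(nm[duplicated(nm)], collapse = ", "))
  stats::setNames(as.numeric(counts), nm)
}
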