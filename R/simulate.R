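#' Simulate progeny S-phenotype count tables
#'
#' Draws multinomial progeny class counts from the expected distribution of
#' a cross — the sampling model the chi-squared analysis assumes.  Each
#' replicate `r` is seeded with `seed + r - 1L`, so a replicate can be
#' regenerated on its own and replicates are mutually independent.
#'
#' @param cross A [cross_spec()].
#' @param n_progeny Progeny per replicate (>= 1).
#' @param seed Integer seed; identical seed and configuration give
#'   bit-identical counts.
#' @param n_replicates Number of independent progeny tables (default 1).
#' @param event_level If `TRUE`, use per-pollination rejection sampling
#'   (draw egg and pollen gametes and apply the acceptance rule event by
#'   event) instead of one multinomial draw from the closed-form class
#'   distribution.  Slower; used to cross-validate the closed form.
#' @return Integer matrix with one row per phenotype class (canonical
#'   order) and one column per replicate; each column sums to `n_progeny`.
#'   The expected distribution is attached as attribute `"distribution"`.
#' @examples
#' dabai <- parent_genotype("Dabai", lapply(c("S1","S2","S5","S8"), s_haplotype))
#' cr <- cross_spec(dabai, dabai, compatibility_rules(si_enabled = FALSE))
#' simulate_progeny_counts(cr, n_progeny = 438, seed = 1)
#' @export
simulate_progeny_counts <- function(cross, n_progeny, seed,
                                    n_replicates = 1L, event_level = FALSE) {
  stopifnot(inherits(cross, "cross_spec"),
            n_progeny >= 1, n_progeny == round(n_progeny),
            n_replicates >= 1, n_replicates == round(n_replicates),
            is.numeric(seed), length(seed) == 1L)
  dist <- expected_phenotype_distribution(cross)
  out <- matrix(0L, nrow = nrow(dist), ncol = n_replicates,
                dimnames = list(dist$class, NULL))
  for (r in seq_len(n_replicates)) {
    set.seed(as.integer(seed) + r - 1L)
    if (event_level) {
      out[, r] <- simulate_events(cross, dist$class, n_progeny)
    } else {
      out[, r] <- as.integer(stats::rmultinom(1L, n_progeny, dist$prob))
    }
  }
  structure(out, distribution = dist)
}

# event-level cross-validation path: sample gametes and apply the
# acceptance rule per pollination rather than using the closed form
simulate_events <- function(cross, classes, n_progeny) {
  eggs <- enumerate_gametes(cross$seed_parent, cross$alpha)
  pollen <- enumerate_gametes(cross$pollen_parent, cross$alpha)
  style <- style_context(cross$seed_parent)
  acc <- pollen_acceptance_table(pollen, style, cross$rules)
  w <- rep(1, nrow(acc))
  if (!is.null(cross$pollen_weights)) {
    hit <- match(acc$alleles, names(cross$pollen_weights))
    w[!is.na(hit)] <- cross$pollen_weights[hit[!is.na(hit)]]
  }
  counts <- stats::setNames(integer(length(classes)), classes)
  done <- 0L
  guard <- 0L
  while (done < n_progeny) {
    guard <- guard + 1L
    if (guard > 1e7) stop("event-level simulation failed to progress")
    j <- sample.int(nrow(acc), 1L, prob = acc$prob * w)
    if (!acc$accepted[j]) next
    i <- sample.int(nrow(eggs), 1L, prob = eggs$prob)
    id <- gamete_id(unique(c(split_alleles(eggs$alleles[i]),
                             split_alleles(acc$alleles[j]))))
    counts[id] <- counts[id] + 1L
    done <- done + 1L
  }
  counts
}

#' Rank candidate cross models against an observed count table
#'
#' Scores each candidate [cross_spec()] by the chi-squared goodness of fit
#' of the observed counts against the candidate's expected class
#' distribution and returns the candidates ranked by ascending chi2.  A
#' candidate under which the cross is fully incompatible (it predicts no
#' progeny at all), or which assigns zero probability to an observed class,
#' scores `Inf` — it cannot explain the data.
#'
#' The observed table must contain a row (possibly zero) for every class of
#' every candidate's distribution, so that all candidates are compared on a
#' common class universe.
#'
#' @param observed Named counts or `count_table`.
#' @param candidates Named list of [cross_spec()] objects.
#' @param alpha_level Passed to [chi2_gof()].
#' @return Data frame ranked by chi2 with columns `model`, `chi2`, `df`,
#'   `fits`; attribute `"results"` carries the full `gof_result` per
#'   candidate.
#' @export
recover_parameters <- function(observed, candidates, alpha_level = 0.05) {
  stopifnot(is.list(candidates), length(candidates) >= 1L)
  if (is.null(names(candidates)))
    names(candidates) <- paste0("model_", seq_along(candidates))
  obs <- as_count_vector(observed)
  results <- lapply(candidates, function(cand) {
    dist <- tryCatch(expected_phenotype_distribution(cand),
                     error = function(e) NULL)
    if (is.null(dist))
      return(list(chi2 = Inf, df = length(obs) - 1L, fits = FALSE,
                  impossible = TRUE))
    missing_rows <- setdiff(dist$class, names(obs))
    obs2 <- c(obs, stats::setNames(rep(0, length(missing_rows)), missing_rows))
    ratio <- dist$prob[match(names(obs2), dist$class)]
    ratio[is.na(ratio)] <- 0
    chi2_gof(obs2, ratio, alpha_level)
  })
  tab <- data.frame(
    model = names(candidates),
    chi2 = vapply(results, `[[`, numeric(1), "chi2"),
    df = vapply(results, `[[`, numeric(1), "df"),
    fits = vapply(results, function(r) isTRUE(r$fits), logical(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$chi2, tab$model), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, results = results)
}
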