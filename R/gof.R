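#' Pearson chi-squared goodness of fit against a segregation ratio
#'
#' Tests observed progeny class counts against expectations proportional to
#' a ratio vector (`expected_i = total * ratio_i / sum(ratio)`).  Zero-ratio
#' cells follow the segregation-analysis convention: a cell expected 0 and
#' observed 0 contributes nothing (but still counts towards the degrees of
#' freedom, df = k - 1 over all k cells); a cell expected 0 but observed
#' positive makes the model impossible and the statistic infinite.  No
#' continuity correction is applied.
#'
#' @param observed Non-negative integer counts; a named vector or a
#'   `count_table` is accepted, a bare numeric vector too.
#' @param ratio Non-negative ratio terms, same length as `observed`.  A
#'   `phenotype_distribution` may be passed; its probabilities are matched
#'   to `observed` by class name when `observed` is named.
#' @param alpha_level Significance level for the critical value (default
#'   0.05).
#' @return A `gof_result` list: `chi2`, `df`, `alpha_level`, `critical`,
#'   `fits` (chi2 <= critical), `p_value`, `contributions`, `expected`,
#'   `observed`, `ratio`, and `impossible` (TRUE when a zero-expectation
#'   cell was observed).
#' @examples
#' chi2_gof(c(25, 24), c(1, 1))                     # chi2 = 0.0204, fits
#' chi2_gof(c(6, 13, 15, 15, 0, 0), c(1, 2, 2, 2, 0, 0))  # chi2 = 0.357
#' @export
chi2_gof <- function(observed, ratio, alpha_level = 0.05) {
  obs_names <- if (is.data.frame(observed)) observed$class else names(observed)
  obs <- if (is.data.frame(observed)) observed$count else as.numeric(observed)
  if (inherits(ratio, "phenotype_distribution")) {
    if (!is.null(obs_names)) {
      key <- vapply(obs_names, function(id) gamete_id(split_alleles(id)),
                    character(1))
      m <- match(key, ratio$class)
      r <- ifelse(is.na(m), 0, ratio$prob[m])
      missed <- setdiff(ratio$class, key)
      if (length(missed))
        stop("observed table lacks model classes: ",
             paste(missed, collapse = ", "),
             " (add zero-count rows to align the class universe)")
      ratio <- r
    } else ratio <- ratio$prob
  }
  ratio <- as.numeric(ratio)
  if (length(obs) != length(ratio))
    stop("'observed' and 'ratio' must have the same length")
  if (any(obs < 0) || any(obs != round(obs)))
    stop("'observed' must be non-negative integers")
  if (any(ratio < 0) || all(ratio == 0))
    stop("'ratio' must be non-negative with at least one positive term")
  total <- sum(obs)
  if (total <= 0) stop("total observed count must be positive")
  stopifnot(alpha_level > 0, alpha_level < 1)

  expected <- total * ratio / sum(ratio)
  contributions <- numeric(length(obs))
  pos <- expected > 0
  contributions[pos] <- (obs[pos] - expected[pos])^2 / expected[pos]
  impossible <- any(!pos & obs > 0)
  chi2 <- if (impossible) Inf else sum(contributions)
  df <- length(obs) - 1L
  critical <- critical_value(df, alpha_level)
  structure(
    list(chi2 = chi2, df = df, alpha_level = alpha_level,
         critical = critical, fits = chi2 <= critical,
         p_value = if (is.finite(chi2)) stats::pchisq(chi2, df,
                                                      lower.tail = FALSE) else 0,
         contributions = contributions, expected = expected,
         observed = obs, ratio = ratio, classes = obs_names,
         impossible = impossible),
    class = "gof_result"
  )
}

#' @export
print.gof_result <- function(x, ...) {
  verdict <- if (x$impossible) "impossible under model (observed count in a zero-expectation class)"
             else if (x$fits) "fits" else "does not fit"
  cat(sprintf("chi2 = %s, df = %d, chi2[%.2g, %d] = %.3f -> %s\n",
              if (is.finite(x$chi2)) sprintf("%.3f", x$chi2) else "Inf",
              x$df, x$alpha_level, x$df, x$critical, verdict))
  invisible(x)
}

#' Format a goodness-of-fit result as a per-class report table
#'
#' @param result A `gof_result`.
#' @return Data frame with one row per class: observed, ratio term, expected
#'   count and chi-squared contribution.
#' @export
gof_report <- function(result) {
  stopifnot(inherits(result, "gof_result"))
  data.frame(
    class = if (is.null(result$classes)) seq_along(result$observed)
            else result$classes,
    observed = result$observed, ratio = result$ratio,
    expected = result$expected, contribution = result$contributions,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Upper-tail chi-squared critical value
#'
#' @param df Degrees of freedom (>= 1).
#' @param alpha_level Upper-tail probability (default 0.05).
#' @return The quantile such that P(Chi2_df > value) = alpha_level; e.g.
#'   3.84 (df 1), 7.815 (df 3), 11.07 (df 5), 19.68 (df 11) at 0.05.
#' @export
critical_value <- function(df, alpha_level = 0.05) {
  stopifnot(df >= 1, df == round(df), alpha_level > 0, alpha_level < 1)
  stats::qchisq(alpha_level, df = df, lower.tail = FALSE)
}

#' Exhaustive small-integer segregation-ratio search
#'
#' Scores every integer ratio vector with terms in 0..`max_term` (excluding
#' the all-zero vector, de-duplicated up to common scaling) against the
#' observed counts by the chi-squared statistic of [chi2_gof()], and returns
#' the best fits.  Formalises the practice of quoting an approximating
#' small-integer ratio such as 5:1:5:5 for a distorted segregation.
#'
#' @param observed Non-negative integer counts (length <= 8).
#' @param max_term Largest integer allowed in a ratio term.
#' @param top_k Number of candidates to return (default 10).
#' @param alpha_level Passed to [chi2_gof()].
#' @return Data frame ranked by ascending chi2 (ties broken by lexical term
#'   order) with columns `ratio` (":"-joined terms), `chi2`, `fits`.
#' @examples
#' find_candidate_ratios(c(34, 6, 28, 30), max_term = 5)[1, ]  # 5:1:5:5
#' @export
find_candidate_ratios <- function(observed, max_term, top_k = 10,
                                  alpha_level = 0.05) {
  observed <- if (is.data.frame(observed)) observed$count
              else as.numeric(observed)
  k <- length(observed)
  stopifnot(max_term >= 1, max_term == round(max_term), top_k >= 1)
  if (k > 8L)
    stop("observed vector longer than 8 classes; ratio search is exhaustive")
  n_grid <- (max_term + 1)^k
  if (n_grid > 5e6)
    stop("search space of ", format(n_grid, big.mark = ","),
         " ratio vectors is too large; reduce 'max_term'")
  grid <- as.matrix(expand.grid(rep(list(0:max_term), k)))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  # canonical representative: divide by gcd of terms, drop duplicates
  g <- apply(grid, 1L, function(r) Reduce(gcd2, r[r > 0]))
  grid <- unique(grid / g)
  chi2 <- apply(grid, 1L, function(r)
    chi2_gof(observed, r, alpha_level)$chi2)
  key <- apply(grid, 1L, paste, collapse = ":")
  ord <- order(chi2, key)
  ord <- ord[seq_len(min(top_k, length(ord)))]
  crit <- critical_value(k - 1L, alpha_level)
  data.frame(ratio = key[ord], chi2 = chi2[ord],
             fits = chi2[ord] <= crit,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify a pollination by fruit set
#'
#' Field criterion for compatibility of a self- or cross-pollination: the
#' percentage of pollinated flowers that set fruit, compatible at or above
#' the threshold (default 2%).
#'
#' @param set_fruits Number of fruits set.
#' @param pollinated_flowers Number of flowers pollinated (> 0).
#' @param threshold_percent Compatibility threshold in percent (default 2).
#' @return `"compatible"` or `"incompatible"`, with the percentage attached
#'   as attribute `"percent"`.
#' @examples
#' classify_fruit_set(105, 5212)  # 2.01% -> compatible
#' @export
classify_fruit_set <- function(set_fruits, pollinated_flowers,
                               threshold_percent = 2.0) {
  if (pollinated_flowers <= 0) stop("'pollinated_flowers' must be positive")
  stopifnot(set_fruits >= 0, set_fruits <= pollinated_flowers)
  pct <- 100 * set_fruits / pollinated_flowers
  structure(if (pct >= threshold_percent) "compatible" else "incompatible",
            percent = pct)
}
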