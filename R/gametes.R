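#' Enumerate gamete classes of a parent
#'
#' Diploid parents produce monoploid gametes (each homologue with
#' probability 1/2).  Tetrasomic tetraploids produce hetero-diploid gametes:
#' every unordered pair of two of the four homologues, each with probability
#' `(1 - alpha) / 6`, plus — when the double-reduction rate `alpha` is
#' positive — the four homozygous doubletons with probability `alpha / 4`
#' each.  Fixed disomic pairing restricts gametes to the four inter-subgenome
#' pairs at 1/4 each (`alpha` does not apply).
#'
#' @param parent A [parent_genotype()].
#' @param alpha Double-reduction rate in \[0, 1\]; probability that a
#'   tetraploid gamete carries two copies of the same homologue.  Default 0.
#'   Ignored for diploid and disomic-fixed parents.
#'
#' @return A `gamete_distribution`: a data frame with columns `alleles`
#'   (canonical "+"-joined sorted allele keys) and `prob`, summing to 1.
#' @examples
#' dabai <- parent_genotype("Dabai", lapply(c("S1", "S2", "S5", "S8"),
#'                                          s_haplotype))
#' enumerate_gametes(dabai)             # six pairs, 1/6 each
#' enumerate_gametes(dabai, alpha = .1) # plus four homozygous doubletons
#' @export
enumerate_gametes <- function(parent, alpha = 0) {
  stopifnot(inherits(parent, "parent_genotype"),
            is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  keys <- parent_keys(parent)

  if (parent$ploidy == 2L) {
    tab <- table(keys)
    out <- data.frame(alleles = names(tab),
                      prob = as.vector(tab) / 2,
                      stringsAsFactors = FALSE)
  } else if (parent$pairing_mode == "disomic_fixed") {
    p1 <- keys[parent$subgenome_pairs[[1L]]]
    p2 <- keys[parent$subgenome_pairs[[2L]]]
    combos <- expand.grid(a = p1, b = p2, stringsAsFactors = FALSE)
    out <- data.frame(alleles = apply(combos, 1L, gamete_id),
                      prob = rep(1 / 4, 4L), stringsAsFactors = FALSE)
  } else {
    if (anyDuplicated(keys))
      stop("tetrasomic gamete enumeration requires four distinct S-haplotypes; ",
           "duplicated allele(s): ",
           paste(unique(keys[duplicated(keys)]), collapse = ", "))
    pairs <- utils::combn(keys, 2L)
    out <- data.frame(
      alleles = apply(pairs, 2L, gamete_id),
      prob = rep((1 - alpha) / 6, 6L),
      stringsAsFactors = FALSE
    )
    if (alpha > 0) {
      out <- rbind(out, data.frame(
        alleles = vapply(keys, function(k) gamete_id(c(k, k)), character(1)),
        prob = rep(alpha / 4, 4L), stringsAsFactors = FALSE
      ))
    }
  }
  out <- out[order(out$alleles), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("gamete_distribution", "data.frame"),
            parent = parent)
}

#' Canonical gamete identifier
#'
#' Sorts allele keys and joins them with `"+"`.  Gamete identity is the
#' unordered multiset of keys; homozygous doubletons keep both copies
#' (`"Pps-S1+Pps-S1"`).
#'
#' @param keys Character vector of allele keys.
#' @return Single string.
#' @export
gamete_id <- function(keys) paste(sort(as.character(keys)), collapse = "+")

#' Split a gamete or class identifier back into allele keys
#'
#' @param id "+"-joined identifier string(s).
#' @return For a single id, a character vector of keys; vectorised input
#'   returns a list.
#' @export
split_alleles <- function(id) {
  parts <- strsplit(as.character(id), "+", fixed = TRUE)
  if (length(parts) == 1L) parts[[1L]] else parts
}

#' @export
print.gamete_distribution <- function(x, digits = 4, ...) {
  p <- attr(x, "parent")
  cat(sprintf("Gamete distribution for %s (%d classes)\n", p$name, nrow(x)))
  print(data.frame(alleles = x$alleles, prob = round(x$prob, digits)),
        row.names = FALSE)
  invisible(x)
}
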