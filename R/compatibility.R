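#' Gametophytic self-incompatibility rule set
#'
#' @param competitive_interaction If `TRUE` (default), a pollen grain
#'   carrying two *different* functional S-specificities escapes stylar
#'   rejection regardless of the style's genotype — the competitive
#'   interaction underlying self-compatibility of hetero-diploid pollen.
#'   If `FALSE`, each effective specificity is tested independently and any
#'   match with the style rejects the grain.
#' @param si_enabled If `FALSE`, self-incompatibility is switched off
#'   entirely and every pollen class is accepted (models a fully compatible
#'   cross).
#' @param accept_null_pollen How to treat gametes with *no* functional
#'   pollen specificity (all haplotypes pollen-dead): `TRUE` (default)
#'   accepts them, following the pollen-part-mutant literature; `FALSE`
#'   models such grains as aborted/rejected.
#'
#' @return An object of class `si_rules`.
#' @export
compatibility_rules <- function(competitive_interaction = TRUE,
                                si_enabled = TRUE,
                                accept_null_pollen = TRUE) {
  structure(
    list(competitive_interaction = isTRUE(competitive_interaction),
         si_enabled = isTRUE(si_enabled),
         accept_null_pollen = isTRUE(accept_null_pollen)),
    class = "si_rules"
  )
}

#' Style context of a seed parent
#'
#' The set of S-specificities a style presents: every allele of the seed
#' parent whose S-RNase is functional (`style_active`).
#'
#' @param parent A [parent_genotype()].
#' @return Character vector of allele keys (class `style_context`).
#' @export
style_context <- function(parent) {
  act <- functionality_map(parent, "style")
  structure(names(act)[act], class = "style_context")
}

#' Effective pollen specificities of a gamete
#'
#' The distinct specificities a style can "see" in a pollen grain: alleles
#' whose SFB is functional.  Pollen-dead haplotypes are invisible, so a
#' hetero-diploid grain carrying one dead haplotype behaves like a monoploid
#' grain of the other.
#'
#' @param gamete Gamete allele keys — a character vector or a "+"-joined
#'   identifier.
#' @param parent The [parent_genotype()] that produced the gamete (source of
#'   the functionality flags).
#' @return Character vector (possibly empty) of distinct functional keys.
#' @examples
#' dabai <- parent_genotype("Dabai", list(
#'   s_haplotype("S1"), s_haplotype("S2", pollen_active = FALSE),
#'   s_haplotype("S5"), s_haplotype("S8")))
#' effective_pollen_specificities("Pps-S2+Pps-S5", dabai)  # "Pps-S5"
#' @export
effective_pollen_specificities <- function(gamete, parent) {
  keys <- unique(if (length(gamete) == 1L) split_alleles(gamete)
                 else as.character(gamete))
  act <- functionality_map(parent, "pollen")
  unknown <- setdiff(keys, names(act))
  if (length(unknown))
    stop("gamete allele(s) not in parent genotype: ",
         paste(unknown, collapse = ", "))
  keys[act[keys]]
}

#' Does a style accept a pollen gamete?
#'
#' Applies the GSI decision rule.  Let E be the effective specificities of
#' the grain ([effective_pollen_specificities()]).  With SI on:
#' \itemize{
#'   \item |E| >= 2 and competitive interaction on: accepted (the two
#'     functional specificities neutralise stylar S-RNase);
#'   \item |E| >= 2 and competitive interaction off: accepted only if no
#'     specificity in E matches the style;
#'   \item |E| = 1: accepted iff that specificity is absent from the style;
#'   \item |E| = 0: decided by `rules$accept_null_pollen`.
#' }
#' Specificity matching is on full species-qualified keys, so alleles from
#' different species never match each other.
#'
#' @param gamete Gamete allele keys or "+"-joined identifier.
#' @param style A [style_context()] (or character vector of style keys).
#' @param parent The pollen parent (functionality flags).
#' @param rules A [compatibility_rules()] object.
#' @return Logical scalar.
#' @export
is_pollen_accepted <- function(gamete, style, parent,
                               rules = compatibility_rules()) {
  stopifnot(inherits(rules, "si_rules"))
  if (!rules$si_enabled) return(TRUE)
  eff <- effective_pollen_specificities(gamete, parent)
  n <- length(eff)
  if (n == 0L) return(rules$accept_null_pollen)
  if (n >= 2L && rules$competitive_interaction) return(TRUE)
  !any(eff %in% as.character(style))
}

#' Per-gamete acceptance table for a cross
#'
#' Convenience/logging view: every pollen gamete class with its effective
#' specificities and the acceptance decision on the given style.
#'
#' @param pollen A `gamete_distribution` from the pollen parent.
#' @param style A [style_context()].
#' @param rules A [compatibility_rules()] object.
#' @return Data frame with columns `alleles`, `prob`, `effective`,
#'   `accepted`.
#' @export
pollen_acceptance_table <- function(pollen, style,
                                    rules = compatibility_rules()) {
  stopifnot(inherits(pollen, "gamete_distribution"))
  parent <- attr(pollen, "parent")
  eff <- vapply(pollen$alleles, function(g)
    paste(effective_pollen_specificities(g, parent), collapse = "+"),
    character(1))
  acc <- vapply(pollen$alleles, is_pollen_accepted, logical(1),
                style = style, parent = parent, rules = rules)
  data.frame(alleles = pollen$alleles, prob = pollen$prob,
             effective = eff, accepted = acc,
             row.names = NULL, stringsAsFactors = FALSE)
}
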