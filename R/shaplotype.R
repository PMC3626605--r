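#' Construct an S-haplotype
#'
#' An S-haplotype is the linked pair of a stylar S-RNase allele and a
#' pollen-expressed SFB allele.  Either side can be non-functional: a
#' haplotype with `style_active = FALSE` is invisible in the pistil, one with
#' `pollen_active = FALSE` is a pollen-part mutant whose specificity the
#' style cannot reject.
#'
#' @param label Short allele label, e.g. `"S1"`.  Must be non-empty and must
#'   not contain the reserved characters `"+"` or `"-"`.
#' @param species Species/genome tag, e.g. `"Pps"` (*Prunus pseudocerasus*)
#'   or `"Pa"` (*P. avium*).  Alleles with equal labels but different tags
#'   are distinct specificities.
#' @param style_active Is the S-RNase functional in the style?
#' @param pollen_active Is the SFB functional in pollen?
#'
#' @return An object of class `s_haplotype`.
#' @examples
#' s_haplotype("S2", "Pps", pollen_active = FALSE)  # pollen-part mutant
#' @export
s_haplotype <- function(label, species = "Pps", style_active = TRUE,
                        pollen_active = TRUE) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            is.character(species), length(species) == 1L, nzchar(species))
  if (grepl("[+-]", label) || grepl("[+-]", species))
    stop("allele labels and species tags must not contain '+' or '-'")
  structure(
    list(label = label, species = species,
         style_active = isTRUE(style_active),
         pollen_active = isTRUE(pollen_active)),
    class = "s_haplotype"
  )
}

#' @export
print.s_haplotype <- function(x, ...) {
  flags <- paste0(if (!x$style_active) " style-dead" else "",
                  if (!x$pollen_active) " pollen-dead" else "")
  cat(sprintf("<S-haplotype %s%s>\n", allele_key(x), flags))
  invisible(x)
}

#' Fully qualified allele key
#'
#' Species-prefixed label (`"Pps-S1"`), the identity used throughout for
#' gametes and phenotype classes.
#'
#' @param x An `s_haplotype`, or a character vector already in key form.
#' @return Character vector of keys.
#' @export
allele_key <- function(x) {
  if (inherits(x, "s_haplotype")) return(paste(x$species, x$label, sep = "-"))
  as.character(x)
}

#' Construct a parent genotype
#'
#' A cultivar with its S-locus constitution.  Tetraploids segregate either
#' tetrasomically (random pairing of the four homologues, all C(4,2) gamete
#' pairs) or with fixed subgenome pairing (`"disomic_fixed"`, as in sour
#' cherry, where only the four inter-pair gametes form).
#'
#' @param name Cultivar name.
#' @param haplotypes List of [s_haplotype()] objects; length 2 or 4 sets the
#'   ploidy.
#' @param pairing_mode `"tetrasomic"` (default for tetraploids) or
#'   `"disomic_fixed"`.
#' @param subgenome_pairs For `"disomic_fixed"` only: a list of two integer
#'   pairs partitioning positions 1..4 of `haplotypes`, e.g.
#'   `list(c(1, 2), c(3, 4))`.
#'
#' @return An object of class `parent_genotype`.
#' @examples
#' dabai <- parent_genotype("Dabai", lapply(c("S1", "S2", "S5", "S8"),
#'                                          s_haplotype))
#' @export
parent_genotype <- function(name, haplotypes, pairing_mode = "tetrasomic",
                            subgenome_pairs = NULL) {
  stopifnot(is.character(name), length(name) == 1L, is.list(haplotypes))
  if (!all(vapply(haplotypes, inherits, logical(1), "s_haplotype")))
    stop("'haplotypes' must be a list of s_haplotype objects")
  ploidy <- length(haplotypes)
  if (!ploidy %in% c(2L, 4L))
    stop("only diploid (2) and tetraploid (4) parents are supported")
  pairing_mode <- match.arg(pairing_mode, c("tetrasomic", "disomic_fixed"))
  if (pairing_mode == "disomic_fixed") {
    if (ploidy != 4L)
      stop("pairing_mode 'disomic_fixed' requires a tetraploid parent")
    if (is.null(subgenome_pairs))
      stop("pairing_mode 'disomic_fixed' requires 'subgenome_pairs'")
    idx <- sort(as.integer(unlist(subgenome_pairs)))
    if (length(subgenome_pairs) != 2L ||
        any(lengths(subgenome_pairs) != 2L) || !identical(idx, 1:4))
      stop("'subgenome_pairs' must partition haplotype positions 1..4 into two pairs")
  } else if (!is.null(subgenome_pairs)) {
    stop("'subgenome_pairs' is only meaningful with pairing_mode 'disomic_fixed'")
  }
  keys <- vapply(haplotypes, allele_key, character(1))
  structure(
    list(name = name, ploidy = ploidy, haplotypes = haplotypes,
         pairing_mode = pairing_mode, subgenome_pairs = subgenome_pairs),
    class = "parent_genotype",
    keys = keys
  )
}

#' @export
print.parent_genotype <- function(x, ...) {
  cat(sprintf("<parent %s: %s, %s>\n", x$name,
              paste(parent_keys(x), collapse = " "),
              if (x$ploidy == 2L) "diploid" else x$pairing_mode))
  invisible(x)
}

#' Allele keys of a parent
#'
#' @param parent A `parent_genotype`.
#' @return Character vector of species-prefixed keys, one per homologue.
#' @export
parent_keys <- function(parent) {
  stopifnot(inherits(parent, "parent_genotype"))
  attr(parent, "keys")
}

# named logical lookups over a parent's haplotypes
functionality_map <- function(parent, side = c("pollen", "style")) {
  side <- match.arg(side)
  field <- if (side == "pollen") "pollen_active" else "style_active"
  vals <- vapply(parent$haplotypes, `[[`, logical(1), field)
  stats::setNames(vals, parent_keys(parent))[!duplicated(parent_keys(parent))]
}
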