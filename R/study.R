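#' Built-in cherry cultivar genotypes
#'
#' The three cultivars of the bundled Chinese cherry study:
#' \describe{
#'   \item{Dabai}{tetraploid *P. pseudocerasus*, S1 S2 S5 S8, tetrasomic}
#'   \item{Taishanganying}{tetraploid *P. pseudocerasus*, S1 S2 S4 S6,
#'     tetrasomic}
#'   \item{Summit}{diploid *P. avium* tester, S1 S2}
#' }
#' The Pps S2-haplotype carries an SFB defect and can be flagged pollen-dead
#' to model the pollen-part-mutant hypothesis; its S-RNase (style side)
#' stays functional either way.
#'
#' @param s2_pollen_dead Flag the Pps S2-haplotype as pollen non-functional
#'   (default `FALSE`).
#' @return Named list of [parent_genotype()] objects.
#' @examples
#' enumerate_gametes(cherry_parents()$Dabai)
#' @export
cherry_parents <- function(s2_pollen_dead = FALSE) {
  pps <- function(labels) lapply(labels, function(l)
    s_haplotype(l, species = "Pps",
                pollen_active = !(s2_pollen_dead && l == "S2")))
  list(
    Dabai = parent_genotype("Dabai", pps(c("S1", "S2", "S5", "S8"))),
    Taishanganying = parent_genotype("Taishanganying",
                                     pps(c("S1", "S2", "S4", "S6"))),
    Summit = parent_genotype("Summit", list(s_haplotype("S1", "Pa"),
                                            s_haplotype("S2", "Pa")))
  )
}

#' Bundled observed progeny count tables
#'
#' The four published progeny S-genotype count tables of the bundled study,
#' shipped as plain TSV under `extdata`: two interspecific crosses of the
#' diploid tester onto each tetraploid cultivar (12 classes: Pps pollen
#' pair x Pa egg allele) and two self pollinations (11 dosage-blind
#' classes).
#'
#' @param name One of `"summit_x_dabai"` (49 seedlings),
#'   `"summit_x_taishanganying"` (24), `"dabai_self"` (438),
#'   `"taishanganying_self"` (450).
#' @return A `count_table` (see [read_count_table()]).
#' @examples
#' sum(cherry_counts("dabai_self")$count)  # 438
#' @export
cherry_counts <- function(name = c("summit_x_dabai",
                                   "summit_x_taishanganying",
                                   "dabai_self", "taishanganying_self")) {
  name <- match.arg(name)
  read_count_table(system.file("extdata", paste0(name, ".tsv"),
                               package = "polySI", mustWork = TRUE))
}
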