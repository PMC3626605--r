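#' Read a progeny class count table
#'
#' Reads a TSV with header `class<TAB>count`, one row per S-phenotype
#' class.  Class syntax is "+"-joined species-prefixed allele keys, e.g.
#' `Pps-S1+Pps-S5` or `Pa-S1+Pps-S1+Pps-S2`.  Validation errors report the
#' offending line number.
#'
#' @param path File path.
#' @return A `count_table` data frame with columns `class` (canonicalised
#'   identifiers) and `count` (integer).
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("no data rows in '", path, "'")
  if (!identical(trimws(lines[1L]), "class\tcount"))
    stop("line 1: expected header 'class\tcount'")
  body <- lines[-1L]
  if (!length(body)) stop("no data rows in '", path, "'")
  cls <- character(length(body))
  cnt <- integer(length(body))
  for (i in seq_along(body)) {
    ln <- i + 1L
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 2L)
      stop("line ", ln, ": expected 2 tab-separated fields, found ",
           length(fields))
    ks <- split_alleles(fields[1L])
    if (!all(grepl("^[^+-]+-[^+-]+$", ks)))
      stop("line ", ln, ": malformed class token '", fields[1L],
           "' (expected species-prefixed keys like Pps-S1, joined by '+')")
    if (anyDuplicated(ks))
      stop("line ", ln, ": duplicate allele within class (classes are sets)")
    n <- suppressWarnings(as.numeric(fields[2L]))
    if (is.na(n) || n < 0 || n != round(n))
      stop("line ", ln, ": count '", fields[2L],
           "' is not a non-negative integer")
    cls[i] <- gamete_id(ks)
    cnt[i] <- as.integer(n)
  }
  dup <- duplicated(cls)
  if (any(dup))
    stop("line ", which(dup)[1L] + 1L, ": duplicate class '",
         cls[dup][1L], "'")
  structure(data.frame(class = cls, count = cnt, stringsAsFactors = FALSE),
            class = c("count_table", "data.frame"))
}

#' Write a progeny class count table
#'
#' Inverse of [read_count_table()]; writing then re-reading a canonical
#' table is byte-stable.
#'
#' @param counts `count_table` data frame or named integer vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  v <- as_count_vector(counts)
  writeLines(c("class\tcount",
               paste(names(v), format(v, scientific = FALSE, trim = TRUE),
                     sep = "\t")),
             path)
  invisible(path)
}

#' Read a study configuration
#'
#' Loads a YAML description of parents (with per-haplotype functionality
#' flags) and crosses into ready-to-use [parent_genotype()] and
#' [cross_spec()] objects.  The schema is strict: the file must declare
#' `schema: polySI/1` and unknown keys anywhere are errors.
#'
#' @param path YAML file path.
#' @return List with elements `parents` (named list of `parent_genotype`),
#'   `crosses` (named list of `cross_spec`) and `alpha_level`.
#' @examples
#' cfg <- read_study_config(system.file("extdata", "cherry_study.yaml",
#'                                      package = "polySI"))
#' names(cfg$crosses)
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, c("schema", "alpha_level", "parents", "crosses"), "top level")
  if (!identical(cfg$schema, "polySI/1"))
    stop("unsupported or missing schema (expected 'polySI/1')")
  alpha_level <- if (is.null(cfg$alpha_level)) 0.05 else cfg$alpha_level

  parents <- list()
  for (p in cfg$parents) {
    check_keys(p, c("name", "species", "haplotypes", "pairing_mode",
                    "subgenome_pairs"), "parent")
    if (is.null(p$name)) stop("parent without 'name'")
    haps <- lapply(p$haplotypes, function(h) {
      check_keys(h, c("label", "species", "style_active", "pollen_active"),
                 paste0("haplotype of parent '", p$name, "'"))
      if (is.null(h$label))
        stop("haplotype without 'label' in parent '", p$name, "'")
      s_haplotype(h$label,
                  species = h$species %||% p$species %||% "Pps",
                  style_active = h$style_active %||% TRUE,
                  pollen_active = h$pollen_active %||% TRUE)
    })
    pairs <- p$subgenome_pairs
    if (!is.null(pairs)) pairs <- lapply(pairs, as.integer)
    parents[[p$name]] <- parent_genotype(
      p$name, haps, pairing_mode = p$pairing_mode %||% "tetrasomic",
      subgenome_pairs = pairs)
  }

  crosses <- list()
  for (cr in cfg$crosses) {
    check_keys(cr, c("name", "seed_parent", "pollen_parent", "si_enabled",
                     "competitive_interaction", "accept_null_pollen",
                     "alpha", "pollen_weights"), "cross")
    if (is.null(cr$name)) stop("cross without 'name'")
    for (side in c("seed_parent", "pollen_parent"))
      if (is.null(cr[[side]]) || is.null(parents[[cr[[side]]]]))
        stop("cross '", cr$name, "': ", side, " '", cr[[side]],
             "' is not a configured parent")
    w <- cr$pollen_weights
    if (!is.null(w)) w <- unlist(w)
    crosses[[cr$name]] <- cross_spec(
      parents[[cr$seed_parent]], parents[[cr$pollen_parent]],
      rules = compatibility_rules(
        competitive_interaction = cr$competitive_interaction %||% TRUE,
        si_enabled = cr$si_enabled %||% TRUE,
        accept_null_pollen = cr$accept_null_pollen %||% TRUE),
      alpha = cr$alpha %||% 0,
      pollen_weights = w)
  }

  list(parents = parents, crosses = crosses, alpha_level = alpha_level)
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("unknown key(s) at ", where, ": ", paste(extra, collapse = ", "))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
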