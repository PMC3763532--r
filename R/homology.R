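#' Build a homology map
#'
#' A homology map is the cross-species locus table consumed by the origin
#' classifier: for every phylogenetic family and every species in the
#' universe, the (possibly empty) set of loci of that family in that
#' species. It is stored as one `mirna_loci` table spanning species, plus
#' the explicit species universe, so that a family absent from a species is
#' an empty set rather than a missing entry.
#'
#' Each locus may carry an `ortholog_group` label (defaulting to its
#' `phylo_family`) that identifies orthologous copies across species at a
#' finer resolution than the family: per-microRNA ages are inferred from
#' ortholog groups, while duplication/fusion logic operates on families.
#'
#' @param loci A `mirna_loci` table covering one or more species.
#' @param species Character vector: the species universe (must cover all
#'   species present in `loci`).
#' @return An object of class `homology_map`.
#' @export
homology_map <- function(loci, species) {
  loci <- validate_mirna_loci(loci)
  extra <- setdiff(unique(loci$species_id), species)
  if (length(extra) > 0)
    stop("loci from species outside the universe: ",
         paste(extra, collapse = ", "))
  hm <- list(loci = loci, species = species)
  class(hm) <- "homology_map"
  hm
}

#' Read a homology table from TSV
#'
#' Expects the `mirna_loci` columns (`mirna_id`, `species_id`, `chrom`,
#' `start`, `end`, `strand`, `annotation_family`, `phylo_family`, and
#' optionally `host_transcript`, `ortholog_group`) with a header row.
#'
#' @param path Path to a tab-separated file.
#' @param species Species universe; defaults to the species present.
#' @return A `homology_map`.
#' @export
read_homology_tsv <- function(path, species = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  loci <- validate_mirna_loci(df)
  if (is.null(species)) species <- unique(loci$species_id)
  homology_map(loci, species)
}

#' @export
print.homology_map <- function(x, ...) {
  cat("homology_map:", nrow(x$loci), "loci,",
      length(unique(x$loci$phylo_family)), "families,",
      length(x$species), "species\n")
  invisible(x)
}

# loci of a family (or ortholog group) in one species
hom_loci <- function(hom, species, family = NULL, group = NULL) {
  sel <- hom$loci$species_id == species
  if (!is.null(family)) sel <- sel & hom$loci$phylo_family == family
  if (!is.null(group)) sel <- sel & hom$loci$ortholog_group == group
  hom$loci[sel, , drop = FALSE]
}

# species possessing >= 1 locus of a family / ortholog group
hom_species_with <- function(hom, family = NULL, group = NULL) {
  sel <- rep(TRUE, nrow(hom$loci))
  if (!is.null(family)) sel <- sel & hom$loci$phylo_family == family
  if (!is.null(group)) sel <- sel & hom$loci$ortholog_group == group
  unique(hom$loci$species_id[sel])
}
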