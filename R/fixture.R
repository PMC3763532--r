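#' Load the packaged 21-cluster Drosophila melanogaster fixture
#'
#' The package ships a fixture encoding the 21 known D. melanogaster
#' microRNA clusters: member microRNAs in genomic order, the recorded
#' founding-event source (NewHairpin / Duplication / Unknown), the origin
#' lineage, and per-member family labels and ages. Genomic coordinates and
#' the cross-species presence/absence pattern are \emph{synthetic}: they are
#' constructed deterministically so that (i) cluster calling at the default
#' 10 kb threshold reproduces the 21 recorded clusters and (ii) Dollo age
#' inference on the companion 7-species tree reproduces each member's
#' recorded origin lineage. They are not real genome annotations.
#'
#' The fixture species tree has leaves dme, dsi, dps, aga, tca, lgi, hsa and
#' named lineages Melanogaster (the dme terminal branch), Drosophila,
#' Diptera, Insects, Protostomes and Metazoans. Homologs of each member are
#' placed, co-located, in every species of the clade subtended by the
#' member's recorded age.
#'
#' @return An object of class `table1_fixture`: a list with `clusters`
#'   (data.frame: `cluster_id`, `members` list-column, `species_id`,
#'   `source`, `lineage`, `original_mirna`, `notes`), `members` (per-member
#'   data.frame incl. `age_lineage`), `loci` (`mirna_loci` for dme),
#'   `homology` (a `homology_map` over all 7 species), `tree`
#'   (a `species_phylogeny`) and `lineage_order` (youngest to oldest).
#' @export
load_table1_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "mircluster",
                                 mustWork = TRUE)
  members <- utils::read.delim(ext("table1_members.tsv"),
                               stringsAsFactors = FALSE)
  clusters <- utils::read.delim(ext("table1_clusters.tsv"),
                                stringsAsFactors = FALSE)
  clusters$notes[is.na(clusters$notes)] <- ""
  tree <- read_species_tree(ext("fixture_tree.nwk"),
                            leaf_lineages = c(dme = "Melanogaster"))

  loci <- mirna_loci(
    mirna_id = members$mirna_id, species_id = "dme",
    chrom = members$chrom, start = members$start, end = members$end,
    strand = members$strand,
    annotation_family = members$annotation_family,
    phylo_family = members$phylo_family
  )

  # synthesize co-located homologs in every species of each member's age clade
  hom_rows <- list(loci)
  for (sp in setdiff(tree$tree$tip.label, "dme")) {
    for (cid in unique(members$cluster_id)) {
      mm <- members[members$cluster_id == cid, , drop = FALSE]
      present <- vapply(mm$age_lineage, function(a)
        sp %in% phy_clade_species(tree, phy_node(tree, a)), TRUE)
      mm <- mm[present, , drop = FALSE]
      if (nrow(mm) == 0) next
      len <- mm$end - mm$start
      start <- 100000L + cumsum(c(0L, (len + 150L)[-nrow(mm)]))
      hom_rows[[length(hom_rows) + 1]] <- mirna_loci(
        mirna_id = sub("^dme-", paste0(sp, "-"), mm$mirna_id),
        species_id = sp,
        chrom = paste0("ctg_", gsub("[^0-9A-Za-z]", "_", cid)),
        start = start, end = start + len, strand = "+",
        annotation_family = mm$annotation_family,
        phylo_family = mm$phylo_family,
        ortholog_group = mm$phylo_family
      )
    }
  }
  hom <- homology_map(do.call(rbind, hom_rows), species = tree$tree$tip.label)

  cl <- clusters
  cl$species_id <- "dme"
  cl$members <- lapply(cl$cluster_id, function(cid)
    members$mirna_id[members$cluster_id == cid][order(members$position[members$cluster_id == cid])])
  cl <- cl[, c("cluster_id", "species_id", "members", "source", "lineage",
               "original_mirna", "notes")]

  fx <- list(clusters = cl, members = members, loci = loci, homology = hom,
             tree = tree,
             lineage_order = c("Melanogaster", "Drosophila", "Insects",
                               "Protostomes", "Metazoans"))
  class(fx) <- "table1_fixture"
  validate_table1_fixture(fx)
  fx
}

# fixture invariants, asserted on load
validate_table1_fixture <- function(fx) {
  cl <- fx$clusters
  stopifnot(nrow(cl) == 21)
  src <- table(cl$source)
  stopifnot(src[["NewHairpin"]] == 13, src[["Duplication"]] == 6,
            src[["Unknown"]] == 2)
  lin <- table(cl$lineage)
  stopifnot(lin[["Melanogaster"]] == 2, lin[["Drosophila"]] == 7,
            lin[["Insects"]] == 5, lin[["Protostomes"]] == 5,
            lin[["Metazoans"]] == 2)
  fam <- stats::setNames(fx$loci$annotation_family, fx$loci$mirna_id)
  n_single <- sum(vapply(cl$members, function(m)
    length(unique(fam[m])) == 1, TRUE))
  stopifnot(n_single == 4)
  invisible(fx)
}

#' @export
print.table1_fixture <- function(x, ...) {
  cat("table1_fixture: 21 D. melanogaster microRNA clusters,",
      nrow(x$loci), "member loci,", length(x$homology$species), "species\n")
  invisible(x)
}
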