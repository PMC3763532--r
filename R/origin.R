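SOURCE_LEVELS <- c("NEW_HAIRPIN", "DUPLICATION", "FUSION", "UNKNOWN")

#' Infer the origin lineage of a character under Dollo parsimony
#'
#' Under the Dollo assumption (a microRNA family is gained once and may be
#' lost any number of times), the origin of a microRNA is the most recent
#' common ancestor of the species in which it is found. This is also the
#' single-gain placement minimising the number of losses.
#'
#' @param present_in Character vector of species codes possessing the
#'   microRNA (non-empty).
#' @param tree A `species_phylogeny`.
#' @return The lineage name (character scalar) of the origin node, with the
#'   internal node number in attribute `"node"`.
#' @export
infer_origin_node <- function(present_in, tree) {
  present_in <- unique(present_in)
  if (length(present_in) == 0) stop("no homologs: empty species set")
  node <- phy_mrca(tree, present_in)
  structure(phy_label(tree, node), node = node)
}

# per-member age table for a set of members of one species
member_ages <- function(members, ref_species, hom, tree) {
  rows <- lapply(members, function(m) {
    lr <- hom_loci(hom, ref_species)
    lr <- lr[lr$mirna_id == m, , drop = FALSE]
    if (nrow(lr) == 0)
      stop("member without homology entry: ", m, " (species ", ref_species, ")")
    grp <- lr$ortholog_group[1]
    fam <- lr$phylo_family[1]
    sp <- hom_species_with(hom, group = grp)
    origin <- infer_origin_node(sp, tree)
    data.frame(mirna_id = m, phylo_family = fam, ortholog_group = grp,
               start = lr$start[1],
               origin_lineage = as.character(origin),
               origin_node = attr(origin, "node"),
               depth = phy_depth(tree, attr(origin, "node")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify the founding event of a microRNA cluster
#'
#' Implements the decision procedure for the origin of a cluster:
#' \enumerate{
#'   \item Infer each member's age (origin node of its ortholog group under
#'     Dollo parsimony); rank members from oldest (closest to the root) to
#'     youngest.
#'   \item The two oldest members are the candidate founders.
#'   \item Founders of the same phylogenetic family imply
#'     \strong{DUPLICATION}.
#'   \item Otherwise, if in a species that diverged at or before the
#'     putative cluster origin the two founder families are present but
#'     unlinked (different chromosome/strand, or gap >= `max_gap`), and no
#'     equally old species shows them linked, the cluster arose by
#'     \strong{FUSION} of pre-existing loci. Requiring the unlinked
#'     configuration in an old species prevents a lineage-specific
#'     translocation away from an ancestral cluster from masquerading as
#'     fusion evidence.
#'   \item Founders of different families but equal age give
#'     \strong{UNKNOWN}: the founding event cannot be ordered.
#'   \item Otherwise the younger founder is a de novo hairpin born within
#'     the transcript of the older one: \strong{NEW_HAIRPIN}, with
#'     `original_mirna` the strictly older founder.
#' }
#' When more than two members tie as oldest, DUPLICATION takes precedence
#' if any two of them share a family; otherwise the call is UNKNOWN.
#' The cluster's `origin_lineage` is the origin node of the younger founder
#' (the time of the cluster-forming event).
#'
#' A DUPLICATION call is annotated with a warning in its evidence when the
#' founder family also has single-copy homologs in species that diverged
#' before the inferred origin, since a de novo origin masked by later gene
#' loss cannot then be excluded.
#'
#' @param cluster One cluster: a single-row slice of [call_clusters()]
#'   output (or any list with `cluster_id`, `species_id`, `members`).
#' @param hom A [homology_map()] covering every member.
#' @param tree A `species_phylogeny`.
#' @param max_gap Linkage threshold in nt (default 10000).
#' @return One-row data.frame (an origin call): `cluster_id`, `source`,
#'   `origin_lineage`, `original_mirna`, `evidence`.
#' @export
classify_cluster_origin <- function(cluster, hom, tree, max_gap = 10000) {
  members <- if (is.list(cluster$members)) cluster$members[[1]] else
    cluster$members
  ref <- cluster$species_id[1]
  ages <- member_ages(members, ref, hom, tree)
  ages <- ages[order(ages$depth, ages$start, ages$mirna_id), , drop = FALSE]
  ev <- paste0("ages: ", paste(sprintf("%s=%s", ages$mirna_id,
                                       ages$origin_lineage), collapse = ", "))
  oldest <- ages[ages$depth == min(ages$depth), , drop = FALSE]

  make_call <- function(source, origin_node, original = NA_character_,
                        extra = NULL) {
    data.frame(cluster_id = cluster$cluster_id[1], source = source,
               origin_lineage = phy_label(tree, origin_node),
               original_mirna = original,
               evidence = paste(c(ev, extra), collapse = "; "),
               stringsAsFactors = FALSE)
  }

  dup_call <- function(f1, f2) {
    # cluster-forming event = appearance of the younger copy
    younger <- if (f1$depth >= f2$depth) f1 else f2
    extra <- sprintf("founders %s,%s share family %s",
                     f1$mirna_id, f2$mirna_id, f1$phylo_family)
    warn <- duplication_loss_caveat(f1$phylo_family, younger$origin_node,
                                    ref, hom, tree)
    make_call("DUPLICATION", younger$origin_node, extra = c(extra, warn))
  }

  if (nrow(oldest) > 2) {
    # >2-way age tie: duplication takes precedence over unknown
    fam_dup <- unique(oldest$phylo_family[duplicated(oldest$phylo_family)])
    if (length(fam_dup) > 0) {
      pair <- oldest[oldest$phylo_family == fam_dup[1], , drop = FALSE]
      return(dup_call(pair[1, ], pair[2, ]))
    }
    return(make_call("UNKNOWN", oldest$origin_node[1],
                     extra = sprintf("%d equally old founders of distinct families",
                                     nrow(oldest))))
  }

  f1 <- ages[1, ]
  f2 <- ages[2, ]
  extra_f <- sprintf("founders: %s (%s), %s (%s)", f1$mirna_id,
                     f1$origin_lineage, f2$mirna_id, f2$origin_lineage)

  if (f1$phylo_family == f2$phylo_family) return(dup_call(f1, f2))

  origin_node <- f2$origin_node  # younger founder (rows are age-sorted)
  fus <- fusion_evidence(f1$phylo_family, f2$phylo_family, origin_node,
                         ref, hom, tree, max_gap)
  if (fus$fusion)
    return(make_call("FUSION", origin_node, extra = c(extra_f, fus$msg)))
  if (f1$origin_node == f2$origin_node)
    return(make_call("UNKNOWN", origin_node,
                     extra = c(extra_f, "equal-age founders of distinct families")))
  make_call("NEW_HAIRPIN", origin_node, original = f1$mirna_id,
            extra = extra_f)
}

# do famA and famB "appear together" in species s? Linkage is cluster
# co-membership: loci chained through intermediates of any family count as
# linked, so a long cluster does not look split merely because its two
# founders sit at opposite ends. NA when either family is absent from s.
families_linked <- function(hom, s, famA, famB, max_gap) {
  ss <- hom_loci(hom, s)
  ia <- ss$phylo_family == famA
  ib <- ss$phylo_family == famB
  if (!any(ia) || !any(ib)) return(NA)
  st <- data.frame(id = ss$mirna_id, chrom = ss$chrom, start = ss$start,
                   end = ss$end, strand = ss$strand, stringsAsFactors = FALSE)
  g <- chain_groups(st, max_gap)
  for (k in unique(g)) {
    rows <- g == k
    ok <- if (famA == famB) sum(ia & rows) >= 2 else
      any(ia & rows) && any(ib & rows)
    if (ok) return(TRUE)
  }
  FALSE
}

# fusion test: founder families unlinked in a species at least as old as the
# putative origin, with no equally old species showing them linked
fusion_evidence <- function(famA, famB, origin_node, ref, hom, tree, max_gap) {
  old_sp <- setdiff(hom$species, ref)
  # "old" = diverged from the reference at or before the putative origin
  old_sp <- old_sp[vapply(old_sp, function(s)
    phy_is_ancestor(tree, phy_mrca(tree, c(s, ref)), origin_node), TRUE)]
  linked <- vapply(old_sp, function(s)
    families_linked(hom, s, famA, famB, max_gap), NA)
  has_unlinked <- any(!is.na(linked) & !linked)
  has_linked <- any(!is.na(linked) & linked)
  if (has_unlinked && !has_linked) {
    list(fusion = TRUE,
         msg = sprintf("families %s,%s unlinked in outgroup species %s",
                       famA, famB,
                       paste(old_sp[!is.na(linked) & !linked], collapse = ",")))
  } else {
    list(fusion = FALSE, msg = NULL)
  }
}

# mir-2/mir-71-style caveat: the duplicated family has single-copy homologs
# in species that diverged before the inferred duplication
duplication_loss_caveat <- function(family, origin_node, ref, hom, tree) {
  deep <- Filter(function(s) {
    if (s == ref) return(FALSE)
    mrca <- phy_mrca(tree, c(s, ref))
    phy_is_ancestor(tree, mrca, origin_node, strict = TRUE) &&
      nrow(hom_loci(hom, s, family = family)) == 1
  }, hom$species)
  if (length(deep) == 0) return(NULL)
  sprintf(paste0("warning: family %s is single-copy in deeper species (%s); ",
                 "a de novo origin masked by later loss cannot be excluded"),
          family, paste(deep, collapse = ","))
}

#' Classify the founding event of every cluster in a table
#'
#' @param clusters Output of [call_clusters()] (or the fixture cluster
#'   table).
#' @param hom A `homology_map`.
#' @param tree A `species_phylogeny`.
#' @param max_gap Linkage threshold in nt.
#' @return data.frame of origin calls, one row per cluster.
#' @export
classify_clusters <- function(clusters, hom, tree, max_gap = 10000) {
  calls <- lapply(seq_len(nrow(clusters)), function(i)
    classify_cluster_origin(clusters[i, , drop = FALSE], hom, tree,
                            max_gap = max_gap))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Tally origin calls by source and by lineage
#'
#' @param calls data.frame of origin calls from [classify_clusters()].
#' @param lineage_order Optional ordering of lineage names in the output.
#' @return A list with `by_source` (named integer vector over the four
#'   sources, zeros included), `by_lineage` (named integer vector) and
#'   `per_branch` (list: lineage -> cluster_ids, the per-branch listing).
#' @export
summarize_origins <- function(calls, lineage_order = NULL) {
  by_source <- vapply(SOURCE_LEVELS, function(s) sum(calls$source == s), 1L)
  lin <- calls$origin_lineage
  lins <- if (is.null(lineage_order)) unique(lin) else
    union(lineage_order, unique(lin))
  by_lineage <- vapply(lins, function(l) sum(lin == l), 1L)
  per_branch <- lapply(lins, function(l) calls$cluster_id[lin == l])
  names(per_branch) <- lins
  list(by_source = by_source, by_lineage = by_lineage,
       per_branch = per_branch)
}

CROSS_SPECIES_LEVELS <- c("INDEPENDENT_DUPLICATION", "INDEPENDENT_NEW_HAIRPIN",
                          "LINKED_BEYOND_THRESHOLD", "CLUSTER_SPLIT")

#' Classify a cross-species clustering discordance
#'
#' For a pair of microRNA families that are clustered in at least one
#' non-reference species but not clustered in the reference species,
#' decide whether the foreign cluster reflects (a) an independent local
#' tandem duplication restricted to the clade where clustering is seen,
#' (b) an independent new-hairpin birth of the younger family inside that
#' clade, (c) a pair that is in fact linked in the reference genome but
#' beyond the distance threshold, or (d) an ancestral cluster that split in
#' the reference lineage.
#'
#' @param famA,famB Phylogenetic family labels (`famA == famB` for a
#'   duplication pair).
#' @param hom A `homology_map`.
#' @param tree A `species_phylogeny`.
#' @param ref_species Reference species code.
#' @param max_gap Linkage threshold in nt.
#' @return One-row data.frame: `family_a`, `family_b`, `category`,
#'   `species_clustered` (comma-joined), `evidence`.
#' @export
classify_cross_species_pair <- function(famA, famB, hom, tree, ref_species,
                                        max_gap = 10000) {
  linked <- vapply(hom$species, function(s)
    families_linked(hom, s, famA, famB, max_gap), NA)
  names(linked) <- hom$species
  clustered_sp <- hom$species[!is.na(linked) & linked]
  if (isTRUE(linked[[ref_species]]))
    stop("pair is clustered in the reference species ", ref_species)
  clustered_sp <- setdiff(clustered_sp, ref_species)
  if (length(clustered_sp) == 0)
    stop("pair not clustered in any species")
  clade_node <- phy_mrca(tree, clustered_sp)
  clade_sp <- phy_clade_species(tree, clade_node)

  category <- NULL
  evidence <- sprintf("clustered in: %s", paste(clustered_sp, collapse = ","))
  if (famA == famB) {
    multi <- Filter(function(s) nrow(hom_loci(hom, s, family = famA)) >= 2,
                    hom$species)
    if (length(multi) > 0 && all(multi %in% clade_sp) &&
        !(ref_species %in% multi)) {
      category <- "INDEPENDENT_DUPLICATION"
      evidence <- c(evidence, sprintf(
        "second copy restricted to clade %s", phy_label(tree, clade_node)))
    }
  } else {
    oa <- infer_origin_node(hom_species_with(hom, family = famA), tree)
    ob <- infer_origin_node(hom_species_with(hom, family = famB), tree)
    da <- phy_depth(tree, attr(oa, "node"))
    db <- phy_depth(tree, attr(ob, "node"))
    if (da != db) {
      young <- if (da > db) oa else ob
      if (phy_is_ancestor(tree, clade_node, attr(young, "node"))) {
        category <- "INDEPENDENT_NEW_HAIRPIN"
        evidence <- c(evidence, sprintf(
          "younger family (%s) originated inside clade %s",
          if (da > db) famA else famB, phy_label(tree, clade_node)))
      }
    }
  }
  if (is.null(category)) {
    ra <- hom_loci(hom, ref_species, family = famA)
    rb <- hom_loci(hom, ref_species, family = famB)
    same_arm <- FALSE
    if (nrow(ra) > 0 && nrow(rb) > 0) {
      for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(rb))) {
        if (identical(ra$mirna_id[i], rb$mirna_id[j])) next
        if (ra$chrom[i] == rb$chrom[j] && ra$strand[i] == rb$strand[j])
          same_arm <- TRUE
      }
    }
    if (same_arm) {
      category <- "LINKED_BEYOND_THRESHOLD"
      evidence <- c(evidence, sprintf(
        "linked in %s but gap >= %d nt", ref_species, as.integer(max_gap)))
    } else {
      category <- "CLUSTER_SPLIT"
      evidence <- c(evidence, sprintf("unlinked in %s", ref_species))
    }
  }
  data.frame(family_a = famA, family_b = famB, category = category,
             species_clustered = paste(clustered_sp, collapse = ","),
             evidence = paste(evidence, collapse = "; "),
             stringsAsFactors = FALSE)
}
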