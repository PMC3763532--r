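#' Inter-microRNA distance between two precursors
#'
#' The gap is the number of nucleotides strictly between the two precursors
#' (nearest-edge convention): `start(downstream) - end(upstream) - 1`.
#' Overlapping precursors have gap 0. Precursors in different species, on
#' different chromosomes, or on different strands are incomparable and the
#' gap is `NA`: statistics never mix strands or chromosomes.
#'
#' @param a,b Single-row `mirna_loci` entries (data.frame rows or lists with
#'   the same fields).
#' @return Gap in nucleotides, or `NA_real_` if incomparable.
#' @export
pairwise_gap <- function(a, b) {
  if (a$species_id != b$species_id || a$chrom != b$chrom ||
      a$strand != b$strand) {
    return(NA_real_)
  }
  gap <- max(a$start, b$start) - min(a$end, b$end) - 1
  max(0, gap)
}

#' Call microRNA clusters by the inter-precursor distance rule
#'
#' A cluster is a maximal group of >= 2 precursors on the same chromosome
#' and strand in which each member is less than `max_gap` nucleotides from
#' the group (strict inequality; the default 10 kb is the co-expression-
#' supported threshold). Chaining is single linkage along the chromosome:
#' loci are sorted by start per (chromosome, strand), and a locus joins the
#' current chain when its distance to the chain's rightmost end so far is
#' `< max_gap` (overlap counts as 0). On non-nested precursors this equals
#' chaining consecutive loci by [pairwise_gap()], and in general it equals
#' the transitive closure over all pairs with gap `< max_gap`. Singletons
#' are not clusters.
#'
#' @param loci A `mirna_loci` table, all from one species.
#' @param max_gap Distance threshold in nucleotides (default 10000).
#' @return A data.frame of class `mirna_clusters`: one row per cluster with
#'   `cluster_id`, `species_id`, `chrom`, `strand`, `start`, `end`, `span`,
#'   `n_members` and a list-column `members` (mirna_ids ordered by start).
#'   The member-to-cluster map is in attribute `"assignment"` (named vector,
#'   `NA` for unclustered loci).
#' @export
call_clusters <- function(loci, max_gap = 10000) {
  loci <- validate_mirna_loci(loci)
  if (nrow(loci) > 0 && length(unique(loci$species_id)) > 1)
    stop("call_clusters expects loci from a single species")
  assignment <- stats::setNames(rep(NA_character_, nrow(loci)), loci$mirna_id)
  rows <- list()
  cl_n <- 0L
  if (nrow(loci) > 0) {
    for (key in unique(paste(loci$chrom, loci$strand))) {
      sel <- paste(loci$chrom, loci$strand) == key
      sub <- loci[sel, , drop = FALSE]
      sub <- sub[order(sub$start, sub$end, sub$mirna_id), , drop = FALSE]
      chain <- 1L
      chain_id <- integer(nrow(sub))
      chain_id[1] <- chain
      right <- sub$end[1]
      if (nrow(sub) > 1) {
        for (i in 2:nrow(sub)) {
          gap <- max(0, sub$start[i] - right - 1)
          if (gap < max_gap) {
            chain_id[i] <- chain
          } else {
            chain <- chain + 1L
            chain_id[i] <- chain
          }
          right <- max(right, sub$end[i])
        }
      }
      for (g in split(seq_len(nrow(sub)), chain_id)) {
        if (length(g) < 2) next
        cl_n <- cl_n + 1L
        id <- sprintf("%s_%s%s_c%02d", sub$species_id[1], sub$chrom[1],
                      sub$strand[1], cl_n)
        rows[[cl_n]] <- data.frame(
          cluster_id = id, species_id = sub$species_id[1],
          chrom = sub$chrom[1], strand = sub$strand[1],
          start = min(sub$start[g]), end = max(sub$end[g]),
          span = max(sub$end[g]) - min(sub$start[g]) + 1L,
          n_members = length(g), stringsAsFactors = FALSE
        )
        rows[[cl_n]]$members <- list(sub$mirna_id[g])
        assignment[sub$mirna_id[g]] <- id
      }
    }
  }
  out <- if (cl_n > 0) do.call(rbind, rows) else
    data.frame(cluster_id = character(), species_id = character(),
               chrom = character(), strand = character(), start = integer(),
               end = integer(), span = integer(), n_members = integer(),
               members = I(list()), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "assignment") <- assignment
  attr(out, "max_gap") <- max_gap
  class(out) <- unique(c("mirna_clusters", class(out)))
  out
}

#' Cluster composition statistics
#'
#' For each cluster, the member count (size) and the number of distinct
#' annotation families among its members, plus the frequency tables of both
#' and the size-by-family-count bubble table.
#'
#' @param clusters Output of [call_clusters()] (or any table with a
#'   `members` list-column).
#' @param loci The `mirna_loci` table the clusters were called from.
#' @return A list with `per_cluster` (data.frame: `cluster_id`, `size`,
#'   `n_annotation_families`), `size_table`, `family_table`, and `bubble`
#'   (a `table` of size x number of families).
#' @export
composition_stats <- function(clusters, loci) {
  fam <- stats::setNames(loci$annotation_family, loci$mirna_id)
  per <- data.frame(
    cluster_id = clusters$cluster_id,
    size = vapply(clusters$members, length, 1L),
    n_annotation_families = vapply(clusters$members, function(m) {
      miss <- setdiff(m, names(fam))
      if (length(miss) > 0)
        stop("composition_stats: members without loci: ",
             paste(miss, collapse = ", "))
      length(unique(fam[m]))
    }, 1L),
    stringsAsFactors = FALSE
  )
  list(
    per_cluster = per,
    size_table = table(size = per$size),
    family_table = table(n_families = per$n_annotation_families),
    bubble = table(size = per$size, n_families = per$n_annotation_families)
  )
}

#' Fraction of microRNAs that are clustered, stratified by age
#'
#' For each origin lineage (age class), the proportion of microRNAs of that
#' age that belong to a cluster. Lineages with zero loci are omitted.
#'
#' @param loci A `mirna_loci` table (one species).
#' @param ages Named character vector: `mirna_id -> lineage name`.
#' @param max_gap Clustering threshold passed to [call_clusters()].
#' @param lineage_order Optional character vector ordering the output rows
#'   (e.g. youngest to oldest).
#' @return data.frame with `lineage`, `n_loci`, `n_clustered`, `fraction`.
#' @export
clustered_fraction_by_age <- function(loci, ages, max_gap = 10000,
                                      lineage_order = NULL) {
  loci <- validate_mirna_loci(loci)
  miss <- setdiff(loci$mirna_id, names(ages))
  if (length(miss) > 0)
    stop("loci without an age label: ", paste(miss, collapse = ", "))
  cl <- call_clusters(loci, max_gap = max_gap)
  assign <- attr(cl, "assignment")
  lin <- unname(ages[loci$mirna_id])
  clustered <- !is.na(assign[loci$mirna_id])
  out <- do.call(rbind, lapply(unique(lin), function(l) {
    sel <- lin == l
    data.frame(lineage = l, n_loci = sum(sel), n_clustered = sum(clustered[sel]),
               fraction = sum(clustered[sel]) / sum(sel),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(lineage_order)) {
    out <- out[order(match(out$lineage, lineage_order)), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
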