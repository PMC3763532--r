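# Shared fixtures and independent oracles. Oracles deliberately use the
# slowest, most literal formulation of each definition.

# quick locus-table builder on one species
loci_tbl <- function(start, end, chrom = "2L", strand = "+", species = "dme",
                     id = sprintf("mir-t%02d", seq_along(start)),
                     ann = NULL, phylo = NULL, group = NULL) {
  mirna_loci(mirna_id = id, species_id = species, chrom = chrom,
             start = start, end = end, strand = strand,
             annotation_family = ann, phylo_family = phylo,
             ortholog_group = group)
}

fixture_tree <- function() {
  read_species_tree(system.file("extdata", "fixture_tree.nwk",
                                package = "mircluster"),
                    leaf_lineages = c(dme = "Melanogaster"))
}

# brute-force cluster oracle: build the full pairwise adjacency (gap <
# max_gap, comparable pairs only) and take its transitive closure by
# label propagation. Independent of the chaining implementation.
oracle_clusters <- function(loci, max_gap) {
  n <- nrow(loci)
  gap <- outer(loci$start, loci$end, function(s, e) s - e - 1)
  gap <- pmax(pmax(gap, t(gap)), 0)            # nearest-edge gap, symmetric
  comparable <- outer(loci$chrom, loci$chrom, "==") &
    outer(loci$strand, loci$strand, "==") &
    outer(loci$species_id, loci$species_id, "==")
  adj <- comparable & gap < max_gap
  diag(adj) <- FALSE
  comp <- seq_len(n)
  repeat {
    nxt <- vapply(seq_len(n), function(i)
      min(comp[c(i, which(adj[i, ]))]), 1)
    if (identical(nxt, comp)) break
    comp <- nxt
  }
  sets <- Filter(function(x) length(x) >= 2, split(loci$mirna_id, comp))
  sets <- lapply(sets, sort)
  unname(sets[order(vapply(sets, paste, "", collapse = "|"))])
}

cluster_sets <- function(clusters) {
  sets <- lapply(clusters$members, sort)
  unname(sets[order(vapply(sets, paste, "", collapse = "|"))])
}

# random non-nested locus instance: spacing always exceeds locus length
random_loci <- function(n, seed) {
  set.seed(seed)
  chrom <- sample(c("2L", "2R"), n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  start <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    spacing <- sample(c(130:2000, seq(8000L, 15000L, 50L), 50000L),
                      length(idx), replace = TRUE)
    start[idx] <- cumsum(spacing)
  }
  len <- sample(60:120, n, replace = TRUE)
  loci_tbl(start = start, end = start + len - 1L, chrom = chrom,
           strand = strand)
}

# exhaustive single-gain minimal-loss (Dollo) placement oracle
oracle_dollo <- function(present, phy) {
  tr <- phy$tree
  ntip <- length(tr$tip.label)
  children <- function(v) tr$edge[tr$edge[, 1] == v, 2]
  clade <- function(v) phy_clade_species_oracle(tr, v)
  losses_under <- function(v) {
    sp <- clade(v)
    if (!any(sp %in% present)) return(1L)  # prune this whole subtree
    if (v <= ntip) return(0L)
    sum(vapply(children(v), losses_under, 1L))
  }
  nodes <- seq_len(ntip + tr$Nnode)
  feasible <- nodes[vapply(nodes, function(v) all(present %in% clade(v)), TRUE)]
  loss <- vapply(feasible, losses_under, 1L)
  best <- feasible[loss == min(loss)]
  labels <- c(tr$tip.label, tr$node.label)
  labels[best]
}

phy_clade_species_oracle <- function(tr, v) {
  ntip <- length(tr$tip.label)
  if (v <= ntip) return(tr$tip.label[v])
  out <- character()
  stack <- v
  while (length(stack)) {
    cur <- stack[1]
    stack <- stack[-1]
    kids <- tr$edge[tr$edge[, 1] == cur, 2]
    out <- c(out, tr$tip.label[kids[kids <= ntip]])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}

# MRCA oracle by path intersection
oracle_mrca <- function(phy, a, b) {
  tr <- phy$tree
  parent_of <- function(v) {
    p <- tr$edge[tr$edge[, 2] == v, 1]
    if (length(p) == 0) NA_integer_ else p
  }
  path <- function(label) {
    v <- match(label, tr$tip.label)
    out <- v
    while (!is.na(parent_of(v))) {
      v <- parent_of(v)
      out <- c(out, v)
    }
    out
  }
  common <- intersect(path(a), path(b))[1]
  ntip <- length(tr$tip.label)
  if (common <= ntip) tr$tip.label[common] else tr$node.label[common - ntip]
}

# random named binary rooted tree for Dollo oracle tests
random_named_tree <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = TRUE)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_leaves))
  tr$node.label <- sprintf("lin%02d", seq_len(tr$Nnode))
  species_phylogeny(tr)
}

# textbook Pearson formula, longhand
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# small 4-species vertebrate-flavoured tree for cross-species tests
cross_tree <- function() {
  txt <- paste0("((dme:1,dsi:1)Drosophila:3,(gga:2.5,(hsa:1.5,",
                "(mmu:1,rno:1)Murids:0.5)Mammals:1)Vertebrates:1.5)Bilateria;")
  f <- tempfile(fileext = ".nwk")
  writeLines(txt, f)
  read_species_tree(f)
}
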