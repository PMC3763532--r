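#' Build a species phylogeny with named lineages
#'
#' Wraps an `ape::phylo` tree whose internal nodes carry lineage names
#' (e.g. Drosophila, Insects, Protostomes, Metazoans). Leaves are species
#' codes; the lineage name of a single-species branch defaults to the
#' species code but can be aliased (e.g. `dme` -> `"Melanogaster"`), so that
#' a microRNA found only in `dme` is reported with age "Melanogaster".
#'
#' @param tree An `ape::phylo` object, rooted, with unique labels.
#' @param leaf_lineages Optional named character vector mapping species codes
#'   to terminal-branch lineage names.
#' @return An object of class `species_phylogeny`.
#' @export
species_phylogeny <- function(tree, leaf_lineages = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  # exactly one root: one node that never appears as a child
  n_root <- sum(!(unique(tree$edge[, 1]) %in% tree$edge[, 2]))
  if (n_root != 1) stop("tree must have exactly one root")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$node.label) || any(is.na(tree$node.label)) ||
      any(!nzchar(tree$node.label)))
    stop("all internal nodes must be named (see auto_name in read_species_tree)")
  if (anyDuplicated(c(tree$tip.label, tree$node.label)))
    stop("duplicate node names in tree")
  ll <- stats::setNames(tree$tip.label, tree$tip.label)
  if (!is.null(leaf_lineages)) {
    unknown <- setdiff(names(leaf_lineages), tree$tip.label)
    if (length(unknown) > 0)
      stop("leaf_lineages for unknown species: ", paste(unknown, collapse = ", "))
    ll[names(leaf_lineages)] <- leaf_lineages
  }
  phy <- list(tree = tree, leaf_lineages = ll)
  class(phy) <- "species_phylogeny"
  phy
}

#' Read a rooted species tree from a Newick file
#'
#' Internal nodes must be named (lineage labels); unnamed nodes are an error
#' unless `auto_name = TRUE`, in which case they are labelled `node<k>`.
#' A multifurcating root is rejected unless `allow_multifurcations = TRUE`.
#'
#' @param path Path to a Newick file.
#' @param auto_name Autolabel unnamed internal nodes.
#' @param allow_multifurcations Accept non-binary nodes.
#' @param leaf_lineages Passed to [species_phylogeny()].
#' @return A `species_phylogeny`.
#' @export
read_species_tree <- function(path, auto_name = FALSE,
                              allow_multifurcations = FALSE,
                              leaf_lineages = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  # ape flags a basal trifurcation as "unrooted": both cases are
  # multifurcations of the root and both need the explicit flag
  if (!allow_multifurcations && (!ape::is.rooted(tree) || !ape::is.binary(tree)))
    stop("tree is unrooted or has multifurcations; ",
         "set allow_multifurcations = TRUE to accept a multifurcating tree")
  if (is.null(tree$node.label))
    tree$node.label <- rep("", tree$Nnode)
  unnamed <- is.na(tree$node.label) | !nzchar(tree$node.label)
  if (any(unnamed)) {
    if (!auto_name)
      stop(sum(unnamed), " unnamed internal node(s); name them or set auto_name = TRUE")
    tree$node.label[unnamed] <- paste0("node", which(unnamed))
  }
  species_phylogeny(tree, leaf_lineages = leaf_lineages)
}

#' @export
print.species_phylogeny <- function(x, ...) {
  cat("species_phylogeny:", length(x$tree$tip.label), "species,",
      x$tree$Nnode, "lineage nodes\n")
  cat("species:", paste(x$tree$tip.label, collapse = ", "), "\n")
  cat("lineages:", paste(x$tree$node.label, collapse = ", "), "\n")
  invisible(x)
}

## ---- internal node arithmetic ------------------------------------------

phy_ntips <- function(phy) length(phy$tree$tip.label)

# node number for a species, lineage, or leaf-lineage alias label
phy_node <- function(phy, label) {
  tips <- phy$tree$tip.label
  i <- match(label, tips)
  if (!is.na(i)) return(i)
  j <- match(label, phy$tree$node.label)
  if (!is.na(j)) return(phy_ntips(phy) + j)
  k <- match(label, unname(phy$leaf_lineages))
  if (!is.na(k)) return(match(names(phy$leaf_lineages)[k], tips))
  stop("unknown node label: ", label)
}

# lineage display name for a node number
phy_label <- function(phy, node) {
  n <- phy_ntips(phy)
  if (node <= n) unname(phy$leaf_lineages[phy$tree$tip.label[node]])
  else phy$tree$node.label[node - n]
}

phy_root <- function(phy) phy_ntips(phy) + 1L

# parent of each node (0 for root)
phy_parents <- function(phy) {
  e <- phy$tree$edge
  p <- integer(phy_ntips(phy) + phy$tree$Nnode)
  p[e[, 2]] <- e[, 1]
  p
}

# path from node up to the root, inclusive
phy_path_to_root <- function(phy, node) {
  p <- phy_parents(phy)
  path <- node
  while (p[node] != 0L) {
    node <- p[node]
    path <- c(path, node)
  }
  path
}

# MRCA node number of a set of species codes
phy_mrca <- function(phy, species) {
  species <- unique(species)
  bad <- setdiff(species, phy$tree$tip.label)
  if (length(bad) > 0)
    stop("species not in tree: ", paste(bad, collapse = ", "))
  if (length(species) == 0) stop("no species given")
  if (length(species) == 1) return(phy_node(phy, species))
  ape::getMRCA(phy$tree, species)
}

# number of edges from the root (root = 0); a smaller depth is more ancestral
phy_depth <- function(phy, node) length(phy_path_to_root(phy, node)) - 1L

# is `anc` an ancestor of (or equal to) `node`?
phy_is_ancestor <- function(phy, anc, node, strict = FALSE) {
  path <- phy_path_to_root(phy, node)
  if (strict) path <- path[-1]
  anc %in% path
}

# species (tip labels) under a node
phy_clade_species <- function(phy, node) {
  n <- phy_ntips(phy)
  if (node <= n) return(phy$tree$tip.label[node])
  desc <- node
  e <- phy$tree$edge
  tips <- character()
  stack <- node
  while (length(stack) > 0) {
    cur <- stack[[1]]
    stack <- stack[-1]
    kids <- e[e[, 1] == cur, 2]
    tips <- c(tips, phy$tree$tip.label[kids[kids <= n]])
    stack <- c(stack, kids[kids > n])
  }
  tips
}

# node times (distance from root along branch lengths)
phy_node_times <- function(phy) {
  tr <- phy$tree
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  nt <- numeric(phy_ntips(phy) + tr$Nnode)
  # edges in preorder: ape's reorder guarantees parents before children
  e <- stats::reorder(tr)$edge
  len <- stats::reorder(tr)$edge.length
  for (i in seq_len(nrow(e))) nt[e[i, 2]] <- nt[e[i, 1]] + len[i]
  nt
}
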