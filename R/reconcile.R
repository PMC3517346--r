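#' Gene-tree/species-tree reconciliation by LCA mapping
#'
#' Maps every gene-tree node to the lowest common ancestor (in the species
#' tree) of the taxa below it; an internal node is labelled a duplication
#' when it maps to the same species node as at least one of its children,
#' and a speciation otherwise.  This formalizes reading a gene tree such as
#' the SMO/APAO phylogeny: the node where the two vertebrate subfamilies
#' diverge maps to the same species branch as its children, exposing the
#' duplication, while the remaining nodes track speciations.
#'
#' @param gene_tree rooted `phylo` gene tree.
#' @param species_tree rooted `phylo` species tree.
#' @param leaf_taxon_map named character vector gene leaf -> taxon;
#'   by default gene leaves named `taxon_suffix` are mapped by stripping
#'   the last `_suffix`.
#' @return object of class `reconciled_tree`: list with `gene_tree`,
#'   `species_tree`, `leaf_taxon_map` and `events`, a data.frame with one
#'   row per internal gene node: `node`, `label`
#'   (`"speciation"`/`"duplication"`), `mapped_species_node`,
#'   `mapped_species_label` (tip label or smallest-clade description).
#' @export
reconcile <- function(gene_tree, species_tree, leaf_taxon_map = NULL) {
  if (!ape::is.rooted(gene_tree)) stop("root required")
  if (!ape::is.rooted(species_tree)) stop("species tree must be rooted")
  if (is.null(leaf_taxon_map)) {
    leaf_taxon_map <- setNames(sub("_[^_]+$", "", gene_tree$tip.label),
                               gene_tree$tip.label)
  }
  miss <- setdiff(gene_tree$tip.label, names(leaf_taxon_map))
  if (length(miss)) stop("unmapped leaf: ", paste(miss, collapse = ", "))
  taxa <- leaf_taxon_map[gene_tree$tip.label]
  bad <- setdiff(taxa, species_tree$tip.label)
  if (length(bad)) stop("taxa not in species tree: ", paste(bad, collapse = ", "))

  # species-tree ancestry
  sp_parent <- integer(ape::Ntip(species_tree) + species_tree$Nnode)
  sp_parent[species_tree$edge[, 2L]] <- species_tree$edge[, 1L]
  sp_depth <- integer(length(sp_parent))
  sp_root <- ape::Ntip(species_tree) + 1L
  order_nodes <- sp_root
  while (length(order_nodes)) {
    node <- order_nodes[1L]; order_nodes <- order_nodes[-1L]
    kids <- species_tree$edge[species_tree$edge[, 1L] == node, 2L]
    sp_depth[kids] <- sp_depth[node] + 1L
    order_nodes <- c(order_nodes, kids)
  }
  sp_lca <- function(a, b) {
    while (a != b) {
      if (sp_depth[a] >= sp_depth[b]) a <- sp_parent[a] else b <- sp_parent[b]
    }
    a
  }

  n_tip <- ape::Ntip(gene_tree)
  n_all <- n_tip + gene_tree$Nnode
  kids <- tree_children(gene_tree)
  mapping <- integer(n_all)
  label <- rep(NA_character_, n_all)
  walk <- function(node) {
    if (node <= n_tip) {
      mapping[node] <<- match(taxa[node], species_tree$tip.label)
      return(mapping[node])
    }
    child_maps <- vapply(kids[[node]], walk, integer(1L))
    m <- child_maps[1L]
    for (cm in child_maps[-1L]) m <- sp_lca(m, cm)
    mapping[node] <<- m
    label[node] <<- if (any(child_maps == m)) "duplication" else "speciation"
    m
  }
  walk(n_tip + 1L)

  internal <- (n_tip + 1L):n_all
  sp_label_of <- function(node) {
    if (node <= ape::Ntip(species_tree)) return(species_tree$tip.label[node])
    paste0("mrca(",
           paste(range_tips(species_tree, node), collapse = ","), ")")
  }
  events <- data.frame(node = internal,
                       label = label[internal],
                       mapped_species_node = mapping[internal],
                       mapped_species_label = vapply(mapping[internal],
                                                     sp_label_of, character(1L)),
                       stringsAsFactors = FALSE)
  structure(list(gene_tree = gene_tree, species_tree = species_tree,
                 leaf_taxon_map = leaf_taxon_map, events = events),
            class = "reconciled_tree")
}

# two representative tips spanning a species-tree clade
range_tips <- function(tree, node) {
  tips <- ape::extract.clade(tree, node)$tip.label
  c(tips[1L], tips[length(tips)])
}

#' @export
print.reconciled_tree <- function(x, ...) {
  n_dup <- sum(x$events$label == "duplication")
  cat(sprintf("Reconciled gene tree: %d leaves, %d duplication node(s)\n",
              ape::Ntip(x$gene_tree), n_dup))
  invisible(x)
}

#' Ortholog/paralog classification of all leaf pairs
#'
#' Two genes are paralogs when their gene-tree LCA is a duplication node,
#' and orthologs when it is a speciation node.
#'
#' @param rt a [reconcile()] result.
#' @return data.frame with `gene_a`, `gene_b` (each unordered pair once),
#'   `relation` (`"ortholog"`/`"paralog"`), `event_node`.
#' @export
classify_pairs <- function(rt) {
  gt <- rt$gene_tree
  tips <- gt$tip.label
  n <- length(tips)
  if (n < 2L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      relation = character(0), event_node = integer(0)))
  mr <- ape::mrca(gt)
  lab <- setNames(rt$events$label, rt$events$node)
  pairs <- t(combn(n, 2L))
  lca <- mr[cbind(pairs[, 1L], pairs[, 2L])]
  data.frame(gene_a = tips[pairs[, 1L]], gene_b = tips[pairs[, 2L]],
             relation = ifelse(lab[as.character(lca)] == "duplication",
                               "paralog", "ortholog"),
             event_node = lca, stringsAsFactors = FALSE)
}

#' Monophyly of designated leaf subsets
#'
#' A subset is monophyletic when it is exactly the leaf set of some node of
#' the rooted tree.  If the tree carries bootstrap supports (from
#' [bootstrap_support()]), the support of the subtending edge is reported.
#'
#' @param tree `phylo` tree.
#' @param subsets named list of leaf-label vectors.
#' @return data.frame `subset`, `n_leaves`, `monophyletic`, `support`.
#' @export
subfamily_monophyly <- function(tree, subsets) {
  if (is.null(names(subsets))) names(subsets) <- paste0("S", seq_along(subsets))
  has_support <- !is.null(attr(tree, "bipartition_support"))
  rows <- lapply(names(subsets), function(nm) {
    leaves <- subsets[[nm]]
    miss <- setdiff(leaves, tree$tip.label)
    if (length(miss)) stop("unknown leaf: ", paste(miss, collapse = ", "))
    mono <- if (length(leaves) <= 1L) TRUE else {
      node <- ape::getMRCA(tree, leaves)
      setequal(ape::extract.clade(tree, node)$tip.label, leaves)
    }
    sup <- if (has_support && length(leaves) >= 2L)
      split_support(tree, leaves) else NA_real_
    data.frame(subset = nm, n_leaves = length(leaves), monophyletic = mono,
               support = sup, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reconciliation TSV/JSON reports
#' @param rt a [reconcile()] result.
#' @param path file path.
#' @export
write_reconciliation <- function(rt, path) {
  write.table(rt$events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
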