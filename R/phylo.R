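#' Pairwise evolutionary distances from a protein alignment
#'
#' For each pair of rows the raw mismatch fraction `p` is computed over
#' columns where neither row is gapped, optionally corrected for multiple
#' substitutions: Poisson `-ln(1 - p)` or Kimura `-ln(1 - p - p^2/5)`.
#'
#' @param aln named character vector of gapped rows (>= 3).
#' @param correction `"poisson"` (default), `"kimura"` or `"none"`.
#' @return symmetric distance matrix with row ids as dimnames.
#' @export
protein_distance <- function(aln, correction = c("poisson", "kimura", "none")) {
  correction <- match.arg(correction)
  m <- alignment_matrix(aln)
  if (nrow(m) < 3L) stop("need at least 3 aligned sequences")
  n <- nrow(m)
  d <- base::matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] > 0L & m[j, ] > 0L
    if (!any(ok)) stop("no shared ungapped columns for a pair")
    p <- mean(m[i, ok] != m[j, ok])
    dd <- switch(correction,
                 none = p,
                 poisson = {
                   if (p >= 1) stop("p out of the Poisson correction domain")
                   -log(1 - p)
                 },
                 kimura = {
                   arg <- 1 - p - p^2 / 5
                   if (arg <= 0) stop("p out of the Kimura correction domain")
                   -log(arg)
                 })
    d[i, j] <- d[j, i] <- dd
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration.  On an additive distance matrix the
#' unique additive tree (topology and branch lengths) is recovered exactly.
#' Ties in the Q-criterion are broken by the smallest `(i, j)` index pair;
#' negative branch-length estimates are clamped to zero with the deficit
#' transferred to the sibling edge.
#'
#' @param d symmetric distance matrix with dimnames (>= 3 taxa).
#' @return unrooted `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 3L)
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  labels <- rownames(d)
  nodes <- as.list(labels)          # newick fragment per active node
  D <- d
  n <- nrow(D)
  while (n > 3L) {
    r <- rowSums(D)
    best <- c(NA_integer_, NA_integer_)
    bestq <- Inf
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      q <- (n - 2) * D[i, j] - r[i] - r[j]
      if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    merged <- paste0("(", nodes[[i]], ":", format(li, digits = 15), ",",
                     nodes[[j]], ":", format(lj, digits = 15), ")")
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- base::matrix(0, n - 1L, n - 1L)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep]
    D2[n - 1L, seq_along(keep)] <- D2[seq_along(keep), n - 1L] <- newd[keep]
    D <- D2
    nodes <- c(nodes[keep], merged)
    n <- n - 1L
  }
  # final three-taxon star: three-point formulas
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  lens <- pmax(c(la, lb, lc), 0)
  nwk <- paste0("(", nodes[[1L]], ":", format(lens[1], digits = 15), ",",
                nodes[[2L]], ":", format(lens[2], digits = 15), ",",
                nodes[[3L]], ":", format(lens[3], digits = 15), ");")
  ape::read.tree(text = nwk)
}

# canonical bipartition strings of the internal edges of an unrooted tree
bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  out <- character(0)
  for (node in setdiff(unique(tree$edge[, 2L]), seq_len(n_tip))) {
    clade <- ape::extract.clade(tree, node)$tip.label
    side <- sort(clade)
    if (tips[1L] %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2L && length(side) <= length(tips) - 2L)
      out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Bootstrap support for a distance tree
#'
#' Resamples alignment columns with replacement, rebuilds the tree
#' (distance + neighbor joining) for each replicate, and reports, on the
#' full-data tree, the fraction of replicates containing each internal-edge
#' bipartition.  Supports are stored as internal node labels.
#'
#' @param aln named character vector of gapped rows.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed RNG seed for the resampling.
#' @param correction distance correction passed to [protein_distance()].
#' @return the full-data `phylo` tree; `node.label` holds per-edge supports
#'   in `[0, 1]` (empty for the unrooted basal node).
#' @export
bootstrap_support <- function(aln, n_replicates = 100L, seed = 1L,
                              correction = "poisson") {
  stopifnot(n_replicates >= 1)
  tree <- neighbor_joining(protein_distance(aln, correction))
  m <- alignment_matrix(aln)
  L <- ncol(m)
  set.seed(seed)
  tab <- integer(0)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- apply(m[, cols, drop = FALSE], 1L, function(r)
      paste(ifelse(r == 0L, "-", AA_WITH_X[pmax(r, 1L)])[seq_along(r)], collapse = ""))
    # guard: a resample can drop all shared columns for a pair; skip if so
    rep_tree <- tryCatch(
      neighbor_joining(protein_distance(setNames(rep_aln, rownames(m)),
                                        correction)),
      error = function(e) NULL)
    if (is.null(rep_tree)) next
    for (bp in bipartitions(rep_tree))
      tab[bp] <- (if (is.na(tab[bp])) 0L else tab[bp]) + 1L
  }
  bps <- bipartitions(tree)
  support <- setNames(numeric(length(bps)), bps)
  hit <- intersect(names(tab), bps)
  support[hit] <- tab[hit] / n_replicates
  # attach supports as node labels
  n_tip <- ape::Ntip(tree)
  labels <- rep("", tree$Nnode)
  for (node in setdiff(unique(tree$edge[, 2L]), seq_len(n_tip))) {
    clade <- sort(ape::extract.clade(tree, node)$tip.label)
    tips <- sort(tree$tip.label)
    side <- clade
    if (tips[1L] %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support))
      labels[node - n_tip] <- format(support[[key]], digits = 4)
  }
  tree$node.label <- labels
  attr(tree, "bipartition_support") <- support
  tree
}

#' Support of the edge subtending a given leaf set
#' @param tree tree from [bootstrap_support()].
#' @param leaves leaf subset.
#' @return support in `[0, 1]`, or `NA` if the subset is not an edge of the
#'   tree.
#' @export
split_support <- function(tree, leaves) {
  support <- attr(tree, "bipartition_support")
  if (is.null(support)) stop("tree carries no bootstrap supports")
  tips <- sort(tree$tip.label)
  side <- sort(intersect(leaves, tips))
  if (tips[1L] %in% side) side <- setdiff(tips, side)
  key <- paste(sort(side), collapse = "|")
  if (key %in% names(support)) support[[key]] else NA_real_
}

#' Root a tree with an outgroup
#'
#' Places the root on the pendant edge of the outgroup leaf, at its
#' midpoint.  Re-rooting an already-rooted tree at the same outgroup leaves
#' the topology unchanged.
#'
#' @param tree a `phylo` tree.
#' @param outgroup_id leaf label.
#' @return rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_id) {
  idx <- match(outgroup_id, tree$tip.label)
  if (is.na(idx)) stop("unknown leaf: ", outgroup_id)
  edge_row <- which(tree$edge[, 2L] == idx)
  pend <- tree$edge.length[edge_row]
  out <- phytools::reroot(tree, idx, position = pend / 2)
  # unrooted bipartitions (hence bootstrap supports) are rooting-invariant
  attr(out, "bipartition_support") <- attr(tree, "bipartition_support")
  out
}
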