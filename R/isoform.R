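#' Long-isoform records
#'
#' Reads a TSV of splice-isoform records (`taxon`, `accession`,
#' `isoform_label`), one row per surveyed SMO gene; a record carries the
#' long isoform unless its label is `"no isoform"`.
#'
#' @param path TSV file path; default the packaged transcription of the
#'   published exon-VIa survey.
#' @return data.frame with the three input columns plus `has_long_isoform`.
#' @export
read_isoform_records <- function(path = paofam_fixture("table2_isoforms.tsv")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "accession", "isoform_label") %in% names(df)))
  df$has_long_isoform <- df$isoform_label != "no isoform"
  df
}

#' Census of long-isoform presence
#' @param records data.frame from [read_isoform_records()] (needs
#'   `has_long_isoform`).
#' @return named integer vector `c(with_isoform, without)`.
#' @export
isoform_census <- function(records) {
  w <- sum(records$has_long_isoform)
  c(with_isoform = as.integer(w),
    without = as.integer(nrow(records) - w))
}

#' Parsimony placement of a presence/absence character
#'
#' Fitch (minimum-change) optimization of a binary character on a rooted
#' species tree, reporting the minimum number of state changes and the
#' branches where the character is gained or lost.  Among equally
#' parsimonious labelings, absence is preferred at the root and a child
#' keeps its parent's state whenever its Fitch set allows, which dates each
#' change to the latest branch compatible with the minimum.
#'
#' @param species_tree rooted `phylo` tree.
#' @param presence named logical vector over all tree leaves.
#' @return list with `n_events`, `gains` and `losses` (data.frames naming
#'   the child node/clade of each event branch), and `node_states`.
#' @export
parsimony_gain <- function(species_tree, presence) {
  tr <- species_tree
  miss <- setdiff(tr$tip.label, names(presence))
  if (length(miss)) stop("presence missing for: ", paste(miss, collapse = ", "))
  n_tip <- ape::Ntip(tr)
  n_all <- n_tip + tr$Nnode
  kids <- tree_children(tr)
  # Fitch bottom-up: sets coded 1 = {absent}, 2 = {present}, 3 = both
  fset <- integer(n_all)
  up <- function(node) {
    if (node <= n_tip) {
      fset[node] <<- if (presence[[tr$tip.label[node]]]) 2L else 1L
      return(fset[node])
    }
    sets <- vapply(kids[[node]], up, integer(1L))
    inter <- Reduce(bitwAnd, sets)
    fset[node] <<- if (inter != 0L) inter else Reduce(bitwOr, sets)
    fset[node]
  }
  up(n_tip + 1L)
  # top-down assignment: prefer parent state when allowed; at the root
  # prefer absence
  state <- logical(n_all)
  root <- n_tip + 1L
  state[root] <- fset[root] == 2L      # only "present" forces presence
  down <- function(node) {
    for (k in kids[[node]]) {
      allowed <- fset[k]
      state[k] <<- if (allowed == 3L) state[node] else allowed == 2L
      if (k > n_tip) down(k)
    }
  }
  down(root)
  changes <- which(tr$edge[, 2L] != root &
                     state[tr$edge[, 1L]] != state[tr$edge[, 2L]])
  child <- tr$edge[changes, 2L]
  gained <- state[child]
  describe <- function(nodes) {
    if (!length(nodes))
      return(data.frame(node = integer(0), clade = character(0)))
    data.frame(node = nodes,
               clade = vapply(nodes, function(nd) {
                 if (nd <= n_tip) tr$tip.label[nd] else
                   paste(ape::extract.clade(tr, nd)$tip.label, collapse = ",")
               }, character(1L)),
               stringsAsFactors = FALSE)
  }
  list(n_events = length(changes),
       gains = describe(child[gained]),
       losses = describe(child[!gained]),
       node_states = state)
}

#' Mean conservation of domain blocks per clade
#'
#' Restricts per-column conservation to designated alignment-column blocks
#' (e.g. the NDA and NDB nuclear-domain regions) and averages it within
#' each clade's rows, quantifying contrasts such as high NDA/NDB
#' conservation inside placental mammals versus its absence outside.
#'
#' @param aln named character vector of gapped rows.
#' @param blocks named list of alignment column index vectors.
#' @param clades named list of row-id vectors.
#' @param gaps_in_denominator passed to [column_conservation()].
#' @return data.frame `block`, `clade`, `n_rows`, `mean_conservation`.
#' @export
domain_conservation <- function(aln, blocks, clades,
                                gaps_in_denominator = TRUE) {
  rows <- list()
  for (bn in names(blocks)) {
    cols <- blocks[[bn]]
    for (cn in names(clades)) {
      ids <- clades[[cn]]
      cons <- column_conservation(aln, rows = ids,
                                  gaps_in_denominator = gaps_in_denominator)
      rows[[paste(bn, cn)]] <- data.frame(
        block = bn, clade = cn, n_rows = length(ids),
        mean_conservation = mean(cons$score[cols]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
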