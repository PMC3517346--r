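#' Species tree with a designated outgroup
#'
#' Thin wrapper around an `ape` phylo object: a rooted binary tree with
#' non-negative branch lengths and a named outgroup leaf.
#'
#' @param tree a rooted `phylo` object or a Newick string.
#' @param outgroup_taxon leaf label used for rooting downstream analyses.
#' @return the `phylo` object with attribute `outgroup`.
#' @export
species_tree <- function(tree, outgroup_taxon = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf label")
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (!is.null(outgroup_taxon)) {
    if (!outgroup_taxon %in% tree$tip.label)
      stop("outgroup_taxon is not a leaf of the tree")
    attr(tree, "outgroup") <- outgroup_taxon
  }
  tree
}

#' Substitution-model data: exchangeabilities and stationary frequencies
#'
#' `jtt_exchange()` returns the JTT empirical amino-acid model (symmetric
#' 20x20 exchangeability matrix plus stationary frequencies), resolved from
#' phangorn's packaged model table.  `read_exchange_matrix()` reads any
#' empirical model in the PAML `.dat` layout (19 lines of lower-triangle
#' exchangeabilities followed by a line of 20 stationary frequencies), so
#' the simulator is not tied to a particular matrix.
#'
#' @return list with `S` (20x20 symmetric, amino-acid dimnames) and `freqs`
#'   (named, summing to 1).
#' @export
jtt_exchange <- function() {
  mod <- get(".JTT", envir = asNamespace("phangorn"))
  S <- base::matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  S[lower.tri(S)] <- mod$Q
  S <- S + t(S)
  freqs <- as.numeric(mod$bf)
  names(freqs) <- AA_ALPHABET
  list(S = S, freqs = freqs / sum(freqs))
}

#' @rdname jtt_exchange
#' @param path path to a PAML-style `.dat` model file.
#' @export
read_exchange_matrix <- function(path) {
  toks <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  if (length(toks) < 190 + 20) stop("expected 190 exchangeabilities + 20 frequencies")
  S <- base::matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  k <- 0L
  for (i in 2:20) for (j in 1:(i - 1)) {
    k <- k + 1L
    S[i, j] <- toks[k]
  }
  S <- S + t(S)
  freqs <- toks[191:210]
  names(freqs) <- AA_ALPHABET
  list(S = S, freqs = freqs / sum(freqs))
}

#' Parameters of the protein evolution process
#'
#' Continuous-time substitution process built from an empirical
#' exchangeability matrix, with invariant-sites plus gamma rate
#' heterogeneity (the I+G model): a site has rate 0 with probability
#' `p_invariant` and otherwise a rate drawn from Gamma(`gamma_shape`, mean
#' 1).  `constrained_columns` (root coordinates) have substitution-rate
#' multiplier 0 everywhere and are never touched by indels, emulating
#' functionally constrained active-site positions.  Single-residue indels
#' occur at `indel_rate` events per site per unit branch length.
#'
#' @param exchange model data from [jtt_exchange()] or
#'   [read_exchange_matrix()].
#' @param gamma_shape positive shape of the gamma rate distribution.
#' @param p_invariant proportion of invariant sites, in `[0, 1]`.
#' @param indel_rate single-residue insertion/deletion rate
#'   (events/site/unit length).
#' @param constrained_columns integer site indices (root coordinates) frozen
#'   in every lineage.
#' @param seed integer master seed; all stochastic draws derive from it.
#' @return list of class `evolver_params`.
#' @export
evolver_params <- function(exchange = jtt_exchange(), gamma_shape = 1,
                           p_invariant = 0.2, indel_rate = 0.01,
                           constrained_columns = integer(), seed = 1L) {
  stopifnot(gamma_shape > 0, p_invariant >= 0, p_invariant <= 1,
            indel_rate >= 0)
  if (abs(sum(exchange$freqs) - 1) > 1e-9)
    stop("stationary frequencies must sum to 1")
  if (any(exchange$S < 0)) stop("exchangeabilities must be non-negative")
  if (!isTRUE(all.equal(exchange$S, t(exchange$S))))
    stop("exchangeability matrix must be symmetric")
  structure(list(exchange = exchange, gamma_shape = gamma_shape,
                 p_invariant = p_invariant, indel_rate = indel_rate,
                 constrained_columns = as.integer(constrained_columns),
                 seed = as.integer(seed)),
            class = "evolver_params")
}

# normalized rate matrix (expected 1 substitution/site/unit time), plus the
# jump-chain decomposition used by the exact simulation
rate_model <- function(exchange) {
  S <- exchange$S
  pi <- exchange$freqs
  Q <- S * rep(pi, each = nrow(S))  # Q[i, j] = S[i, j] * pi[j]
  diag(Q) <- 0
  leave <- rowSums(Q)
  mu <- sum(pi * leave)
  Q <- Q / mu
  leave <- leave / mu
  jump <- Q / leave
  list(leave = leave, jump = jump, freqs = pi)
}

#' Duplication scenario for a simulated gene family
#'
#' Describes where on the species tree the family duplicates (the stem edge
#' of the given clade, at its midpoint), which copies are retained per
#' taxon, which clade carries the extra-exon long isoform, and optional
#' per-locus constrained columns (columns frozen only within one
#' post-duplication subfamily, emulating subfamily-specific active-site
#' constraints).
#'
#' Loci are labelled `"pre"` (the ancestral, pre-duplication copy carried by
#' taxa outside the duplication clade), `"A"` and `"B"` (the two
#' post-duplication copies).  The extra exon is carried by the `"A"` copy of
#' taxa in `isoform_clade` (or by the `"pre"` copy when there is no
#' duplication).
#'
#' @param duplication_clade character vector of taxa whose stem edge carries
#'   the duplication; `NULL` for a single-copy family.
#' @param retained optional named list `taxon -> c(A = 0/1, B = 0/1)` (or
#'   `c(pre = 0/1)` outside the clade) overriding the default of retaining
#'   every copy; models secondary gene losses.
#' @param isoform_clade taxa whose long isoform carries the extra exon.
#' @param locus_constraints named list (`A`/`B`) of root column indices
#'   frozen only within that subfamily.
#' @param exon_length length of the extra-exon block (residues).
#' @param exon_anchor root column after which the block sits (default: the
#'   end of the sequence).
#' @param exon_rate_scale rate multiplier for the block (slow-evolving by
#'   default, emulating a conserved nuclear-localization domain).
#' @return list of class `duplication_scenario`.
#' @export
duplication_scenario <- function(duplication_clade = NULL, retained = NULL,
                                 isoform_clade = character(),
                                 locus_constraints = list(),
                                 exon_length = 40L, exon_anchor = NULL,
                                 exon_rate_scale = 0.3) {
  stopifnot(exon_length >= 1, exon_rate_scale >= 0)
  if (length(locus_constraints) &&
      !all(names(locus_constraints) %in% c("A", "B")))
    stop("locus_constraints must be named 'A' and/or 'B'")
  structure(list(duplication_clade = duplication_clade, retained = retained,
                 isoform_clade = isoform_clade,
                 locus_constraints = lapply(locus_constraints, as.integer),
                 exon_length = as.integer(exon_length),
                 exon_anchor = exon_anchor,
                 exon_rate_scale = exon_rate_scale),
            class = "duplication_scenario")
}

# ---- gene-tree construction ------------------------------------------------

tree_children <- function(phy) {
  n_node <- ape::Ntip(phy) + phy$Nnode
  kids <- vector("list", n_node)
  for (k in seq_len(nrow(phy$edge)))
    kids[[phy$edge[k, 1L]]] <- c(kids[[phy$edge[k, 1L]]], phy$edge[k, 2L])
  kids
}

edge_length_of_child <- function(phy) {
  len <- numeric(ape::Ntip(phy) + phy$Nnode)
  len[phy$edge[, 2L]] <- phy$edge.length
  len
}

#' Build the true gene tree implied by a duplication scenario
#'
#' The gene tree mirrors the species tree; on the stem edge of the
#' duplication clade a duplication node (labelled `"D"`) is inserted at the
#' edge midpoint, below which the clade subtree appears twice (copies `A`
#' and `B`).  Leaves are named `taxon_locus`; copies not retained under the
#' scenario are pruned.
#'
#' @param species_tree rooted `phylo` (see [species_tree()]).
#' @param scenario a [duplication_scenario()].
#' @return list with `tree` (`phylo`; duplication node labelled `"D"`),
#'   `leaf_taxon` (named map leaf -> taxon), `leaf_locus`, and
#'   `dup_species_mrca` (species-tree node number under the duplication
#'   edge, or `NA` if no duplication).
#' @export
simulate_gene_tree <- function(species_tree, scenario) {
  phy <- species_tree
  taxa <- phy$tip.label
  if (length(taxa) == 0L) stop("empty scenario")
  if (any(grepl("_", taxa, fixed = TRUE)))
    stop("taxon labels must not contain '_'")
  kids <- tree_children(phy)
  elen <- edge_length_of_child(phy)
  root <- ape::Ntip(phy) + 1L

  dup_node <- NA_integer_
  if (!is.null(scenario$duplication_clade)) {
    dc <- scenario$duplication_clade
    if (!all(dc %in% taxa)) stop("duplication clade contains unknown taxa")
    dup_node <- if (length(dc) == 1L) match(dc, taxa) else
      ape::getMRCA(phy, dc)
    if (dup_node == root)
      stop("duplication clade must be a proper subset of the taxa")
  }

  tip_name <- function(node, locus) paste0(phy$tip.label[node], "_", locus)
  sub_nwk <- function(node, locus) {
    if (node <= ape::Ntip(phy)) return(tip_name(node, locus))
    parts <- vapply(kids[[node]], function(k)
      paste0(sub_nwk(k, locus), ":", format(elen[k], digits = 12)),
      character(1L))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rec <- function(node) {
    if (node <= ape::Ntip(phy)) return(tip_name(node, "pre"))
    parts <- vapply(kids[[node]], function(k) {
      if (!is.na(dup_node) && k == dup_node) {
        half <- elen[k] / 2
        paste0("(", sub_nwk(k, "A"), ":", format(half, digits = 12), ",",
               sub_nwk(k, "B"), ":", format(half, digits = 12), ")D:",
               format(half, digits = 12))
      } else {
        paste0(rec(k), ":", format(elen[k], digits = 12))
      }
    }, character(1L))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- if (!is.na(dup_node) && dup_node != root) {
    paste0(rec(root), ";")
  } else {
    paste0(rec(root), ";")
  }
  gt <- ape::read.tree(text = nwk)

  # default retention: every generated copy kept
  keep <- gt$tip.label
  if (!is.null(scenario$retained)) {
    drop <- character(0)
    for (tx in names(scenario$retained)) {
      r <- scenario$retained[[tx]]
      for (loc in names(r))
        if (r[[loc]] == 0) drop <- c(drop, paste0(tx, "_", loc))
    }
    keep <- setdiff(keep, drop)
    if (length(keep) == 0L) stop("empty scenario")
    if (length(drop))
      gt <- ape::drop.tip(gt, intersect(drop, gt$tip.label))
  }
  leaf_taxon <- sub("_[^_]+$", "", gt$tip.label)
  leaf_locus <- sub("^.*_", "", gt$tip.label)
  names(leaf_taxon) <- names(leaf_locus) <- gt$tip.label
  list(tree = gt, leaf_taxon = leaf_taxon, leaf_locus = leaf_locus,
       dup_species_mrca = dup_node)
}

# locus context of every gene-tree node: "A"/"B" if all descendant leaves
# carry that locus, otherwise "pre"
node_locus <- function(gt) {
  n_tip <- ape::Ntip(gt)
  n_all <- n_tip + gt$Nnode
  locus <- character(n_all)
  leaf_locus <- sub("^.*_", "", gt$tip.label)
  kids <- tree_children(gt)
  assign_rec <- function(node) {
    if (node <= n_tip) {
      locus[node] <<- leaf_locus[node]
      return(locus[node])
    }
    ls <- vapply(kids[[node]], assign_rec, character(1L))
    locus[node] <<- if (all(ls == "A")) "A" else if (all(ls == "B")) "B" else "pre"
    locus[node]
  }
  assign_rec(n_tip + 1L)
  locus
}

# ---- sequence evolution ----------------------------------------------------

# draw a per-site rate under I+G
draw_rates <- function(n, params) {
  inv <- runif(n) < params$p_invariant
  r <- rgamma(n, shape = params$gamma_shape, rate = params$gamma_shape)
  r[inv] <- 0
  r
}

# simulate the jump chain of one site for duration t; returns c(state, nsub)
evolve_site <- function(state, t, model) {
  nsub <- 0L
  repeat {
    lam <- model$leave[state]
    dt <- rexp(1L, lam)
    if (dt > t) break
    t <- t - dt
    state <- sample.int(20L, 1L, prob = model$jump[state, ])
    nsub <- nsub + 1L
  }
  c(state, nsub)
}

# evolve a node state along one branch. state: list(res, key, col, rate, orig)
evolve_branch <- function(state, t, locus, params, model, scenario, counts) {
  if (t > 0) {
    frozen <- state$orig %in% params$constrained_columns
    lc <- scenario$locus_constraints[[locus]]
    if (!is.null(lc)) frozen <- frozen | state$orig %in% lc
    active <- which(!frozen & state$rate > 0)
    for (i in active) {
      res <- evolve_site(state$res[i], t * state$rate[i], model)
      state$res[i] <- res[1L]
      if (res[2L] > 0L) {
        id <- as.character(state$col[i])
        counts$n[[id]] <- (if (is.null(counts$n[[id]])) 0L else counts$n[[id]]) + res[2L]
      }
    }
    if (params$indel_rate > 0) {
      n_ev <- rpois(1L, params$indel_rate * length(state$res) * t)
      for (e in seq_len(n_ev)) {
        if (length(state$res) == 0L) break
        frozen <- state$orig %in% params$constrained_columns
        if (!is.null(lc)) frozen <- frozen | state$orig %in% lc
        if (runif(1L) < 0.5) {
          free <- which(!frozen)
          if (length(free) == 0L) next
          del <- free[sample.int(length(free), 1L)]
          state$res <- state$res[-del]
          state$key <- state$key[-del]
          state$col <- state$col[-del]
          state$rate <- state$rate[-del]
          state$orig <- state$orig[-del]
        } else {
          slot <- sample.int(length(state$res) + 1L, 1L)  # insert before slot
          lo <- if (slot == 1L) state$key[1L] - 1 else state$key[slot - 1L]
          hi <- if (slot > length(state$res)) state$key[length(state$res)] + 1 else state$key[slot]
          newkey <- (lo + hi) / 2
          counts$next_col <- counts$next_col + 1L
          state$res <- append(state$res, sample.int(20L, 1L, prob = model$freqs), slot - 1L)
          state$key <- append(state$key, newkey, slot - 1L)
          state$col <- append(state$col, counts$next_col, slot - 1L)
          state$rate <- append(state$rate, draw_rates(1L, params), slot - 1L)
          state$orig <- append(state$orig, NA_integer_, slot - 1L)
        }
      }
    }
  }
  state
}

# preorder evolution over a gene tree; returns leaf states
evolve_over_tree <- function(gt, root_state, params, model, scenario,
                             counts, time_scale = 1) {
  n_tip <- ape::Ntip(gt)
  kids <- tree_children(gt)
  elen <- edge_length_of_child(gt)
  locus <- node_locus(gt)
  leaves <- vector("list", n_tip)
  walk <- function(node, state) {
    if (node <= n_tip) {
      leaves[[node]] <<- state
      return(invisible())
    }
    for (k in kids[[node]]) {
      st <- evolve_branch(state, elen[k] * time_scale, locus[k], params,
                          model, scenario, counts)
      walk(k, st)
    }
  }
  walk(n_tip + 1L, root_state)
  names(leaves) <- gt$tip.label
  leaves
}

#' Simulate a protein family evolving on a species tree
#'
#' Evolves a root protein of `root_length` sites over the gene tree implied
#' by the scenario (species tree + duplication + losses), under the I+G
#' substitution process of `params`, with optional single-residue indels,
#' globally or per-subfamily constrained columns, and a slow-evolving
#' extra-exon block appended to the long-isoform carriers.  Fully
#' deterministic given `params$seed`.
#'
#' @param species_tree rooted `phylo` (see [species_tree()]).
#' @param scenario a [duplication_scenario()].
#' @param params an [evolver_params()].
#' @param root_length number of sites in the root sequence (>= 1).
#' @param family_id family label recorded in the truth table.
#' @return list with:
#'   * `sequences`: named character vector (one per retained copy);
#'   * `truth`: data.frame `sequence_id`, `taxon`, `locus`, `family_id`,
#'     `has_extra_exon`, with attribute `true_tree` (Newick);
#'   * `gene_tree`: the true gene tree (`phylo`, duplication node labelled
#'     `"D"`);
#'   * `alignment`: the true multiple alignment (named character vector of
#'     gapped rows);
#'   * `site_counts`: per-alignment-column realized substitution counts;
#'   * `constrained_alignment_columns`: alignment columns corresponding to
#'     `params$constrained_columns`;
#'   * `locus_constrained_alignment_columns`: ditto for the per-locus sets;
#'   * `exon_columns`: alignment columns of the extra-exon block;
#'   * `dup_species_mrca`: species-tree node under the duplication edge.
#' @export
simulate_family <- function(species_tree, scenario = duplication_scenario(),
                            params = evolver_params(), root_length = 500L,
                            family_id = "F1") {
  stopifnot(root_length >= 1)
  if (length(species_tree$tip.label) == 0L) stop("empty scenario")
  set.seed(params$seed)
  model <- rate_model(params$exchange)
  sim <- simulate_gene_tree(species_tree, scenario)
  gt <- sim$tree

  counts <- new.env(parent = emptyenv())
  counts$n <- list()
  counts$next_col <- as.integer(root_length)

  root_state <- list(res = sample.int(20L, root_length, replace = TRUE,
                                      prob = model$freqs),
                     key = as.numeric(seq_len(root_length)),
                     col = seq_len(root_length),
                     rate = draw_rates(root_length, params),
                     orig = seq_len(root_length))
  leaves <- evolve_over_tree(gt, root_state, params, model, scenario, counts)

  # extra-exon block for isoform carriers
  iso_locus <- if (is.null(scenario$duplication_clade)) "pre" else "A"
  carriers <- intersect(paste0(scenario$isoform_clade, "_", iso_locus),
                        gt$tip.label)
  exon_leaves <- list()
  if (length(carriers)) {
    exon_root <- list(res = sample.int(20L, scenario$exon_length,
                                       replace = TRUE, prob = model$freqs),
                      key = as.numeric(seq_len(scenario$exon_length)),
                      col = counts$next_col + seq_len(scenario$exon_length),
                      rate = draw_rates(scenario$exon_length, params),
                      orig = rep(NA_integer_, scenario$exon_length))
    counts$next_col <- counts$next_col + scenario$exon_length
    if (length(carriers) == 1L) {
      exon_leaves <- setNames(list(exon_root), carriers)
    } else {
      sub <- ape::extract.clade(gt, ape::getMRCA(gt, carriers))
      exon_leaves <- evolve_over_tree(sub, exon_root, params, model,
                                      duplication_scenario(
                                        exon_length = scenario$exon_length),
                                      counts,
                                      time_scale = scenario$exon_rate_scale)
      exon_leaves <- exon_leaves[intersect(names(exon_leaves), carriers)]
    }
  }

  # ---- assemble truth alignment -------------------------------------------
  all_cols <- unique(do.call(rbind, lapply(leaves, function(s)
    data.frame(col = s$col, key = s$key))))
  all_cols <- all_cols[order(all_cols$key, all_cols$col), , drop = FALSE]
  anchor <- if (is.null(scenario$exon_anchor)) root_length else scenario$exon_anchor
  main_cols <- all_cols$col
  exon_cols <- if (length(exon_leaves))
    sort(unique(unlist(lapply(exon_leaves, `[[`, "col")))) else integer(0)
  # the exon block is inserted, as a contiguous group, after the last main
  # column whose key is <= anchor
  cut <- sum(all_cols$key <= anchor)
  col_order <- append(main_cols, exon_cols, after = cut)

  row_of <- function(id) {
    s <- leaves[[id]]
    main <- setNames(rep("-", length(main_cols)), main_cols)
    main[as.character(s$col)] <- AA_ALPHABET[s$res]
    exo <- setNames(rep("-", length(exon_cols)), exon_cols)
    if (id %in% names(exon_leaves)) {
      e <- exon_leaves[[id]]
      exo[as.character(e$col)] <- AA_ALPHABET[e$res]
    }
    paste(c(main, exo)[as.character(col_order)], collapse = "")
  }
  aln <- vapply(gt$tip.label, row_of, character(1L))

  sequences <- vapply(aln, function(x) gsub("-", "", x, fixed = TRUE),
                      character(1L))
  names(sequences) <- names(aln) <- gt$tip.label

  sub_counts <- setNames(rep(0L, length(col_order)), col_order)
  hit <- intersect(names(counts$n), names(sub_counts))
  sub_counts[hit] <- unlist(counts$n[hit])

  constrained_aln <- which(col_order %in% params$constrained_columns)
  locus_constrained_aln <- lapply(scenario$locus_constraints, function(v)
    which(col_order %in% v))
  exon_aln <- which(col_order %in% exon_cols)

  truth <- data.frame(
    sequence_id = gt$tip.label,
    taxon = sim$leaf_taxon[gt$tip.label],
    locus = sim$leaf_locus[gt$tip.label],
    family_id = family_id,
    has_extra_exon = gt$tip.label %in% names(exon_leaves),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  attr(truth, "true_tree") <- ape::write.tree(gt)

  list(sequences = sequences, truth = truth, gene_tree = gt,
       alignment = aln, site_counts = unname(sub_counts),
       constrained_alignment_columns = constrained_aln,
       locus_constrained_alignment_columns = locus_constrained_aln,
       exon_columns = exon_aln,
       dup_species_mrca = sim$dup_species_mrca)
}

#' Realized per-site substitution counts under the rate model
#'
#' Evolves `n_sites` independent sites along a single lineage of duration
#' `time` and returns the realized substitution count of each site; useful
#' for goodness-of-fit checks of the invariant-sites + gamma emulation.
#'
#' @param params an [evolver_params()].
#' @param n_sites number of sites (>= 100).
#' @param time lineage duration in expected substitutions/site.
#' @return integer vector of per-site substitution counts (constrained
#'   columns report 0).
#' @export
realized_rate_distribution <- function(params, n_sites, time = 5) {
  stopifnot(n_sites >= 100)
  set.seed(params$seed)
  model <- rate_model(params$exchange)
  rates <- draw_rates(n_sites, params)
  rates[seq_len(n_sites) %in% params$constrained_columns] <- 0
  states <- sample.int(20L, n_sites, replace = TRUE, prob = model$freqs)
  counts <- integer(n_sites)
  for (i in which(rates > 0)) {
    res <- evolve_site(states[i], time * rates[i], model)
    counts[i] <- res[2L]
  }
  counts
}

#' FASTA input/output
#'
#' `read_fasta()` wraps `Biostrings::readAAStringSet()`; `write_fasta()`
#' writes a named character vector wrapped at `width` columns.
#'
#' @param x named character vector of sequences.
#' @param path file path.
#' @param width line-wrap width.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(x, path, width = 60L) {
  x <- as_protein_set(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(x)) {
    writeLines(paste0(">", id), con)
    s <- x[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' Truth-table TSV input/output
#' @param truth truth data.frame from [simulate_family()].
#' @param path file path.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) read.delim(path, stringsAsFactors = FALSE)
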