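# Independent oracles, coded separately from the package internals.

# Affine-gap Smith-Waterman score by row-vectorized DP (gap of length L costs
# go + (L-1)*ge).  Score only; independent of the C++ kernel's formulation.
sw_score_oracle <- function(a, b, scoring) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  S <- scoring$matrix
  go <- scoring$gap_open
  ge <- scoring$gap_extend
  n <- length(A); m <- length(B)
  s_rows <- S[A, B, drop = FALSE]
  prevM <- prevX <- prevY <- rep(-Inf, m)
  best <- 0
  jge <- seq_len(m) * ge
  for (i in seq_len(n)) {
    X <- pmax(prevM - go, prevX - ge)
    diagbest <- pmax(0, c(0, pmax(prevM, prevX, prevY)[-m]))
    M <- s_rows[i, ] + diagbest
    # Y[j] = max_{k<j} M[k] - go - (j-1-k)*ge, via cumulative max
    cm <- cummax(c(-Inf, (M + jge)[-m]))
    Y <- cm - go - (jge - ge)
    best <- max(best, M)
    prevM <- M; prevX <- X; prevY <- Y
  }
  best
}

# exhaustive-subset chaining oracle: maximum total aligned length over all
# subsets of hits pairwise non-overlapping in both coordinate systems
chain_objective_oracle <- function(hits) {
  n <- nrow(hits)
  stopifnot(n <= 20)
  w <- (hits$q_end - hits$q_start + 1) + (hits$s_end - hits$s_start + 1)
  cm <- integer(n)
  for (i in seq_len(n)) {
    bits <- 0L
    for (j in seq_len(n)) {
      if (i == j) next
      qd <- hits$q_end[i] < hits$q_start[j] || hits$q_end[j] < hits$q_start[i]
      sd <- hits$s_end[i] < hits$s_start[j] || hits$s_end[j] < hits$s_start[i]
      if (qd && sd) bits <- bitwOr(bits, bitwShiftL(1L, j - 1L))
    }
    cm[i] <- bits
  }
  n_masks <- bitwShiftL(1L, n)
  valid <- logical(n_masks); valid[1L] <- TRUE
  weight <- numeric(n_masks)
  best <- 0
  for (mask in seq_len(n_masks - 1L)) {
    low <- bitwAnd(mask, -mask)
    i <- as.integer(round(log2(low))) + 1L
    rest <- mask - low
    ok <- valid[rest + 1L] && bitwAnd(cm[i], rest) == rest
    valid[mask + 1L] <- ok
    if (ok) {
      weight[mask + 1L] <- weight[rest + 1L] + w[i]
      if (weight[mask + 1L] > best) best <- weight[mask + 1L]
    }
  }
  best
}

# random hit set for one ordered pair
random_hits <- function(n, span_max = 40L, coord_max = 200L) {
  qs <- sample.int(coord_max, n, replace = TRUE)
  ql <- sample.int(span_max, n, replace = TRUE)
  ss <- sample.int(coord_max, n, replace = TRUE)
  sl <- sample.int(span_max, n, replace = TRUE)
  data.frame(query_id = "q", subject_id = "s",
             q_start = qs, q_end = qs + ql - 1L,
             s_start = ss, s_end = ss + sl - 1L,
             raw_score = sample.int(500L, n, replace = TRUE),
             identities = pmin(ql, sl),
             aligned_columns = pmax(ql, sl),
             bitscore = runif(n, 20, 200),
             evalue = runif(n) * 1e-12,
             stringsAsFactors = FALSE)
}

# breadth-first-search connected components; returns canonical partition
# (list of sorted member vectors, ordered by first member)
bfs_components_oracle <- function(ids, edge_a, edge_b) {
  adj <- setNames(vector("list", length(ids)), ids)
  for (k in seq_along(edge_a)) {
    adj[[edge_a[k]]] <- c(adj[[edge_a[k]]], edge_b[k])
    adj[[edge_b[k]]] <- c(adj[[edge_b[k]]], edge_a[k])
  }
  seen <- setNames(rep(FALSE, length(ids)), ids)
  comps <- list()
  for (id in ids) {
    if (seen[[id]]) next
    queue <- id; seen[[id]] <- TRUE; comp <- character(0)
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      comp <- c(comp, v)
      for (w in adj[[v]]) if (!seen[[w]]) { seen[[w]] <- TRUE; queue <- c(queue, w) }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, `[`, character(1L), 1L))]
}

canonical_partition <- function(membership) {
  comps <- split(names(membership), membership)
  comps <- lapply(comps, sort)
  names(comps) <- NULL
  comps[order(vapply(comps, `[`, character(1L), 1L))]
}

# exhaustive Fitch oracle: minimum number of state changes over all internal
# labelings of a rooted tree (for small trees)
fitch_count_oracle <- function(tree, presence) {
  n_tip <- ape::Ntip(tree)
  n_int <- tree$Nnode
  stopifnot(n_int <= 12)
  tip_state <- as.integer(presence[tree$tip.label])
  best <- Inf
  for (mask in 0:(2^n_int - 1)) {
    int_state <- as.integer(bitwAnd(bitwShiftR(mask, 0:(n_int - 1)), 1L))
    state <- c(tip_state, int_state)
    changes <- sum(state[tree$edge[, 1L]] != state[tree$edge[, 2L]])
    if (changes < best) best <- changes
  }
  best
}

random_protein <- function(len) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"), len, replace = TRUE),
        collapse = "")
}

# 0-row hit table in the canonical layout
empty_hit_table_for_test <- function() random_hits(1)[0, ]

# gapped rows -> character matrix
alignment_rows_to_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln), ""))
}

# random undirected two-way edge table over ids (self-loops removed)
random_edge_table <- function(ids, n_edge) {
  ea <- sample(ids, n_edge, replace = TRUE)
  eb <- sample(ids, n_edge, replace = TRUE)
  keep <- ea != eb
  m <- sum(keep)
  data.frame(id_a = pmin(ea, eb)[keep], id_b = pmax(ea, eb)[keep],
             passed_ab = rep(TRUE, m), passed_ba = rep(TRUE, m),
             two_way = rep(TRUE, m), stringsAsFactors = FALSE)
}
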