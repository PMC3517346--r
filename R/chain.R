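#' Chain multiple local hits for one ordered sequence pair
#'
#' When a pair of sequences has several local hits, selects the subset of
#' hits that are pairwise non-overlapping in the query AND in the subject
#' coordinates and maximizes the total aligned length
#' (query-span residues + subject-span residues), by exact search over
#' subsets.  The selected combination is then treated as a single composite
#' hit: its identity is pooled (`sum(identities) / sum(aligned_columns)`) and
#' its bitscore is the sum of the member bitscores.  Ties on the objective
#' are broken by higher total raw score, then by the lexicographically
#' smallest sorted hit-index set.  Intervals that merely touch do not
#' overlap; overlap means at least one shared residue position.
#'
#' @param hits data.frame of hits for a single ordered pair, in the layout of
#'   [local_align()] (with or without the id columns).  At most 64 hits.
#' @param require_collinear if `TRUE`, additionally require the selected hits
#'   to appear in the same relative order on query and subject (off by
#'   default; the combination step imposes no order constraint).
#' @return an object of class `chained_pair`: a list with `query_id`,
#'   `subject_id`, `selected` (row indices into `hits`), `n_hits`,
#'   `total_aligned_query`, `total_aligned_subject`, `combined_identity`,
#'   `combined_bitscore`, `combined_raw_score` and `objective`.
#' @export
chain_hits <- function(hits, require_collinear = FALSE) {
  if (is.null(hits) || nrow(hits) == 0L) stop("no hits")
  qid <- if ("query_id" %in% names(hits)) unique(hits$query_id) else NA_character_
  sid <- if ("subject_id" %in% names(hits)) unique(hits$subject_id) else NA_character_
  if (length(qid) > 1L || length(sid) > 1L) stop("heterogeneous pair")
  n <- nrow(hits)
  if (n > 64L) stop("more than 64 hits for one pair")

  qlen <- hits$q_end - hits$q_start + 1L
  slen <- hits$s_end - hits$s_start + 1L
  w <- qlen + slen

  ord <- order(hits$q_start, hits$q_end, hits$s_start)
  # pairwise compatibility in the sorted order
  compat <- base::matrix(TRUE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- ord[i]; b <- ord[j]
    q_disjoint <- hits$q_end[a] < hits$q_start[b] || hits$q_end[b] < hits$q_start[a]
    s_disjoint <- hits$s_end[a] < hits$s_start[b] || hits$s_end[b] < hits$s_start[a]
    ok <- q_disjoint && s_disjoint
    if (ok && require_collinear) {
      ok <- (hits$q_start[a] < hits$q_start[b]) == (hits$s_start[a] < hits$s_start[b])
    }
    compat[i, j] <- ok
  }

  suffix_w <- rev(cumsum(rev(w[ord])))
  best <- list(obj = -Inf, score = -Inf, set = integer(0))

  better <- function(obj, score, set) {
    if (obj > best$obj + 1e-9) return(TRUE)
    if (obj < best$obj - 1e-9) return(FALSE)
    if (score > best$score + 1e-9) return(TRUE)
    if (score < best$score - 1e-9) return(FALSE)
    lex_less(sort(ord[set]), sort(ord[best$set]))
  }

  dfs <- function(i, chosen, obj, score) {
    if (i > n) {
      if (better(obj, score, chosen)) best <<- list(obj = obj, score = score, set = chosen)
      return(invisible())
    }
    if (obj + suffix_w[i] < best$obj - 1e-9) return(invisible())
    ok <- length(chosen) == 0L || all(compat[chosen, i])
    if (ok) {
      dfs(i + 1L, c(chosen, i), obj + w[ord[i]], score + hits$raw_score[ord[i]])
    }
    dfs(i + 1L, chosen, obj, score)
  }
  dfs(1L, integer(0), 0, 0)

  sel <- sort(ord[best$set])
  structure(list(
    query_id = qid, subject_id = sid,
    selected = sel, n_hits = length(sel),
    total_aligned_query = sum(qlen[sel]),
    total_aligned_subject = sum(slen[sel]),
    combined_identity = sum(hits$identities[sel]) / sum(hits$aligned_columns[sel]),
    combined_bitscore = sum(hits$bitscore[sel]),
    combined_raw_score = sum(hits$raw_score[sel]),
    objective = best$obj), class = "chained_pair")
}

# strict lexicographic order on integer vectors ({1} < {1,3})
lex_less <- function(a, b) {
  if (length(b) == 0L) return(FALSE)
  if (length(a) == 0L) return(TRUE)
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' @export
print.chained_pair <- function(x, ...) {
  cat(sprintf("Chained pair %s -> %s: %d hit(s), identity %.3f, bitscore %.1f\n",
              x$query_id, x$subject_id, x$n_hits, x$combined_identity,
              x$combined_bitscore))
  invisible(x)
}

#' Chain every ordered pair in a hit table
#'
#' Groups a hit table by `(query_id, subject_id)` and applies [chain_hits()]
#' to each group.  Both hit directions of a pair, when present, are chained
#' independently (the reciprocal-hit test downstream needs both).
#'
#' @param hit_table data.frame as produced by [all_vs_all()].
#' @inheritParams chain_hits
#' @return data.frame with one row per ordered pair: `query_id`,
#'   `subject_id`, `n_hits`, `total_aligned_q`, `total_aligned_s`,
#'   `combined_identity`, `combined_bitscore`.
#' @export
chain_all <- function(hit_table, require_collinear = FALSE) {
  if (nrow(hit_table) == 0L) return(empty_chain_table())
  key <- paste(hit_table$query_id, hit_table$subject_id, sep = "\r")
  groups <- split(seq_len(nrow(hit_table)), key)
  rows <- lapply(groups, function(idx) {
    cp <- chain_hits(hit_table[idx, , drop = FALSE], require_collinear)
    data.frame(query_id = cp$query_id, subject_id = cp$subject_id,
               n_hits = cp$n_hits,
               total_aligned_q = cp$total_aligned_query,
               total_aligned_s = cp$total_aligned_subject,
               combined_identity = cp$combined_identity,
               combined_bitscore = cp$combined_bitscore,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$query_id, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_chain_table <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             n_hits = integer(0), total_aligned_q = integer(0),
             total_aligned_s = integer(0), combined_identity = numeric(0),
             combined_bitscore = numeric(0), stringsAsFactors = FALSE)
}

#' Chained-pair TSV input/output
#' @param chained chained-pair data.frame from [chain_all()].
#' @param path file path.
#' @return `read_chain_table()` returns the chained-pair data.frame.
#' @export
write_chain_table <- function(chained, path) {
  write.table(chained, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chain_table
#' @export
read_chain_table <- function(path) read.delim(path, stringsAsFactors = FALSE)
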