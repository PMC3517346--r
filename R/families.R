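#' Homology filter thresholds
#'
#' The filters applied to chained hits before family building: at least 30%
#' pooled identity, combined bitscore of at least 50, at least 50% of the
#' length of BOTH sequences aligned, and no self-hits.  All thresholds are
#' inclusive.
#'
#' @param min_identity minimum combined identity (fraction).
#' @param min_bitscore minimum combined bitscore.
#' @param min_coverage_both minimum aligned fraction of each sequence length.
#' @param exclude_self drop self-pairs.
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_identity = 0.30, min_bitscore = 50,
                              min_coverage_both = 0.50, exclude_self = TRUE) {
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_bitscore >= 0, min_coverage_both >= 0, min_coverage_both <= 1)
  structure(list(min_identity = min_identity, min_bitscore = min_bitscore,
                 min_coverage_both = min_coverage_both,
                 exclude_self = isTRUE(exclude_self)),
            class = "filter_thresholds")
}

#' Apply the homology filters to chained pairs
#'
#' A chained ordered pair passes iff its combined identity, combined
#' bitscore, and the aligned coverage of both the query and the subject meet
#' the thresholds (all inclusive), and it is not a self-pair.
#'
#' @param chained data.frame from [chain_all()].
#' @param lengths named integer vector mapping sequence id to length
#'   (or the sequence set itself, from which lengths are taken).
#' @param thresholds a [filter_thresholds()].
#' @return `chained` with an added logical column `pass`.
#' @export
apply_filters <- function(chained, lengths, thresholds = filter_thresholds()) {
  if (!is.numeric(lengths)) lengths <- nchar(as_protein_set(lengths))
  ids <- unique(c(chained$query_id, chained$subject_id))
  missing <- setdiff(ids, names(lengths))
  if (length(missing))
    stop("unknown sequence length for: ", paste(missing, collapse = ", "))
  lq <- lengths[chained$query_id]
  ls <- lengths[chained$subject_id]
  pass <- chained$combined_identity >= thresholds$min_identity &
    chained$combined_bitscore >= thresholds$min_bitscore &
    chained$total_aligned_q >= thresholds$min_coverage_both * lq &
    chained$total_aligned_s >= thresholds$min_coverage_both * ls
  if (thresholds$exclude_self)
    pass <- pass & chained$query_id != chained$subject_id
  chained$pass <- as.logical(pass)
  chained
}

#' Reciprocal (two-way) homology edges
#'
#' Collapses the directional pass table to one record per unordered pair of
#' distinct sequences, recording whether each direction passed and whether
#' the pair is a two-way (reciprocal) hit.
#'
#' @param passes data.frame from [apply_filters()] (needs `query_id`,
#'   `subject_id`, `pass`).
#' @return data.frame with columns `id_a`, `id_b` (`id_a < id_b`),
#'   `passed_ab`, `passed_ba`, `two_way`.
#' @export
reciprocal_edges <- function(passes) {
  passes <- passes[passes$query_id != passes$subject_id, , drop = FALSE]
  if (nrow(passes) == 0L)
    return(data.frame(id_a = character(0), id_b = character(0),
                      passed_ab = logical(0), passed_ba = logical(0),
                      two_way = logical(0), stringsAsFactors = FALSE))
  a <- pmin(passes$query_id, passes$subject_id)
  b <- pmax(passes$query_id, passes$subject_id)
  fwd <- passes$query_id == a
  key <- paste(a, b, sep = "\r")
  rows <- lapply(split(seq_along(key), key), function(idx) {
    pa <- passes$pass[idx][fwd[idx]]
    pb <- passes$pass[idx][!fwd[idx]]
    data.frame(id_a = a[idx[1L]], id_b = b[idx[1L]],
               passed_ab = length(pa) > 0L && any(pa),
               passed_ba = length(pb) > 0L && any(pb),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$two_way <- out$passed_ab & out$passed_ba
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single-linkage gene families
#'
#' Starts with every sequence in its own family and merges the whole
#' families of any two sequences linked by a two-way hit, repeating until no
#' merge is possible — i.e. the connected components of the two-way-hit
#' graph, computed with union-find.  Families are numbered deterministically
#' in order of their smallest member id.
#'
#' @param ids character vector of all sequence ids.
#' @param edges data.frame from [reciprocal_edges()] (only rows with
#'   `two_way = TRUE` link families).
#' @return data.frame with one row per sequence: `id`, `family_id`
#'   (`"F1"`, `"F2"`, ... ), `is_singleton`.
#' @export
single_linkage_families <- function(ids, edges) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate id")
  unknown <- setdiff(c(edges$id_a, edges$id_b), ids)
  if (length(unknown))
    stop("edge references unknown id: ", paste(unknown, collapse = ", "))
  parent <- seq_along(ids)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  link <- edges[edges$two_way, , drop = FALSE]
  ai <- match(link$id_a, ids)
  bi <- match(link$id_b, ids)
  for (k in seq_along(ai)) {
    ra <- find(ai[k]); rb <- find(bi[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_along(ids), find, integer(1L))
  # number families by the smallest member id (alphabetical)
  comp <- split(ids, roots)
  comp <- comp[order(vapply(comp, min, character(1L)))]
  fam_of <- setNames(rep(seq_along(comp), lengths(comp)), unlist(comp))
  sizes <- setNames(rep(lengths(comp), lengths(comp)), unlist(comp))
  out <- data.frame(id = ids,
                    family_id = paste0("F", fam_of[ids]),
                    is_singleton = sizes[ids] == 1L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$family_id, out$id), , drop = FALSE]
}

#' Summarize families one row per family
#' @param families data.frame from [single_linkage_families()].
#' @return data.frame `family_id`, `member_count`, `members`
#'   (comma-separated), `is_singleton`.
#' @export
family_summary <- function(families) {
  comp <- split(families$id, families$family_id)
  out <- data.frame(family_id = names(comp),
                    member_count = lengths(comp),
                    members = vapply(comp, function(m)
                      paste(sort(m), collapse = ","), character(1L)),
                    is_singleton = lengths(comp) == 1L,
                    stringsAsFactors = FALSE)
  out <- out[order(as.integer(sub("^F", "", out$family_id))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Families TSV output
#' @param families data.frame from [single_linkage_families()].
#' @param path file path.
#' @export
write_family_table <- function(families, path) {
  write.table(family_summary(families), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
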