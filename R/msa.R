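#' Progressive multiple sequence alignment
#'
#' Basic progressive aligner: pairwise global (Needleman-Wunsch, affine gap)
#' alignments give a distance matrix (1 - identity); a UPGMA guide tree is
#' built from it; profiles are merged bottom-up by profile-profile affine
#' alignment with sum-of-pairs scoring.  This is a surrogate for an external
#' aligner such as ClustalW — externally computed alignments can be imported
#' instead via [read_alignment()].
#'
#' @param sequences named character vector (or `AAStringSet`) of proteins.
#' @param scoring a [scoring_scheme()].
#' @return named character vector of equal-length gapped rows, in the input
#'   order.
#' @export
progressive_align <- function(sequences, scoring = scoring_scheme()) {
  seqs <- as_protein_set(sequences)
  n <- length(seqs)
  if (n == 1L) {
    warning("single sequence: returning it unchanged")
    return(seqs)
  }
  enc <- lapply(seqs, aa_encode)
  S <- scoring$matrix
  if (n == 2L) {
    res <- .cpp_nw_global(enc[[1L]], enc[[2L]], S, scoring$gap_open,
                          scoring$gap_extend)
    return(setNames(c(path_to_row(enc[[1L]], res$path_a),
                      path_to_row(enc[[2L]], res$path_b)), names(seqs)))
  }
  d <- base::matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    res <- .cpp_nw_global(enc[[i]], enc[[j]], S, scoring$gap_open,
                          scoring$gap_extend)
    d[i, j] <- d[j, i] <- 1 - res$identity
  }
  hc <- hclust(as.dist(d), method = "average")
  # progressive merge following the UPGMA join order
  groups <- vector("list", n - 1L)
  get_group <- function(idx) {
    if (idx < 0) {
      id <- -idx
      list(ids = names(seqs)[id],
           rows = base::matrix(enc[[id]], nrow = 1L))
    } else groups[[idx]]
  }
  for (k in seq_len(n - 1L)) {
    ga <- get_group(hc$merge[k, 1L])
    gb <- get_group(hc$merge[k, 2L])
    pa <- profile_of(ga$rows)
    pb <- profile_of(gb$rows)
    res <- .cpp_profile_align(pa, pb, S, scoring$gap_open, scoring$gap_extend)
    rows_a <- expand_rows(ga$rows, res$path_a)
    rows_b <- expand_rows(gb$rows, res$path_b)
    groups[[k]] <- list(ids = c(ga$ids, gb$ids), rows = rbind(rows_a, rows_b))
  }
  final <- groups[[n - 1L]]
  ord <- match(names(seqs), final$ids)
  rows <- final$rows[ord, , drop = FALSE]
  out <- apply(rows, 1L, function(r) {
    chars <- rep("-", length(r))
    chars[r > 0L] <- AA_WITH_X[r[r > 0L]]
    paste(chars, collapse = "")
  })
  setNames(out, names(seqs))
}

# gapped row (code 0 = gap) from an alignment path
path_to_row <- function(codes, path) {
  chars <- rep("-", length(path))
  chars[path > 0L] <- AA_WITH_X[codes[path[path > 0L]]]
  paste(chars, collapse = "")
}

# column frequency profile (21 states; gaps carry no mass)
profile_of <- function(rows) {
  L <- ncol(rows)
  p <- base::matrix(0, 21L, L)
  nr <- nrow(rows)
  for (j in seq_len(L)) {
    cod <- rows[, j]
    cod <- cod[cod > 0L]
    if (length(cod)) {
      tab <- tabulate(cod, 21L)
      p[, j] <- tab / nr
    }
  }
  p
}

# apply a profile path (0 = gap column) to integer alignment rows
expand_rows <- function(rows, path) {
  out <- base::matrix(0L, nrow(rows), length(path))
  keep <- path != 0L
  out[, keep] <- rows[, path[keep], drop = FALSE]
  out
}

# named character vector of gapped rows -> integer matrix (0 = gap)
alignment_matrix <- function(aln) {
  rows <- lapply(aln, function(x) {
    chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
    codes <- match(chars, AA_WITH_X)
    codes[chars == "-" | chars == "."] <- 0L
    if (anyNA(codes)) stop("invalid residue in alignment")
    codes
  })
  if (length(unique(lengths(rows))) != 1L)
    stop("alignment rows must have equal length")
  m <- do.call(rbind, rows)
  rownames(m) <- names(aln)
  m
}

#' Per-column conservation of a multiple alignment
#'
#' The conservation of a column is the fraction of rows carrying its most
#' frequent residue; by default gaps count as mismatches (they stay in the
#' denominator).  Columns at or above `threshold` are flagged (use
#' `strict_gt = TRUE` for a strictly-greater test).
#'
#' @param aln named character vector of gapped rows.
#' @param rows optional subset of row ids to score.
#' @param threshold flagging threshold (default 0.90).
#' @param strict_gt flag only columns strictly above the threshold.
#' @param gaps_in_denominator if `FALSE`, score each column over its non-gap
#'   rows only.
#' @return data.frame with `column`, `majority` (majority residue, `NA` for
#'   all-gap columns), `score`, `flagged`.
#' @export
column_conservation <- function(aln, rows = NULL, threshold = 0.90,
                                strict_gt = FALSE, gaps_in_denominator = TRUE) {
  m <- alignment_matrix(aln)
  if (!is.null(rows)) {
    miss <- setdiff(rows, rownames(m))
    if (length(miss)) stop("unknown row id: ", paste(miss, collapse = ", "))
    m <- m[rows, , drop = FALSE]
  }
  nr <- nrow(m)
  score <- numeric(ncol(m))
  maj <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    tab <- tabulate(m[, j], 21L)
    denom <- if (gaps_in_denominator) nr else sum(tab)
    if (sum(tab) == 0L) {
      score[j] <- 0; maj[j] <- NA_character_
    } else {
      best <- max(tab)
      score[j] <- best / denom
      maj[j] <- sort(AA_WITH_X[tab == best])[1L]  # alphabetic tie-break
    }
  }
  flagged <- if (strict_gt) score > threshold else score >= threshold
  data.frame(column = seq_len(ncol(m)), majority = maj, score = score,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Consensus sequence of a row subset
#'
#' Per column, the most frequent non-gap residue, ties broken alphabetically;
#' a column is dropped when the gap state is strictly the most frequent.
#'
#' @param aln named character vector of gapped rows.
#' @param ids row subset (default: all rows).
#' @return consensus string (ungapped).
#' @export
consensus_of <- function(aln, ids = names(aln)) {
  miss <- setdiff(ids, names(aln))
  if (length(miss)) stop("unknown row id: ", paste(miss, collapse = ", "))
  m <- alignment_matrix(aln[ids])
  out <- character(0)
  for (j in seq_len(ncol(m))) {
    cod <- m[, j]
    n_gap <- sum(cod == 0L)
    tab <- tabulate(cod, 21L)
    if (sum(tab) == 0L) next
    best <- max(tab)
    if (n_gap > best) next                      # gap is the majority state
    cand <- AA_WITH_X[which(tab == best)]
    out <- c(out, sort(cand)[1L])               # alphabetic tie-break
  }
  paste(out, collapse = "")
}

#' Column-to-reference-position map
#'
#' Maps each non-gap column of the reference row to the 1-based residue
#' number in the ungapped reference sequence.
#'
#' @param aln named character vector of gapped rows.
#' @param reference_id row id of the reference sequence.
#' @return data.frame `column`, `ref_pos`, `ref_residue`.
#' @export
reference_map <- function(aln, reference_id) {
  if (!reference_id %in% names(aln)) stop("unknown reference id")
  chars <- strsplit(aln[[reference_id]], "", fixed = TRUE)[[1L]]
  non_gap <- which(chars != "-" & chars != ".")
  data.frame(column = non_gap, ref_pos = seq_along(non_gap),
             ref_residue = chars[non_gap], stringsAsFactors = FALSE)
}

#' Active-site panel
#'
#' A list of residue positions (in a reference sequence's own numbering)
#' with their expected residues, e.g. the mouse SMO panel Trp80, His82, ...
#' Panels can be read from a TSV with columns `ref_id`, `pos`,
#' `expected_aa` via [read_panel()].
#'
#' @param reference_id id of the reference sequence.
#' @param positions integer residue numbers (strictly increasing).
#' @param residues expected one-letter residues at those positions.
#' @return data.frame of class `active_site_panel`.
#' @export
active_site_panel <- function(reference_id, positions, residues) {
  stopifnot(length(positions) == length(residues), all(positions > 0),
            !is.unsorted(positions, strictly = TRUE))
  structure(data.frame(ref_id = reference_id, pos = as.integer(positions),
                       expected_aa = toupper(residues),
                       stringsAsFactors = FALSE),
            class = c("active_site_panel", "data.frame"))
}

#' @rdname active_site_panel
#' @param path TSV file with columns `ref_id`, `pos`, `expected_aa`.
#' @export
read_panel <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  active_site_panel(df$ref_id[1L], df$pos, df$expected_aa)
}

#' Conservation report for active-site positions
#'
#' Resolves each panel position through the reference row to an alignment
#' column and scores its conservation within the requested row subset.
#' Errors if the reference residue at a panel position does not match the
#' panel's expectation (guards against numbering drift).
#'
#' @param aln named character vector of gapped rows.
#' @param panel an [active_site_panel()].
#' @param ids row subset to score (default: all rows).
#' @param threshold conservation threshold (default 0.90, inclusive).
#' @param strict_gt use a strictly-greater test.
#' @return data.frame `pos`, `expected_aa`, `column`, `majority`,
#'   `score`, `conserved`.
#' @export
map_active_sites <- function(aln, panel, ids = names(aln), threshold = 0.90,
                             strict_gt = FALSE) {
  ref <- unique(panel$ref_id)
  if (!ref %in% names(aln)) stop("panel reference not in alignment")
  rm_ <- reference_map(aln, ref)
  idx <- match(panel$pos, rm_$ref_pos)
  if (anyNA(idx)) stop("panel position beyond reference length")
  mismatch <- rm_$ref_residue[idx] != panel$expected_aa
  if (any(mismatch))
    stop("panel/reference disagreement at position(s): ",
         paste(panel$pos[mismatch], collapse = ", "))
  cons <- column_conservation(aln, rows = ids, threshold = threshold,
                              strict_gt = strict_gt)
  cols <- rm_$column[idx]
  data.frame(pos = panel$pos, expected_aa = panel$expected_aa,
             column = cols, majority = cons$majority[cols],
             score = cons$score[cols], conserved = cons$flagged[cols],
             stringsAsFactors = FALSE)
}

#' Import an existing multiple alignment
#'
#' Reads aligned FASTA or Clustal (`.aln`) files into the package's
#' alignment representation (named character vector of gapped rows).
#'
#' @param path file path.
#' @param format `"fasta"` or `"clustal"`; guessed from the extension by
#'   default.
#' @return named character vector of equal-length gapped rows.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("aln", "clustal", "clw")) "clustal" else "fasta"
  }
  if (format == "fasta") {
    msa <- Biostrings::readAAStringSet(path)
    out <- as.character(msa)
    names(out) <- sub("\\s.*$", "", names(out))
  } else {
    lines <- readLines(path)
    if (!grepl("^CLUSTAL", lines[1L])) stop("not a Clustal file")
    lines <- lines[-1L]
    out <- character(0)
    for (l in lines) {
      if (!nzchar(trimws(l))) next
      if (grepl("^\\s", l)) next                    # conservation line
      parts <- strsplit(trimws(l), "\\s+")[[1L]]
      if (length(parts) < 2L) next
      id <- parts[1L]
      seg <- paste(parts[-1L][!grepl("^[0-9]+$", parts[-1L])], collapse = "")
      out[id] <- paste0(if (is.na(out[id])) "" else out[id], seg)
    }
  }
  lens <- unique(nchar(out))
  if (length(lens) != 1L) stop("alignment rows must have equal length")
  out
}

#' Write an alignment as aligned FASTA
#' @param aln named character vector of gapped rows.
#' @param path file path.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(aln)) {
    writeLines(paste0(">", id), con)
    s <- aln[[id]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Conservation TSV report
#' @param aln alignment rows.
#' @param reference_id reference row for position numbering (optional).
#' @param path file path.
#' @inheritParams column_conservation
#' @export
write_conservation_table <- function(aln, path, reference_id = NULL,
                                     threshold = 0.90, strict_gt = FALSE) {
  cons <- column_conservation(aln, threshold = threshold, strict_gt = strict_gt)
  if (!is.null(reference_id)) {
    rm_ <- reference_map(aln, reference_id)
    cons$ref_pos <- rm_$ref_pos[match(cons$column, rm_$column)]
  } else {
    cons$ref_pos <- NA_integer_
  }
  out <- cons[c("column", "ref_pos", "score", "flagged", "majority")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
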