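#' Local alignment of two protein sequences
#'
#' Exact affine-gap Smith-Waterman.  After the optimal local alignment is
#' reported, its aligned spans are masked in both sequences (masked residues
#' score minus infinity and cannot be traversed), and the search is repeated,
#' so successive hits occupy disjoint spans in both coordinate systems.  This
#' is the in-package stand-in for a BLASTP search; externally produced BLAST
#' tabular hits can be injected instead via [read_blast_tab()].
#'
#' @param seq_a,seq_b protein sequences (single strings; standard 20-letter
#'   alphabet, `X` tolerated and scoring 0 against everything).
#' @param scoring a [scoring_scheme()].
#' @param max_hits maximum number of hits to report.
#' @param min_score report only hits with raw score at least this value
#'   (always strictly positive).
#' @return data.frame with columns `q_start`, `q_end`, `s_start`, `s_end`
#'   (1-based inclusive), `raw_score`, `identities`, `aligned_columns`,
#'   `bitscore`, `evalue`, sorted by decreasing raw score.
#' @export
#' @examples
#' sc <- scoring_scheme(blosum50(), gap_open = 10, gap_extend = 1)
#' local_align("PAWHEAE", "HEAGAWGHEE", sc)
local_align <- function(seq_a, seq_b, scoring = scoring_scheme(),
                        max_hits = 25L, min_score = 1) {
  a <- aa_encode(seq_a)
  b <- aa_encode(seq_b)
  res <- .cpp_sw_hits(a, b, scoring$matrix, scoring$gap_open,
                      scoring$gap_extend, as.integer(max_hits),
                      max(1, min_score))
  hits <- as.data.frame(res)
  if (nrow(hits)) {
    ka <- evalue_of_vec(hits$raw_score, length(a), length(b), scoring)
    hits$bitscore <- ka$bitscore
    hits$evalue <- ka$evalue
  } else {
    hits$bitscore <- numeric(0)
    hits$evalue <- numeric(0)
  }
  hits[c("q_start", "q_end", "s_start", "s_end", "raw_score",
         "identities", "aligned_columns", "bitscore", "evalue")]
}

evalue_of_vec <- function(raw, m, n, scoring) {
  bitscore <- (scoring$lambda * raw - log(scoring$K)) / log(2)
  list(bitscore = bitscore, evalue = m * n * 2^(-bitscore))
}

#' All-against-all local alignment
#'
#' Runs [local_align()] for every ordered pair of sequences (self-pairs
#' included; they are removed later by the homology filter) and keeps hits
#' with E-value at or below `evalue_cutoff`.
#'
#' @param sequences named character vector or `AAStringSet` of at least two
#'   protein sequences with unique identifiers.
#' @param scoring a [scoring_scheme()].
#' @param evalue_cutoff E-value threshold (default 1e-10).
#' @param max_hits per-pair hit cap.
#' @return hit table data.frame with `query_id`, `subject_id` and the
#'   [local_align()] columns.
#' @export
all_vs_all <- function(sequences, scoring = scoring_scheme(),
                       evalue_cutoff = 1e-10, max_hits = 25L) {
  seqs <- as_protein_set(sequences)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  ids <- names(seqs)
  out <- vector("list", length(ids)^2)
  k <- 0L
  for (qi in ids) {
    for (si in ids) {
      m <- nchar(seqs[[qi]]); n <- nchar(seqs[[si]])
      min_raw <- min_raw_for_evalue(evalue_cutoff, m, n, scoring)
      hits <- local_align(seqs[[qi]], seqs[[si]], scoring,
                          max_hits = max_hits, min_score = min_raw)
      hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
      if (nrow(hits)) {
        k <- k + 1L
        out[[k]] <- cbind(query_id = qi, subject_id = si, hits,
                          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(empty_hit_table())
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

empty_hit_table <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             raw_score = numeric(0), identities = integer(0),
             aligned_columns = integer(0), bitscore = numeric(0),
             evalue = numeric(0), stringsAsFactors = FALSE)
}

hit_table_columns <- c("query_id", "subject_id", "q_start", "q_end",
                       "s_start", "s_end", "raw_score", "identities",
                       "aligned_columns", "bitscore", "evalue")

#' Hit-table TSV input/output
#'
#' Tab-separated hit tables with a header row and 1-based inclusive
#' coordinates, matching the columns produced by [all_vs_all()].
#'
#' @param hits hit table data.frame.
#' @param path file path.
#' @return `read_hit_table()` returns the hit table data.frame.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(all(hit_table_columns %in% names(hits)))
  write.table(hits[hit_table_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(hit_table_columns %in% names(df)))
  df[hit_table_columns]
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Adapter for the standard 12-column BLAST tabular dialect
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), converting it to the package's hit-table layout.
#' `identities` is reconstructed from `pident` and the alignment length;
#' `raw_score` is back-computed from the bitscore with the scheme's
#' Karlin-Altschul constants.
#'
#' @param path path to a BLAST outfmt-6 file.
#' @param scoring a [scoring_scheme()] (for the bitscore-to-raw transform).
#' @return hit table data.frame as from [all_vs_all()].
#' @export
read_blast_tab <- function(path, scoring = scoring_scheme()) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stop("expected 12 tab-separated columns (BLAST outfmt 6)")
  names(df)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")
  data.frame(query_id = df$qseqid, subject_id = df$sseqid,
             q_start = as.integer(df$qstart), q_end = as.integer(df$qend),
             s_start = as.integer(df$sstart), s_end = as.integer(df$send),
             raw_score = (df$bitscore * log(2) + log(scoring$K)) / scoring$lambda,
             identities = as.integer(round(df$pident / 100 * df$length)),
             aligned_columns = as.integer(df$length),
             bitscore = df$bitscore, evalue = df$evalue,
             stringsAsFactors = FALSE)
}
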