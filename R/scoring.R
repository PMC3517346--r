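#' Scoring scheme for protein local alignment
#'
#' Bundles a residue substitution matrix, affine gap penalties, and the
#' Karlin-Altschul parameters used to convert raw alignment scores into
#' bitscores and E-values.  A gap of length L costs
#' `gap_open + (L - 1) * gap_extend`.  The default Karlin-Altschul constants
#' are the widely used gapped BLOSUM62 values (lambda = 0.267, K = 0.041).
#'
#' @param matrix 20x20 (or 21x21 including `X`) integer substitution matrix
#'   with amino-acid dimnames; default [blosum62()].
#' @param gap_open positive gap-opening penalty.
#' @param gap_extend positive gap-extension penalty, at most `gap_open`.
#' @param lambda,K positive Karlin-Altschul parameters.
#' @return an object of class `scoring_scheme`.
#' @export
#' @examples
#' sc <- scoring_scheme()
#' evalue_of(100, 100, 100, sc)
scoring_scheme <- function(matrix = blosum62(), gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  m <- expand_matrix_with_x(matrix)
  if (!isTRUE(all.equal(m, t(m), tolerance = 0)))
    stop("substitution matrix must be symmetric")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive")
  if (gap_extend > gap_open) stop("gap_extend must not exceed gap_open")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  core <- m[AA_ALPHABET, AA_ALPHABET]
  if (mean(core) >= 0)
    stop("expected substitution score under background frequencies must be negative")
  structure(list(matrix = m, gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

# accept a 20x20 matrix and append an all-zero X row/column (X is treated as
# scoring 0 against everything, including itself)
expand_matrix_with_x <- function(m) {
  if (!is.matrix(m) || is.null(dimnames(m))) stop("substitution matrix needs dimnames")
  if (!all(AA_ALPHABET %in% rownames(m)))
    stop("substitution matrix must cover the 20 standard amino acids")
  out <- base::matrix(0, 21, 21, dimnames = list(AA_WITH_X, AA_WITH_X))
  out[AA_ALPHABET, AA_ALPHABET] <- m[AA_ALPHABET, AA_ALPHABET]
  storage.mode(out) <- "integer"
  out
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("Protein scoring scheme\n")
  cat("  gap open/extend:", x$gap_open, "/", x$gap_extend, "\n")
  cat("  Karlin-Altschul lambda =", x$lambda, ", K =", x$K, "\n")
  invisible(x)
}

#' Standard substitution matrices
#'
#' The BLOSUM62 and BLOSUM50 score tables, restricted to the 20 standard
#' amino acids (sourced from the Biostrings data sets).
#' @return 20x20 integer matrix with amino-acid dimnames.
#' @export
blosum62 <- function() biostrings_matrix("BLOSUM62")

#' @rdname blosum62
#' @export
blosum50 <- function() biostrings_matrix("BLOSUM50")

biostrings_matrix <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- get(name, envir = env)
  m <- m[AA_ALPHABET, AA_ALPHABET]
  storage.mode(m) <- "integer"
  m
}

#' Read a substitution matrix from an NCBI-style text table
#'
#' Parses the plain-text layout used by NCBI BLAST matrix files: `#` comment
#' lines, a header row of residue letters, then one labelled row of integer
#' scores per residue.
#'
#' @param path file path.
#' @return integer score matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  labels <- vapply(rows, `[`, character(1L), 1L)
  vals <- t(vapply(rows, function(r) as.integer(r[-1L]), integer(length(header))))
  dimnames(vals) <- list(labels, header)
  vals
}

#' Bitscore and E-value of a raw alignment score
#'
#' Karlin-Altschul transform: `bitscore = (lambda * raw - ln K) / ln 2` and
#' `evalue = m * n * 2^(-bitscore)` for sequence lengths m and n.
#'
#' @param raw_score non-negative raw alignment score.
#' @param m,n lengths of the two sequences.
#' @param scoring a [scoring_scheme()].
#' @return list with elements `bitscore` and `evalue`.
#' @export
evalue_of <- function(raw_score, m, n, scoring = scoring_scheme()) {
  stopifnot(raw_score >= 0, m >= 1, n >= 1)
  bitscore <- (scoring$lambda * raw_score - log(scoring$K)) / log(2)
  list(bitscore = bitscore, evalue = m * n * 2^(-bitscore))
}

# smallest raw score whose E-value can still pass `cutoff` for lengths m, n;
# used to stop the masked re-search early
min_raw_for_evalue <- function(cutoff, m, n, scoring) {
  if (!is.finite(cutoff)) return(1)
  bits_needed <- log2(m * n / cutoff)
  max(1, (bits_needed * log(2) + log(scoring$K)) / scoring$lambda)
}
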