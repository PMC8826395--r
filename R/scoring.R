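#' Scoring scheme for pairwise protein alignment
#'
#' Bundles a substitution matrix, affine gap penalties, and Karlin-Altschul
#' parameters (`lambda`, `K`) used to convert raw alignment scores to bit
#' scores. The default matrix is BLOSUM62 (as shipped with Biostrings)
#' restricted to the 20 standard residues, extended with an `X` row/column
#' that scores 0 against everything. A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' The default `lambda = 0.267` nats and `K = 0.041` are the standard gapped
#' BLOSUM62 parameters (gap open 11, extend 1).
#'
#' @param matrix Square integer substitution matrix with residue dimnames, or
#'   `NULL` for the BLOSUM62 default.
#' @param gap_open,gap_extend Non-negative integer gap penalties.
#' @param lambda,K Positive Karlin-Altschul parameters.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11L, gap_extend = 1L,
                           lambda = 0.267, K = 0.041) {
  if (is.null(matrix)) matrix <- default_blosum62x()
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix) ||
      is.null(rownames(matrix)) ||
      !identical(rownames(matrix), colnames(matrix)))
    stop("substitution matrix must be square with matching dimnames")
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  core <- setdiff(rownames(matrix), "X")
  if (any(diag(matrix[core, core, drop = FALSE]) <= 0))
    stop("substitution matrix diagonal must be positive")
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

default_blosum62x <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  b <- env$BLOSUM62[AA20, AA20]
  m <- matrix(0L, 21L, 21L, dimnames = list(c(AA20, "X"), c(AA20, "X")))
  m[AA20, AA20] <- as.integer(b)
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text matrix format used by BLAST (`#` comments, a header
#' row of residue letters, one labelled row per residue).
#'
#' @param path Path to a matrix file.
#' @return Integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))])
  header <- strsplit(lines[1], "\\s+")[[1]]
  rows <- strsplit(lines[-1], "\\s+")
  labs <- vapply(rows, `[`, "", 1L)
  vals <- lapply(rows, function(r) as.integer(r[-1]))
  if (any(lengths(vals) != length(header)))
    stop("malformed matrix: row length does not match header")
  m <- do.call(rbind, vals)
  dimnames(m) <- list(labs, header)
  m
}

encode_aa <- function(seq, scheme) {
  codes <- match(strsplit(seq, "")[[1]], rownames(scheme$matrix)) - 1L
  if (anyNA(codes)) stop("sequence contains residues absent from the matrix")
  codes
}

#' Smith-Waterman local alignment score
#'
#' Optimal local alignment score under affine gap penalties. Only the score
#' is computed (no traceback); the empty alignment scores 0, so the result is
#' always non-negative and symmetric in its arguments.
#'
#' @param a,b Protein sequences (non-empty strings).
#' @param scheme A [scoring_scheme()].
#' @return Integer raw score.
#' @export
local_align_score <- function(a, b, scheme = scoring_scheme()) {
  validate_protein(a, "a"); validate_protein(b, "b")
  sw_score_cpp(encode_aa(a, scheme), encode_aa(b, scheme),
               scheme$matrix, scheme$gap_open, scheme$gap_extend)
}

#' Convert a raw alignment score to bits
#'
#' Karlin-Altschul normalization: `bits = (lambda * raw - ln K) / ln 2`,
#' strictly increasing in the raw score and comparable across matrices.
#'
#' @param raw Non-negative raw score(s).
#' @param scheme A [scoring_scheme()] supplying `lambda` and `K`.
#' @return Bit score(s).
#' @export
to_bits <- function(raw, scheme = scoring_scheme()) {
  if (any(raw < 0)) stop("raw score must be >= 0")
  (scheme$lambda * raw - log(scheme$K)) / log(2)
}

#' Bit-score density of a query against a target
#'
#' The query-target bit score divided by the query's self bit score: a
#' normalized similarity on a 0-1 scale with self-similarity exactly 1.
#' This is the atom of the accumulated-genetic-divergence (AGD) statistic.
#'
#' @param query,target Protein sequences.
#' @param scheme A [scoring_scheme()].
#' @param query_id,target_id Identifiers recorded in the result.
#' @return One-row data frame: `query_id`, `target_id`, `raw_score`, `bits`,
#'   `self_bits`, `density`.
#' @export
bitscore_density <- function(query, target, scheme = scoring_scheme(),
                             query_id = "query", target_id = "target") {
  raw <- local_align_score(query, target, scheme)
  self_raw <- local_align_score(query, query, scheme)
  bits <- to_bits(raw, scheme)
  self_bits <- to_bits(self_raw, scheme)
  if (self_bits <= 0)
    stop("degenerate query: self bit score is not positive")
  density <- if (identical(query, target)) 1 else bits / self_bits
  data.frame(query_id = query_id, target_id = target_id,
             raw_score = raw, bits = bits, self_bits = self_bits,
             density = density, stringsAsFactors = FALSE)
}

#' All-pairs bit-score table
#'
#' Computes raw score, bits and density for every ordered pair of sequences,
#' suitable for export as TSV.
#'
#' @param seqs Named character vector of protein sequences.
#' @param scheme A [scoring_scheme()].
#' @return Data frame with one row per ordered pair.
#' @export
pairwise_score_table <- function(seqs, scheme = scoring_scheme()) {
  ids <- names(seqs)
  out <- vector("list", length(ids)^2)
  n <- 0L
  for (q in ids) for (t in ids) {
    n <- n + 1L
    out[[n]] <- bitscore_density(seqs[[q]], seqs[[t]], scheme, q, t)
  }
  do.call(rbind, out)
}

#' Global percent identity (Needleman-Wunsch)
#'
#' Global alignment with affine gap penalties; returns
#' `100 * identical aligned positions / alignment length`. Protein pairs are
#' aligned under BLOSUM62, nucleotide pairs under a +5/-4 match/mismatch
#' matrix; end gaps are penalized. Defaults mirror the EMBOSS Needle gap
#' penalties (open 10, extend 0.5).
#'
#' @param a,b Sequences (both protein or both nucleotide).
#' @param gap_open,gap_extend Gap penalties.
#' @param type `"auto"` detects nucleotide sequences (A/C/G/T/N only).
#' @return Percent identity in `[0, 100]`.
#' @export
global_identity <- function(a, b, gap_open = 10, gap_extend = 0.5,
                            type = c("auto", "protein", "dna")) {
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  a <- toupper(a); b <- toupper(b)
  is_dna <- function(s) !grepl("[^ACGTN]", s)
  if (type == "auto") type <- if (is_dna(a) && is_dna(b)) "dna" else "protein"
  if (type == "dna") {
    alpha <- c("A", "C", "G", "T", "N")
    mat <- matrix(-4, 5, 5, dimnames = list(alpha, alpha))
    diag(mat) <- 5
    mat["N", ] <- 0; mat[, "N"] <- 0
  } else {
    mat <- default_blosum62x()
    alpha <- rownames(mat)
  }
  enc <- function(s) {
    codes <- match(strsplit(s, "")[[1]], alpha) - 1L
    if (anyNA(codes)) stop("sequence contains characters absent from the matrix")
    codes
  }
  res <- nw_identity_cpp(enc(a), enc(b), mat + 0.0, gap_open, gap_extend)
  100 * res[["identical"]] / res[["length"]]
}
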