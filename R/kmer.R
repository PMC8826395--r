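#' All k-mers of length k in lexicographic order
#'
#' @param k Word length.
#' @return Character vector of length `4^k`.
#' @export
kmer_names <- function(k) {
  bases <- c("A", "C", "G", "T")
  out <- bases
  if (k > 1) for (i in 2:k)
    out <- as.vector(t(outer(out, bases, paste0)))
  out
}

# Integer kmer index (0-based, lexicographic) at each start position; NA where
# the window contains a non-ACGT character.
kmer_indices <- function(bases_code, k) {
  n <- length(bases_code)
  if (n < k) return(integer(0))
  np <- n - k + 1L
  idx <- numeric(np)
  ok <- !is.na(bases_code)
  valid <- rep(TRUE, np)
  for (j in seq_len(k)) {
    v <- bases_code[j:(j + np - 1L)]
    idx <- idx * 4
    idx <- idx + ifelse(is.na(v), 0, v)
    valid <- valid & ok[j:(j + np - 1L)]
  }
  out <- as.integer(idx)
  out[!valid] <- NA_integer_
  out
}

encode_bases <- function(seq) {
  code <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T")) - 1L
  code # NA for N or anything else
}

#' Normalized k-mer spectrum of a DNA sequence
#'
#' Counts every position whose k-mer consists only of A/C/G/T (windows
#' containing N are skipped) and normalizes by the total number of counted
#' words, giving a frequency vector that sums to 1.
#'
#' @param seq DNA sequence (string over A/C/G/T/N) or a named length-1 vector.
#' @param k Word length (`k >= 1`); the genome-signature scan uses `k = 4`.
#' @return Object of class `kmer_spectrum`: `k`, `freqs` (length `4^k`,
#'   lexicographic order), `n_counted`.
#' @export
kmer_spectrum <- function(seq, k = 4L) {
  seq <- toupper(seq)
  validate_dna(seq)
  if (nchar(seq) < k) stop("sequence shorter than k")
  idx <- kmer_indices(encode_bases(seq), k)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) stop("no countable k-mers (sequence is all N?)")
  counts <- tabulate(idx + 1L, nbins = 4L^k)
  structure(list(k = as.integer(k),
                 freqs = stats::setNames(counts / sum(counts), kmer_names(k)),
                 n_counted = sum(counts)),
            class = "kmer_spectrum")
}

#' Sliding-window k-mer deviation scan of a genome
#'
#' Computes the genome-average k-mer spectrum, then a spectrum per sliding
#' window, and scores each window by the summed absolute difference (L1
#' distance) between the window and genome spectra. Compositionally
#' anomalous segments -- candidate horizontally transferred or misattributed
#' regions -- stand out as high-scoring runs of windows.
#'
#' Windows are emitted only where a full window fits (no partial tail), at
#' 0-based half-open coordinates. Windows with more than 50% N are reported
#' with `NA` score and excluded from flagging.
#'
#' @param genome DNA sequence string; a name, if present, becomes the genome
#'   id.
#' @param k Word length (default 4).
#' @param window Window size in bp (default 1000).
#' @param step Step size in bp (default 500).
#' @param norm `"l1"` (frequencies, default) or `"l2"` (unit Euclidean norm)
#'   spectrum normalization.
#' @param genome_id Identifier for outputs.
#' @return Object of class `kmer_scan`: parameters, `genome_spectrum`, and a
#'   `windows` data frame (`start`, `end`, `score`, `n_valid_kmers`).
#' @export
sliding_scan <- function(genome, k = 4L, window = 1000L, step = 500L,
                         norm = c("l1", "l2"),
                         genome_id = names(genome) %||% "genome") {
  norm <- match.arg(norm)
  genome <- toupper(unname(genome))
  validate_dna(genome)
  L <- nchar(genome)
  if (window < k) stop("window must be >= k")
  if (window > L) stop("window larger than genome")
  if (step < 1) stop("step must be >= 1")
  code <- encode_bases(genome)
  idx <- kmer_indices(code, k)
  nb <- 4L^k
  normalize <- function(counts) {
    if (norm == "l1") counts / sum(counts) else counts / sqrt(sum(counts^2))
  }
  gcounts <- tabulate(idx[!is.na(idx)] + 1L, nbins = nb)
  gfreq <- normalize(gcounts)
  genome_spectrum <- structure(
    list(k = as.integer(k), freqs = stats::setNames(gfreq, kmer_names(k)),
         n_counted = sum(gcounts)), class = "kmer_spectrum")
  starts <- seq.int(0L, L - window, by = step)
  n_count <- cumsum(is.na(code))
  scores <- numeric(length(starts))
  nvalid <- integer(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    widx <- idx[(s + 1L):(s + window - k + 1L)]
    widx <- widx[!is.na(widx)]
    nvalid[i] <- length(widx)
    n_in_win <- n_count[s + window] - if (s > 0) n_count[s] else 0L
    if (n_in_win > window / 2 || length(widx) == 0L) {
      scores[i] <- NA_real_
    } else {
      wfreq <- normalize(tabulate(widx + 1L, nbins = nb))
      scores[i] <- sum(abs(wfreq - gfreq))
    }
  }
  structure(list(genome_id = genome_id, k = as.integer(k),
                 window = as.integer(window), step = as.integer(step),
                 norm = norm, genome_spectrum = genome_spectrum,
                 windows = data.frame(start = starts, end = starts + window,
                                      score = scores,
                                      n_valid_kmers = nvalid)),
            class = "kmer_scan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag compositionally anomalous windows and merge them into intervals
#'
#' The scan itself is threshold-free; this step is an explicit extension that
#' turns per-window deviation scores into calls. The default flags windows
#' whose robust z-score, `(score - median) / MAD`, exceeds `cutoff`; if the
#' MAD is zero it falls back to the quantile method with a warning. Adjacent
#' or overlapping flagged windows are merged into intervals.
#'
#' @param scan A `kmer_scan` from [sliding_scan()].
#' @param method `"robust_z"` (default) or `"quantile"`.
#' @param cutoff Robust z cutoff (default 5).
#' @param prob Quantile for the quantile method (default 0.99; scores must
#'   strictly exceed the quantile to be flagged).
#' @return The scan with a logical `flagged` column and an `anomalies` data
#'   frame of merged intervals (`start`, `end`, `max_score`).
#' @export
flag_anomalies <- function(scan, method = c("robust_z", "quantile"),
                           cutoff = 5, prob = 0.99) {
  method <- match.arg(method)
  w <- scan$windows
  if (sum(!is.na(w$score)) < 5L) stop("need at least 5 scored windows")
  sc <- w$score
  if (method == "robust_z") {
    m <- median(sc, na.rm = TRUE)
    s <- mad(sc, na.rm = TRUE)
    if (s == 0) {
      warning("MAD of window scores is zero; falling back to quantile method")
      method <- "quantile"
    } else {
      flagged <- !is.na(sc) & (sc - m) / s > cutoff
    }
  }
  if (method == "quantile") {
    q <- quantile(sc, prob, na.rm = TRUE, names = FALSE)
    flagged <- !is.na(sc) & sc > q
  }
  w$flagged <- flagged
  scan$windows <- w
  scan$cutoff <- cutoff
  scan$method <- method
  fl <- w[which(flagged), , drop = FALSE]
  if (nrow(fl) == 0L) {
    scan$anomalies <- data.frame(start = integer(0), end = integer(0),
                                 max_score = numeric(0))
    return(scan)
  }
  fl <- fl[order(fl$start), ]
  starts <- fl$start[1]; ends <- fl$end[1]; mx <- fl$score[1]
  if (nrow(fl) > 1) for (i in 2:nrow(fl)) {
    if (fl$start[i] <= ends[length(ends)]) {
      ends[length(ends)] <- max(ends[length(ends)], fl$end[i])
      mx[length(mx)] <- max(mx[length(mx)], fl$score[i])
    } else {
      starts <- c(starts, fl$start[i]); ends <- c(ends, fl$end[i])
      mx <- c(mx, fl$score[i])
    }
  }
  scan$anomalies <- data.frame(start = starts, end = ends, max_score = mx)
  scan
}

#' @export
print.kmer_scan <- function(x, ...) {
  cat("k-mer scan of ", x$genome_id, ": k = ", x$k, ", window = ", x$window,
      ", step = ", x$step, ", ", nrow(x$windows), " windows\n", sep = "")
  if (!is.null(x$anomalies))
    cat(nrow(x$anomalies), "merged anomalous interval(s)\n")
  invisible(x)
}

#' Write per-window scan scores as TSV
#'
#' @param scan A `kmer_scan`.
#' @param path Output path.
#' @export
write_scan_tsv <- function(scan, path) {
  w <- scan$windows
  out <- data.frame(chrom = scan$genome_id, start = w$start, end = w$end,
                    score = w$score,
                    flagged = if (!is.null(w$flagged)) w$flagged else NA)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write merged anomalous intervals as BED
#'
#' BED is 0-based half-open, matching the scan's internal coordinates.
#'
#' @param scan A flagged `kmer_scan` (see [flag_anomalies()]).
#' @param path Output path.
#' @export
write_anomalies_bed <- function(scan, path) {
  if (is.null(scan$anomalies)) stop("run flag_anomalies() first")
  a <- scan$anomalies
  lines <- sprintf("%s\t%d\t%d\tanomaly_%d\t%.4f", scan$genome_id,
                   a$start, a$end, seq_len(nrow(a)), a$max_score)
  writeLines(lines, path)
  invisible(path)
}
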