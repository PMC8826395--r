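# Independent oracles used across tests. These deliberately share no code
# with the package implementation.

AA20_T <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) paste(sample(AA20_T, n, replace = TRUE),
                                    collapse = "")

random_dna <- function(n, freqs = rep(0.25, 4))
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")

# Brute-force Smith-Waterman with affine gaps: full three-state DP in plain
# R, no rolling arrays, no pruning. Gap of length L costs open + L * extend.
sw_oracle <- function(a, b, mat, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1) # gap in a (moves along j)
  F <- matrix(NEG, n + 1, m + 1) # gap in b (moves along i)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]],
                   E[i, j], F[i, j])
  }
  max(H)
}

# Naive k-mer counting via substring extraction into a dictionary.
kmer_count_oracle <- function(seq, k) {
  n <- nchar(seq)
  words <- substring(seq, 1:(n - k + 1), k:n)
  words <- words[!grepl("[^ACGT]", words)]
  counts <- table(factor(words, levels = hgtrace::kmer_names(k)))
  as.integer(counts)
}

# Window score recomputed from scratch (naive recount, L1 on frequencies).
window_score_oracle <- function(genome, start0, window, k, gfreq) {
  win <- substr(genome, start0 + 1, start0 + window)
  counts <- kmer_count_oracle(win, k)
  sum(abs(counts / sum(counts) - gfreq))
}

three_taxon_triple <- list(label = "fam", reference_id = "reference",
                           bridge_id = "bridge", distal_id = "distal")
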