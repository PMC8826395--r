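test_that("k-mer spectra match constructed cases", {
  sp <- kmer_spectrum("AAAA", 2)
  expect_equal(sp$freqs[["AA"]], 1.0)
  expect_equal(sum(sp$freqs), 1.0)
  expect_equal(sp$n_counted, 3L)
  sp1 <- kmer_spectrum("ACGT", 1)
  expect_equal(unname(sp1$freqs), rep(0.25, 4))
  # N windows are skipped
  spn <- kmer_spectrum("AANAA", 2)
  expect_equal(spn$freqs[["AA"]], 1.0)
  expect_equal(spn$n_counted, 2L)
  expect_error(kmer_spectrum("AC", 4), "shorter than k")
  expect_error(kmer_spectrum("NNNN", 2), "no countable")
})

test_that("spectrum equals a naive dictionary-count oracle on random DNA", {
  set.seed(8)
  g <- random_dna(10000)
  for (k in c(1, 2, 4)) {
    sp <- kmer_spectrum(g, k)
    counts <- kmer_count_oracle(g, k)
    expect_equal(unname(sp$freqs), counts / sum(counts), tolerance = 1e-15)
  }
})

test_that("sliding windows are placed by the documented arithmetic", {
  set.seed(9)
  g <- random_dna(10000)
  sc <- sliding_scan(g, k = 4, window = 1000, step = 500)
  expect_equal(nrow(sc$windows), 19L) # floor((10000-1000)/500)+1
  expect_equal(sc$windows$start, seq(0L, 9000L, by = 500L))
  expect_true(all(sc$windows$end - sc$windows$start == 1000L))
  expect_error(sliding_scan(random_dna(500), window = 1000), "larger")
})

test_that("window scores equal a naive recount oracle and lie in [0, 2]", {
  set.seed(10)
  for (rep in 1:50) {
    g <- random_dna(sample(2000:8000, 1),
                    freqs = as.vector(stats::runif(4, 0.1, 0.4)) |>
                      (\(x) x / sum(x))())
    sc <- sliding_scan(g, k = 3, window = 500, step = 250)
    gfreq <- unname(sc$genome_spectrum$freqs)
    i <- sample(nrow(sc$windows), 3)
    for (w in i) {
      expect_equal(sc$windows$score[w],
                   window_score_oracle(g, sc$windows$start[w], 500, 3, gfreq),
                   tolerance = 1e-12)
    }
    expect_true(all(sc$windows$score >= 0 & sc$windows$score <= 2))
  }
})

test_that("a window with the genome-average composition scores zero", {
  # perfect 4-periodic repeat; k = 1 windows of 1024 hold exactly 256 of
  # each base, matching the genome average exactly
  g <- strrep("ACGT", 512) # 2048 bp
  sc <- sliding_scan(g, k = 1, window = 1024, step = 512)
  expect_true(all(sc$windows$score < 1e-12))
})

test_that("an inserted skewed island dominates the deviation scores", {
  gs <- simulate_genome_with_island(20000, rep(0.25, 4), 3000,
                                    c(0.1, 0.4, 0.4, 0.1),
                                    position = 8000, seed = 21)
  sc <- sliding_scan(gs$genome, 4, 1000, 500)
  w <- sc$windows
  inside <- w$start >= gs$island["start"] & w$end <= gs$island["end"]
  expect_true(min(w$score[inside]) > max(w$score[!inside]))
})

test_that("anomaly flagging handles degenerate and extreme inputs", {
  g <- strrep("ACGT", 2048)
  sc <- sliding_scan(g, k = 1, window = 1024, step = 512)
  expect_warning(fl <- flag_anomalies(sc), "MAD")
  expect_equal(nrow(fl$anomalies), 0L)
  set.seed(22)
  sc2 <- sliding_scan(random_dna(20000), 4, 1000, 500)
  fl2 <- flag_anomalies(sc2, cutoff = Inf)
  expect_equal(sum(fl2$windows$flagged), 0L)
})

test_that("island recovery: merged flags cover the island", {
  hits <- vapply(1:5, function(i) {
    pos <- 20000 + 2000 * i
    gs <- simulate_genome_with_island(100000, rep(0.25, 4), 5000,
                                      c(0.1, 0.4, 0.4, 0.1),
                                      position = pos, seed = 3000 + i)
    sc <- flag_anomalies(sliding_scan(gs$genome, 4, 1000, 500), cutoff = 5)
    a <- sc$anomalies
    if (nrow(a) == 0) return(0)
    ov <- sum(pmax(0, pmin(a$end, gs$island["end"]) -
                     pmax(a$start, gs$island["start"])))
    ov / 5000
  }, 0)
  expect_gte(mean(hits >= 0.8), 0.8)
})

test_that("scan is deterministic and ignores metadata", {
  set.seed(30)
  g <- random_dna(5000)
  s1 <- sliding_scan(g, 4, 1000, 500, genome_id = "a")
  s2 <- sliding_scan(g, 4, 1000, 500, genome_id = "b")
  expect_equal(s1$windows$score, s2$windows$score)
})

test_that("windows that are mostly N are skipped, not scored", {
  set.seed(31)
  g <- paste0(random_dna(2000), strrep("N", 900), random_dna(2100))
  sc <- sliding_scan(g, 4, 1000, 500)
  n_scores <- sc$windows$score[sc$windows$start %in% c(2000)]
  expect_true(all(is.na(n_scores)))
  expect_false(anyNA(sc$windows$score[sc$windows$start < 1500]))
})

test_that("TSV and BED writers emit the scan coordinates", {
  set.seed(32)
  gs <- simulate_genome_with_island(20000, rep(0.25, 4), 4000,
                                    c(0.05, 0.45, 0.45, 0.05),
                                    position = 8000, seed = 5)
  sc <- flag_anomalies(sliding_scan(gs$genome, 4, 1000, 500))
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  write_scan_tsv(sc, tsv)
  write_anomalies_bed(sc, bed)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), nrow(sc$windows))
  bedlines <- read.delim(bed, header = FALSE)
  expect_equal(nrow(bedlines), nrow(sc$anomalies))
  expect_true(all(bedlines$V2 >= 0))
})
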