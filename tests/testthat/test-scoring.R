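test_that("local alignment score matches hand-checkable cases", {
  sch <- scoring_scheme()
  # single residue pair: the BLOSUM62 W-W diagonal
  expect_identical(local_align_score("W", "W", sch), 11L)
  # classic textbook pair against the brute-force oracle
  expect_identical(
    local_align_score("HEAGAWGHEE", "PAWHEAE", sch),
    as.integer(sw_oracle("HEAGAWGHEE", "PAWHEAE", sch$matrix, 11, 1)))
  # no positively scoring residue pair -> empty local alignment scores 0
  expect_identical(local_align_score("AAAA", "WWWW", sch), 0L)
  # symmetry
  expect_identical(local_align_score("HEAGAWGHEE", "PAWHEAE", sch),
                   local_align_score("PAWHEAE", "HEAGAWGHEE", sch))
  expect_error(local_align_score("", "W", sch), "non-empty")
})

test_that("local alignment equals the brute-force DP oracle on random pairs", {
  sch <- scoring_scheme()
  set.seed(42)
  for (i in 1:200) {
    a <- random_protein(sample(1:30, 1))
    b <- random_protein(sample(1:30, 1))
    expect_identical(local_align_score(a, b, sch),
                     as.integer(sw_oracle(a, b, sch$matrix,
                                          sch$gap_open, sch$gap_extend)),
                     info = paste(a, b))
  }
})

test_that("bit conversion follows the Karlin-Altschul form", {
  sch <- scoring_scheme()
  expect_equal(to_bits(0, sch), (0 - log(0.041)) / log(2), tolerance = 1e-12)
  expect_equal(round(to_bits(0, sch), 3), 4.608)
  # identity scaling: lambda = ln 2, K = 1 makes bits equal the raw score
  id <- scoring_scheme(lambda = log(2), K = 1)
  expect_equal(to_bits(10, id), 10.0)
  # strictly increasing in the raw score
  raws <- 0:50
  expect_true(all(diff(to_bits(raws, sch)) > 0))
  expect_error(to_bits(-1, sch), ">= 0")
})

test_that("self bit-score density is exactly 1 and densities stay in [0, 1]", {
  sch <- scoring_scheme()
  set.seed(7)
  for (len in c(1, 5, 60, 200)) {
    q <- random_protein(len)
    expect_identical(bitscore_density(q, q, sch)$density, 1)
  }
  # bounds over many random pairs (diagonally dominant BLOSUM62)
  set.seed(99)
  for (i in 1:1000) {
    q <- random_protein(sample(5:60, 1))
    t <- random_protein(sample(5:60, 1))
    d <- bitscore_density(q, t, sch)$density
    expect_true(d >= 0 && d <= 1 + 1e-9)
  }
})

test_that("unrelated long random sequences have low density", {
  sch <- scoring_scheme()
  set.seed(123)
  low <- vapply(1:100, function(i)
    bitscore_density(random_protein(300), random_protein(300), sch)$density,
    0)
  expect_gte(mean(low < 0.15), 0.95)
})

test_that("density decreases, on average, with point substitutions", {
  sch <- scoring_scheme()
  set.seed(31)
  q <- random_protein(200)
  n_subs <- rep(c(0, 10, 30, 60, 100, 150), each = 4)
  dens <- vapply(n_subs, function(k) {
    x <- strsplit(q, "")[[1]]
    sites <- sample(200, k)
    x[sites] <- sample(AA20_T, k, replace = TRUE)
    bitscore_density(q, paste(x, collapse = ""), sch)$density
  }, 0)
  ct <- suppressWarnings(cor.test(n_subs, dens, method = "spearman",
                                  alternative = "less"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("global identity matches enumerable cases and is symmetric", {
  expect_equal(global_identity("ACGT", "ACGT"), 100.0)
  # best alignment of ACGT/ACGA is gapless: 3/4 identical
  expect_equal(global_identity("ACGT", "ACGA"), 75.0)
  expect_equal(global_identity("HEAGAWGHEE", "PAWHEAE"),
               global_identity("PAWHEAE", "HEAGAWGHEE"))
  expect_equal(global_identity("MKVLA", "MKVLA"), 100.0)
  expect_error(global_identity("", "ACGT"), "non-empty")
})

test_that("global identity agrees with Biostrings on random protein pairs", {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  set.seed(55)
  for (i in 1:20) {
    a <- random_protein(sample(20:60, 1))
    b <- random_protein(sample(20:60, 1))
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = env$BLOSUM62, gapOpening = 10, gapExtension = 0.5,
      type = "global")
    # same optimal score implies an equally scoring alignment was found
    ours <- hgtrace:::nw_identity_cpp(
      match(strsplit(a, "")[[1]], rownames(env$BLOSUM62)) - 1L,
      match(strsplit(b, "")[[1]], rownames(env$BLOSUM62)) - 1L,
      env$BLOSUM62 + 0.0, 10, 0.5)
    expect_equal(unname(ours[["score"]]), Biostrings::score(aln),
                 tolerance = 1e-9, info = paste(a, b))
  }
})

test_that("NCBI matrix text parsing round-trips BLOSUM62 values", {
  sch <- scoring_scheme()
  tmp <- tempfile(fileext = ".txt")
  m <- sch$matrix
  writeLines(c("# test matrix",
               paste(c(" ", colnames(m)), collapse = " "),
               vapply(seq_len(nrow(m)), function(i)
                 paste(c(rownames(m)[i], m[i, ]), collapse = " "), "")),
             tmp)
  m2 <- read_score_matrix(tmp)
  expect_identical(unname(m2), unname(m))
  expect_identical(rownames(m2), rownames(m))
})
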