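make_seqs <- function(ref, bridge, distal)
  c(reference = ref, bridge = bridge, distal = distal)

test_that("AGD is zero when bridge and distal homologs are identical", {
  set.seed(1)
  ref <- random_protein(120)
  other <- random_protein(120)
  agd <- compute_agd(three_taxon_triple, make_seqs(ref, other, other))
  expect_equal(agd$agd, 0.0)
})

test_that("swapping bridge and distal negates the AGD", {
  set.seed(2)
  seqs <- make_seqs(random_protein(150), random_protein(150),
                    random_protein(150))
  fwd <- compute_agd(three_taxon_triple, seqs)
  swapped <- list(label = "fam", reference_id = "reference",
                  bridge_id = "distal", distal_id = "bridge")
  rev <- compute_agd(swapped, seqs)
  expect_equal(fwd$agd, -rev$agd, tolerance = 1e-12)
})

test_that("missing sequences are an input error", {
  expect_error(compute_agd(three_taxon_triple, c(reference = "MKV")),
               "not loaded")
})

test_that("externally supplied bit scores reproduce the sequence route", {
  set.seed(3)
  st <- agd_species_tree()
  fam <- simulate_family(st, scenario("vertical"), 200, seed = 10)
  direct <- compute_agd(three_taxon_triple, fam$sequences)
  sch <- scoring_scheme()
  scores <- pairwise_score_table(fam$sequences, sch)
  triples <- data.frame(label = "fam", reference_id = "reference",
                        bridge_id = "bridge", distal_id = "distal")
  via_tsv <- agd_from_scores(triples, scores)
  expect_equal(via_tsv$agd, direct$agd, tolerance = 1e-12)
})

test_that("panel summary matches frozen scipy Shapiro-Wilk values", {
  # samples generated under fixed seeds; W and p frozen from
  # scipy.stats.shapiro (an independent Royston implementation)
  x1 <- c(-0.326036, 0.552462, -0.674944, 0.214359, 0.310769, 1.173966,
          0.61879, -0.112734, 0.917028, -0.223259)
  x2 <- c(2.736431, 4.119013, 4.3272, 3.305902, 4.707945, 2.138901,
          3.446799, 1.133375, 5.626092, 5.937304, 4.72312, 7.359765)
  x3 <- c(0.931611, 0.669147, 0.219631, 0.479954, 0.299368, 0.195163,
          0.808193, 0.071874, 2.936946, 1.53395, 1.840125, 0.693044,
          0.310757, 0.65469, 1.809752)
  frozen <- list(list(W = 0.9801450365, p = 0.9659395319),
                 list(W = 0.9929377803, p = 0.9999843661),
                 list(W = 0.8517932482, p = 0.0184131301))
  for (i in 1:3) {
    pan <- panel_summary(list(x1, x2, x3)[[i]])
    expect_equal(pan$shapiro_W, frozen[[i]]$W, tolerance = 1e-6)
    expect_equal(pan$shapiro_p, frozen[[i]]$p, tolerance = 1e-6)
  }
  expect_equal(panel_summary(x1)$mean, mean(x1))
  expect_equal(panel_summary(x1)$sd, sd(x1))
})

test_that("degenerate panels are flagged and rejected for z-testing", {
  pan <- panel_summary(rep(0.5, 6))
  expect_false(pan$usable_z)
  expect_error(z_outlier_test(0.1, pan), "sd is zero")
  expect_error(panel_summary(c(1, 2)), "at least 3")
})

test_that("z-score to one-tailed p conversion is correct", {
  pan <- panel_summary(c(0.6, 0.7, 0.8, 0.65, 0.75))
  # value exactly at the mean
  at_mean <- z_outlier_test(pan$mean, pan)
  expect_equal(at_mean$z, 0)
  expect_equal(at_mean$p_one_tailed, 0.5)
  # z = -1.645 is the classic 5% lower-tail point
  v <- pan$mean - 1.645 * pan$sd
  expect_lt(abs(z_outlier_test(v, pan)$p_one_tailed - 0.05), 1e-4)
  # upper tail mirrors the lower tail
  vu <- pan$mean + 1.645 * pan$sd
  expect_lt(abs(z_outlier_test(vu, pan, tail = "upper")$p_one_tailed - 0.05),
            1e-4)
  expect_true(z_outlier_test(v, pan)$reject)
})

test_that("normal CDF is accurate against an erfc oracle across z", {
  skip_if_not_installed("pracma")
  zs <- seq(-8, 8, by = 0.25)
  oracle <- 0.5 * pracma::erfc(-zs / sqrt(2))
  pan <- panel_summary(c(-1, 0, 1, 0.5, -0.5))
  got <- vapply(zs, function(z)
    z_outlier_test(pan$mean + z * pan$sd, pan)$p_one_tailed, 0)
  expect_true(all(abs(got - oracle) < 1e-7))
})

test_that("panel membership fixture carries the three control panels", {
  pm <- panel_members()
  expect_equal(sum(pm$category == "vertical_ribosomal"), 26L)
  expect_equal(sum(pm$category == "egt_candidate"), 19L)
  expect_equal(sum(pm$category == "mito_encoded"), 10L)
})

test_that("panel mean AGD grows with the distal lineage's extra depth", {
  depths <- c(1500, 2100, 2700)
  means <- vapply(depths, function(d) {
    st <- agd_species_tree(root_age = d)
    agds <- vapply(1:8, function(i) {
      fam <- simulate_family(st, scenario("vertical"), 300,
                             seed = 1000L * d + i)
      compute_agd(three_taxon_triple, fam$sequences)$agd
    }, 0)
    mean(agds)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("HGT families fall far below the vertical panel", {
  st <- agd_species_tree()
  vertical <- vapply(1:12, function(i) {
    fam <- simulate_family(st, scenario("vertical"), 300, seed = 500 + i)
    compute_agd(three_taxon_triple, fam$sequences)$agd
  }, 0)
  pan <- panel_summary(vertical, "vertical_ribosomal")
  hits <- vapply(1:10, function(i) {
    fam <- simulate_family(
      st, scenario("hgt", donor = "distal",
                   recipient = c("reference", "bridge"), time_ma = 750),
      300, seed = 900 + i)
    agd <- compute_agd(three_taxon_triple, fam$sequences)$agd
    agd < pan$mean - 2 * pan$sd
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
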