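test_that("peptide filters use strict boundaries and conserve row counts", {
  tab <- data.frame(
    peptide_seq = sprintf("PEP%d", 1:6), protein_id = "P1",
    intensity = c(999, 1000, 5000, 5000, 5000, 5000),
    hl_ratio = c(1, 1, 0.009, 0.01, 100, 100.5),
    ts = 7, is_contaminant = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  out <- filter_peptides(tab)
  expect_setequal(out$peptides$peptide_seq, c("PEP2", "PEP4", "PEP5"))
  log <- out$removal_log
  expect_identical(sum(log$n_removed), nrow(tab))
  expect_identical(log$n_removed[log$criterion == "low_intensity"], 1L)
  expect_identical(log$n_removed[log$criterion == "ratio_out_of_range"], 2L)
  # contaminants removed before any other criterion
  tab$is_contaminant[3] <- TRUE
  out2 <- filter_peptides(tab)
  expect_identical(
    out2$removal_log$n_removed[out2$removal_log$criterion == "contaminant"],
    1L)
  expect_identical(sum(out2$removal_log$n_removed), nrow(tab))
})

test_that("half-life formula matches hand values and inverts exactly", {
  expect_equal(peptide_half_life(1, 7), 7)
  expect_equal(peptide_half_life(3, 4), 2)
  expect_equal(peptide_half_life(2^(7 / 10) - 1, 7), 10, tolerance = 1e-12)
  # round trip over a grid of half-lives for both labeling times
  t_grid <- exp(seq(log(0.5), log(100), length.out = 200))
  for (ts in c(7, 15)) {
    back <- peptide_half_life(2^(ts / t_grid) - 1, ts)
    expect_lt(max(abs(back / t_grid - 1)), 1e-12)
  }
  # strictly decreasing in R
  r <- seq(0.01, 50, length.out = 500)
  expect_true(all(diff(peptide_half_life(r, 7)) < 0))
  expect_error(peptide_half_life(0, 7), "> 0")
  expect_error(peptide_half_life(-1, 7), "> 0")
  expect_error(peptide_half_life(1, 0), "> 0")
})

test_that("protein rollup is the harmonic mean over unique peptides", {
  tab <- data.frame(peptide_seq = c("AAK", "CCK"), protein_id = "P1",
                    hl_ratio = 2^(7 / c(6, 3)) - 1, ts = 7)
  expect_equal(protein_half_life(tab)$half_life, 4, tolerance = 1e-12)
  # single peptide and all-equal peptides return that value
  one <- tab[1, ]
  expect_equal(protein_half_life(one)$half_life, 6, tolerance = 1e-12)
  eq <- data.frame(peptide_seq = c("AAK", "CCK", "DDK"), protein_id = "P1",
                   hl_ratio = 2^(7 / 5) - 1, ts = 7)
  expect_equal(protein_half_life(eq)$half_life, 5, tolerance = 1e-12)
  # duplicate sequences collapse by median before the harmonic mean
  dup <- data.frame(peptide_seq = c("AAK", "AAK", "AAK", "CCK"),
                    protein_id = "P1",
                    hl_ratio = 2^(7 / c(2, 6, 10, 3)) - 1, ts = 7)
  expect_equal(protein_half_life(dup)$half_life, 4, tolerance = 1e-12)
  expect_identical(protein_half_life(dup)$n_peptides, 2L)
})

test_that("harmonic mean never exceeds the arithmetic mean", {
  set.seed(12)
  for (i in 1:50) {
    t <- runif(sample(2:8, 1), 0.5, 40)
    tab <- data.frame(peptide_seq = sprintf("PEP%d", seq_along(t)),
                      protein_id = "P", hl_ratio = 2^(7 / t) - 1, ts = 7)
    expect_lte(protein_half_life(tab)$half_life, mean(t) + 1e-12)
  }
})

test_that("simulated half-lives are recovered exactly without noise", {
  cfg <- sim_config(seed = 8, n_proteins = 40, ratio_cv = 0,
                    frac_contaminant = 0, frac_outlier = 0)
  sim <- gen_peptide_table(cfg)
  hl <- protein_half_life(filter_peptides(sim$peptides)$peptides)
  m <- merge(hl, sim$truth, by = c("protein_id", "condition"))
  expect_equal(m$half_life, m$truth_halflife, tolerance = 1e-9)
})

test_that("differential testing applies the volcano rule", {
  set.seed(3)
  kd <- matrix(rlnorm(40, log(10), 0.05), 10,
               dimnames = list(sprintf("P%d", 1:10), NULL))
  nt <- kd
  # feature with lfc 0.9 cannot pass the abundance threshold of 1
  kd["P1", ] <- nt["P1", ] * 2^0.9
  kd["P2", ] <- nt["P2", ] * 2^1.6
  res <- differential_features(kd, nt, log2fc_threshold = 1, alpha = 0.05)
  expect_false(res$is_significant[res$feature_id == "P1"])
  expect_true(res$is_significant[res$feature_id == "P2"])
  expect_true(all(res$adj_p >= res$p))
  # identical conditions: no fold change, nothing significant
  res0 <- differential_features(nt, nt)
  expect_true(all(res0$log2fc == 0))
  expect_false(any(res0$is_significant))
  # features with < 2 replicates on a side are omitted
  kd2 <- kd
  kd2["P3", 2:4] <- NA
  res2 <- differential_features(kd2, nt)
  expect_identical(attr(res2, "omitted"), "P3")
})

test_that("planted 2-fold half-life increases are recovered with power", {
  set.seed(21)
  hits <- 0
  for (i in 1:30) {
    nt <- matrix(rlnorm(4, log(10), 0.05), 1,
                 dimnames = list("P1", NULL))
    kd <- matrix(rlnorm(4, log(20), 0.05), 1,
                 dimnames = list("P1", NULL))
    res <- differential_features(kd, nt, log2fc_threshold = 0.5,
                                 alpha = 0.05)
    hits <- hits + res$is_significant[1]
  }
  expect_gte(hits / 30, 0.9)
})

test_that("density shift summarizes the paired half-life distribution", {
  hl <- data.frame(protein_id = rep(sprintf("P%02d", 1:30), 2),
                   condition = rep(c("NT", "KD"), each = 30),
                   half_life = c(1:30, 2 * (1:30)), n_peptides = 1L)
  s <- density_shift_summary(hl)
  expect_identical(s$n_shared, 30L)
  expect_equal(s$median_log2_ratio, 1)
  expect_lt(s$p_value, 0.01)
  hl2 <- hl
  hl2$half_life <- rep(1:30, 2)
  s2 <- density_shift_summary(hl2)
  expect_equal(s2$median_log2_ratio, 0)
  expect_equal(s2$p_value, 1)
  expect_warning(density_shift_summary(hl[c(1:5, 31:35), ]), "shared")
})
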