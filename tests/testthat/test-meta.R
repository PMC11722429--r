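test_that("p truncation clamps the tails and is monotone", {
  expect_identical(truncate_p(0), 1e-300)
  expect_identical(truncate_p(0.5), 0.5)
  expect_identical(truncate_p(1), 1 - 1e-16)
  expect_error(truncate_p(-0.1), "\\[0, 1\\]")
  expect_error(truncate_p(1.1), "\\[0, 1\\]")
  p <- sort(runif(100))
  expect_true(all(diff(truncate_p(p)) >= 0))
})

test_that("harmonization standardizes effects and derives SE = |beta|/|z|", {
  set.seed(1)
  n <- 200
  tab <- data.frame(gene_id = sprintf("g%03d", 1:n),
                    effect = rnorm(n, 3, 2), p_raw = runif(n))
  h <- harmonize_screen(tab)
  expect_equal(mean(h$beta), 0, tolerance = 1e-12)
  expect_equal(sd(h$beta), 1, tolerance = 1e-12)
  expect_true(all(sign(h$z) == sign(h$beta) | h$beta == 0))
  expect_true(all(h$se > 0 & is.finite(h$se)))
  expect_equal(h$se, abs(h$beta) / abs(h$z), tolerance = 1e-12)
  # a gene with standardized beta at the 0.05 two-sided quantile has se ~ 1
  tab2 <- tab
  tab2$effect <- scale(tab2$effect)[, 1]
  tab2$effect[1] <- stats::qnorm(0.975)
  tab2$p_raw[1] <- 0.05
  h2 <- harmonize_screen(tab2, beta_mode = "raw_effect")
  expect_equal(h2$z[1], 1.959964, tolerance = 1e-6)
  expect_equal(h2$se[1], 1, tolerance = 1e-6)
  # idempotence: an already standardized effect column is returned as-is
  tab3 <- tab
  tab3$effect <- (tab$effect - mean(tab$effect)) / sd(tab$effect)
  expect_equal(harmonize_screen(tab3)$beta, tab3$effect, tolerance = 1e-12)
})

test_that("harmonization guards degenerate inputs", {
  tab <- data.frame(gene_id = c("a", "b", "c"), effect = c(1, 1, 1),
                    p_raw = c(0.1, 0.2, 0.3))
  expect_error(harmonize_screen(tab), "zero spread")
  tab2 <- data.frame(gene_id = c("a", "b"), effect = c(1, 2),
                     p_raw = c(0.1, 0.2))
  expect_error(harmonize_screen(tab2), "at least 3")
  # p_raw = 0 is truncated, giving a finite z and se
  tab3 <- data.frame(gene_id = c("a", "b", "c", "d"),
                     effect = c(-2, 0.1, 1, 4), p_raw = c(0, 0.5, 0.9, 1))
  h3 <- harmonize_screen(tab3)
  expect_true(all(is.finite(h3$z) & is.finite(h3$se)))
  # beta exactly zero is flagged and gets the epsilon SE
  tab4 <- data.frame(gene_id = c("a", "b", "c"),
                     effect = c(-1, 0, 1), p_raw = c(0.2, 0.9, 0.2))
  h4 <- harmonize_screen(tab4, beta_mode = "raw_effect")
  expect_true(h4$zero_beta[2])
  expect_equal(h4$se[2], 1e-8 / stats::qnorm(1 - 0.9 / 2), tolerance = 1e-12)
})

test_that("fixed-effect pooling matches the closed forms", {
  r <- fixed_effect_pool(c(1, 1), c(1, 1))
  expect_equal(r$beta_pooled, 1)
  expect_equal(r$se_pooled, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(r$q_stat, 0)
  expect_equal(r$i2, 0)
  r2 <- fixed_effect_pool(c(2, 0), c(1, 1))
  expect_equal(r2$beta_pooled, 1)
  expect_equal(r2$q_stat, 2)
  expect_identical(r2$q_df, 1L)
  k <- 5
  r3 <- fixed_effect_pool(rep(0.7, k), rep(0.3, k))
  expect_equal(r3$beta_pooled, 0.7, tolerance = 1e-12)
  expect_equal(r3$se_pooled, 0.3 / sqrt(k), tolerance = 1e-12)
  expect_error(fixed_effect_pool(1, 1), "k >= 2")
  expect_error(fixed_effect_pool(c(1, 2), c(1, 0)), "> 0")
})

test_that("pooling equals a weighted-least-squares intercept oracle", {
  set.seed(42)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    beta <- rnorm(k, 0, 2)
    se <- runif(k, 0.2, 3)
    r <- fixed_effect_pool(beta, se)
    fit <- stats::lm(beta ~ 1, weights = 1 / se^2)
    expect_equal(r$beta_pooled, unname(coef(fit)[1]), tolerance = 1e-10)
    # pooled SE never exceeds the best constituent SE
    expect_lte(r$se_pooled, min(se))
    # and matches metafor's fixed-effect model when available
    if (requireNamespace("metafor", quietly = TRUE)) {
      m <- metafor::rma(yi = beta, sei = se, method = "FE")
      expect_equal(r$beta_pooled, as.numeric(m$beta), tolerance = 1e-10)
      expect_equal(r$se_pooled, as.numeric(m$se), tolerance = 1e-10)
      expect_equal(r$q_stat, as.numeric(m$QE), tolerance = 1e-8)
    }
  }
})

test_that("pooled SE decreases monotonically as screens are added", {
  se_seq <- vapply(2:8, function(k) {
    fixed_effect_pool(rep(1, k), rep(1, k))$se_pooled
  }, numeric(1))
  expect_true(all(diff(se_seq) < 0))
})

test_that("run_meta enumerates combinations and adjusts within each", {
  sim <- gen_screen_tables(sim_config(seed = 5, n_genes = 300,
                                      n_screens = 3))
  harm <- lapply(sim$screens, harmonize_screen)
  res <- run_meta(harm)
  expect_setequal(names(res), c("S1+S2", "S1+S3", "S2+S3", "S1+S2+S3"))
  expect_true(all(res[["S1+S2+S3"]]$fdr_meta >= res[["S1+S2+S3"]]$p_meta))
  # a gene absent from one member drops out of that combination only
  harm2 <- harm
  harm2$S2 <- harm2$S2[harm2$S2$gene_id != "G00001", ]
  res2 <- run_meta(harm2)
  expect_false("G00001" %in% res2[["S1+S2"]]$gene_id)
  expect_true("G00001" %in% res2[["S1+S3"]]$gene_id)
  # explicit combinations
  res3 <- run_meta(harm, combinations = list(c("S1", "S3")))
  expect_identical(names(res3), "S1+S3")
  # BH step-up frozen example: {0.01, 0.02, 0.03, 0.04} -> all 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
})

test_that("novelty requires meta significance without constituent significance", {
  expect_true(assess_novelty(0.01, matrix(c(0.2, 0.3), 1), alpha = 0.05))
  expect_false(assess_novelty(0.01, matrix(c(0.2, 0.01), 1), alpha = 0.05))
  expect_false(assess_novelty(0.2, matrix(c(0.2, 0.3), 1), alpha = 0.05))
  # vectorized flags equal a literal transcription of the rule
  set.seed(9)
  n <- 50
  fm <- runif(n, 0, 0.2)
  sf <- matrix(runif(n * 3, 0, 0.2), n, 3)
  got <- assess_novelty(fm, sf, alpha = 0.05)
  brute <- vapply(seq_len(n), function(i) {
    all_ns <- TRUE
    for (j in 1:3) if (sf[i, j] < 0.05) all_ns <- FALSE
    all_ns && fm[i] < 0.05
  }, logical(1))
  expect_identical(got, brute)
})

test_that("hit classification is directional with inclusive boundaries", {
  expect_identical(classify_hits(1.5, TRUE, 0, 1), "up")
  expect_identical(classify_hits(0.5, TRUE, 0, 1), "none")
  expect_identical(classify_hits(-1.0, TRUE, 0, 1), "down")
  expect_identical(classify_hits(1.0, TRUE, 0, 1), "up")
  expect_identical(classify_hits(5, FALSE, 0, 1), "none")
  expect_identical(classify_hits(c(2, -3), c(TRUE, TRUE), 1, 1),
                   c("up", "down"))
  expect_error(classify_hits(1, TRUE, NaN, 1), "finite")
})
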