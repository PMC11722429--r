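make_lib <- function(n_genes = 6, n_nt = 2, seed = 1) {
  sim_guide_library(n_genes = n_genes, n_nt = n_nt, seed = seed)
}

test_that("read-pair matching distinguishes matched, recombined, unmapped", {
  lib <- make_lib()
  r1 <- paste0("ACGT", lib$guide_a_seq[1], "TTAACC")
  r2 <- paste0("ACGT", lib$guide_b_seq[1], "GGTTAA")
  m <- match_read_pair(r1, r2, lib)
  expect_identical(m$outcome, "matched")
  expect_identical(m$construct_id, lib$construct_id[1])
  # guide-A from C1, guide-B from C2 -> recombined
  r2x <- paste0("ACGT", lib$guide_b_seq[2], "GGTTAA")
  expect_identical(match_read_pair(r1, r2x, lib)$outcome, "recombined")
  # no library guide, or empty read -> unmapped, not an exception
  expect_identical(match_read_pair(strrep("A", 30), r2, lib)$outcome,
                   "unmapped")
  expect_identical(match_read_pair("", "", lib)$outcome, "unmapped")
})

test_that("matching agrees with a brute-force grepl scan on random pairs", {
  lib <- make_lib(n_genes = 15, n_nt = 3, seed = 7)
  set.seed(7)
  n <- 1000
  # mixture: true pairs, recombined pairs, junk reads
  ci <- sample.int(nrow(lib), n, replace = TRUE)
  bi <- ifelse(runif(n) < 0.3, sample.int(nrow(lib), n, replace = TRUE), ci)
  junk <- runif(n) < 0.1
  rand_flank <- function(k) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = ""),
    character(1))
  r1 <- paste0(rand_flank(4), lib$guide_a_seq[ci], rand_flank(5))
  r2 <- paste0(rand_flank(4), lib$guide_b_seq[bi], rand_flank(5))
  r1[junk] <- vapply(which(junk), function(i)
    paste(sample(c("A", "C", "G", "T"), 29, TRUE), collapse = ""),
    character(1))
  got <- match_read_pairs(r1, r2, lib)
  brute <- vapply(seq_len(n), function(i) {
    a <- which(vapply(lib$guide_a_seq, grepl, logical(1), x = r1[i],
                      fixed = TRUE))
    b <- which(vapply(lib$guide_b_seq, grepl, logical(1), x = r2[i],
                      fixed = TRUE))
    if (length(a) == 1 && length(b) == 1) {
      if (a == b) "matched" else "recombined"
    } else "unmapped"
  }, character(1))
  expect_identical(got$outcome, unname(brute))
})

test_that("counting conserves totals and recovers truth at zero recombination", {
  lib <- make_lib(n_genes = 20, n_nt = 4, seed = 3)
  cfg0 <- sim_config(seed = 13, n_reads = 3000, recombination_rate = 0)
  rd_lo <- gen_dual_guide_reads(cfg0, lib, stage = "low")
  rd_hi <- gen_dual_guide_reads(cfg0, lib, stage = "high")
  res <- count_constructs(rd_lo, rd_hi, lib)
  expect_identical(res$counts$count_low, rd_lo$truth$counts$truth_count)
  expect_identical(res$counts$count_high, rd_hi$truth$counts$truth_count)
  expect_true(all(res$stats$n_pairs_total ==
                    res$stats$n_matched + res$stats$n_recombined +
                    res$stats$n_unmapped))
  expect_identical(sum(res$stats$n_recombined), 0L)
})

test_that("counting handles FASTQ round-trips and empty streams", {
  lib <- make_lib(seed = 5)
  cfg <- sim_config(seed = 17, n_reads = 200, recombination_rate = 0.2)
  rd <- gen_dual_guide_reads(cfg, lib)
  tmp <- withr::local_tempdir()
  paths <- write_read_pairs(rd, file.path(tmp, "bin"))
  res_file <- count_constructs(paths, paths, lib)
  res_mem <- count_constructs(rd, rd, lib)
  expect_identical(res_file$counts, res_mem$counts)
  empty <- list(read1 = character(0), read2 = character(0))
  res0 <- count_constructs(empty, empty, lib)
  expect_true(all(res0$counts$count_low == 0L))
  expect_true(all(res0$stats$n_pairs_total == 0L))
  expect_error(count_constructs(list(read1 = "A", read2 = character(0)),
                                empty, lib), "differ in length")
})

test_that("low-count filtering keeps constructs at or above the threshold", {
  tab <- data.frame(construct_id = c("C1", "C2", "C3"),
                    count_low = c(2, 5, 30), count_high = c(3, 5, 20))
  expect_identical(filter_low_count(tab, 0), tab)
  expect_identical(filter_low_count(tab, 10)$construct_id, c("C2", "C3"))
  expect_warning(out <- filter_low_count(tab, 1000), "below min_total")
  expect_identical(nrow(out), 0L)
})

test_that("permutation scorer: zero effect, planted depletion, null validity", {
  lib <- sim_guide_library(n_genes = 40, n_nt = 10, seed = 9)
  # equal bins -> effect exactly 0
  tab <- data.frame(construct_id = lib$construct_id,
                    count_low = 100L, count_high = 100L)
  sc <- score_genes_permutation(tab, lib, n_perm = 200, seed = 1)
  expect_true(all(sc$effect == 0))
  expect_identical(nrow(sc), 40L)
  # planted strong depletion of one gene, genome-scale null pool
  lib2 <- sim_guide_library(n_genes = 200, n_nt = 20, seed = 10)
  tab2 <- data.frame(construct_id = lib2$construct_id,
                     count_low = 100L, count_high = 100L)
  tab2$count_high[lib2$target_gene == "G00001"] <- 5L
  sc2 <- score_genes_permutation(tab2, lib2, n_perm = 5000, seed = 1)
  hit <- sc2[sc2$gene_id == "G00001", ]
  expect_lt(hit$effect, -2)
  expect_lt(hit$p_raw, 0.01)
  # permutation p-values carry the +1 validity correction
  expect_true(all(sc2$p_raw >= 1 / 5001))
  # NT pseudo-genes drawn from a null table give non-extreme p-values
  null_lib <- lib
  null_lib$target_gene <- rep(sprintf("PSEUDO%02d", 1:10), 5)
  null_lib$is_nt <- FALSE
  set.seed(4)
  tab3 <- data.frame(construct_id = lib$construct_id,
                     count_low = rpois(50, 100),
                     count_high = rpois(50, 100))
  sc3 <- score_genes_permutation(tab3, null_lib, n_perm = 500, seed = 2)
  expect_gt(min(sc3$p_raw), 1 / 501 - 1e-12)
  expect_gt(mean(sc3$p_raw), 0.2)
})

test_that("genes lost to filtering are omitted with a warning", {
  lib <- make_lib(n_genes = 3, n_nt = 1, seed = 2)
  tab <- data.frame(construct_id = lib$construct_id[-1],
                    count_low = c(50L, 60L, 70L),
                    count_high = c(55L, 65L, 75L))
  expect_warning(sc <- score_genes_permutation(tab, lib, n_perm = 100,
                                               seed = 1),
                 "omitted")
  expect_false("G00001" %in% sc$gene_id)
})
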