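#' Filter a peptide quantification table before half-life computation
#'
#' Applies, in order: removal of contaminant-flagged peptides, removal of
#' peptides with intensity below `min_intensity`, removal of peptides with
#' missing heavy/light ratio, and removal of ratios strictly below
#' `ratio_low` or strictly above `ratio_high` (outlier half-life guards).
#' All boundary comparisons are strict, mirroring "below" / "lower than" /
#' "higher than": an intensity of exactly `min_intensity` or a ratio of
#' exactly `ratio_low` is retained.
#'
#' @param table Peptide table with columns `peptide_seq`, `protein_id`,
#'   `intensity`, `hl_ratio`, `ts` and optionally `is_contaminant`,
#'   `condition`, `replicate`.
#' @param min_intensity Intensity floor (default 1000).
#' @param ratio_low,ratio_high Retention window for heavy/light ratios
#'   (defaults 0.01 and 100).
#' @return A list with `peptides` (the retained rows) and `removal_log`
#'   (data frame `criterion`, `n_removed`, ending with a `kept` row);
#'   removed plus kept always equals the input row count.
#' @examples
#' tab <- data.frame(peptide_seq = c("AAK", "CCK"), protein_id = "P1",
#'                   intensity = c(999, 2000), hl_ratio = c(1, 0.009),
#'                   ts = 7, is_contaminant = FALSE)
#' filter_peptides(tab)$removal_log
#' @export
filter_peptides <- function(table, min_intensity = 1000, ratio_low = 0.01,
                            ratio_high = 100) {
  n0 <- nrow(table)
  log <- list()
  if (!is.null(table$is_contaminant)) {
    drop <- table$is_contaminant %in% TRUE
    log$contaminant <- sum(drop)
    table <- table[!drop, , drop = FALSE]
  } else log$contaminant <- 0L
  drop <- table$intensity < min_intensity
  log$low_intensity <- sum(drop)
  table <- table[!drop, , drop = FALSE]
  drop <- is.na(table$hl_ratio)
  log$missing_ratio <- sum(drop)
  table <- table[!drop, , drop = FALSE]
  drop <- table$hl_ratio < ratio_low | table$hl_ratio > ratio_high
  log$ratio_out_of_range <- sum(drop)
  table <- table[!drop, , drop = FALSE]
  rownames(table) <- NULL
  removal_log <- data.frame(
    criterion = c(names(log), "kept"),
    n_removed = c(unlist(log, use.names = FALSE), NA),
    stringsAsFactors = FALSE)
  removal_log$n_removed[removal_log$criterion == "kept"] <- nrow(table)
  stopifnot(sum(removal_log$n_removed) == n0)
  list(peptides = table, removal_log = removal_log)
}

#' Single-timepoint peptide half-life
#'
#' Under steady-state turnover with a media switch at time 0, the fraction
#' of heavy (new) protein after labeling time ts gives the half-life
#' `t_half = ts * ln(2) / ln(1 + R)`, where R is the heavy/light intensity
#' ratio.  The function is strictly decreasing in R and is the exact
#' inverse of `R = 2^(ts / t_half) - 1`.
#'
#' @param R Heavy/light ratio(s), must be > 0.
#' @param ts Labeling time in days, must be > 0.
#' @return Half-life in days.
#' @examples
#' peptide_half_life(1, 7)   # 7 days
#' peptide_half_life(3, 4)   # 2 days
#' @export
peptide_half_life <- function(R, ts) {
  if (any(!is.finite(R)) || any(R <= 0))
    stop("heavy/light ratio must be finite and > 0")
  if (any(ts <= 0)) stop("labeling time must be > 0")
  ts * log(2) / log(1 + R)
}

#' Protein half-life as the harmonic mean of its unique peptides
#'
#' Peptide half-lives are computed with [peptide_half_life()]; duplicate
#' observations of the same peptide sequence (charge states, replicates)
#' are collapsed to their median half-life, and the protein half-life is
#' the harmonic mean over unique peptide sequences,
#' `n / sum(1 / t_i)`.
#'
#' @param peptides A filtered peptide table with columns `peptide_seq`,
#'   `protein_id`, `hl_ratio`, `ts` and optionally `condition` (default
#'   condition `"all"`) and `replicate`.
#' @param by_replicate If `TRUE`, roll up within each replicate separately
#'   instead of pooling a condition's peptides.
#' @return A data frame `protein_id`, `condition` (and `replicate` if
#'   requested), `half_life` (days), `n_peptides` (unique contributing
#'   peptide sequences).
#' @examples
#' tab <- data.frame(peptide_seq = c("AAK", "CCK"), protein_id = "P1",
#'                   hl_ratio = 2^(7 / c(6, 3)) - 1, ts = 7)
#' protein_half_life(tab)$half_life  # harmonic mean of 6 and 3 = 4
#' @export
protein_half_life <- function(peptides, by_replicate = FALSE) {
  if (nrow(peptides) == 0L) stop("no peptides to roll up")
  t_pep <- peptide_half_life(peptides$hl_ratio, peptides$ts)
  cond <- if (is.null(peptides$condition)) "all" else peptides$condition
  keys <- if (by_replicate) {
    if (is.null(peptides$replicate))
      stop("by_replicate = TRUE requires a `replicate` column")
    list(protein_id = peptides$protein_id, condition = cond,
         replicate = peptides$replicate)
  } else {
    list(protein_id = peptides$protein_id, condition = cond)
  }
  df <- data.frame(keys, peptide_seq = peptides$peptide_seq, t = t_pep,
                   stringsAsFactors = FALSE)
  # collapse duplicate sequences within each rollup group by median, then
  # take the harmonic mean over unique sequences
  key_cols <- names(keys)
  pep_key <- do.call(paste, c(df[c(key_cols, "peptide_seq")], sep = "\r"))
  t_u <- tapply(df$t, pep_key, median)
  uniq <- df[!duplicated(pep_key), c(key_cols, "peptide_seq"), drop = FALSE]
  uniq$t <- as.numeric(t_u[pep_key[!duplicated(pep_key)]])
  prot_key <- do.call(paste, c(uniq[key_cols], sep = "\r"))
  hl <- tapply(uniq$t, prot_key, function(t) length(t) / sum(1 / t))
  np <- tapply(uniq$t, prot_key, length)
  first <- uniq[!duplicated(prot_key), key_cols, drop = FALSE]
  ord <- match(names(hl), prot_key[!duplicated(prot_key)])
  out <- data.frame(first[ord, , drop = FALSE],
                    half_life = as.numeric(hl),
                    n_peptides = as.integer(np), stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(out$protein_id), , drop = FALSE]
}

#' Differential testing of positive-valued features between conditions
#'
#' Computes `log2fc = log2(mean(KD) / mean(NT))` per feature, a two-sided
#' Welch t-test on the log2-transformed replicate values, BH adjustment
#' across tested features, and the volcano significance rule
#' `|log2fc| >= log2fc_threshold AND adj_p < alpha`.  Used for protein
#' half-lives (default thresholds 0.5 / 0.05), protein abundances and
#' phosphosites (1 / 0.05).
#'
#' @param kd,nt Numeric matrices (features x replicates) of positive
#'   values, with matching rownames.  Features with fewer than 2 finite
#'   replicates in either condition are omitted.
#' @param log2fc_threshold Absolute log2 fold-change threshold.
#' @param alpha Adjusted-p threshold.
#' @return A data frame `feature_id`, `log2fc`, `p`, `adj_p`,
#'   `is_significant`, plus an `"omitted"` attribute listing untested
#'   features.
#' @export
differential_features <- function(kd, nt, log2fc_threshold = 0.5,
                                  alpha = 0.05) {
  kd <- as.matrix(kd)
  nt <- as.matrix(nt)
  feats <- intersect(rownames(kd), rownames(nt))
  kd <- kd[feats, , drop = FALSE]
  nt <- nt[feats, , drop = FALSE]
  ok <- rowSums(is.finite(kd)) >= 2L & rowSums(is.finite(nt)) >= 2L
  omitted <- feats[!ok]
  kd <- kd[ok, , drop = FALSE]
  nt <- nt[ok, , drop = FALSE]
  lfc <- log2(rowMeans(kd, na.rm = TRUE) / rowMeans(nt, na.rm = TRUE))
  p <- vapply(seq_len(nrow(kd)), function(i) {
    x <- log2(kd[i, ])
    y <- log2(nt[i, ])
    x <- x[is.finite(x)]
    y <- y[is.finite(y)]
    if (sd(c(x, y)) == 0) return(1)
    tryCatch(t.test(x, y)$p.value, error = function(e) 1)
  }, numeric(1))
  adj <- p.adjust(p, method = "BH")
  out <- data.frame(feature_id = rownames(kd), log2fc = unname(lfc),
                    p = p, adj_p = adj,
                    is_significant = abs(lfc) >= log2fc_threshold &
                      adj < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "omitted") <- omitted
  out
}

#' Paired summary of a global half-life distribution shift
#'
#' Over proteins quantified in both conditions, reports the median paired
#' `log2(t_half_KD / t_half_NT)` and a two-sided Wilcoxon signed-rank
#' p-value, the summary behind a turnover density-shift plot.
#'
#' @param half_lives A protein half-life table (see [protein_half_life()])
#'   with conditions `"KD"` and `"NT"`.
#' @return A list with `n_shared`, `median_log2_ratio` and `p_value`.
#' @export
density_shift_summary <- function(half_lives) {
  kd <- half_lives[half_lives$condition == "KD", ]
  nt <- half_lives[half_lives$condition == "NT", ]
  shared <- intersect(kd$protein_id, nt$protein_id)
  if (length(shared) < 10L)
    warning("only ", length(shared), " proteins shared between conditions")
  r <- log2(kd$half_life[match(shared, kd$protein_id)] /
              nt$half_life[match(shared, nt$protein_id)])
  p <- if (all(r == 0)) 1 else {
    suppressWarnings(wilcox.test(r, mu = 0, exact = FALSE)$p.value)
  }
  list(n_shared = length(shared), median_log2_ratio = median(r),
       p_value = p)
}
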