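#' Truncate extreme p-values
#'
#' Stabilizes p-values before conversion to z-scores: values below
#' `p_floor` are raised to it and values above `1 - p_ceiling_margin` are
#' lowered to that bound, keeping the normal quantile finite in both tails.
#' The defaults accommodate double-precision floating point and make the
#' downstream meta-analysis conservative for the most extreme genes.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param p_floor Lower truncation bound.
#' @param p_ceiling_margin Margin below 1 for the upper bound.
#' @return Truncated p-values; monotone non-decreasing in `p`.
#' @examples
#' truncate_p(c(0, 0.5, 1))
#' @export
truncate_p <- function(p, p_floor = 1e-300, p_ceiling_margin = 1e-16) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  pmin(pmax(p, p_floor), 1 - p_ceiling_margin)
}

#' Harmonize one screen's gene statistics to the common meta-analysis scale
#'
#' Screens report effects on heterogeneous native scales (log fold changes,
#' phenotype scores).  Harmonization makes them poolable: the effect column
#' is standardized across the screen's genes to a zero-mean, unit-variance
#' "beta" (`beta_mode = "zscored_effect"`, the default) or taken as-is
#' (`"raw_effect"`); the reported p-value is truncated and converted to an
#' absolute z via the normal quantile, signed by beta; and the standard
#' error is derived as `|beta| / |z|`, which reproduces the effect's
#' sampling scale when beta and z measure the same signal.
#'
#' Genes with beta exactly 0 have no informative SE; they receive
#' `se = epsilon_beta / |z|` and are flagged (`zero_beta`).  Per-screen BH
#' FDR over the screen's full gene universe is attached for later novelty
#' assessment.
#'
#' @param table Screen result table with columns `gene_id`, `effect`,
#'   `p_raw` (and optionally `screen_id`).
#' @param p_floor,p_ceiling_margin Passed to [truncate_p()].
#' @param beta_mode `"zscored_effect"` (standardize the effect column) or
#'   `"raw_effect"` (use it unchanged).
#' @param epsilon_beta Substitute |beta| for exactly-zero betas.
#' @return A harmonized screen data frame: `gene_id`, `beta`, `p_trunc`,
#'   `z`, `se`, `fdr`, `zero_beta`, with the screen id as the
#'   `"screen_id"` attribute.
#' @examples
#' tab <- data.frame(gene_id = c("a", "b", "c"),
#'                   effect = c(-1, 0.2, 2), p_raw = c(0.3, 0.9, 0.01))
#' harmonize_screen(tab)
#' @export
harmonize_screen <- function(table, p_floor = 1e-300,
                             p_ceiling_margin = 1e-16,
                             beta_mode = c("zscored_effect", "raw_effect"),
                             epsilon_beta = 1e-8) {
  beta_mode <- match.arg(beta_mode)
  eff <- table$effect
  if (sum(is.finite(eff)) < 3L)
    stop("need at least 3 genes with finite effects")
  s <- sd(eff, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("effect column has zero spread; cannot standardize")
  beta <- if (beta_mode == "zscored_effect") {
    (eff - mean(eff, na.rm = TRUE)) / s
  } else eff
  p_trunc <- truncate_p(table$p_raw, p_floor, p_ceiling_margin)
  # lower-tail quantile avoids cancellation in 1 - p/2; the floor keeps the
  # magnitude strictly positive even when p/2 rounds to 0.5, so the derived
  # SE is always finite (and huge, as an uninformative p deserves)
  zmag <- pmax(qnorm(p_trunc / 2, lower.tail = FALSE), 1e-15)
  z <- sign(beta) * zmag
  zero_beta <- beta == 0
  se <- ifelse(zero_beta, epsilon_beta, abs(beta)) / zmag
  out <- data.frame(gene_id = table$gene_id, beta = beta, p_trunc = p_trunc,
                    z = z, se = se, fdr = p.adjust(p_trunc, method = "BH"),
                    zero_beta = zero_beta, stringsAsFactors = FALSE)
  attr(out, "screen_id") <- if (!is.null(table$screen_id))
    table$screen_id[1] else NA_character_
  out
}

#' Inverse-variance fixed-effect pooling for one gene
#'
#' Pools k per-screen estimates under the fixed-effect model: weights
#' `w_i = 1/se_i^2`, pooled effect `sum(w * beta) / sum(w)`, pooled SE
#' `1/sqrt(sum(w))`, z and two-sided normal p, plus Cochran's Q
#' heterogeneity statistic with `k - 1` degrees of freedom and
#' `I^2 = max(0, (Q - df) / Q)`.
#'
#' @param beta,se Numeric vectors of per-screen estimates and standard
#'   errors (k >= 2, all `se > 0`).
#' @return A one-row data frame: `beta_pooled`, `se_pooled`, `z_meta`,
#'   `p_meta`, `q_stat`, `q_df`, `i2`, `k_screens`.
#' @examples
#' fixed_effect_pool(c(2, 0), c(1, 1))
#' @export
fixed_effect_pool <- function(beta, se) {
  if (length(beta) != length(se)) stop("beta and se lengths differ")
  if (length(beta) < 2L) stop("fixed-effect pooling needs k >= 2 screens")
  if (any(!is.finite(beta)) || any(!is.finite(se)))
    stop("beta and se must be finite")
  if (any(se <= 0)) stop("all standard errors must be > 0")
  w <- 1 / se^2
  bp <- sum(w * beta) / sum(w)
  sp <- 1 / sqrt(sum(w))
  z <- bp / sp
  q <- sum(w * (beta - bp)^2)
  df <- length(beta) - 1L
  data.frame(beta_pooled = bp, se_pooled = sp, z_meta = z,
             p_meta = 2 * pnorm(-abs(z)), q_stat = q, q_df = df,
             i2 = if (q > 0) max(0, (q - df) / q) else 0,
             k_screens = length(beta))
}

# Vectorized pooling over a gene x screen matrix pair; rows are genes.
pool_matrix <- function(B, S) {
  W <- 1 / S^2
  sw <- rowSums(W)
  bp <- rowSums(W * B) / sw
  sp <- 1 / sqrt(sw)
  z <- bp / sp
  q <- rowSums(W * (B - bp)^2)
  df <- ncol(B) - 1L
  i2 <- ifelse(q > 0, pmax(0, (q - df) / q), 0)
  data.frame(beta_pooled = bp, se_pooled = sp, z_meta = z,
             p_meta = 2 * pnorm(-abs(z)), q_stat = q, q_df = df, i2 = i2,
             k_screens = ncol(B))
}

#' Novelty flags for pooled genes
#'
#' A gene is novel when it is significant after FDR adjustment of the
#' meta-analysis but was not FDR-significant in any constituent screen.
#'
#' @param fdr_meta Vector of meta-analysis BH-adjusted p-values.
#' @param screen_fdr Matrix (genes x screens) of per-screen BH-adjusted
#'   p-values computed within each screen over its own gene universe.
#' @param alpha Significance level (default 0.05).
#' @return Logical vector of novelty flags.
#' @export
assess_novelty <- function(fdr_meta, screen_fdr, alpha = 0.05) {
  screen_fdr <- as.matrix(screen_fdr)
  if (nrow(screen_fdr) != length(fdr_meta))
    stop("fdr_meta and screen_fdr disagree on gene count")
  rowSums(screen_fdr < alpha) == 0L & fdr_meta < alpha
}

#' Directional hit classification against a population reference
#'
#' Novel genes whose pooled effect departs from the population reference by
#' at least `lfc_threshold` (boundary inclusive) are called `up` or `down`;
#' everything else is `none`.
#'
#' @param beta_pooled Pooled effect estimates.
#' @param is_novel Logical novelty flags.
#' @param reference Population reference value (e.g. the mean pooled beta
#'   over all genes in the combination).
#' @param lfc_threshold Departure threshold (default 1).
#' @return Character vector in \{up, down, none\}.
#' @export
classify_hits <- function(beta_pooled, is_novel, reference,
                          lfc_threshold = 1) {
  if (!is.finite(reference)) stop("population reference must be finite")
  delta <- beta_pooled - reference
  out <- rep("none", length(beta_pooled))
  out[is_novel & delta >= lfc_threshold] <- "up"
  out[is_novel & delta <= -lfc_threshold] <- "down"
  out
}

#' Fixed-effect meta-analysis across screen combinations
#'
#' Runs the full cross-screen analysis: for every requested combination of
#' at least two screens, genes present in all members are pooled by
#' [fixed_effect_pool()], BH FDR is computed within the combination over
#' its own gene set, novelty is assessed against the constituent screens'
#' per-screen FDR, and hits are classified directionally against the
#' population reference.
#'
#' @param screens A named list of harmonized screens
#'   (see [harmonize_screen()]).  Names are the screen ids.
#' @param combinations `"all"` (every subset of size >= 2) or a list of
#'   character vectors of screen ids.
#' @param alpha Significance level for FDR and novelty.
#' @param lfc_threshold Directionality threshold for [classify_hits()].
#' @param population_ref `"all"` (mean pooled beta over all genes in the
#'   combination, the default) or `"hits"` (mean over FDR-significant
#'   genes).
#' @return A named list of meta-result data frames, one per combination,
#'   keyed by the sorted screen ids joined with `"+"`.  Each has columns
#'   `gene_id`, `beta_pooled`, `se_pooled`, `z_meta`, `p_meta`, `q_stat`,
#'   `q_df`, `i2`, `fdr_meta`, `is_novel`, `hit_direction`, `k_screens`.
#' @examples
#' sim <- gen_screen_tables(sim_config(seed = 1, n_genes = 300,
#'                                     n_screens = 3))
#' harm <- lapply(sim$screens, harmonize_screen)
#' res <- run_meta(harm)
#' names(res)
#' @export
run_meta <- function(screens, combinations = "all", alpha = 0.05,
                     lfc_threshold = 1,
                     population_ref = c("all", "hits")) {
  population_ref <- match.arg(population_ref)
  if (length(screens) < 2L) stop("need at least 2 screens")
  ids <- names(screens)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- names(screens) <- vapply(seq_along(screens), function(i) {
      sid <- attr(screens[[i]], "screen_id")
      if (is.null(sid) || is.na(sid)) sprintf("S%d", i) else sid
    }, character(1))
  combos <- if (identical(combinations, "all")) {
    unlist(lapply(2:length(ids), function(m) {
      asplit(combn(ids, m), 2)
    }), recursive = FALSE)
  } else {
    lapply(combinations, as.character)
  }

  out <- list()
  for (members in combos) {
    members <- sort(members)
    key <- paste(members, collapse = "+")
    sub <- screens[members]
    genes <- Reduce(intersect, lapply(sub, function(s) s$gene_id))
    if (length(genes) == 0L)
      stop("empty gene intersection for combination ", key)
    B <- vapply(sub, function(s) s$beta[match(genes, s$gene_id)],
                numeric(length(genes)))
    S <- vapply(sub, function(s) s$se[match(genes, s$gene_id)],
                numeric(length(genes)))
    F <- vapply(sub, function(s) s$fdr[match(genes, s$gene_id)],
                numeric(length(genes)))
    res <- pool_matrix(B, S)
    res$fdr_meta <- p.adjust(res$p_meta, method = "BH")
    res$is_novel <- assess_novelty(res$fdr_meta, F, alpha)
    ref <- if (population_ref == "all") {
      mean(res$beta_pooled)
    } else {
      sig <- res$fdr_meta < alpha
      if (!any(sig)) mean(res$beta_pooled) else mean(res$beta_pooled[sig])
    }
    res$hit_direction <- classify_hits(res$beta_pooled, res$is_novel, ref,
                                       lfc_threshold)
    out[[key]] <- cbind(data.frame(gene_id = genes,
                                   stringsAsFactors = FALSE), res)
  }
  out
}
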