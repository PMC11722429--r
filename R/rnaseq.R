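#' Gene-length normalization
#'
#' Divides counts by gene length in kilobases (reads per kilobase), the
#' first step of the normalization chain.
#'
#' @param counts Genes x samples numeric matrix.
#' @param gene_length Gene lengths in bases, one per row of `counts`.
#' @return Length-normalized matrix.
#' @export
length_normalize <- function(counts, gene_length) {
  if (length(gene_length) != nrow(counts))
    stop("gene_length must have one value per gene")
  if (any(gene_length <= 0)) stop("gene lengths must be > 0")
  counts / (gene_length / 1000)
}

#' Counts-per-million scaling
#'
#' Scales each sample so its column sums to one million.
#'
#' @param x Genes x samples numeric matrix (e.g. length-normalized counts).
#' @return CPM matrix; every column sums to 1e6.
#' @export
cpm_normalize <- function(x) {
  tot <- colSums(x)
  if (any(tot == 0)) {
    bad <- colnames(x)[tot == 0]
    stop("sample(s) with zero total counts: ",
         paste(if (is.null(bad)) which(tot == 0) else bad, collapse = ", "))
  }
  sweep(x, 2, tot, "/") * 1e6
}

#' Pedestalled log2 transform
#'
#' Adds a pedestal (default 2) before the log2 transform, so zero
#' expression maps to `log2(0 + 2) = 1` and small counts are stabilized.
#'
#' @param x Non-negative matrix.
#' @param pedestal Additive pedestal.
#' @return `log2(x + pedestal)`.
#' @export
pedestal_log2 <- function(x, pedestal = 2) {
  log2(x + pedestal)
}

#' The full RNA-seq normalization chain
#'
#' Runs, in order: gene-length normalization, counts-per-million scaling,
#' pedestalling with 2, log2 transform, and cyclic loess cross-sample
#' normalization (pairwise, via [limma::normalizeCyclicLoess()]).  Cyclic
#' loess removes smooth intensity-dependent (M-versus-A) trends between
#' every sample pair and is a no-op when samples are already identical.
#'
#' @param counts Genes x samples count matrix.
#' @param gene_length Gene lengths in bases.
#' @param loess_cycles Number of cyclic loess iterations (default 3).
#' @param pedestal Additive pedestal before log2 (default 2).
#' @return Normalized log2 matrix.  Attribute `"steps"` records the chain;
#'   attribute `"cpm"` holds the pre-pedestal CPM matrix for QC.
#' @examples
#' sim <- gen_count_matrix(sim_config(seed = 1, n_genes = 100))
#' norm <- normalize_chain(sim$counts, sim$gene_length)
#' attr(norm, "steps")
#' @export
normalize_chain <- function(counts, gene_length, loess_cycles = 3L,
                            pedestal = 2) {
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  rpk <- length_normalize(counts, gene_length)
  cpm <- cpm_normalize(rpk)
  logged <- pedestal_log2(cpm, pedestal)
  norm <- limma::normalizeCyclicLoess(logged, method = "pairs",
                                      iterations = loess_cycles)
  dimnames(norm) <- dimnames(counts)
  attr(norm, "steps") <- c("length_normalize", "cpm", "pedestal_log2",
                           sprintf("cyclic_loess_x%d", loess_cycles))
  attr(norm, "cpm") <- cpm
  norm
}

#' Fit a CV-versus-mean noise model per condition
#'
#' For each condition, computes per-gene mean log2 expression and the
#' coefficient of variation on the linearized (2^x) scale, fits a loess
#' curve of CV on mean, and takes as that condition's noise threshold the
#' smallest observed mean at which the fitted CV drops below `cv_cutoff`.
#' The final threshold is the maximum over conditions, so a gene must be
#' above the noise floor of the noisier condition to survive.
#'
#' @param normalized Normalized log2 matrix ([normalize_chain()]).
#' @param groups Named character vector mapping columns to conditions.
#' @param cv_cutoff CV level defining "quiet enough" (default 0.5).
#' @param span Loess span.
#' @return An object of class `noise_model`: per-condition thresholds and
#'   fitted curves, plus the combined `threshold`.
#' @export
fit_noise_model <- function(normalized, groups, cv_cutoff = 0.5,
                            span = 0.5) {
  if (nrow(normalized) < 50L)
    stop("refusing to fit a noise model on fewer than 50 genes")
  conds <- unique(groups)
  fits <- list()
  thresholds <- numeric(0)
  for (cond in conds) {
    cols <- names(groups)[groups == cond]
    if (length(cols) < 2L)
      stop("condition ", cond, " has fewer than 2 replicates")
    sub <- normalized[, cols, drop = FALSE]
    lin <- 2^sub
    m <- rowMeans(sub)
    cv <- apply(lin, 1, sd) / rowMeans(lin)
    fit <- loess(cv ~ m, span = span, degree = 2,
                 control = stats::loess.control(surface = "direct"))
    grid <- sort(unique(m))
    pred <- predict(fit, newdata = data.frame(m = grid))
    below <- which(pred < cv_cutoff)
    thr <- if (length(below)) grid[min(below)] else max(grid)
    fits[[cond]] <- list(fit = fit, grid = grid, pred = pred,
                         threshold = thr)
    thresholds[cond] <- thr
  }
  structure(list(fits = fits, thresholds = thresholds,
                 threshold = max(thresholds), cv_cutoff = cv_cutoff,
                 mean_range = range(rowMeans(normalized))),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat("noise_model: cv_cutoff", x$cv_cutoff, "| thresholds:",
      paste(sprintf("%s=%.3f", names(x$thresholds), x$thresholds),
            collapse = " "),
      "| combined", sprintf("%.3f", x$threshold), "\n")
  invisible(x)
}

#' Remove noise-biased genes below the fitted threshold
#'
#' Keeps genes whose largest per-condition mean expression reaches the
#' noise threshold; removed plus kept always partitions the input.
#'
#' @param normalized Normalized log2 matrix.
#' @param model A [fit_noise_model()] object.
#' @param groups Named condition vector (as in [fit_noise_model()]).
#' @return A list with `kept` (filtered matrix) and `removed` (character
#'   vector of removed gene ids).
#' @export
filter_noise <- function(normalized, model, groups) {
  stopifnot(inherits(model, "noise_model"))
  conds <- unique(groups)
  cond_means <- vapply(conds, function(cond) {
    rowMeans(normalized[, names(groups)[groups == cond], drop = FALSE])
  }, numeric(nrow(normalized)))
  keep <- apply(cond_means, 1, max) >= model$threshold
  list(kept = normalized[keep, , drop = FALSE],
       removed = rownames(normalized)[!keep])
}

#' Per-gene differential expression on the normalized matrix
#'
#' Welch's t-test on the normalized log2 values per gene (KD versus NT),
#' BH adjustment across genes, and a direction call by the sign of the
#' KD - NT difference for FDR-significant genes.
#'
#' @param normalized Normalized (and typically noise-filtered) log2 matrix.
#' @param groups Named vector mapping columns to `"NT"` / `"KD"`.
#' @param alpha FDR significance level for the direction call.
#' @return A data frame `gene_id`, `log2fc`, `p`, `adj_p`, `direction`.
#' @export
differential_expression <- function(normalized, groups, alpha = 0.05) {
  kd_cols <- names(groups)[groups == "KD"]
  nt_cols <- names(groups)[groups == "NT"]
  if (length(kd_cols) < 2L || length(nt_cols) < 2L)
    stop("need at least 2 replicates per condition")
  kd <- normalized[, kd_cols, drop = FALSE]
  nt <- normalized[, nt_cols, drop = FALSE]
  lfc <- rowMeans(kd) - rowMeans(nt)
  p <- vapply(seq_len(nrow(normalized)), function(i) {
    if (sd(c(kd[i, ], nt[i, ])) == 0) return(1)
    tryCatch(t.test(kd[i, ], nt[i, ])$p.value, error = function(e) 1)
  }, numeric(1))
  adj <- p.adjust(p, method = "BH")
  direction <- ifelse(adj < alpha, ifelse(lfc > 0, "up", "down"), "none")
  data.frame(gene_id = rownames(normalized), log2fc = unname(lfc), p = p,
             adj_p = adj, direction = direction, stringsAsFactors = FALSE)
}

#' Relative quantification by the 2^-(delta delta Ct) method
#'
#' Classic qPCR fold change: the target gene's Ct is referenced to a
#' housekeeping gene within each of the treated and control samples, and
#' the fold change is `2^-((Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control))`.
#'
#' @param ct_target_treated,ct_ref_treated Ct values in the treated sample.
#' @param ct_target_control,ct_ref_control Ct values in the control sample.
#' @return Fold change (1 = no change).
#' @examples
#' ddct(21, 20, 20, 20)  # delta delta Ct of 1 -> 0.5
#' @export
ddct <- function(ct_target_treated, ct_ref_treated, ct_target_control,
                 ct_ref_control) {
  vals <- c(ct_target_treated, ct_ref_treated, ct_target_control,
            ct_ref_control)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  2^-((ct_target_treated - ct_ref_treated) -
        (ct_target_control - ct_ref_control))
}
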