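#' Simulate a negative-binomial count matrix with planted DE genes
#'
#' Baseline expression is log-normal; expected counts scale with gene length
#' (so length normalization is meaningful) and with a per-sample library
#' size factor.  A fraction `cfg$frac_de` of genes is shifted by
#' `cfg$de_lfc` log2 units in the KD condition with random sign.  Counts are
#' negative binomial with dispersion `cfg$nb_dispersion`
#' (`size = 1/dispersion`).
#'
#' @param cfg A [sim_config()] object.
#' @return A list with `counts` (genes x samples integer matrix),
#'   `gene_length` (bases), `groups` (named vector mapping samples to
#'   \{NT, KD\}) and `truth` (data frame `gene_id`, `truth_de`,
#'   `truth_sign`).
#' @examples
#' sim <- gen_count_matrix(sim_config(seed = 1, n_genes = 100))
#' dim(sim$counts)
#' @export
gen_count_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  with_seed(substream_seed(cfg$seed, "counts"), {
    n <- cfg$n_genes
    ns <- cfg$n_replicates
    genes <- sprintf("G%05d", seq_len(n))
    len <- sample(500:5000, n, replace = TRUE)
    base <- rlnorm(n, log(200), 1.2) * (len / 1000)

    n_de <- round(cfg$frac_de * n)
    de_idx <- sample.int(n, n_de)
    sgn <- integer(n)
    sgn[de_idx] <- sample(c(-1L, 1L), n_de, replace = TRUE)
    lfc <- sgn * cfg$de_lfc

    samp <- c(sprintf("NT_%d", seq_len(ns)), sprintf("KD_%d", seq_len(ns)))
    groups <- stats::setNames(rep(c("NT", "KD"), each = ns), samp)
    sf <- runif(2 * ns, 0.8, 1.2)
    size <- 1 / cfg$nb_dispersion
    counts <- vapply(seq_len(2 * ns), function(j) {
      mu <- base * sf[j]
      if (groups[j] == "KD") mu <- mu * 2^lfc
      rnbinom(n, mu = mu, size = size)
    }, numeric(n))
    dimnames(counts) <- list(genes, samp)
    list(counts = counts, gene_length = stats::setNames(len, genes),
         groups = groups,
         truth = data.frame(gene_id = genes, truth_de = sgn != 0L,
                            truth_sign = sgn, stringsAsFactors = FALSE))
  })
}
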