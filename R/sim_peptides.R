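#' Simulate a peptide-level dSILAC quantification table
#'
#' For each protein a true half-life is drawn uniformly from
#' `cfg$true_halflife_range`; in the KD condition it is multiplied by
#' `cfg$kd_halflife_factor`.  Under steady-state turnover the noiseless
#' heavy/light ratio after labeling time ts is `R = 2^(ts / t_half) - 1`;
#' measured peptide ratios are that value under multiplicative log-normal
#' noise with coefficient of variation `cfg$ratio_cv` (mean-preserving, so
#' `ratio_cv = 0` reproduces the noiseless ratio exactly).  Intensities are
#' log-normal.  A fraction of proteins is flagged as contaminants and a
#' fraction of peptides is injected with out-of-range ratios, exercising the
#' downstream filters.
#'
#' @param cfg A [sim_config()] object.
#' @param conditions Conditions to simulate (default `c("NT", "KD")`).
#' @return A list with `peptides` (data frame `peptide_seq`, `protein_id`,
#'   `condition`, `replicate`, `intensity`, `hl_ratio`, `ts`,
#'   `is_contaminant`) and `truth` (data frame `protein_id`, `condition`,
#'   `truth_halflife` in days).
#' @examples
#' sim <- gen_peptide_table(sim_config(seed = 1, n_proteins = 5,
#'                                     ratio_cv = 0, frac_contaminant = 0,
#'                                     frac_outlier = 0))
#' head(sim$peptides)
#' @export
gen_peptide_table <- function(cfg, conditions = c("NT", "KD")) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  with_seed(substream_seed(cfg$seed, "peptides"), {
    np <- cfg$n_proteins
    ts <- cfg$labeling_time
    prot <- sprintf("P%04d", seq_len(np))
    contam <- runif(np) < cfg$frac_contaminant
    prot[contam] <- sub("^P", "CON_P", prot[contam])
    t_base <- runif(np, cfg$true_halflife_range[1], cfg$true_halflife_range[2])
    n_pep <- sample(seq(cfg$peptides_per_protein[1],
                        cfg$peptides_per_protein[2]), np, replace = TRUE)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    pep_seqs <- lapply(seq_len(np), function(i) {
      vapply(seq_len(n_pep[i]), function(j) {
        paste(sample(aa, sample(8:18, 1), replace = TRUE), collapse = "")
      }, character(1))
    })
    sdlog <- sqrt(log(1 + cfg$ratio_cv^2))

    rows <- list()
    truth <- list()
    for (cond in conditions) {
      t_true <- if (cond == "KD") t_base * cfg$kd_halflife_factor else t_base
      truth[[cond]] <- data.frame(protein_id = prot, condition = cond,
                                  truth_halflife = t_true,
                                  stringsAsFactors = FALSE)
      for (rep_i in seq_len(cfg$n_replicates)) {
        pid <- rep(prot, n_pep)
        tt <- rep(t_true, n_pep)
        r0 <- 2^(ts / tt) - 1
        m <- length(pid)
        noise <- if (cfg$ratio_cv > 0) {
          rlnorm(m, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        } else rep(1, m)
        ratio <- r0 * noise
        out <- runif(m) < cfg$frac_outlier
        if (any(out))
          ratio[out] <- sample(c(0.005, 200), sum(out), replace = TRUE)
        rows[[paste(cond, rep_i)]] <- data.frame(
          peptide_seq = unlist(pep_seqs), protein_id = pid,
          condition = cond, replicate = rep_i,
          intensity = rlnorm(m, log(1e5), 1), hl_ratio = ratio, ts = ts,
          is_contaminant = rep(grepl("^CON_", prot), n_pep),
          stringsAsFactors = FALSE)
      }
    }
    list(peptides = do.call(rbind, c(rows, make.row.names = FALSE)),
         truth = do.call(rbind, c(truth, make.row.names = FALSE)))
  })
}
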