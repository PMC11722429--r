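#' Simulation configuration for the synthetic-data generators
#'
#' Bundles every tunable of the synthetic-data module into one validated
#' object.  The defaults are the study conditions the generators emulate: a
#' genome-scale screen universe (5,000 genes across 4 screens), a dual-guide
#' library sequenced to 100,000 read pairs with a 30% lentiviral
#' recombination rate, a single-timepoint dynamic SILAC experiment (200
#' proteins, 3-8 peptides each, 7-day labeling, 5% multiplicative ratio
#' noise), a junction table with 10% planted cryptic events, and a
#' negative-binomial count matrix with 10% of genes differentially expressed
#' at |log2FC| = 2.
#'
#' @param seed Integer seed; every generator derives an independent
#'   substream from it by stage name, so a fixed seed plus a fixed
#'   configuration gives byte-identical outputs.
#' @param n_genes Number of genes in the screen/count universes.
#' @param n_screens Number of screens generated by [gen_screen_tables()].
#' @param frac_shared_hits,frac_specific_hits,frac_weak_hits Fractions of
#'   genes planted as shared hits (same effect in every screen), single-screen
#'   hits, and "distributed-weak" hits (sub-threshold in every screen but
#'   detectable when pooled).  Must sum to at most 1.
#' @param effect_mean,effect_sd Mean and gene-level spread of the planted hit
#'   effect on the standardized (z) scale.
#' @param weak_effect Mean per-screen effect of distributed-weak genes on the
#'   z scale.  Chosen so pooling across screens is decisive while single
#'   screens stay below the FDR threshold.
#' @param weak_cap Per-screen absolute effect cap for distributed-weak genes.
#'   Clipping at this value guarantees, not just in expectation, that no
#'   weak gene can reach per-screen significance at the default universe
#'   size, which is what "sub-threshold in every screen" means here.
#' @param n_reads Read pairs per simulated FASTQ bin.
#' @param recombination_rate Fraction of read pairs whose two guides come
#'   from different constructs targeting different genes.
#' @param n_proteins Number of proteins in the simulated peptide table.
#' @param peptides_per_protein Integer range (length 2) of peptides per
#'   protein.
#' @param true_halflife_range Range (days) of planted protein half-lives.
#' @param labeling_time Labeling time ts in days.
#' @param ratio_cv Multiplicative coefficient of variation of peptide
#'   heavy/light ratios (log-normal noise; 0 gives noiseless ratios).
#' @param frac_contaminant Fraction of proteins flagged as contaminants.
#' @param frac_outlier Fraction of peptides injected with out-of-range
#'   ratios (outside the default 0.01-100 retention window).
#' @param n_replicates Replicates per condition for the peptide and count
#'   generators.
#' @param kd_halflife_factor Multiplier applied to KD-condition half-lives
#'   (1 = no condition effect).
#' @param n_junctions Number of junction records.
#' @param frac_cryptic Fraction of junctions planted as cryptic events.
#' @param cryptic_dpsi Planted PSI difference for cryptic junctions.
#' @param junction_noise_sd Gaussian PSI noise (0 gives exact geometry).
#' @param n_samples_per_group Samples per group (control/KD) for the
#'   junction generator; must be at least 2.
#' @param nb_dispersion Negative-binomial dispersion of simulated counts.
#' @param frac_de Fraction of genes planted as differentially expressed.
#' @param de_lfc Planted |log2 fold change| for DE genes; must be nonzero
#'   whenever `frac_de > 0`.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 500)
#' cfg$n_screens
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 5000L,
                       n_screens = 4L,
                       frac_shared_hits = 0.01,
                       frac_specific_hits = 0.01,
                       frac_weak_hits = 0,
                       effect_mean = 2,
                       effect_sd = 0.25,
                       weak_effect = 2.5,
                       weak_cap = 3.2,
                       n_reads = 100000L,
                       recombination_rate = 0.3,
                       n_proteins = 200L,
                       peptides_per_protein = c(3L, 8L),
                       true_halflife_range = c(1, 30),
                       labeling_time = 7,
                       ratio_cv = 0.05,
                       frac_contaminant = 0.02,
                       frac_outlier = 0.01,
                       n_replicates = 4L,
                       kd_halflife_factor = 1,
                       n_junctions = 500L,
                       frac_cryptic = 0.1,
                       cryptic_dpsi = 0.3,
                       junction_noise_sd = 0.02,
                       n_samples_per_group = 4L,
                       nb_dispersion = 0.05,
                       frac_de = 0.1,
                       de_lfc = 2) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_screens = as.integer(n_screens),
              frac_shared_hits = frac_shared_hits,
              frac_specific_hits = frac_specific_hits,
              frac_weak_hits = frac_weak_hits,
              effect_mean = effect_mean, effect_sd = effect_sd,
              weak_effect = weak_effect, weak_cap = weak_cap,
              n_reads = as.integer(n_reads),
              recombination_rate = recombination_rate,
              n_proteins = as.integer(n_proteins),
              peptides_per_protein = as.integer(peptides_per_protein),
              true_halflife_range = true_halflife_range,
              labeling_time = labeling_time, ratio_cv = ratio_cv,
              frac_contaminant = frac_contaminant,
              frac_outlier = frac_outlier,
              n_replicates = as.integer(n_replicates),
              kd_halflife_factor = kd_halflife_factor,
              n_junctions = as.integer(n_junctions),
              frac_cryptic = frac_cryptic, cryptic_dpsi = cryptic_dpsi,
              junction_noise_sd = junction_noise_sd,
              n_samples_per_group = as.integer(n_samples_per_group),
              nb_dispersion = nb_dispersion, frac_de = frac_de,
              de_lfc = de_lfc)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  frac_fields <- c("frac_shared_hits", "frac_specific_hits", "frac_weak_hits",
                   "recombination_rate", "ratio_cv", "frac_contaminant",
                   "frac_outlier", "frac_cryptic", "frac_de")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("invalid config: `", f, "` must be a fraction in [0, 1]")
  }
  counts <- c("n_genes", "n_screens", "n_reads", "n_proteins",
              "n_replicates", "n_junctions", "n_samples_per_group")
  for (f in counts) {
    if (cfg[[f]] < 1L) stop("invalid config: `", f, "` must be >= 1")
  }
  if (cfg$frac_shared_hits + cfg$frac_specific_hits + cfg$frac_weak_hits > 1)
    stop("invalid config: hit fractions sum to more than 1")
  if (cfg$labeling_time <= 0)
    stop("invalid config: `labeling_time` must be > 0")
  if (cfg$nb_dispersion <= 0)
    stop("invalid config: `nb_dispersion` must be > 0")
  if (any(cfg$true_halflife_range <= 0) ||
      length(cfg$true_halflife_range) != 2L)
    stop("invalid config: `true_halflife_range` must be two positive values")
  if (length(cfg$peptides_per_protein) != 2L ||
      any(cfg$peptides_per_protein < 1L))
    stop("invalid config: `peptides_per_protein` must be a range of counts >= 1")
  if (cfg$frac_de > 0 && cfg$de_lfc == 0)
    stop("invalid config: `de_lfc` must be nonzero when `frac_de` > 0")
  if (cfg$n_samples_per_group < 2L)
    stop("invalid config: `n_samples_per_group` must be >= 2")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,", x$n_screens, "screens, seed",
      x$seed, "\n")
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Fields absent from the file keep their [sim_config()] defaults.
#'
#' @param path Path to a YAML file whose keys are `sim_config()` arguments.
#' @return A `sim_config` object.
#' @export
sim_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}
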