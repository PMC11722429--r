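#' Toy exon annotation for the junction generator
#'
#' One gene model per junction: three exons of 200 bp separated by 800 bp
#' introns on a single forward-strand chromosome, each model offset by 10 kb.
#' Coordinates are 0-based half-open (BED convention).
#'
#' @param n_models Number of gene models.
#' @param chrom Chromosome name.
#' @return Exon annotation data frame (`gene`, `chrom`, `start`, `end`,
#'   `strand`).
#' @export
toy_annotation <- function(n_models, chrom = "chrS") {
  off <- (seq_len(n_models) - 1L) * 10000L + 1000L
  data.frame(
    gene = rep(sprintf("J%05d", seq_len(n_models)), each = 3L),
    chrom = chrom,
    start = as.integer(c(rbind(off, off + 1000L, off + 2000L))),
    end = as.integer(c(rbind(off + 200L, off + 1200L, off + 2200L))),
    strand = "+", stringsAsFactors = FALSE)
}

#' Simulate a splice-junction PSI table with planted categories
#'
#' Junctions are laid out on the [toy_annotation()] geometry, one per gene
#' model, with planted categories:
#'
#' * `canonical`: joins the ends of two adjacent annotated exons; PSI high
#'   in both groups.
#' * `exon_skipping`: joins annotated splice sites spanning the middle exon;
#'   usage rises in KD but the junction is readily detected in controls.
#' * `cryptic_exon`: the acceptor end falls mid-intron at an unannotated
#'   position; control PSI is 0 (detected in none of the control samples)
#'   and KD PSI equals `cfg$cryptic_dpsi`.
#' * `intron_retention`: the record lies wholly within an annotated intron
#'   (intronic inclusion signal) with inclusion elevated in KD.
#'
#' Per-sample PSI values get Gaussian noise `cfg$junction_noise_sd`,
#' truncated to \[0, 1\]; zero noise gives the planted values exactly.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with `junctions` (data frame `junction_id`, `chrom`,
#'   `start`, `end`, `strand`, `annotation`, plus one PSI column per
#'   sample), `groups` (named character vector mapping PSI columns to
#'   \{control, KD\}), `annotation` (the exon table) and `truth` (data frame
#'   `junction_id`, `truth_category`).
#' @examples
#' sim <- gen_junction_table(sim_config(seed = 1, n_junctions = 20))
#' table(sim$truth$truth_category)
#' @export
gen_junction_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  if (cfg$n_samples_per_group < 2L)
    stop("n_samples_per_group must be >= 2")
  with_seed(substream_seed(cfg$seed, "junctions"), {
    n <- cfg$n_junctions
    ann <- toy_annotation(n)
    off <- (seq_len(n) - 1L) * 10000L + 1000L

    n_cry <- round(cfg$frac_cryptic * n)
    other <- n - n_cry
    cat_pool <- c(rep("cryptic_exon", n_cry),
                  rep(c("canonical", "exon_skipping", "intron_retention"),
                      length.out = other))
    category <- sample(cat_pool)

    start <- integer(n)
    end <- integer(n)
    annot <- character(n)
    start[category == "canonical"] <- off[category == "canonical"] + 200L
    end[category == "canonical"] <- off[category == "canonical"] + 1000L
    annot[category == "canonical"] <- "both_ends_annotated"
    start[category == "exon_skipping"] <- off[category == "exon_skipping"] + 200L
    end[category == "exon_skipping"] <- off[category == "exon_skipping"] + 2000L
    annot[category == "exon_skipping"] <- "both_ends_annotated"
    start[category == "cryptic_exon"] <- off[category == "cryptic_exon"] + 200L
    end[category == "cryptic_exon"] <- off[category == "cryptic_exon"] + 600L
    annot[category == "cryptic_exon"] <- "one_end_novel"
    start[category == "intron_retention"] <-
      off[category == "intron_retention"] + 400L
    end[category == "intron_retention"] <-
      off[category == "intron_retention"] + 800L
    annot[category == "intron_retention"] <- "within_intron"

    ns <- cfg$n_samples_per_group
    ctrl_mu <- c(canonical = 0.9, exon_skipping = 0.10,
                 cryptic_exon = 0, intron_retention = 0.05)[category]
    kd_mu <- c(canonical = 0.9, exon_skipping = 0.10 + cfg$cryptic_dpsi,
               cryptic_exon = cfg$cryptic_dpsi,
               intron_retention = 0.05 + cfg$cryptic_dpsi)[category]
    noisy <- function(mu) {
      m <- matrix(rnorm(n * ns, mu, cfg$junction_noise_sd), n, ns)
      m[mu == 0, ] <- 0   # cryptic junctions are truly absent from controls
      pmin(pmax(m, 0), 1)
    }
    psi <- cbind(noisy(ctrl_mu), noisy(kd_mu))
    samp <- c(sprintf("ctrl_%d", seq_len(ns)), sprintf("kd_%d", seq_len(ns)))
    colnames(psi) <- samp
    groups <- stats::setNames(rep(c("control", "KD"), each = ns), samp)

    junctions <- cbind(
      data.frame(junction_id = sprintf("J%05d", seq_len(n)), chrom = "chrS",
                 start = start, end = end, strand = "+", annotation = annot,
                 stringsAsFactors = FALSE),
      as.data.frame(psi))
    list(junctions = junctions, groups = groups, annotation = ann,
         truth = data.frame(junction_id = junctions$junction_id,
                            truth_category = category,
                            stringsAsFactors = FALSE))
  })
}
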