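#' Simulate per-screen gene-level result tables with planted hits
#'
#' Emulates the gene-level exports of FACS CRISPRi screens: one table per
#' screen over a common gene universe, each row carrying a raw effect
#' estimate and a two-sided p-value.  Null genes draw effects from a
#' standard normal, so that the p-value `2 * (1 - pnorm(|effect|))` is
#' uniform under the null and the effect column is already on the z scale
#' the harmonizer targets.  Hit genes shift the mean:
#'
#' * `shared` hits carry the same planted effect (gene-specific sign and
#'   magnitude) in every screen;
#' * `specific` hits carry it in exactly one screen;
#' * `weak` ("distributed-weak") hits carry a sub-threshold effect in every
#'   screen — per-screen draws are clipped at `weak_cap` so no single screen
#'   can reach FDR significance, while the pooled signal remains strong.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with `screens` (a list of data frames `screen_id`,
#'   `gene_id`, `effect`, `p_raw`, one per screen) and `truth` (a data frame
#'   `gene_id`, `truth_class` in \{null, shared, specific, weak\},
#'   `truth_sign`, `truth_effect`, `truth_screen` — the hosting screen for
#'   specific hits, NA otherwise).
#' @examples
#' sim <- gen_screen_tables(sim_config(seed = 1, n_genes = 200,
#'                                     frac_shared_hits = 0.05))
#' table(sim$truth$truth_class)
#' @export
gen_screen_tables <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  with_seed(substream_seed(cfg$seed, "screens"), {
    n <- cfg$n_genes
    k <- cfg$n_screens
    genes <- sprintf("G%05d", seq_len(n))
    n_shared <- round(cfg$frac_shared_hits * n)
    n_spec <- round(cfg$frac_specific_hits * n)
    n_weak <- round(cfg$frac_weak_hits * n)

    cls <- rep("null", n)
    planted <- sample.int(n, n_shared + n_spec + n_weak)
    shared_idx <- planted[seq_len(n_shared)]
    spec_idx <- planted[n_shared + seq_len(n_spec)]
    weak_idx <- planted[n_shared + n_spec + seq_len(n_weak)]
    cls[shared_idx] <- "shared"
    cls[spec_idx] <- "specific"
    cls[weak_idx] <- "weak"

    sign_g <- sample(c(-1, 1), n, replace = TRUE)
    mag <- rep(0, n)
    mag[c(shared_idx, spec_idx)] <-
      pmax(0.5, rnorm(n_shared + n_spec, cfg$effect_mean, cfg$effect_sd))
    mag[weak_idx] <- cfg$weak_effect
    host <- rep(NA_integer_, n)
    host[spec_idx] <- sample.int(k, n_spec, replace = TRUE)

    screens <- lapply(seq_len(k), function(s) {
      mu <- rep(0, n)
      mu[shared_idx] <- sign_g[shared_idx] * mag[shared_idx]
      in_s <- spec_idx[host[spec_idx] == s]
      mu[in_s] <- sign_g[in_s] * mag[in_s]
      eff <- rnorm(n, mu, 1)
      if (n_weak) {
        raw <- rnorm(n_weak, cfg$weak_effect, 1)
        eff[weak_idx] <- sign_g[weak_idx] * pmin(abs(raw), cfg$weak_cap)
      }
      data.frame(screen_id = sprintf("S%d", s), gene_id = genes,
                 effect = eff, p_raw = 2 * pnorm(-abs(eff)),
                 stringsAsFactors = FALSE)
    })
    names(screens) <- sprintf("S%d", seq_len(k))

    truth <- data.frame(gene_id = genes, truth_class = cls,
                        truth_sign = ifelse(cls == "null", 0L, sign_g),
                        truth_effect = mag,
                        truth_screen = ifelse(is.na(host), NA_character_,
                                              sprintf("S%d", host)),
                        stringsAsFactors = FALSE)
    list(screens = screens, truth = truth)
  })
}
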