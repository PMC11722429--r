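#' Group-mean PSI difference for one junction
#'
#' `mean(PSI over KD samples) - mean(PSI over control samples)`, with
#' missing values excluded per group.  Returns `NA` when a group has no
#' non-missing value (such records are skipped and logged by
#' [classify_junctions()]).
#'
#' @param psi Numeric vector of per-sample PSI values in \[0, 1\].
#' @param groups Character vector of the same length with values
#'   `"control"` or `"KD"`.
#' @return Signed PSI difference in \[-1, 1\], or NA.
#' @examples
#' delta_psi(c(0.1, 0.1, 0.3, 0.3), c("control", "control", "KD", "KD"))
#' @export
delta_psi <- function(psi, groups) {
  kd <- psi[groups == "KD"]
  ctrl <- psi[groups == "control"]
  if (all(is.na(kd)) || all(is.na(ctrl))) return(NA_real_)
  mean(kd, na.rm = TRUE) - mean(ctrl, na.rm = TRUE)
}

#' Fraction of control samples in which a junction is detected
#'
#' A junction counts as "present" in a sample when its PSI is at least
#' `detect_psi_min` (default 0.01; the detection floor is configurable
#' because quantifiers differ in what they emit for unused junctions).
#'
#' @inheritParams delta_psi
#' @param detect_psi_min Detection floor.
#' @return Fraction in \[0, 1\] of control samples with detected usage.
#' @export
control_presence <- function(psi, groups, detect_psi_min = 0.01) {
  ctrl <- psi[groups == "control"]
  if (!length(ctrl)) stop("no control samples")
  mean(ctrl >= detect_psi_min, na.rm = TRUE)
}

#' Cryptic-splicing flags from PSI difference and control presence
#'
#' A junction is significantly mis-spliced when `|dpsi| > dpsi_threshold`
#' (strict).  It is cryptic when it gains usage while being essentially
#' absent from controls, or loses usage while being established in
#' controls: `(dpsi > dpsi_threshold AND presence < low_presence) OR
#' (dpsi < -dpsi_threshold AND presence > high_presence)`.  All
#' inequalities are strict, mirroring the thresholds' wording
#' (">10%", "<5%").  Cryptic implies significant by construction.
#'
#' @param dpsi Signed PSI difference(s).
#' @param presence Control-presence fraction(s).
#' @param dpsi_threshold PSI-difference threshold (default 0.10).
#' @param low_presence Maximum control presence for a gained cryptic
#'   junction (default 0.05).
#' @param high_presence Minimum control presence for a lost junction
#'   (default 0.10).
#' @return A data frame with logical columns `significant` and `cryptic`.
#' @examples
#' call_cryptic(c(0.15, 0.15, 0.1), c(0, 0.5, 0))
#' @export
call_cryptic <- function(dpsi, presence, dpsi_threshold = 0.10,
                         low_presence = 0.05, high_presence = 0.10) {
  significant <- !is.na(dpsi) & abs(dpsi) > dpsi_threshold
  cryptic <- !is.na(dpsi) & !is.na(presence) &
    ((dpsi > dpsi_threshold & presence < low_presence) |
       (dpsi < -dpsi_threshold & presence > high_presence))
  data.frame(significant = significant, cryptic = cryptic)
}

#' Categorize junctions against an exon annotation
#'
#' Assigns each junction record one of four categories by comparing its
#' 0-based half-open coordinates with annotated splice sites:
#'
#' * `canonical`: both ends match annotated exon boundaries (start at an
#'   exon end, end at an exon start) with no annotated exon fully inside
#'   the junction;
#' * `exon_skipping`: both ends match annotated boundaries and the
#'   junction spans at least one annotated exon;
#' * `cryptic_exon`: exactly one end matches an annotated boundary and the
#'   other falls inside an annotated intron;
#' * `intron_retention`: neither end is annotated and the record lies
#'   wholly within one annotated intron (intronic inclusion signal);
#' * `other`: anything unresolvable.
#'
#' Categories are strand-symmetric; strand is carried, not interpreted.
#'
#' @param junctions Data frame with columns `chrom`, `start`, `end` (and
#'   any others, carried through).
#' @param annotation Exon table (`gene`, `chrom`, `start`, `end`,
#'   `strand`), 0-based half-open.
#' @return Character vector of categories, one per junction.
#' @export
categorize_junctions <- function(junctions, annotation) {
  if (any(junctions$start >= junctions$end))
    stop("junction records must satisfy start < end")
  n <- nrow(junctions)
  out <- character(n)
  for (ch in unique(junctions$chrom)) {
    jidx <- which(junctions$chrom == ch)
    ex <- annotation[annotation$chrom == ch, , drop = FALSE]
    donors <- unique(ex$end)     # exon ends: junction starts
    acceptors <- unique(ex$start)  # exon starts: junction ends
    # introns: gaps between consecutive exons within a gene
    introns <- do.call(rbind, lapply(split(ex, ex$gene), function(g) {
      g <- g[order(g$start), , drop = FALSE]
      if (nrow(g) < 2L) return(NULL)
      data.frame(start = g$end[-nrow(g)], end = g$start[-1])
    }))
    in_intron <- function(pos) {
      if (is.null(introns)) return(rep(FALSE, length(pos)))
      vapply(pos, function(p) {
        any(introns$start < p & p < introns$end)
      }, logical(1))
    }
    s <- junctions$start[jidx]
    e <- junctions$end[jidx]
    s_ann <- s %in% donors
    e_ann <- e %in% acceptors
    spans_exon <- vapply(seq_along(jidx), function(i) {
      any(ex$start > s[i] & ex$end < e[i])
    }, logical(1))
    same_intron <- if (is.null(introns)) rep(FALSE, length(jidx)) else {
      vapply(seq_along(jidx), function(i) {
        any(introns$start <= s[i] & e[i] <= introns$end &
              introns$start < s[i] & e[i] < introns$end)
      }, logical(1))
    }
    cat_i <- rep("other", length(jidx))
    cat_i[s_ann & e_ann & !spans_exon] <- "canonical"
    cat_i[s_ann & e_ann & spans_exon] <- "exon_skipping"
    one_novel <- xor(s_ann, e_ann)
    novel_in_intron <- ifelse(s_ann, in_intron(e), in_intron(s))
    cat_i[one_novel & novel_in_intron] <- "cryptic_exon"
    cat_i[!s_ann & !e_ann & same_intron] <- "intron_retention"
    out[jidx] <- cat_i
  }
  out
}

#' Full junction classification: PSI calls plus categories
#'
#' Computes per-junction PSI difference, control presence, significance and
#' cryptic flags ([call_cryptic()]) and the annotation category
#' ([categorize_junctions()]).  Records whose PSI is entirely missing in a
#' group are skipped and listed in the `"skipped"` attribute.
#'
#' @param junctions Junction table as produced by [gen_junction_table()]:
#'   coordinate/annotation columns plus one PSI column per sample.
#' @param groups Named character vector mapping PSI column names to
#'   `"control"` / `"KD"`.
#' @param annotation Exon annotation table.
#' @param dpsi_threshold,low_presence,high_presence See [call_cryptic()].
#' @param detect_psi_min See [control_presence()].
#' @return A data frame `junction_id`, `delta_psi`, `control_presence`,
#'   `significant`, `cryptic`, `category`.
#' @examples
#' sim <- gen_junction_table(sim_config(seed = 1, n_junctions = 40))
#' calls <- classify_junctions(sim$junctions, sim$groups, sim$annotation)
#' table(calls$category)
#' @export
classify_junctions <- function(junctions, groups, annotation,
                               dpsi_threshold = 0.10, low_presence = 0.05,
                               high_presence = 0.10, detect_psi_min = 0.01) {
  samp <- names(groups)
  missing_cols <- setdiff(samp, names(junctions))
  if (length(missing_cols))
    stop("junction table lacks PSI columns: ",
         paste(missing_cols, collapse = ", "))
  psi <- as.matrix(junctions[, samp, drop = FALSE])
  dpsi <- apply(psi, 1, delta_psi, groups = groups)
  pres <- apply(psi, 1, control_presence, groups = groups,
                detect_psi_min = detect_psi_min)
  flags <- call_cryptic(dpsi, pres, dpsi_threshold, low_presence,
                        high_presence)
  category <- categorize_junctions(junctions, annotation)
  out <- data.frame(junction_id = junctions$junction_id, delta_psi = dpsi,
                    control_presence = pres, significant = flags$significant,
                    cryptic = flags$cryptic, category = category,
                    stringsAsFactors = FALSE)
  skipped <- out$junction_id[is.na(dpsi)]
  out <- out[!is.na(out$delta_psi), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
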