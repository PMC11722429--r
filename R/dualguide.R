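#' Classify a single dual-guide read pair
#'
#' A pair is `matched` when read 1 contains a known guide-A and read 2 a
#' known guide-B belonging to the same construct (by default; see
#' `same_gene_ok`), `recombined` when both guides are found but belong to
#' different constructs, and `unmapped` otherwise.  Detection is exact
#' substring match within the configured window — no mismatches are
#' tolerated, the conservative default when the sequencing architecture
#' places guides at fixed but unspecified offsets.
#'
#' @param read1_seq,read2_seq Read sequences (character scalars).
#' @param library A guide library data frame.
#' @param search_window Optional `c(start, end)` 1-based window within each
#'   read to search; default the whole read.
#' @param same_gene_ok If `TRUE`, pairs whose two guides come from
#'   different constructs targeting the same gene count as matched (to the
#'   guide-A construct).  Default `FALSE`: "same target gene" is read
#'   strictly as "same construct".
#' @return A list with `outcome` in \{matched, recombined, unmapped\} and
#'   `construct_id` (NA unless matched).
#' @examples
#' lib <- sim_guide_library(n_genes = 3, n_nt = 0, seed = 1)
#' match_read_pair(paste0("AC", lib$guide_a_seq[1]),
#'                 paste0("TG", lib$guide_b_seq[1]), lib)$outcome
#' @export
match_read_pair <- function(read1_seq, read2_seq, library,
                            search_window = NULL, same_gene_ok = FALSE) {
  res <- match_read_pairs(read1_seq, read2_seq, library,
                          search_window = search_window,
                          same_gene_ok = same_gene_ok)
  list(outcome = res$outcome[1], construct_id = res$construct_id[1])
}

#' Vectorized read-pair matching
#'
#' @inheritParams match_read_pair
#' @param reads1,reads2 Character vectors of equal length.
#' @return A data frame with one row per pair: `outcome` and `construct_id`.
#' @export
match_read_pairs <- function(reads1, reads2, library, search_window = NULL,
                             same_gene_ok = FALSE) {
  validate_guide_library(library)
  if (length(reads1) != length(reads2))
    stop("read streams differ in length: ", length(reads1), " vs ",
         length(reads2))
  a <- find_guide_hits(reads1, library$guide_a_seq, search_window)
  b <- find_guide_hits(reads2, library$guide_b_seq, search_window)
  outcome <- rep("unmapped", length(reads1))
  both <- !is.na(a) & !is.na(b)
  same <- both & a == b
  if (same_gene_ok) {
    same_gene <- both & !same &
      library$target_gene[pmax(a, 1L)] == library$target_gene[pmax(b, 1L)] &
      !library$is_nt[pmax(a, 1L)]
    same <- same | same_gene
  }
  outcome[both & !same] <- "recombined"
  outcome[same] <- "matched"
  data.frame(outcome = outcome,
             construct_id = ifelse(same, library$construct_id[a],
                                   NA_character_),
             stringsAsFactors = FALSE)
}

# Exact-substring guide lookup: for each read, the index of the (unique)
# guide it contains, or NA.  Scans every offset with a vectorized hash
# lookup, so cost is O(read_length) vector operations, not O(n_guides).
find_guide_hits <- function(reads, guides, search_window = NULL) {
  reads <- as.character(reads)
  reads[is.na(reads)] <- ""
  if (!is.null(search_window)) {
    stopifnot(length(search_window) == 2L, search_window[1] >= 1L)
    reads <- substr(reads, search_window[1], search_window[2])
  }
  hit <- rep(NA_integer_, length(reads))
  if (!length(reads)) return(hit)
  for (L in unique(nchar(guides))) {
    in_len <- which(nchar(guides) == L)
    max_off <- max(nchar(reads)) - L + 1L
    if (max_off < 1L) next
    for (o in seq_len(max_off)) {
      m <- match(substr(reads, o, o + L - 1L), guides[in_len])
      fill <- is.na(hit) & !is.na(m)
      hit[fill] <- in_len[m[fill]]
    }
  }
  hit
}

#' Count matched construct pairs in two sorted-bin FASTQ streams
#'
#' Parses the low- and high-fluorescence bins of a FACS screen, discards
#' recombined and unmapped pairs, and tabulates matched pairs per construct.
#'
#' @param fastq_low,fastq_high Either paths to paired FASTQ files
#'   (`list(r1 = , r2 = )` or a length-2 character vector) or in-memory
#'   lists with elements `read1` and `read2` as returned by
#'   [gen_dual_guide_reads()].
#' @inheritParams match_read_pair
#' @return A list with `counts` (data frame `construct_id`, `count_low`,
#'   `count_high`) and `stats` (data frame with one row per bin:
#'   `bin`, `n_pairs_total`, `n_matched`, `n_recombined`, `n_unmapped`).
#' @export
count_constructs <- function(fastq_low, fastq_high, library,
                             search_window = NULL, same_gene_ok = FALSE) {
  validate_guide_library(library)
  one_bin <- function(input, bin) {
    pr <- as_read_pairs(input)
    res <- match_read_pairs(pr$read1, pr$read2, library,
                            search_window = search_window,
                            same_gene_ok = same_gene_ok)
    tab <- table(factor(res$construct_id, levels = library$construct_id))
    stats <- data.frame(
      bin = bin, n_pairs_total = nrow(res),
      n_matched = sum(res$outcome == "matched"),
      n_recombined = sum(res$outcome == "recombined"),
      n_unmapped = sum(res$outcome == "unmapped"),
      stringsAsFactors = FALSE)
    list(counts = as.integer(tab), stats = stats)
  }
  lo <- one_bin(fastq_low, "low")
  hi <- one_bin(fastq_high, "high")
  list(counts = data.frame(construct_id = library$construct_id,
                           count_low = lo$counts, count_high = hi$counts,
                           stringsAsFactors = FALSE),
       stats = rbind(lo$stats, hi$stats))
}

as_read_pairs <- function(input) {
  if (is.list(input) && !is.null(input$read1) && !is.null(input$read2))
    return(list(read1 = input$read1, read2 = input$read2))
  if (is.list(input) && !is.null(input$r1))
    input <- c(input$r1, input$r2)
  if (is.character(input) && length(input) == 2L &&
      all(file.exists(input))) {
    r1 <- read_fastq_seqs(input[1])
    r2 <- read_fastq_seqs(input[2])
    if (length(r1) != length(r2))
      stop("malformed FASTQ pair: ", length(r1), " reads in ", input[1],
           " vs ", length(r2), " in ", input[2])
    return(list(read1 = r1, read2 = r2))
  }
  stop("expected a list with read1/read2 or two FASTQ paths")
}

#' Drop constructs with too few reads across both bins
#'
#' @param table A construct count table (`construct_id`, `count_low`,
#'   `count_high`).
#' @param min_total Minimum `count_low + count_high` to keep (default 10).
#' @return The filtered table.  Warns when nothing survives.
#' @export
filter_low_count <- function(table, min_total = 10L) {
  stopifnot(min_total >= 0)
  keep <- (table$count_low + table$count_high) >= min_total
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("all constructs fall below min_total = ", min_total)
  rownames(out) <- NULL
  out
}

#' Permutation-based gene scoring of a construct count table
#'
#' A deliberately simple scorer used to run the synthetic pipeline end to
#' end (production screens use dedicated rank-aggregation tools).  Counts
#' are normalized per bin to counts-per-million, each construct gets the
#' effect `log2((cpm_high + 1) / (cpm_low + 1))`, and a gene's effect is the
#' median over its constructs.  The two-sided p-value is the fraction of
#' `n_perm` random same-size construct sets (sampled from all constructs,
#' without replacement within a set) whose |median effect| is at least the
#' observed one, with the +1 correction that makes permutation p-values
#' valid (sub-uniform under the null).
#'
#' @param table Construct count table (`construct_id`, `count_low`,
#'   `count_high`).
#' @param library Guide library; non-targeting constructs enter the
#'   permutation pool but are not scored as genes.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param pseudocount Added to both CPM values before the log ratio.
#' @return A screen result table: `gene_id`, `effect`, `p_raw`,
#'   `n_constructs`.  Genes with no surviving constructs are omitted with a
#'   warning.
#' @export
score_genes_permutation <- function(table, library, n_perm = 1000L,
                                    seed = 1L, pseudocount = 1) {
  validate_guide_library(library)
  tot_low <- sum(table$count_low)
  tot_high <- sum(table$count_high)
  if (tot_low == 0 || tot_high == 0)
    stop("a bin has zero total counts; cannot normalize")
  cpm_low <- table$count_low / tot_low * 1e6
  cpm_high <- table$count_high / tot_high * 1e6
  eff <- log2((cpm_high + pseudocount) / (cpm_low + pseudocount))

  gene <- library$target_gene[match(table$construct_id,
                                    library$construct_id)]
  is_nt <- library$is_nt[match(table$construct_id, library$construct_id)]
  scored <- !is.na(gene) & !is_nt
  missing_genes <- setdiff(library$target_gene[!library$is_nt],
                           gene[scored])
  if (length(missing_genes))
    warning(length(missing_genes),
            " gene(s) had no constructs after filtering and were omitted")
  by_gene <- split(eff[scored], gene[scored])
  obs <- vapply(by_gene, median, numeric(1))
  sizes <- vapply(by_gene, length, integer(1))

  with_seed(substream_seed(seed, "score"), {
    null_by_size <- lapply(
      stats::setNames(nm = sort(unique(sizes))),
      function(m) {
        m <- as.integer(m)
        vapply(seq_len(n_perm), function(i) {
          median(eff[sample.int(length(eff), m)])
        }, numeric(1))
      })
    p <- vapply(seq_along(obs), function(i) {
      null <- null_by_size[[as.character(sizes[i])]]
      (1 + sum(abs(null) >= abs(obs[i]))) / (n_perm + 1)
    }, numeric(1))
    data.frame(gene_id = names(obs), effect = unname(obs), p_raw = p,
               n_constructs = unname(sizes), stringsAsFactors = FALSE)
  })
}
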