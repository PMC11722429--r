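#' Simulate a dual-guide CRISPRi library
#'
#' One construct per targeted gene plus a block of non-targeting (NT)
#' controls.  Guide sequences are random 20-mers, unique within each cassette
#' position, as required by the read parser.
#'
#' @param n_genes Number of targeted genes.
#' @param n_nt Number of non-targeting constructs.
#' @param guide_length Guide length in nucleotides.
#' @param constructs_per_gene Constructs per targeted gene.
#' @param seed Integer seed.
#' @return A guide library data frame with columns `construct_id`,
#'   `guide_a_seq`, `guide_b_seq`, `target_gene` and `is_nt`.
#' @examples
#' lib <- sim_guide_library(n_genes = 10, n_nt = 2, seed = 1)
#' head(lib)
#' @export
sim_guide_library <- function(n_genes = 250L, n_nt = 25L, guide_length = 20L,
                              constructs_per_gene = 1L, seed = 1L) {
  with_seed(substream_seed(seed, "library"), {
    n_con <- n_genes * constructs_per_gene + n_nt
    repeat {
      ga <- random_dna(n_con, guide_length)
      gb <- random_dna(n_con, guide_length)
      if (!anyDuplicated(ga) && !anyDuplicated(gb)) break
    }
    gene <- c(rep(sprintf("G%05d", seq_len(n_genes)),
                  each = constructs_per_gene),
              rep("non-targeting", n_nt))
    lib <- data.frame(
      construct_id = sprintf("C%05d", seq_len(n_con)),
      guide_a_seq = ga, guide_b_seq = gb, target_gene = gene,
      is_nt = gene == "non-targeting", stringsAsFactors = FALSE)
    validate_guide_library(lib)
    lib
  })
}

validate_guide_library <- function(library) {
  need <- c("construct_id", "guide_a_seq", "guide_b_seq", "target_gene",
            "is_nt")
  if (!all(need %in% names(library)))
    stop("guide library must have columns: ", paste(need, collapse = ", "))
  if (nrow(library) == 0L) stop("guide library is empty")
  if (anyDuplicated(library$guide_a_seq))
    stop("guide_a_seq must be unique across constructs")
  if (anyDuplicated(library$guide_b_seq))
    stop("guide_b_seq must be unique across constructs")
  if (!all(library$is_nt == (library$target_gene == "non-targeting")))
    stop("is_nt flag must match target_gene == 'non-targeting'")
  invisible(library)
}

#' Read a guide library TSV
#'
#' Expects the columns `construct_id`, `guide_a_seq`, `guide_b_seq`,
#' `target_gene`, `is_nt` and validates the position-wise uniqueness
#' invariants.
#'
#' @param path Path to the library TSV.
#' @return A validated guide library data frame.
#' @export
read_guide_library <- function(path) {
  lib <- read_tsv_table(path)
  lib$is_nt <- as.logical(lib$is_nt)
  validate_guide_library(lib)
  lib
}

#' Simulate paired dual-guide reads with lentiviral recombination
#'
#' Each read pair is assigned a construct (optionally with per-construct
#' weights, e.g. to plant depletion or enrichment in a sorted bin).  With
#' probability `cfg$recombination_rate` the guide-B read is swapped for the
#' guide-B of a different construct targeting a different gene, emulating
#' template switching during lentiviral packaging.  Guides are embedded at a
#' fixed offset behind a short random flank, with random flanking sequence
#' after them.
#'
#' @param cfg A [sim_config()] object (`n_reads`, `recombination_rate`).
#' @param library A guide library data frame (see [sim_guide_library()]).
#' @param construct_weights Optional sampling weights, one per construct.
#' @param stage Substream label, so distinct bins drawn from the same seed
#'   are independent.
#' @return A list with `read1` and `read2` (named character vectors of read
#'   sequences) and `truth`: `counts` (data frame `construct_id`,
#'   `truth_count` of non-recombined pairs per construct) and
#'   `n_recombined`, the realized number of recombined pairs.
#' @examples
#' lib <- sim_guide_library(n_genes = 5, n_nt = 1, seed = 1)
#' rd <- gen_dual_guide_reads(sim_config(seed = 1, n_reads = 100,
#'                                       recombination_rate = 0), lib)
#' rd$truth$n_recombined
#' @export
gen_dual_guide_reads <- function(cfg, library, construct_weights = NULL,
                                 stage = "reads") {
  stopifnot(inherits(cfg, "sim_config"))
  validate_guide_library(library)
  n_con <- nrow(library)
  if (!is.null(construct_weights) && length(construct_weights) != n_con)
    stop("construct_weights must have one weight per construct")
  with_seed(substream_seed(cfg$seed, stage), {
    n <- cfg$n_reads
    ci <- sample.int(n_con, n, replace = TRUE, prob = construct_weights)
    recomb <- runif(n) < cfg$recombination_rate
    bi <- ci
    if (any(recomb)) {
      idx <- which(recomb)
      genes <- library$target_gene
      if (length(unique(genes)) < 2L)
        stop("recombination requires constructs targeting >= 2 distinct genes")
      for (i in idx) {
        other <- which(genes != genes[ci[i]])
        bi[i] <- if (length(other) == 1L) other else sample(other, 1L)
      }
    }
    flank <- function(k) random_dna(n, k)
    read1 <- paste0(flank(4L), library$guide_a_seq[ci], flank(6L))
    read2 <- paste0(flank(4L), library$guide_b_seq[bi], flank(6L))
    ids <- sprintf("read_%06d", seq_len(n))
    names(read1) <- ids
    names(read2) <- ids
    counts <- data.frame(
      construct_id = library$construct_id,
      truth_count = tabulate(ci[!recomb], nbins = n_con),
      stringsAsFactors = FALSE)
    list(read1 = read1, read2 = read2,
         truth = list(counts = counts, n_recombined = sum(recomb)))
  })
}

#' Write simulated read pairs as a pair of FASTQ files
#'
#' @param reads A list as returned by [gen_dual_guide_reads()].
#' @param prefix Output prefix; files `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` are written (add `.gz` to compress).
#' @param gzip Compress the output.
#' @return Character vector of the two paths, invisibly.
#' @export
write_read_pairs <- function(reads, prefix, gzip = FALSE) {
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_R1", "_R2"), ext)
  for (i in 1:2) {
    seqs <- reads[[i]]
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- names(seqs)
    quals <- Biostrings::PhredQuality(
      vapply(nchar(seqs), function(w) strrep("I", w), character(1)))
    qx <- Biostrings::QualityScaledDNAStringSet(x, quals)
    Biostrings::writeQualityScaledXStringSet(qx, paths[i], compress = gzip)
  }
  invisible(paths)
}

#' Read a FASTQ file into a named character vector of sequences
#'
#' @param path Path to a FASTQ (optionally gzipped) file.
#' @return Named character vector of read sequences.
#' @export
read_fastq_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
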