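#' @keywords internal
"_PACKAGE"

#' @importFrom stats loess median p.adjust pnorm predict qnorm rbinom rlnorm
#'   rnbinom rnorm runif sd t.test wilcox.test rbeta
#' @importFrom utils read.delim write.table combn
NULL

# Derive a reproducible per-stage seed from the global seed so that each
# generator draws from an independent substream.  Kept below 2^31 - 1.
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 69621) %% 2147483647)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Read a tab-separated table
#'
#' Thin wrapper around [utils::read.delim()] with the conventions used by
#' every table in this package (no factors, header row, tab separator).
#'
#' @param path Path to a TSV file.
#' @return A data frame.
#' @export
read_tsv_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a tab-separated table
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
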