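#' @importFrom rlang .data abort warn .env
#' @importFrom stats setNames
NULL

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. seed = NULL means "use the ambient RNG".
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Documented stage-seed derivation: sub-seeds are offset from the master seed
# by a fixed prime multiple of the stage index, kept inside 32-bit range so
# stages can be rerun in isolation.
derive_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) + 7919 * stage_index) %% .Machine$integer.max)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_bad_arg <- function(msg, ...) abort(sprintf(msg, ...), class = "methylodecode_error")

site_key <- function(chrom, pos, strand) paste(chrom, pos, strand, sep = ":")

DNA_BASES <- c("A", "C", "G", "T")

# character vector of equal-length sequences -> M x N character matrix
seqs_to_matrix <- function(seqs) {
  if (is.matrix(seqs)) return(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop_bad_arg("sequences must all have the same length (saw widths %s)",
                 paste(unique(widths), collapse = ", "))
  }
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), byrow = TRUE)
}

reverse_complement_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
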