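#' @importFrom stats rbinom rnorm rpois runif median setNames quantile
#' @importFrom utils write.table read.table head tail
NULL

.datatable.aware <- TRUE

DNA_BASES <- c("A", "C", "G", "T")

#' Generate a uniform-random DNA sequence
#'
#' @param n Sequence length in bases.
#' @return A character scalar of length-`n` DNA.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse-complement a DNA string
#' @param x Character scalar (ACGT alphabet).
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Shannon entropy of overlapping dinucleotides
#'
#' Used as a low-complexity filter on soft-clipped sequences: homopolymers and
#' simple repeats have entropy well below 1 bit, random sequence close to 4.
#'
#' @param x Character scalar DNA sequence.
#' @return Entropy in bits.
#' @export
dinucleotide_entropy <- function(x) {
  n <- nchar(x)
  if (n < 2L) return(0)
  ch <- seq_chars(x)
  din <- paste0(ch[-n], ch[-1L])
  p <- table(din) / (n - 1L)
  -sum(p * log2(p))
}

## Derive a per-stage seed from a master seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Write a BED file (0-based half-open)
#' @param df Data frame with columns contig, start, end, name, score, strand.
#' @param path Output path.
#' @keywords internal
write_bed <- function(df, path) {
  bed <- df[, c("contig", "start", "end", "name", "score", "strand")]
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(seqs)), path, width = 80L)
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

## Fixed nucleotide scoring (match 1, mismatch -1); computed once.
dna_score_matrix <- local({
  mat <- NULL
  function() {
    if (is.null(mat))
      mat <<- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                       mismatch = -1)
    mat
  }
})

stopifnot_scalar_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(what, " must be a single value in [0, 1]", call. = FALSE)
}
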