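#' Write simulated alignments to a SAM file
#'
#' Emits a coordinate-sorted SAM 1.6 file with `@SQ` lines for every host and
#' library contig and the generating seed recorded in a `@CO` line.
#'
#' @param aln An `erv_alignments` object from [simulate_alignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path) {
  seqinfo <- attr(aln, "seqinfo")
  cfg <- attr(aln, "read_cfg")
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(seqinfo), seqinfo),
    "@PG\tID:ervcensus\tPN:ervcensus",
    sprintf("@CO\tseed=%d individual=%s", cfg$seed,
            attr(aln, "individual")))
  qual <- vapply(nchar(aln$seq), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  body <- paste(aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq, aln$cigar,
                aln$rnext, aln$pnext, aln$tlen, aln$seq, qual, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a SAM file into an alignment table
#'
#' Conversion and parsing go through Rsamtools (`asBam`/`scanBam`); the
#' result has the same columns as [simulate_alignments()] output.
#'
#' @param path SAM file path.
#' @return An `erv_alignments` data frame with a `seqinfo` attribute.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
             "mrnm", "mpos", "isize", "seq"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  aln <- data.frame(
    qname = x$qname, flag = x$flag, rname = as.character(x$rname),
    pos = x$pos, mapq = x$mapq, cigar = x$cigar,
    rnext = ifelse(is.na(x$mrnm) | as.character(x$mrnm) ==
                     as.character(x$rname), "=", as.character(x$mrnm)),
    pnext = x$mpos, tlen = x$isize,
    seq = as.character(x$seq), stringsAsFactors = FALSE)
  structure(aln, class = c("erv_alignments", "data.frame"), seqinfo = hdr)
}

## Split a CIGAR into leading clip, matched length and trailing clip.
## The simulator only emits [S]M[S] patterns.
parse_cigar <- function(cigar) {
  lead <- integer(length(cigar))
  has_lead <- grepl("^[0-9]+S", cigar)
  lead[has_lead] <- as.integer(sub("^([0-9]+)S.*$", "\\1", cigar[has_lead]))
  trail <- integer(length(cigar))
  has_trail <- grepl("[0-9]+S$", cigar)
  trail[has_trail] <- as.integer(sub("^.*?([0-9]+)S$", "\\1",
                                     cigar[has_trail]))
  m <- as.integer(sub("^(?:[0-9]+S)?([0-9]+)M.*$", "\\1", cigar))
  data.frame(lead_clip = lead, match_len = m, trail_clip = trail)
}
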