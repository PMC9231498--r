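#' Find candidate LTR pairs in a contig
#'
#' Desk-scale provirus screen: seeds exact k-mer anchors (k = 12) shared
#' between two positions of the contig whose separation falls in the expected
#' element length range, chains anchors on near-constant diagonals, and keeps
#' chains whose two repeat copies align at or above `min_identity`. Candidate
#' pairs are non-overlapping, ordered leftmost-first then longest.
#'
#' @param contig_seq Character scalar.
#' @param min_ltr_len Minimum LTR length (>= 50).
#' @param ltr_len_max Maximum LTR length.
#' @param element_len_range Length-2 numeric: admissible distance between the
#'   starts of the 5' and 3' LTR copies.
#' @param min_identity Minimum global alignment identity between the two
#'   repeat copies (>= 0.7).
#' @param k Anchor k-mer size.
#' @param min_anchors Minimum chained anchors per candidate.
#' @return Data frame with 0-based half-open intervals `ltr5_start`,
#'   `ltr5_end`, `ltr3_start`, `ltr3_end` and `identity`; zero rows when
#'   nothing is found.
#' @export
find_ltr_pairs <- function(contig_seq, min_ltr_len = 100L,
                           ltr_len_max = 1500L,
                           element_len_range = c(4000L, 15000L),
                           min_identity = 0.85, k = 12L, min_anchors = 5L) {
  stopifnot(min_ltr_len >= 50L, min_identity >= 0.7)
  n <- nchar(contig_seq)
  if (n < element_len_range[1]) return(empty_ltr_pairs())

  starts <- seq_len(n - k + 1L)
  kmers <- substring(contig_seq, starts, starts + k - 1L)
  dt <- data.table::data.table(kmer = kmers, pos = starts - 1L)
  dup <- dt[, .N, by = "kmer"][N > 1L & N <= 50L]
  dt <- dt[dt$kmer %in% dup$kmer]
  if (!nrow(dt)) return(empty_ltr_pairs())
  anchors <- merge(dt, dt, by = "kmer", allow.cartesian = TRUE,
                   suffixes = c("_a", "_b"))
  anchors <- anchors[anchors$pos_b - anchors$pos_a >= element_len_range[1] &
                     anchors$pos_b - anchors$pos_a <= element_len_range[2], ]
  if (!nrow(anchors)) return(empty_ltr_pairs())
  anchors$diag <- anchors$pos_b - anchors$pos_a
  anchors <- anchors[order(anchors$pos_a), ]

  ## single-linkage chaining: successive anchors join a chain when both the
  ## position gap and the diagonal drift are small
  chains <- chain_anchors(anchors$pos_a, anchors$diag,
                          max_gap = 200L, band = 50L)
  cand <- list()
  for (ch in chains) {
    if (length(ch) < min_anchors) next
    p1 <- anchors$pos_a[ch]; p2 <- anchors$pos_b[ch]
    l5 <- c(min(p1), max(p1) + k)
    l3 <- c(min(p2), max(p2) + k)
    len5 <- l5[2] - l5[1]; len3 <- l3[2] - l3[1]
    if (len5 < min_ltr_len || len5 > ltr_len_max ||
        len3 < min_ltr_len || len3 > ltr_len_max) next
    s5 <- substr(contig_seq, l5[1] + 1L, l5[2])
    s3 <- substr(contig_seq, l3[1] + 1L, l3[2])
    ident <- 1 - pairwise_p_distance(s5, s3)
    if (is.na(ident) || ident < min_identity) next
    cand[[length(cand) + 1L]] <- data.frame(
      ltr5_start = l5[1], ltr5_end = l5[2],
      ltr3_start = l3[1], ltr3_end = l3[2],
      identity = ident)
  }
  if (!length(cand)) return(empty_ltr_pairs())
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$ltr5_start, -(cand$ltr3_end - cand$ltr5_start)), ,
               drop = FALSE]
  ## greedy non-overlap selection, leftmost-first then longest
  keep <- logical(nrow(cand)); last_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$ltr5_start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- cand$ltr3_end[i]
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_ltr_pairs <- function() {
  data.frame(ltr5_start = integer(), ltr5_end = integer(),
             ltr3_start = integer(), ltr3_end = integer(),
             identity = numeric())
}

chain_anchors <- function(pos, diag, max_gap, band) {
  n <- length(pos)
  if (!n) return(list())
  ## order by diagonal then position; break chains on large jumps in either
  o <- order(diag, pos)
  pos <- pos[o]; diag <- diag[o]
  brk <- c(TRUE, abs(diff(diag)) > band | abs(diff(pos)) > max_gap)
  grp <- cumsum(brk)
  split(o, grp)
}

#' Detect a target site duplication around an element
#'
#' Returns the longest `k <= max_tsd` such that the `k` bases immediately 5'
#' of the element exactly equal the `k` bases immediately 3' of it. At a
#' contig edge the search runs over the available flank only.
#'
#' @param contig_seq Character scalar.
#' @param element_interval 0-based half-open `c(start, end)`.
#' @param max_tsd Maximum TSD length considered (default 20).
#' @return List with `tsd_len` and `tsd_seq` (`0` / `""` when none).
#' @examples
#' detect_tsd(paste0("ACGTAG", strrep("T", 30), "ACGTAG"), c(6, 36))
#' @export
detect_tsd <- function(contig_seq, element_interval, max_tsd = 20L) {
  start <- element_interval[1]; end <- element_interval[2]
  n <- nchar(contig_seq)
  lim <- min(max_tsd, start, n - end)
  for (k in rev(seq_len(max(lim, 0L)))) {
    left <- substr(contig_seq, start - k + 1L, start)
    right <- substr(contig_seq, end + 1L, end + k)
    if (left == right) return(list(tsd_len = k, tsd_seq = left))
  }
  list(tsd_len = 0L, tsd_seq = "")
}

#' Profile the coding genes of an element against a template
#'
#' Globally aligns the element to the full template (affine gaps) and reports
#' per gene: identity over aligned columns, premature stop codons counted in
#' the template frame, and frame-disrupting indel events (net length not a
#' multiple of 3). A gene whose aligned identity falls below
#' `detect_threshold` is reported as undetected rather than as mutation-free.
#'
#' @param element_seq Character scalar (full element, LTR to LTR).
#' @param template A [provirus_template()].
#' @param detect_threshold Minimum aligned identity for a gene to count as
#'   detected (default 0.4).
#' @return Named list (gag/pro/pol/env) of lists with `detected`,
#'   `identity`, `n_stops`, `n_frameshifts`.
#' @export
profile_genes <- function(element_seq, template, detect_threshold = 0.4) {
  tpl_seq <- template_sequence(template)
  ## gap extension is kept expensive: short biological indels still gap, but
  ## an unrelated region cannot inflate its aligned-column identity by
  ## gapping around mismatches (random DNA then aligns near 0.33, safely
  ## below the 0.4 detection threshold)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(tpl_seq), Biostrings::DNAString(element_seq),
    type = "global", substitutionMatrix = dna_score_matrix(),
    gapOpening = 10, gapExtension = 4)
  t_al <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  e_al <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  ## template position (0-based) per column; NA on template gaps
  t_pos <- ifelse(t_al != "-", cumsum(t_al != "-") - 1L, NA_integer_)

  out <- list()
  for (g in names(template$gene_map)) {
    iv <- template$gene_map[[g]] + template$ltr_len  # full-sequence coords
    cols <- which(!is.na(t_pos) & t_pos >= iv[1] & t_pos < iv[2])
    if (!length(cols)) {
      out[[g]] <- list(detected = FALSE, identity = NA_real_,
                       n_stops = NA_integer_, n_frameshifts = NA_integer_)
      next
    }
    both <- cols[e_al[cols] != "-"]
    identity <- if (length(both)) mean(t_al[both] == e_al[both]) else 0
    if (identity < detect_threshold) {
      out[[g]] <- list(detected = FALSE, identity = identity,
                       n_stops = NA_integer_, n_frameshifts = NA_integer_)
      next
    }
    ## stops in template frame: element bases gathered per template codon
    codon_starts <- seq(iv[1], iv[2] - 3L, by = 3L)
    col_of <- match(codon_starts, t_pos)
    col_of2 <- match(codon_starts + 1L, t_pos)
    col_of3 <- match(codon_starts + 2L, t_pos)
    codons <- paste0(e_al[col_of], e_al[col_of2], e_al[col_of3])
    tpl_codons <- paste0(t_al[col_of], t_al[col_of2], t_al[col_of3])
    complete <- !grepl("-", codons, fixed = TRUE)
    n_stops <- sum(complete & codons %in% c("TAA", "TAG", "TGA") &
                     !(tpl_codons %in% c("TAA", "TAG", "TGA")))
    ## indel events: runs of element gaps (deletions) at template positions
    ## in the gene, and runs of template gaps (insertions) inside the gene
    n_fs <- count_frameshift_events(t_al, e_al, t_pos, iv)
    out[[g]] <- list(detected = TRUE, identity = identity,
                     n_stops = as.integer(n_stops),
                     n_frameshifts = as.integer(n_fs))
  }
  out
}

count_frameshift_events <- function(t_al, e_al, t_pos, iv) {
  in_gene_col <- function(i) {
    p <- t_pos[i]
    !is.na(p) && p >= iv[1] && p < iv[2]
  }
  ncol <- length(t_al)
  n_fs <- 0L
  i <- 1L
  while (i <= ncol) {
    if (e_al[i] == "-" && in_gene_col(i)) {
      j <- i
      while (j < ncol && e_al[j + 1L] == "-" && in_gene_col(j + 1L))
        j <- j + 1L
      if ((j - i + 1L) %% 3L != 0L) n_fs <- n_fs + 1L
      i <- j + 1L
    } else if (t_al[i] == "-") {
      ## insertion: assign to gene of the last template position seen
      prev <- max(which(!is.na(t_pos[seq_len(i)])), 0L)
      inside <- prev > 0L && t_pos[prev] >= iv[1] && t_pos[prev] < iv[2] - 1L
      j <- i
      while (j < ncol && t_al[j + 1L] == "-") j <- j + 1L
      if (inside && (j - i + 1L) %% 3L != 0L) n_fs <- n_fs + 1L
      i <- j + 1L
    } else i <- i + 1L
  }
  n_fs
}

#' Classify the structure of one annotated element
#'
#' Combines LTR-pair detection, TSD detection and gene profiling into a
#' provirus annotation. Full length requires both LTRs and all of gag, pro,
#' pol, env detected.
#'
#' @param contig Contig id.
#' @param contig_seq Contig sequence.
#' @param ltr_pair One row of [find_ltr_pairs()] output (or a list with the
#'   same fields); pass `NULL` together with `solo_ltr_interval` for a solo
#'   LTR.
#' @param template A [provirus_template()] for gene profiling.
#' @param solo_ltr_interval Optional 0-based half-open interval of a lone
#'   LTR-like repeat.
#' @param max_tsd Maximum TSD length searched.
#' @return An object of class `provirus_annotation`: contig,
#'   `element_interval`, `ltr5_interval`, `ltr3_interval`, `ltr_identity`,
#'   `strand` (orientation of the element relative to the template),
#'   `tsd_len`, `tsd_seq`, `structure_tokens`, `full_length`, `solo_ltr`,
#'   `genes` (the [profile_genes()] result, `NULL` for solo LTRs).
#' @export
classify_structure <- function(contig, contig_seq, ltr_pair, template,
                               solo_ltr_interval = NULL, max_tsd = 20L) {
  if (is.null(ltr_pair)) {
    stopifnot(!is.null(solo_ltr_interval))
    tsd <- detect_tsd(contig_seq, solo_ltr_interval, max_tsd)
    return(structure(list(
      contig = contig, element_interval = solo_ltr_interval,
      ltr5_interval = solo_ltr_interval, ltr3_interval = NULL,
      ltr_identity = NA_real_, tsd_len = tsd$tsd_len, tsd_seq = tsd$tsd_seq,
      structure_tokens = "5LTR", full_length = FALSE, solo_ltr = TRUE,
      genes = NULL), class = "provirus_annotation"))
  }
  element_interval <- c(ltr_pair$ltr5_start, ltr_pair$ltr3_end)
  ## NB: when a flanking base coincidentally equals the opposite LTR end the
  ## detected boundary (and hence the TSD length) is ambiguous by 1-2 bases;
  ## the TSD at the detected boundary is reported as-is
  tsd <- detect_tsd(contig_seq, element_interval, max_tsd)
  elem_seq <- substr(contig_seq, element_interval[1] + 1L,
                     element_interval[2])
  ## orientation: proviruses integrate on either strand; profile the strand
  ## whose leading LTR is closer to the template LTR
  strand <- "+"
  lead <- substr(elem_seq, 1L, template$ltr_len)
  rc_seq <- revcomp(elem_seq)
  if (pairwise_p_distance(substr(rc_seq, 1L, template$ltr_len),
                          template$ltr) <
      pairwise_p_distance(lead, template$ltr)) {
    strand <- "-"
    elem_seq <- rc_seq
  }
  genes <- profile_genes(elem_seq, template)
  detected <- names(genes)[vapply(genes, function(g)
    isTRUE(g$detected), logical(1))]
  tokens <- c("5LTR", intersect(c("gag", "pro", "pol", "env"), detected),
              "3LTR")
  structure(list(
    contig = contig, element_interval = element_interval,
    ltr5_interval = c(ltr_pair$ltr5_start, ltr_pair$ltr5_end),
    ltr3_interval = c(ltr_pair$ltr3_start, ltr_pair$ltr3_end),
    ltr_identity = ltr_pair$identity, strand = strand,
    tsd_len = tsd$tsd_len, tsd_seq = tsd$tsd_seq,
    structure_tokens = tokens,
    full_length = all(c("gag", "pro", "pol", "env") %in% detected),
    solo_ltr = FALSE, genes = genes), class = "provirus_annotation")
}

#' Annotate all proviruses in an assembly
#'
#' Runs [find_ltr_pairs()] per contig and [classify_structure()] per
#' candidate.
#'
#' @param assembly Named character vector of contig sequences.
#' @param template A [provirus_template()].
#' @param ... Passed to [find_ltr_pairs()].
#' @return List of `provirus_annotation` objects.
#' @export
annotate_assembly <- function(assembly, template, ...) {
  out <- list()
  for (ctg in names(assembly)) {
    pairs <- find_ltr_pairs(assembly[[ctg]], ...)
    for (i in seq_len(nrow(pairs))) {
      out[[length(out) + 1L]] <- classify_structure(
        ctg, assembly[[ctg]], pairs[i, ], template)
    }
  }
  out
}

#' Tabulate provirus annotations
#'
#' @param annotations List of `provirus_annotation`.
#' @return Data frame (contig, start, end, ltr_identity, tsd_len,
#'   structure_tokens, full_length).
#' @export
annotation_table <- function(annotations) {
  if (!length(annotations)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), ltr_identity = numeric(),
                      tsd_len = integer(), structure_tokens = character(),
                      full_length = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(annotations, function(a) data.frame(
    contig = a$contig, start = a$element_interval[1],
    end = a$element_interval[2], ltr_identity = a$ltr_identity,
    tsd_len = a$tsd_len,
    structure_tokens = paste(a$structure_tokens, collapse = ","),
    full_length = a$full_length, stringsAsFactors = FALSE)))
}
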