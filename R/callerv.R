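#' Filter policy for ERV presence/absence calling
#'
#' Two regimes mirror the discovery-vs-typing distinction: high-coverage
#' samples require 5 supporting reads, low-coverage 2; the stringent tier
#' additionally requires >= 2 clipped reads on each side of the breakpoint
#' and total support within a coverage sanity window (<= 5x coverage). The
#' relaxed tier (used for typing loci across individuals) requires
#' `relaxed_min` total supporting reads.
#'
#' @param sample_class `"hc"` (high coverage, min 5 reads) or `"lc"` (low
#'   coverage, min 2 reads).
#' @param coverage Sample mean coverage (x).
#' @param relaxed_min Relaxed-tier minimum total support (default 2).
#' @param min_clip_each_side Stringent-tier per-side clip minimum (default 2).
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(sample_class = c("hc", "lc"), coverage,
                          relaxed_min = 2L, min_clip_each_side = 2L) {
  sample_class <- match.arg(sample_class)
  min_reads <- if (sample_class == "hc") 5L else 2L
  stopifnot(min_reads >= relaxed_min, min_clip_each_side >= 0L)
  structure(list(sample_class = sample_class, min_reads = min_reads,
                 relaxed_min = as.integer(relaxed_min),
                 min_clip_each_side = as.integer(min_clip_each_side),
                 coverage = coverage),
            class = "filter_policy")
}

#' Extract insertion evidence from alignments
#'
#' Collects (i) soft-clipped reads on host contigs whose clipped tail (>=
#' `min_clip` bases, passing a dinucleotide-entropy low-complexity filter)
#' locally aligns to a library LTR on either strand at >=
#' `clip_match_identity` with at least `min_score` matching bases, and (ii)
#' discordant pairs: host-anchored reads whose mates map to library contigs.
#' Records on library contigs themselves are ignored.
#'
#' @param aln An `erv_alignments` data frame (coordinate-sorted).
#' @param library An [erv_library()] (needs `$ltrs`).
#' @param min_clip Minimum clip length (default 10).
#' @param clip_match_identity Minimum identity of the clip-to-LTR local
#'   alignment (default 0.8).
#' @param min_score Minimum matching bases in the local alignment
#'   (default 10).
#' @param min_entropy Minimum dinucleotide entropy of a clip, in bits
#'   (default 1).
#' @return An `erv_evidence` list: `softclips` (contig, clip_point (0-based),
#'   side "5"/"3", len, lineage, qname), `discordant` (contig, pos =
#'   junction-proximal anchor edge, side, lineage, qname).
#' @export
extract_evidence <- function(aln, library, min_clip = 10L,
                             clip_match_identity = 0.8, min_score = 10L,
                             min_entropy = 1.0) {
  stopifnot(is.data.frame(aln))
  if (nrow(aln) &&
      any(vapply(split(aln$pos, aln$rname), is.unsorted, logical(1))))
    stop("alignments must be coordinate-sorted", call. = FALSE)
  host <- aln[!is_library_contig(aln$rname), , drop = FALSE]

  softclips <- empty_softclips()
  if (nrow(host)) {
    cg <- parse_cigar(host$cigar)
    lead <- which(cg$lead_clip >= min_clip)
    trail <- which(cg$trail_clip >= min_clip)
    clips <- rbind(
      if (length(lead)) data.frame(
        contig = host$rname[lead], clip_point = host$pos[lead] - 1L,
        side = "3", len = cg$lead_clip[lead],
        clip_seq = substr(host$seq[lead], 1L, cg$lead_clip[lead]),
        qname = host$qname[lead], stringsAsFactors = FALSE),
      if (length(trail)) data.frame(
        contig = host$rname[trail],
        clip_point = host$pos[trail] - 1L + cg$match_len[trail],
        side = "5", len = cg$trail_clip[trail],
        clip_seq = substring(host$seq[trail],
                             nchar(host$seq[trail]) - cg$trail_clip[trail] + 1L),
        qname = host$qname[trail], stringsAsFactors = FALSE))
    if (!is.null(clips) && nrow(clips)) {
      ent <- vapply(clips$clip_seq, dinucleotide_entropy, numeric(1))
      clips <- clips[ent >= min_entropy, , drop = FALSE]
    }
    if (!is.null(clips) && nrow(clips)) {
      m <- match_clips_to_ltrs(clips$clip_seq, library$ltrs,
                               clip_match_identity, min_score)
      clips$lineage <- m$lineage
      softclips <- clips[!is.na(m$lineage),
                         c("contig", "clip_point", "side", "len",
                           "lineage", "qname")]
      rownames(softclips) <- NULL
    }
  }

  ## discordant anchors: a forward-strand host anchor sits 5' of the
  ## insertion (junction at or beyond its end), a reverse-strand anchor 3'
  ## of it; position records the junction-proximal anchor edge
  disc <- host[host$rnext != "=" & is_library_contig(host$rnext), ,
               drop = FALSE]
  dcg <- parse_cigar(disc$cigar)
  fwd <- bitwAnd(disc$flag, 16L) == 0L
  discordant <- data.frame(
    contig = disc$rname,
    pos = ifelse(fwd, disc$pos - 1L + dcg$match_len, disc$pos - 1L),
    side = ifelse(fwd, "5", "3"),
    lineage = sub("^lib_", "", disc$rnext),
    qname = disc$qname, stringsAsFactors = FALSE)
  structure(list(softclips = softclips, discordant = discordant),
            class = "erv_evidence")
}

empty_softclips <- function() {
  data.frame(contig = character(), clip_point = integer(), side = character(),
             len = integer(), lineage = character(), qname = character(),
             stringsAsFactors = FALSE)
}

## Batch local alignment of clip sequences against every library LTR (both
## strands); returns best lineage per clip, NA when no LTR reaches the
## thresholds. Besides identity and score, the local alignment must cover
## >= 80% of the clip: true element-derived clips align end-to-end, while
## chance high-identity islands inside unrelated (host-derived) clips do not.
match_clips_to_ltrs <- function(clip_seqs, ltrs, min_identity, min_score,
                                min_coverage = 0.8) {
  n <- length(clip_seqs)
  best <- rep(NA_integer_, n)
  best_score <- rep(-Inf, n)
  pats <- Biostrings::DNAStringSet(clip_seqs)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  for (i in seq_along(ltrs)) {
    for (subject in c(ltrs[[i]], revcomp(ltrs[[i]]))) {
      al <- Biostrings::pairwiseAlignment(
        pats, Biostrings::DNAString(subject), type = "local",
        substitutionMatrix = mat, gapOpening = 5, gapExtension = 2)
      nm <- Biostrings::nmatch(al)
      alen <- Biostrings::nchar(al)
      ok <- nm >= min_score & nm / pmax(alen, 1L) >= min_identity &
        alen >= min_coverage * nchar(clip_seqs)
      better <- ok & nm > best_score
      best[better] <- i
      best_score[better] <- nm[better]
    }
  }
  list(lineage = names(ltrs)[best], score = best_score)
}

#' Call non-reference ERV insertions from evidence
#'
#' Evidence is clustered within `cluster_window` bp (single linkage) per
#' contig. Per cluster, discovery support counts the clips consistent with
#' the modal clip point of each side (within +/- 8 bp) plus discordant
#' pairs; the breakpoint is refined to the interval between the modal
#' 3'-anchored clip point (left edge) and the modal 5'-anchored clip point
#' (right edge) whose width estimates the target site duplication. Tier
#' assignment: stringent requires >= `min_clip_each_side` consistent clips on
#' both sides, total support in `[min_reads, 5 * coverage]`; relaxed requires
#' total support >= `relaxed_min`.
#'
#' @param evidence An `erv_evidence` from [extract_evidence()].
#' @param policy A [filter_policy()].
#' @param cluster_window Clustering window (bp, default 200).
#' @return Data frame of `InsertionCall`s ordered by contig and position:
#'   contig, bp_start, bp_end (0-based half-open breakpoint/TSD interval),
#'   clip5_support, clip3_support, pair_support, lineage, tier, tsd_len_est.
#' @export
call_nonreference_insertions <- function(evidence, policy,
                                         cluster_window = 200L) {
  sc <- evidence$softclips
  dp <- evidence$discordant
  pts <- rbind(
    if (nrow(sc)) data.frame(contig = sc$contig, pos = sc$clip_point,
                             kind = "clip", side = sc$side,
                             lineage = sc$lineage, stringsAsFactors = FALSE),
    if (nrow(dp)) data.frame(contig = dp$contig, pos = dp$pos, kind = "pair",
                             side = dp$side, lineage = dp$lineage,
                             stringsAsFactors = FALSE))
  if (is.null(pts) || !nrow(pts)) return(empty_insertion_calls())

  calls <- list()
  for (ctg in unique(pts$contig)) {
    p <- pts[pts$contig == ctg, , drop = FALSE]
    ir <- IRanges::IRanges(start = p$pos, width = 1L)
    red <- IRanges::reduce(ir, min.gapwidth = cluster_window)
    grp <- IRanges::findOverlaps(ir, red, select = "first")
    for (g in seq_along(red)) {
      cl <- p[grp == g, , drop = FALSE]
      call <- summarise_cluster(cl, ctg, policy)
      if (!is.null(call)) calls[[length(calls) + 1L]] <- call
    }
  }
  if (!length(calls)) return(empty_insertion_calls())
  out <- do.call(rbind, calls)
  out <- out[order(out$contig, out$bp_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_insertion_calls <- function() {
  data.frame(contig = character(), bp_start = integer(), bp_end = integer(),
             clip5_support = integer(), clip3_support = integer(),
             pair_support = integer(), lineage = character(),
             tier = character(), tsd_len_est = integer(),
             stringsAsFactors = FALSE)
}

## Breakpoint estimate from discordant pairs alone: 5'-side anchor ends
## bound the junction from below, 3'-side anchor starts from above.
pair_breakpoint <- function(cl) {
  p5 <- cl$pos[cl$kind == "pair" & cl$side == "5"]
  p3 <- cl$pos[cl$kind == "pair" & cl$side == "3"]
  if (length(p5) && length(p3) && min(p3) >= max(p5))
    as.integer((max(p5) + min(p3)) %/% 2)
  else if (length(p5)) as.integer(max(p5))
  else if (length(p3)) as.integer(min(p3))
  else as.integer(median(cl$pos))
}

mode_int <- function(x) {
  if (!length(x)) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

summarise_cluster <- function(cl, ctg, policy, consistency_tol = 8L) {
  c5 <- cl$pos[cl$kind == "clip" & cl$side == "5"]
  c3 <- cl$pos[cl$kind == "clip" & cl$side == "3"]
  mode5 <- mode_int(c5); mode3 <- mode_int(c3)
  clip5 <- if (is.na(mode5)) 0L else sum(abs(c5 - mode5) <= consistency_tol)
  clip3 <- if (is.na(mode3)) 0L else sum(abs(c3 - mode3) <= consistency_tol)
  pairs <- sum(cl$kind == "pair")
  total <- clip5 + clip3 + pairs
  ## support sanity window: a diploid homozygous locus contributes clip and
  ## pair evidence from both haplotypes (~3x coverage combined), so the
  ## upper bound sits at 5x coverage; pileups driven by repeats land far
  ## above it
  stringent <- clip5 >= policy$min_clip_each_side &&
    clip3 >= policy$min_clip_each_side &&
    total >= policy$min_reads && total <= 5 * policy$coverage
  relaxed <- total >= policy$relaxed_min
  if (!relaxed) return(NULL)
  if (!is.na(mode5) && !is.na(mode3) && mode5 > mode3) {
    bp <- c(mode3, mode5); tsd <- mode5 - mode3
  } else {
    p <- if (!is.na(mode5)) mode5 else if (!is.na(mode3)) mode3 else
      pair_breakpoint(cl)
    bp <- c(p, p + 1L); tsd <- NA_integer_
  }
  lin <- names(sort(table(cl$lineage), decreasing = TRUE))[1]
  data.frame(contig = ctg, bp_start = bp[1], bp_end = bp[2],
             clip5_support = clip5, clip3_support = clip3,
             pair_support = pairs, lineage = lin,
             tier = if (stringent) "stringent" else "relaxed",
             tsd_len_est = tsd, stringsAsFactors = FALSE)
}

#' Call absences of reference ERV loci (preintegration state)
#'
#' For each reference ERV interval and the given individual's alignments:
#' read pairs with one mate on each side of the locus whose apparent insert
#' is stretched by about the element length (within 4 standard deviations)
#' count as spanning support; reads soft-clipped at the locus's outer flanks
#' whose clip matches the opposite flank count as split support. An absence
#' is called when combined support reaches `policy$min_reads`. The zygosity
#' hint is `hom_absent` when concordant coverage inside the element falls
#' below half the single-haplotype expectation, `het` otherwise.
#'
#' @param aln An `erv_alignments` data frame.
#' @param ref_ervs Data frame from [reference_erv_table()] (locus_id, contig,
#'   start, end, optional tsd_len).
#' @param policy A [filter_policy()].
#' @param reference Named character vector of reference contigs (for flank
#'   matching of split reads).
#' @param insert_mean,insert_sd Fragment length distribution of the sample.
#' @param read_len Read length (default 150).
#' @param min_clip Minimum clip length considered (default 10).
#' @return Data frame of `AbsenceCall`s: locus_id, contig, start, end,
#'   spanning_support, split_support, zygosity_hint.
#' @export
call_reference_absences <- function(aln, ref_ervs, policy, reference,
                                    insert_mean = 400L, insert_sd = 50L,
                                    read_len = 150L, min_clip = 10L) {
  out <- list()
  if (!nrow(ref_ervs)) return(empty_absence_calls())
  cg <- parse_cigar(aln$cigar)
  pos0 <- aln$pos - 1L
  aend <- pos0 + cg$match_len
  for (j in seq_len(nrow(ref_ervs))) {
    lc <- ref_ervs[j, ]
    tsd <- if ("tsd_len" %in% names(lc) && !is.na(lc$tsd_len)) lc$tsd_len
           else 0L
    elem_len <- lc$end - lc$start
    on_ctg <- aln$rname == lc$contig

    ## spanning pairs: leftmost (tlen > 0) mate entirely 5' of the locus,
    ## mate end beyond it, apparent insert ~ insert_mean + deleted length
    expected <- insert_mean + elem_len + tsd
    span <- on_ctg & aln$tlen > 0 & aend <= lc$start &
      pos0 + aln$tlen >= lc$end &
      abs(aln$tlen - expected) <= 4L * insert_sd
    spanning <- sum(span)

    ## split reads: clips at the outer junctions matching the opposite flank
    right_flank_start <- lc$end + tsd
    side5 <- on_ctg & cg$trail_clip >= min_clip &
      abs(aend - lc$start) <= 30L
    side3 <- on_ctg & cg$lead_clip >= min_clip &
      abs(pos0 - right_flank_start) <= 30L
    split <- 0L
    if (any(side5)) {
      clip <- substring(aln$seq[side5],
                        nchar(aln$seq[side5]) - cg$trail_clip[side5] + 1L)
      flank <- substr(reference[[lc$contig]], right_flank_start + 1L,
                      right_flank_start + 400L)
      split <- split + sum(clip_matches(clip, flank))
    }
    if (any(side3)) {
      clip <- substr(aln$seq[side3], 1L, cg$lead_clip[side3])
      flank <- substr(reference[[lc$contig]],
                      max(1L, lc$start - 400L + 1L), lc$start)
      split <- split + sum(clip_matches(clip, flank))
    }

    support <- spanning + split
    if (support < policy$min_reads) next

    internal <- sum(on_ctg & pos0 >= lc$start & aend <= lc$end &
                      cg$lead_clip == 0L & cg$trail_clip == 0L)
    expect_het <- (policy$coverage / 2) *
      max(elem_len - read_len, 1L) / read_len
    zyg <- if (internal < 0.5 * expect_het) "hom_absent" else "het"
    out[[length(out) + 1L]] <- data.frame(
      locus_id = lc$locus_id, contig = lc$contig, start = lc$start,
      end = lc$end, spanning_support = spanning, split_support = split,
      zygosity_hint = zyg, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_absence_calls())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_absence_calls <- function() {
  data.frame(locus_id = character(), contig = character(), start = integer(),
             end = integer(), spanning_support = integer(),
             split_support = integer(), zygosity_hint = character(),
             stringsAsFactors = FALSE)
}

clip_matches <- function(clips, flank, min_identity = 0.8, min_score = 10L) {
  if (!length(clips)) return(logical(0))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(clips), Biostrings::DNAString(flank),
    type = "local", gapOpening = 5, gapExtension = 2)
  nm <- Biostrings::nmatch(al)
  nm >= min_score & nm / pmax(Biostrings::nchar(al), 1L) >= min_identity
}

#' Rescue soft-clip support at known candidate loci
#'
#' Re-tests all soft-clipped reads within +/- `window` bp of each candidate
#' locus (typically loci discovered in other, higher-coverage individuals)
#' against the library LTRs, regardless of clip-point consistency, and adds
#' discordant-pair support in the same window. A locus is typed present when
#' the pooled support reaches the relaxed policy minimum. Intended for
#' low-coverage samples, where junction evidence is sparse and scattered;
#' applying it to a sample already called present leaves presence unchanged.
#'
#' @param aln An `erv_alignments` data frame for one individual.
#' @param candidate_loci Data frame with columns `locus_id`, `contig`, `pos`
#'   (0-based breakpoint).
#' @param library An [erv_library()].
#' @param policy A [filter_policy()].
#' @param window Search window around each locus (default 300 bp each side).
#' @param min_clip Minimum clip length (default 10).
#' @param ... Passed to [extract_evidence()].
#' @return Data frame: locus_id, contig, pos, clip_support, pair_support,
#'   present (logical, support >= relaxed minimum).
#' @export
rescue_softclips <- function(aln, candidate_loci, library, policy,
                             window = 300L, min_clip = 10L, ...) {
  ev <- extract_evidence(aln, library, min_clip = min_clip, ...)
  sc <- ev$softclips; dp <- ev$discordant
  res <- candidate_loci[, c("locus_id", "contig", "pos")]
  res$clip_support <- rep(0L, nrow(res))
  res$pair_support <- rep(0L, nrow(res))
  for (i in seq_len(nrow(res))) {
    near_clip <- sc$contig == res$contig[i] &
      abs(sc$clip_point - res$pos[i]) <= window
    near_pair <- dp$contig == res$contig[i] &
      abs(dp$pos - res$pos[i]) <= window
    res$clip_support[i] <- sum(near_clip)
    res$pair_support[i] <- sum(near_pair)
  }
  res$present <- res$clip_support + res$pair_support >= policy$relaxed_min
  res
}
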