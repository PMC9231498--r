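#' Simulate paired-end alignments for one individual
#'
#' Emulates mapping of reads from the individual's diploid genome back to the
#' reference-plus-library index, without running an aligner: read placement is
#' truth-guided, with CIGARs derived from junction arithmetic, so the output
#' carries exactly the breakpoint signatures a mobile-element caller consumes:
#'
#' * reads wholly inside host sequence map concordantly at host coordinates;
#' * reads crossing the junction of a non-reference element are soft-clipped
#'   at the junction, the clip holding element sequence, with the matched
#'   segment extending through the target site duplication (so clips on the
#'   two sides bracket the TSD);
#' * reads wholly inside a non-reference element map to the lineage's library
#'   contig; their mates anchored in the host make discordant host/library
#'   pairs;
#' * for a haplotype lacking a reference-assembly element, pairs spanning the
#'   empty site show an apparent insert stretched by the element length, and
#'   reads crossing the empty junction are clipped with the clip matching the
#'   opposite flank (a deletion signature relative to the reference).
#'
#' Base-call errors are applied as independent substitutions at
#' `cfg$error_rate`.
#'
#' @param cohort An `erv_cohort` from [plant_cohort()].
#' @param individual Individual id (must be in `cohort$individuals`).
#' @param cfg A [read_sim_config()]. Fragment count is
#'   `coverage/2 * haplotype_length / (2 * read_len)` per haplotype.
#' @param min_anchor Minimum matched bases for a junction read to be anchored
#'   on a side (default 15); reads with a shorter host anchor are placed on
#'   the library contig instead.
#' @return An `erv_alignments` data frame (qname, flag, rname, pos (1-based),
#'   mapq, cigar, rnext, pnext, tlen, seq) sorted by contig then position,
#'   with attributes `seqinfo` (named contig lengths, host + library),
#'   `individual`, `coverage`, and `read_cfg`.
#' @export
simulate_alignments <- function(cohort, individual, cfg, min_anchor = 15L) {
  stopifnot(inherits(cohort, "erv_cohort"), inherits(cfg, "read_sim_config"))
  idx <- match(individual, cohort$individuals$id)
  if (is.na(idx)) stop("unknown individual: ", individual, call. = FALSE)
  coverage <- cohort$individuals$coverage[idx]
  if (coverage <= 0) stop("coverage must be > 0", call. = FALSE)
  rl <- cfg$read_len

  seqinfo <- c(vapply(cohort$reference, nchar, integer(1)),
               vapply(cohort$library$contigs, nchar, integer(1)))

  with_seed(derive_seed(cfg$seed, idx), {
    recs <- list()
    for (ctg in names(cohort$reference)) {
      for (hap in 1:2) {
        hs <- haplotype_segments(cohort, individual, ctg, hap)
        hap_len <- hs$hap_len
        n_frag <- max(0L, round((coverage / 2) * hap_len / (2 * rl)))
        if (n_frag == 0L) next
        frag_len <- pmin(pmax(rl, round(rnorm(n_frag, cfg$insert_mean,
                                              cfg$insert_sd))),
                         hap_len)
        frag_start <- floor(runif(n_frag, 0, hap_len - frag_len + 1))
        recs[[paste(ctg, hap)]] <- place_fragments(
          hs, frag_start, frag_len, cfg, cohort, individual, ctg, hap,
          min_anchor)
      }
    }
    aln <- if (length(recs)) do.call(rbind, recs) else empty_alignments()
    if (nrow(aln) && cfg$error_rate > 0) {
      aln$seq <- apply_read_errors(aln$seq, cfg$error_rate)
    }
    ord <- order(match(aln$rname, names(seqinfo)), aln$pos)
    aln <- aln[ord, , drop = FALSE]
    rownames(aln) <- NULL
    structure(aln, class = c("erv_alignments", "data.frame"),
              seqinfo = seqinfo, individual = individual,
              coverage = coverage, read_cfg = cfg)
  })
}

empty_alignments <- function() {
  data.frame(qname = character(), flag = integer(), rname = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             rnext = character(), pnext = integer(), tlen = integer(),
             seq = character(), stringsAsFactors = FALSE)
}

## Piecewise map from one haplotype of one contig to the reference/library.
## Segments are (hap_start, hap_end) half-open 0-based with either a host
## reference offset or a library contig. For a non-reference carrier the
## upstream host segment runs through the TSD (ref end = ins_pos + tsd_len)
## while the downstream host segment restarts at ins_pos, reproducing how an
## aligner extends matches through the duplicated target site.
haplotype_segments <- function(cohort, individual, ctg, hap) {
  loci <- cohort$loci[cohort$loci$contig == ctg, , drop = FALSE]
  ref <- cohort$reference[[ctg]]
  ref_len <- nchar(ref)
  carried <- hap_carries(cohort, individual, loci, hap)

  segs <- list(); contents <- list()
  cur <- 0L
  hap_cursor <- 0L
  add_host <- function(ref_from, ref_to) {
    if (ref_to <= ref_from) return(invisible())
    len <- ref_to - ref_from
    segs[[length(segs) + 1L]] <<- data.frame(
      kind = "host", hap_start = hap_cursor, hap_end = hap_cursor + len,
      ref_start = ref_from, lib = NA_character_, stringsAsFactors = FALSE)
    contents[[length(contents) + 1L]] <<- substr(ref, ref_from + 1L, ref_to)
    hap_cursor <<- hap_cursor + len
  }
  add_elem <- function(seq, lineage) {
    len <- nchar(seq)
    segs[[length(segs) + 1L]] <<- data.frame(
      kind = "elem", hap_start = hap_cursor, hap_end = hap_cursor + len,
      ref_start = NA_integer_, lib = paste0("lib_", lineage),
      stringsAsFactors = FALSE)
    contents[[length(contents) + 1L]] <<- seq
    hap_cursor <<- hap_cursor + len
  }

  if (nrow(loci)) {
    for (j in seq_len(nrow(loci))) {
      if (loci$in_reference[j]) {
        if (!carried[j]) {
          ## preintegration state: skip element + duplicated TSD
          add_host(cur, loci$elem_start[j])
          cur <- loci$elem_end[j] + loci$tsd_len[j]
        }
      } else if (carried[j]) {
        add_host(cur, loci$ins_pos[j] + loci$tsd_len[j])
        add_elem(cohort$copies[[loci$locus_id[j]]]$elem_seq, loci$lineage[j])
        cur <- loci$ins_pos[j]
      }
    }
  }
  add_host(cur, ref_len)
  segs <- do.call(rbind, segs)
  list(segments = segs, hap_seq = paste(unlist(contents), collapse = ""),
       hap_len = hap_cursor)
}

## Which loci (rows of `loci`) haplotype `hap` (1 or 2) of this individual
## carries. A genotype-1 allele is assigned to a haplotype chosen
## deterministically from the cohort seed, so the two haplotypes of the same
## individual agree on the assignment.
hap_carries <- function(cohort, individual, loci, hap) {
  if (!nrow(loci)) return(logical(0))
  g <- cohort$genotypes[loci$locus_id, individual]
  pick <- vapply(loci$locus_id, function(id) {
    h <- derive_seed(cohort$seed,
                     7L * match(id, rownames(cohort$genotypes)) +
                       match(individual, cohort$individuals$id))
    with_seed(h, sample(1:2, 1L))
  }, integer(1))
  unname(g == 2L | (g == 1L & pick == hap))
}

place_fragments <- function(hs, frag_start, frag_len, cfg, cohort,
                            individual, ctg, hap, min_anchor) {
  rl <- cfg$read_len
  n <- length(frag_start)
  a1 <- frag_start; b1 <- frag_start + rl
  a2 <- frag_start + frag_len - rl; b2 <- frag_start + frag_len

  m1 <- map_reads(hs, a1, b1, ctg, min_anchor, cfg)
  m2 <- map_reads(hs, a2, b2, ctg, min_anchor, cfg)
  seq1 <- substring(hs$hap_seq, a1 + 1L, b1)
  seq2 <- substring(hs$hap_seq, a2 + 1L, b2)

  same <- m1$rname == m2$rname
  end1 <- m1$pos + m1$mlen
  end2 <- m2$pos + m2$mlen
  tl <- integer(n)
  lo <- pmin(m1$pos, m2$pos)
  hi <- pmax(end1, end2)
  tl <- hi - lo
  tlen1 <- ifelse(same, ifelse(m1$pos <= m2$pos, tl, -tl), 0L)
  tlen2 <- ifelse(same, ifelse(m1$pos <= m2$pos, -tl, tl), 0L)
  proper <- same & tl <= cfg$insert_mean + 4L * cfg$insert_sd & tl >= rl
  flag1 <- 1L + 32L + 64L + ifelse(proper, 2L, 0L)
  flag2 <- 1L + 16L + 128L + ifelse(proper, 2L, 0L)

  qname <- sprintf("%s_%s_h%d_%06d", individual, ctg, hap, seq_len(n))
  rnext1 <- ifelse(same, "=", m2$rname)
  rnext2 <- ifelse(same, "=", m1$rname)
  data.frame(
    qname = c(qname, qname),
    flag = as.integer(c(flag1, flag2)),
    rname = c(m1$rname, m2$rname),
    pos = as.integer(c(m1$pos, m2$pos)),
    mapq = 60L,
    cigar = c(m1$cigar, m2$cigar),
    rnext = c(rnext1, rnext2),
    pnext = as.integer(c(m2$pos, m1$pos)),
    tlen = as.integer(c(tlen1, tlen2)),
    seq = c(seq1, seq2),
    stringsAsFactors = FALSE)
}

## Vectorised truth-guided placement of reads [a, b) in haplotype space.
## Returns 1-based pos, cigar, matched length and rname per read.
map_reads <- function(hs, a, b, ctg, min_anchor, cfg) {
  segs <- hs$segments
  rl <- b - a
  i1 <- findInterval(a, segs$hap_start)
  i2 <- findInterval(b - 1L, segs$hap_start)
  n <- length(a)
  rname <- character(n); pos <- integer(n)
  cigar <- character(n); mlen <- integer(n)

  inside <- i1 == i2
  ih <- inside & segs$kind[i1] == "host"
  ie <- inside & segs$kind[i1] == "elem"
  if (any(ih)) {
    rname[ih] <- ctg
    pos[ih] <- as.integer(segs$ref_start[i1[ih]] +
                            (a[ih] - segs$hap_start[i1[ih]]) + 1L)
    cigar[ih] <- paste0(rl[ih], "M")
    mlen[ih] <- as.integer(rl[ih])
  }
  if (any(ie)) {
    lib <- segs$lib[i1[ie]]
    off <- as.integer(a[ie] - segs$hap_start[i1[ie]] + 1L)
    rname[ie] <- lib
    pos[ie] <- off
    cigar[ie] <- paste0(rl[ie], "M")
    mlen[ie] <- as.integer(rl[ie])
  }
  for (k in which(!inside)) {
    r <- map_junction_read(segs, a[k], b[k], ctg, min_anchor, cfg)
    rname[k] <- r$rname; pos[k] <- r$pos
    cigar[k] <- r$cigar; mlen[k] <- r$mlen
  }
  list(rname = rname, pos = pos, cigar = cigar, mlen = mlen)
}

## A read crossing one junction: anchor the longer part that sits in a host
## segment (if it reaches min_anchor), soft-clipping the remainder; else
## anchor the element part on its library contig. With probability
## cfg$clip_jitter_prob the matched segment over-extends into the clipped
## side (aligner end-placement ambiguity), scattering the clip point by up
## to cfg$clip_jitter_max bases.
map_junction_read <- function(segs, a, b, ctg, min_anchor, cfg) {
  idx <- which(segs$hap_end > a & segs$hap_start < b)
  parts <- data.frame(
    seg = idx,
    from = pmax(a, segs$hap_start[idx]),
    to = pmin(b, segs$hap_end[idx]))
  parts$len <- parts$to - parts$from
  kind <- segs$kind[parts$seg]
  host_ok <- which(kind == "host" & parts$len >= min_anchor)
  anchor <- if (length(host_ok)) host_ok[which.max(parts$len[host_ok])]
            else which.max(parts$len)
  seg <- segs[parts$seg[anchor], ]
  off <- parts$from[anchor] - seg$hap_start
  left_clip <- parts$from[anchor] - a
  right_clip <- b - parts$to[anchor]
  mlen <- parts$len[anchor]
  if (cfg$clip_jitter_prob > 0 && runif(1) < cfg$clip_jitter_prob) {
    j <- sample.int(cfg$clip_jitter_max, 1L)
    if (right_clip > 0) {
      j <- min(j, right_clip)
      mlen <- mlen + j
      right_clip <- right_clip - j
    } else if (left_clip > 0) {
      j <- min(j, left_clip, off)
      mlen <- mlen + j
      left_clip <- left_clip - j
      off <- off - j
    }
  }
  cig <- paste0(if (left_clip > 0) paste0(left_clip, "S"),
                mlen, "M",
                if (right_clip > 0) paste0(right_clip, "S"))
  if (seg$kind == "host") {
    list(rname = ctg, pos = as.integer(seg$ref_start + off + 1L),
         cigar = cig, mlen = as.integer(mlen))
  } else {
    list(rname = seg$lib, pos = as.integer(off + 1L), cigar = cig,
         mlen = as.integer(mlen))
  }
}

apply_read_errors <- function(seqs, error_rate) {
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- rbinom(1L, total, error_rate)
  if (n_err == 0L) return(seqs)
  at <- sort(sample.int(total, n_err))
  cum <- cumsum(lens)
  read_i <- findInterval(at - 1L, c(0L, cum), rightmost.closed = FALSE)
  pos_i <- at - c(0L, cum)[read_i]
  for (j in seq_len(n_err)) {
    i <- read_i[j]; p <- pos_i[j]
    old <- substr(seqs[i], p, p)
    substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
  }
  seqs
}
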