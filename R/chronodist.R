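#' Pairwise p-distance between two nucleotide sequences
#'
#' Sequences are globally aligned (Needleman-Wunsch with affine gaps via
#' [Biostrings::pairwiseAlignment()]); the distance is the proportion of
#' mismatched columns among aligned columns, excluding columns containing a
#' gap. This is the raw (uncorrected) p-distance the LTR molecular clock is
#' applied to.
#'
#' @param seq_a,seq_b Character scalars (non-empty DNA).
#' @return Proportion in `[0, 1]`.
#' @examples
#' pairwise_p_distance("ACGTACGT", "ACGTACGT")  # 0
#' @export
pairwise_p_distance <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("sequences must be non-empty", call. = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = dna_score_matrix(),
    gapOpening = 10, gapExtension = 0.5)
  a <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  b <- seq_chars(as.character(Biostrings::alignedSubject(al)))
  keep <- a != "-" & b != "-"
  if (!any(keep)) return(NA_real_)
  sum(a[keep] != b[keep]) / sum(keep)
}

#' 5'-3' LTR divergence of an annotated provirus
#'
#' LTRs are identical at integration; their pairwise p-distance is the raw
#' input of the molecular clock. A solo LTR has no defined divergence and is
#' reported as `NA`, never 0.
#'
#' @param annotation A `provirus_annotation` (or any list with
#'   `ltr5_interval` and `ltr3_interval`, 0-based half-open).
#' @param contig_seq Character scalar containing the element.
#' @return Divergence proportion, or `NA_real_` for a solo LTR.
#' @export
ltr_divergence <- function(annotation, contig_seq) {
  l5 <- annotation$ltr5_interval
  l3 <- annotation$ltr3_interval
  if (is.null(l5) || is.null(l3) || anyNA(l5) || anyNA(l3))
    return(NA_real_)
  pairwise_p_distance(substr(contig_seq, l5[1] + 1L, l5[2]),
                      substr(contig_seq, l3[1] + 1L, l3[2]))
}

#' Integration age from LTR divergence
#'
#' Both LTRs accumulate substitutions independently after integration, so an
#' observed LTR-pair divergence `d` corresponds to `t = d / (2 * mu)` years
#' under a clock with substitution rate `mu`.
#'
#' @param d LTR divergence (proportion in `[0, 1]`).
#' @param mu Substitution rate (substitutions / site / year, > 0).
#' @return Age in years.
#' @examples
#' estimate_age(0.022, 2e-9)   # 5.5e6
#' @export
estimate_age <- function(d, mu) {
  if (any(mu <= 0)) stop("mu must be > 0", call. = FALSE)
  if (any(d < 0 | d > 1)) stop("d must be in [0, 1]", call. = FALSE)
  d / (2 * mu)
}

#' Age interval under a mutation-rate interval
#'
#' With the true host rate only known to lie in `[mu_low, mu_high]`, a fixed
#' divergence maps to an age window: the slower rate gives the older bound.
#'
#' @param d LTR divergence (proportion).
#' @param mu_low,mu_high Rate interval bounds (`0 < mu_low <= mu_high`).
#' @return Named numeric `c(t_low, t_high)` in years (`t_low` from
#'   `mu_high`).
#' @export
estimate_age_interval <- function(d, mu_low, mu_high) {
  stopifnot(mu_low > 0, mu_high >= mu_low)
  c(t_low = estimate_age(d, mu_high), t_high = estimate_age(d, mu_low))
}

#' Display-round an age in years to millions of years
#'
#' Ages are reported to one decimal in My (5.5, 2.4, 1.5, 0.7 ...), matching
#' the conventional presentation of LTR-clock windows.
#'
#' @param t_years Age(s) in years.
#' @return Numeric, My to 1 decimal.
#' @export
format_age_my <- function(t_years) round(t_years / 1e6, 1)

#' Distance summary for a clade of ERV sequences
#'
#' Computes all unordered pairwise p-distances among member sequences and a
#' histogram of them.
#'
#' @param seqs Character vector of member sequences (>= 2 for pairwise
#'   statistics).
#' @param clade Clade label.
#' @param bin_width Histogram bin width as a proportion (default 0.0025,
#'   i.e. 0.25%).
#' @return List of class `distance_summary`: `clade`, `n`, `pairwise`
#'   (min/max/mean/median as proportions, `NA` when < 2 members), `distances`
#'   (all pairwise values) and `histogram` (data frame bin_start, bin_end,
#'   count).
#' @export
clade_distance_summary <- function(seqs, clade, bin_width = 0.0025) {
  n <- length(seqs)
  if (n < 2L) {
    return(structure(list(clade = clade, n = n,
                          pairwise = c(min = NA_real_, max = NA_real_,
                                       mean = NA_real_, median = NA_real_),
                          distances = numeric(), histogram = NULL),
                     class = "distance_summary"))
  }
  pairs <- utils::combn(n, 2L)
  d <- vapply(seq_len(ncol(pairs)), function(i)
    pairwise_p_distance(seqs[pairs[1, i]], seqs[pairs[2, i]]), numeric(1))
  breaks <- seq(0, max(d, bin_width) + bin_width, by = bin_width)
  h <- hist(d, breaks = breaks, plot = FALSE)
  structure(list(clade = clade, n = n,
                 pairwise = c(min = min(d), max = max(d),
                              mean = mean(d), median = median(d)),
                 distances = d,
                 histogram = data.frame(bin_start = head(h$breaks, -1L),
                                        bin_end = tail(h$breaks, -1L),
                                        count = h$counts)),
            class = "distance_summary")
}

#' Inactivating-mutation summary for pol across a clade
#'
#' Per copy, the inactivating load is the number of premature stop codons
#' plus the number of frame-disrupting indels in pol. Copies in which pol was
#' not detected are excluded from the statistics and counted separately.
#'
#' @param profiles List of per-copy gene profiles (as from [profile_genes()]):
#'   each must contain `pol` with `n_stops`, `n_frameshifts`, and `detected`.
#' @param clade Clade label.
#' @return List: `clade`, `n`, `n_undetected`, `counts` (per-copy totals),
#'   and `stats` (min/max/mean/median).
#' @export
inactivation_summary <- function(profiles, clade) {
  det <- vapply(profiles, function(p) isTRUE(p$pol$detected), logical(1))
  counts <- vapply(profiles[det], function(p)
    p$pol$n_stops + p$pol$n_frameshifts, numeric(1))
  stats <- if (length(counts)) {
    c(min = min(counts), max = max(counts),
      mean = mean(counts), median = median(counts))
  } else c(min = NA_real_, max = NA_real_, mean = NA_real_, median = NA_real_)
  list(clade = clade, n = sum(det), n_undetected = sum(!det),
       counts = counts, stats = stats)
}

#' @importFrom graphics hist
NULL
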