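#' Specification of one ERV lineage expansion
#'
#' Describes a burst of germline integrations: how long ago it happened (which
#' drives LTR divergence and coding decay), how many loci it left, what
#' fraction of them the reference assembly haplotype carries, and the
#' population allele-frequency distribution of the loci.
#'
#' @param name Lineage label.
#' @param age_years Time since the burst midpoint (years). Individual copies
#'   are spread uniformly over `[0.5, 1.5] * age_years`.
#' @param mu Substitution rate (substitutions / site / year).
#' @param n_loci Number of germline loci.
#' @param ref_fraction Fraction of loci carried by the reference assembly
#'   haplotype.
#' @param allele_freq Either a length-2 numeric (Beta shape parameters) or a
#'   function `n -> frequencies` over `[0, 1]`.
#' @param indel_rate Indel rate (indels / site / year).
#' @return A `lineage_spec` list.
#' @export
lineage_spec <- function(name, age_years, mu = 3e-9, n_loci,
                         ref_fraction = 0.1, allele_freq = c(0.5, 2),
                         indel_rate = 0) {
  stopifnot(mu > 0, n_loci >= 0, age_years >= 0)
  stopifnot_scalar_prob(ref_fraction, "ref_fraction")
  structure(list(name = name, age_years = age_years, mu = mu,
                 n_loci = as.integer(n_loci), ref_fraction = ref_fraction,
                 allele_freq = allele_freq, indel_rate = indel_rate),
            class = "lineage_spec")
}

draw_allele_freqs <- function(spec, n) {
  af <- spec$allele_freq
  if (is.function(af)) af(n) else stats::rbeta(n, af[1], af[2])
}

#' Read-simulation configuration
#'
#' @param read_len Read length (default 150).
#' @param insert_mean,insert_sd Fragment-length distribution (default 400/50).
#' @param error_rate Per-base substitution error rate.
#' @param clip_jitter_prob Probability that the emulated aligner over-extends
#'   a junction read's matched segment into the adjacent sequence (end
#'   placement ambiguity; default 0.25). Scattered clip points are what the
#'   low-coverage soft-clip rescue step recovers.
#' @param clip_jitter_max Maximum over-extension in bases (default 30).
#' @param seed Mandatory integer seed.
#' @return A `read_sim_config` list.
#' @export
read_sim_config <- function(read_len = 150L, insert_mean = 400L,
                            insert_sd = 50L, error_rate = 0,
                            clip_jitter_prob = 0.25,
                            clip_jitter_max = 30L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(insert_mean >= read_len, error_rate >= 0, error_rate < 1)
  stopifnot_scalar_prob(clip_jitter_prob, "clip_jitter_prob")
  structure(list(read_len = as.integer(read_len),
                 insert_mean = as.integer(insert_mean),
                 insert_sd = as.integer(insert_sd),
                 error_rate = error_rate,
                 clip_jitter_prob = clip_jitter_prob,
                 clip_jitter_max = as.integer(clip_jitter_max),
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Generate a random host genome
#'
#' @param contig_lens Named integer vector of contig lengths.
#' @param seed Integer seed.
#' @return Named character vector of contig sequences.
#' @export
simulate_host_genome <- function(contig_lens, seed = 1L) {
  if (is.null(names(contig_lens)))
    names(contig_lens) <- paste0("chr", seq_along(contig_lens))
  with_seed(seed, vapply(contig_lens, random_dna, character(1)))
}

#' Plant a cohort of polymorphic ERV lineages into a host genome
#'
#' For each lineage, integration sites are drawn uniformly across the host
#' subject to a minimum spacing, each with a 4-6 bp target site duplication
#' (TSD), random strand, a per-copy age around the lineage burst, and a
#' population allele frequency. A configured fraction of loci is written into
#' the reference assembly haplotype (`in_reference`); reference-carrier loci
#' are chosen with probability weights proportional to allele frequency, since
#' the assembly individual is itself a population sample. Per-individual
#' diploid genotypes are binomial draws from the allele frequency.
#'
#' The insertion convention: `host_pos` is the first base of the TSD in the
#' pre-insertion sequence; an integrated element reads
#' `TSD + 5'LTR...3'LTR + TSD`.
#'
#' @param host Named character vector of host contigs (no pre-existing
#'   planted loci).
#' @param lineages List of [lineage_spec()] objects.
#' @param cohort Data frame with columns `id` and `coverage`.
#' @param templates Named list of per-lineage [provirus_template()]s (names
#'   must cover the lineage names). Default: derived with
#'   [lineage_templates()] from `provirus_template(seed = seed)`.
#' @param tsd_range Integer range of TSD lengths (default 4:6).
#' @param min_spacing Minimum distance between planted loci (default 800 =
#'   2x default insert size).
#' @param seed Integer seed.
#' @return An object of class `erv_cohort`: list with `reference` (named
#'   character, assembly with reference ERVs inserted), `host`, `library`
#'   (from [erv_library()]), `templates`, `loci` (truth table, 0-based
#'   half-open reference coordinates), `copies` (per-locus `erv_copy`),
#'   `genotypes` (loci x individuals matrix of 0/1/2), `individuals`, `seed`.
#' @export
plant_cohort <- function(host, lineages, cohort, templates = NULL,
                         tsd_range = 4:6, min_spacing = 800L, seed = 1L) {
  stopifnot(is.character(host), !is.null(names(host)),
            all(c("id", "coverage") %in% names(cohort)))
  if (any(cohort$coverage <= 0)) stop("coverage must be > 0", call. = FALSE)
  lineage_names <- vapply(lineages, `[[`, character(1), "name")
  if (is.null(templates)) {
    templates <- lineage_templates(provirus_template(seed = seed),
                                   lineage_names, seed = seed)
  }
  stopifnot(all(lineage_names %in% names(templates)))

  with_seed(derive_seed(seed, 1L), {
    n_total <- sum(vapply(lineages, `[[`, integer(1), "n_loci"))
    positions <- draw_spaced_positions(host, n_total, min_spacing,
                                       edge = 2000L)

    loci <- list(); copies <- list(); k <- 0L
    for (ls in lineages) {
      if (ls$n_loci == 0L) next
      af <- draw_allele_freqs(ls, ls$n_loci)
      ages <- if (ls$age_years > 0)
        ls$age_years * runif(ls$n_loci, 0.5, 1.5) else rep(0, ls$n_loci)
      n_ref <- round(ls$ref_fraction * ls$n_loci)
      in_ref <- rep(FALSE, ls$n_loci)
      if (n_ref > 0L) {
        w <- pmax(af, 1e-6)
        in_ref[sample.int(ls$n_loci, n_ref, prob = w)] <- TRUE
      }
      for (i in seq_len(ls$n_loci)) {
        k <- k + 1L
        pos <- positions[k, ]
        tsd_len <- sample(tsd_range, 1L)
        cp <- evolve_copy(templates[[ls$name]], ages[i], ls$mu,
                          ls$indel_rate, seed = derive_seed(seed, k + 200L))
        strand <- if (runif(1) < 0.5) "+" else "-"
        elem <- if (strand == "+") cp$seq else revcomp(cp$seq)
        loci[[k]] <- data.frame(
          locus_id = sprintf("%s|L%03d", ls$name, i),
          contig = pos$contig, host_pos = pos$pos,
          tsd_len = tsd_len,
          tsd_seq = substr(host[[pos$contig]], pos$pos + 1L,
                           pos$pos + tsd_len),
          strand = strand, lineage = ls$name,
          age_years = ages[i], allele_freq = af[i],
          in_reference = in_ref[i], elem_len = nchar(elem),
          stringsAsFactors = FALSE)
        copies[[k]] <- cp
        copies[[k]]$elem_seq <- elem
      }
    }
    loci <- if (length(loci)) do.call(rbind, loci) else empty_loci_df()
    names(copies) <- loci$locus_id

    ## Reference assembly: host plus the in_reference copies. Insertion of a
    ## locus shifts downstream coordinates by elem_len + tsd_len (element
    ## plus the duplicated TSD copy).
    loci <- loci[order(loci$contig, loci$host_pos), , drop = FALSE]
    rownames(loci) <- NULL
    reference <- host
    loci$ins_pos <- rep(NA_integer_, nrow(loci))  # TSD start, ref coords
    loci$elem_start <- rep(NA_integer_, nrow(loci))  # element interval
    loci$elem_end <- rep(NA_integer_, nrow(loci))
    for (ctg in names(host)) {
      sel <- which(loci$contig == ctg)
      offset <- 0L
      pieces <- character(0)
      cursor <- 0L  # 0-based position in host contig consumed so far
      for (j in sel) {
        loci$ins_pos[j] <- loci$host_pos[j] + offset
        if (loci$in_reference[j]) {
          tl <- loci$tsd_len[j]
          cut <- loci$host_pos[j] + tl  # host coord after original TSD
          pieces <- c(pieces,
                      substr(host[[ctg]], cursor + 1L, cut),
                      copies[[loci$locus_id[j]]]$elem_seq,
                      loci$tsd_seq[j])
          cursor <- cut
          loci$elem_start[j] <- loci$ins_pos[j] + tl
          loci$elem_end[j] <- loci$elem_start[j] + loci$elem_len[j]
          offset <- offset + loci$elem_len[j] + tl
        }
      }
      pieces <- c(pieces, substr(host[[ctg]], cursor + 1L, nchar(host[[ctg]])))
      reference[[ctg]] <- paste(pieces, collapse = "")
    }

    genotypes <- matrix(0L, nrow = nrow(loci), ncol = nrow(cohort),
                        dimnames = list(loci$locus_id, cohort$id))
    for (j in seq_len(nrow(loci))) {
      genotypes[j, ] <- rbinom(nrow(cohort), 2L, loci$allele_freq[j])
    }

    structure(list(reference = reference, host = host,
                   library = erv_library(templates), templates = templates,
                   loci = loci, copies = copies, genotypes = genotypes,
                   individuals = cohort, tsd_range = tsd_range,
                   min_spacing = as.integer(min_spacing), seed = seed),
              class = "erv_cohort")
  })
}

empty_loci_df <- function() {
  data.frame(locus_id = character(), contig = character(),
             host_pos = integer(), tsd_len = integer(), tsd_seq = character(),
             strand = character(), lineage = character(),
             age_years = numeric(), allele_freq = numeric(),
             in_reference = logical(), elem_len = integer(),
             stringsAsFactors = FALSE)
}

## Uniform positions across contigs (weighted by length) with pairwise
## spacing > min_spacing on each contig. Explicit failure when infeasible.
draw_spaced_positions <- function(host, n, min_spacing, edge = 2000L) {
  if (n == 0L)
    return(data.frame(contig = character(), pos = integer()))
  lens <- nchar(host)
  usable <- pmax(lens - 2L * edge, 0L)
  if (sum(usable %/% (min_spacing + 1L)) < n)
    stop("cannot place ", n, " loci with spacing ", min_spacing,
         " in the given host genome", call. = FALSE)
  placed <- list(); tries <- 0L
  by_contig <- lapply(host, function(x) integer(0))
  while (length(placed) < n) {
    tries <- tries + 1L
    if (tries > 200L * n)
      stop("cannot place ", n, " loci with spacing ", min_spacing,
           " in the given host genome", call. = FALSE)
    ctg <- sample(names(host), 1L, prob = pmax(usable, 1L))
    pos <- edge + sample.int(max(1L, usable[[ctg]]), 1L) - 1L
    if (length(by_contig[[ctg]]) &&
        min(abs(by_contig[[ctg]] - pos)) <= min_spacing) next
    by_contig[[ctg]] <- c(by_contig[[ctg]], pos)
    placed[[length(placed) + 1L]] <- data.frame(contig = ctg, pos = pos,
                                                stringsAsFactors = FALSE)
  }
  do.call(rbind, placed)
}

#' Truth BED for a planted cohort
#'
#' Reference loci span the element interval; non-reference loci span the TSD
#' at the insertion point. Coordinates are 0-based half-open.
#'
#' @param cohort An `erv_cohort`.
#' @return Data frame with BED columns (`contig`, `start`, `end`, `name` =
#'   `lineage|locus`, `score` = `allele_freq * 1000`, `strand`).
#' @export
truth_bed <- function(cohort) {
  loci <- cohort$loci
  if (!nrow(loci)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), name = character(), score = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  data.frame(contig = loci$contig,
             start = ifelse(loci$in_reference, loci$elem_start, loci$ins_pos),
             end = ifelse(loci$in_reference, loci$elem_end,
                          loci$ins_pos + loci$tsd_len),
             name = loci$locus_id,
             score = round(loci$allele_freq * 1000),
             strand = loci$strand, stringsAsFactors = FALSE)
}

#' Reference-ERV interval table for a cohort (assembly loci only)
#' @param cohort An `erv_cohort`.
#' @return Data frame: locus_id, contig, start, end, tsd_len, lineage.
#' @export
reference_erv_table <- function(cohort) {
  loci <- cohort$loci[cohort$loci$in_reference, , drop = FALSE]
  data.frame(locus_id = loci$locus_id, contig = loci$contig,
             start = loci$elem_start, end = loci$elem_end,
             tsd_len = loci$tsd_len, lineage = loci$lineage,
             stringsAsFactors = FALSE)
}
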