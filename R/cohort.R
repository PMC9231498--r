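#' Merge per-individual insertion calls into unified loci
#'
#' Single-linkage clustering of call breakpoints within `tolerance_bp` on the
#' same contig and lineage; a cluster containing conflicting lineage labels
#' is split by lineage. Locus intervals span the member breakpoints; ids are
#' assigned in (contig, start) order, so merging is deterministic and
#' idempotent.
#'
#' @param calls_by_individual Named list (individual -> data frame from
#'   [call_nonreference_insertions()]).
#' @param tolerance_bp Breakpoint matching tolerance (default 100).
#' @return List of class `merged_loci`: `loci` (locus_id, contig, start, end,
#'   lineage) and `presence` (locus_id, individual, tier).
#' @export
merge_loci <- function(calls_by_individual, tolerance_bp = 100L) {
  all <- do.call(rbind, lapply(names(calls_by_individual), function(id) {
    x <- calls_by_individual[[id]]
    if (is.null(x) || !nrow(x)) return(NULL)
    x$individual <- id
    x
  }))
  if (is.null(all) || !nrow(all)) {
    return(structure(list(
      loci = data.frame(locus_id = character(), contig = character(),
                        start = integer(), end = integer(),
                        lineage = character(), stringsAsFactors = FALSE),
      presence = data.frame(locus_id = character(), individual = character(),
                            tier = character(), stringsAsFactors = FALSE)),
      class = "merged_loci"))
  }
  all$cluster <- NA_integer_
  next_id <- 1L
  for (key in unique(paste(all$contig, all$lineage))) {
    sel <- which(paste(all$contig, all$lineage) == key)
    ir <- IRanges::IRanges(start = all$bp_start[sel], width = 1L)
    red <- IRanges::reduce(ir, min.gapwidth = tolerance_bp)
    grp <- IRanges::findOverlaps(ir, red, select = "first")
    all$cluster[sel] <- next_id + grp - 1L
    next_id <- next_id + length(red)
  }
  loci <- do.call(rbind, lapply(split(all, all$cluster), function(cl) {
    data.frame(contig = cl$contig[1], start = min(cl$bp_start),
               end = max(cl$bp_end), lineage = cl$lineage[1],
               cluster = cl$cluster[1], stringsAsFactors = FALSE)
  }))
  loci <- loci[order(loci$contig, loci$start), , drop = FALSE]
  loci$locus_id <- sprintf("NR%04d", seq_len(nrow(loci)))
  presence <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
    cl <- all[all$cluster == loci$cluster[i], , drop = FALSE]
    ag <- split(cl$tier, cl$individual)
    data.frame(locus_id = loci$locus_id[i], individual = names(ag),
               tier = vapply(ag, function(t)
                 if ("stringent" %in% t) "stringent" else "relaxed",
                 character(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(loci) <- rownames(presence) <- NULL
  structure(list(loci = loci[, c("locus_id", "contig", "start", "end",
                                 "lineage")],
                 presence = presence),
            class = "merged_loci")
}

#' Build the loci-by-individuals presence matrix
#'
#' Rows are unified non-reference loci plus reference-assembly ERV loci;
#' values are carrier status (0/1). A reference locus is a carrier for an
#' individual unless that individual has a homozygous absence call for it;
#' reference loci carried by no resequenced individual are retained and
#' flagged (the assembly haplotype itself carries them). Rescue results, when
#' given, upgrade non-reference presence for the rescued individuals.
#'
#' @param merged A `merged_loci` from [merge_loci()].
#' @param abs_calls_by_individual Named list (individual -> data frame from
#'   [call_reference_absences()]).
#' @param ref_ervs Data frame from [reference_erv_table()].
#' @param individuals Character vector of individual ids (column order).
#' @param rescued_by_individual Optional named list (individual -> data
#'   frame from [rescue_softclips()]); rows with `present = TRUE` set
#'   presence at the matching locus.
#' @return Object of class `presence_matrix`: `loci` (locus_id, contig,
#'   start, end, lineage, in_reference), `individuals`, `values` (0/1
#'   matrix).
#' @export
build_presence_matrix <- function(merged, abs_calls_by_individual, ref_ervs,
                                  individuals,
                                  rescued_by_individual = NULL) {
  loci <- rbind(
    cbind(merged$loci,
          in_reference = rep(FALSE, nrow(merged$loci))),
    if (nrow(ref_ervs)) data.frame(
      locus_id = ref_ervs$locus_id, contig = ref_ervs$contig,
      start = ref_ervs$start, end = ref_ervs$end,
      lineage = ref_ervs$lineage, in_reference = TRUE,
      stringsAsFactors = FALSE))
  values <- matrix(0L, nrow = nrow(loci), ncol = length(individuals),
                   dimnames = list(loci$locus_id, individuals))
  for (i in seq_len(nrow(merged$presence))) {
    p <- merged$presence[i, ]
    values[p$locus_id, p$individual] <- 1L
  }
  if (!is.null(rescued_by_individual)) {
    for (id in names(rescued_by_individual)) {
      r <- rescued_by_individual[[id]]
      hit <- r$locus_id[r$present & r$locus_id %in% rownames(values)]
      values[hit, id] <- 1L
    }
  }
  if (nrow(ref_ervs)) {
    values[ref_ervs$locus_id, ] <- 1L
    for (id in intersect(names(abs_calls_by_individual), individuals)) {
      ab <- abs_calls_by_individual[[id]]
      if (is.null(ab) || !nrow(ab)) next
      hom <- ab$locus_id[ab$zygosity_hint == "hom_absent"]
      values[intersect(hom, ref_ervs$locus_id), id] <- 0L
    }
  }
  rownames(loci) <- NULL
  structure(list(loci = loci, individuals = individuals, values = values),
            class = "presence_matrix")
}

#' Presence matrix from simulation truth
#'
#' Detection-free counterpart of [build_presence_matrix()]: an individual
#' carries a locus when its true genotype is >= 1. Used to study properties
#' of the simulated population itself (for example the age-sharing gradient)
#' without conflating them with caller performance.
#'
#' @param cohort An `erv_cohort`.
#' @return A `presence_matrix`.
#' @export
truth_presence_matrix <- function(cohort) {
  loci <- cohort$loci
  structure(list(
    loci = data.frame(locus_id = loci$locus_id, contig = loci$contig,
                      start = loci$ins_pos, end = loci$ins_pos + 1L,
                      lineage = loci$lineage,
                      in_reference = loci$in_reference,
                      stringsAsFactors = FALSE),
    individuals = cohort$individuals$id,
    values = (cohort$genotypes >= 1L) * 1L), class = "presence_matrix")
}

#' Fraction of loci shared by more than one individual
#'
#' @param pm A `presence_matrix`.
#' @param lineage Lineage label.
#' @return Percentage of the lineage's loci (with at least one carrier)
#'   present in more than one individual; `NA` when the lineage has no such
#'   loci.
#' @export
sharing_fraction <- function(pm, lineage) {
  rows <- which(pm$loci$lineage == lineage)
  if (!length(rows)) return(NA_real_)
  carriers <- rowSums(pm$values[rows, , drop = FALSE])
  carriers <- carriers[carriers >= 1]
  if (!length(carriers)) return(NA_real_)
  100 * mean(carriers > 1)
}

#' Per-lineage locus summary table
#'
#' One row per lineage: identified loci split into assembly (in the
#' reference) and nonassembly classes, with carrier-frequency range and mean
#' per class formatted `"N (lo-hi / mean)"`.
#'
#' @param pm A `presence_matrix`.
#' @return Data frame: lineage, identified_loci, assembly_loci,
#'   assembly_freq, nonassembly_loci, nonassembly_freq, and numeric
#'   assembly/nonassembly carrier means.
#' @export
summarize_lineages <- function(pm) {
  out <- lapply(unique(pm$loci$lineage), function(lin) {
    rows <- which(pm$loci$lineage == lin)
    carriers <- rowSums(pm$values[rows, , drop = FALSE])
    in_ref <- pm$loci$in_reference[rows]
    fmt <- function(cnt) {
      if (!length(cnt)) return("0")
      sprintf("%d (%d-%d / %.1f)", length(cnt), min(cnt), max(cnt),
              mean(cnt))
    }
    data.frame(lineage = lin, identified_loci = length(rows),
               assembly_loci = sum(in_ref),
               assembly_freq = fmt(carriers[in_ref]),
               nonassembly_loci = sum(!in_ref),
               nonassembly_freq = fmt(carriers[!in_ref]),
               assembly_mean_freq = if (any(in_ref))
                 mean(carriers[in_ref]) else NA_real_,
               nonassembly_mean_freq = if (any(!in_ref))
                 mean(carriers[!in_ref]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Row ordering for a locus-sharing heatmap
#'
#' Sorts loci by their presence pattern over a set of focus individuals:
#' descending carrier count, then the binary presence code lexicographically,
#' then locus id — a deterministic, idempotent permutation that groups loci
#' shared by all focus individuals at the top.
#'
#' @param pm A `presence_matrix`.
#' @param focus_individuals Subset of `pm$individuals`.
#' @return Integer permutation of row indices.
#' @export
order_rows_for_heatmap <- function(pm, focus_individuals) {
  stopifnot(all(focus_individuals %in% pm$individuals))
  v <- pm$values[, focus_individuals, drop = FALSE]
  count <- rowSums(v)
  code <- apply(v, 1L, paste, collapse = "")
  order(-count, code, pm$loci$locus_id)
}
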