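#' Default end-to-end run configuration
#'
#' Desk-scale mirror of a three-lineage ERV expansion study: an old lineage
#' (median LTR divergence ~2.2%), an intermediate one (~0.6%) and a very
#' recent one (~0%), surveyed in a cohort of 3 high-coverage (40x) and 8
#' low-coverage (6x) individuals, dated under a mutation-rate interval of
#' 2e-9 to 4.5e-9 substitutions/site/year. Older lineages get a larger
#' reference-assembly fraction and higher allele frequencies (more drift
#' time), which is what produces the assembly-fraction and locus-sharing
#' gradients downstream.
#'
#' @param seed Master seed; every stage derives its own substream from it.
#' @param host_contig_lens Named host contig lengths.
#' @param lineages List of [lineage_spec()]s.
#' @param cohort Data frame (id, coverage).
#' @param read_len,insert_mean,insert_sd,error_rate Read simulation
#'   parameters.
#' @param mu_interval Dating mutation-rate interval (years^-1).
#' @param merge_tolerance_bp Cross-sample locus merge tolerance.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       host_contig_lens = c(chr1 = 400000L),
                       lineages = NULL,
                       cohort = NULL,
                       read_len = 150L, insert_mean = 400L, insert_sd = 50L,
                       error_rate = 0.002,
                       mu_interval = c(2e-9, 4.5e-9),
                       merge_tolerance_bp = 100L) {
  sim_mu <- 3e-9
  if (is.null(lineages)) lineages <- default_lineages(n_scale = 0.5)
  if (is.null(cohort)) {
    cohort <- data.frame(
      id = c(paste0("HC", 1:3), paste0("LC", 1:8)),
      coverage = c(rep(40, 3), rep(6, 8)), stringsAsFactors = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 host_contig_lens = host_contig_lens, lineages = lineages,
                 cohort = cohort, read_len = as.integer(read_len),
                 insert_mean = as.integer(insert_mean),
                 insert_sd = as.integer(insert_sd), error_rate = error_rate,
                 mu_interval = mu_interval,
                 merge_tolerance_bp = as.integer(merge_tolerance_bp)),
            class = "run_config")
}

#' Default three-lineage design
#'
#' Ages are set so the median LTR divergences are ~2.2%, ~0.6% and ~0% under
#' a 3e-9 clock. Population allele frequencies follow a drift-ordered Beta
#' model (older burst, more drift time, higher frequencies): means 0.20,
#' 0.08 and 0.03 with increasing concentration for the younger lineages.
#' Reference-assembly fractions follow the oldest-highest gradient
#' (0.19 / 0.14 / 0.07). Locus counts keep the youngest lineage most
#' numerous; `n_scale` rescales them for smaller hosts.
#'
#' @param n_scale Multiplier on the per-lineage locus counts (30/45/80 at
#'   scale 1).
#' @param mu Simulation substitution rate (default 3e-9).
#' @return List of three [lineage_spec()]s.
#' @export
default_lineages <- function(n_scale = 1, mu = 3e-9) {
  list(
    lineage_spec("betaLike", age_years = 0.022 / (2 * mu), mu = mu,
                 n_loci = max(1L, round(30 * n_scale)), ref_fraction = 0.19,
                 allele_freq = c(3, 12), indel_rate = 1e-10),
    lineage_spec("beta", age_years = 0.006 / (2 * mu), mu = mu,
                 n_loci = max(1L, round(45 * n_scale)), ref_fraction = 0.14,
                 allele_freq = c(2, 23), indel_rate = 1e-10),
    lineage_spec("korv", age_years = 5e4, mu = mu,
                 n_loci = max(1L, round(80 * n_scale)), ref_fraction = 0.07,
                 allele_freq = c(1.5, 48.5), indel_rate = 1e-10))
}

#' Run the full census pipeline on synthetic data
#'
#' simulate -> annotate -> call -> rescue -> merge -> date -> summarise,
#' with every stage's outputs written under `out_dir` and all randomness
#' derived from `config$seed` (re-running with the same config reproduces
#' byte-identical outputs).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param write_sams Write per-individual SAM files (default TRUE; the
#'   in-memory pipeline does not need them).
#' @return Invisibly, a list with the cohort truth, per-individual calls,
#'   the presence matrix, lineage summaries, sharing fractions, dating
#'   tables and truth-evaluation metrics.
#' @export
run_end_to_end <- function(config, out_dir, write_sams = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  ## --- simulate -----------------------------------------------------------
  host <- simulate_host_genome(config$host_contig_lens,
                               seed = derive_seed(seed, 11L))
  cohort <- plant_cohort(host, config$lineages, config$cohort,
                         min_spacing = 2L * config$insert_mean,
                         seed = derive_seed(seed, 12L))
  write_fasta(cohort$reference, file.path(out_dir, "reference.fa"))
  write_fasta(cohort$library$contigs, file.path(out_dir, "library.fa"))
  write_bed(truth_bed(cohort), file.path(out_dir, "truth.bed"))
  gt <- data.frame(locus_id = rep(rownames(cohort$genotypes),
                                  ncol(cohort$genotypes)),
                   individual = rep(colnames(cohort$genotypes),
                                    each = nrow(cohort$genotypes)),
                   genotype = as.vector(cohort$genotypes))
  write_tsv(gt, file.path(out_dir, "cohort_truth.tsv"))
  ref_ervs <- reference_erv_table(cohort)

  ## --- annotate the reference assembly ------------------------------------
  annotations <- annotate_assembly(cohort$reference,
                                   cohort$templates[[1]],
                                   min_identity = 0.8)
  annotations <- lapply(annotations, function(a) {
    a$lineage <- assign_lineage_by_ltr(
      substr(cohort$reference[[a$contig]], a$ltr5_interval[1] + 1L,
             a$ltr5_interval[2]), cohort$library$ltrs)
    a
  })
  ann_tab <- annotation_table(annotations)
  ann_tab$lineage <- vapply(annotations, `[[`, character(1), "lineage")
  write_tsv(ann_tab, file.path(out_dir, "annotations.tsv"))

  ## --- per-individual calling ---------------------------------------------
  ins_calls <- list(); abs_calls <- list(); alns <- list()
  for (i in seq_len(nrow(config$cohort))) {
    id <- config$cohort$id[i]
    cfg <- read_sim_config(read_len = config$read_len,
                           insert_mean = config$insert_mean,
                           insert_sd = config$insert_sd,
                           error_rate = config$error_rate,
                           seed = derive_seed(seed, 13L))
    aln <- simulate_alignments(cohort, id, cfg)
    if (write_sams) write_sam(aln, file.path(out_dir, paste0(id, ".sam")))
    policy <- filter_policy(
      if (config$cohort$coverage[i] >= 20) "hc" else "lc",
      coverage = config$cohort$coverage[i])
    ev <- extract_evidence(aln, cohort$library)
    ins_calls[[id]] <- call_nonreference_insertions(ev, policy)
    abs_calls[[id]] <- call_reference_absences(
      aln, ref_ervs, policy, cohort$reference,
      insert_mean = config$insert_mean, insert_sd = config$insert_sd,
      read_len = config$read_len)
    alns[[id]] <- aln
    write_tsv(calls_table(ins_calls[[id]], abs_calls[[id]]),
              file.path(out_dir, paste0(id, ".calls.tsv")))
  }

  ## --- soft-clip rescue at cross-sample candidate loci --------------------
  merged0 <- merge_loci(ins_calls, config$merge_tolerance_bp)
  cand <- data.frame(locus_id = merged0$loci$locus_id,
                     contig = merged0$loci$contig,
                     pos = merged0$loci$start, stringsAsFactors = FALSE)
  rescued <- list()
  for (i in seq_len(nrow(config$cohort))) {
    id <- config$cohort$id[i]
    policy <- filter_policy(
      if (config$cohort$coverage[i] >= 20) "hc" else "lc",
      coverage = config$cohort$coverage[i])
    rescued[[id]] <- rescue_softclips(alns[[id]], cand, cohort$library,
                                      policy)
  }

  ## --- cohort aggregation --------------------------------------------------
  pm <- build_presence_matrix(merged0, abs_calls, ref_ervs,
                              config$cohort$id, rescued)
  lineage_names <- vapply(config$lineages, `[[`, character(1), "name")
  sharing <- setNames(vapply(lineage_names, function(l)
    sharing_fraction(pm, l), numeric(1)), lineage_names)
  lin_summary <- summarize_lineages(pm)
  write_tsv(lin_summary, file.path(out_dir, "lineage_summary.tsv"))
  write_tsv(presence_matrix_table(pm), file.path(out_dir, "matrix.tsv"))
  n_uni <- nrow(pm$loci)
  write_bed(data.frame(contig = pm$loci$contig, start = pm$loci$start,
                       end = pm$loci$end, name = pm$loci$locus_id,
                       score = rep(0L, n_uni),
                       strand = rep(".", n_uni)),
            file.path(out_dir, "unified_loci.bed"))

  ## --- dating from assembly annotations ------------------------------------
  dating <- do.call(rbind, lapply(annotations, function(a) {
    d <- ltr_divergence(a, cohort$reference[[a$contig]])
    iv <- if (!is.na(d))
      estimate_age_interval(d, config$mu_interval[1], config$mu_interval[2])
    else c(t_low = NA_real_, t_high = NA_real_)
    data.frame(contig = a$contig, start = a$element_interval[1],
               end = a$element_interval[2], lineage = a$lineage,
               ltr_divergence = d,
               age_low_my = format_age_my(iv[["t_low"]]),
               age_high_my = format_age_my(iv[["t_high"]]),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(dating)) write_tsv(dating, file.path(out_dir, "dating.tsv"))

  ## --- evaluation against truth --------------------------------------------
  metrics <- evaluate_against_truth(ins_calls, abs_calls, cohort)
  write_tsv(metrics$per_individual, file.path(out_dir, "metrics.tsv"))

  report <- c(
    "# ERV census run report", "",
    sprintf("seed: %d", seed),
    sprintf("individuals: %s", paste(config$cohort$id, collapse = ", ")),
    sprintf("planted loci: %d", nrow(cohort$loci)),
    sprintf("unified non-reference loci: %d", nrow(merged0$loci)),
    sprintf("reference ERV loci: %d", nrow(ref_ervs)), "",
    "## Sharing fractions (% loci in >1 individual)",
    sprintf("- %s: %.1f", names(sharing), sharing), "",
    "## Mean insertion recall / precision (HC individuals)",
    sprintf("- recall %.3f precision %.3f",
            metrics$hc_insertion_recall, metrics$hc_insertion_precision))
  writeLines(report, file.path(out_dir, "report.md"))

  invisible(list(cohort = cohort, annotations = annotations,
                 ins_calls = ins_calls, abs_calls = abs_calls,
                 rescued = rescued, matrix = pm, sharing = sharing,
                 lineage_summary = lin_summary, dating = dating,
                 metrics = metrics))
}

assign_lineage_by_ltr <- function(ltr_seq, library_ltrs) {
  d <- vapply(library_ltrs, function(l) pairwise_p_distance(ltr_seq, l),
              numeric(1))
  names(library_ltrs)[which.min(d)]
}

calls_table <- function(ins, abs) {
  rbind(
    if (nrow(ins)) data.frame(
      type = "INS", contig = ins$contig, start = ins$bp_start,
      end = ins$bp_end, support = ins$clip5_support + ins$clip3_support +
        ins$pair_support, tier = ins$tier, lineage = ins$lineage,
      tsd_len_est = ins$tsd_len_est, stringsAsFactors = FALSE),
    if (nrow(abs)) data.frame(
      type = "ABS", contig = abs$contig, start = abs$start, end = abs$end,
      support = abs$spanning_support + abs$split_support,
      tier = abs$zygosity_hint, lineage = NA_character_,
      tsd_len_est = NA_integer_, stringsAsFactors = FALSE))
}

presence_matrix_table <- function(pm) {
  cbind(pm$loci, as.data.frame(pm$values))
}

#' Compare calls with simulation truth
#'
#' Per individual: insertion recall and precision against the planted
#' non-reference loci the individual actually carries (breakpoint within
#' `tolerance_bp`); absence recall and precision against reference loci at
#' which the individual lacks at least one allele; genotype concordance at
#' reference loci (called state 2 / 1 / 0 from no-call / het / hom_absent).
#'
#' @param ins_calls_by_individual,abs_calls_by_individual Named lists of call
#'   tables.
#' @param cohort An `erv_cohort` (truth).
#' @param tolerance_bp Breakpoint tolerance (default 25).
#' @return List: `per_individual` data frame, aggregated `hc_*`/`lc_*`
#'   insertion metrics, `absence_recall`, `genotype_concordance`,
#'   `breakpoint_errors` (signed distances of matched calls).
#' @export
evaluate_against_truth <- function(ins_calls_by_individual,
                                   abs_calls_by_individual, cohort,
                                   tolerance_bp = 25L) {
  loci <- cohort$loci
  nonref <- loci[!loci$in_reference, , drop = FALSE]
  refs <- loci[loci$in_reference, , drop = FALSE]
  rows <- list(); bp_err <- numeric()
  for (id in names(ins_calls_by_individual)) {
    g <- cohort$genotypes[, id]
    truth_ins <- nonref[g[nonref$locus_id] >= 1L, , drop = FALSE]
    calls <- ins_calls_by_individual[[id]]
    if (!is.null(calls) && nrow(calls) &&
        !all(calls$contig %in% names(cohort$reference)))
      stop("call contigs do not match the truth reference", call. = FALSE)
    matched_truth <- logical(nrow(truth_ins))
    matched_call <- logical(if (is.null(calls)) 0L else nrow(calls))
    if (!is.null(calls) && nrow(calls)) {
      for (ci in seq_len(nrow(calls))) {
        dd <- ifelse(truth_ins$contig == calls$contig[ci],
                     calls$bp_start[ci] - truth_ins$ins_pos, NA_real_)
        hit <- which(!is.na(dd) & abs(dd) <= tolerance_bp)
        if (length(hit)) {
          hit <- hit[which.min(abs(dd[hit]))]
          matched_truth[hit] <- TRUE
          matched_call[ci] <- TRUE
          bp_err <- c(bp_err, dd[hit])
        }
      }
    }
    truth_abs <- refs[g[refs$locus_id] <= 1L, , drop = FALSE]
    ab <- abs_calls_by_individual[[id]]
    ab_ids <- if (is.null(ab)) character() else ab$locus_id
    gt_called <- setNames(rep(2L, nrow(refs)), refs$locus_id)
    if (length(ab_ids)) {
      gt_called[ab$locus_id[ab$zygosity_hint == "het"]] <- 1L
      gt_called[ab$locus_id[ab$zygosity_hint == "hom_absent"]] <- 0L
    }
    rows[[id]] <- data.frame(
      individual = id,
      n_truth_ins = nrow(truth_ins), n_ins_calls = length(matched_call),
      ins_recall = if (nrow(truth_ins)) mean(matched_truth) else NA_real_,
      ins_precision = if (length(matched_call)) mean(matched_call)
                      else NA_real_,
      n_truth_abs = nrow(truth_abs),
      abs_recall = if (nrow(truth_abs))
        mean(truth_abs$locus_id %in% ab_ids) else NA_real_,
      abs_precision = if (length(ab_ids))
        mean(ab_ids %in% truth_abs$locus_id) else NA_real_,
      genotype_concordance = if (nrow(refs))
        mean(gt_called[refs$locus_id] ==
               pmin(cohort$genotypes[refs$locus_id, id], 2L)) else NA_real_,
      stringsAsFactors = FALSE)
  }
  per_ind <- do.call(rbind, rows)
  rownames(per_ind) <- NULL
  hc <- cohort$individuals$id[cohort$individuals$coverage >= 20]
  lc <- setdiff(cohort$individuals$id, hc)
  agg <- function(col, ids) {
    v <- per_ind[[col]][per_ind$individual %in% ids]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  list(per_individual = per_ind,
       hc_insertion_recall = agg("ins_recall", hc),
       hc_insertion_precision = agg("ins_precision", hc),
       lc_insertion_recall = agg("ins_recall", lc),
       lc_insertion_precision = agg("ins_precision", lc),
       absence_recall = agg("abs_recall", c(hc, lc)),
       genotype_concordance = agg("genotype_concordance", c(hc, lc)),
       breakpoint_errors = bp_err)
}
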