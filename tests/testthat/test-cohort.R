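ins_call <- function(contig, bp, lineage = "beta", tier = "relaxed") {
  data.frame(contig = contig, bp_start = bp, bp_end = bp + 5L,
             clip5_support = 2L, clip3_support = 2L, pair_support = 1L,
             lineage = lineage, tier = tier, tsd_len_est = 5L,
             stringsAsFactors = FALSE)
}

test_that("breakpoints within tolerance merge; distant ones stay apart", {
  m <- merge_loci(list(A = ins_call("c1", 10050L), B = ins_call("c1", 10080L)),
                  tolerance_bp = 100L)
  expect_equal(nrow(m$loci), 1L)
  expect_setequal(m$presence$individual, c("A", "B"))

  m2 <- merge_loci(list(A = ins_call("c1", 10050L),
                        B = ins_call("c1", 10200L)), tolerance_bp = 100L)
  expect_equal(nrow(m2$loci), 2L)

  # clusters never mix lineages
  m3 <- merge_loci(list(A = ins_call("c1", 10050L, "beta"),
                        B = ins_call("c1", 10060L, "korv")))
  expect_equal(nrow(m3$loci), 2L)
  expect_setequal(m3$loci$lineage, c("beta", "korv"))
})

test_that("merging is idempotent and conserves presences", {
  calls <- list(A = rbind(ins_call("c1", 1000L), ins_call("c1", 5000L)),
                B = rbind(ins_call("c1", 1030L), ins_call("c2", 700L)))
  m <- merge_loci(calls)
  expect_equal(nrow(m$presence), 4L)  # one presence per input call
  # re-merging the merged loci as single-individual calls is a no-op
  again <- merge_loci(list(X = data.frame(
    contig = m$loci$contig, bp_start = m$loci$start, bp_end = m$loci$end,
    clip5_support = 1L, clip3_support = 1L, pair_support = 0L,
    lineage = m$loci$lineage, tier = "relaxed", tsd_len_est = NA_integer_,
    stringsAsFactors = FALSE)))
  expect_equal(nrow(again$loci), nrow(m$loci))
  expect_equal(again$loci$start, m$loci$start)
})

test_that("presence matrix encodes carriers and reference absences", {
  m <- merge_loci(list(A = ins_call("c1", 1000L),
                       B = rbind(ins_call("c1", 1010L),
                                 ins_call("c1", 9000L))))
  refs <- data.frame(locus_id = "beta|L001", contig = "c1", start = 20000L,
                     end = 28000L, tsd_len = 5L, lineage = "beta",
                     stringsAsFactors = FALSE)
  abs_calls <- list(A = data.frame(
    locus_id = "beta|L001", contig = "c1", start = 20000L, end = 28000L,
    spanning_support = 10L, split_support = 5L,
    zygosity_hint = "hom_absent", stringsAsFactors = FALSE))
  pm <- build_presence_matrix(m, abs_calls, refs, c("A", "B"))
  expect_equal(dim(pm$values), c(3L, 2L))
  # column sums equal per-individual called locus counts
  expect_equal(unname(colSums(pm$values)), c(1 + 0, 2 + 1))
  # the reference locus is absent in A (hom) and present in B
  expect_equal(unname(pm$values["beta|L001", ]), c(0L, 1L))
  expect_true(pm$loci$in_reference[pm$loci$locus_id == "beta|L001"])
})

test_that("sharing fraction counts multi-carrier loci", {
  mk_pm <- function(patterns, lineage = "x") {
    v <- do.call(rbind, patterns)
    structure(list(
      loci = data.frame(locus_id = paste0("L", seq_along(patterns)),
                        contig = "c", start = seq_along(patterns) * 1000L,
                        end = seq_along(patterns) * 1000L + 5L,
                        lineage = lineage, in_reference = FALSE,
                        stringsAsFactors = FALSE),
      individuals = c("A", "B"),
      values = matrix(v, ncol = 2,
                      dimnames = list(paste0("L", seq_along(patterns)),
                                      c("A", "B")))),
      class = "presence_matrix")
  }
  # {A},{A,B},{B},{A,B},{A} -> 2 of 5 shared
  pm <- mk_pm(list(c(1, 0), c(1, 1), c(0, 1), c(1, 1), c(1, 0)))
  expect_equal(sharing_fraction(pm, "x"), 40)
  expect_equal(sharing_fraction(mk_pm(list(c(1, 0), c(0, 1))), "x"), 0)
  expect_equal(sharing_fraction(mk_pm(list(c(1, 1), c(1, 1))), "x"), 100)
  expect_true(is.na(sharing_fraction(pm, "absent-lineage")))
})

test_that("lineage summary formats Table-1 style rows", {
  loci <- data.frame(
    locus_id = c("R1", "R2", "R3"), contig = "c",
    start = c(1, 2, 3) * 10000L, end = c(1, 2, 3) * 10000L + 8000L,
    lineage = "beta", in_reference = TRUE, stringsAsFactors = FALSE)
  values <- matrix(c(1, 1, 0, 0,
                     1, 1, 1, 0,
                     1, 1, 1, 1), nrow = 3, byrow = TRUE,
                   dimnames = list(loci$locus_id, LETTERS[1:4]))
  pm <- structure(list(loci = loci, individuals = LETTERS[1:4],
                       values = values), class = "presence_matrix")
  s <- summarize_lineages(pm)
  expect_equal(s$identified_loci, 3L)
  expect_identical(s$assembly_freq, "3 (2-4 / 3.0)")
  expect_identical(s$nonassembly_freq, "0")
})

test_that("heatmap ordering is a deterministic idempotent bijection", {
  set.seed(61)
  n <- 20L
  values <- matrix(rbinom(n * 5, 1, 0.4), nrow = n,
                   dimnames = list(sprintf("L%02d", 1:n),
                                   c("HC1", "HC2", "HC3", "LC1", "LC2")))
  pm <- structure(list(
    loci = data.frame(locus_id = rownames(values), contig = "c",
                      start = 1:n, end = 1:n + 5L, lineage = "x",
                      in_reference = FALSE, stringsAsFactors = FALSE),
    individuals = colnames(values), values = values),
    class = "presence_matrix")
  ord <- order_rows_for_heatmap(pm, c("HC1", "HC2", "HC3"))
  expect_setequal(ord, seq_len(n))
  counts <- rowSums(values[ord, c("HC1", "HC2", "HC3")])
  expect_true(all(diff(counts) <= 0))  # descending carrier count
  # idempotent: re-ordering the ordered matrix is the identity
  pm2 <- pm
  pm2$values <- values[ord, ]
  pm2$loci <- pm$loci[ord, ]
  expect_equal(order_rows_for_heatmap(pm2, c("HC1", "HC2", "HC3")),
               seq_len(n))
})

test_that("merged loci match simulator truth on a full cohort", {
  cc <- small_cohort(seed = 63, contig_len = 150000L,
                     cohort = data.frame(id = c("HC1", "HC2"),
                                         coverage = c(40, 40)),
                     n_loci = c(3L, 3L, 3L), ref_fraction = c(0, 0, 0))
  cfg_seed <- 10L
  ins <- list(); policy <- filter_policy("hc", coverage = 40)
  for (id in c("HC1", "HC2")) {
    aln <- simulate_alignments(cc, id, read_sim_config(error_rate = 0.002,
                                                       seed = cfg_seed))
    ins[[id]] <- call_nonreference_insertions(
      extract_evidence(aln, cc$library), policy)
  }
  m <- merge_loci(ins)
  g <- cc$genotypes
  carried <- rowSums(g >= 1) > 0
  expect_equal(nrow(m$loci), sum(carried))
  # each merged locus sits within 25 bp of a distinct truth locus
  d <- vapply(seq_len(nrow(m$loci)), function(i)
    min(abs(cc$loci$ins_pos - m$loci$start[i])), numeric(1))
  expect_true(all(d <= 25))
})
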