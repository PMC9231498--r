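make_library <- function() {
  tpls <- lineage_templates(test_template(), c("beta", "korv"), seed = 50)
  erv_library(tpls)
}

test_that("evidence extraction keeps LTR-matching clips and drops junk", {
  lib <- make_library()
  ltr <- lib$ltrs[["beta"]]
  host_seq <- ervcensus:::random_dna(150)
  aln <- rbind(
    # trailing clip holding the start of the beta LTR: 5'-side evidence
    aln_row("r1", "chr1", 1001L, "30M120S",
            paste0(substr(host_seq, 1, 30), substr(ltr, 1, 120))),
    # leading clip holding the LTR end: 3'-side evidence
    aln_row("r2", "chr1", 1031L, "120S30M",
            paste0(substr(ltr, 381, 500), substr(host_seq, 31, 60))),
    # homopolymer clip: removed by the entropy filter
    aln_row("r3", "chr1", 1200L, "30M120S",
            paste0(substr(host_seq, 1, 30), strrep("A", 120))),
    # clip of random host sequence: no LTR match
    aln_row("r4", "chr1", 1300L, "30M120S", ervcensus:::random_dna(150)),
    # discordant pair: mate on a library contig
    aln_row("r5", "chr1", 900L, "150M", ervcensus:::random_dna(150),
            rnext = "lib_beta"),
    # record on a library contig itself: never evidence
    aln_row("r6", "lib_beta", 10L, "30M120S",
            paste0(substr(ltr, 1, 30), substr(ltr, 31, 150))))
  aln <- aln[order(aln$rname, aln$pos), ]
  ev <- extract_evidence(aln, lib)
  expect_equal(nrow(ev$softclips), 2L)
  expect_setequal(ev$softclips$qname, c("r1", "r2"))
  expect_identical(sort(ev$softclips$side), c("3", "5"))
  expect_true(all(ev$softclips$lineage == "beta"))
  expect_equal(ev$softclips$clip_point[ev$softclips$qname == "r1"], 1030L)
  expect_equal(ev$softclips$clip_point[ev$softclips$qname == "r2"], 1030L)
  expect_equal(nrow(ev$discordant), 1L)
  expect_identical(ev$discordant$lineage, "beta")

  unsorted <- aln[c(2, 1), ]
  expect_error(extract_evidence(unsorted, lib), "sorted")
  empty <- extract_evidence(aln[0, ], lib)
  expect_equal(nrow(empty$softclips), 0L)
})

test_that("the dinucleotide entropy filter separates repeats from sequence", {
  expect_equal(dinucleotide_entropy(strrep("A", 50)), 0)
  expect_lt(dinucleotide_entropy(strrep("AT", 25)), 1.01)
  set.seed(41)
  expect_gt(dinucleotide_entropy(ervcensus:::random_dna(100)), 3)
})

test_that("insertion calling applies tiers, thresholds and TSD refinement", {
  policy <- filter_policy("hc", coverage = 40)
  ev <- function(clip5_at, clip3_at, pairs_at) {
    structure(list(
      softclips = rbind(
        if (length(clip5_at)) data.frame(
          contig = "c", clip_point = clip5_at, side = "5", len = 50L,
          lineage = "beta", qname = paste0("a", seq_along(clip5_at)),
          stringsAsFactors = FALSE),
        if (length(clip3_at)) data.frame(
          contig = "c", clip_point = clip3_at, side = "3", len = 50L,
          lineage = "beta", qname = paste0("b", seq_along(clip3_at)),
          stringsAsFactors = FALSE)),
      discordant = if (length(pairs_at)) data.frame(
        contig = "c", pos = pairs_at, side = "5", lineage = "beta",
        qname = paste0("p", seq_along(pairs_at)),
        stringsAsFactors = FALSE) else
          data.frame(contig = character(), pos = integer(),
                     side = character(), lineage = character(),
                     qname = character())),
      class = "erv_evidence") -> out
    if (is.null(out$softclips)) out$softclips <- ervcensus:::empty_softclips()
    out
  }
  # planted TSD of 6: 5'-clips at 1006, 3'-clips at 1000
  full <- call_nonreference_insertions(
    ev(rep(1006L, 3), rep(1000L, 3), rep(950L, 4)), policy)
  expect_equal(nrow(full), 1L)
  expect_identical(full$tier, "stringent")
  expect_equal(full$tsd_len_est, 6L)
  expect_equal(full$bp_start, 1000L)
  expect_equal(full$bp_end, 1006L)

  # two pairs only: relaxed, never stringent
  weak <- call_nonreference_insertions(ev(integer(), integer(),
                                          c(950L, 960L)), policy)
  expect_identical(weak$tier, "relaxed")

  # a single read of support: no call
  none <- call_nonreference_insertions(ev(1006L, integer(), integer()),
                                       policy)
  expect_equal(nrow(none), 0L)

  # clusters 1 kb apart stay distinct
  two <- call_nonreference_insertions(
    ev(c(rep(1006L, 3), rep(2006L, 3)), c(rep(1000L, 3), rep(2000L, 3)),
       integer()), policy)
  expect_equal(nrow(two), 2L)

  # support above the coverage sanity window: relaxed only
  noisy <- call_nonreference_insertions(
    ev(rep(1006L, 150), rep(1000L, 150), integer()), policy)
  expect_identical(noisy$tier, "relaxed")
})

test_that("stringent calls are a subset of relaxed calls on real evidence", {
  cc <- small_cohort(seed = 43, contig_len = 120000L,
                     cohort = data.frame(id = "HC1", coverage = 40),
                     n_loci = c(2L, 2L, 2L), ref_fraction = c(0, 0, 0))
  aln <- simulate_alignments(cc, "HC1",
                             read_sim_config(error_rate = 0.002, seed = 8))
  ev <- extract_evidence(aln, cc$library)
  policy <- filter_policy("hc", coverage = 40)
  calls <- call_nonreference_insertions(ev, policy)
  stringent <- calls[calls$tier == "stringent", ]
  # every stringent call satisfies the relaxed threshold componentwise
  expect_true(all(stringent$clip5_support >= policy$min_clip_each_side))
  expect_true(all(stringent$clip3_support >= policy$min_clip_each_side))
  total <- calls$clip5_support + calls$clip3_support + calls$pair_support
  expect_true(all(total >= policy$relaxed_min))
  expect_true(all(total[calls$tier == "stringent"] >= policy$min_reads))
  # no call on library contigs
  expect_true(all(!startsWith(calls$contig, "lib_")))
})

test_that("reference absences are called with correct zygosity", {
  host <- simulate_host_genome(c(c1 = 120000L), seed = 44)
  cc <- plant_cohort(
    host,
    list(lineage_spec("beta", 1e6, mu = 3e-9, n_loci = 3L,
                      ref_fraction = 1,
                      allele_freq = function(n) c(0, 0.5, 1)[seq_len(n)])),
    data.frame(id = "HC1", coverage = 40), seed = 44)
  refs <- reference_erv_table(cc)
  g <- cc$genotypes[refs$locus_id, "HC1"]
  aln <- simulate_alignments(cc, "HC1",
                             read_sim_config(error_rate = 0.002, seed = 9))
  policy <- filter_policy("hc", coverage = 40)
  abs_calls <- call_reference_absences(aln, refs, policy, cc$reference)
  called <- setNames(rep("present", nrow(refs)), refs$locus_id)
  called[abs_calls$locus_id] <- abs_calls$zygosity_hint
  for (id in refs$locus_id) {
    expected <- c("hom_absent", "het", "present")[g[id] + 1L]
    expect_identical(unname(called[id]), expected)
  }
  expect_true(all(abs_calls$spanning_support + abs_calls$split_support >=
                    policy$min_reads))
})

test_that("soft-clip rescue recovers scattered junction support", {
  lib <- make_library()
  ltr <- lib$ltrs[["korv"]]
  host_seq <- ervcensus:::random_dna(200)
  # two clips at the same breakpoint: discovery-grade support 2
  aln <- rbind(
    aln_row("r1", "chr1", 4971L, "30M120S",
            paste0(substr(host_seq, 1, 30), substr(ltr, 1, 120))),
    aln_row("r2", "chr1", 4966L, "35M115S",
            paste0(substr(host_seq, 36, 70), substr(ltr, 1, 115))))
  aln <- aln[order(aln$pos), ]
  policy <- filter_policy("lc", coverage = 6)
  ev <- extract_evidence(aln, lib)
  expect_equal(nrow(call_nonreference_insertions(ev, policy)), 1L)
  # force the discovery-consistency situation: clip points 5000 and 5040
  aln2 <- rbind(
    aln_row("r1", "chr1", 4971L, "30M120S",
            paste0(substr(host_seq, 1, 30), substr(ltr, 1, 120))),
    aln_row("r2", "chr1", 5021L, "20M130S",
            paste0(substr(host_seq, 41, 60), substr(ltr, 1, 130))))
  ev2 <- extract_evidence(aln2, lib)
  expect_equal(nrow(call_nonreference_insertions(ev2, policy)), 0L)
  cand <- data.frame(locus_id = c("L1", "L2"), contig = "chr1",
                     pos = c(5000L, 90000L), stringsAsFactors = FALSE)
  resc <- rescue_softclips(aln2, cand, lib, policy)
  expect_true(resc$present[resc$locus_id == "L1"])
  expect_equal(resc$clip_support[resc$locus_id == "L1"], 2L)
  # a locus with no nearby clips is untouched
  expect_equal(resc$clip_support[resc$locus_id == "L2"], 0L)
  expect_false(resc$present[resc$locus_id == "L2"])
  # idempotence: rescuing an already-supported locus does not change presence
  resc2 <- rescue_softclips(aln, cand, lib, policy)
  expect_true(resc2$present[resc2$locus_id == "L1"])
})
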