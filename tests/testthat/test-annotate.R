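test_that("a planted provirus is found with exact boundaries", {
  set.seed(31)
  tpl <- test_template()
  host <- ervcensus:::random_dna(100000)
  elem <- template_sequence(tpl)
  ins_at <- 50000L
  contig <- paste0(substr(host, 1, ins_at), "ACGTAG", elem, "ACGTAG",
                   substr(host, ins_at + 7, 100000))
  pairs <- find_ltr_pairs(contig)
  expect_equal(nrow(pairs), 1L)
  truth5 <- ins_at + 6L
  expect_lte(abs(pairs$ltr5_start - truth5), 5)
  expect_lte(abs(pairs$ltr5_end - (truth5 + 500L)), 5)
  expect_lte(abs(pairs$ltr3_start - (truth5 + nchar(elem) - 500L)), 5)
  expect_lte(abs(pairs$ltr3_end - (truth5 + nchar(elem))), 5)
  expect_gte(pairs$identity, 0.99)

  ann <- classify_structure("c", contig, pairs[1, ], tpl)
  expect_identical(ann$structure_tokens,
                   c("5LTR", "gag", "pro", "pol", "env", "3LTR"))
  expect_true(ann$full_length)
  # boundary is ambiguous by <=1 base when a flank base matches the LTR end
  expect_lte(abs(ann$tsd_len - 6L), 1L)
  expect_equal(nchar(ann$tsd_seq), ann$tsd_len)
  # at the true interval the TSD is exact
  expect_equal(detect_tsd(contig, c(truth5, truth5 + nchar(elem))),
               list(tsd_len = 6L, tsd_seq = "ACGTAG"))
})

test_that("element-free random sequence yields no candidates", {
  for (s in 1:5) {
    set.seed(1000 + s)
    expect_equal(nrow(find_ltr_pairs(ervcensus:::random_dna(40000),
                                     min_identity = 0.85)), 0L)
  }
})

test_that("identity threshold separates mutated LTR pairs", {
  set.seed(33)
  tpl <- test_template()
  # mutate one LTR at exactly 30 of 500 sites (94% identity)
  ltr2 <- strsplit(tpl$ltr, "")[[1]]
  at <- sample(500, 30)
  ltr2[at] <- vapply(ltr2[at], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  ltr2 <- paste(ltr2, collapse = "")
  contig <- paste0(ervcensus:::random_dna(20000), tpl$ltr, tpl$internal,
                   ltr2, ervcensus:::random_dna(20000))
  expect_equal(nrow(find_ltr_pairs(contig, min_identity = 0.85)), 1L)
  expect_equal(nrow(find_ltr_pairs(contig, min_identity = 0.95)), 0L)
})

test_that("TSD detection is exact, bounded and edge-safe", {
  mid <- strrep("T", 40)
  expect_equal(detect_tsd(paste0("ACGTAG", mid, "ACGTAG"), c(6L, 46L)),
               list(tsd_len = 6L, tsd_seq = "ACGTAG"))
  # no shared flank
  expect_equal(detect_tsd(paste0("AAACCC", mid, "GGGTTT"),
                          c(6L, 46L))$tsd_len, 0L)
  # element at contig edge: search over available flank only
  expect_equal(detect_tsd(paste0("AG", mid, "AGCCCC"), c(2L, 42L))$tsd_len,
               2L)
})

test_that("TSD length is invariant under reverse complement", {
  set.seed(35)
  for (i in 1:8) {
    left <- ervcensus:::random_dna(30)
    tsd <- ervcensus:::random_dna(5)
    elem <- ervcensus:::random_dna(60)
    right <- ervcensus:::random_dna(30)
    ctg <- paste0(left, tsd, elem, tsd, right)
    iv <- c(35L, 100L)  # element after first TSD copy
    fwd <- detect_tsd(ctg, iv)$tsd_len
    n <- nchar(ctg)
    rc <- ervcensus:::revcomp(ctg)
    iv_rc <- c(n - iv[2], n - iv[1])
    expect_equal(detect_tsd(rc, iv_rc)$tsd_len, fwd)
  }
})

test_that("gene profiling counts stops and frameshifts in template frame", {
  tpl <- test_template()
  elem <- template_sequence(tpl)
  clean <- profile_genes(elem, tpl)
  for (g in c("gag", "pro", "pol", "env")) {
    expect_true(clean[[g]]$detected)
    expect_equal(clean[[g]]$identity, 1)
    expect_equal(clean[[g]]$n_stops, 0L)
    expect_equal(clean[[g]]$n_frameshifts, 0L)
  }

  pol <- tpl$gene_map$pol + tpl$ltr_len
  stopped <- elem
  cs <- pol[1] + 300L  # codon boundary inside pol
  substr(stopped, cs + 1, cs + 3) <- "TAA"
  p <- profile_genes(stopped, tpl)
  expect_equal(p$pol$n_stops, 1L)
  expect_equal(p$pol$n_frameshifts, 0L)
  expect_equal(p$gag$n_stops, 0L)

  shifted <- paste0(substr(elem, 1, pol[1] + 500),
                    substr(elem, pol[1] + 502, nchar(elem)))
  p2 <- profile_genes(shifted, tpl)
  expect_equal(p2$pol$n_frameshifts, 1L)

  # gene replaced by unrelated sequence: undetected, not mutation-free
  env <- tpl$gene_map$env + tpl$ltr_len
  set.seed(36)
  scrambled <- paste0(substr(elem, 1, env[1]),
                      ervcensus:::random_dna(env[2] - env[1]),
                      substr(elem, env[2] + 1, nchar(elem)))
  p3 <- profile_genes(scrambled, tpl)
  expect_false(p3$env$detected)
  expect_true(is.na(p3$env$n_stops))
})

test_that("structure classification distinguishes full, deleted and solo", {
  set.seed(37)
  tpl <- test_template()
  # internal deletion removing env
  env <- tpl$gene_map$env + tpl$ltr_len
  elem <- template_sequence(tpl)
  deleted <- paste0(substr(elem, 1, env[1]), substr(elem, env[2] + 1,
                                                    nchar(elem)))
  ctg <- paste0(ervcensus:::random_dna(15000), "AACCGT", deleted, "AACCGT",
                ervcensus:::random_dna(15000))
  pairs <- find_ltr_pairs(ctg, element_len_range = c(4000, 15000))
  expect_equal(nrow(pairs), 1L)
  ann <- classify_structure("c", ctg, pairs[1, ], tpl)
  expect_false(ann$full_length)
  expect_false("env" %in% ann$structure_tokens)
  expect_true(all(c("gag", "pro", "pol") %in% ann$structure_tokens))

  solo <- classify_structure("c", ctg, NULL, tpl,
                             solo_ltr_interval = c(100L, 600L))
  expect_true(solo$solo_ltr)
  expect_identical(solo$structure_tokens, "5LTR")
  expect_false(solo$full_length)
})

test_that("age-0 planted cohorts are annotated with full recall", {
  cc <- small_cohort(seed = 39, contig_len = 120000L,
                     cohort = data.frame(id = "A", coverage = 10),
                     n_loci = c(0L, 0L, 4L), ref_fraction = c(0, 0, 1))
  anns <- annotate_assembly(cc$reference, cc$templates[["korv"]],
                            min_identity = 0.85)
  truth <- reference_erv_table(cc)
  expect_equal(length(anns), nrow(truth))
  tab <- annotation_table(anns)
  tab <- tab[order(tab$start), ]
  truth <- truth[order(truth$start), ]
  expect_true(all(abs(tab$start - truth$start) <= 5))
  expect_true(all(abs(tab$end - truth$end) <= 5))
  expect_true(all(tab$full_length))
  # exact TSD recovery at every age-0 locus, measured at the truth interval
  for (j in seq_len(nrow(truth))) {
    det <- detect_tsd(cc$reference[[truth$contig[j]]],
                      c(truth$start[j], truth$end[j]))
    expect_equal(det$tsd_len, truth$tsd_len[j])
  }
  # annotated-boundary TSD agrees within the boundary ambiguity
  expect_true(all(abs(tab$tsd_len - truth$tsd_len) <= 2))
})
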