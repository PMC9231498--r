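# Shared fixtures, built in code. The template is deterministic in its seed,
# so every test file sees the same provirus.

test_template <- function() provirus_template(seed = 42L)

# A small three-lineage cohort with read-level signatures: one contig,
# mixed reference / non-reference loci, one HC and one LC individual.
small_cohort <- function(seed = 1L, contig_len = 150000L,
                         cohort = data.frame(id = c("HC1", "LC1"),
                                             coverage = c(40, 6)),
                         n_loci = c(3L, 3L, 3L),
                         ref_fraction = c(0.4, 0.3, 0),
                         allele_freq = list(c(2, 2), c(2, 2), c(2, 2))) {
  host <- simulate_host_genome(c(chrT = contig_len), seed = seed)
  lineages <- list(
    lineage_spec("betaLike", 3.667e6, mu = 3e-9, n_loci = n_loci[1],
                 ref_fraction = ref_fraction[1],
                 allele_freq = allele_freq[[1]], indel_rate = 1e-10),
    lineage_spec("beta", 1e6, mu = 3e-9, n_loci = n_loci[2],
                 ref_fraction = ref_fraction[2],
                 allele_freq = allele_freq[[2]], indel_rate = 1e-10),
    lineage_spec("korv", 5e4, mu = 3e-9, n_loci = n_loci[3],
                 ref_fraction = ref_fraction[3],
                 allele_freq = allele_freq[[3]]))
  plant_cohort(host, lineages, cohort, seed = seed)
}

# Hamming-based distance oracle for gap-free, equal-length sequences --
# independent of the alignment-based implementation.
hamming_p <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  mean(ca != cb)
}

# Minimal hand-built alignment rows for caller unit tests.
aln_row <- function(qname, rname, pos, cigar, seq, rnext = "=", flag = 99L,
                    pnext = pos, tlen = 0L) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = 60L, cigar = cigar, rnext = rnext, pnext = pnext,
             tlen = tlen, seq = seq, stringsAsFactors = FALSE)
}
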