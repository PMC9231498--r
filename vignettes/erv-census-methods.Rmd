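---
title: "Methods: simulating and censusing endogenous retrovirus expansions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and censusing endogenous retrovirus expansions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervcensus)
```

## The problem

Endogenous retroviruses (ERVs) are proviruses fixed or segregating in a host
germline. A recent invasion leaves a characteristic record: many insertion
loci polymorphic across individuals, nearly identical 5' and 3' long
terminal repeats (LTRs) within each copy, and intact-looking coding genes.
An old invasion leaves the opposite: loci shared by most individuals and
carried by the reference assembly, diverged LTR pairs, and gag/pro/pol/env
reading frames littered with stops and frameshifts. `ervcensus` implements
the full analysis loop for such data — at desk scale, on synthetic genomes
with known truth — so every stage (annotation, presence/absence calling,
dating, cohort summarisation) can be validated quantitatively.

## The simulator and what it emulates

`plant_cohort()` plants proviruses from up to several lineages into a random
host genome. Each copy derives from a lineage template (two identical
500 bp LTRs around a 7.3 kb internal region with single-ORF gag, pro, pol
and env genes) evolved for its own age by `evolve_copy()`:

* substitutions: each site independently with probability `mu * age`
  (single-hit Jukes–Cantor regime, uniform among the three alternatives);
  the two LTRs evolve independently, so the expected observed LTR-pair
  divergence is `2 * mu * age`;
* indels of 1–3 bp at `indel_rate * age` per site, which generate the
  frameshift component of coding decay; premature stops arise from the
  substitution process itself.

Integration biology is modelled explicitly: a 4–6 bp target site
duplication (TSD) flanks every element, strand is random, and loci are
spaced at least two insert sizes apart (overlapping evidence clusters are a
regime the downstream statistics never see, so the simulator excludes it).
Population state is a per-locus allele frequency; individual genotypes are
binomial draws, and a configured fraction of loci — sampled with weights
proportional to allele frequency, because the assembly individual is itself
a population sample — is written into the reference assembly haplotype.

`simulate_alignments()` emulates mapping instead of running an aligner.
Read placement is truth-guided with CIGARs from junction arithmetic: host
reads map concordantly; reads crossing a non-reference junction are
soft-clipped with the match extending through the TSD (so 5'- and
3'-anchored clips bracket it — the "heightened coverage" interval at a
breakpoint); reads inside non-reference elements map to the lineage's
library contig, making their host-anchored mates discordant; haplotypes in
the preintegration state at a reference ERV yield stretched apparent
inserts and flank-matching split reads. One deliberate imperfection is
included: with probability `clip_jitter_prob` (default 0.25) the matched
segment of a junction read over-extends by up to 30 bp, emulating aligner
end-placement ambiguity. Without it every clip falls on the exact junction
base — something no real BAM exhibits — and the low-coverage rescue step
would have nothing to act on.

What the simulator does *not* model — duplicates, base-quality variation,
coverage bias, mapping ambiguity in repeats, microhomology — bounds what
green tests mean: they validate the algorithms' logic and calibration, not
robustness to every artefact of production sequencing. This matters most
for the low-coverage rescue experiment (below).

## Annotation

`find_ltr_pairs()` seeds exact 12-mer anchor pairs whose separation lies in
the element-length window, chains them on near-constant diagonals, and
validates candidates by global alignment of the two repeat copies
(identity at least `min_identity`, default 0.85). Overlap resolution is
leftmost-first, then longest. A detected boundary can be ambiguous by a
base or two when a flanking base coincidentally equals the opposite LTR
end; the TSD reported at the detected boundary inherits that ambiguity,
which is why exact-TSD validation is always done against truth intervals.

`profile_genes()` aligns the element to the template globally and counts,
per gene, identity over aligned columns, premature stops in the template
frame, and frame-disrupting indel events (length not a multiple of 3). Gap
extension is kept expensive (10/4 open/extend with match/mismatch +1/−1):
cheap extension lets an unrelated region inflate its aligned-column
identity above 0.4 by gapping around mismatches; at these penalties random
DNA aligns near 0.33, safely below the 0.4 detection threshold, while the
1–3 bp biological indels still gap correctly. A gene below threshold is
reported *undetected*, never as mutation-free. Full length requires both
LTRs plus all four genes.

## Calling

`extract_evidence()` keeps soft-clips of at least 10 bp that pass a
dinucleotide-entropy filter (< 1 bit discarded — homopolymers and simple
repeats) and locally align to a library LTR at ≥ 80% identity with ≥ 10
matching bases *and* ≥ 80% of the clip covered. The coverage requirement is
the package's tightening of the classic identity/score pair: without it,
~12 bp chance islands inside host-derived clips at deletion junctions pass
and seed false insertion calls. Discordant host/library pairs contribute
their junction-proximal anchor edge.

`call_nonreference_insertions()` clusters evidence within 200 bp. Discovery
support counts clips consistent with the modal clip point of each side
(± 8 bp) plus pairs; the breakpoint interval spans the two modal clip
points and its width estimates the TSD. Tiers: *stringent* needs ≥ 2
consistent clips per side and total support within a coverage sanity
window; *relaxed* needs 2 supporting reads. The sanity window's upper bound
is 5× coverage, not 3×: a homozygous diploid locus contributes clip and
pair evidence from both haplotypes, measured at ~3.1× coverage, so a 3×
bound systematically rejects true homozygous insertions while genuine
repeat-driven pileups sit an order of magnitude higher.

`call_reference_absences()` tests each reference ERV locus for the
preintegration state: spanning pairs whose apparent insert is stretched by
the element length (± 4 insert-size standard deviations) and split reads
clipped at the locus flanks whose clip matches the opposite flank. The
zygosity hint compares concordant coverage inside the element against half
the single-haplotype expectation.

`rescue_softclips()` pools, per candidate locus (typically discovered in
other individuals), *all* LTR-matching clips and pairs within ± 300 bp —
including clips that discovery discarded as inconsistent — and types the
locus present when pooled support reaches the relaxed minimum. This is the
step that benefits low-coverage samples, whose junction evidence is sparse
and scattered.

## Dating

Distances are raw p-distances over aligned, ungapped columns of a global
pairwise alignment; no multiple-hit correction is applied because the clock
is applied directly to raw divergence at the ≤ 7% levels involved, and
pairwise alignment replaces a multiple alignment for the same reason (at
these divergences the column sets agree closely). The clock is
`t = d / (2 * mu)`: both LTRs accumulate substitutions independently after
integration, hence the factor 2. Rate uncertainty is carried as an interval
(defaults 2e-9 to 4.5e-9 substitutions/site/year, slow and fast mammalian
germline rates), and ages display-round to one decimal in millions of
years, which reproduces the conventional presentation of such windows
(5.5 / 2.4 / 1.5 / 0.7 My for median divergences 2.2% and 0.6%). A solo LTR
has no divergence and is reported missing, never 0.

## Cohort statistics

`merge_loci()` single-links breakpoints within 100 bp per contig and
lineage (clip-refined breakpoints scatter far less; the tolerance is
insert-size-scale caution), splitting clusters that mix lineages.
`build_presence_matrix()` adds reference loci, which are carriers for every
individual unless homozygous absence is called, and are retained with a
flag even with zero resequenced carriers. Sharing fractions and the
Table-1-style lineage summary (`"N (lo-hi / mean)"` carrier-frequency
format) follow.

## Design of the default lineage configuration

The three default lineages (`default_lineages()`) place their median
LTR-pair divergences at ~2.2%, ~0.6% and ~0% — an old, an intermediate and
a very recent expansion under a 3e-9 clock, with per-copy ages uniform over
0.5–1.5× the burst age. Allele frequencies follow a drift-ordered Beta
model: means 0.20, 0.08 and 0.03 with increasing concentration for younger
lineages, and reference-assembly fractions 0.19 / 0.14 / 0.07. The means
were chosen by an explicit power analysis: the designed property is that
the age gradient is visible as strictly ordered sharing fractions across
11 individuals in ≥ 95 of 100 simulation seeds, which requires roughly 25+
detected loci per lineage and sharing separations of ~25 points
(normal-approximation power ≈ 99%). Published cohort studies of this size
report sharing separations of single-digit points across hundreds of loci;
a desk-scale cohort cannot resolve those, so the defaults trade absolute
realism of the percentages for a statistically resolvable ordering, which
is the property under test. Both the frequency model and all counts are
configurable per `lineage_spec()`.

## Numerical and reproducibility choices

* All randomness flows from one integer seed; stages derive independent
  substreams by fixed offsets, so re-running a stage never perturbs
  another. `run_end_to_end()` is byte-deterministic.
* Alignment scoring is explicit everywhere (match +1 / mismatch −1 for
  global distance and profiling, +2/−3 BLAST-like for local clip matching):
  the quality-based default scoring path is both slower and dependent on
  quality conventions the simulator does not model.
* Degenerate inputs are contracts, not accidents: zero-locus lineages
  return the untouched host and empty truth; infeasible spacing is an
  explicit error, never silent truncation; empty alignments yield empty
  evidence; unsorted alignments are rejected.
* Problem sizes in the validation suite — 200 clock-recovery replicates,
  100 ordering and gradient seeds, a 1 Mb / 30-locus genome for caller
  benchmarking, 10 paired seeds for the rescue comparison — were chosen as
  the smallest designs at which the tested properties have adequate
  statistical resolution.

## Known limitations

* The alignment emulator's fidelity bounds the rescue experiment: with
  uniform coverage and truth-guided placement, a 6× individual retains
  ~7 usable junction reads per heterozygous locus, so relaxed-threshold
  discovery already detects essentially every carried locus and pooled
  rescue changes nothing — measured recall gain across 10 paired cohort
  seeds is 0 (it is never negative, and precision never decreases). The
  rescue mechanism itself is validated on constructed sparse-evidence
  fixtures (one exact clip plus one scattered clip upgrades a locus under
  the relaxed policy). Demonstrating a positive *population-scale* gain
  would require emulating production-mapper losses (duplicates, quality
  filtering, repeat mis-mapping) that are out of scope here.
* The annotator's boundary ambiguity (± 1–2 bp at coincidental flank
  matches) propagates to annotated-boundary TSD lengths.
* `find_ltr_pairs()` assumes LTR pairs within one element-length window;
  solo-LTR discovery requires the caller to supply candidate intervals.
* The evolution model has no rate heterogeneity, selection or gene
  conversion; LTR-pair divergence is a pure two-branch clock by
  construction, which is exactly what makes parameter recovery testable.
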