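---
title: "UMI amplicon consensus, HLA typing and allele-specific expression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UMI amplicon consensus, HLA typing and allele-specific expression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umihla)
```

## The problem

Long-read sequencers make full-length cDNA amplicons of the highly
polymorphic HLA genes easy to sequence, but their raw per-base accuracy
(roughly 88–94% depending on chemistry) is far too low to distinguish
alleles that differ at a handful of positions. Attaching a random
oligonucleotide — a unique molecular identifier (UMI) — to each input
molecule before PCR solves two problems at once: reads sharing a UMI are
PCR copies of one molecule, so (i) collapsing them to a consensus removes
random sequencing error, and (ii) counting distinct UMIs counts input
transcripts rather than PCR products, giving allele-specific expression
estimates.

`umihla` implements the computational half of such an assay as a set of
composable stages, together with a fully ground-truthed read simulator
used to validate every stage.

## Pipeline model

A read is modelled as

```
fwd_primer + UMI_f + insert + UMI_r + revcomp(rev_primer)
```

with dual 12-mer UMIs, one inside each locus-specific primer. The stages
are:

1. **Orientation and trimming** (`tag_reads()`). Both orientations of each
   read are scanned with a semi-global (pattern-global, subject-local)
   edit-distance search: the forward primer within the first `window`
   (default 64) bases, the reverse-complemented reverse primer within the
   last `window` bases, each within an edit budget of 20% of the primer
   length. The amplicon whose primer pair matches with the fewest total
   edits wins; ties across amplicons reject the read
   (`ambiguous_amplicon`), no qualifying pair rejects it (`no_primer`).
   The UMIs are the 12 bases immediately inside each primer match, and
   primers + UMIs are trimmed from the retained insert.

2. **UMI clustering** (`group_umis()`). Sequencing errors corrupt the tag
   as well as the insert, so exact-match deduplication would shatter
   molecules into many small groups. We use greedy directional
   clustering on the concatenated 24-nt tag: unique UMIs are processed in
   descending count order and merge into an existing group when the
   Levenshtein distance to the group centroid is ≤ 2 *and* their count is
   ≤ `ceiling(centroid_count / 2)`. Levenshtein (not Hamming) distance is
   used because long-read errors include indels. Both thresholds are
   configuration; the defaults follow common directional-clustering
   practice. Grouping on the dual-end concatenated tag doubles the tag
   length and so makes UMI collisions between distinct molecules
   negligible at desk scale (the simulator records any collision it
   creates rather than hiding it).

3. **Consensus** (`call_consensus()`). Groups below `min_reads` are
   dropped first (`filter_groups()`); `min_reads = 1` is pure PCR
   deduplication, `min_reads = 10` the stringent consensus mode. Each
   member is globally aligned to a representative (the member of median
   length, lower median, ties by quality then read id) with an
   affine-gap Needleman–Wunsch aligner (match +2, mismatch −4, gap open
   −4, extend −2; compiled, optionally banded). Per alignment column the
   plurality symbol wins, ties break toward the representative's base,
   gap-winning columns are deleted, and insertions relative to the
   representative are kept only when a strict majority of members carries
   one — deliberately conservative, because indels dominate the nanopore
   error profile. This is a pileup majority vote, not a neural polisher:
   it is deterministic, dependency-free, and at a group size of 10 it
   already reduces the 6% substitution error of single reads to well
   below one error per 500-bp molecule (see the acceptance suite). It
   makes no claim of equivalence with signal-level polishing.

4. **Typing** (`assign_alleles()`, `call_genotypes()`). Each consensus is
   aligned on both strands against the alleles of the loci covered by its
   amplicon (an amplicon may cover several loci, as with a shared
   DRB1/3/4/5 primer pair); identity is matches over alignment columns.
   Assignments below `min_identity` (default 85%, tolerant of residual
   min1 noise) are tallied as unassigned. Per locus, the top allele by
   UMI count is always called; a second allele is called when its share
   of the top-two counts is at least `min_minor_fraction` (default 0.05);
   heterozygotes with a minor share below `imbalance_threshold` (default
   0.20) are flagged, motivated by reports of imbalanced heterozygotes
   with minor shares down around 8–19%. Loci without assigned UMIs are
   reported blank rather than invented — transcript-based typing cannot
   see null or unexpressed alleles, and `concordance()` therefore
   excludes reference null alleles (suffix `N`) from comparison when the
   transcript call is blank.

5. **Quantitation** (`normalize_counts()`). Allele-level UMI counts are
   scaled to counts-per-million within the sample
   (`cpm = count / sample_total * 1e6`) and log-transformed as
   `log2(cpm + 1)`. The pseudocount keeps zero-count alleles
   representable and is configurable. A per-locus denominator is offered
   as a toggle (`per_locus = TRUE`) for analyses of allele balance within
   a locus; the per-sample total is the default. `locus_totals()`
   aggregates alleles to loci, and `coefficient_of_variation()` /
   `mann_whitney_u()` provide the replicate-precision and two-group
   comparison statistics commonly reported with such data. The
   Mann–Whitney implementation enumerates all rank splits exactly up to a
   combined n of 12 and otherwise uses the normal approximation with tie
   and continuity correction.

## The simulator and what it does (not) show

`simulate_sample()` draws, per amplicon, `n_molecules` (default 200)
tagged molecules from the two alleles of a locus at configurable
expression weights, amplifies each into `1 + Geometric` reads
(mean `pcr_duplication`, default 10 — a simple heavy-tailed stand-in for
PCR jackpotting), and corrupts reads base by base: substitutions first
(default 6%), then left-to-right independent deletions (1%) and
insertions (1%), i.e. 92% read accuracy, inside the 88–94% regime of
current long-read chemistries. UMIs additionally receive a small
polymerase substitution rate (0.002/base) before read errors. Half the
reads are emitted reverse-complemented. Every read and molecule carries
complete ground truth, and identical configurations reproduce identical
bytes.

The synthetic allele database (`make_synthetic_allele_db()`) derives
alleles from a per-locus founder by 2% point substitutions — about 10
diagnostic positions per 500-bp cDNA, comparable to close HLA allele
pairs at two-field resolution.

What the simulator does **not** emulate: homopolymer-biased indels,
chimeric reads, quality-score structure (qualities are flat and unused),
reference databases with thousands of alleles per locus, partial-length
transcripts from degraded RNA, and adapter/barcode remnants. Passing the
simulation suite therefore demonstrates the correctness of the
algorithms under a clean error model, not clinical-grade performance on
real nanopore data.

## Numerical and design choices

* **Alignment backend.** A single compiled affine-gap global aligner
  (Gotoh recursion, deterministic trace-back preference diagonal >
  vertical > horizontal) serves consensus pileup, accuracy scoring and
  allele assignment. It is cross-checked against
  `Biostrings::pairwiseAlignment` scores in the test suite. Pileup and
  assignment alignments run banded (half-width 64/96 plus the length
  difference), which is exact for the ≤ ~10% error regimes involved;
  accuracy scoring (`consensus_accuracy()`) defaults to the full dynamic
  program. `consensus_accuracy()` orders its arguments canonically
  before aligning so the measure is exactly symmetric.
* **Tie-breaking** is deterministic everywhere: UMI processing order is
  count-descending then lexicographic; candidate groups by distance,
  centroid count, creation order; assignment ties by identity, then
  mismatches, then allele name; genotype count ties by allele name.
* **Degenerate inputs.** Empty sequences are rejected by the aligner;
  empty tag tables produce empty group sets; a zero-UMI sample is a
  normalization error naming the sample; singleton groups are their own
  consensus, which also makes consensus idempotent.
* **Problem sizes.** The validation suite runs cohorts of 6 samples × 8
  amplicons × 200 molecules (about 16,000 reads per sample at mean
  duplication 10) over five seeds for genotype recovery, and 200
  groups × 10 reads for the consensus-accuracy bounds — sizes chosen so
  the full suite completes comfortably on a laptop-class single core
  while keeping binomial sampling noise well inside the tested
  tolerances.
* **Interfaces.** The functions, the YAML-driven `run_pipeline()`, and
  `inst/cli/umihla` (a thin Rscript with `simulate`, `run`, `type`,
  `quantify`, `concordance` subcommands) are the supported entry points.

## Known limitations

Majority-vote consensus is weaker than signal-level polishing at small
group sizes; `min_reads = 1` output is raw-read accuracy by definition.
The directional clustering threshold (edit distance 2 on a 24-mer) trims
reads whose tags carry three or more errors, so effective group sizes run
~30% below the true PCR duplication at 8% total error — harmless for
genotyping but a downward bias on per-molecule *read* counts (not on
molecule counts). Allele assignment against very large references would
need a k-mer prescreen; at panel scale the exhaustive alignment is fast
and exact, so none is used. Phasing, novel-allele discovery and G/P-group
ambiguity handling are out of scope.
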