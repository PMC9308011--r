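# umihla

UMI-based long-read amplicon consensus, HLA typing and allele-specific
expression, in R.

## The problem

Long-read (nanopore-class) sequencing of full-length HLA cDNA amplicons
enables same-day, high-resolution HLA genotyping directly from RNA — but
raw read accuracy of only ~88–94% is hopeless for telling apart alleles
that differ at a few bases. Tagging each input molecule with a **unique
molecular identifier (UMI)** before PCR fixes this: reads sharing a UMI
are copies of one molecule, so collapsing each UMI group to a consensus
removes random sequencing error, and counting distinct UMIs per allele
counts transcripts instead of PCR products, yielding allele-specific
expression.

`umihla` implements this pipeline end to end for people building or
validating UMI amplicon assays:

* primer-anchored read orientation/trimming and dual-end UMI extraction;
* error-tolerant **directional UMI clustering** (greedy, on Levenshtein
  distance *d* ≤ 2 over the combined 24-nt tag, with the count condition
  `count ≤ ceil(centroid_count / 2)`);
* per-group **consensus by alignment-pileup majority vote** with a
  minimum group size (`min_reads = 1` = pure PCR deduplication,
  `min_reads = 10` = stringent consensus), scored as
  `identity = 100 · matches / alignment_columns`;
* **allele assignment** against an IMGT-style cDNA FASTA, per-locus
  genotype calls with allele-balance flags, and field-level
  **concordance** (`100 · n_match / n_total`, order-insensitive within a
  locus, reference null alleles excluded when the transcript call is
  blank);
* **expression normalization** `cpm = count / sample_total · 10⁶`,
  `log2(cpm + 1)`, plus coefficient-of-variation and exact Mann–Whitney U
  utilities;
* a fully ground-truthed **read simulator** (substitution/indel error
  model, geometric PCR duplication, UMI errors) for validating all of the
  above.

## Worked example

Simulate one patient (8 HLA amplicons, heterozygous loci, 100 molecules
per amplicon, 6% substitution + 1% insertion + 1% deletion error, mean
PCR duplication 10), then run the full pipeline at `min_reads = 10`:

```r
library(umihla)

db  <- make_synthetic_allele_db(seed = 1)          # 8 loci x 2 alleles
cfg <- sim_config(seed = 42, n_molecules = 100, sample_id = "patient01")
sim <- simulate_sample(cfg, db)
run <- run_pipeline(run_config(samples = list(patient01 = sim$reads),
                               reference = db, min_reads = 10))
print(run)
#> umihla_run: 1 sample(s)
#>   patient01: 7739 reads, 97.1% UMI-tagged, 100 consensus, 100 assigned
head(run$genotypes[, c("locus", "allele1", "count1", "allele2", "count2",
                       "minor_fraction", "zygosity")], 3)
#>   locus    allele1 count1    allele2 count2 minor_fraction zygosity
#> 1     A A*01:01:01     11 A*02:01:01     11          0.500      het
#> 2     B B*01:01:01      7 B*02:01:01      4          0.364      het
#> 3     C C*02:01:01      4 C*01:01:01      3          0.429      het
head(run$expression, 4)
#>   sample_id locus allele_name umi_count    cpm log2_norm
#> 1 patient01     A  A*01:01:01        11 110000   16.7472
#> 2 patient01     A  A*02:01:01        11 110000   16.7472
#> 3 patient01     B  B*01:01:01         7  70000   16.0951
#> 4 patient01     B  B*02:01:01         4  40000   15.2877
```

97.1% of reads carried recognizable primers + UMIs; 100 UMI groups had
≥ 10 reads and every consensus was assigned to an allele. Each
`umi_count` is a number of *molecules* (distinct UMIs), `cpm` scales
them to the sample's million, and `log2_norm = log2(cpm + 1)`. Checking
the calls against the simulation's ground truth:

```r
cc <- concordance(run$genotypes[, c("sample_id", "locus", "allele1", "allele2")],
                  truth_genotype_calls(sim))
#> genotype concordance: 100.00% (16/16 alleles at full field depth)
```

A thin CLI wrapping the same functions ships in `inst/cli/umihla`
(subcommands `simulate`, `run`, `type`, `quantify`, `concordance`), and
`run_pipeline()` accepts a YAML configuration via `read_run_config()`.

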