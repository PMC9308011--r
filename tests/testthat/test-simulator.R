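small_cfg <- function(seed = 1, pcr_duplication = 3, ...) {
  sim_config(seed = seed, amplicons = toy_amplicons(), n_molecules = 40L,
             pcr_duplication = pcr_duplication, sample_id = "s1", ...)
}

test_that("synthetic allele database is deterministic and well-formed", {
  db1 <- make_synthetic_allele_db(seed = 9, loci = c("A", "B"),
                                  length = 400, divergence = 0.02)
  db2 <- make_synthetic_allele_db(seed = 9, loci = c("A", "B"),
                                  length = 400, divergence = 0.02)
  expect_identical(db1$records, db2$records)
  expect_equal(length(db1), 4L)
  # intra-locus alleles differ
  for (loc in names(db1$by_locus)) {
    seqs <- db1$records$sequence[db1$by_locus[[loc]]]
    expect_equal(anyDuplicated(seqs), 0L)
  }
  expect_error(make_synthetic_allele_db(seed = 1, divergence = 0),
               "divergence")
  expect_error(make_synthetic_allele_db(seed = 1, length = 100), "300")
})

test_that("zero-error simulation reproduces the exact read layout", {
  db <- make_synthetic_allele_db(seed = 2, loci = c("A", "B"), length = 350)
  cfg <- small_cfg(error_rates = c(sub = 0, ins = 0, del = 0),
                   umi_error_rate = 0, pcr_duplication = 1)
  sim <- simulate_sample(cfg, db)
  expect_equal(nrow(sim$reads), 80L) # 40 molecules x 2 amplicons, 1 read each
  amp <- cfg$amplicons
  for (i in seq_len(nrow(sim$reads))) {
    tr <- sim$truth_reads[i, ]
    a <- amp[amp$amplicon == tr$amplicon, ]
    template <- db$records$sequence[db$records$allele_name == tr$allele_name]
    expected <- paste0(a$fwd_primer, tr$true_umi_fwd, template,
                       tr$true_umi_rev, revcomp(a$rev_primer))
    got <- if (tr$flipped) revcomp(sim$reads$sequence[i])
           else sim$reads$sequence[i]
    expect_identical(got, expected)
  }
})

test_that("simulation is byte-deterministic under a fixed config", {
  db <- make_synthetic_allele_db(seed = 2, loci = c("A", "B"), length = 350)
  s1 <- simulate_sample(small_cfg(seed = 77), db)
  s2 <- simulate_sample(small_cfg(seed = 77), db)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth_reads, s2$truth_reads)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(s1$reads, f1); write_fastq(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_sample(small_cfg(seed = 78), db)
  expect_false(identical(s1$reads$sequence, s3$reads$sequence))
})

test_that("every read has exactly one truth record and molecules have distinct UMI pairs", {
  db <- make_synthetic_allele_db(seed = 2, loci = c("A", "B"), length = 350)
  sim <- simulate_sample(small_cfg(seed = 5), db)
  expect_identical(sim$truth_reads$read_id, sim$reads$read_id)
  expect_equal(anyDuplicated(sim$reads$read_id), 0L)
  tm <- sim$truth_molecules
  for (amp in unique(tm$amplicon)) {
    pairs <- paste(tm$umi_fwd[tm$amplicon == amp],
                   tm$umi_rev[tm$amplicon == amp])
    expect_equal(length(unique(pairs)) + nrow(sim$umi_collisions),
                 sum(tm$amplicon == amp))
  }
  # read counts per molecule reconcile with the truth table
  expect_equal(sum(tm$n_reads), nrow(sim$reads))
})

test_that("read identity under 6% substitutions matches the direct expectation", {
  db <- make_synthetic_allele_db(seed = 3, loci = "A", length = 500)
  cfg <- sim_config(seed = 13, amplicons = toy_amplicons()[1, ],
                    n_molecules = 120L, pcr_duplication = 1,
                    error_rates = c(sub = 0.06, ins = 0, del = 0),
                    umi_error_rate = 0, sample_id = "s1")
  sim <- simulate_sample(cfg, db)
  ids <- vapply(seq_len(nrow(sim$reads)), function(i) {
    tmpl <- db$records$sequence[db$records$allele_name ==
                                  sim$truth_reads$allele_name[i]]
    read <- if (sim$truth_reads$flipped[i]) revcomp(sim$reads$sequence[i])
            else sim$reads$sequence[i]
    # strip primers/UMIs by coordinates (no errors outside substitutions)
    insert <- substr(read, 20 + 12 + 1, nchar(read) - 20 - 12)
    consensus_accuracy(insert, tmpl, band = 16)
  }, numeric(1))
  set.seed(99)
  expected <- oracle_identity_mc(0.06, 500)
  expect_lt(abs(mean(ids) - expected), 1)
})
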