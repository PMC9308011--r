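toy_db <- function() {
  allele_db(data.frame(
    allele_name = c("A*01:01", "A*02:01", "B*07:02", "B*07:06"),
    locus = c("A", "A", "B", "B"),
    sequence = c(rand_seq(400, seed = 11), rand_seq(400),
                 rand_seq(400), rand_seq(400)),
    stringsAsFactors = FALSE))
}

test_that("an exact consensus is assigned to its allele at 100% identity", {
  db <- toy_db()
  a <- assign_allele(db$records$sequence[1], db)
  expect_equal(a$best_allele, "A*01:01")
  expect_equal(a$identity, 100)
  expect_true(a$assigned)
  expect_lt(a$second_best_identity, 100)
})

test_that("assignment works on the reverse strand", {
  db <- toy_db()
  a <- assign_allele(revcomp(db$records$sequence[2]), db)
  expect_equal(a$best_allele, "A*02:01")
  expect_equal(a$identity, 100)
})

test_that("identity ties resolve by mismatches then lexicographic name", {
  # two alleles at equal distance from the query
  base <- rand_seq(300, seed = 12)
  v1 <- strsplit(base, "")[[1]]; v2 <- v1
  v1[50] <- setdiff(c("A", "C", "G", "T"), v1[50])[1]
  v2[250] <- setdiff(c("A", "C", "G", "T"), v2[250])[1]
  db <- allele_db(data.frame(
    allele_name = c("B*07:06", "B*07:02"),
    locus = "B",
    sequence = c(paste(v1, collapse = ""), paste(v2, collapse = "")),
    stringsAsFactors = FALSE))
  a <- assign_allele(base, db)
  expect_equal(a$identity, a$second_best_identity)
  expect_equal(a$best_allele, "B*07:02")
})

test_that("random sequences fall below the identity threshold", {
  db <- toy_db()
  set.seed(13)
  for (i in 1:5) {
    a <- assign_allele(rand_seq(400), db, min_identity = 90)
    expect_false(a$assigned)
    expect_lt(a$identity, 90)
  }
})

test_that("UMI counting conserves assigned + unassigned totals", {
  asn <- data.frame(
    group_id = 1:6, sample_id = "s1",
    locus = c("A", "A", "A", "A", "A", "B"),
    best_allele = c("A*01:01", "A*01:01", "A*01:01", "A*02:01", "A*02:01",
                    "B*07:02"),
    assigned = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  cnt <- count_umis_per_allele(asn)
  expect_equal(cnt$counts$umi_count[cnt$counts$allele_name == "A*01:01"], 3L)
  expect_equal(cnt$counts$umi_count[cnt$counts$allele_name == "A*02:01"], 2L)
  expect_equal(cnt$unassigned, 1L)
  expect_equal(sum(cnt$counts$umi_count) + cnt$unassigned, nrow(asn))

  none <- asn; none$assigned <- FALSE
  cnt0 <- count_umis_per_allele(none)
  expect_equal(nrow(cnt0$counts), 0L)
  expect_equal(cnt0$unassigned, 6L)
})

test_that("genotype calls follow the dominant-pair / threshold rules", {
  g <- call_genotype(c("A*01:01" = 48, "A*02:01" = 45, "A*03:01" = 2),
                     min_minor_fraction = 0.05)
  expect_equal(g$zygosity, "het")
  expect_equal(c(g$allele1, g$allele2), c("A*01:01", "A*02:01"))
  expect_equal(g$minor_fraction, 45 / 93)
  expect_false(g$imbalance_flag)

  g2 <- call_genotype(c("B*07:02" = 90, "B*44:03" = 10),
                      imbalance_threshold = 0.20)
  expect_equal(g2$zygosity, "het")
  expect_equal(g2$minor_fraction, 0.10)
  expect_true(g2$imbalance_flag)

  g3 <- call_genotype(c("C*04:01" = 50, "C*07:01" = 1),
                      min_minor_fraction = 0.05)
  expect_equal(g3$zygosity, "hom")
  expect_true(is.na(g3$allele2))
  expect_equal(g3$allele1, "C*04:01")
})

test_that("concordance is order-insensitive and matches printed arithmetic", {
  a <- data.frame(sample_id = "s1", locus = "A",
                  allele1 = "A*01:01", allele2 = "A*02:01",
                  stringsAsFactors = FALSE)
  b <- data.frame(sample_id = "s1", locus = "A",
                  allele1 = "A*02:01", allele2 = "A*01:01",
                  stringsAsFactors = FALSE)
  expect_equal(concordance(a, b)$n_match, 2L)
  expect_equal(concordance(a, a)$percentage, 100)

  # 313 of 314 alleles -> 99.68% (heterozygous loci, one discordant allele)
  n_loci <- 157L
  calls <- data.frame(
    sample_id = rep(sprintf("p%03d", 1:n_loci)),
    locus = "DQA1",
    allele1 = rep("DQA1*01:01:01", n_loci),
    allele2 = rep("DQA1*02:01:01", n_loci),
    stringsAsFactors = FALSE)
  refs <- calls
  refs$allele1[1] <- "DQA1*05:05:01" # the one discordant call
  cc <- concordance(calls, refs)
  expect_equal(cc$n_total, 314L)
  expect_equal(cc$n_match, 313L)
  expect_equal(round(cc$percentage, 2), 99.68)
})

test_that("concordance truncates to the requested field depth", {
  a <- data.frame(sample_id = "s", locus = "A",
                  allele1 = "A*02:01:01", allele2 = "A*03:01:02",
                  stringsAsFactors = FALSE)
  b <- data.frame(sample_id = "s", locus = "A",
                  allele1 = "A*02:01:05", allele2 = "A*03:01:02",
                  stringsAsFactors = FALSE)
  expect_equal(concordance(a, b, fields = 3)$n_match, 1L)
  expect_equal(concordance(a, b, fields = 2)$n_match, 2L)
})

test_that("reference null alleles are excluded when the call is blank", {
  calls <- data.frame(sample_id = "s", locus = "DRB5",
                      allele1 = NA_character_, allele2 = NA_character_,
                      stringsAsFactors = FALSE)
  refs <- data.frame(sample_id = "s", locus = "DRB5",
                     allele1 = "DRB5*01:08:01N", allele2 = NA_character_,
                     stringsAsFactors = FALSE)
  cc <- concordance(calls, refs)
  expect_equal(cc$n_total, 0L)
  # a non-null reference allele with a blank call counts as a mismatch
  refs2 <- refs; refs2$allele1 <- "DRB5*01:01:01"
  cc2 <- concordance(calls, refs2)
  expect_equal(cc2$n_total, 1L)
  expect_equal(cc2$n_match, 0L)
})

test_that("concordance rejects mismatched keys and is reflexive/symmetric", {
  a <- data.frame(sample_id = "s", locus = "A",
                  allele1 = "A*01:01", allele2 = "A*02:01",
                  stringsAsFactors = FALSE)
  b <- data.frame(sample_id = "s", locus = "B",
                  allele1 = "B*07:02", allele2 = NA_character_,
                  stringsAsFactors = FALSE)
  expect_error(concordance(a, b), "keys")
  two <- rbind(a, b)
  expect_equal(concordance(two, two)$percentage, 100)
  shuffled <- two[2:1, ]
  expect_equal(concordance(two, shuffled)$percentage, 100)
  expect_equal(concordance(shuffled, two)$percentage, 100)
})
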