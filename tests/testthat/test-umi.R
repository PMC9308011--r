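test_that("zero-error reads are oriented, trimmed and tagged exactly", {
  db <- make_synthetic_allele_db(seed = 21, loci = c("A", "B"), length = 350)
  cfg <- sim_config(seed = 4, amplicons = toy_amplicons(), n_molecules = 30L,
                    pcr_duplication = 1,
                    error_rates = c(sub = 0, ins = 0, del = 0),
                    umi_error_rate = 0, sample_id = "s1")
  sim <- simulate_sample(cfg, db)
  tg <- tag_reads(sim$reads, cfg$amplicons)
  expect_equal(nrow(tg$rejected), 0L)
  expect_equal(nrow(tg$tagged), nrow(sim$reads))
  m <- merge(tg$tagged, sim$truth_reads, by = "read_id")
  expect_equal(nrow(m), nrow(sim$reads))
  expect_identical(m$umi_fwd, m$true_umi_fwd)
  expect_identical(m$umi_rev, m$true_umi_rev)
  expect_identical(m$amplicon.x, m$amplicon.y)
  tmpl <- db$records$sequence[match(m$allele_name, db$records$allele_name)]
  expect_identical(m$sequence, tmpl)
})

test_that("tagging is orientation invariant", {
  db <- make_synthetic_allele_db(seed = 21, loci = "A", length = 350)
  cfg <- sim_config(seed = 8, amplicons = toy_amplicons()[1, ],
                    n_molecules = 15L, pcr_duplication = 1,
                    sample_id = "s1")
  sim <- simulate_sample(cfg, db)
  tg1 <- tag_reads(sim$reads, cfg$amplicons)
  flipped <- sim$reads
  flipped$sequence <- revcomp(flipped$sequence)
  flipped$quality <- vapply(strsplit(flipped$quality, ""), function(v)
    paste(rev(v), collapse = ""), character(1))
  tg2 <- tag_reads(flipped, cfg$amplicons)
  # strand labels flip with the input; everything else is invariant
  canon <- function(df) {
    df <- df[order(df$read_id), setdiff(names(df), "strand")]
    rownames(df) <- NULL
    df
  }
  expect_identical(canon(tg1$tagged), canon(tg2$tagged))
})

test_that("reads without primers are rejected with reason no_primer", {
  reads <- data.frame(read_id = c("x1", "x2"),
                      sequence = c(rand_seq(400, seed = 1), rand_seq(420)),
                      quality = NA_character_, sample_id = "s1",
                      stringsAsFactors = FALSE)
  tg <- tag_reads(reads, toy_amplicons())
  expect_equal(nrow(tg$tagged), 0L)
  expect_equal(tg$rejected$reason, c("no_primer", "no_primer"))
})

test_that("orient_and_trim wraps the batch tagger for a single read", {
  db <- make_synthetic_allele_db(seed = 22, loci = "A", length = 350)
  cfg <- sim_config(seed = 9, amplicons = toy_amplicons()[1, ],
                    n_molecules = 1L, pcr_duplication = 1,
                    error_rates = c(sub = 0, ins = 0, del = 0),
                    umi_error_rate = 0, sample_id = "s1")
  sim <- simulate_sample(cfg, db)
  res <- orient_and_trim(sim$reads[1, ], cfg$amplicons)
  expect_false(res$rejected)
  expect_equal(res$amplicon, "HLA-A")
  expect_equal(res$umi$combined, paste0(sim$truth_reads$true_umi_fwd[1],
                                        sim$truth_reads$true_umi_rev[1]))
  bad <- orient_and_trim(list(sequence = rand_seq(300, seed = 2)),
                         cfg$amplicons)
  expect_true(bad$rejected)
  expect_equal(bad$reason, "no_primer")
})

test_that("identical UMIs collapse into one group", {
  tagged <- make_tagged(rep("AAAATTTTCCCCGGGGAAAATTTT", 10))
  g <- group_umis(tagged)
  expect_length(g, 1L)
  expect_equal(g[[1]]$size, 10L)
  expect_equal(g[[1]]$centroid_umi, "AAAATTTTCCCCGGGGAAAATTTT")
})

test_that("a one-off UMI variant merges under the directional rule", {
  x <- strrep("ACGT", 6)
  x1 <- paste0("T", substr(x, 2, 24)) # 1 substitution
  tagged <- make_tagged(c(rep(x, 10), x1))
  g <- group_umis(tagged, max_edit_distance = 1, ratio_threshold = 2)
  expect_length(g, 1L)
  expect_equal(g[[1]]$size, 11L)
  expect_equal(g[[1]]$centroid_umi, x)
})

test_that("UMIs beyond the edit threshold stay separate", {
  x <- strrep("ACGT", 6)
  y <- paste0("TTT", substr(x, 4, 24)) # distance 3
  tagged <- make_tagged(c(rep(x, 5), rep(y, 4)))
  g <- group_umis(tagged, max_edit_distance = 2)
  expect_length(g, 2L)
  expect_equal(sort(vapply(g, `[[`, integer(1), "size")), c(4L, 5L))
})

test_that("grouping partitions the reads and empty input yields empty output", {
  set.seed(17)
  umis <- sample(random_umi(30), 200, replace = TRUE)
  tagged <- make_tagged(umis)
  g <- group_umis(tagged)
  sizes <- vapply(g, `[[`, integer(1), "size")
  expect_equal(sum(sizes), nrow(tagged))
  all_ids <- unlist(lapply(g, function(x) x$members$read_id))
  expect_setequal(all_ids, tagged$read_id)
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_length(group_umis(make_tagged(character(0))), 0L)
})

test_that("greedy clustering matches the brute-force oracle on random instances", {
  set.seed(31)
  for (i in 1:60) {
    n_true <- sample(2:12, 1)
    true <- random_umi(n_true)
    umis <- character(0); counts <- integer(0)
    for (u in true) {
      k <- sample(1:20, 1)
      umis <- c(umis, u); counts <- c(counts, k)
      if (runif(1) < 0.7) { # error variant at distance 1-3
        v <- strsplit(u, "")[[1]]
        for (p in sample(24, sample(1:3, 1)))
          v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
        umis <- c(umis, paste(v, collapse = ""))
        counts <- c(counts, sample(1:5, 1))
      }
    }
    dup <- duplicated(umis)
    umis <- umis[!dup]; counts <- counts[!dup]
    oracle <- oracle_group_umis(umis, counts)
    tagged <- make_tagged(rep(umis, counts))
    g <- group_umis(tagged)
    got <- vapply(g, function(x)
      paste(sort(unique(x$members$umi)), collapse = "|"), character(1))
    want <- vapply(split(oracle$umis, oracle$gid), function(u)
      paste(sort(u), collapse = "|"), character(1))
    expect_setequal(got, unname(want))
  }
})

test_that("filter_groups applies the min-reads threshold in order", {
  tagged <- make_tagged(c(rep("A", 1), rep("C", 3), rep("G", 10),
                          rep("T", 12)))
  tagged$umi <- strrep(tagged$umi, 24)
  g <- group_umis(tagged)
  expect_length(filter_groups(g, 10), 2L)
  expect_identical(filter_groups(g, 1), g)
  expect_length(filter_groups(structure(list(), class = "umi_group_set"),
                              5), 0L)
  expect_error(filter_groups(g, 0), ">= 1")
})
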