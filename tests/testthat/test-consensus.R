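test_that("representative selection follows the lower-median length rule", {
  g <- make_group(c(rand_seq(480, seed = 1), rand_seq(500), rand_seq(520)))
  expect_equal(nchar(select_representative(g)$sequence), 500L)

  g2 <- make_group(c(rand_seq(500, seed = 2), rand_seq(502)))
  expect_equal(nchar(select_representative(g2)$sequence), 500L)

  g3 <- make_group(rand_seq(333, seed = 3))
  expect_equal(select_representative(g3)$read_id, "r01")

  # equal lengths: higher mean quality wins, then read id
  g4 <- make_group(c("ACGTACGT", "ACGTACGA", "ACGTACGC"),
                   quals = c("IIIIIIII", "########", "IIIIIIII"))
  expect_true(select_representative(g4)$read_id %in% c("r01", "r03"))
  expect_equal(select_representative(g4)$read_id, "r01")
})

test_that("consensus of identical members is the member itself (unanimity, idempotence)", {
  s <- rand_seq(300, seed = 4)
  g <- make_group(rep(s, 5))
  cs <- call_consensus(g)
  expect_identical(cs$sequence, s)
  expect_identical(call_consensus(make_group(cs$sequence))$sequence, s)
  expect_equal(cs$group_size, 5L)
})

test_that("a lone substitution is outvoted by the majority", {
  set.seed(5)
  tmpl <- rand_seq(400)
  reads <- rep(tmpl, 10)
  v <- strsplit(tmpl, "")[[1]]
  v[100] <- setdiff(c("A", "C", "G", "T"), v[100])[1]
  reads[4] <- paste(v, collapse = "")
  cs <- call_consensus(make_group(reads))
  expect_identical(cs$sequence, tmpl)
})

test_that("column plurality and tie-to-representative rules hold", {
  # hand-built alignment-free case: 3 equal-length reads, one column differs
  # column tally {A, A, G} -> A
  reads <- c("AACCGGTTAACCGGTT", "AACCGGTTAACCGGTT", "AACCGGTTGACCGGTT")
  cs <- call_consensus(make_group(reads))
  expect_identical(cs$sequence, "AACCGGTTAACCGGTT")

  # 2-2 tie at a column resolves toward the representative's base; with
  # lengths equal and no qualities the representative is the first read id
  reads <- c("AACCGGTTAACCGGTT", "AACCGGTTAACCGGTT",
             "AACCGGTTGACCGGTT", "AACCGGTTGACCGGTT")
  cs <- call_consensus(make_group(reads))
  expect_identical(cs$sequence, "AACCGGTTAACCGGTT")
})

test_that("deletions and insertions follow the majority rules", {
  tmpl <- "ACGTACGTACGTACGTACGT"
  # majority carries a deletion of position 5
  del <- paste0(substr(tmpl, 1, 4), substr(tmpl, 6, 20))
  cs <- call_consensus(make_group(c(tmpl, del, del)))
  expect_identical(cs$sequence, del)
  # insertion present in 2 of 3 members (strict majority) is kept
  ins <- paste0(substr(tmpl, 1, 10), "GGG", substr(tmpl, 11, 20))
  cs2 <- call_consensus(make_group(c(tmpl, ins, ins)))
  expect_identical(cs2$sequence, ins)
  # insertion in only 1 of 3 members is dropped
  cs3 <- call_consensus(make_group(c(tmpl, tmpl, ins)))
  expect_identical(cs3$sequence, tmpl)
})

test_that("consensus of noisy groups recovers the template", {
  set.seed(6)
  tmpl <- rand_seq(500)
  for (rep_i in 1:5) {
    reads <- vapply(1:12, function(i) {
      v <- strsplit(mutate_subs(tmpl, 0.06), "")[[1]]
      keep <- runif(length(v)) >= 0.01
      out <- v[keep]
      ins <- which(runif(length(out)) < 0.01)
      for (p in rev(ins)) out <- append(out, sample(c("A", "C", "G", "T"), 1),
                                        after = p)
      paste(out, collapse = "")
    }, character(1))
    cs <- call_consensus(make_group(reads))
    expect_gte(consensus_accuracy(cs$sequence, tmpl), 99.4)
  }
})

test_that("consensus accuracy equals the exhaustive-alignment oracle on short sequences", {
  expect_equal(consensus_accuracy(strrep("ACGTT", 100), strrep("ACGTT", 100)),
               100)
  expect_equal(consensus_accuracy("ACGACGT", "ACGTACGT"), 87.5)
  set.seed(7)
  for (i in 1:25) {
    a <- rand_seq(sample(4:7, 1))
    b <- if (i %% 3 == 0) rand_seq(sample(4:7, 1)) else mutate_subs(a, 0.2)
    got <- consensus_accuracy(a, b)
    ora <- oracle_exhaustive_accuracy(a, b)
    expect_true(got %in% ora$accuracies,
                info = sprintf("a=%s b=%s got=%f", a, b, got))
  }
})

test_that("consensus accuracy is symmetric", {
  set.seed(8)
  for (i in 1:10) {
    a <- rand_seq(80)
    b <- mutate_subs(a, 0.1)
    expect_identical(consensus_accuracy(a, b), consensus_accuracy(b, a))
  }
})
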