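# Shared fixture builders (everything generated in code; no data files).

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitutions-only mutant of a sequence
mutate_subs <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

# a two-amplicon primer panel small enough for focused tests
toy_amplicons <- function() {
  default_amplicons()[1:2, ]
}

# hand-built UMI group from raw member sequences
make_group <- function(seqs, quals = NULL, ids = NULL,
                       umi = strrep("A", 24)) {
  n <- length(seqs)
  if (is.null(ids)) ids <- sprintf("r%02d", seq_len(n))
  if (is.null(quals)) quals <- rep(NA_character_, n)
  members <- data.frame(read_id = ids, sample_id = "s1", amplicon = "HLA-A",
                        strand = "+", umi_fwd = substr(umi, 1, 12),
                        umi_rev = substr(umi, 13, 24), umi = umi,
                        sequence = seqs, quality = quals,
                        stringsAsFactors = FALSE)
  structure(list(group_id = 1L, centroid_umi = umi, members = members,
                 size = n), class = "umi_group")
}

# tagged read table with given UMIs (sequence content irrelevant)
make_tagged <- function(umis) {
  n <- length(umis)
  if (n == 0L) {
    return(data.frame(read_id = character(0), sample_id = character(0),
                      amplicon = character(0), strand = character(0),
                      umi_fwd = character(0), umi_rev = character(0),
                      umi = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  data.frame(read_id = sprintf("r%04d", seq_len(n)), sample_id = "s1",
             amplicon = "HLA-A", strand = "+",
             umi_fwd = substr(umis, 1, 12), umi_rev = substr(umis, 13, 24),
             umi = umis, sequence = strrep("ACGT", 25),
             quality = NA_character_, stringsAsFactors = FALSE)
}

random_umi <- function(n, len = 24) {
  vapply(seq_len(n), function(i) rand_seq(len), character(1))
}
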