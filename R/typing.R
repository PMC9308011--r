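# Allele assignment of consensus sequences, per-allele UMI counting,
# per-locus genotype calls with allele-balance flags, and concordance
# against reference genotypes.

#' Assign a consensus sequence to its best-matching allele
#'
#' The sequence is globally aligned on both strands against every
#' candidate allele; identity is `100 * matches / alignment_columns`. Best
#' allele by identity; ties are broken by fewer mismatches, then by the
#' lexicographically smallest allele name. Assignment fails (but is still
#' reported) when the best identity falls below `min_identity`.
#'
#' @param sequence consensus nucleotide string.
#' @param db an [allele_db()].
#' @param loci restrict candidates to these loci (`NULL` = all).
#' @param min_identity minimum percent identity for a confident
#'   assignment, in (0, 100].
#' @param scores an [align_scores()].
#' @param band alignment band half-width (widened by length difference).
#' @return list with `best_allele`, `locus`, `identity`,
#'   `second_best_identity` (`NA` with a single candidate) and `assigned`.
#' @export
assign_allele <- function(sequence, db, loci = NULL, min_identity = 85,
                          scores = align_scores(), band = 96L) {
  stopifnot(min_identity > 0, min_identity <= 100)
  cand <- db_alleles(db, loci)
  if (nrow(cand) == 0L) {
    stop("no alleles in the reference for loci: ",
         paste(loci, collapse = ", "))
  }
  strands <- c(sequence, revcomp(sequence))
  identity <- numeric(nrow(cand))
  mism <- integer(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cpp_align_batch(strands, cand$sequence[i], scores$match,
                         scores$mismatch, scores$gap_open,
                         scores$gap_extend, as.integer(band), FALSE)
    id <- 100 * r$matches / r$columns
    s <- which.max(id)
    identity[i] <- id[s]
    mism[i] <- r$mismatches[s]
  }
  ord <- order(-identity, mism, cand$allele_name, method = "radix")
  best <- ord[1]
  list(best_allele = cand$allele_name[best],
       locus = cand$locus[best],
       identity = identity[best],
       second_best_identity = if (nrow(cand) > 1L) identity[ord[2]]
                              else NA_real_,
       assigned = identity[best] >= min_identity)
}

#' Assign every consensus sequence of a sample
#'
#' Candidate alleles for each consensus are the alleles of the loci
#' covered by its amplicon (one amplicon may cover several loci, e.g. a
#' shared DRB1/3/4/5 amplicon).
#'
#' @param consensus data.frame from [consensus_for_groups()].
#' @param db an [allele_db()].
#' @param amplicons amplicon table mapping `amplicon` to `loci`.
#' @inheritParams assign_allele
#' @return `consensus` with added columns `best_allele`, `locus`,
#'   `identity`, `second_best_identity`, `assigned`.
#' @export
assign_alleles <- function(consensus, db, amplicons, min_identity = 85,
                           scores = align_scores(), band = 96L) {
  loci_map <- amplicon_loci(amplicons)
  res <- lapply(seq_len(nrow(consensus)), function(i) {
    loci <- loci_map[[consensus$amplicon[i]]]
    a <- assign_allele(consensus$sequence[i], db, loci = loci,
                       min_identity = min_identity, scores = scores,
                       band = band)
    data.frame(best_allele = a$best_allele, locus = a$locus,
               identity = a$identity,
               second_best_identity = a$second_best_identity,
               assigned = a$assigned, stringsAsFactors = FALSE)
  })
  cbind(consensus, do.call(rbind, res))
}

#' UMI counts per allele
#'
#' Each assigned consensus sequence represents one unique UMI, so the
#' per-allele UMI count is the number of assigned consensus sequences.
#' Unassigned consensus sequences are excluded from the counts but
#' tallied, so that counts + unassigned = total consensus sequences.
#'
#' @param assignments data.frame from [assign_alleles()] (one sample).
#' @return list with `counts` (data.frame `sample_id`, `locus`,
#'   `allele_name`, `umi_count`) and `unassigned` (integer).
#' @export
count_umis_per_allele <- function(assignments) {
  if (nrow(assignments) == 0L) {
    return(list(counts = data.frame(sample_id = character(0),
                                    locus = character(0),
                                    allele_name = character(0),
                                    umi_count = integer(0),
                                    stringsAsFactors = FALSE),
                unassigned = 0L))
  }
  ok <- assignments[assignments$assigned, , drop = FALSE]
  if (nrow(ok) == 0L) {
    counts <- data.frame(sample_id = character(0), locus = character(0),
                         allele_name = character(0), umi_count = integer(0),
                         stringsAsFactors = FALSE)
  } else {
    counts <- aggregate(list(umi_count = ok$group_id),
                        by = list(sample_id = ok$sample_id,
                                  locus = ok$locus,
                                  allele_name = ok$best_allele),
                        FUN = length)
    counts <- counts[order(counts$sample_id, counts$locus,
                           counts$allele_name), ]
    counts <- counts[, c("sample_id", "locus", "allele_name", "umi_count")]
    rownames(counts) <- NULL
  }
  list(counts = counts, unassigned = sum(!assignments$assigned))
}

#' Call the genotype of one locus from allele UMI counts
#'
#' The top allele by count is always called. A second allele is called
#' (heterozygote) when its share of the top-two counts is at least
#' `min_minor_fraction`; otherwise the call is homozygous. Heterozygotes
#' whose minor fraction falls below `imbalance_threshold` are flagged as
#' allele-imbalanced (observed imbalanced heterozygotes can run as low as
#' ~8-19\% minor share). Count ties break by allele name.
#'
#' @param locus_counts named integer vector (names = allele names), or a
#'   data.frame with `allele_name` and `umi_count`.
#' @param min_minor_fraction minimum minor-allele share of the top-two
#'   counts for a heterozygous call.
#' @param imbalance_threshold minor fraction below which a heterozygote is
#'   flagged.
#' @return list with `allele1`, `count1`, `allele2`, `count2`,
#'   `minor_fraction`, `zygosity` (`"het"`/`"hom"`), `imbalance_flag`.
#' @export
call_genotype <- function(locus_counts, min_minor_fraction = 0.05,
                          imbalance_threshold = 0.20) {
  if (is.data.frame(locus_counts)) {
    locus_counts <- stats::setNames(locus_counts$umi_count,
                                    locus_counts$allele_name)
  }
  if (length(locus_counts) == 0L) stop("locus_counts is empty")
  ord <- order(-locus_counts, names(locus_counts), method = "radix")
  cnt <- locus_counts[ord]
  if (length(cnt) == 1L) {
    return(list(allele1 = names(cnt)[1], count1 = unname(cnt[1]),
                allele2 = NA_character_, count2 = NA_integer_,
                minor_fraction = NA_real_, zygosity = "hom",
                imbalance_flag = FALSE))
  }
  f <- unname(cnt[2] / (cnt[1] + cnt[2]))
  if (f >= min_minor_fraction) {
    list(allele1 = names(cnt)[1], count1 = unname(cnt[1]),
         allele2 = names(cnt)[2], count2 = unname(cnt[2]),
         minor_fraction = f, zygosity = "het",
         imbalance_flag = f < imbalance_threshold)
  } else {
    list(allele1 = names(cnt)[1], count1 = unname(cnt[1]),
         allele2 = NA_character_, count2 = NA_integer_,
         minor_fraction = NA_real_, zygosity = "hom",
         imbalance_flag = FALSE)
  }
}

#' Genotype calls for every (sample, locus) in a count table
#'
#' Loci with no assigned UMIs are absent from the output (blank calls),
#' which is the expected outcome for e.g. DRB3/4/5 loci a sample does not
#' carry, or null alleles without transcripts.
#'
#' @param counts count table from [count_umis_per_allele()].
#' @inheritParams call_genotype
#' @return data.frame with one row per (sample, locus): `sample_id`,
#'   `locus`, `allele1`, `count1`, `allele2`, `count2`, `minor_fraction`,
#'   `zygosity`, `imbalance_flag`.
#' @export
call_genotypes <- function(counts, min_minor_fraction = 0.05,
                           imbalance_threshold = 0.20) {
  if (nrow(counts) == 0L) {
    return(data.frame(sample_id = character(0), locus = character(0),
                      allele1 = character(0), count1 = integer(0),
                      allele2 = character(0), count2 = integer(0),
                      minor_fraction = numeric(0), zygosity = character(0),
                      imbalance_flag = logical(0), stringsAsFactors = FALSE))
  }
  keys <- unique(counts[, c("sample_id", "locus")])
  keys <- keys[order(keys$sample_id, keys$locus), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- counts[counts$sample_id == keys$sample_id[i] &
                    counts$locus == keys$locus[i], , drop = FALSE]
    g <- call_genotype(sub, min_minor_fraction, imbalance_threshold)
    data.frame(sample_id = keys$sample_id[i], locus = keys$locus[i],
               allele1 = g$allele1, count1 = g$count1,
               allele2 = g$allele2, count2 = g$count2,
               minor_fraction = g$minor_fraction, zygosity = g$zygosity,
               imbalance_flag = g$imbalance_flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concordance between two genotype call sets
#'
#' Allele-level comparison after truncating names to `fields` fields,
#' order-insensitive within a locus (best pairing of the two allele
#' slots). Reference null alleles (expression suffix `N`) are excluded
#' when the corresponding call is blank, since transcript-based typing
#' cannot observe untranscribed alleles.
#'
#' @param calls,reference_calls data.frames with `sample_id`, `locus`,
#'   `allele1`, `allele2` (`NA` for absent). Both sides must cover the
#'   same (sample, locus) keys.
#' @param fields field depth of the comparison, 1-4.
#' @return list with `n_match`, `n_total`, `percentage`.
#' @examples
#' a <- data.frame(sample_id = "s1", locus = "A",
#'                 allele1 = "A*01:01", allele2 = "A*02:01")
#' b <- data.frame(sample_id = "s1", locus = "A",
#'                 allele1 = "A*02:01", allele2 = "A*01:01")
#' concordance(a, b, fields = 2)  # order-insensitive: 2/2
#' @export
concordance <- function(calls, reference_calls, fields = 4L) {
  stopifnot(fields >= 1L, fields <= 4L)
  key <- function(df) paste(df$sample_id, df$locus, sep = "\r")
  k1 <- key(calls); k2 <- key(reference_calls)
  if (!setequal(k1, k2) || anyDuplicated(k1) || anyDuplicated(k2)) {
    stop("call sets do not share the same (sample, locus) keys")
  }
  trunc_ok <- function(x) {
    vapply(x, function(a) if (is.na(a)) NA_character_
           else truncate_fields(a, fields), character(1), USE.NAMES = FALSE)
  }
  is_null_allele <- function(a) {
    !is.na(a) & vapply(a, function(x) {
      if (is.na(x)) return(FALSE)
      identical(parse_allele_name(x)$suffix, "N")
    }, logical(1), USE.NAMES = FALSE)
  }
  n_match <- 0L; n_total <- 0L
  for (k in k1) {
    cal <- calls[k1 == k, ]
    ref <- reference_calls[k2 == k, ]
    cal_alleles <- c(cal$allele1, cal$allele2)
    ref_alleles <- c(ref$allele1, ref$allele2)
    cal_alleles <- cal_alleles[!is.na(cal_alleles)]
    # drop reference null alleles that the transcript-based call left blank
    excess <- length(ref_alleles[!is.na(ref_alleles)]) - length(cal_alleles)
    if (excess > 0L) {
      nulls <- which(is_null_allele(ref_alleles))
      drop <- head(nulls, excess)
      if (length(drop)) ref_alleles <- ref_alleles[-drop]
    }
    ref_alleles <- ref_alleles[!is.na(ref_alleles)]
    ct <- trunc_ok(cal_alleles)
    rt <- trunc_ok(ref_alleles)
    n_slots <- max(length(ct), length(rt))
    if (n_slots == 0L) next
    m <- best_pairing_matches(ct, rt)
    n_total <- n_total + n_slots
    n_match <- n_match + m
  }
  list(n_match = n_match, n_total = n_total,
       percentage = if (n_total > 0L) 100 * n_match / n_total else NA_real_)
}

# maximum number of equal pairs over all pairings of the two allele lists
best_pairing_matches <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0L)
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  perms <- if (length(b) == 1L) list(1L) else
    if (length(b) == 2L) list(c(1L, 2L), c(2L, 1L)) else
      combinat_perms(seq_along(b))
  best <- 0L
  for (p in perms) {
    m <- sum(a == b[p[seq_along(a)]])
    if (m > best) best <- m
  }
  best
}

combinat_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}
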