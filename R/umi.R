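# Read orientation, primer trimming, dual-UMI extraction, and
# error-tolerant directional UMI clustering.

#' Orient, trim and UMI-tag a batch of reads
#'
#' For each read, both orientations are scanned with a semi-global
#' (anchored) primer search: the forward primer must sit within the first
#' `window` bases and the reverse-complemented reverse primer within the
#' last `window` bases, each within an edit budget of
#' `ceiling(max_mismatch_frac * primer_length)`. The read is assigned to
#' the amplicon whose primer pair matches with the fewest total edits;
#' ties across amplicons reject the read. The UMIs are the `umi_length`
#' bases immediately inside each primer match; primers and UMIs are
#' trimmed from the retained insert.
#'
#' @param reads read table (`read_id`, `sequence`, optional `quality`,
#'   `sample_id`).
#' @param amplicons amplicon/primer table as in [default_amplicons()].
#' @param umi_length UMI length per end.
#' @param max_mismatch_frac primer edit budget as a fraction of primer
#'   length.
#' @param window how far from each read end primers are searched.
#' @return list with `tagged` (data.frame: `read_id`, `sample_id`,
#'   `amplicon`, `strand`, `umi_fwd`, `umi_rev`, `umi`, `sequence` (the
#'   trimmed insert, forward orientation), `quality`) and `rejected`
#'   (data.frame: `read_id`, `reason` of `"no_primer"` or
#'   `"ambiguous_amplicon"`).
#' @export
tag_reads <- function(reads, amplicons, umi_length = 12L,
                      max_mismatch_frac = 0.2, window = 64L) {
  stopifnot(nrow(amplicons) >= 1L,
            all(nchar(amplicons$fwd_primer) >= 15L),
            all(nchar(amplicons$rev_primer) >= 15L))
  if (nrow(reads) == 0L) {
    return(list(tagged = empty_tagged(), rejected =
                  data.frame(read_id = character(0), reason = character(0))))
  }
  fwd <- reads$sequence
  rc <- revcomp(fwd)
  fb <- as.integer(floor(max_mismatch_frac * nchar(amplicons$fwd_primer)))
  rb <- as.integer(floor(max_mismatch_frac * nchar(amplicons$rev_primer)))
  hit <- cpp_orient_reads(fwd, rc, amplicons$fwd_primer,
                          revcomp(amplicons$rev_primer), fb, rb,
                          as.integer(window))
  qual <- reads$quality %||% rep(NA_character_, nrow(reads))
  oriented <- ifelse(hit[, "strand"] == 2L, rc, fwd)
  oriented_q <- qual
  flipq <- which(hit[, "strand"] == 2L & !is.na(qual))
  if (length(flipq)) {
    oriented_q[flipq] <- vapply(strsplit(qual[flipq], ""), function(v) {
      paste(rev(v), collapse = "")
    }, character(1))
  }
  ok <- hit[, "status"] == 0L
  u_start <- hit[, "fwd_end"] + 1L
  u_end <- hit[, "fwd_end"] + umi_length
  v_start <- hit[, "rev_start"] - umi_length
  v_end <- hit[, "rev_start"] - 1L
  ins_start <- u_end + 1L
  ins_end <- v_start - 1L
  # degenerate placements (overlapping primers, no room for UMIs + insert)
  ok <- ok & (ins_start <= ins_end) & (u_start >= 1L) &
    (v_end <= nchar(oriented))
  umi_f <- substr(oriented, u_start, u_end)
  umi_r <- substr(oriented, v_start, v_end)
  ok <- ok & nchar(umi_f) == umi_length & nchar(umi_r) == umi_length
  reason <- ifelse(hit[, "status"] == 2L, "ambiguous_amplicon", "no_primer")
  tagged <- data.frame(
    read_id = reads$read_id[ok],
    sample_id = reads$sample_id[ok],
    amplicon = amplicons$amplicon[hit[ok, "amp"]],
    strand = c("+", "-")[hit[ok, "strand"]],
    umi_fwd = umi_f[ok],
    umi_rev = umi_r[ok],
    umi = paste0(umi_f[ok], umi_r[ok]),
    sequence = substr(oriented[ok], ins_start[ok], ins_end[ok]),
    quality = substr(oriented_q[ok], ins_start[ok], ins_end[ok]),
    stringsAsFactors = FALSE)
  rejected <- data.frame(read_id = reads$read_id[!ok],
                         reason = reason[!ok],
                         stringsAsFactors = FALSE)
  list(tagged = tagged, rejected = rejected)
}

empty_tagged <- function() {
  data.frame(read_id = character(0), sample_id = character(0),
             amplicon = character(0), strand = character(0),
             umi_fwd = character(0), umi_rev = character(0),
             umi = character(0), sequence = character(0),
             quality = character(0), stringsAsFactors = FALSE)
}

#' Orient and trim a single read
#'
#' Single-read convenience wrapper over [tag_reads()]. Returns the
#' oriented, trimmed read with its UMI tag and amplicon assignment, or a
#' rejection with reason.
#'
#' @param read one-row read table, or a list with `read_id`, `sequence`,
#'   optional `quality`, `sample_id`.
#' @inheritParams tag_reads
#' @return list with either `rejected = FALSE`, `read` (one-row tagged
#'   table), `umi` (list `umi_fwd`, `umi_rev`, `combined`), `amplicon`; or
#'   `rejected = TRUE` and `reason`.
#' @export
orient_and_trim <- function(read, amplicons, umi_length = 12L,
                            max_mismatch_frac = 0.2, window = 64L) {
  if (!is.data.frame(read)) {
    read <- data.frame(read_id = read$read_id %||% "read1",
                       sequence = read$sequence,
                       quality = read$quality %||% NA_character_,
                       sample_id = read$sample_id %||% "sample1",
                       stringsAsFactors = FALSE)
  }
  res <- tag_reads(read, amplicons, umi_length = umi_length,
                   max_mismatch_frac = max_mismatch_frac, window = window)
  if (nrow(res$tagged) == 1L) {
    t1 <- res$tagged
    list(rejected = FALSE, read = t1,
         umi = list(umi_fwd = t1$umi_fwd, umi_rev = t1$umi_rev,
                    combined = t1$umi),
         amplicon = t1$amplicon)
  } else {
    list(rejected = TRUE, reason = res$rejected$reason[1])
  }
}

#' Cluster tagged reads into UMI groups
#'
#' Greedy directional clustering on the combined dual-end UMI, tolerant to
#' sequencing errors in the tag. Exact-duplicate UMIs are collapsed first;
#' unique UMIs are processed in descending count order (ties
#' lexicographic). A UMI merges into an existing group when its
#' Levenshtein distance to the group centroid is at most
#' `max_edit_distance` and its count is at most
#' `ceiling(centroid_count / ratio_threshold)`; otherwise it founds a new
#' group. Deterministic.
#'
#' @param tagged tagged read table from [tag_reads()], all from one
#'   amplicon of one sample.
#' @param max_edit_distance maximum Levenshtein distance to a centroid.
#' @param ratio_threshold directional count ratio.
#' @return list of class `umi_group_set`; each element is a `umi_group`
#'   list with `group_id`, `centroid_umi`, `members` (tagged rows) and
#'   `size`.
#' @export
group_umis <- function(tagged, max_edit_distance = 2L, ratio_threshold = 2) {
  stopifnot(max_edit_distance >= 0L, ratio_threshold >= 1)
  if (is.null(tagged) || nrow(tagged) == 0L) {
    return(structure(list(), class = "umi_group_set"))
  }
  counts <- table(tagged$umi)
  umis <- names(counts)
  n <- as.integer(counts)
  ord <- order(-n, umis, method = "radix")
  umis <- umis[ord]; n <- n[ord]
  gid <- cpp_group_umis(umis, n, as.integer(max_edit_distance),
                        ratio_threshold)
  umi_gid <- stats::setNames(gid, umis)
  centroid <- stats::setNames(umis[!duplicated(gid)], gid[!duplicated(gid)])
  member_gid <- umi_gid[tagged$umi]
  groups <- lapply(sort(unique(gid)), function(g) {
    members <- tagged[member_gid == g, , drop = FALSE]
    rownames(members) <- NULL
    structure(list(group_id = g,
                   centroid_umi = unname(centroid[as.character(g)]),
                   members = members,
                   size = nrow(members)),
              class = "umi_group")
  })
  structure(groups, class = "umi_group_set")
}

#' @export
print.umi_group_set <- function(x, ...) {
  sizes <- vapply(x, `[[`, integer(1), "size")
  cat("umi_group_set:", length(x), "groups,", sum(sizes), "reads",
      if (length(sizes)) paste0("(sizes ", min(sizes), "-", max(sizes), ")"),
      "\n")
  invisible(x)
}

#' Drop UMI groups below a minimum read count
#'
#' `min_reads = 1` keeps every group (pure PCR deduplication);
#' `min_reads = 10` is the stringent consensus threshold.
#'
#' @param groups a `umi_group_set` from [group_umis()].
#' @param min_reads minimum group size, >= 1.
#' @return the surviving groups, input order preserved.
#' @export
filter_groups <- function(groups, min_reads = 1L) {
  if (min_reads < 1L) stop("min_reads must be >= 1")
  keep <- vapply(groups, function(g) g$size >= min_reads, logical(1))
  structure(unclass(groups)[keep], class = "umi_group_set")
}
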