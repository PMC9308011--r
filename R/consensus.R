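# Per-UMI-group consensus by alignment-pileup majority vote, and the
# accuracy metric used to score consensus sequences against a template.

#' Pick the representative read of a UMI group
#'
#' The member whose length equals the (lower) median group length; ties go
#' to the higher mean base quality, then the lexicographically first
#' read id. Deterministic.
#'
#' @param group a `umi_group`.
#' @return one-row data.frame (the representative member).
#' @export
select_representative <- function(group) {
  m <- group$members
  stopifnot(nrow(m) >= 1L)
  len <- nchar(m$sequence)
  target <- sort(len)[(nrow(m) + 1L) %/% 2L]
  cand <- which(len == target)
  if (length(cand) > 1L) {
    mq <- vapply(cand, function(i) {
      q <- m$quality[i]
      if (is.na(q) || !nzchar(q)) return(-Inf)
      mean(utf8ToInt(q)) - 33
    }, numeric(1))
    cand <- cand[mq == max(mq)]
    if (length(cand) > 1L) cand <- cand[order(m$read_id[cand])][1]
  }
  m[cand[1], , drop = FALSE]
}

#' Consensus sequence of a UMI group
#'
#' Every member is globally aligned to the representative read; per
#' alignment column the plurality symbol (A/C/G/T/gap) wins, with ties
#' broken toward the representative's base, and gap-winning columns are
#' deleted. Insertions relative to the representative are kept only when
#' a strict majority of members carries an insertion at that junction (the
#' most common inserted string is used). A singleton group's consensus is
#' the read itself.
#'
#' @param group a `umi_group` (must have passed [filter_groups()]).
#' @param scores an [align_scores()].
#' @param band band half-width for member-to-representative alignments.
#' @return list of class `consensus_seq` with `sequence`, `group_id`,
#'   `group_size`, `sample_id`, `amplicon`, `centroid_umi`.
#' @export
call_consensus <- function(group, scores = align_scores(), band = 64L) {
  m <- group$members
  stopifnot(nrow(m) >= 1L)
  seq <- if (nrow(m) == 1L) {
    m$sequence[1]
  } else {
    rep_seq <- select_representative(group)$sequence
    pileup_consensus(m$sequence, rep_seq, scores, band)
  }
  structure(list(sequence = seq,
                 group_id = group$group_id,
                 group_size = group$size,
                 sample_id = m$sample_id[1],
                 amplicon = m$amplicon[1],
                 centroid_umi = group$centroid_umi),
            class = "consensus_seq")
}

pileup_consensus <- function(seqs, rep_seq, scores, band) {
  aln <- cpp_align_batch(seqs, rep_seq, scores$match, scores$mismatch,
                         scores$gap_open, scores$gap_extend,
                         as.integer(band), TRUE)
  L <- nchar(rep_seq)
  nmem <- length(seqs)
  syms <- c("A", "C", "G", "T", "-")
  vote <- matrix(0L, nrow = 5L, ncol = L)
  ins_strings <- vector("list", L + 1L)  # junction j = after ref pos j
  for (i in seq_len(nmem)) {
    pa <- strsplit(aln$aligned_pattern[i], "")[[1]]
    ps <- strsplit(aln$aligned_subject[i], "")[[1]]
    is_ref <- ps != "-"
    refpos <- cumsum(is_ref)
    idx <- match(pa[is_ref], syms)
    pos <- refpos[is_ref]
    vote[cbind(idx, pos)] <- vote[cbind(idx, pos)] + 1L
    if (any(!is_ref)) {
      ins <- vapply(split(pa[!is_ref], refpos[!is_ref]), paste,
                    character(1), collapse = "")
      for (j in names(ins)) {
        jj <- as.integer(j) + 1L
        ins_strings[[jj]] <- c(ins_strings[[jj]], ins[[j]])
      }
    }
  }
  rep_idx <- match(strsplit(rep_seq, "")[[1]], syms)
  tilted <- vote + 0  # representative's symbol wins ties
  tilted[cbind(rep_idx, seq_len(L))] <-
    tilted[cbind(rep_idx, seq_len(L))] + 0.5
  sel <- max.col(t(tilted), ties.method = "first")
  cons <- syms[sel]
  ins_at <- character(L + 1L)
  for (jj in seq_len(L + 1L)) {
    v <- ins_strings[[jj]]
    if (!is.null(v) && length(v) > nmem / 2) {
      tab <- sort(table(v), decreasing = TRUE)
      top <- names(tab)[tab == tab[1]]
      ins_at[jj] <- sort(top)[1]
    }
  }
  body <- paste0(ifelse(cons == "-", "", cons), ins_at[-1L])
  paste0(ins_at[1L], paste(body, collapse = ""))
}

#' Consensus sequences for a set of UMI groups
#'
#' @param groups a `umi_group_set`.
#' @inheritParams call_consensus
#' @return data.frame with one row per group: `group_id`, `sample_id`,
#'   `amplicon`, `centroid_umi`, `group_size`, `sequence`.
#' @export
consensus_for_groups <- function(groups, scores = align_scores(),
                                 band = 64L) {
  rows <- lapply(groups, function(g) {
    cs <- call_consensus(g, scores = scores, band = band)
    data.frame(group_id = cs$group_id, sample_id = cs$sample_id,
               amplicon = cs$amplicon, centroid_umi = cs$centroid_umi,
               group_size = cs$group_size, sequence = cs$sequence,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(group_id = integer(0), sample_id = character(0),
                      amplicon = character(0), centroid_umi = character(0),
                      group_size = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write consensus sequences to FASTA
#'
#' Headers follow `group_id|amplicon|size`.
#'
#' @param consensus data.frame from [consensus_for_groups()].
#' @param path output FASTA path.
#' @export
write_consensus_fasta <- function(consensus, path) {
  x <- Biostrings::DNAStringSet(consensus$sequence)
  names(x) <- sprintf("%d|%s|%d", consensus$group_id, consensus$amplicon,
                      consensus$group_size)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
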