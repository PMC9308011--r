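# End-to-end orchestration: reads -> UMI tagging -> grouping -> consensus
# -> typing -> expression, with machine-readable outputs and a run summary.

#' Build a pipeline run configuration
#'
#' @param samples named list mapping sample id to a FASTQ path, or to an
#'   in-memory read table (as from [read_fastq()] / [simulate_sample()]).
#' @param reference path to an allele FASTA, or an [allele_db()].
#' @param amplicons amplicon/primer table; see [default_amplicons()].
#' @param umi_length,max_edit_distance,ratio_threshold UMI extraction and
#'   clustering parameters (see [tag_reads()], [group_umis()]).
#' @param min_reads minimum UMI group size for consensus (1 = pure PCR
#'   deduplication, 10 = stringent consensus).
#' @param min_identity minimum percent identity for allele assignment.
#' @param min_minor_fraction,imbalance_threshold genotype-call thresholds
#'   (see [call_genotype()]).
#' @param pseudocount,per_locus normalization parameters (see
#'   [normalize_counts()]).
#' @param scores an [align_scores()].
#' @param max_mismatch_frac,window primer-matching parameters (see
#'   [tag_reads()]).
#' @param outdir output directory, or `NULL` to skip writing files.
#' @return list of class `run_config`.
#' @export
run_config <- function(samples, reference, amplicons = default_amplicons(),
                       umi_length = 12L, max_edit_distance = 2L,
                       ratio_threshold = 2, min_reads = 1L,
                       min_identity = 85, min_minor_fraction = 0.05,
                       imbalance_threshold = 0.20, pseudocount = 1,
                       per_locus = FALSE, scores = align_scores(),
                       max_mismatch_frac = 0.2, window = 64L,
                       outdir = NULL) {
  if (min_reads < 1L) stop("invalid config field 'min_reads': must be >= 1")
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("invalid config field 'samples': must be a named list")
  }
  for (s in names(samples)) {
    if (is.character(samples[[s]]) && !file.exists(samples[[s]])) {
      stop("invalid config field 'samples': file not found for ", s, ": ",
           samples[[s]])
    }
  }
  if (is.character(reference) && !file.exists(reference)) {
    stop("invalid config field 'reference': file not found: ", reference)
  }
  structure(list(samples = samples, reference = reference,
                 amplicons = amplicons, umi_length = as.integer(umi_length),
                 max_edit_distance = as.integer(max_edit_distance),
                 ratio_threshold = ratio_threshold,
                 min_reads = as.integer(min_reads),
                 min_identity = min_identity,
                 min_minor_fraction = min_minor_fraction,
                 imbalance_threshold = imbalance_threshold,
                 pseudocount = pseudocount, per_locus = per_locus,
                 scores = scores, max_mismatch_frac = max_mismatch_frac,
                 window = as.integer(window), outdir = outdir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [run_config()]; `samples` is a
#' mapping of sample id to FASTQ path, `reference` a FASTA path,
#' `amplicons` an optional list of records with `amplicon`, `loci`,
#' `fwd_primer`, `rev_primer`.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$samples)) stop("invalid config field 'samples': missing")
  if (is.null(y$reference)) stop("invalid config field 'reference': missing")
  amp <- if (is.null(y$amplicons)) default_amplicons() else {
    do.call(rbind, lapply(y$amplicons, function(a) {
      data.frame(amplicon = a$amplicon,
                 loci = paste(a$loci, collapse = ","),
                 fwd_primer = a$fwd_primer, rev_primer = a$rev_primer,
                 stringsAsFactors = FALSE)
    }))
  }
  args <- y[intersect(names(y),
                      c("umi_length", "max_edit_distance", "ratio_threshold",
                        "min_reads", "min_identity", "min_minor_fraction",
                        "imbalance_threshold", "pseudocount", "per_locus",
                        "max_mismatch_frac", "window", "outdir"))]
  do.call(run_config, c(list(samples = y$samples, reference = y$reference,
                             amplicons = amp), args))
}

#' Run the full pipeline
#'
#' For every sample: orient/trim/UMI-tag the reads, cluster UMIs per
#' amplicon, drop groups below `min_reads`, build consensus sequences,
#' assign them to alleles, call genotypes, and finally normalize UMI
#' counts across the whole cohort. Per-sample failures are recorded in the
#' summary without aborting the batch. Fully deterministic for a given
#' configuration.
#'
#' @param config a [run_config()].
#' @return list of class `umihla_run` with `summary` (per-sample tallies),
#'   `consensus`, `assignments`, `counts`, `genotypes`, `expression`,
#'   `locus_expression`, `rejected`. When `config$outdir` is set, also
#'   writes `<sample>.consensus.fasta`, `<sample>.rejects.tsv`,
#'   `genotypes.tsv`, `expression.tsv`, `locus_totals.tsv` and
#'   `run_summary.json` there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  db <- if (inherits(config$reference, "allele_db")) config$reference
        else read_allele_fasta(config$reference)
  out <- list(summary = list(samples = list()), consensus = list(),
              assignments = list(), counts = list(), genotypes = list(),
              rejected = list())
  unassigned <- list()
  for (sid in names(config$samples)) {
    res <- tryCatch(
      run_one_sample(sid, config$samples[[sid]], db, config),
      error = function(e) e)
    if (inherits(res, "error")) {
      out$summary$samples[[sid]] <- list(error = conditionMessage(res))
      next
    }
    out$summary$samples[[sid]] <- res$summary
    out$consensus[[sid]] <- res$consensus
    out$assignments[[sid]] <- res$assignments
    out$counts[[sid]] <- res$counts
    out$genotypes[[sid]] <- res$genotypes
    out$rejected[[sid]] <- res$rejected
    unassigned[[sid]] <- res$unassigned
  }
  counts_all <- do.call(rbind, unname(out$counts))
  out$counts <- counts_all
  out$genotypes <- do.call(rbind, unname(out$genotypes))
  out$assignments <- do.call(rbind, unname(out$assignments))
  out$consensus <- do.call(rbind, unname(out$consensus))
  out$rejected <- do.call(rbind, unname(out$rejected))
  if (!is.null(counts_all) && nrow(counts_all) > 0L) {
    out$expression <- normalize_counts(counts_all,
                                       pseudocount = config$pseudocount,
                                       per_locus = config$per_locus)
    out$locus_expression <- locus_totals(out$expression)
  } else {
    out$expression <- NULL
    out$locus_expression <- NULL
  }
  out$summary$n_samples <- length(config$samples)
  out$summary$min_reads <- config$min_reads
  class(out) <- "umihla_run"
  if (!is.null(config$outdir)) write_run_outputs(out, config)
  out
}

run_one_sample <- function(sid, src, db, config) {
  reads <- if (is.data.frame(src)) src else read_fastq(src, sample_id = sid)
  reads$sample_id <- sid
  tg <- tag_reads(reads, config$amplicons, umi_length = config$umi_length,
                  max_mismatch_frac = config$max_mismatch_frac,
                  window = config$window)
  per_amp <- list()
  consensus_l <- list()
  for (amp in config$amplicons$amplicon) {
    sub <- tg$tagged[tg$tagged$amplicon == amp, , drop = FALSE]
    groups <- group_umis(sub, config$max_edit_distance,
                         config$ratio_threshold)
    kept <- filter_groups(groups, config$min_reads)
    cons <- consensus_for_groups(kept, scores = config$scores)
    per_amp[[amp]] <- list(amplicon = amp, reads = nrow(sub),
                           groups_min1 = length(groups),
                           groups_kept = length(kept),
                           consensus_n = nrow(cons))
    consensus_l[[amp]] <- cons
  }
  consensus <- do.call(rbind, unname(consensus_l))
  assignments <- if (nrow(consensus) > 0L) {
    assign_alleles(consensus, db, config$amplicons,
                   min_identity = config$min_identity,
                   scores = config$scores)
  } else {
    cbind(consensus, data.frame(best_allele = character(0),
                                locus = character(0), identity = numeric(0),
                                second_best_identity = numeric(0),
                                assigned = logical(0)))
  }
  if (nrow(tg$rejected) > 0L) tg$rejected$sample_id <- sid
  cnt <- count_umis_per_allele(assignments)
  genotypes <- call_genotypes(cnt$counts, config$min_minor_fraction,
                              config$imbalance_threshold)
  for (amp in names(per_amp)) {
    sub <- assignments[assignments$amplicon == amp, , drop = FALSE]
    per_amp[[amp]]$unassigned <- sum(!sub$assigned)
  }
  n_total <- nrow(reads)
  n_tagged <- nrow(tg$tagged)
  summary <- list(
    total_reads = n_total,
    umi_recognized = n_tagged,
    umi_recognized_pct = if (n_total > 0) 100 * n_tagged / n_total else 0,
    rejected = nrow(tg$rejected),
    consensus_total = nrow(consensus),
    assigned = sum(assignments$assigned),
    unassigned = cnt$unassigned,
    assigned_pct = if (nrow(assignments) > 0)
      100 * sum(assignments$assigned) / nrow(assignments) else NA,
    per_amplicon = unname(per_amp))
  list(summary = summary, consensus = consensus, assignments = assignments,
       counts = cnt$counts, genotypes = genotypes, rejected = tg$rejected,
       unassigned = cnt$unassigned)
}

write_run_outputs <- function(run, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  od <- config$outdir
  if (!is.null(run$genotypes) && nrow(run$genotypes %||% data.frame()) > 0L) {
    write_tsv(run$genotypes, file.path(od, "genotypes.tsv"))
  }
  if (!is.null(run$expression)) {
    write_tsv(run$expression, file.path(od, "expression.tsv"))
    write_tsv(run$locus_expression, file.path(od, "locus_totals.tsv"))
  }
  for (sid in names(config$samples)) {
    cs <- run$consensus[run$consensus$sample_id == sid, , drop = FALSE]
    if (!is.null(cs) && nrow(cs) > 0L) {
      write_consensus_fasta(cs, file.path(od,
                                          paste0(sid, ".consensus.fasta")))
    }
  }
  if (!is.null(run$rejected) && nrow(run$rejected %||% data.frame()) > 0L) {
    write_tsv(run$rejected, file.path(od, "rejects.tsv"))
  }
  jsonlite::write_json(run$summary, file.path(od, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(od)
}

#' @export
print.umihla_run <- function(x, ...) {
  s <- x$summary$samples
  cat("umihla_run:", length(s), "sample(s)\n")
  for (sid in names(s)) {
    si <- s[[sid]]
    if (!is.null(si$error)) {
      cat("  ", sid, ": ERROR - ", si$error, "\n", sep = "")
    } else {
      cat(sprintf("  %s: %d reads, %.1f%% UMI-tagged, %d consensus, %d assigned\n",
                  sid, si$total_reads, si$umi_recognized_pct,
                  si$consensus_total, si$assigned))
    }
  }
  invisible(x)
}
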