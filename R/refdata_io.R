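# Reference and read I/O: allele FASTA (IMGT-style headers), FASTQ
# (gzip-transparent), and the allele database container.

#' Build an allele database
#'
#' @param records data.frame with columns `allele_name`, `locus`,
#'   `sequence`.
#' @return object of class `allele_db` with elements `records` and
#'   `by_locus` (named list mapping locus to row indices).
#' @export
allele_db <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("allele_name", "locus", "sequence") %in% names(records)))
  if (nrow(records) == 0L) stop("allele database is empty")
  dup <- records$allele_name[duplicated(records$allele_name)]
  if (length(dup) > 0L) {
    stop("duplicate allele name(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(records$sequence))) stop("empty allele sequence")
  bad <- grepl("[^ACGT]", records$sequence)
  if (any(bad)) {
    stop("non-nucleotide characters in sequence of ",
         records$allele_name[which(bad)[1]])
  }
  rownames(records) <- NULL
  structure(list(records = records,
                 by_locus = split(seq_len(nrow(records)), records$locus)),
            class = "allele_db")
}

#' @export
print.allele_db <- function(x, ...) {
  cat("allele_db:", nrow(x$records), "alleles across",
      length(x$by_locus), "loci\n")
  for (loc in names(x$by_locus)) {
    cat("  ", loc, ": ", length(x$by_locus[[loc]]), " allele(s)\n", sep = "")
  }
  invisible(x)
}

#' @export
length.allele_db <- function(x) nrow(x$records)

#' Alleles of one or more loci
#'
#' @param db an `allele_db`.
#' @param loci character vector of locus names; `NULL` returns all records.
#' @return data.frame of matching records.
#' @export
db_alleles <- function(db, loci = NULL) {
  stopifnot(inherits(db, "allele_db"))
  if (is.null(loci)) return(db$records)
  idx <- unlist(db$by_locus[intersect(loci, names(db$by_locus))],
                use.names = FALSE)
  db$records[sort(idx), , drop = FALSE]
}

#' Read an allele reference FASTA
#'
#' Headers may be plain allele names (`>A*02:01:01`) or IMGT-style
#' (`>HLA:HLA00005 A*02:01:01:01 1098 bp`); the allele name is the first
#' `LOCUS*FIELDS` token found in the header. Sequences are uppercased and
#' `U` is mapped to `T` (cDNA convention). Line wrapping is immaterial.
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @return an [allele_db()].
#' @export
read_allele_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  headers <- names(seqs)
  names_tok <- vapply(headers, extract_allele_token, character(1),
                      USE.NAMES = FALSE)
  if (anyNA(names_tok)) {
    stop("no allele name token in header: ",
         headers[which(is.na(names_tok))[1]])
  }
  sequence <- chartr("u", "t", toupper(as.character(seqs)))
  sequence <- chartr("U", "T", sequence)
  locus <- vapply(names_tok, function(n) parse_allele_name(n)$locus,
                  character(1), USE.NAMES = FALSE)
  allele_db(data.frame(allele_name = names_tok, locus = locus,
                       sequence = unname(sequence),
                       stringsAsFactors = FALSE))
}

#' Write an allele database to FASTA
#'
#' @param db an `allele_db`.
#' @param path output path; `.gz` suffix triggers compression.
#' @export
write_allele_fasta <- function(db, path) {
  stopifnot(inherits(db, "allele_db"))
  x <- Biostrings::DNAStringSet(db$records$sequence)
  names(x) <- db$records$allele_name
  Biostrings::writeXStringSet(x, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @param sample_id sample label attached to every read; defaults to the
#'   file name without extensions.
#' @return data.frame with columns `read_id`, `sequence`, `quality`,
#'   `sample_id`.
#' @export
read_fastq <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  }
  validate_fastq(path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sequence = unname(as.character(x)),
             quality = unname(qual),
             sample_id = sample_id,
             stringsAsFactors = FALSE)
}

# Structural pre-check so malformed files fail with the record index.
validate_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record at record ", length(lines) %/% 4L + 1L,
         " in ", path)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(invisible(TRUE))
  seqlen <- nchar(lines[seq(2L, by = 4L, length.out = n)])
  quallen <- nchar(lines[seq(4L, by = 4L, length.out = n)])
  bad <- which(seqlen != quallen)
  if (length(bad) > 0L) {
    stop("sequence/quality length mismatch at record ", bad[1], " in ", path)
  }
  invisible(TRUE)
}

#' Write reads to FASTQ
#'
#' `write_fastq()` followed by [read_fastq()] is the identity on read ids,
#' sequences and qualities. Missing qualities are written as flat `I`.
#'
#' @param reads read table as returned by [read_fastq()] or
#'   [simulate_sample()].
#' @param path output path; `.gz` suffix triggers compression.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  qual <- reads$quality
  if (is.null(qual)) qual <- rep(NA_character_, nrow(reads))
  flat <- is.na(qual)
  qual[flat] <- strrep("I", nchar(reads$sequence[flat]))
  if (any(nchar(qual) != nchar(reads$sequence))) {
    stop("sequence/quality length mismatch at record ",
         which(nchar(qual) != nchar(reads$sequence))[1])
  }
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
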