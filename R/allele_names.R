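# HLA allele nomenclature: LOCUS*F1:F2:F3:F4 with an optional single-letter
# expression suffix (N, L, S, C, A, Q; unknown letters are carried opaque).

#' Parse an HLA allele name
#'
#' Splits a name such as `"A*02:01:01"` or `"DRB5*01:08:01N"` into its
#' locus, colon-delimited numeric fields and optional expression suffix.
#' Formatting the parts with [format_allele_name()] reproduces the input.
#'
#' @param name allele name containing a `*` between locus and fields.
#' @return list with `locus` (character), `fields` (character vector of 1-4
#'   numeric field strings, leading zeros preserved) and `suffix`
#'   (single uppercase letter or `NA`).
#' @examples
#' parse_allele_name("A*02:01:01")
#' parse_allele_name("DRB5*01:08:01N")
#' @export
parse_allele_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!grepl("*", name, fixed = TRUE)) {
    stop("allele name '", name, "' lacks the '*' locus separator")
  }
  parts <- strsplit(name, "*", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !nzchar(parts[1])) {
    stop("allele name '", name, "' has a malformed locus token")
  }
  locus <- parts[1]
  rest <- parts[2]
  suffix <- NA_character_
  if (grepl("[A-Z]$", rest)) {
    suffix <- substr(rest, nchar(rest), nchar(rest))
    rest <- substr(rest, 1L, nchar(rest) - 1L)
  }
  fields <- strsplit(rest, ":", fixed = TRUE)[[1]]
  if (length(fields) < 1L || length(fields) > 4L ||
      any(!nzchar(fields)) || any(!grepl("^[0-9]+$", fields))) {
    stop("allele name '", name, "' has malformed fields '", rest, "'")
  }
  list(locus = locus, fields = fields, suffix = suffix)
}

#' Format allele name parts back into a name
#'
#' @param locus locus string (e.g. `"A"`, `"DRB1"`).
#' @param fields character vector of 1-4 field strings.
#' @param suffix optional expression suffix letter (`NA` for none).
#' @return the allele name string.
#' @export
format_allele_name <- function(locus, fields, suffix = NA_character_) {
  paste0(locus, "*", paste(fields, collapse = ":"),
         if (!is.na(suffix)) suffix else "")
}

#' Truncate an allele name to at most k fields
#'
#' Used for field-level concordance (e.g. two-field resolution). The
#' expression suffix is retained only when no field is dropped.
#'
#' @param name allele name.
#' @param k number of fields to keep, 1-4.
#' @return truncated allele name.
#' @examples
#' truncate_fields("A*02:01:01", 2)   # "A*02:01"
#' truncate_fields("DRB5*01:08:01N", 2)  # suffix dropped
#' @export
truncate_fields <- function(name, k) {
  stopifnot(length(k) == 1L, k >= 1L, k <= 4L)
  p <- parse_allele_name(name)
  keep <- head(p$fields, k)
  suffix <- if (length(keep) == length(p$fields)) p$suffix else NA_character_
  format_allele_name(p$locus, keep, suffix)
}

# First LOCUS*FIELDS token found anywhere in a FASTA header, or NA.
extract_allele_token <- function(header) {
  m <- regmatches(header,
                  regexpr("[A-Za-z0-9]+\\*[0-9]+(:[0-9]+){0,3}[A-Z]?",
                          header))
  if (length(m) == 0L) NA_character_ else m
}
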