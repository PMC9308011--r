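# Expression quantitation: counts-per-million normalization of per-allele
# UMI counts, per-locus aggregation, and the precision/comparison
# statistics reported alongside (coefficient of variation, Mann-Whitney U).

#' Normalize per-allele UMI counts to log2 counts-per-million
#'
#' `cpm = umi_count / total_sample_umi * 1e6` and
#' `log2_norm = log2(cpm + pseudocount)`. Per sample the cpm values sum to
#' one million. With `per_locus = TRUE` the denominator is the locus total
#' within the sample instead of the sample total.
#'
#' @param counts data.frame with `sample_id`, `locus`, `allele_name`,
#'   `umi_count`.
#' @param pseudocount added inside the log2 so zero counts are
#'   representable; default 1.
#' @param per_locus use per-locus denominators.
#' @return `counts` with added `cpm` and `log2_norm` columns.
#' @examples
#' x <- data.frame(sample_id = "s", locus = "A",
#'                 allele_name = c("A*01:01", "A*02:01"),
#'                 umi_count = c(30, 70))
#' normalize_counts(x)
#' @export
normalize_counts <- function(counts, pseudocount = 1, per_locus = FALSE) {
  stopifnot(all(c("sample_id", "locus", "allele_name", "umi_count") %in%
                  names(counts)),
            pseudocount >= 0)
  if (nrow(counts) == 0L) {
    counts$cpm <- numeric(0); counts$log2_norm <- numeric(0)
    return(counts)
  }
  if (any(counts$umi_count < 0)) stop("negative UMI count")
  denom_key <- if (per_locus) {
    paste(counts$sample_id, counts$locus, sep = "\r")
  } else {
    counts$sample_id
  }
  totals <- tapply(counts$umi_count, denom_key, sum)
  zero <- names(totals)[totals <= 0]
  if (length(zero) > 0L) {
    stop("zero total UMI count for sample ",
         sub("\r.*$", "", zero[1]))
  }
  counts$cpm <- counts$umi_count / as.numeric(totals[denom_key]) * 1e6
  counts$log2_norm <- log2(counts$cpm + pseudocount)
  counts
}

#' Per-locus expression totals
#'
#' Sums counts and cpm over the alleles of each locus; summing the locus
#' totals of a sample recovers the sample total.
#'
#' @param table output of [normalize_counts()].
#' @return data.frame with `sample_id`, `locus`, `umi_count`, `cpm`.
#' @export
locus_totals <- function(table) {
  if (nrow(table) == 0L) stop("empty expression table")
  out <- aggregate(table[, c("umi_count", "cpm")],
                   by = list(sample_id = table$sample_id,
                             locus = table$locus),
                   FUN = sum)
  out <- out[order(out$sample_id, out$locus), ]
  rownames(out) <- NULL
  out
}

#' Coefficient of variation of replicate measurements
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation.
#'
#' @param replicate_values numeric vector, length >= 2, positive mean.
#' @return percentage.
#' @examples
#' coefficient_of_variation(c(100, 110, 90))  # 10
#' @export
coefficient_of_variation <- function(replicate_values) {
  if (length(replicate_values) < 2L) {
    stop("need at least two replicate values")
  }
  m <- mean(replicate_values)
  if (m <= 0) stop("mean of replicate values must be positive")
  100 * sd(replicate_values) / m
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups. The p value is exact (full
#' enumeration of all rank assignments) when `n_a + n_b` is at most
#' `exact_limit`, and a normal approximation with tie correction and
#' continuity correction otherwise. The U statistic satisfies
#' `U(a, b) + U(b, a) = n_a * n_b`.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @param exact_limit maximum combined size for the exact enumeration.
#' @return list with `U` (statistic for `group_a`), `p` (two-sided) and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(group_a, group_b, exact_limit = 12L) {
  na <- length(group_a); nb <- length(group_b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty")
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  n <- na + nb
  if (n <= exact_limit) {
    splits <- combn(n, na)
    Uall <- apply(splits, 2L, function(idx) sum(r[idx]) - na * (na + 1) / 2)
    u_lo <- min(U, na * nb - U)
    u_hi <- na * nb - u_lo
    p <- mean(Uall <= u_lo) + mean(Uall >= u_hi)
    p <- min(1, p)
    list(U = U, p = p, method = "exact")
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    list(U = U, p = min(1, 2 * pnorm(-z)), method = "normal")
  }
}
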