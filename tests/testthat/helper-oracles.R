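# Independent oracles used to validate the package implementations.
# These deliberately use naive/exhaustive algorithms and share no code
# with the package internals.

# Brute-force directional UMI clustering: full all-pairs Levenshtein
# matrix via utils::adist, then the same merge rule applied sequentially.
# Returns group id per (sorted) UMI.
oracle_group_umis <- function(umis, counts, max_ed = 2L, ratio = 2) {
  ord <- order(-counts, umis, method = "radix")
  umis <- umis[ord]; counts <- counts[ord]
  d <- utils::adist(umis, umis)
  gid <- integer(length(umis))
  cent <- integer(0) # indices of centroids
  for (i in seq_along(umis)) {
    best <- NA_integer_; best_d <- max_ed + 1L; best_c <- -1L
    for (g in seq_along(cent)) {
      ci <- cent[g]
      if (counts[i] > ceiling(counts[ci] / ratio)) next
      if (d[i, ci] > max_ed) next
      if (d[i, ci] < best_d || (d[i, ci] == best_d && counts[ci] > best_c)) {
        best <- g; best_d <- d[i, ci]; best_c <- counts[ci]
      }
    }
    if (is.na(best)) {
      cent <- c(cent, i)
      gid[i] <- length(cent)
    } else {
      gid[i] <- best
    }
  }
  list(umis = umis, counts = counts, gid = gid)
}

# Exhaustive global alignment by recursion over all monotone paths with
# affine gap states; returns the optimal score and the set of accuracy
# values (100 * matches / columns) achievable at that score.
oracle_exhaustive_accuracy <- function(a, b, match = 2, mismatch = -4,
                                       gap_open = 4, gap_ext = 2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf; best$acc <- numeric(0)
  recurse <- function(i, j, score, matches, cols, state) {
    if (i > length(av) && j > length(bv)) {
      if (score > best$score) {
        best$score <- score; best$acc <- 100 * matches / cols
      } else if (score == best$score) {
        best$acc <- unique(c(best$acc, 100 * matches / cols))
      }
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      recurse(i + 1, j + 1, score + s, matches + (av[i] == bv[j]),
              cols + 1, 0L)
    }
    if (i <= length(av)) {
      pen <- if (state == 1L) gap_ext else gap_open + gap_ext
      recurse(i + 1, j, score - pen, matches, cols + 1, 1L)
    }
    if (j <= length(bv)) {
      pen <- if (state == 2L) gap_ext else gap_open + gap_ext
      recurse(i, j + 1, score - pen, matches, cols + 1, 2L)
    }
  }
  recurse(1L, 1L, 0, 0L, 0L, -1L)
  list(score = best$score, accuracies = best$acc)
}

# Exact Mann-Whitney by enumeration of value splits, with U computed by
# direct pair counting (independent of the rank-sum formula).
oracle_mann_whitney <- function(a, b) {
  u_pairs <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  U <- u_pairs(a, b)
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  splits <- utils::combn(n, na)
  Uall <- apply(splits, 2, function(idx) {
    u_pairs(pooled[idx], pooled[-idx])
  })
  u_lo <- min(U, na * length(b) - U)
  u_hi <- na * length(b) - u_lo
  p <- min(1, mean(Uall <= u_lo) + mean(Uall >= u_hi))
  list(U = U, p = p)
}

# Expected read-vs-template identity under a substitution-only error
# model, by direct Monte-Carlo draws (no alignment involved).
oracle_identity_mc <- function(sub_rate, len, n = 2000) {
  mean(replicate(n, {
    errs <- sum(runif(len) < sub_rate)
    100 * (len - errs) / len
  }))
}
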