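# Independent brute-force oracles used by property and acceptance tests.
# These deliberately avoid the code paths they check.

# per-base reciprocal overlap on small coordinates
roOracle <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0)
  inter <- length(intersect(seq2(s1, e1), seq2(s2, e2)))
  inter / max(e1 - s1 + 1L, e2 - s2 + 1L)
}
seq2 <- function(a, b) if (b < a) integer() else seq.int(a, b)

# transitive closure single-linkage over an explicit all-pairs link matrix
bruteClusterOracle <- function(chrom, start, end, bpTol, minRo) {
  n <- length(start)
  link <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    link[i, j] <- chrom[i] == chrom[j] &&
      abs(start[i] - start[j]) <= bpTol &&
      abs(end[i] - end[j]) <= bpTol &&
      roOracle(chrom[i], start[i], end[i], chrom[j], start[j], end[j]) >=
        minRo
  }
  # Warshall closure
  for (k in seq_len(n)) for (i in seq_len(n)) {
    if (link[i, k]) link[i, ] <- link[i, ] | link[k, ]
  }
  membership <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (membership[i] == 0L) {
      cl <- cl + 1L
      membership[link[i, ]] <- cl
      membership[i] <- cl
    }
  }
  membership
}

# canonical form of a partition for comparison: sorted list of sorted groups
canonicalPartition <- function(membership, keys) {
  groups <- split(sort(keys), membership[order(keys)])
  unname(groups[order(vapply(groups, `[[`, "", 1L))])
}

# exact HWE test by direct per-configuration probability (log-factorial
# closed form), independent of the recurrence used in the package
hweOracle <- function(aa, ab, bb) {
  n <- aa + ab + bb
  nA <- 2L * aa + ab
  rare <- min(nA, 2L * n - nA)
  if (rare == 0L) return(1)
  hs <- seq.int(rare %% 2L, rare, by = 2L)
  homr <- (rare - hs) / 2
  homc <- n - hs - homr
  lp <- lfactorial(n) - lfactorial(homr) - lfactorial(hs) -
    lfactorial(homc) + hs * log(2) +
    lfactorial(rare) + lfactorial(2L * n - rare) - lfactorial(2L * n)
  p <- exp(lp)
  pObs <- p[match(ab, hs)]
  min(1, sum(p[p <= pObs * (1 + 1e-10)]))
}

# hand step-up BH, independent of stats::p.adjust
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# mean score over an interval by explicit per-base summation
meanScoreOracle <- function(s, e, runStarts, runEnds, runScores) {
  vals <- rep(NA_real_, e - s + 1L)
  for (k in seq_along(runStarts)) {
    idx <- seq2(max(s, runStarts[k]), min(e, runEnds[k]))
    vals[idx - s + 1L] <- runScores[k]
  }
  covered <- !is.na(vals)
  if (!any(covered)) return(list(mean = NA_real_, frac = 0))
  list(mean = mean(vals[covered]), frac = mean(covered))
}
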