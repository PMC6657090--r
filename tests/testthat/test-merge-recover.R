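test_that("six samples calling the same deletion form one cluster", {
  calls <- mkCalls(chrom = "chr7", start = rep(152419400L, 6),
                   end = rep(152419715L, 6),
                   sample = sprintf("S%d", 1:6),
                   orient = c("forward_only", "reverse_only",
                              "forward_only", "reverse_only",
                              "both", "both"))
  merged <- clusterCalls(calls)
  expect_length(merged, 1L)
  lo <- loci(merged)
  expect_identical(mcols(lo)$n_members, 6L)
  expect_identical(mcols(lo)$n_both, 2L)
  expect_identical(width(lo), 315L)
  expect_length(clusterCalls(mkCalls()[0]), 0L)
})

test_that("jittered calls split into the right clusters and match the brute-force oracle", {
  set.seed(11)
  # locus A jittered +-3 bp, locus B 1 kb away
  sA <- 20000L + sample(-3:3, 5, replace = TRUE)
  eA <- 20400L + sample(-3:3, 5, replace = TRUE)
  calls <- mkCalls(start = c(sA, 21000L, 21002L),
                   end = c(eA, 21400L, 21398L),
                   sample = sprintf("S%d", 1:7))
  merged <- clusterCalls(calls)
  expect_length(merged, 2L)
  memb <- bruteClusterOracle(rep("chr1", 7), c(sA, 21000L, 21002L) + 1L,
                             c(eA, 21400L, 21398L), 10L, 0.8)
  keys <- sprintf("S%d", 1:7)
  got <- canonicalPartition(
    as.integer(factor(mcols(memberCalls(merged))$locus_id)),
    mcols(memberCalls(merged))$sample_id)
  expect_identical(got, canonicalPartition(memb, keys))
})

test_that("clustering is permutation invariant and idempotent on consensus", {
  set.seed(23)
  calls <- mkCalls(start = c(1000L, 1003L, 1001L, 6000L, 6002L),
                   end = c(1400L, 1398L, 1401L, 6400L, 6404L),
                   sample = sprintf("S%d", 1:5))
  m1 <- clusterCalls(calls)
  perm <- sample(length(calls))
  m2 <- clusterCalls(calls[perm])
  expect_identical(granges(loci(m1)), granges(loci(m2)))
  expect_identical(as.data.frame(mcols(loci(m1))),
                   as.data.frame(mcols(loci(m2))))
  # consensus output re-clusters to itself
  consCalls <- mkCalls(start = start(loci(m1)) - 1L,
                       end = end(loci(m1)),
                       sample = sprintf("C%d", seq_along(loci(m1))))
  m3 <- clusterCalls(consCalls)
  expect_identical(granges(loci(m3)), granges(loci(m1)))
})

test_that("consensus breakpoints take the mode with documented tie-breaks", {
  cl <- mkCalls(start = c(100L, 100L, 100L, 102L),
                end = c(200L, 200L, 200L, 199L),
                sample = sprintf("S%d", 1:4))
  cons <- consensusBreakpoints(cl)
  expect_identical(regionString(cons), "chr1:100-200")

  # identical members -> that interval
  same <- mkCalls(start = rep(500L, 3), end = rep(800L, 3),
                  sample = sprintf("S%d", 1:3))
  expect_identical(regionString(consensusBreakpoints(same)),
                   "chr1:500-800")

  # 2-2 tie: the pair seen in a both-orientation call wins
  tied <- mkCalls(start = c(100L, 100L, 98L, 98L),
                  end = c(200L, 200L, 201L, 201L),
                  orient = c("forward_only", "forward_only",
                             "both", "reverse_only"),
                  sample = sprintf("S%d", 1:4))
  expect_identical(regionString(consensusBreakpoints(tied)),
                   "chr1:98-201")
  expect_error(consensusBreakpoints(mkCalls()[0]), "empty")
})

test_that("consensus matches an exhaustive mode-with-tiebreak oracle", {
  set.seed(31)
  for (rep in 1:40) {
    k <- sample(2:8, 1)
    starts <- 1000L + sample(0:3, k, replace = TRUE)
    ends <- 1300L + sample(0:3, k, replace = TRUE)
    orient <- sample(c("both", "forward_only", "reverse_only"), k,
                     replace = TRUE)
    cl <- mkCalls(start = starts, end = ends, orient = orient,
                  sample = sprintf("S%d", seq_len(k)))
    # oracle: enumerate every observed pair with counts and flags
    key <- paste(starts + 1L, ends)
    tab <- table(key)
    best <- NULL
    for (kk in names(tab)) {
      cnt <- tab[[kk]]
      fromBoth <- any(key == kk & orient == "both")
      sv <- as.integer(strsplit(kk, " ")[[1]])
      cand <- list(n = cnt, fb = fromBoth, s = sv[1], e = sv[2])
      better <- is.null(best) || cand$n > best$n ||
        (cand$n == best$n && cand$fb > best$fb) ||
        (cand$n == best$n && cand$fb == best$fb && cand$s < best$s) ||
        (cand$n == best$n && cand$fb == best$fb && cand$s == best$s &&
           cand$e < best$e)
      if (better) best <- cand
    }
    cons <- consensusBreakpoints(cl)
    expect_identical(c(start(cons), end(cons)), c(best$s, best$e))
  }
})

test_that("joint-call recovery keeps singles only with two or more both-orientation backers", {
  # 2 both + 4 single-orientation -> all four recovered
  calls <- mkCalls(start = rep(152419400L, 6), end = rep(152419715L, 6),
                   sample = sprintf("S%d", 1:6),
                   orient = c("forward_only", "reverse_only",
                              "forward_only", "reverse_only",
                              "both", "both"))
  rec <- mkMerged(calls)
  st <- mcols(memberCalls(rec))$call_status
  expect_identical(sum(st == "recovered"), 4L)
  expect_identical(sum(st == "dropped"), 0L)
  expect_identical(mcols(loci(rec))$n_recovered, 4L)

  # only both-orientation members -> unchanged
  allBoth <- mkMerged(mkCalls(start = rep(100L, 3), end = rep(400L, 3),
                              sample = sprintf("S%d", 1:3)))
  expect_true(all(mcols(memberCalls(allBoth))$call_status == "both"))

  # 1 both + 3 singles -> none recovered
  one <- mkMerged(mkCalls(start = rep(100L, 4), end = rep(400L, 4),
                          sample = sprintf("S%d", 1:4),
                          orient = c("both", rep("forward_only", 3))))
  st1 <- mcols(memberCalls(one))$call_status
  expect_identical(sum(st1 == "recovered"), 0L)
  expect_identical(sum(st1 == "dropped"), 3L)
})

test_that("a sample's own both-orientation call does not back its single call", {
  # S1 has both a single call and a both call in the cluster; S2 has both.
  # Only one *other* sample (S2) backs S1's single call -> dropped.
  calls <- mkCalls(start = c(100L, 100L, 100L),
                   end = c(400L, 400L, 400L),
                   sample = c("S1", "S1", "S2"),
                   orient = c("forward_only", "both", "both"))
  rec <- mkMerged(calls)
  mc <- memberCalls(rec)
  single <- mcols(mc)$support_orientation == "forward_only"
  expect_identical(mcols(mc)$call_status[single], "dropped")
})

test_that("recovery is monotone relative to the no-recovery baseline", {
  set.seed(47)
  starts <- rep(seq(10000L, by = 2000L, length.out = 10L), each = 5)
  orient <- sample(c("both", "forward_only", "reverse_only"), 50,
                   replace = TRUE)
  calls <- mkCalls(start = starts, end = starts + 300L,
                   sample = rep(sprintf("S%d", 1:5), times = 10),
                   orient = orient)
  rec <- mkMerged(calls)
  mc <- memberCalls(rec)
  keptKeys <- paste(mcols(mc)$locus_id, mcols(mc)$sample_id)[
    mcols(mc)$call_status != "dropped"]
  baselineKeys <- paste(mcols(mc)$locus_id, mcols(mc)$sample_id)[
    mcols(mc)$support_orientation == "both"]
  expect_true(all(baselineKeys %in% keptKeys))
  # both-orientation calls never altered
  expect_true(all(mcols(mc)$call_status[
    mcols(mc)$support_orientation == "both"] == "both"))
  # no locus gains members
  expect_identical(length(mc), length(calls))
})
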