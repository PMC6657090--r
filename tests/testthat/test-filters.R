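mergedOfLengths <- function(lens, start0 = NULL, ...) {
  n <- length(lens)
  if (is.null(start0)) start0 <- seq(10000L, by = 50000L, length.out = n)
  mkMerged(mkCalls(start = start0, end = start0 + lens,
                   sample = sprintf("S%d", seq_len(n)), ...))
}

test_that("size filter drops below 30 bp and above 10 kb, boundaries exact", {
  m <- mergedOfLengths(c(29L, 30L, 315L, 10000L))
  part <- filterSize(m)
  expect_identical(part$keep, c(FALSE, TRUE, TRUE, TRUE))
  # 10 kb is the caller ceiling; anything at it still passes
  expect_length(part$kept, 3L)
  expect_length(part$dropped, 1L)
})

test_that("region filter excludes track overlap and 100 bp repeat flanks", {
  # deletion body [10000,10300) 0-based
  del <- mkMerged(mkCalls(start = 10000L, end = 10300L))
  mkT <- function(simpleStart0, simpleEnd0) {
    mkTracks(simple = gr1("chr1", simpleStart0 + 1L, simpleEnd0))
  }
  # 1 bp body overlap -> dropped
  expect_false(filterRegionAnnotations(del, mkT(10299L, 10400L))$keep)
  # repeat begins exactly 100 bp past the end: flank [10300,10400) misses
  # a repeat starting at 0-based 10400 -> kept
  expect_true(filterRegionAnnotations(del, mkT(10400L, 10500L))$keep)
  # repeat starting at 0-based 10399 is the 100th flank base -> dropped
  expect_false(filterRegionAnnotations(del, mkT(10399L, 10500L))$keep)
  # left flank symmetric: repeat ending at 0-based 9900 -> dropped;
  # ending at 9900 - 1 bp earlier is still within? one base beyond -> kept
  expect_false(filterRegionAnnotations(del, mkT(9850L, 9901L))$keep)
  expect_true(filterRegionAnnotations(del, mkT(9850L, 9900L))$keep)
  # telomere/centromere and microsatellite overlap also drop
  expect_false(filterRegionAnnotations(
    del, mkTracks(telo = gr1("chr1", 10001L, 10300L)))$keep)
  expect_false(filterRegionAnnotations(
    del, mkTracks(micro = gr1("chr1", 10200L, 10210L)))$keep)
  expect_error(filterRegionAnnotations(del, list(simple_repeat = GRanges())),
               "missing annotation track")
})

test_that("region filter partition equals a per-base overlap oracle", {
  set.seed(99)
  for (rep in 1:25) {
    n <- 8L
    s0 <- sample(500:3000, n) * 1L
    lens <- sample(30:200, n, replace = TRUE)
    m <- mergedOfLengths(lens, start0 = s0)
    trS <- sort(gr1("chr1", sample(500:3500, 5), width = sample(20:120, 5)))
    tracks <- mkTracks(simple = trS)
    part <- filterRegionAnnotations(m, tracks)
    lo <- loci(m)
    for (i in seq_along(lo)) {
      s <- start(lo)[i]; e <- end(lo)[i]
      body <- seq2(s, e)
      flank <- c(seq2(s - 100L, s - 1L), seq2(e + 1L, e + 100L))
      trBases <- unlist(lapply(seq_along(trS), function(k)
        seq2(start(trS)[k], end(trS)[k])))
      dropOracle <- length(intersect(body, trBases)) > 0 ||
        length(intersect(flank, trBases)) > 0
      expect_identical(part$keep[i], !dropOracle)
    }
  }
})

test_that("depth filter applies 'over 150' and 'deeper than flank' strictly", {
  m <- mergedOfLengths(rep(300L, 4),
                       ddel = c(151, 30, 40, 150),
                       dflank = c(151, 30, 35, 150))
  part <- filterDepth(m)
  # 151 with equal flank: over 150 -> dropped; 30/30 equal -> kept;
  # 40 > 35 -> dropped; 150/150 boundary -> kept
  expect_identical(part$keep, c(FALSE, TRUE, FALSE, TRUE))
  # all depths missing -> kept and flagged
  mNA <- mergedOfLengths(300L, ddel = NA_real_, dflank = NA_real_)
  pNA <- filterDepth(mNA)
  expect_true(pNA$keep)
  expect_true(pNA$flagged)
})

test_that("soft-clip quality filter drops strictly below 15, member-mean", {
  m <- mergedOfLengths(rep(300L, 3), qual = c(14.9, 15.0, 30))
  expect_identical(filterSoftclipQuality(m)$keep, c(FALSE, TRUE, TRUE))
  # members {14, 18} -> mean 16 -> kept
  two <- mkMerged(mkCalls(start = rep(10000L, 2), end = rep(10300L, 2),
                          sample = c("S1", "S2"), qual = c(14, 18)))
  expect_true(filterSoftclipQuality(two)$keep)
  # no member has a value -> kept, flagged
  none <- mergedOfLengths(300L, qual = NA)
  pn <- filterSoftclipQuality(none)
  expect_true(pn$keep)
  expect_true(pn$flagged)
})

test_that("similar-repeat filter needs both breakpoints in distinct same-name elements", {
  del <- mkMerged(mkCalls(start = 10150L, end = 10500L))  # bps 10151/10500 1-based
  repelAt <- function(names, s1based) {
    g <- gr1("chr1", s1based, s1based + 299L)
    mcols(g)$name <- names
    g
  }
  # start in AluY #1, end in AluY #2 -> dropped
  two <- repelAt(c("AluY", "AluY"), c(10001L, 10351L))
  expect_false(filterSimilarRepeat(del, two)$keep)
  # different names -> kept
  expect_true(filterSimilarRepeat(
    del, repelAt(c("AluY", "L1PA3"), c(10001L, 10351L)))$keep)
  # only one breakpoint covered -> kept
  expect_true(filterSimilarRepeat(del, repelAt("AluY", 10001L))$keep)
  # both breakpoints inside one and the same element -> kept
  wide <- gr1("chr1", 10001L, 10600L)
  mcols(wide)$name <- "AluY"
  expect_true(filterSimilarRepeat(del, wide)$keep)
  # family mode links AluY with AluSx
  fam <- repelAt(c("AluY", "AluSx"), c(10001L, 10351L))
  expect_true(filterSimilarRepeat(del, fam)$keep)
  expect_false(filterSimilarRepeat(
    del, fam, filterParams(repeatMatch = "family"))$keep)
  # unlabeled track -> configuration error
  bad <- gr1("chr1", 10001L, 10300L)
  expect_error(filterSimilarRepeat(del, bad), "name label")
})

test_that("the cascade chains, conserves loci and is deterministic", {
  tracks <- mkTracks(simple = gr1("chr1", 60001L, 60100L))
  # five loci, one engineered violation each except the last
  m <- mkMerged(mkCalls(start = c(10000L, 60000L, 110000L, 160000L,
                                  210000L),
                        end = c(10020L, 60300L, 110310L, 160320L,
                                210330L),
                        sample = sprintf("S%d", 1:5),
                        ddel = c(20, 20, 200, 20, 20),
                        dflank = rep(40, 5),
                        qual = c(30, 30, 30, 5, 30)))
  res <- runProgressivePipeline(m, tracks)
  acc <- res$accounting
  expect_identical(acc$n_in[-1], acc$n_out[-nrow(acc)])
  expect_true(all(acc$n_out <= acc$n_in))
  expect_identical(acc$n_out[nrow(acc)], 1L)
  # union of dropped + kept = input, no duplication
  ids <- c(mcols(loci(res$kept))$locus_id,
           unlist(lapply(res$dropped, function(d) mcols(loci(d))$locus_id)))
  expect_setequal(ids, mcols(loci(m))$locus_id)
  expect_identical(anyDuplicated(ids), 0L)
  # pure function: identical on re-run
  res2 <- runProgressivePipeline(m, tracks)
  expect_identical(res$accounting, res2$accounting)
  expect_identical(granges(loci(res$kept)), granges(loci(res2$kept)))
  # empty input
  e <- runProgressivePipeline(m[FALSE], tracks)
  expect_identical(e$accounting$n_out, rep(0L, 5))
})
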