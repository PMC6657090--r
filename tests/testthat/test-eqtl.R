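test_that("cis pairing is boundary-inclusive at 1 Mb and chromosome-aware", {
  v <- gr1("chr1", c(2e6, 2e6, 2e6), width = 1L)
  mcols(v)$locus_id <- c("v1", "v2", "v3")
  v <- v[1]
  tss <- data.frame(gene_id = c("gAt", "gOver", "gOther", "gNoTss"),
                    chrom = c("chr1", "chr1", "chr2", NA),
                    tss = c(1e6, 1e6 - 1, 2e6, NA))
  suppressMessages(p <- cisPairs(v, tss, window = 1e6))
  expect_setequal(p$gene_id, "gAt")  # exactly 1 Mb paired, 1 Mb + 1 not
  expect_equal(p$distance, 1e6)
})

test_that("cis pairs equal a brute-force distance scan on random layouts", {
  set.seed(202)
  for (rep in 1:10) {
    nv <- 30L; ng <- 12L
    v <- gr1(sample(c("chr1", "chr2"), nv, replace = TRUE),
             sample(1:5e6, nv), width = sample(50:500, nv, replace = TRUE))
    mcols(v)$locus_id <- sprintf("v%02d", seq_len(nv))
    tss <- data.frame(gene_id = sprintf("g%02d", seq_len(ng)),
                      chrom = sample(c("chr1", "chr2"), ng, replace = TRUE),
                      tss = sample(1:5e6, ng))
    got <- cisPairs(v, tss, window = 5e5)
    gotKeys <- sort(paste(got$gene_id, got$variant_id))
    oracleKeys <- character()
    for (i in seq_len(nv)) for (j in seq_len(ng)) {
      if (as.character(seqnames(v))[i] == tss$chrom[j] &&
          abs(start(v)[i] - tss$tss[j]) <= 5e5) {
        oracleKeys <- c(oracleKeys,
                        paste(tss$gene_id[j], mcols(v)$locus_id[i]))
      }
    }
    expect_identical(gotKeys, sort(oracleKeys))
  }
})

test_that("the additive linear model agrees with lm() to 1e-10", {
  set.seed(82)
  g <- sample(0:2, 82, replace = TRUE, prob = c(0.49, 0.42, 0.09))
  y <- 2 * g + rnorm(82, 0, 0.1)
  fit <- linearEqtl(y, g)
  expect_identical(fit$status, "ok")
  expect_true(fit$beta > 1.9 && fit$beta < 2.1)
  ref <- summary(lm(y ~ g))$coefficients
  expect_equal(fit$beta, ref["g", "Estimate"], tolerance = 1e-10)
  expect_equal(fit$t_stat, ref["g", "t value"], tolerance = 1e-10)
  expect_equal(fit$p_value, ref["g", "Pr(>|t|)"], tolerance = 1e-10)

  # monomorphic genotype is skipped with a reason
  expect_identical(linearEqtl(y, rep(1, 82))$status, "monomorphic")
  # missing pairs are dropped before the monomorphism check
  g2 <- g; g2[g2 == 2] <- NA
  expect_identical(linearEqtl(y, g2)$n, sum(!is.na(g2)))
  expect_identical(linearEqtl(y[1:2], g[1:2])$status, "too_few_samples")
})

test_that("permutation null p-values are uniform", {
  set.seed(303)
  y <- rnorm(60)
  g <- sample(0:2, 60, replace = TRUE)
  p <- replicate(500, linearEqtl(y, sample(g))$p_value)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("per-window BH follows the step-up rule", {
  expect_equal(bhWithinWindow(0.005), 0.005)
  expect_equal(bhWithinWindow(c(0.001, 0.002, 0.04)),
               c(0.003, 0.003, 0.04))
  expect_identical(bhWithinWindow(numeric()), numeric())
  expect_error(bhWithinWindow(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bhWithinWindow(c(0.5, 1.2)), "\\(0, 1\\]")
  # matches an independent step-up implementation over a grid
  grid <- c(0.0004, 0.004, 0.04, 0.4, 0.9, 1)
  set.seed(17)
  for (m in 1:8) {
    for (rep in 1:10) {
      p <- sample(grid, m, replace = TRUE)
      expect_equal(bhWithinWindow(p), bhOracle(p), tolerance = 1e-12)
    }
  }
})

test_that("genomic inflation is calibrated and scales with the statistics", {
  expect_equal(genomicInflation(rep(0.5, 7)), 1.0)
  set.seed(404)
  expect_equal(genomicInflation(runif(10000)), 1.0, tolerance = 0.05)
  chi <- rchisq(10000, df = 1) * 1.3
  pInfl <- pchisq(chi, df = 1, lower.tail = FALSE)
  expect_equal(genomicInflation(pInfl), 1.3, tolerance = 0.05)
  expect_error(genomicInflation(numeric()), "no p-values")
})

test_that("causal fractions reproduce printed-ratio arithmetic", {
  assoc <- data.frame(
    variant_id = sprintf("v%03d", 1:250),
    significant = c(rep(TRUE, 217), rep(FALSE, 33)),
    causal = c(rep(TRUE, 181), rep(FALSE, 69)))
  s <- causalFractionSummary(assoc, universeSize = 4378)
  expect_identical(s$n_significant, 217L)
  expect_identical(s$n_causal, 181L)
  expect_equal(s$pct_causal_of_significant, 83.4)
  expect_equal(s$pct_causal_of_universe, 4.1)
  z <- causalFractionSummary(assoc[assoc$significant == FALSE, ], 100)
  expect_true(z$degenerate)
  expect_equal(z$frac_causal_of_significant, 0)
  expect_error(causalFractionSummary(assoc, 0), "positive")
})

test_that("Fisher enrichment builds 2x2 tables with sample odds ratios", {
  causal <- matrix(c(rep(TRUE, 10), rep(FALSE, 10)), ncol = 1,
                   dimnames = list(NULL, "enhancer"))
  other <- matrix(c(rep(TRUE, 10), rep(FALSE, 10)), ncol = 1,
                  dimnames = list(NULL, "enhancer"))
  r <- fisherEnrichment(causal, other)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)

  c2 <- matrix(c(rep(TRUE, 8), rep(FALSE, 2)), ncol = 1,
               dimnames = list(NULL, "f"))
  o2 <- matrix(c(rep(TRUE, 2), rep(FALSE, 8)), ncol = 1,
               dimnames = list(NULL, "f"))
  r2 <- fisherEnrichment(c2, o2)
  expect_equal(r2$odds_ratio, 16)
  # hypergeometric enumeration oracle for the two-sided p
  pObs <- dhyper(8, 10, 10, 10)
  pOracle <- sum(dhyper(0:10, 10, 10, 10)[
    dhyper(0:10, 10, 10, 10) <= pObs * (1 + 1e-7)])
  expect_equal(r2$p_value, pOracle, tolerance = 1e-10)

  c3 <- matrix(rep(TRUE, 5), ncol = 1, dimnames = list(NULL, "f"))
  o3 <- matrix(c(rep(TRUE, 5), rep(FALSE, 5)), ncol = 1,
               dimnames = list(NULL, "f"))
  r3 <- fisherEnrichment(c3, o3)
  expect_true(is.infinite(r3$odds_ratio))
  expect_true(r3$zero_cell)
  expect_error(fisherEnrichment(c3[0, , drop = FALSE], o3), "non-empty")
})

test_that("interval score averaging matches per-base summation", {
  iv <- gr1("chr1", 101L, 200L)
  sc <- gr1("chr1", 1L, 1000L); mcols(sc)$score <- 0.7
  expect_equal(meanIntervalScore(iv, sc)$mean_score, 0.7)

  half <- gr1("chr1", c(101L, 151L), c(150L, 200L))
  mcols(half)$score <- c(1, 0)
  expect_equal(meanIntervalScore(iv, half)$mean_score, 0.5)

  none <- gr1("chr1", 500L, 600L); mcols(none)$score <- 1
  r <- meanIntervalScore(iv, none)
  expect_true(is.na(r$mean_score))
  expect_equal(r$coverage_fraction, 0)

  set.seed(606)
  for (rep in 1:20) {
    rs <- sort(sample(seq(1L, 900L, by = 60L), 6))
    re <- rs + sample(10:40, 6, replace = TRUE)
    tr <- gr1("chr1", rs, re)
    mcols(tr)$score <- runif(6)
    s <- sample(1:800, 1); e <- s + sample(50:150, 1)
    got <- meanIntervalScore(gr1("chr1", s, e), tr)
    want <- meanScoreOracle(s, e, rs, re, mcols(tr)$score)
    expect_equal(got$mean_score, want$mean)
    expect_equal(got$coverage_fraction, want$frac)
  }
})

test_that("rank-sum wrapper reproduces the standard two-sided test", {
  set.seed(70)
  x <- rnorm(10, 1); y <- rnorm(8)
  r <- rankSumCompare(x, y)
  ref <- wilcox.test(x, y)
  expect_equal(r$p_value, ref$p.value)
  expect_equal(r$statistic, unname(ref$statistic))
})

test_that("the scan flags planted effects and the lead-variant stand-in marks them", {
  set.seed(808)
  nS <- 82L
  samples <- sprintf("S%02d", seq_len(nS))
  geno <- matrix(sample(0:2, 10 * nS, replace = TRUE,
                        prob = c(0.36, 0.48, 0.16)),
                 nrow = 10, dimnames = list(sprintf("v%02d", 1:10),
                                            samples))
  v <- gr1("chr1", seq(1e6, by = 1e5, length.out = 10), width = 100L)
  mcols(v)$locus_id <- rownames(geno)
  tss <- data.frame(gene_id = "g1", chrom = "chr1", tss = 1.5e6)
  expr <- matrix(rnorm(nS), nrow = 1,
                 dimnames = list("g1", samples))
  expr["g1", ] <- expr["g1", ] + 1.5 * geno["v03", ]
  scan <- eqtlScan(geno, expr, v, tss)
  expect_identical(nrow(scan), 10L)
  hit <- scan[scan$variant_id == "v03", ]
  expect_true(hit$significant)
  flagged <- flagLeadVariants(scan)
  expect_true(flagged$causal[flagged$variant_id == "v03"])
})
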