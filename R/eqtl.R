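#' @include popgen.R
NULL

#' Enumerate cis gene-variant pairs
#'
#' A variant is paired with a gene when both lie on the same chromosome
#' and the variant start is within `window` bases of the gene's
#' transcription start site (boundary inclusive at exactly `window`).
#'
#' @param variants `GRanges` of variants (names or mcol `locus_id` used as
#'   variant ids)
#' @param tss `data.frame` with columns `gene_id`, `chrom`, `tss`
#'   (1-based TSS position)
#' @param window cis-window half-width in bases (1 Mb)
#' @return `data.frame` with columns `gene_id`, `variant_id`, `distance`
#' @export
cisPairs <- function(variants, tss, window = 1e6) {
  vid <- mcols(variants)$locus_id %||% names(variants)
  if (is.null(vid)) vid <- as.character(seq_along(variants))
  keep <- !is.na(tss$tss) & !is.na(tss$chrom)
  skipped <- tss$gene_id[!keep]
  if (length(skipped)) {
    message("cisPairs: skipping ", length(skipped),
            " gene(s) without TSS")
  }
  tss <- tss[keep, , drop = FALSE]
  tssGr <- GRanges(tss$chrom, IRanges(tss$tss, width = 1L))
  hits <- findOverlaps(GRanges(seqnames(variants),
                               IRanges(start(variants), width = 1L)),
                       tssGr, maxgap = window, ignore.strand = TRUE)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  dist <- abs(start(variants)[qh] - tss$tss[sh])
  ok <- dist <= window
  data.frame(gene_id = tss$gene_id[sh][ok], variant_id = vid[qh][ok],
             distance = dist[ok], stringsAsFactors = FALSE)
}

#' Additive linear eQTL model for one gene-variant pair
#'
#' Ordinary least squares of expression on genotype dosage (0/1/2) with an
#' intercept; two-sided t-test on the slope with n - 2 degrees of freedom.
#' Pairs with missing genotype or expression are dropped; a genotype that
#' is constant after dropping is skipped with reason `"monomorphic"`.
#'
#' @param expression numeric vector of expression values
#' @param genotype numeric vector of genotype dosages (0/1/2, NA allowed)
#' @return one-row `data.frame` with `beta`, `t_stat`, `p_value`, `n`,
#'   `status` (`"ok"` or a skip reason)
#' @export
linearEqtl <- function(expression, genotype) {
  stopifnot(length(expression) == length(genotype))
  ok <- !is.na(expression) & !is.na(genotype)
  y <- expression[ok]; g <- genotype[ok]
  skip <- function(reason) {
    data.frame(beta = NA_real_, t_stat = NA_real_, p_value = NA_real_,
               n = length(y), status = reason, stringsAsFactors = FALSE)
  }
  if (length(y) < 3L) return(skip("too_few_samples"))
  if (length(unique(g)) < 2L) return(skip("monomorphic"))
  n <- length(y)
  gc <- g - mean(g); yc <- y - mean(y)
  sxx <- sum(gc^2)
  beta <- sum(gc * yc) / sxx
  resid <- yc - beta * gc
  df <- n - 2L
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 / sxx)
  tStat <- beta / se
  p <- 2 * stats::pt(abs(tStat), df = df, lower.tail = FALSE)
  data.frame(beta = beta, t_stat = tStat, p_value = max(p, .Machine$double.xmin),
             n = n, status = "ok", stringsAsFactors = FALSE)
}

#' Benjamini--Hochberg q-values within one cis-window
#'
#' Step-up FDR adjustment over the p-values of all variants tested against
#' one gene.
#'
#' @param pvalues numeric vector in (0, 1]
#' @return q-values, same order as input
#' @export
bhWithinWindow <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Cis-eQTL scan over a genotype panel and expression matrix
#'
#' For every cis pair (same chromosome, variant within `window` of the
#' TSS) an additive OLS model is fit; q-values are computed per gene
#' (per cis-window) with Benjamini--Hochberg, and associations with
#' q <= `fdrAlpha` are flagged significant.
#'
#' @param geno genotype dosage matrix (variants x samples, codes 0/1/2/NA)
#' @param expr expression matrix (genes x samples)
#' @param variants `GRanges` of variant positions with mcol `locus_id`
#'   matching `rownames(geno)`
#' @param tss TSS table as in [cisPairs()]
#' @param window cis-window half-width (1 Mb)
#' @param fdrAlpha per-window FDR level (0.01)
#' @return `data.frame`: `gene_id`, `variant_id`, `beta`, `t_stat`,
#'   `p_value`, `q_value`, `significant`, `status`
#' @export
eqtlScan <- function(geno, expr, variants, tss, window = 1e6,
                     fdrAlpha = 0.01) {
  common <- intersect(colnames(geno), colnames(expr))
  if (length(common) < 3L) stop("fewer than 3 shared samples")
  geno <- geno[, common, drop = FALSE]
  expr <- expr[, common, drop = FALSE]
  pairs <- cisPairs(variants, tss, window = window)
  pairs <- pairs[pairs$gene_id %in% rownames(expr) &
                   pairs$variant_id %in% rownames(geno), , drop = FALSE]
  if (nrow(pairs) == 0L) {
    return(data.frame(gene_id = character(), variant_id = character(),
                      beta = numeric(), t_stat = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      significant = logical(), status = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    linearEqtl(expr[pairs$gene_id[i], ], geno[pairs$variant_id[i], ])
  }))
  out <- cbind(pairs[, c("gene_id", "variant_id")], res)
  out$q_value <- NA_real_
  for (g in unique(out$gene_id)) {
    idx <- which(out$gene_id == g & out$status == "ok")
    if (length(idx)) out$q_value[idx] <- bhWithinWindow(out$p_value[idx])
  }
  out$significant <- !is.na(out$q_value) & out$q_value <= fdrAlpha
  rownames(out) <- NULL
  out
}

#' Genomic inflation factor
#'
#' lambda = median of the association chi-square statistics (one degree of
#' freedom, obtained by inverting the p-values) divided by the null
#' chi-square median (0.4549364...). Values near 1 indicate calibrated
#' tests.
#'
#' @param pvalues numeric vector in (0, 1]
#' @return lambda
#' @export
genomicInflation <- function(pvalues) {
  if (length(pvalues) == 0L) stop("no p-values")
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  chi <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Summaries of causal deletion fractions
#'
#' Counts unique significantly associated variants and, among them, those
#' flagged causal; reports causal/significant and causal/universe both as
#' fractions and as percentages rounded half-up to one decimal.
#'
#' @param associations `data.frame` with columns `variant_id`,
#'   `significant` (logical) and `causal` (logical)
#' @param universeSize total number of deletion candidates tested
#' @return list with `n_significant`, `n_causal`,
#'   `frac_causal_of_significant`, `frac_causal_of_universe`,
#'   `pct_causal_of_significant`, `pct_causal_of_universe`, `degenerate`
#' @export
causalFractionSummary <- function(associations, universeSize) {
  if (universeSize <= 0) stop("universeSize must be positive")
  sig <- unique(associations$variant_id[associations$significant])
  causal <- unique(
    associations$variant_id[associations$significant &
                              associations$causal])
  nSig <- length(sig); nCausal <- length(causal)
  degenerate <- nSig == 0L
  fracSig <- if (degenerate) 0 else nCausal / nSig
  fracUni <- nCausal / universeSize
  list(n_significant = nSig, n_causal = nCausal,
       frac_causal_of_significant = fracSig,
       frac_causal_of_universe = fracUni,
       pct_causal_of_significant = roundHalfUp(100 * fracSig, 1L),
       pct_causal_of_universe = roundHalfUp(100 * fracUni, 1L),
       degenerate = degenerate)
}

#' Lead-variant stand-in for external fine-mapping
#'
#' Multivariate fine-mapping (credible-set selection given local LD) is an
#' external step; when no externally supplied causal flag is available
#' this heuristic flags, within each gene's cis-window, the variant
#' attaining the minimum p-value together with any variant within one
#' log10 of it. It is *not* equivalent to fine-mapping and is labeled as a
#' stand-in.
#'
#' @param associations output of [eqtlScan()]
#' @param log10Tol flag variants within this many log10 units of the
#'   window minimum
#' @return `associations` with a logical `causal` column added
#' @export
flagLeadVariants <- function(associations, log10Tol = 1) {
  causal <- rep(FALSE, nrow(associations))
  for (g in unique(associations$gene_id)) {
    idx <- which(associations$gene_id == g & associations$status == "ok")
    if (!length(idx)) next
    pmin <- min(associations$p_value[idx])
    causal[idx] <- log10(associations$p_value[idx]) - log10(pmin) <=
      log10Tol
  }
  associations$causal <- causal & associations$significant
  associations
}

#' Fisher enrichment of features in causal vs other deletions
#'
#' For each feature, builds the 2x2 table (causal-with, causal-without,
#' other-with, other-without), computes the sample odds ratio
#' a*d / (b*c) and the two-sided Fisher exact p-value. A zero cell yields
#' an infinite or zero odds ratio, flagged rather than corrected.
#'
#' @param causalFlags logical matrix, causal deletions x features
#' @param otherFlags logical matrix, other deletions x features (same
#'   columns)
#' @return `data.frame`: `feature`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p_value`, `zero_cell`
#' @export
fisherEnrichment <- function(causalFlags, otherFlags) {
  if (nrow(causalFlags) == 0L || nrow(otherFlags) == 0L) {
    stop("both groups must be non-empty")
  }
  stopifnot(identical(colnames(causalFlags), colnames(otherFlags)))
  do.call(rbind, lapply(colnames(causalFlags), function(f) {
    a <- sum(causalFlags[, f]); b <- sum(!causalFlags[, f])
    cc <- sum(otherFlags[, f]); d <- sum(!otherFlags[, f])
    orv <- (a * d) / (b * cc)
    p <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2L))$p.value
    data.frame(feature = f, a = a, b = b, c = cc, d = d,
               odds_ratio = orv, p_value = p,
               zero_cell = any(c(a, b, cc, d) == 0L),
               stringsAsFactors = FALSE)
  }))
}

#' Mean per-base score over an interval
#'
#' Arithmetic mean of a per-base score track (disjoint scored runs, e.g.
#' conservation scores) over the bases of `interval` the track covers;
#' also reports the covered fraction.
#'
#' @param interval length-1 `GRanges`
#' @param scores `GRanges` with numeric mcol `score` (disjoint runs)
#' @return list with `mean_score` (NA when nothing is covered) and
#'   `coverage_fraction`
#' @export
meanIntervalScore <- function(interval, scores) {
  stopifnot(length(interval) == 1L)
  if (length(scores) && !isDisjoint(scores)) {
    stop("score track runs must be disjoint")
  }
  hits <- findOverlaps(interval, scores, ignore.strand = TRUE)
  sh <- subjectHits(hits)
  if (!length(sh)) {
    return(list(mean_score = NA_real_, coverage_fraction = 0))
  }
  ov <- pintersect(rep(interval, length(sh)), scores[sh])
  w <- width(ov)
  list(mean_score = sum(w * mcols(scores)$score[sh]) / sum(w),
       coverage_fraction = sum(w) / width(interval))
}

#' Two-sided rank-sum comparison
#'
#' Thin wrapper around the Wilcoxon rank-sum test (two-sided,
#' tie-corrected normal approximation when ties are present) for group
#' comparisons such as conservation scores or carrier frequencies between
#' causal and non-causal deletions.
#'
#' @param x,y numeric vectors
#' @return list with `statistic` (W) and `p_value`
#' @export
rankSumCompare <- function(x, y) {
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = NULL, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}
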