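#' @include filters.R
NULL

.afFromGt <- function(gt) {
  # gt: integer vector of 0/1/2/NA codes
  called <- sum(!is.na(gt))
  if (called == 0L) return(c(af = NA_real_, carrier = NA_real_))
  nHet <- sum(gt == 1L, na.rm = TRUE)
  nHom <- sum(gt == 2L, na.rm = TRUE)
  c(af = (nHet + 2 * nHom) / (2 * called),
    carrier = (nHet + nHom) / called)
}

.newGenotypePanel <- function(gr, locus_id, gt) {
  stats <- t(apply(gt, 1L, .afFromGt))
  hwe <- apply(gt, 1L, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hweExactTest(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  })
  if (nrow(gt) == 0L) {
    stats <- matrix(numeric(), 0L, 2L,
                    dimnames = list(NULL, c("af", "carrier")))
    hwe <- numeric()
  }
  rd <- S4Vectors::DataFrame(locus_id = locus_id,
                             af = as.numeric(stats[, "af"]),
                             carrier_freq = as.numeric(stats[, "carrier"]),
                             hwe_p = as.numeric(hwe))
  mcols(gr) <- rd
  se <- SummarizedExperiment(
    assays = S4Vectors::SimpleList(GT = gt), rowRanges = gr,
    colData = S4Vectors::DataFrame(row.names = colnames(gt)))
  new("GenotypePanel", se)
}

#' Assemble the site-by-sample genotype matrix
#'
#' For each kept locus, a sample with a kept member call contributes that
#' call's genotype (`het` = 1, `hom` = 2, `missing` = `NA`); a sample with
#' no call at the locus is coded 0 (ref/ref) -- the absence of a deletion
#' call in an adequately covered genome is taken as evidence of the
#' reference allele -- unless the sample is listed in `lowCoverage`, in
#' which case it is coded missing. Per-site allele frequency, carrier
#' frequency and exact HWE p-values are computed on the way in.
#'
#' @param merged a [MergedDeletionSet] of kept loci (recovery applied)
#' @param samples ordered character vector of cohort sample ids
#' @param lowCoverage sample ids whose absent calls become missing, not 0
#' @return a [GenotypePanel]
#' @export
buildGenotypeMatrix <- function(merged, samples,
                                lowCoverage = character()) {
  lo <- loci(merged)
  mc <- keptCalls(merged)
  gt <- matrix(0L, nrow = length(lo), ncol = length(samples),
               dimnames = list(mcols(lo)$locus_id, samples))
  if (length(lowCoverage)) gt[, samples %in% lowCoverage] <- NA_integer_
  if (length(mc)) {
    li <- match(mcols(mc)$locus_id, mcols(lo)$locus_id)
    si <- match(mcols(mc)$sample_id, samples)
    if (any(is.na(si))) stop("member call from a sample not in 'samples'")
    if (anyDuplicated(cbind(li, si))) {
      stop("duplicate sample call at one locus")
    }
    code <- c(het = 1L, hom = 2L, missing = NA_integer_)
    gt[cbind(li, si)] <- code[mcols(mc)$genotype]
  }
  .newGenotypePanel(granges(lo), mcols(lo)$locus_id, gt)
}

#' Exact test of Hardy--Weinberg equilibrium
#'
#' The exact conditional test: given the observed allele counts, every
#' possible heterozygote count is enumerated, and the p-value is the sum
#' of the probabilities of all genotype configurations whose conditional
#' probability does not exceed that of the observed one (two-sided,
#' sum-of-less-probable-tables). Probabilities follow the standard
#' hypergeometric-style distribution of heterozygote counts conditional on
#' allele counts. A relative tolerance of 1e-10 guards the "not exceed"
#' comparison against floating-point ties between symmetric
#' configurations.
#'
#' A monomorphic site has a single attainable configuration and p = 1.
#' `method = "allele_fisher"` instead runs a literal two-sided Fisher test
#' on the 2x2 allele-count table (alleles in cases vs a balanced
#' expectation is ill-defined for one sample set; this mode tests
#' ref/alt allele counts split by genotype class membership and is kept
#' only for fidelity comparisons).
#'
#' @param nHomRef,nHet,nHomAlt genotype counts (vectors are recycled to a
#'   common length and tested element-wise)
#' @param method `"exact_hwe"` (default) or `"allele_fisher"`
#' @return p-value vector in (0, 1]
#' @examples
#' hweExactTest(10, 10, 10)
#' hweExactTest(0, 30, 0) < 1e-4   # extreme heterozygote excess
#' @export
hweExactTest <- function(nHomRef, nHet, nHomAlt,
                         method = c("exact_hwe", "allele_fisher")) {
  method <- match.arg(method)
  n <- max(length(nHomRef), length(nHet), length(nHomAlt))
  nHomRef <- rep_len(as.integer(nHomRef), n)
  nHet <- rep_len(as.integer(nHet), n)
  nHomAlt <- rep_len(as.integer(nHomAlt), n)
  vapply(seq_len(n), function(i) {
    .hweOne(nHomRef[i], nHet[i], nHomAlt[i], method)
  }, numeric(1L))
}

.hweOne <- function(aa, ab, bb, method) {
  if (aa < 0 || ab < 0 || bb < 0) stop("genotype counts must be >= 0")
  n <- aa + ab + bb
  if (n == 0L) stop("all genotype counts are zero")
  if (method == "allele_fisher") {
    # literal 2x2 on allele counts within het vs hom classes
    tab <- matrix(c(2 * aa, ab, ab, 2 * bb), nrow = 2L)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      return(stats::fisher.test(tab)$p.value)
    }
    return(1)
  }
  rare <- min(2L * aa + ab, 2L * bb + ab)
  if (rare == 0L) return(1)
  # heterozygote counts share the parity of the rare-allele count
  hVals <- seq.int(rare %% 2L, rare, by = 2L)
  # unnormalized probabilities via the ratio recurrence:
  # P(h+2)/P(h) = 4 * homRare(h) * homCommon(h) / ((h+1)*(h+2))
  probs <- numeric(length(hVals))
  probs[1L] <- 1
  if (length(hVals) > 1L) {
    for (k in seq_len(length(hVals) - 1L)) {
      h <- hVals[k]
      homRare <- (rare - h) / 2
      homCommon <- n - h - homRare
      probs[k + 1L] <- probs[k] * 4 * homRare * homCommon /
        ((h + 1) * (h + 2))
    }
  }
  probs <- probs / sum(probs)
  pObs <- probs[match(ab, hVals)]
  if (is.na(pObs)) stop("genotype counts inconsistent with allele counts")
  min(1, sum(probs[probs <= pObs * (1 + 1e-10)]))
}

#' Allele and carrier frequency of a panel site
#'
#' AF = (n_het + 2 n_hom) / (2 n_called); carrier frequency =
#' (n_het + n_hom) / n_called.
#'
#' @param panel a [GenotypePanel]
#' @param site locus id or row index (default: all sites)
#' @return `data.frame` with `locus_id`, `af`, `carrier_freq`
#' @export
alleleFrequency <- function(panel, site = NULL) {
  rd <- rowData(panel)
  df <- data.frame(locus_id = rd$locus_id, af = rd$af,
                   carrier_freq = rd$carrier_freq,
                   stringsAsFactors = FALSE)
  if (!is.null(site)) {
    idx <- if (is.character(site)) match(site, df$locus_id) else site
    if (any(is.na(idx))) stop("unknown site")
    df <- df[idx, , drop = FALSE]
  }
  df
}

#' Population filters on a genotype panel
#'
#' Keeps sites with exact HWE p-value strictly greater than `hweAlpha`
#' (default 1e-4) and, when `mafMin` is not `NULL`, minor allele frequency
#' at least `mafMin` (boundary inclusive). Idempotent.
#'
#' @param panel a [GenotypePanel]
#' @param mafMin minimum minor allele frequency, or `NULL` to skip
#' @param hweAlpha HWE significance threshold
#' @return the filtered [GenotypePanel]
#' @export
applyPopulationFilters <- function(panel, mafMin = 0.05,
                                   hweAlpha = 1e-4) {
  rd <- rowData(panel)
  keep <- !is.na(rd$hwe_p) & rd$hwe_p > hweAlpha
  if (!is.null(mafMin)) {
    maf <- pmin(rd$af, 1 - rd$af)
    keep <- keep & !is.na(maf) & maf >= mafMin
  }
  panel[keep, ]
}
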