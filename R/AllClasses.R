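#' @include delrecover-package.R
NULL

.ORIENTATIONS <- c("forward_only", "reverse_only", "both")
.GENOTYPES <- c("het", "hom", "missing")

.CALL_MCOLS <- c("sample_id", "support_orientation", "n_support_reads",
                 "mean_softclip_quality", "depth_del", "depth_flank",
                 "genotype")

#' Per-sample deletion calls
#'
#' A `DeletionCallSet` is a [GenomicRanges::GRanges] holding one per-sample
#' deletion observation per range. Required metadata columns:
#' `sample_id` (character), `support_orientation` (one of `"forward_only"`,
#' `"reverse_only"`, `"both"` -- which read orientations contributed
#' soft-clip evidence), `n_support_reads` (integer), `mean_softclip_quality`
#' (Phred-scaled mean over soft-clipped bases, `NA` allowed), `depth_del`
#' (mean read depth over the deletion span), `depth_flank` (mean depth over
#' the two 100 bp flanks) and `genotype` (`"het"`, `"hom"`, `"missing"`).
#'
#' Ranges use the 1-based closed GRanges convention; the on-disk call-table
#' and BED surfaces are 0-based half-open and are converted on read/write,
#' so `width()` is always the number of deleted bases.
#'
#' @export
setClass("DeletionCallSet", contains = "GRanges")

setValidity("DeletionCallSet", function(object) {
  m <- mcols(object)
  missing <- setdiff(.CALL_MCOLS, colnames(m))
  if (length(missing)) {
    return(sprintf("missing metadata column(s): %s",
                   paste(missing, collapse = ", ")))
  }
  if (length(object)) {
    if (!all(m$support_orientation %in% .ORIENTATIONS)) {
      return("support_orientation must be forward_only/reverse_only/both")
    }
    if (!all(m$genotype %in% .GENOTYPES)) {
      return("genotype must be het/hom/missing")
    }
    if (any(is.na(m$n_support_reads)) || any(m$n_support_reads < 0)) {
      return("n_support_reads must be a non-negative count")
    }
    q <- m$mean_softclip_quality
    if (any(!is.na(q) & q < 0)) {
      return("mean_softclip_quality must be >= 0 when present")
    }
    if (any(width(object) > 10000L)) {
      return("deletion calls longer than 10,000 bp are not supported")
    }
  }
  TRUE
})

#' Construct a DeletionCallSet
#'
#' @param gr a `GRanges` carrying the metadata columns documented in
#'   [DeletionCallSet-class], or a `data.frame` with columns `chrom`,
#'   `start`, `end` (0-based half-open) plus those metadata columns.
#' @param sample_id optional sample id recycled over all rows when the
#'   input lacks a `sample_id` column.
#' @return a `DeletionCallSet`
#' @examples
#' df <- data.frame(chrom = "chr9", start = 130330770, end = 130330813,
#'                  support_orientation = "both", n_support_reads = 8,
#'                  mean_softclip_quality = 32, depth_del = 18,
#'                  depth_flank = 30, genotype = "het")
#' DeletionCallSet(df, sample_id = "S1")
#' @export
DeletionCallSet <- function(gr, sample_id = NULL) {
  if (is.data.frame(gr)) {
    df <- gr
    gr <- GRanges(df$chrom, IRanges(start = df$start + 1L, end = df$end))
    keep <- intersect(.CALL_MCOLS, colnames(df))
    mcols(gr) <- df[, keep, drop = FALSE]
  }
  m <- mcols(gr)
  if (!is.null(sample_id)) {
    m$sample_id <- rep(as.character(sample_id), length.out = length(gr))
  }
  if (is.null(m$sample_id)) stop("sample_id is required")
  if (is.null(m$mean_softclip_quality)) m$mean_softclip_quality <- NA_real_
  m$sample_id <- as.character(m$sample_id)
  m$support_orientation <- as.character(m$support_orientation)
  m$genotype <- as.character(m$genotype)
  m$n_support_reads <- as.integer(m$n_support_reads)
  mcols(gr) <- m[, c(.CALL_MCOLS,
                     setdiff(colnames(m), .CALL_MCOLS)), drop = FALSE]
  new("DeletionCallSet", gr)
}

#' Cohort-level merged deletion loci
#'
#' A `MergedDeletionSet` pairs consensus deletion loci with their member
#' calls. `loci` is a `GRanges` (one consensus interval per locus) with
#' metadata columns `locus_id`, `n_members`, `n_both` (members supported by
#' both read orientations) and `n_single`; after [jointCallRecover()] it
#' gains `n_recovered` and `n_dropped`. `memberCalls` is the clustered
#' [DeletionCallSet] with a `locus_id` column and a `call_status` column
#' (`"both"`, `"single"`, and after recovery `"recovered"` or `"dropped"`).
#'
#' @slot loci consensus loci (`GRanges`)
#' @slot memberCalls member calls (`DeletionCallSet`)
#' @slot recovered has joint-call recovery been applied?
#' @export
setClass("MergedDeletionSet",
         representation(loci = "GRanges",
                        memberCalls = "DeletionCallSet",
                        recovered = "logical"))

setValidity("MergedDeletionSet", function(object) {
  lo <- object@loci
  mc <- object@memberCalls
  need <- c("locus_id", "n_members", "n_both", "n_single")
  if (!all(need %in% colnames(mcols(lo)))) {
    return("loci must carry locus_id, n_members, n_both, n_single")
  }
  if (!all(c("locus_id", "call_status") %in% colnames(mcols(mc)))) {
    return("memberCalls must carry locus_id and call_status")
  }
  if (!all(mcols(mc)$locus_id %in% mcols(lo)$locus_id)) {
    return("memberCalls reference unknown loci")
  }
  if (anyDuplicated(mcols(lo)$locus_id)) return("duplicate locus_id")
  tab <- table(factor(mcols(mc)$locus_id, levels = mcols(lo)$locus_id))
  if (!all(as.integer(tab) == mcols(lo)$n_members)) {
    return("n_members inconsistent with memberCalls")
  }
  both <- mcols(mc)$support_orientation == "both"
  nb <- tapply(both, factor(mcols(mc)$locus_id, levels = mcols(lo)$locus_id),
               sum)
  nb[is.na(nb)] <- 0L
  if (!all(as.integer(nb) == mcols(lo)$n_both)) {
    return("n_both inconsistent with member support orientations")
  }
  TRUE
})

#' Site-by-sample deletion genotype panel
#'
#' Extends `RangedSummarizedExperiment`: one row per deletion locus, one
#' column per sample, a single `"GT"` assay of genotype codes
#' (0 = ref/ref, 1 = het, 2 = hom-alt, `NA` = missing), and row metadata
#' `locus_id`, `af` (alt allele frequency), `carrier_freq` and `hwe_p`
#' (exact Hardy--Weinberg p-value).
#'
#' @export
setClass("GenotypePanel",
         contains = "RangedSummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  if (!"GT" %in% names(assays(object))) return("assay 'GT' is required")
  gt <- assay(object, "GT")
  if (length(gt) && !all(gt %in% c(0L, 1L, 2L, NA))) {
    return("GT codes must be 0/1/2/NA")
  }
  need <- c("locus_id", "af", "carrier_freq", "hwe_p")
  if (!all(need %in% colnames(rowData(object)))) {
    return("rowData must carry locus_id, af, carrier_freq, hwe_p")
  }
  af <- rowData(object)$af
  if (any(!is.na(af) & (af < 0 | af > 1))) return("af outside [0,1]")
  TRUE
})

#' Concordance of a query deletion set against a truth set
#'
#' Produced by [matchCallsets()]. Holds the totals, the matched pairs and
#' the matching parameters used.
#'
#' @slot nTotal number of query deletions entering the denominator
#' @slot nMatched number matched one-to-one to a truth event
#' @slot rate `nMatched / nTotal`
#' @slot matches `data.frame` of matched (query, truth) index pairs with
#'   their reciprocal overlap
#' @slot params matching parameters (`min_ro`, `bp_tol`, `min_query_len`)
#' @export
setClass("ConcordanceReport",
         representation(nTotal = "integer", nMatched = "integer",
                        rate = "numeric", matches = "data.frame",
                        params = "list"))

setValidity("ConcordanceReport", function(object) {
  if (object@nMatched > object@nTotal) return("nMatched > nTotal")
  if (object@rate < 0 || object@rate > 1) return("rate outside [0,1]")
  TRUE
})
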