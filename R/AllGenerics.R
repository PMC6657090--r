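#' @include AllClasses.R
NULL

#' @rdname MergedDeletionSet-class
#' @param x a `MergedDeletionSet`
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname MergedDeletionSet-class
#' @export
setGeneric("memberCalls", function(x) standardGeneric("memberCalls"))

#' @rdname GenotypePanel-class
#' @param x object
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("carrierFreq", function(x) standardGeneric("carrierFreq"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("hweP", function(x) standardGeneric("hweP"))

#' @rdname ConcordanceReport-class
#' @param x a `ConcordanceReport`
#' @export
setGeneric("concordanceRate", function(x) standardGeneric("concordanceRate"))

#' @rdname MergedDeletionSet-class
setMethod("loci", "MergedDeletionSet", function(x) x@loci)

#' @rdname MergedDeletionSet-class
setMethod("memberCalls", "MergedDeletionSet", function(x) x@memberCalls)

#' @rdname MergedDeletionSet-class
#' @aliases length,MergedDeletionSet-method
setMethod("length", "MergedDeletionSet", function(x) length(x@loci))

#' Subset a MergedDeletionSet by locus
#'
#' @param x a `MergedDeletionSet`
#' @param i logical or integer index over loci
#' @param j,...,drop ignored
#' @rdname MergedDeletionSet-class
setMethod("[", "MergedDeletionSet", function(x, i, j, ..., drop = FALSE) {
  lo <- x@loci[i]
  keep <- mcols(x@memberCalls)$locus_id %in% mcols(lo)$locus_id
  initialize(x, loci = lo,
             memberCalls = x@memberCalls[keep],
             recovered = x@recovered)
})

setMethod("show", "MergedDeletionSet", function(object) {
  lo <- object@loci
  cat(sprintf(
    "MergedDeletionSet: %d loci, %d member calls (%d both-orientation)%s\n",
    length(lo), length(object@memberCalls), sum(mcols(lo)$n_both),
    if (object@recovered) ", recovery applied" else ""))
  if (length(lo)) show(head(lo, 5L))
})

#' @rdname GenotypePanel-class
setMethod("genotypes", "GenotypePanel", function(x) assay(x, "GT"))

#' @rdname GenotypePanel-class
setMethod("alleleFreq", "GenotypePanel", function(x) {
  setNames(rowData(x)$af, rowData(x)$locus_id)
})

#' @rdname GenotypePanel-class
setMethod("carrierFreq", "GenotypePanel", function(x) {
  setNames(rowData(x)$carrier_freq, rowData(x)$locus_id)
})

#' @rdname GenotypePanel-class
setMethod("hweP", "GenotypePanel", function(x) {
  setNames(rowData(x)$hwe_p, rowData(x)$locus_id)
})

#' @rdname ConcordanceReport-class
setMethod("concordanceRate", "ConcordanceReport", function(x) x@rate)

setMethod("show", "ConcordanceReport", function(object) {
  cat(sprintf("ConcordanceReport: %d/%d matched (rate %.4f; min_ro %.2f, bp_tol %d)\n",
              object@nMatched, object@nTotal, object@rate,
              object@params$min_ro, object@params$bp_tol))
})
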