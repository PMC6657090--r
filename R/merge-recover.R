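#' @include core-model.R
NULL

#' Merge and recovery parameters
#'
#' Two calls from different samples are treated as the same deletion when
#' they lie on the same chromosome, both breakpoints differ by at most
#' `bpTolerance` bases, and their reciprocal overlap is at least
#' `minReciprocalOverlap`. Soft-clip breakpoints are near-exact, so the
#' default tolerance is tight (10 bp) with an overlap guard against
#' size-discordant chaining. `minBothSamples` is the number of *other*
#' samples that must carry a both-orientation call at a locus for a
#' single-orientation call to be recovered (two or more).
#'
#' @param bpTolerance maximum breakpoint delta in bases
#' @param minReciprocalOverlap minimum reciprocal overlap fraction
#' @param minBothSamples both-orientation samples required for recovery
#' @return a `MergeParams` list
#' @export
mergeParams <- function(bpTolerance = 10L, minReciprocalOverlap = 0.8,
                        minBothSamples = 2L) {
  stopifnot(bpTolerance >= 0,
            minReciprocalOverlap > 0, minReciprocalOverlap <= 1,
            minBothSamples >= 1)
  structure(list(bpTolerance = as.integer(bpTolerance),
                 minReciprocalOverlap = minReciprocalOverlap,
                 minBothSamples = as.integer(minBothSamples)),
            class = "MergeParams")
}

.canonicalCallOrder <- function(calls) {
  order(as.character(seqnames(calls)), start(calls), end(calls),
        mcols(calls)$sample_id)
}

#' Cluster per-sample deletion calls into cohort loci
#'
#' Single-linkage clustering: two calls link when they are on the same
#' chromosome, both breakpoint deltas are within `params$bpTolerance`, and
#' reciprocal overlap is at least `params$minReciprocalOverlap`. Calls are
#' canonically sorted first, so the result is independent of input order.
#' Each cluster becomes one locus with consensus breakpoints from
#' [consensusBreakpoints()].
#'
#' @param calls a [DeletionCallSet] spanning samples and chromosomes
#' @param params a [mergeParams()] object
#' @return a [MergedDeletionSet]
#' @export
clusterCalls <- function(calls, params = mergeParams()) {
  if (length(calls) == 0L) {
    lo <- GRanges()
    mcols(lo) <- S4Vectors::DataFrame(locus_id = character(),
                                      n_members = integer(),
                                      n_both = integer(),
                                      n_single = integer())
    mc <- calls
    mcols(mc)$locus_id <- character(0)
    mcols(mc)$call_status <- character(0)
    return(new("MergedDeletionSet", loci = lo, memberCalls = mc,
               recovered = FALSE))
  }
  calls <- calls[.canonicalCallOrder(calls)]
  hits <- findOverlaps(calls, calls, ignore.strand = TRUE)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  keep <- qh < sh
  qh <- qh[keep]; sh <- sh[keep]
  if (length(qh)) {
    dStart <- abs(start(calls)[qh] - start(calls)[sh])
    dEnd <- abs(end(calls)[qh] - end(calls)[sh])
    ro <- reciprocalOverlap(calls[qh], calls[sh])
    ok <- dStart <= params$bpTolerance & dEnd <= params$bpTolerance &
      ro >= params$minReciprocalOverlap
    qh <- qh[ok]; sh <- sh[ok]
  }
  n <- length(calls)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(qh), to = as.character(sh)),
    directed = FALSE, vertices = data.frame(name = as.character(seq_len(n))))
  comp <- igraph::components(g)$membership[as.character(seq_len(n))]

  consensus <- lapply(split(seq_len(n), comp), function(idx) {
    consensusBreakpoints(calls[idx])
  })
  cons <- do.call(c, unname(consensus))
  ord <- order(as.character(seqnames(cons)), start(cons), end(cons))
  clusterIdx <- split(seq_len(n), comp)[ord]
  cons <- cons[ord]
  locusIds <- sprintf("L%06d", seq_along(cons))

  nBoth <- unname(vapply(clusterIdx, function(idx) {
    sum(mcols(calls)$support_orientation[idx] == "both")
  }, 1L))
  nMembers <- lengths(clusterIdx)
  mcols(cons) <- S4Vectors::DataFrame(
    locus_id = locusIds, n_members = as.integer(nMembers),
    n_both = nBoth, n_single = as.integer(nMembers) - nBoth)

  memberOrder <- unlist(clusterIdx, use.names = FALSE)
  mc <- calls[memberOrder]
  mcols(mc)$locus_id <- rep(locusIds, nMembers)
  mcols(mc)$call_status <- ifelse(
    mcols(mc)$support_orientation == "both", "both", "single")
  new("MergedDeletionSet", loci = cons, memberCalls = mc,
      recovered = FALSE)
}

#' Consensus breakpoints of a cluster of calls
#'
#' The modal (start, end) pair over members. Ties are broken by preferring
#' pairs observed in both-orientation members, then the smallest start,
#' then the smallest end.
#'
#' @param cluster a non-empty [DeletionCallSet] on a single chromosome
#' @return a length-1 `GRanges`
#' @export
consensusBreakpoints <- function(cluster) {
  if (length(cluster) == 0L) stop("empty cluster")
  chrom <- unique(as.character(seqnames(cluster)))
  if (length(chrom) != 1L) stop("cluster spans chromosomes")
  key <- paste(start(cluster), end(cluster))
  cnt <- table(key)
  isBoth <- mcols(cluster)$support_orientation == "both"
  bothCnt <- table(key[isBoth])
  cand <- data.frame(key = names(cnt), n = as.integer(cnt),
                     stringsAsFactors = FALSE)
  cand$fromBoth <- cand$key %in% names(bothCnt)[as.integer(bothCnt) > 0]
  parts <- strsplit(cand$key, " ")
  cand$start <- as.integer(vapply(parts, `[[`, "", 1L))
  cand$end <- as.integer(vapply(parts, `[[`, "", 2L))
  cand <- cand[order(-cand$n, -cand$fromBoth, cand$start, cand$end), ]
  GRanges(factor(chrom, levels = GenomeInfoDb::seqlevels(cluster)),
          IRanges(cand$start[1L], cand$end[1L]))
}

#' Joint-call recovery of single-orientation calls
#'
#' A deletion call supported by only forward- or only reverse-oriented
#' soft-clipped reads is lower-confidence, but when two or more *other*
#' samples carry the same deletion supported by both orientations, the
#' single-orientation call is retained ("recovered") rather than dropped.
#' Both-orientation members are never altered, and no locus gains members.
#'
#' Member `call_status` becomes `"both"`, `"recovered"` or `"dropped"`;
#' loci gain `n_recovered` and `n_dropped` counts.
#'
#' @param merged a [MergedDeletionSet] from [clusterCalls()]
#' @param params a [mergeParams()] object (`minBothSamples` is used)
#' @return the updated [MergedDeletionSet]
#' @export
jointCallRecover <- function(merged, params = mergeParams()) {
  mc <- merged@memberCalls
  lo <- merged@loci
  status <- mcols(mc)$call_status
  locus <- mcols(mc)$locus_id
  orient <- mcols(mc)$support_orientation
  sample <- mcols(mc)$sample_id

  bothSamples <- split(sample[orient == "both"], locus[orient == "both"])
  singleIdx <- which(orient != "both")
  for (i in singleIdx) {
    others <- unique(setdiff(bothSamples[[locus[i]]] %||% character(),
                             sample[i]))
    status[i] <- if (length(others) >= params$minBothSamples)
      "recovered" else "dropped"
  }
  mcols(mc)$call_status <- status
  nRec <- tapply(status == "recovered",
                 factor(locus, levels = mcols(lo)$locus_id), sum)
  nDrop <- tapply(status == "dropped",
                  factor(locus, levels = mcols(lo)$locus_id), sum)
  mcols(lo)$n_recovered <- as.integer(ifelse(is.na(nRec), 0L, nRec))
  mcols(lo)$n_dropped <- as.integer(ifelse(is.na(nDrop), 0L, nDrop))
  new("MergedDeletionSet", loci = lo, memberCalls = mc, recovered = TRUE)
}

#' Member calls kept after recovery
#'
#' @param merged a [MergedDeletionSet]
#' @return the member [DeletionCallSet] without dropped calls
#' @export
keptCalls <- function(merged) {
  mc <- merged@memberCalls
  mc[mcols(mc)$call_status != "dropped"]
}
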