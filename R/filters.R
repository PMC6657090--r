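#' @include merge-recover.R
NULL

#' Filter cascade parameters
#'
#' Thresholds are interpreted strictly from their textual definitions:
#' deletions shorter than `minSize` (30 bp) are dropped, depths *over*
#' `maxDepth` (150) are dropped, soft-clip quality strictly below
#' `minSoftclipQual` (Phred 15) is dropped. `flankBp` (100 bp) is both the
#' breakpoint-flank width used against the simple-repeat track and the
#' flank width the caller's `depth_flank` refers to.
#'
#' @param minSize minimum deletion length in bases
#' @param maxSize maximum deletion length in bases
#' @param flankBp breakpoint flank width in bases
#' @param maxDepth maximum mean read depth over the deletion span
#' @param minSoftclipQual minimum mean Phred quality of soft-clipped bases
#' @param repeatMatch `"name"` to require identical repeat names (e.g.
#'   both `"AluY"`) in the similar-repeat filter, `"family"` to match on
#'   the family prefix (e.g. any two Alu elements)
#' @return a `FilterParams` list
#' @export
filterParams <- function(minSize = 30L, maxSize = 10000L, flankBp = 100L,
                         maxDepth = 150, minSoftclipQual = 15,
                         repeatMatch = c("name", "family")) {
  stopifnot(minSize > 0, maxSize > minSize, flankBp > 0, maxDepth > 0,
            minSoftclipQual > 0)
  structure(list(minSize = as.integer(minSize),
                 maxSize = as.integer(maxSize),
                 flankBp = as.integer(flankBp),
                 maxDepth = maxDepth,
                 minSoftclipQual = minSoftclipQual,
                 repeatMatch = match.arg(repeatMatch)),
            class = "FilterParams")
}

# per-locus means of caller QC fields over non-dropped members
.locusStats <- function(merged) {
  mc <- keptCalls(merged)
  lo <- loci(merged)
  f <- factor(mcols(mc)$locus_id, levels = mcols(lo)$locus_id)
  meanOrNA <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  }
  data.frame(
    locus_id = mcols(lo)$locus_id,
    depth_del = as.numeric(tapply(mcols(mc)$depth_del, f, meanOrNA)),
    depth_flank = as.numeric(tapply(mcols(mc)$depth_flank, f, meanOrNA)),
    softclip_qual = as.numeric(tapply(mcols(mc)$mean_softclip_quality, f,
                                      meanOrNA)),
    stringsAsFactors = FALSE)
}

.partition <- function(merged, keep, flagged = logical(length(keep))) {
  list(kept = merged[keep], dropped = merged[!keep],
       keep = keep, flagged = flagged)
}

#' Size filter
#'
#' Keeps loci whose deletion length lies in
#' `[params$minSize, params$maxSize]`; a 29 bp candidate is dropped, a
#' 30 bp candidate kept.
#'
#' @param merged a [MergedDeletionSet]
#' @param params a [filterParams()] object
#' @return list with elements `kept`, `dropped` (both `MergedDeletionSet`),
#'   `keep` (logical over loci) and `flagged`
#' @export
filterSize <- function(merged, params = filterParams()) {
  len <- width(loci(merged))
  .partition(merged, len >= params$minSize & len <= params$maxSize)
}

#' Region-annotation filter
#'
#' Drops a locus when its interval overlaps a telomere/centromere,
#' simple-repeat or microsatellite interval by at least one base, or when
#' either 100 bp breakpoint flank (the `flankBp` bases immediately outside
#' each breakpoint) overlaps a simple repeat.
#'
#' @param merged a [MergedDeletionSet]
#' @param tracks named list of `GRanges` with elements
#'   `telomere_centromere`, `simple_repeat`, `microsatellite`
#' @param params a [filterParams()] object
#' @return partition list as in [filterSize()]
#' @export
filterRegionAnnotations <- function(merged, tracks,
                                    params = filterParams()) {
  need <- c("telomere_centromere", "simple_repeat", "microsatellite")
  missing <- setdiff(need, names(tracks))
  if (length(missing)) {
    stop("missing annotation track(s): ", paste(missing, collapse = ", "))
  }
  lo <- loci(merged)
  excluded <- .bindGr(granges(tracks$telomere_centromere),
                      granges(tracks$simple_repeat),
                      granges(tracks$microsatellite))
  hitBody <- overlapsAny(lo, excluded, ignore.strand = TRUE)
  fb <- params$flankBp
  left <- GRanges(seqnames(lo),
                  IRanges(pmax(start(lo) - fb, 1L), pmax(start(lo) - 1L, 1L)))
  right <- GRanges(seqnames(lo), IRanges(end(lo) + 1L, end(lo) + fb))
  hitFlank <- (start(lo) > 1L &
                 overlapsAny(left, tracks$simple_repeat,
                             ignore.strand = TRUE)) |
    overlapsAny(right, tracks$simple_repeat, ignore.strand = TRUE)
  .partition(merged, !(hitBody | hitFlank))
}

#' Read-depth filter
#'
#' Drops a locus when the member-mean depth over the deletion span exceeds
#' `params$maxDepth`, or is strictly higher than the member-mean flank
#' depth (a deletion should not be deeper than its flanks). Loci with no
#' depth values are kept and flagged.
#'
#' @inheritParams filterSize
#' @return partition list as in [filterSize()]
#' @export
filterDepth <- function(merged, params = filterParams()) {
  st <- .locusStats(merged)
  noData <- is.na(st$depth_del) & is.na(st$depth_flank)
  drop <- !noData & (st$depth_del > params$maxDepth |
                       (!is.na(st$depth_flank) &
                          st$depth_del > st$depth_flank))
  drop[is.na(drop)] <- FALSE
  .partition(merged, !drop, flagged = noData)
}

#' Soft-clip quality filter
#'
#' Drops a locus when the member-mean Phred quality of soft-clipped bases
#' at its breakpoints (over members carrying the value) is strictly below
#' `params$minSoftclipQual`. Loci where no member carries a value are kept
#' and flagged.
#'
#' @inheritParams filterSize
#' @return partition list as in [filterSize()]
#' @export
filterSoftclipQuality <- function(merged, params = filterParams()) {
  st <- .locusStats(merged)
  noData <- is.na(st$softclip_qual)
  drop <- !noData & st$softclip_qual < params$minSoftclipQual
  .partition(merged, !drop, flagged = noData)
}

.repeatLabel <- function(track, mode) {
  lab <- mcols(track)$name
  if (is.null(lab) || any(is.na(lab)) || any(!nzchar(lab))) {
    stop("repeat_element track must carry a name label per interval")
  }
  if (mode == "family") sub("[0-9].*$|[a-z].*$", "", lab) else lab
}

#' Similar-repeat breakpoint filter
#'
#' A deletion whose two breakpoints each fall inside *distinct* repeat
#' elements sharing the same repeat name (e.g. two `AluY` copies) is
#' likely an alignment artifact between near-identical sequences and is
#' dropped. Breakpoints inside one and the same element do not trigger the
#' rule, nor do elements of different names.
#'
#' @param merged a [MergedDeletionSet]
#' @param repeatTrack `GRanges` of repeat-masked elements with an mcol
#'   `name` (repeat name, e.g. `"AluY"`, `"L1PA3"`)
#' @param params a [filterParams()] object (`repeatMatch` selects
#'   name- vs family-level matching)
#' @return partition list as in [filterSize()]
#' @export
filterSimilarRepeat <- function(merged, repeatTrack,
                                params = filterParams()) {
  lo <- loci(merged)
  lab <- .repeatLabel(repeatTrack, params$repeatMatch)
  bpStart <- GRanges(seqnames(lo), IRanges(start(lo), width = 1L))
  bpEnd <- GRanges(seqnames(lo), IRanges(end(lo), width = 1L))
  hs <- findOverlaps(bpStart, repeatTrack, ignore.strand = TRUE)
  he <- findOverlaps(bpEnd, repeatTrack, ignore.strand = TRUE)
  drop <- logical(length(lo))
  for (i in seq_along(lo)) {
    es <- subjectHits(hs)[queryHits(hs) == i]
    ee <- subjectHits(he)[queryHits(he) == i]
    if (!length(es) || !length(ee)) next
    # distinct elements with a shared label
    pairs <- expand.grid(s = es, e = ee)
    pairs <- pairs[pairs$s != pairs$e, , drop = FALSE]
    drop[i] <- any(lab[pairs$s] == lab[pairs$e])
  }
  .partition(merged, !drop)
}

#' Run the progressive filter cascade
#'
#' Applies, in order: size, region annotations, depth, soft-clip quality,
#' similar-repeat. Emits per-step accounting of input/output locus counts;
#' counts are monotone non-increasing and chain step to step.
#'
#' @param merged a [MergedDeletionSet] (after [jointCallRecover()])
#' @param tracks named list of `GRanges` annotation tracks, with elements
#'   `telomere_centromere`, `simple_repeat`, `microsatellite`,
#'   `repeat_element`
#' @param params a [filterParams()] object
#' @param order character vector of step names to run, in order
#' @return list with `kept` (a `MergedDeletionSet`), `accounting`
#'   (`data.frame` of `step`, `n_in`, `n_out`), and `dropped` (named list
#'   of per-step dropped `MergedDeletionSet`s)
#' @export
runProgressivePipeline <- function(merged, tracks,
                                   params = filterParams(),
                                   order = c("size", "region", "depth",
                                             "softclip_quality",
                                             "similar_repeat")) {
  steps <- list(
    size = function(x) filterSize(x, params),
    region = function(x) filterRegionAnnotations(x, tracks, params),
    depth = function(x) filterDepth(x, params),
    softclip_quality = function(x) filterSoftclipQuality(x, params),
    similar_repeat = function(x)
      filterSimilarRepeat(x, tracks$repeat_element, params))
  unknown <- setdiff(order, names(steps))
  if (length(unknown)) stop("unknown filter step(s): ",
                            paste(unknown, collapse = ", "))
  acc <- data.frame(step = character(), n_in = integer(),
                    n_out = integer(), stringsAsFactors = FALSE)
  dropped <- list()
  cur <- merged
  for (s in order) {
    nIn <- length(cur)
    part <- steps[[s]](cur)
    cur <- part$kept
    dropped[[s]] <- part$dropped
    acc <- rbind(acc, data.frame(step = s, n_in = nIn,
                                 n_out = length(cur),
                                 stringsAsFactors = FALSE))
  }
  list(kept = cur, accounting = acc, dropped = dropped)
}
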