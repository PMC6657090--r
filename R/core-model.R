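#' @include AllClasses.R
NULL

#' Parse a region string into a GRanges
#'
#' Region strings of the form `"chr9:130330770-130330813"` use 0-based
#' half-open coordinates, so the deletion length is `end - start` (the
#' example is a 43 bp deletion). The returned `GRanges` is 1-based closed
#' per the Bioconductor convention, with `width()` equal to that length.
#'
#' @param x character vector of `"chrom:start-end"` strings
#' @return `GRanges`, one range per input string
#' @examples
#' width(parseRegion("chr9:130330770-130330813"))  # 43
#' @export
parseRegion <- function(x) {
  m <- regmatches(x, regexec("^([^:[:space:]]+):([0-9,]+)-([0-9,]+)$", x))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed region string: ", paste(x[bad], collapse = ", "))
  }
  chrom <- vapply(m, `[[`, "", 2L)
  a <- as.numeric(gsub(",", "", vapply(m, `[[`, "", 3L)))
  b <- as.numeric(gsub(",", "", vapply(m, `[[`, "", 4L)))
  if (any(b <= a)) stop("invalid interval: end must exceed start")
  GRanges(chrom, IRanges(start = a + 1, end = b))
}

#' Format a GRanges as 0-based half-open region strings
#'
#' Inverse of [parseRegion()].
#'
#' @param gr a `GRanges`
#' @return character vector of `"chrom:start-end"` strings
#' @export
regionString <- function(gr) {
  sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr) - 1L, end(gr))
}

#' Number of deleted bases of each interval
#'
#' @param x a `GRanges` (or anything with a `width()`), or a region string
#' @return integer vector of deletion lengths
#' @examples
#' deletionLength("chr12:122230008-122230060")  # 52
#' @export
deletionLength <- function(x) {
  if (is.character(x)) x <- parseRegion(x)
  if (any(width(x) < 1L)) stop("invalid interval: empty range")
  width(x)
}

#' Reciprocal overlap between interval pairs
#'
#' The standard SV-matching statistic: intersection length divided by the
#' length of the longer interval. Pairs on different chromosomes (and
#' disjoint pairs) get 0.
#'
#' @param a,b parallel `GRanges` of equal length (or length 1, recycled)
#' @return numeric vector of fractions in \[0, 1\]
#' @export
reciprocalOverlap <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  inter <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  inter <- pmax(inter, 0L)
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  out <- ifelse(same, inter / pmax(width(a), width(b)), 0)
  as.numeric(out)
}

#' Breakpoint distances between interval pairs
#'
#' Absolute coordinate differences of the two breakpoints of each pair.
#'
#' @param a,b parallel `GRanges` on the same chromosome
#' @return two-column integer matrix with columns `start_delta`, `end_delta`
#' @export
breakpointDistance <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  if (any(as.character(seqnames(a)) != as.character(seqnames(b)))) {
    stop("breakpointDistance requires intervals on the same chromosome")
  }
  cbind(start_delta = abs(start(a) - start(b)),
        end_delta = abs(end(a) - end(b)))
}
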