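#' @include core-model.R
NULL

.CIGAR_OPS <- c("M", "I", "D", "S", "H", "=", "X", "N", "P")

#' Parse a CIGAR string into operations
#'
#' @param cigar CIGAR string, e.g. `"50M130D50M"`
#' @return `data.frame` with columns `op`, `len`
#' @export
parseCigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*" || !nzchar(cigar)) {
    return(data.frame(op = character(), len = integer()))
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Za-z=]", cigar))[[1L]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(cigar)) {
    stop("invalid CIGAR string: ", cigar)
  }
  op <- substr(toks, nchar(toks), nchar(toks))
  if (!all(op %in% .CIGAR_OPS)) {
    stop("invalid CIGAR operation in: ", cigar)
  }
  data.frame(op = op,
             len = as.integer(substr(toks, 1L, nchar(toks) - 1L)),
             stringsAsFactors = FALSE)
}

#' Extract deletions from one long-read alignment
#'
#' Walks the CIGAR accumulating the reference coordinate; every run of
#' `D` operations is a candidate deletion. Adjacent `D` runs separated by
#' at most `gapMergeBp` reference-consuming bases are merged (noisy
#' long-read alignments often split one deletion into several `D`
#' operations); merged runs whose total deleted length is at least
#' `minLen` are reported. Coordinates are 1-based closed over the deleted
#' reference bases.
#'
#' @param chrom chromosome name
#' @param pos 1-based leftmost reference position of the alignment
#' @param cigar CIGAR string
#' @param minLen minimum total deleted length (120 bp: smaller events are
#'   unreliable at long-read error rates)
#' @param gapMergeBp merge adjacent `D` runs separated by at most this
#'   many reference bases; 0 disables merging
#' @return `GRanges` of per-read deletion intervals (mcol `del_len` =
#'   deleted bases, excluding any merged gap)
#' @export
extractCigarDeletions <- function(chrom, pos, cigar, minLen = 120L,
                                  gapMergeBp = 10L) {
  ops <- parseCigar(cigar)
  refPos <- pos
  dels <- list()
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op == "D") {
      dels[[length(dels) + 1L]] <- c(start = refPos, end = refPos + len - 1L)
    }
    if (op %in% c("M", "D", "=", "X", "N")) refPos <- refPos + len
  }
  if (!length(dels)) return(GRanges())
  d <- do.call(rbind, dels)
  # merge runs separated by <= gapMergeBp reference bases
  merged <- list()
  cur <- d[1L, ]
  curDel <- cur["end"] - cur["start"] + 1L
  if (nrow(d) > 1L) {
    for (i in 2L:nrow(d)) {
      gap <- d[i, "start"] - cur["end"] - 1L
      if (gapMergeBp > 0L && gap <= gapMergeBp) {
        cur["end"] <- d[i, "end"]
        curDel <- curDel + (d[i, "end"] - d[i, "start"] + 1L)
      } else {
        merged[[length(merged) + 1L]] <- c(cur, del = unname(curDel))
        cur <- d[i, ]
        curDel <- cur["end"] - cur["start"] + 1L
      }
    }
  }
  merged[[length(merged) + 1L]] <- c(cur, del = unname(curDel))
  m <- do.call(rbind, merged)
  keep <- m[, "del"] >= minLen
  m <- m[keep, , drop = FALSE]
  out <- GRanges(rep(chrom, nrow(m)), IRanges(m[, "start"], m[, "end"]))
  mcols(out)$del_len <- as.integer(m[, "del"])
  out
}

#' Extract deletions from a table of alignments
#'
#' Vectorized driver over [extractCigarDeletions()] for the output of
#' [readLongReadAlignments()].
#'
#' @param alignments `data.frame` with `read_id`, `chrom`, `pos`, `cigar`
#' @inheritParams extractCigarDeletions
#' @return `GRanges` of per-read deletions with mcol `read_id`
#' @export
extractReadDeletions <- function(alignments, minLen = 120L,
                                 gapMergeBp = 10L) {
  out <- lapply(seq_len(nrow(alignments)), function(i) {
    g <- extractCigarDeletions(alignments$chrom[i], alignments$pos[i],
                               alignments$cigar[i], minLen = minLen,
                               gapMergeBp = gapMergeBp)
    if (length(g)) mcols(g)$read_id <- alignments$read_id[i]
    g
  })
  out <- out[lengths(out) > 0L]
  if (!length(out)) {
    g <- GRanges()
    mcols(g)$del_len <- integer()
    mcols(g)$read_id <- character()
    return(g)
  }
  do.call(.bindGr, out)
}

#' Cluster per-read deletions into supported events
#'
#' Single-linkage clustering of per-read deletion intervals (link when
#' reciprocal overlap >= `minRo` and both breakpoint deltas <= `bpTol`);
#' clusters supported by at least `minReads` distinct reads become events
#' whose interval is the median start / median end over members.
#'
#' @param perReadDels `GRanges` from [extractReadDeletions()] with mcol
#'   `read_id`
#' @param minReads minimum distinct supporting reads (2)
#' @param minRo minimum reciprocal overlap for linking
#' @param bpTol maximum breakpoint delta for linking (long-read
#'   breakpoints are imprecise, hence the loose 100 bp default)
#' @return `GRanges` of events with mcols `n_reads` and `read_ids`
#'   (CharacterList)
#' @export
clusterReadEvents <- function(perReadDels, minReads = 2L, minRo = 0.5,
                              bpTol = 100L) {
  emptyOut <- function() {
    g <- GRanges()
    mcols(g)$n_reads <- integer()
    mcols(g)$read_ids <- IRanges::CharacterList()
    g
  }
  if (length(perReadDels) == 0L) return(emptyOut())
  ord <- order(as.character(seqnames(perReadDels)), start(perReadDels),
               end(perReadDels), mcols(perReadDels)$read_id)
  perReadDels <- perReadDels[ord]
  hits <- findOverlaps(perReadDels, perReadDels, maxgap = bpTol,
                       ignore.strand = TRUE)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  keep <- qh < sh
  qh <- qh[keep]; sh <- sh[keep]
  if (length(qh)) {
    ok <- abs(start(perReadDels)[qh] - start(perReadDels)[sh]) <= bpTol &
      abs(end(perReadDels)[qh] - end(perReadDels)[sh]) <= bpTol &
      reciprocalOverlap(perReadDels[qh], perReadDels[sh]) >= minRo
    qh <- qh[ok]; sh <- sh[ok]
  }
  n <- length(perReadDels)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(qh), to = as.character(sh)),
    directed = FALSE, vertices = data.frame(name = as.character(seq_len(n))))
  comp <- igraph::components(g)$membership[as.character(seq_len(n))]
  groups <- split(seq_len(n), comp)
  ev <- lapply(groups, function(idx) {
    reads <- unique(mcols(perReadDels)$read_id[idx])
    list(chrom = as.character(seqnames(perReadDels))[idx[1L]],
         start = as.integer(round(median(start(perReadDels)[idx]))),
         end = as.integer(round(median(end(perReadDels)[idx]))),
         reads = sort(reads))
  })
  ev <- ev[vapply(ev, function(e) length(e$reads), 1L) >= minReads]
  if (!length(ev)) return(emptyOut())
  out <- GRanges(vapply(ev, `[[`, "", "chrom"),
                 IRanges(vapply(ev, `[[`, 1L, "start"),
                         vapply(ev, `[[`, 1L, "end")))
  mcols(out)$n_reads <- unname(vapply(ev, function(e) length(e$reads), 1L))
  mcols(out)$read_ids <- IRanges::CharacterList(lapply(ev, `[[`, "reads"))
  out <- sort(out, ignore.strand = TRUE)
  out
}

#' Match a query deletion set against a truth set
#'
#' Greedy one-to-one matching in descending reciprocal-overlap order
#' (ties broken by smaller query start): a query deletion matches a truth
#' event when their reciprocal overlap is at least `minRo` and both
#' breakpoint deltas are within `bpTol`. Query deletions shorter than
#' `minQueryLen` are excluded from the denominator, mirroring the size
#' floor of the long-read truth set.
#'
#' @param query `GRanges` of query deletions (e.g. kept short-read loci)
#' @param truth `GRanges` of truth events (e.g. long-read events)
#' @param minRo minimum reciprocal overlap
#' @param bpTol maximum breakpoint delta in bases
#' @param minQueryLen query size floor (120 bp)
#' @return a [ConcordanceReport]
#' @export
matchCallsets <- function(query, truth, minRo = 0.5, bpTol = 200L,
                          minQueryLen = 120L) {
  query <- query[width(query) >= minQueryLen]
  if (length(query) == 0L) {
    stop("empty query set after size floor: concordance rate undefined")
  }
  hits <- findOverlaps(query, truth, maxgap = bpTol, ignore.strand = TRUE)
  qh <- queryHits(hits); sh <- subjectHits(hits)
  cand <- data.frame(q = qh, t = sh,
                     ro = reciprocalOverlap(query[qh], truth[sh]))
  ds <- abs(start(query)[qh] - start(truth)[sh])
  de <- abs(end(query)[qh] - end(truth)[sh])
  cand <- cand[cand$ro >= minRo & ds <= bpTol & de <= bpTol, , drop = FALSE]
  cand <- cand[order(-cand$ro, start(query)[cand$q], cand$q, cand$t), ,
               drop = FALSE]
  usedQ <- logical(length(query)); usedT <- logical(length(truth))
  sel <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!usedQ[cand$q[i]] && !usedT[cand$t[i]]) {
      sel[i] <- TRUE
      usedQ[cand$q[i]] <- TRUE
      usedT[cand$t[i]] <- TRUE
    }
  }
  matches <- cand[sel, , drop = FALSE]
  rownames(matches) <- NULL
  new("ConcordanceReport",
      nTotal = length(query), nMatched = nrow(matches),
      rate = nrow(matches) / length(query),
      matches = matches,
      params = list(min_ro = minRo, bp_tol = as.integer(bpTol),
                    min_query_len = as.integer(minQueryLen)))
}

#' Concordance as a percentage
#'
#' `100 * nMatched / nTotal`, rounded half-up to one decimal, matching
#' how consistency rates are conventionally reported (e.g. 921/947
#' -> 97.3).
#'
#' @param nMatched matched count
#' @param nTotal total count (> 0)
#' @return percentage rounded to one decimal
#' @export
concordancePercentage <- function(nMatched, nTotal) {
  if (any(nTotal <= 0)) stop("nTotal must be positive")
  roundHalfUp(100 * nMatched / nTotal, 1L)
}
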