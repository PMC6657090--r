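suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# one-liner DeletionCallSet builder; all arguments vectorized
mkCalls <- function(chrom = "chr1", start = 1000L, end = 1315L,
                    sample = "S1", orient = "both", nsup = 5L,
                    qual = 30, ddel = 20, dflank = 30, gt = "het") {
  df <- data.frame(chrom = chrom, start = start, end = end,
                   support_orientation = orient, n_support_reads = nsup,
                   mean_softclip_quality = qual, depth_del = ddel,
                   depth_flank = dflank, genotype = gt,
                   sample_id = sample, stringsAsFactors = FALSE)
  DeletionCallSet(df)
}

# empty annotation tracks (repeat_element keeps its name mcol)
mkTracks <- function(telo = GRanges(), simple = GRanges(),
                     micro = GRanges(), repel = NULL) {
  if (is.null(repel)) {
    repel <- GRanges()
    mcols(repel)$name <- character()
  }
  list(telomere_centromere = telo, simple_repeat = simple,
       microsatellite = micro, repeat_element = repel)
}

gr1 <- function(chrom, start, end = NULL, width = NULL) {
  GRanges(chrom, if (is.null(end)) IRanges(start, width = width)
          else IRanges(start, end))
}

# merged set with recovery applied, from a call set
mkMerged <- function(calls, params = mergeParams()) {
  jointCallRecover(clusterCalls(calls, params), params)
}

# tiny genotype panel via the public path: calls -> cluster -> panel
mkPanel <- function(gtRows, samples, chrom = "chr1", start0 = NULL,
                    len = 200L) {
  # gtRows: matrix loci x samples of 0/1/2
  nL <- nrow(gtRows)
  if (is.null(start0)) start0 <- seq(10000L, by = 5000L, length.out = nL)
  dfs <- list()
  for (i in seq_len(nL)) for (j in seq_along(samples)) {
    g <- gtRows[i, j]
    if (!is.na(g) && g > 0L) {
      dfs[[length(dfs) + 1L]] <- data.frame(
        chrom = chrom, start = start0[i], end = start0[i] + len,
        support_orientation = "both", n_support_reads = 5L,
        mean_softclip_quality = 30, depth_del = 20, depth_flank = 30,
        genotype = if (g == 2L) "hom" else "het",
        sample_id = samples[j], stringsAsFactors = FALSE)
    }
  }
  calls <- DeletionCallSet(do.call(rbind, dfs))
  buildGenotypeMatrix(mkMerged(calls), samples)
}

writeSamFile <- function(lines, genome = c(chr1 = 1e6)) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                       as.integer(genome)),
               lines), path)
  path
}

samLine <- function(id, chrom, pos, cigarStr, mapped = TRUE) {
  if (mapped) {
    sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*", id, chrom, pos,
            cigarStr)
  } else {
    sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*", id)
  }
}
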