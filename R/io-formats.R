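#' @include AllClasses.R
NULL

.CALL_TABLE_COLS <- c("chrom", "start", "end", "support_orientation",
                      "n_support_reads", "mean_softclip_quality",
                      "depth_del", "depth_flank", "genotype")

#' Read a per-sample deletion call table
#'
#' The canonical ingestion format is a tab-separated file with a header row
#' and columns `chrom`, `start`, `end` (0-based half-open),
#' `support_orientation`, `n_support_reads`, `mean_softclip_quality`
#' (empty or `NA` when absent), `depth_del`, `depth_flank`, `genotype`.
#' Output from an upstream soft-clip deletion caller is adapted to this
#' schema once, upstream of the pipeline.
#'
#' @param path file path
#' @param sample_id sample identifier attached to every call
#' @return a [DeletionCallSet]
#' @export
readCallTable <- function(path, sample_id) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.CALL_TABLE_COLS, colnames(df))
  if (length(missing)) {
    stop(sprintf("call table %s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    return(DeletionCallSet(df, sample_id = sample_id))
  }
  bad <- which(!df$support_orientation %in% .ORIENTATIONS)
  if (length(bad)) {
    stop(sprintf(
      "call table %s line %d: unknown support_orientation '%s'",
      path, bad[1L] + 1L, df$support_orientation[bad[1L]]))
  }
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$end <= df$start)
  if (length(bad)) {
    stop(sprintf("call table %s line %d: invalid coordinates",
                 path, bad[1L] + 1L))
  }
  DeletionCallSet(df, sample_id = sample_id)
}

#' Write a deletion call table
#'
#' Inverse of [readCallTable()]; coordinates are written 0-based half-open.
#'
#' @param calls a [DeletionCallSet]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeCallTable <- function(calls, path) {
  df <- data.frame(chrom = as.character(seqnames(calls)),
                   start = start(calls) - 1L, end = end(calls),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(mcols(calls)[, setdiff(.CALL_MCOLS,
                                                       "sample_id")]))
  df <- cbind(df[, c("chrom", "start", "end")],
              support_orientation = mcols(calls)$support_orientation,
              n_support_reads = mcols(calls)$n_support_reads,
              mean_softclip_quality = mcols(calls)$mean_softclip_quality,
              depth_del = mcols(calls)$depth_del,
              depth_flank = mcols(calls)$depth_flank,
              genotype = mcols(calls)$genotype)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation track from BED
#'
#' BED3 or BED4 (4th column = feature label, e.g. a repeat name such as
#' `"AluY"` or a chromatin-state label). BED is 0-based half-open; the
#' returned `GRanges` is 1-based closed and sorted by (chrom, start).
#'
#' @param path BED file
#' @param name track category label stored in `metadata(track)$name`
#' @return sorted `GRanges`; BED4 labels land in mcol `name`
#' @export
readBedTrack <- function(path, name = NA_character_) {
  gr <- rtracklayer::import(path, format = "BED")
  gr <- sort(gr, ignore.strand = TRUE)
  strand(gr) <- "*"
  metadata(gr)$track_name <- name
  gr
}

#' Write an annotation track to BED
#'
#' @param gr `GRanges`; an mcol `name` becomes the BED4 label column
#' @param path output path (plain text, uncompressed)
#' @return `path`, invisibly
#' @export
writeBedTrack <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read long-read alignments
#'
#' Accepts SAM text or BAM; SAM is converted on the fly. Unmapped records
#' are skipped. Returns one row per aligned read with its leftmost 1-based
#' reference position and CIGAR string, ready for
#' [extractCigarDeletions()].
#'
#' @param path SAM (`.sam`) or BAM file
#' @return `data.frame` with columns `read_id`, `chrom`, `pos`, `cigar`
#' @export
readLongReadAlignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- suppressMessages(
      Rsamtools::asBam(path, dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  param <- Rsamtools::ScanBamParam(
    what = "qname",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  data.frame(read_id = mcols(ga)$qname,
             chrom = as.character(seqnames(ga)),
             pos = start(ga),
             cigar = GenomicAlignments::cigar(ga),
             stringsAsFactors = FALSE)
}

#' Export a genotype panel as VCF 4.2
#'
#' Deletions are written as symbolic `<DEL>` records: `POS` is the 1-based
#' anchor base immediately before the deleted run, `INFO/END` the last
#' deleted base, `INFO/SVLEN` minus the deletion length, and `FORMAT/GT`
#' one of `0/0`, `0/1`, `1/1`, `./.`. No reference FASTA is needed
#' (`REF` is written as `N`). The file round-trips through
#' [VariantAnnotation::readVcf()]; see [readPanelVcf()].
#'
#' @param panel a [GenotypePanel]
#' @param path output path (uncompressed `.vcf`)
#' @return `path`, invisibly
#' @export
writePanelVcf <- function(panel, path) {
  if (ncol(panel) == 0L) stop("refusing to write a panel with no samples")
  if (nrow(panel) == 0L) stop("refusing to write a panel with no sites")
  gr <- rowRanges(panel)
  ids <- rowData(panel)$locus_id
  samples <- colnames(panel)

  hdr <- VariantAnnotation::VCFHeader(samples = samples)
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                      row.names = "fileformat"))
  VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
    Number = "1", Type = "String", Description = "Genotype",
    row.names = "GT")
  VariantAnnotation::info(hdr) <- S4Vectors::DataFrame(
    Number = c("1", "1", "1"),
    Type = c("Integer", "Integer", "String"),
    Description = c("End position of the deletion (1-based, inclusive)",
                    "Difference in length between ALT and REF alleles",
                    "Type of structural variant"),
    row.names = c("END", "SVLEN", "SVTYPE"))

  anchor <- GRanges(seqnames(gr), IRanges(start(gr) - 1L, width = 1L))
  names(anchor) <- ids
  gt <- genotypes(panel)
  gtChar <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow = nrow(gt))
  gtChar[is.na(gt)] <- "./."
  dimnames(gtChar) <- list(ids, samples)

  v <- VariantAnnotation::VCF(
    rowRanges = anchor,
    colData = S4Vectors::DataFrame(Samples = seq_along(samples),
                                   row.names = samples),
    exptData = list(header = hdr),
    fixed = S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(rep("N", length(anchor))),
      ALT = IRanges::CharacterList(as.list(rep("<DEL>", length(anchor)))),
      QUAL = rep(NA_real_, length(anchor)),
      FILTER = rep("PASS", length(anchor))),
    info = S4Vectors::DataFrame(END = end(gr),
                                SVLEN = -width(gr),
                                SVTYPE = rep("DEL", length(gr))),
    geno = S4Vectors::SimpleList(GT = gtChar))
  VariantAnnotation::writeVcf(v, path)
  invisible(path)
}

#' Read a panel VCF back into a GenotypePanel
#'
#' Companion reader for [writePanelVcf()] output (symbolic `<DEL>` records
#' with `END`/`SVLEN` and `GT`).
#'
#' @param path VCF file
#' @return a [GenotypePanel]
#' @export
readPanelVcf <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  anchor <- rowRanges(v)
  endPos <- VariantAnnotation::info(v)$END
  gr <- GRanges(seqnames(anchor), IRanges(start(anchor) + 1L, endPos))
  gtChar <- VariantAnnotation::geno(v)$GT
  gt <- matrix(match(gtChar, c("0/0", "0/1", "1/1")) - 1L,
               nrow = nrow(gtChar), dimnames = dimnames(gtChar))
  mode(gt) <- "integer"
  .newGenotypePanel(gr, locus_id = rownames(gtChar), gt = gt)
}

#' Read/write a named numeric matrix as TSV
#'
#' Row = feature (first column `id`), remaining columns = samples. Used for
#' genotype-code and expression matrices.
#'
#' @param path TSV file
#' @return numeric matrix with row and column names
#' @export
readMatrixTsv <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("matrix row/column ids must be unique")
  }
  m
}

#' @rdname readMatrixTsv
#' @param m matrix with dimnames
#' @export
writeMatrixTsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
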