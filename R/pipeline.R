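#' @include synthgen.R
NULL

#' Run the full curation pipeline in memory
#'
#' Orchestrates cluster -> joint-call recovery -> progressive filters ->
#' genotype panel -> population filters, with optional long-read
#' concordance evaluation and cis-eQTL scan, and returns every
#' intermediate object plus chained per-step accounting
#' (`step`, `n_in`, `n_out` over loci; counts are monotone
#' non-increasing).
#'
#' @param calls a [DeletionCallSet] over all cohort samples
#' @param tracks named list of annotation `GRanges`
#'   (`telomere_centromere`, `simple_repeat`, `microsatellite`,
#'   `repeat_element`)
#' @param samples ordered cohort sample ids
#' @param merge a [mergeParams()] object
#' @param filters a [filterParams()] object
#' @param mafMin,hweAlpha population-filter thresholds (see
#'   [applyPopulationFilters()])
#' @param longReadSam optional SAM/BAM of long-read alignments for
#'   concordance evaluation
#' @param expression,tss optional expression matrix and TSS table for the
#'   eQTL scan
#' @param fdrAlpha per-window FDR level for the eQTL scan
#' @param outDir optional directory; when given, writes `merged.tsv`,
#'   `kept.tsv`, `accounting.json`, `panel.vcf` and `report.json`
#' @return list with `merged`, `recovered`, `kept`
#'   (`MergedDeletionSet`s), `accounting` (`data.frame`), `panel`,
#'   `filteredPanel` ([GenotypePanel]s), and when inputs were supplied
#'   `concordance` ([ConcordanceReport]) and `eqtl` (`data.frame`)
#' @export
runFullPipeline <- function(calls, tracks, samples,
                            merge = mergeParams(),
                            filters = filterParams(),
                            mafMin = 0.05, hweAlpha = 1e-4,
                            longReadSam = NULL,
                            expression = NULL, tss = NULL,
                            fdrAlpha = 0.01, outDir = NULL) {
  acc <- data.frame(step = character(), n_in = integer(),
                    n_out = integer(), stringsAsFactors = FALSE)
  addStep <- function(step, nIn, nOut) {
    acc <<- rbind(acc, data.frame(step = step, n_in = as.integer(nIn),
                                  n_out = as.integer(nOut),
                                  stringsAsFactors = FALSE))
  }
  merged <- clusterCalls(calls, merge)
  addStep("cluster", length(calls), length(merged))
  recovered <- jointCallRecover(merged, merge)
  lo <- loci(recovered)
  nonEmpty <- mcols(lo)$n_members > mcols(lo)$n_dropped
  recoveredKept <- recovered[nonEmpty]
  addStep("recover", length(recovered), length(recoveredKept))

  filt <- runProgressivePipeline(recoveredKept, tracks, filters)
  acc <- rbind(acc, filt$accounting)
  kept <- filt$kept

  panel <- buildGenotypeMatrix(kept, samples)
  filteredPanel <- applyPopulationFilters(panel, mafMin = mafMin,
                                          hweAlpha = hweAlpha)
  addStep("population", nrow(panel), nrow(filteredPanel))

  out <- list(merged = merged, recovered = recovered, kept = kept,
              accounting = acc, panel = panel,
              filteredPanel = filteredPanel)

  if (!is.null(longReadSam)) {
    aln <- readLongReadAlignments(longReadSam)
    perRead <- extractReadDeletions(aln)
    events <- clusterReadEvents(perRead)
    out$longReadEvents <- events
    out$concordance <- matchCallsets(granges(loci(kept)), events)
  }
  if (!is.null(expression) && !is.null(tss)) {
    sites <- rowRanges(filteredPanel)
    mcols(sites)$locus_id <- rowData(filteredPanel)$locus_id
    scan <- eqtlScan(genotypes(filteredPanel), expression, sites, tss,
                     fdrAlpha = fdrAlpha)
    out$eqtl <- flagLeadVariants(scan)
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeCallTable(memberCalls(recovered),
                   file.path(outDir, "merged_members.tsv"))
    keptDf <- data.frame(
      locus_id = mcols(loci(kept))$locus_id,
      region = regionString(loci(kept)),
      n_members = mcols(loci(kept))$n_members,
      n_both = mcols(loci(kept))$n_both,
      n_recovered = mcols(loci(kept))$n_recovered,
      stringsAsFactors = FALSE)
    write.table(keptDf, file.path(outDir, "kept.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(acc, file.path(outDir, "accounting.json"),
                         dataframe = "rows", auto_unbox = TRUE)
    if (nrow(filteredPanel) > 0L && ncol(filteredPanel) > 0L) {
      writePanelVcf(filteredPanel, file.path(outDir, "panel.vcf"))
    }
    report <- list(n_input_calls = length(calls),
                   n_loci = length(merged),
                   n_kept = length(kept),
                   n_panel = nrow(filteredPanel))
    if (!is.null(out$concordance)) {
      report$concordance_rate <- out$concordance@rate
      report$concordance_matched <- out$concordance@nMatched
      report$concordance_total <- out$concordance@nTotal
    }
    if (!is.null(out$eqtl)) {
      report$n_eqtl_significant <-
        length(unique(out$eqtl$variant_id[out$eqtl$significant]))
    }
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
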