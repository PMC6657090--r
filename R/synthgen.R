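#' @include longread.R eqtl.R
NULL

#' Synthetic-cohort configuration
#'
#' Deterministic generator settings for a cohort of per-sample deletion
#' calls with planted truth, matching long-read alignments, and an
#' expression study with planted cis effects. All randomness flows from
#' `seed` through fixed per-component sub-seeds, so the same seed yields
#' byte-identical outputs and each stage is independently reproducible.
#'
#' Defaults emulate the study conditions this pipeline is built for: a
#' 174-sample whole-genome cohort; a bimodal deletion size distribution
#' with a 30--100 bp mode and a 300--400 bp mode (the second reflecting
#' polymorphic Alu insertions seen as deletions against the reference);
#' allele frequencies of polymorphic, panel-worthy deletions (>= 5%);
#' ~30x mean autosomal depth; and a both-orientation degradation
#' probability that grows as a sample's depth drops, which is what makes
#' joint-call recovery worthwhile.
#'
#' @param seed master seed (integer)
#' @param nSamples cohort size
#' @param nLoci number of clean planted deletion loci
#' @param sizeWeights mixture weights of the two size modes
#' @param smallRange,largeRange size ranges (bases) of the two modes
#' @param afRange planted alt-allele frequency range
#' @param meanDepth,depthSd per-sample mean depth distribution
#' @param degradationProb baseline probability that a carrier's
#'   both-orientation call degrades to a single orientation at mean depth;
#'   scaled by `meanDepth / sampleDepth` and capped at 0.9
#' @param violationsPerFilter planted filter violations per filter rule
#' @param readsPerLocus simulated long reads covering each true locus
#' @param jitterSd SD (bases) of Gaussian long-read breakpoint jitter
#' @param nGenes genes in the expression study
#' @param causalFraction fraction of genes given one causal cis variant
#' @param effectSize planted |beta| in noise-SD units
#' @param noiseSd expression noise SD
#' @param genome named vector of chromosome lengths
#' @return a `SimulationConfig` list
#' @export
simulationConfig <- function(seed = 1L, nSamples = 174L, nLoci = 300L,
                             sizeWeights = c(0.6, 0.4),
                             smallRange = c(30L, 100L),
                             largeRange = c(300L, 400L),
                             afRange = c(0.05, 0.5),
                             meanDepth = 30, depthSd = 5,
                             degradationProb = 0.2,
                             violationsPerFilter = 4L,
                             readsPerLocus = 5L, jitterSd = 10,
                             nGenes = 100L, causalFraction = 0.05,
                             effectSize = 1, noiseSd = 1,
                             genome = c(chr1 = 60e6, chr2 = 60e6)) {
  stopifnot(nSamples >= 0, nLoci >= 0, degradationProb >= 0,
            degradationProb <= 1, causalFraction >= 0,
            causalFraction <= 1, jitterSd >= 0, readsPerLocus >= 0)
  if (nLoci == 0L && violationsPerFilter > 0L && nSamples > 0L) {
    stop("infeasible config: violations requested with no loci")
  }
  structure(list(seed = as.integer(seed), nSamples = as.integer(nSamples),
                 nLoci = as.integer(nLoci),
                 sizeWeights = sizeWeights / sum(sizeWeights),
                 smallRange = smallRange, largeRange = largeRange,
                 afRange = afRange, meanDepth = meanDepth,
                 depthSd = depthSd, degradationProb = degradationProb,
                 violationsPerFilter = as.integer(violationsPerFilter),
                 readsPerLocus = as.integer(readsPerLocus),
                 jitterSd = jitterSd, nGenes = as.integer(nGenes),
                 causalFraction = causalFraction,
                 effectSize = effectSize, noiseSd = noiseSd,
                 genome = genome),
            class = "SimulationConfig")
}

.randIntervals <- function(n, widthRange, genome, lo = 2e5) {
  chrom <- factor(sample(names(genome), n, replace = TRUE,
                         prob = as.numeric(genome)),
                  levels = names(genome))
  w <- sample(widthRange[1L]:widthRange[2L], n, replace = TRUE)
  hi <- genome[chrom] - 2e5
  s <- floor(runif(n, lo, hi))
  GRanges(chrom, IRanges(s, width = w))
}

# rejection-sample n positions whose [pos, pos+len) stays >= margin away
# from everything in `occupied`; returns GRanges and updates via attr
.placeClean <- function(n, lens, occupied, genome, margin = 500L) {
  out <- GRanges()
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 200L * max(n, 1L)) stop("could not place clean intervals")
    chrom <- sample(names(genome), 1L, prob = as.numeric(genome))
    len <- lens[length(out) + 1L]
    s <- floor(runif(1L, 2e5, genome[[chrom]] - 2e5))
    lev <- factor(chrom, levels = names(genome))
    cand <- GRanges(lev, IRanges(s, width = len))
    pad <- GRanges(lev, IRanges(s - margin, width = len + 2L * margin))
    if (!overlapsAny(pad, occupied, ignore.strand = TRUE)) {
      out <- c(out, cand)
      occupied <- c(occupied, granges(cand))
    }
  }
  list(intervals = out, occupied = occupied)
}

#' Simulate annotation tracks
#'
#' Random telomere/centromere blocks (chromosome ends plus a central
#' block), simple repeats, microsatellites and named repeat elements
#' (Alu/L1/MIR-style labels) over the configured genome. Deterministic
#' under the config seed.
#'
#' @param config a [simulationConfig()] object
#' @return named list of `GRanges` tracks (`telomere_centromere`,
#'   `simple_repeat`, `microsatellite`, `repeat_element`)
#' @export
simulateAnnotationTracks <- function(config) {
  set.seed(.subSeed(config$seed, "tracks"))
  genome <- config$genome
  telo <- do.call(c, lapply(names(genome), function(ch) {
    len <- genome[[ch]]
    mid <- floor(len / 2)
    GRanges(factor(ch, levels = names(genome)),
            IRanges(c(1L, mid, len - 1e5), width = c(1e5, 5e5, 1e5)))
  }))
  simple <- sort(.randIntervals(150L, c(50L, 500L), genome))
  micro <- sort(.randIntervals(80L, c(20L, 100L), genome))
  rep <- sort(.randIntervals(200L, c(250L, 350L), genome))
  mcols(rep)$name <- sample(c("AluY", "AluSx", "AluSq", "L1PA3", "L1HS",
                              "MIR", "L2"), length(rep), replace = TRUE)
  list(telomere_centromere = sort(telo), simple_repeat = simple,
       microsatellite = micro, repeat_element = rep)
}

.VIOLATIONS <- c("size", "region", "depth", "softclip_quality",
                 "similar_repeat")

#' Simulate a cohort of per-sample deletion calls with planted truth
#'
#' Plants `nLoci` clean deletion loci (bimodal sizes, Hardy--Weinberg
#' genotypes at drawn allele frequencies) plus `violationsPerFilter`
#' loci engineered to violate each filter rule, labeled in the truth
#' table. Carriers emit calls whose support orientation degrades from
#' `"both"` to a single orientation with a depth-dependent probability.
#' Caller QC fields (support reads, soft-clip quality, depths) are drawn
#' to be unremarkable except where a violation dictates otherwise.
#'
#' @param config a [simulationConfig()] object
#' @return list with `calls` (a [DeletionCallSet] over all samples),
#'   `truth` (`data.frame`: `locus_id`, `chrom`, `start`, `end` 0-based
#'   half-open, `length`, `af`, `violation`), `genotypes` (truth
#'   locus x sample codes), `tracks`, `samples`, `sampleDepths`
#' @export
simulateCohortCalls <- function(config) {
  tracks <- simulateAnnotationTracks(config)
  set.seed(.subSeed(config$seed, "cohort"))
  genome <- config$genome
  samples <- sprintf("S%03d", seq_len(config$nSamples))
  if (config$nSamples == 0L) {
    truth <- data.frame(locus_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        length = integer(), af = numeric(),
                        violation = character(), stringsAsFactors = FALSE)
    empty <- DeletionCallSet(data.frame(
      chrom = character(), start = integer(), end = integer(),
      support_orientation = character(), n_support_reads = integer(),
      mean_softclip_quality = numeric(), depth_del = numeric(),
      depth_flank = numeric(), genotype = character(),
      sample_id = character()))
    return(list(calls = empty, truth = truth,
                genotypes = matrix(integer(), 0L, 0L), tracks = tracks,
                samples = character(), sampleDepths = numeric()))
  }

  occupied <- c(granges(tracks$telomere_centromere),
                granges(tracks$simple_repeat),
                granges(tracks$microsatellite),
                granges(tracks$repeat_element))

  # clean loci: bimodal sizes
  mode <- sample(1:2, config$nLoci, replace = TRUE,
                 prob = config$sizeWeights)
  lens <- ifelse(
    mode == 1L,
    sample(config$smallRange[1L]:config$smallRange[2L], config$nLoci,
           replace = TRUE),
    sample(config$largeRange[1L]:config$largeRange[2L], config$nLoci,
           replace = TRUE))
  placed <- .placeClean(config$nLoci, lens, occupied, genome)
  cleanGr <- placed$intervals
  occupied <- placed$occupied

  vio <- character(0)
  vioGr <- GRanges(seqinfo = GenomeInfoDb::Seqinfo(names(genome)))
  nv <- config$violationsPerFilter
  if (nv > 0L) {
    # size violations: clean placement, 15-29 bp
    p <- .placeClean(nv, sample(15:29, nv, replace = TRUE), occupied,
                     genome)
    vioGr <- c(vioGr, p$intervals); occupied <- p$occupied
    vio <- c(vio, rep("size", nv))
    # region violations: a planted simple repeat overlapped by the body
    # (odd) or sitting within the 100 bp flank (even)
    p <- .placeClean(nv, rep(900L, nv), occupied, genome, margin = 800L)
    occupied <- p$occupied
    anchors <- p$intervals
    regionDel <- GRanges(seqinfo = GenomeInfoDb::Seqinfo(names(genome)))
    for (i in seq_len(nv)) {
      a <- start(anchors[i])
      ch <- as.character(seqnames(anchors[i]))
      repInt <- GRanges(factor(ch, levels = names(genome)),
                        IRanges(a, width = 200L))
      tracks$simple_repeat <- sort(c(tracks$simple_repeat, repInt))
      occupied <- c(occupied, repInt)
      lev <- factor(ch, levels = names(genome))
      if (i %% 2L == 1L) {
        d <- GRanges(lev, IRanges(a + 150L, width = 100L))  # body overlap
      } else {
        d <- GRanges(lev, IRanges(a + 250L, width = 100L))  # 50 bp gap
      }
      regionDel <- c(regionDel, d)
    }
    vioGr <- c(vioGr, regionDel)
    vio <- c(vio, rep("region", nv))
    # depth and soft-clip violations: clean placement, QC fields doctored
    for (lab in c("depth", "softclip_quality")) {
      p <- .placeClean(nv, sample(60:200, nv, replace = TRUE), occupied,
                       genome)
      vioGr <- c(vioGr, p$intervals); occupied <- p$occupied
      vio <- c(vio, rep(lab, nv))
    }
    # similar-repeat violations: two same-name elements, one per breakpoint
    p <- .placeClean(nv, rep(700L, nv), occupied, genome, margin = 800L)
    occupied <- p$occupied
    simDel <- GRanges(seqinfo = GenomeInfoDb::Seqinfo(names(genome)))
    for (i in seq_len(nv)) {
      a <- start(p$intervals[i])
      ch <- as.character(seqnames(p$intervals[i]))
      el <- GRanges(factor(ch, levels = names(genome)),
                    IRanges(c(a, a + 350L), width = 300L))
      mcols(el)$name <- "AluY"
      tracks$repeat_element <- sort(c(tracks$repeat_element, el))
      occupied <- c(occupied, granges(el))
      simDel <- c(simDel, GRanges(factor(ch, levels = names(genome)),
                                  IRanges(a + 150L, a + 500L)))
    }
    vioGr <- c(vioGr, simDel)
    vio <- c(vio, rep("similar_repeat", nv))
  }

  allGr <- c(cleanGr, vioGr)
  violation <- c(rep("none", length(cleanGr)), vio)
  ord <- order(as.character(seqnames(allGr)), start(allGr), end(allGr))
  allGr <- allGr[ord]; violation <- violation[ord]
  nTot <- length(allGr)
  locusIds <- sprintf("T%05d", seq_len(nTot))
  af <- runif(nTot, config$afRange[1L], config$afRange[2L])

  gt <- matrix(rbinom(nTot * config$nSamples, 2L, rep(af, config$nSamples)),
               nrow = nTot, dimnames = list(locusIds, samples))
  sampleDepths <- pmax(10, rnorm(config$nSamples, config$meanDepth,
                                 config$depthSd))
  names(sampleDepths) <- samples
  degrade <- pmin(0.9, config$degradationProb * config$meanDepth /
                    sampleDepths)

  carrier <- which(gt > 0L, arr.ind = TRUE)
  nC <- nrow(carrier)
  li <- carrier[, 1L]; si <- carrier[, 2L]
  isDeg <- runif(nC) < degrade[si]
  orient <- ifelse(isDeg,
                   sample(c("forward_only", "reverse_only"), nC,
                          replace = TRUE), "both")
  vioHere <- violation[li]
  dFlank <- sampleDepths[si] * runif(nC, 0.95, 1.05)
  dDel <- dFlank * ifelse(gt[cbind(li, si)] == 2L,
                          runif(nC, 0.05, 0.15), runif(nC, 0.5, 0.6))
  dDel[vioHere == "depth"] <- dFlank[vioHere == "depth"] *
    runif(sum(vioHere == "depth"), 1.1, 1.3) + 150
  qual <- rnorm(nC, 30, 3)
  qual[vioHere == "softclip_quality"] <-
    rnorm(sum(vioHere == "softclip_quality"), 8, 1)
  calls <- DeletionCallSet(data.frame(
    chrom = as.character(seqnames(allGr))[li],
    start = start(allGr)[li] - 1L, end = end(allGr)[li],
    support_orientation = orient,
    n_support_reads = pmax(2L, rpois(nC, sampleDepths[si] / 4)),
    mean_softclip_quality = pmax(0, qual),
    depth_del = round(dDel, 2), depth_flank = round(dFlank, 2),
    genotype = ifelse(gt[cbind(li, si)] == 2L, "hom", "het"),
    sample_id = samples[si], stringsAsFactors = FALSE))

  truth <- data.frame(locus_id = locusIds,
                      chrom = as.character(seqnames(allGr)),
                      start = start(allGr) - 1L, end = end(allGr),
                      length = width(allGr), af = af,
                      violation = violation, stringsAsFactors = FALSE)
  list(calls = calls, truth = truth, genotypes = gt, tracks = tracks,
       samples = samples, sampleDepths = sampleDepths)
}

#' Simulate long-read alignments over the planted truth
#'
#' Emits `readsPerLocus` reads per true (non-violation) locus, each with
#' a CIGAR of the form `500M <len> D 500M` whose deletion boundaries are
#' jittered by Gaussian noise of SD `jitterSd`, plus a handful of
#' deletion-free reads. Written as SAM text with proper `@SQ` headers.
#'
#' @param config a [simulationConfig()] object
#' @param truth truth table from [simulateCohortCalls()]
#' @param path output SAM path
#' @return `path`, invisibly; the file is deterministic under the seed
#' @export
simulateLongReads <- function(config, truth, path) {
  set.seed(.subSeed(config$seed, "longread"))
  genome <- config$genome
  loci <- truth[truth$violation == "none", , drop = FALSE]
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                     as.integer(genome)))
  flank <- 500L
  for (i in seq_len(nrow(loci))) {
    for (r in seq_len(config$readsPerLocus)) {
      js <- as.integer(round(rnorm(1L, 0, config$jitterSd)))
      je <- as.integer(round(rnorm(1L, 0, config$jitterSd)))
      s0 <- loci$start[i] + js          # jittered 0-based start
      e0 <- loci$end[i] + je
      if (e0 - s0 < 1L) e0 <- s0 + 1L
      pos <- s0 - flank + 1L            # SAM POS, 1-based
      cig <- sprintf("%dM%dD%dM", flank, e0 - s0, flank)
      lines <- c(lines, sprintf(
        "%s_r%d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
        loci$locus_id[i], r, loci$chrom[i], pos, cig))
    }
  }
  # background reads with no deletion
  for (k in seq_len(20L)) {
    ch <- sample(names(genome), 1L)
    pos <- floor(runif(1L, 2e5, genome[[ch]] - 2e5))
    lines <- c(lines, sprintf("bg_r%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                              k, ch, as.integer(pos), 2000L))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate an expression study with planted cis effects
#'
#' A fraction of genes receive one causal cis deletion: their TSS is
#' placed within half the cis-window of the chosen variant and their
#' expression is `beta * genotype + noise`; the remaining genes are pure
#' noise with random TSS positions. Effect signs are random; |beta| is
#' `config$effectSize` in units of the noise SD.
#'
#' @param config a [simulationConfig()] object
#' @param panel a [GenotypePanel] (its samples become the study samples)
#' @return list with `expression` (genes x samples), `tss`
#'   (`data.frame`: `gene_id`, `chrom`, `tss`), `effects`
#'   (`data.frame`: `gene_id`, `variant_id`, `beta`)
#' @export
simulateExpressionWithEffects <- function(config, panel) {
  set.seed(.subSeed(config$seed, "expression"))
  genome <- config$genome
  samples <- colnames(panel)
  nG <- config$nGenes
  geneIds <- sprintf("G%04d", seq_len(nG))
  nCausal <- round(config$causalFraction * nG)
  sites <- rowRanges(panel)
  siteIds <- rowData(panel)$locus_id
  nCausal <- min(nCausal, length(sites))
  causalGenes <- if (nCausal > 0L) sample(geneIds, nCausal) else character()
  expr <- matrix(rnorm(nG * length(samples), 0, config$noiseSd),
                 nrow = nG, dimnames = list(geneIds, samples))
  tss <- data.frame(gene_id = geneIds,
                    chrom = sample(names(genome), nG, replace = TRUE),
                    tss = NA_integer_, stringsAsFactors = FALSE)
  tss$tss <- vapply(tss$chrom, function(ch) {
    as.integer(floor(runif(1L, 2e5, genome[[ch]] - 2e5)))
  }, 1L)
  effects <- data.frame(gene_id = character(), variant_id = character(),
                        beta = numeric(), stringsAsFactors = FALSE)
  if (nCausal > 0L) {
    vidx <- sample(seq_along(sites), nCausal,
                   replace = nCausal > length(sites))
    for (k in seq_len(nCausal)) {
      g <- causalGenes[k]; v <- vidx[k]
      beta <- sample(c(-1, 1), 1L) * config$effectSize * config$noiseSd
      off <- as.integer(round(runif(1L, -5e5, 5e5)))
      row <- which(tss$gene_id == g)
      tss$chrom[row] <- as.character(seqnames(sites)[v])
      tss$tss[row] <- max(1L, start(sites)[v] + off)
      expr[g, ] <- expr[g, ] + beta * as.numeric(genotypes(panel)[v, ])
      effects <- rbind(effects, data.frame(
        gene_id = g, variant_id = siteIds[v], beta = beta,
        stringsAsFactors = FALSE))
    }
  }
  list(expression = expr, tss = tss, effects = effects)
}
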