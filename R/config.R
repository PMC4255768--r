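#' Cohort simulation configuration
#'
#' Assembles and validates the configuration consumed by
#' [simulateCohort()]. The focal block and decoy CNVs must not overlap;
#' decoy copy numbers are drawn independently of the block's, so that probe
#' intensities in decoys are uncorrelated with focal copy number by
#' construction (the repeat-rich flanking-region analogue).
#'
#' @param name configuration label.
#' @param chrom chromosome name.
#' @param regionStart,regionEnd region covered by the array (1-based,
#'   inclusive).
#' @param blockStart,blockEnd true CNV block.
#' @param decoys data.frame with \code{start}, \code{end} columns (may have
#'   zero rows).
#' @param cnRange length-2 integer range of diploid copy numbers at the
#'   block.
#' @param decoyCnRange copy-number range at decoys.
#' @param refCn reference diploid copy number (2).
#' @param nSamples cohort size.
#' @param noiseSd per-probe Gaussian noise sd (log2 units).
#' @param attenuation probe response attenuation factor in (0, 1].
#' @param probeSpacing,probeLength,jitterFrac array design parameters.
#' @param r2Threshold,minProbes,maxGapProbes block-calling thresholds
#'   packaged with the locus (see [callBlocks()]); the gap tolerance is
#'   sized to the locus: wide where the block contains a low-correlation
#'   core section, narrow for a short block with no such section.
#' @param dropout optional list(\code{start}, \code{end}, \code{nCarriers},
#'   \code{delta}): a sub-interval of the block in which \code{nCarriers}
#'   samples lose \code{delta} log2 units (polymorphic element-absence
#'   analogue).
#' @param seed default top-level seed for this configuration.
#' @return validated config list.
#' @export
cohortConfig <- function(name, chrom, regionStart, regionEnd, blockStart,
                         blockEnd, decoys = NULL, cnRange = c(2L, 7L),
                         decoyCnRange = c(1L, 4L), refCn = 2,
                         nSamples = 68L, noiseSd = 0.15, attenuation = 1,
                         probeSpacing = 400, probeLength = 50,
                         jitterFrac = 0.25, r2Threshold = 0.5,
                         minProbes = 10, maxGapProbes = 20,
                         dropout = NULL, seed = 1L) {
  region <- GRanges(chrom, IRanges(regionStart, regionEnd))
  block <- GRanges(chrom, IRanges(blockStart, blockEnd))
  dec <- if (is.null(decoys) || nrow(decoys) == 0) GRanges()
         else GRanges(chrom, IRanges(decoys$start, decoys$end))
  if (!is.null(dropout))
    dropout$interval <- GRanges(chrom, IRanges(dropout$start, dropout$end))
  cfg <- list(name = name, chrom = chrom, region = region, block = block,
              decoys = dec, cnRange = as.integer(cnRange),
              decoyCnRange = as.integer(decoyCnRange), refCn = refCn,
              nSamples = as.integer(nSamples), noiseSd = noiseSd,
              attenuation = attenuation, probeSpacing = probeSpacing,
              probeLength = probeLength, jitterFrac = jitterFrac,
              r2Threshold = r2Threshold, minProbes = minProbes,
              maxGapProbes = maxGapProbes,
              dropout = dropout, seed = as.integer(seed))
  validateCohortConfig(cfg)
}

#' @rdname cohortConfig
#' @param config a config list to validate.
#' @export
validateCohortConfig <- function(config) {
  req <- c("region", "block", "decoys", "cnRange", "decoyCnRange", "refCn",
           "nSamples", "noiseSd", "attenuation", "probeSpacing", "seed")
  miss <- setdiff(req, names(config))
  if (length(miss))
    stop("config is missing fields: ", paste(miss, collapse = ", "))
  if (config$noiseSd < 0) stop("noiseSd must be >= 0")
  if (config$attenuation <= 0 || config$attenuation > 1)
    stop("attenuation must be in (0, 1]")
  if (config$cnRange[1] > config$cnRange[2] || config$cnRange[1] < 0)
    stop("invalid cnRange")
  if (config$nSamples < 2) stop("need at least 2 samples")
  feat <- c(config$block, config$decoys)
  if (length(feat) > 1 && any(countOverlaps(feat, feat) > 1))
    stop("block and decoys must not overlap")
  if (!all(overlapsAny(feat, config$region, type = "within")))
    stop("block and decoys must lie within the region")
  if (!is.null(config$dropout)) {
    d <- config$dropout
    if (!all(c("interval", "nCarriers", "delta") %in% names(d)))
      stop("dropout needs interval, nCarriers, delta")
    if (!overlapsAny(d$interval, config$block, type = "within"))
      stop("dropout interval must lie within the block")
    if (d$nCarriers < 2 || d$nCarriers > config$nSamples / 2)
      stop("dropout nCarriers must be in [2, nSamples/2]")
  }
  config
}

#' Packaged locus configurations
#'
#' \code{humanLocusConfig()}: a 68-sample cohort with a 322-kb contiguous
#' CNV block (diploid copy numbers 2-7) flanked by two decoy CNVs inside a
#' 1-Mb tiled region at 400-bp probe spacing, probe noise sd 0.15, plus a
#' 2-kb polymorphic-dropout element carried by 12 samples (an endogenous
#' retrovirus absence analogue). \code{macaqueLocusConfig()}: a 16-sample
#' cohort with a 20-kb tandem-repeat CNV (copy numbers 3-6) inside a 982-kb
#' region at 667-bp spacing (~1.5 probes/kb) with the higher noise sd of
#' 0.25 typical of sparse designs on draft assemblies. Both configs keep the common
#' 20-probe gap tolerance when calling blocks: beyond bridging the human
#' block's weakly correlating core section, it also holds the short
#' macaque block together in cohorts whose drawn copy numbers happen to
#' span little of the 3-6 range, where per-probe r2 dips below threshold
#' in runs.
#'
#' @param seed top-level seed.
#' @return a config list for [simulateCohort()].
#' @export
humanLocusConfig <- function(seed = 1L) {
  cohortConfig(
    name = "human-like", chrom = "chr8",
    regionStart = 1, regionEnd = 1000000,
    blockStart = 300001, blockEnd = 622000,        # 322 kb
    decoys = data.frame(start = c(80001, 760001), end = c(140000, 830000)),
    cnRange = c(2L, 7L), decoyCnRange = c(1L, 4L),
    nSamples = 68L, noiseSd = 0.15, probeSpacing = 400,
    dropout = list(start = 450001, end = 452000, nCarriers = 12,
                   delta = 0.8),
    seed = seed)
}

#' @rdname humanLocusConfig
#' @export
macaqueLocusConfig <- function(seed = 1L) {
  cohortConfig(
    name = "macaque-like", chrom = "chr8",
    regionStart = 1, regionEnd = 982000,
    blockStart = 481001, blockEnd = 501000,        # 20 kb
    decoys = data.frame(start = c(100001, 800001), end = c(160000, 860000)),
    cnRange = c(3L, 6L), decoyCnRange = c(2L, 5L),
    nSamples = 16L, noiseSd = 0.25, probeSpacing = 667,
    seed = seed)
}

#' Run the full cohort analysis end to end
#'
#' Simulates (or accepts) a cohort, runs probe-copy-number correlation
#' boundary mapping, simulates the PRT/ddPCR assay panel from the cohort's
#' true copy numbers, quantifies the assays, integrates them with the aCGH
#' first principal component over the called block, and calls integer copy
#' numbers anchored on ddPCR.
#'
#' @param config a cohort config (see [cohortConfig()]).
#' @param seed top-level seed (defaults to the config's).
#' @param cohort optionally a pre-built \linkS4class{CNVCohort}.
#' @param r2Threshold,minProbes,maxGapProbes block-calling thresholds
#'   (default: the ones packaged in the config).
#' @return list with \code{cohort}, \code{track} (per-probe r2 GRanges),
#'   \code{blocks} (block calls), \code{methods} (sample x method estimate
#'   matrix), \code{calls} (integer call data.frame), \code{concordance}
#'   (pairwise method r2).
#' @export
runCohortPipeline <- function(config, seed = config$seed, cohort = NULL,
                              r2Threshold = config$r2Threshold,
                              minProbes = config$minProbes,
                              maxGapProbes = config$maxGapProbes) {
  if (is.null(cohort)) cohort <- simulateCohort(config, seed = seed)
  cn <- trueCopyNumber(cohort)
  panel <- simulateAssayPanel(cn, seed = deriveSeed(seed, "assays"))
  prtEst <- vapply(panel$prt, prtCopyNumber, numeric(1))
  ddEst <- vapply(panel$ddpcr, ddpcrCopyNumber, numeric(1))

  track <- probeCnR2(cohort, ddEst)
  blocks <- callBlocks(track, r2Threshold = r2Threshold,
                       minProbes = minProbes, maxGapProbes = maxGapProbes)
  if (length(blocks) == 0) stop("no CNV block called")
  pc1 <- blockPC1(cohort, blocks[1])

  m <- cbind(acgh = pc1, prt = prtEst[names(pc1)], ddpcr = ddEst[names(pc1)])
  conc <- methodConcordance(m)
  score <- integrateMethods(m)
  calls <- callIntegers(score, m, anchorMethod = "ddpcr")
  list(cohort = cohort, track = track, blocks = blocks, methods = m,
       calls = calls, concordance = conc, panel = panel)
}
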