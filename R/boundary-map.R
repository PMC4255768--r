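## Boundary mapping: locate the contiguous CNV block by correlating probe
## intensities with independently assayed copy number. Methods that look
## for a transition from diploid to variable copy number fail when the
## block sits inside complex repeat-rich CNV regions; correlation with an
## independent copy-number assay does not, because unrelated flanking CNVs
## are uncorrelated with the focal copy number.

#' Per-probe squared correlation with copy number
#'
#' For every probe, the squared Pearson correlation (across samples)
#' between its log2 ratios and an independently measured per-sample copy
#' number. Probes with fewer than \code{minSamples} paired observations are
#' masked (\code{NA}); probes with zero intensity variance get r2 = 0 by
#' convention, so segmentation treats them as non-supporting evidence
#' rather than missing. Pearson correlation is used deliberately: the probe
#' response is modelled as linear in log2 copy-number ratio.
#'
#' @param x a \linkS4class{CNVCohort} or a probes x samples numeric matrix.
#' @param cn named per-sample copy-number vector (names matched against
#'   sample ids).
#' @param probes probe \code{GRanges} (taken from \code{x} when it is a
#'   cohort).
#' @param minSamples minimum paired samples per probe (default 3).
#' @return the probe \code{GRanges} with metadata columns \code{r2} and
#'   \code{nUsed}.
#' @export
probeCnR2 <- function(x, cn, probes = NULL, minSamples = 3) {
  if (is(x, "CNVCohort")) {
    probes <- probes(x)
    x <- intensities(x)
  }
  if (is.null(names(cn))) names(cn) <- colnames(x)
  shared <- intersect(colnames(x), names(cn)[!is.na(cn)])
  if (length(shared) < minSamples)
    stop("need at least ", minSamples, " samples with both intensity and ",
         "copy-number values")
  m <- x[, shared, drop = FALSE]
  v <- cn[shared]
  nUsed <- rowSums(!is.na(m))
  r <- suppressWarnings(as.vector(cor(t(m), v,
                                      use = "pairwise.complete.obs")))
  r2 <- r^2
  zeroVar <- nUsed >= minSamples & is.na(r2)   # constant probe
  r2[zeroVar] <- 0
  r2[nUsed < minSamples] <- NA_real_
  out <- probes
  mcols(out)$r2 <- r2
  mcols(out)$nUsed <- as.integer(nUsed)
  out
}

#' Call contiguous CNV blocks from an r2 track
#'
#' Finds maximal runs of probes with r2 >= \code{r2Threshold}, tolerating
#' up to \code{maxGapProbes} consecutive sub-threshold probes inside a run
#' (so that a lower-correlation core section, e.g. a shared low-copy
#' repeat inside the block, does not split the call). Block edges are the
#' outermost qualifying probes; each edge also carries the flanking
#' probe-gap interval within which the true boundary must lie. Calls with
#' fewer than \code{minProbes} qualifying probes are discarded; results are
#' sorted by width, largest first.
#'
#' @param track output of [probeCnR2()].
#' @param r2Threshold qualification threshold (default 0.5).
#' @param minProbes minimum qualifying probes per call (default 10).
#' @param maxGapProbes tolerated consecutive sub-threshold probes inside a
#'   run (default 20).
#' @return \code{GRanges} of block calls with metadata columns
#'   \code{nProbes} (qualifying probes), \code{meanR2} (over the spanned
#'   probes) and boundary intervals \code{leftBoundaryStart/End},
#'   \code{rightBoundaryStart/End}; empty when nothing qualifies.
#' @export
callBlocks <- function(track, r2Threshold = 0.5, minProbes = 10,
                       maxGapProbes = 20) {
  r2 <- mcols(track)$r2
  qual <- which(!is.na(r2) & r2 >= r2Threshold)
  empty <- GRanges()
  if (length(qual) == 0) return(empty)
  ## group qualifying probes: a new run starts when more than maxGapProbes
  ## non-qualifying probes intervene
  grp <- cumsum(c(1, diff(qual) > maxGapProbes + 1))
  calls <- lapply(split(qual, grp), function(idx) {
    first <- min(idx); last <- max(idx)
    if (length(idx) < minProbes) return(NULL)
    gr <- GRanges(seqnames(track)[first],
                  IRanges(start(track)[first], end(track)[last]))
    span <- r2[first:last]
    mcols(gr)$nProbes <- length(idx)
    mcols(gr)$meanR2 <- mean(span, na.rm = TRUE)
    mcols(gr)$leftBoundaryStart <-
      if (first > 1) end(track)[first - 1] else start(track)[first]
    mcols(gr)$leftBoundaryEnd <- start(track)[first]
    mcols(gr)$rightBoundaryStart <- end(track)[last]
    mcols(gr)$rightBoundaryEnd <-
      if (last < length(track)) start(track)[last + 1] else end(track)[last]
    gr
  })
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (length(calls) == 0) return(empty)
  out <- do.call(c, unname(calls))
  out[order(width(out), decreasing = TRUE)]
}

#' Scan a called block for internal polymorphic signal dropout
#'
#' Looks for sub-runs of probes inside a block where a minority subset of
#' samples shows intensity well below the rest, relative to each sample's
#' own block-wide level - the signature of a polymorphic insertion absent
#' in the carriers (e.g. an endogenous retrovirus present in the reference
#' but missing from some genomes). Per probe, carriers are samples whose
#' residual (probe value minus the sample's block mean) falls below
#' \code{-delta}; a probe is flagged when the carrier count is between
#' \code{minCarriers} and \code{maxCarrierFrac} of the cohort, and runs of
#' at least \code{minProbes} consecutive flagged probes are reported.
#'
#' @param cohort a \linkS4class{CNVCohort}.
#' @param block a length-1 \code{GRanges} (e.g. the top [callBlocks()]
#'   call).
#' @param delta minimum signal loss in log2 units (default 0.4).
#' @param minCarriers,maxCarrierFrac carrier-subset bounds (defaults 2 and
#'   0.5).
#' @param minProbes minimum consecutive flagged probes (default 3; short
#'   enough to catch a kilobase-scale element at typical probe spacings,
#'   long enough that isolated noise-flagged probes are ignored).
#' @return \code{GRanges} of dropout intervals with metadata columns
#'   \code{nCarriers} and \code{carriers} (comma-separated sample ids);
#'   empty when nothing is found.
#' @export
dropoutScan <- function(cohort, block, delta = 0.4, minCarriers = 2,
                        maxCarrierFrac = 0.5, minProbes = 3) {
  stopifnot(is(cohort, "CNVCohort"), is(block, "GRanges"),
            length(block) == 1L)
  inBlock <- overlapsAny(probes(cohort), block)
  if (sum(inBlock) < minProbes) stop("block spans too few probes")
  lr <- intensities(cohort)[inBlock, , drop = FALSE]
  pr <- probes(cohort)[inBlock]
  resid <- sweep(lr, 2, colMeans(lr, na.rm = TRUE))
  low <- !is.na(resid) & resid < -delta
  counts <- rowSums(low)
  flagged <- counts >= minCarriers & counts <= maxCarrierFrac * ncol(lr)
  if (!any(flagged)) return(GRanges())
  idx <- which(flagged)
  grp <- cumsum(c(1, diff(idx) > 1))
  runs <- lapply(split(idx, grp), function(ii) {
    if (length(ii) < minProbes) return(NULL)
    carrierFrac <- colMeans(low[ii, , drop = FALSE])
    carriers <- colnames(lr)[carrierFrac >= 0.5]
    gr <- GRanges(seqnames(pr)[ii[1]],
                  IRanges(start(pr)[ii[1]], end(pr)[ii[length(ii)]]))
    mcols(gr)$nCarriers <- length(carriers)
    mcols(gr)$carriers <- paste(sort(carriers), collapse = ",")
    gr
  })
  runs <- runs[!vapply(runs, is.null, logical(1))]
  if (length(runs) == 0) return(GRanges())
  do.call(c, unname(runs))
}
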