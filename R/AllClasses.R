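#' @import GenomicRanges
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @import IRanges
#' @importFrom Biostrings DNAStringSet DNAString readDNAStringSet
#'   writeXStringSet translate GENETIC_CODE pairwiseAlignment
#'   nucleotideSubstitutionMatrix alignedPattern alignedSubject nmatch
NULL

#' CNVCohort: tiling-array cohort with per-sample copy-number truth
#'
#' A \linkS4class{RangedSummarizedExperiment} whose rows are tiling-array
#' probes (a \link[GenomicRanges]{GRanges} with unique \code{probe_id} names),
#' whose single assay \code{"lr"} holds per-probe, per-sample log2
#' test/reference intensity ratios, and whose \code{colData} carries the
#' per-sample diploid copy number of the focal CNV block (column
#' \code{trueCN}, populated by the simulator; \code{NA} for real cohorts).
#' Block truth, decoy CNVs and generator configuration live in
#' \code{metadata()$truth} / \code{metadata()$config}.
#'
#' @seealso [simulateCohort()], [probeCnR2()], [blockPC1()]
#' @export
setClass("CNVCohort", contains = "RangedSummarizedExperiment")

setValidity("CNVCohort", function(object) {
  msg <- NULL
  if (!"lr" %in% assayNames(object))
    msg <- c(msg, "assay 'lr' (log2 ratios) is required")
  if (is.null(names(rowRanges(object))) ||
      anyDuplicated(names(rowRanges(object))))
    msg <- c(msg, "probe ids (rownames) must be present and unique")
  if (!"trueCN" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'trueCN' column (may be NA)")
  a <- assay(object, "lr")
  if (any(!is.finite(a) & !is.na(a)))
    msg <- c(msg, "log2 ratios must be finite or NA")
  if (is.null(msg)) TRUE else msg
})

#' PRTRun: replicate paralog-ratio-test measurements for one sample
#'
#' Holds the per-replicate areas under the test and reference peaks from
#' capillary electrophoresis of a paralog ratio test (PRT), in arbitrary
#' fluorescence units. The test amplicon sits inside the CNV; the reference
#' amplicon sits at a non-CNV locus assumed to be present at two copies per
#' diploid genome.
#'
#' @slot sampleId single sample identifier.
#' @slot testArea,refArea numeric vectors of equal length (>= 1 replicate),
#'   peak areas, must be > 0 (a zero reference area invalidates a replicate
#'   and is rejected downstream, see [prtCopyNumber()]).
#' @export
setClass("PRTRun", representation(sampleId = "character",
                                  testArea = "numeric",
                                  refArea = "numeric"))

setValidity("PRTRun", function(object) {
  if (length(object@sampleId) != 1L) return("sampleId must be length 1")
  if (length(object@testArea) < 1L) return("at least one replicate required")
  if (length(object@testArea) != length(object@refArea))
    return("testArea and refArea must have equal length")
  if (any(object@testArea < 0) || any(object@refArea < 0))
    return("peak areas must be non-negative")
  TRUE
})

#' @rdname PRTRun-class
#' @param sampleId sample identifier.
#' @param testArea,refArea replicate peak areas.
#' @export
PRTRun <- function(sampleId, testArea, refArea) {
  new("PRTRun", sampleId = as.character(sampleId),
      testArea = as.numeric(testArea), refArea = as.numeric(refArea))
}

#' DdpcrRun: droplet digital PCR replicate counts for one sample
#'
#' Per-replicate droplet counts from a duplex ddPCR: total droplets read and
#' droplets positive for the test (CNV) and reference (diploid control)
#' amplicons. Copy number is recovered by Poisson inversion of the negative
#' fractions ([ddpcrLambda()], [ddpcrCopyNumber()]).
#'
#' @slot sampleId single sample identifier.
#' @slot nDroplets,nTestPositive,nRefPositive integer vectors, one entry per
#'   replicate; positives cannot exceed droplets.
#' @slot saturated logical per replicate: all droplets positive in a channel
#'   at generation time (estimate undefined).
#' @export
setClass("DdpcrRun", representation(sampleId = "character",
                                    nDroplets = "numeric",
                                    nTestPositive = "numeric",
                                    nRefPositive = "numeric",
                                    saturated = "logical"))

setValidity("DdpcrRun", function(object) {
  n <- length(object@nDroplets)
  if (length(object@sampleId) != 1L) return("sampleId must be length 1")
  if (n < 1L) return("at least one replicate required")
  if (length(object@nTestPositive) != n || length(object@nRefPositive) != n ||
      length(object@saturated) != n)
    return("replicate vectors must have equal length")
  if (any(object@nTestPositive > object@nDroplets) ||
      any(object@nRefPositive > object@nDroplets))
    return("positive counts cannot exceed droplet counts")
  if (any(c(object@nDroplets, object@nTestPositive, object@nRefPositive) < 0))
    return("counts must be non-negative")
  TRUE
})

#' @rdname DdpcrRun-class
#' @param sampleId sample identifier.
#' @param nDroplets,nTestPositive,nRefPositive per-replicate counts.
#' @param saturated per-replicate saturation flag.
#' @export
DdpcrRun <- function(sampleId, nDroplets, nTestPositive, nRefPositive,
                     saturated = rep(FALSE, length(nDroplets))) {
  new("DdpcrRun", sampleId = as.character(sampleId),
      nDroplets = as.numeric(nDroplets),
      nTestPositive = as.numeric(nTestPositive),
      nRefPositive = as.numeric(nRefPositive),
      saturated = as.logical(saturated))
}

#' QpcrRun: real-time quantitative PCR measurement for one sample
#'
#' Ct values for test and reference amplifications plus the standard curves
#' (log10 input quantity vs Ct) generated for each assay from known-quantity
#' standards, from which per-assay amplification efficiencies are estimated
#' ([qpcrStandardCurve()], [qpcrCopyNumber()]).
#'
#' @slot sampleId single sample identifier.
#' @slot ctTest,ctRef cycle-threshold values (> 0).
#' @slot curveTest,curveRef data.frames with columns \code{log10Quantity}
#'   and \code{ct}, at least two distinct quantities each.
#' @export
setClass("QpcrRun", representation(sampleId = "character",
                                   ctTest = "numeric", ctRef = "numeric",
                                   curveTest = "data.frame",
                                   curveRef = "data.frame"))

setValidity("QpcrRun", function(object) {
  if (object@ctTest <= 0 || object@ctRef <= 0) return("Ct values must be > 0")
  for (nm in c("curveTest", "curveRef")) {
    cv <- slot(object, nm)
    if (!all(c("log10Quantity", "ct") %in% colnames(cv)))
      return(sprintf("%s needs columns log10Quantity, ct", nm))
    if (length(unique(cv$log10Quantity)) < 2L)
      return(sprintf("%s needs >= 2 distinct quantities", nm))
  }
  TRUE
})

#' @rdname QpcrRun-class
#' @param sampleId sample identifier.
#' @param ctTest,ctRef observed Ct values.
#' @param curveTest,curveRef standard-curve data.frames
#'   (\code{log10Quantity}, \code{ct}).
#' @export
QpcrRun <- function(sampleId, ctTest, ctRef, curveTest, curveRef) {
  new("QpcrRun", sampleId = as.character(sampleId), ctTest = ctTest,
      ctRef = ctRef, curveTest = curveTest, curveRef = curveRef)
}

#' HaplotypeSet: paralog- and allele-labelled coding sequences
#'
#' In-frame coding sequences of one CNV gene, each labelled with the
#' haplotype it was phased to (e.g. a fully sequenced BAC clone, which
#' derives from a single chromosome homolog) and its paralog position on
#' that haplotype (\code{"proximal"} or \code{"distal"} copy of the tandem
#' repeat). Differences between positions within a haplotype are paralog
#' divergence; differences between haplotypes at the same position are
#' allelic diversity.
#'
#' @slot sequences a \link[Biostrings]{DNAStringSet}, equal widths, length
#'   divisible by 3, no internal stop codons in frame.
#' @slot haplotype,position character vectors parallel to \code{sequences}.
#' @slot truth list of generator truth labels (empty for real data).
#' @export
setClass("HaplotypeSet", representation(sequences = "DNAStringSet",
                                        haplotype = "character",
                                        position = "character",
                                        truth = "list"))

setValidity("HaplotypeSet", function(object) {
  n <- length(object@sequences)
  if (n < 1L) return("at least one sequence required")
  if (length(object@haplotype) != n || length(object@position) != n)
    return("labels must parallel sequences")
  w <- Biostrings::width(object@sequences)
  if (length(unique(w)) != 1L) return("sequences must share one length")
  if (w[1] %% 3L != 0L) return("length must be divisible by 3")
  if (!all(object@position %in% c("proximal", "distal")))
    return("position must be 'proximal' or 'distal'")
  aa <- as.character(Biostrings::translate(object@sequences,
                                           if.fuzzy.codon = "X"))
  if (any(grepl("\\*", sub("\\*$", "", aa))))
    return("internal stop codon in reading frame")
  TRUE
})

#' @rdname HaplotypeSet-class
#' @param sequences DNAStringSet (or character) of in-frame CDS.
#' @param haplotype,position parallel label vectors.
#' @param truth optional generator truth list.
#' @export
HaplotypeSet <- function(sequences, haplotype, position, truth = list()) {
  if (!is(sequences, "DNAStringSet")) sequences <- DNAStringSet(sequences)
  new("HaplotypeSet", sequences = sequences,
      haplotype = as.character(haplotype), position = as.character(position),
      truth = truth)
}

#' MKCounts: divergence/diversity substitution counts
#'
#' The 2x2 contingency structure of a paralog-versus-allele
#' McDonald-Kreitman comparison: nonsynonymous and synonymous changes
#' between paralogs within haplotypes (divergence) and between alleles at
#' the same paralog position (diversity), with Jukes-Cantor multiple-hit
#' corrected counterparts and the synonymous/nonsynonymous site totals used
#' as correction denominators.
#'
#' @slot counts 2x2 numeric matrix, rows \code{divergence}/\code{diversity},
#'   columns \code{nonsyn}/\code{syn} (pathway counting yields fractional
#'   values).
#' @slot corrected like \code{counts} after Jukes-Cantor correction
#'   (\code{NA} where applied without correction).
#' @slot sites named numeric \code{c(nonsyn=, syn=)} site totals.
#' @slot nHaplotypes number of haplotypes contributing.
#' @export
setClass("MKCounts", representation(counts = "matrix", corrected = "matrix",
                                    sites = "numeric",
                                    nHaplotypes = "integer"))

setValidity("MKCounts", function(object) {
  dn <- list(c("divergence", "diversity"), c("nonsyn", "syn"))
  if (!identical(dimnames(object@counts), dn))
    return("counts must be 2x2 with divergence/diversity x nonsyn/syn")
  if (any(object@counts < 0)) return("counts must be non-negative")
  ok <- is.finite(object@corrected)
  if (any(object@corrected[ok] < object@counts[ok] - 1e-9))
    return("corrected counts cannot fall below raw counts")
  TRUE
})

#' MKResult: outcome of a McDonald-Kreitman test
#'
#' @slot table the integer 2x2 table tested (rows divergence/diversity,
#'   columns nonsyn/syn).
#' @slot pValue two-sided Fisher exact p-value.
#' @slot neutralityIndex (diversity_nonsyn/diversity_syn) /
#'   (divergence_nonsyn/divergence_syn); \code{NA} when a denominator is 0.
#' @slot direction \code{"positive"}, \code{"negative"} or \code{"neutral"}.
#' @slot informative FALSE when a margin was all zero (p forced to 1).
#' @export
setClass("MKResult", representation(table = "matrix", pValue = "numeric",
                                    neutralityIndex = "numeric",
                                    direction = "character",
                                    informative = "logical"))

#' HMMModel: Gaussian-emission copy-number-state HMM
#'
#' A univariate hidden Markov model over an ordered log2-ratio probe track,
#' with one Gaussian emission distribution per copy-number state (typically
#' loss / neutral / gain) and a single conservative probability of switching
#' between distinct states (default 1e-6), used by [hmmSegment()] to place
#' CNV breakpoints between probes.
#'
#' @slot stateNames state labels, ordered by mean.
#' @slot means,sds per-state emission mean and sd (log2-ratio units; sds > 0).
#' @slot transProb probability of moving to any one *other* state per step.
#' @slot initProb initial state probabilities (sum to 1).
#' @export
setClass("HMMModel", representation(stateNames = "character",
                                    means = "numeric", sds = "numeric",
                                    transProb = "numeric",
                                    initProb = "numeric"))

setValidity("HMMModel", function(object) {
  k <- length(object@stateNames)
  if (k < 2L) return("need at least two states")
  if (length(object@means) != k || length(object@sds) != k ||
      length(object@initProb) != k)
    return("means, sds, initProb must match number of states")
  if (any(object@sds <= 0)) return("emission sds must be > 0")
  if (anyDuplicated(object@means)) return("emission means must be distinct")
  if (object@transProb <= 0 || object@transProb * (k - 1) >= 1)
    return("transProb must satisfy 0 < (k-1)*transProb < 1")
  if (abs(sum(object@initProb) - 1) > 1e-8)
    return("initProb must sum to 1")
  TRUE
})

#' @rdname HMMModel-class
#' @param means,sds per-state Gaussian emission parameters.
#' @param stateNames state labels (default loss/neutral/gain patterns for 3
#'   states, otherwise \code{S1..Sk}).
#' @param transProb per-step probability of switching to any one other state.
#' @param initProb initial distribution (default uniform).
#' @export
HMMModel <- function(means, sds, stateNames = NULL, transProb = 1e-6,
                     initProb = NULL) {
  k <- length(means)
  if (length(sds) == 1L) sds <- rep(sds, k)
  if (is.null(stateNames))
    stateNames <- if (k == 3L) c("loss", "neutral", "gain")
                  else paste0("S", seq_len(k))
  if (is.null(initProb)) initProb <- rep(1 / k, k)
  o <- order(means)
  new("HMMModel", stateNames = stateNames[o], means = as.numeric(means[o]),
      sds = as.numeric(sds[o]), transProb = transProb,
      initProb = as.numeric(initProb[o]))
}

#' Transition matrix of an HMMModel
#' @param model an \linkS4class{HMMModel}.
#' @return k x k row-stochastic matrix.
#' @export
transitionMatrix <- function(model) {
  k <- length(model@stateNames)
  m <- matrix(model@transProb, k, k,
              dimnames = list(model@stateNames, model@stateNames))
  diag(m) <- 1 - (k - 1) * model@transProb
  m
}

#' InsertionMatrix: diagnostic-marker presence/absence across lineages
#'
#' Presence or absence of duplication-diagnostic mobile-element insertions
#' (e.g. an AluY-family SINE, an L1 LINE) across lineages with known
#' divergence times from the focal lineage, plus optional published
#' subfamily-age estimates per marker. Input to [markerWindow()] and
#' [duplicationBracket()].
#'
#' @slot lineages data.frame with columns \code{lineage},
#'   \code{divergenceMa} (> 0; the focal lineage itself may be encoded with
#'   a divergence of 0 and is then uninformative for upper bounds).
#' @slot status character matrix markers x lineages with entries
#'   \code{"present"}, \code{"absent"} or \code{"unknown"}. A lineage in
#'   which the marker segregates (present in some individuals) is encoded
#'   \code{"present"}: presence anywhere in the lineage establishes the
#'   marker's age; record the polymorphism in \code{notes}.
#' @slot markerAges named numeric, published subfamily age (Ma) per marker,
#'   \code{NA} when unknown.
#' @slot notes free-form metadata list (e.g. polymorphic lineages).
#' @export
setClass("InsertionMatrix", representation(lineages = "data.frame",
                                           status = "matrix",
                                           markerAges = "numeric",
                                           notes = "list"))

setValidity("InsertionMatrix", function(object) {
  if (!all(c("lineage", "divergenceMa") %in% colnames(object@lineages)))
    return("lineages needs columns lineage, divergenceMa")
  if (any(object@lineages$divergenceMa < 0))
    return("divergence times must be >= 0")
  if (nrow(object@status) < 1L) return("at least one marker required")
  if (!identical(colnames(object@status), object@lineages$lineage))
    return("status columns must match lineages")
  if (!all(object@status %in% c("present", "absent", "unknown")))
    return("status entries must be present/absent/unknown")
  if (!identical(names(object@markerAges), rownames(object@status)))
    return("markerAges must be named by marker")
  TRUE
})

#' @rdname InsertionMatrix-class
#' @param lineages data.frame (\code{lineage}, \code{divergenceMa}).
#' @param status marker x lineage character matrix.
#' @param markerAges optional named subfamily ages (Ma).
#' @param notes metadata list.
#' @export
InsertionMatrix <- function(lineages, status, markerAges = NULL,
                            notes = list()) {
  status <- as.matrix(status)
  if (is.null(colnames(status))) colnames(status) <- lineages$lineage
  if (is.null(markerAges)) {
    markerAges <- rep(NA_real_, nrow(status))
    names(markerAges) <- rownames(status)
  } else {
    markerAges <- markerAges[rownames(status)]
    names(markerAges) <- rownames(status)
  }
  new("InsertionMatrix", lineages = lineages, status = status,
      markerAges = markerAges, notes = notes)
}

#' AgeBracket: bracketed age of a duplication event
#'
#' @slot minAge,maxAge bounds in Ma (million years), \code{maxAge >= minAge}.
#' @slot evidence character vector describing the supporting markers.
#' @export
setClass("AgeBracket", representation(minAge = "numeric", maxAge = "numeric",
                                      evidence = "character"))

setValidity("AgeBracket", function(object) {
  if (object@minAge <= 0) return("minAge must be > 0")
  if (object@maxAge < object@minAge) return("maxAge must be >= minAge")
  TRUE
})
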