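#' Accessors for CNVCohort objects
#'
#' \code{probes()} returns the probe \code{GRanges}; \code{intensities()}
#' the log2-ratio matrix (probes x samples); \code{trueCopyNumber()} the
#' per-sample diploid copy number at the focal block (NA for real cohorts);
#' \code{truthBlock()} the simulated block interval, or \code{NULL}.
#'
#' @param x a \linkS4class{CNVCohort}.
#' @name CNVCohort-accessors
NULL

#' @rdname CNVCohort-accessors
#' @export
setGeneric("probes", function(x) standardGeneric("probes"))

#' @rdname CNVCohort-accessors
#' @export
setMethod("probes", "CNVCohort", function(x) rowRanges(x))

#' @rdname CNVCohort-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname CNVCohort-accessors
#' @export
setMethod("intensities", "CNVCohort", function(x) assay(x, "lr"))

#' @rdname CNVCohort-accessors
#' @export
setGeneric("trueCopyNumber", function(x) standardGeneric("trueCopyNumber"))

#' @rdname CNVCohort-accessors
#' @export
setMethod("trueCopyNumber", "CNVCohort", function(x) {
  cn <- colData(x)$trueCN
  names(cn) <- colnames(x)
  cn
})

#' @rdname CNVCohort-accessors
#' @export
setGeneric("truthBlock", function(x) standardGeneric("truthBlock"))

#' @rdname CNVCohort-accessors
#' @export
setMethod("truthBlock", "CNVCohort", function(x) metadata(x)$truth$block)

setMethod("show", "PRTRun", function(object) {
  r <- prtRatios(object)
  cat("PRTRun for sample", object@sampleId, "-", length(r),
      "replicate(s); mean test/ref ratio",
      format(mean(r, na.rm = TRUE), digits = 4), "\n")
})

setMethod("show", "DdpcrRun", function(object) {
  cat("DdpcrRun for sample", object@sampleId, "-",
      length(object@nDroplets), "replicate(s),",
      "droplets:", paste(object@nDroplets, collapse = ", "), "\n")
})

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet:", length(object@sequences), "CDS of",
      Biostrings::width(object@sequences)[1], "bp;",
      length(unique(object@haplotype)), "haplotype(s)\n")
  for (h in unique(object@haplotype))
    cat("  ", h, ": ",
        paste(object@position[object@haplotype == h], collapse = " + "),
        "\n", sep = "")
})

setMethod("show", "MKCounts", function(object) {
  cat("MKCounts over", object@nHaplotypes, "haplotype(s)\n")
  cat("raw counts:\n"); print(round(object@counts, 3))
  if (all(is.finite(object@corrected))) {
    cat("Jukes-Cantor corrected:\n"); print(round(object@corrected, 3))
  }
  cat("sites: nonsyn", round(object@sites["nonsyn"], 1),
      "/ syn", round(object@sites["syn"], 1), "\n")
})

setMethod("show", "MKResult", function(object) {
  cat("McDonald-Kreitman test\n")
  print(object@table)
  cat("p =", format(object@pValue, digits = 3),
      " NI =", format(object@neutralityIndex, digits = 3),
      " direction:", object@direction,
      if (!object@informative) " (uninformative table)" else "", "\n")
})

setMethod("show", "HMMModel", function(object) {
  cat("Gaussian-emission HMM,", length(object@stateNames), "states\n")
  print(data.frame(state = object@stateNames, mean = object@means,
                   sd = object@sds))
  cat("inter-state transition probability:", object@transProb, "\n")
})

setMethod("show", "InsertionMatrix", function(object) {
  cat("InsertionMatrix:", nrow(object@status), "marker(s) x",
      ncol(object@status), "lineage(s)\n")
  print(object@status)
})

setMethod("show", "AgeBracket", function(object) {
  cat("Duplication age bracket: between", object@minAge, "and",
      object@maxAge, "Ma\n")
  for (e in object@evidence) cat("  -", e, "\n")
})
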