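## Assay quantification: PRT, ddPCR and qPCR measurements -> per-sample
## continuous copy-number estimates on the diploid scale.

#' Replicate test/reference peak-area ratios of a PRT run
#'
#' Replicates with a zero reference area are rejected (returned as
#' \code{NA}).
#'
#' @param run a \linkS4class{PRTRun}.
#' @return numeric vector of ratios, \code{NA} for rejected replicates.
#' @export
prtRatios <- function(run) {
  stopifnot(is(run, "PRTRun"))
  ifelse(run@refArea > 0, run@testArea / run@refArea, NA_real_)
}

#' PRT relative copy number
#'
#' The average of the replicate test/reference ratios, scaled by the
#' reference-locus diploid copy number (2 for a non-CNV reference locus),
#' taken to represent the sample's diploid-scale relative copy number.
#'
#' @param run a \linkS4class{PRTRun}.
#' @param refCn diploid copy number of the reference locus.
#' @return single numeric estimate.
#' @examples
#' prtCopyNumber(PRTRun("s1", testArea = rep(1.5, 5), refArea = rep(1, 5)))
#' @export
prtCopyNumber <- function(run, refCn = 2) {
  r <- prtRatios(run)
  if (all(is.na(r)))
    stop("all replicates rejected (zero reference areas) for sample ",
         run@sampleId)
  refCn * mean(r, na.rm = TRUE)
}

#' Poisson inversion of a droplet-PCR negative fraction
#'
#' The mean number of target molecules per droplet given \code{nNegative}
#' negative droplets out of \code{nDroplets}:
#' \eqn{\lambda = -\ln(n_{neg}/n_{tot})}. The standard digital-PCR
#' concentration estimator.
#'
#' @param nNegative negative droplet count (> 0; 0 means saturation and is
#'   an error).
#' @param nDroplets total droplets (>= nNegative).
#' @return lambda, mean molecules per droplet.
#' @examples
#' ddpcrLambda(3679, 10000)  # ~1.0
#' @export
ddpcrLambda <- function(nNegative, nDroplets) {
  if (nDroplets <= 0) stop("nDroplets must be > 0")
  if (nNegative > nDroplets) stop("nNegative cannot exceed nDroplets")
  if (nNegative == 0)
    stop("all droplets positive: assay saturated, lambda undefined")
  -log(nNegative / nDroplets)
}

#' ddPCR diploid copy number
#'
#' Per replicate, copy number is \code{refCn * lambda_test / lambda_ref}
#' with each lambda obtained by Poisson inversion ([ddpcrLambda()]).
#' Replicates with \code{nDroplets <= minDroplets} fail QC and are excluded
#' from the average; the per-sample value is the mean of the remaining
#' replicates.
#'
#' @param run a \linkS4class{DdpcrRun}.
#' @param minDroplets QC threshold: a replicate must have strictly more
#'   droplets than this to be used (default 10000).
#' @param refCn reference diploid copy number.
#' @return single numeric estimate; attribute \code{"nUsed"} gives the
#'   number of replicates passing QC.
#' @export
ddpcrCopyNumber <- function(run, minDroplets = 10000, refCn = 2) {
  stopifnot(is(run, "DdpcrRun"))
  keep <- run@nDroplets > minDroplets & !run@saturated
  if (!any(keep))
    stop("no replicate passed QC (> ", minDroplets, " droplets) for sample ",
         run@sampleId)
  est <- vapply(which(keep), function(i) {
    negT <- run@nDroplets[i] - run@nTestPositive[i]
    negR <- run@nDroplets[i] - run@nRefPositive[i]
    lamT <- ddpcrLambda(negT, run@nDroplets[i])
    lamR <- ddpcrLambda(negR, run@nDroplets[i])
    if (lamR == 0)
      stop("no reference molecules detected for sample ", run@sampleId)
    refCn * lamT / lamR
  }, numeric(1))
  structure(mean(est), nUsed = sum(keep))
}

#' Fit a qPCR standard curve
#'
#' Least-squares line of Ct against log10 input quantity; the amplification
#' efficiency is \code{10^(-1/slope)} (2 for perfect doubling, slope
#' -3.3219).
#'
#' @param points data.frame with columns \code{log10Quantity}, \code{ct}.
#' @return list with \code{slope}, \code{intercept}, \code{efficiency},
#'   \code{residuals}.
#' @export
qpcrStandardCurve <- function(points) {
  if (!all(c("log10Quantity", "ct") %in% colnames(points)))
    stop("points needs columns log10Quantity, ct")
  if (length(unique(points$log10Quantity)) < 2)
    stop("need at least two distinct standard quantities")
  fit <- lm(ct ~ log10Quantity, data = points)
  slope <- unname(coef(fit)[2])
  list(slope = slope, intercept = unname(coef(fit)[1]),
       efficiency = 10^(-1 / slope), residuals = unname(fit$residuals))
}

#' qPCR diploid copy number by efficiency-corrected delta-Ct
#'
#' Computes the efficiency-corrected abundance ratio
#' \eqn{R = E_{ref}^{Ct_{ref}} / E_{test}^{Ct_{test}}} with per-assay
#' efficiencies from the standard curves, then normalizes against the same
#' ratio in a calibrator sample of known diploid copy number:
#' \code{calibratorCn * R_sample / R_calibrator}. Without a calibrator the
#' raw ratio is returned with attribute \code{"uncalibrated" = TRUE} and a
#' warning.
#'
#' @param run a \linkS4class{QpcrRun}.
#' @param calibrator a \linkS4class{QpcrRun} of a sample with known copy
#'   number, or \code{NULL}.
#' @param calibratorCn the calibrator's known diploid copy number.
#' @return single numeric estimate.
#' @export
qpcrCopyNumber <- function(run, calibrator = NULL, calibratorCn = 2) {
  stopifnot(is(run, "QpcrRun"))
  eT <- qpcrStandardCurve(run@curveTest)$efficiency
  eR <- qpcrStandardCurve(run@curveRef)$efficiency
  ratio <- function(r) eR^r@ctRef / eT^r@ctTest
  if (is.null(calibrator)) {
    warning("no calibrator: returning un-normalized qPCR ratio")
    return(structure(ratio(run), uncalibrated = TRUE))
  }
  calibratorCn * ratio(run) / ratio(calibrator)
}

#' Calibrate continuous estimates onto the integer copy-number scale
#'
#' Least-squares affine map of per-sample values onto a set of anchor
#' samples with asserted integer copy numbers; with fewer than two distinct
#' anchor values the identity map is returned with a warning.
#'
#' @param values named numeric vector of per-sample estimates.
#' @param anchors named numeric vector of asserted integer copy numbers for
#'   a subset of samples.
#' @return calibrated values (same names).
#' @export
calibrateToIntegerScale <- function(values, anchors = NULL) {
  if (is.null(anchors) || length(anchors) == 0) return(values)
  shared <- intersect(names(values), names(anchors))
  if (length(unique(values[shared])) < 2 || length(shared) < 2) {
    warning("need >= 2 anchors with distinct values; returning identity map")
    return(values)
  }
  fit <- lm(anchors[shared] ~ values[shared])
  unname(coef(fit)[1]) + unname(coef(fit)[2]) * values
}
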