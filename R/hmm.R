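## Gaussian-emission HMM segmentation of a single log2-ratio probe track.
## A deliberately simple univariate analogue of bivariate breakpoint
## HMMs trained on sequence features: states are copy-number levels
## (loss / neutral / gain), emissions are Gaussian, and a single small
## inter-state transition probability (default 1e-6) makes state switches
## expensive, suppressing single-probe outlier segments.

#' Viterbi segmentation of a log2-ratio track
#'
#' Computes the maximum-likelihood state path of \code{values} under
#' \code{model} by Viterbi decoding in log space, and reports every state
#' change as a breakpoint. Boundaries are intervals, never point
#' estimates: each breakpoint spans from the last probe of the left-hand
#' state to the first probe of the right-hand state (the true breakpoint
#' can lie anywhere in the inter-probe gap).
#'
#' @param values ordered numeric log2-ratio track (>= 2 probes, no NA).
#' @param model an \linkS4class{HMMModel}.
#' @param probes optional \code{GRanges} parallel to \code{values}; when
#'   supplied, breakpoints carry genomic coordinates (from the end of the
#'   last left-state probe to the start of the first right-state probe).
#' @return list with \code{states} (character vector of state labels per
#'   probe) and \code{breakpoints} (data.frame with \code{leftIndex},
#'   \code{rightIndex}, \code{fromState}, \code{toState} and, with probes,
#'   \code{chrom}, \code{start}, \code{end}).
#' @export
hmmSegment <- function(values, model, probes = NULL) {
  stopifnot(is(model, "HMMModel"))
  validObject(model)
  if (length(values) < 2) stop("need at least 2 probes")
  if (anyNA(values)) stop("track must not contain NA values")
  if (!is.null(probes)) stopifnot(length(probes) == length(values))

  k <- length(model@stateNames)
  n <- length(values)
  logTrans <- log(transitionMatrix(model))
  logEmit <- vapply(seq_len(k), function(s)
    dnorm(values, model@means[s], model@sds[s], log = TRUE),
    numeric(n))                               # n x k
  delta <- matrix(-Inf, n, k)
  psi <- matrix(0L, n, k)
  delta[1, ] <- log(model@initProb) + logEmit[1, ]
  for (t in 2:n) {
    for (s in seq_len(k)) {
      cand <- delta[t - 1, ] + logTrans[, s]
      psi[t, s] <- which.max(cand)
      delta[t, s] <- cand[psi[t, s]] + logEmit[t, s]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  states <- model@stateNames[path]

  chg <- which(diff(path) != 0)
  bp <- data.frame(leftIndex = chg, rightIndex = chg + 1L,
                   fromState = states[chg], toState = states[chg + 1L])
  if (!is.null(probes) && nrow(bp) > 0) {
    bp$chrom <- as.character(seqnames(probes))[bp$leftIndex]
    bp$start <- end(probes)[bp$leftIndex]
    bp$end <- start(probes)[bp$rightIndex]
  }
  list(states = states, breakpoints = bp)
}

#' Default three-state copy-number HMM
#'
#' Loss / neutral / gain states with means at \code{log2(1/2)}, 0 and
#' \code{log2(3/2)} (one copy lost or gained against a diploid reference)
#' and a common emission sd.
#'
#' @param sd emission standard deviation (log2 units).
#' @param transProb inter-state transition probability (default 1e-6).
#' @return an \linkS4class{HMMModel}.
#' @export
copyNumberHMM <- function(sd = 0.2, transProb = 1e-6) {
  HMMModel(means = c(log2(1 / 2), 0, log2(3 / 2)), sds = sd,
           transProb = transProb)
}
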