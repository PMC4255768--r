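## Copy-number integration: fuse aCGH, PRT and ddPCR estimates into one
## per-sample score and call integer diploid copy numbers.

#' First principal component of block intensities
#'
#' Per-sample score summarizing the aCGH signal over a called CNV block:
#' the first principal component of the sample x probe matrix (probes as
#' variables), sign-oriented to correlate positively with each sample's
#' mean block intensity, so larger scores mean more copies.
#'
#' @param cohort a \linkS4class{CNVCohort} (or probes x samples matrix with
#'   \code{probes} supplied).
#' @param block length-1 \code{GRanges} delimiting the block.
#' @param probes probe \code{GRanges} when \code{cohort} is a bare matrix.
#' @return named numeric vector of per-sample PC1 scores; attribute
#'   \code{"varExplained"} gives PC1's share of total variance.
#' @export
blockPC1 <- function(cohort, block, probes = NULL) {
  if (is(cohort, "CNVCohort")) {
    probes <- probes(cohort)
    lr <- intensities(cohort)
  } else lr <- cohort
  stopifnot(is(block, "GRanges"), length(block) == 1L)
  inBlock <- overlapsAny(probes, block)
  if (sum(inBlock) < 2) stop("block must span at least 2 probes")
  if (ncol(lr) < 2) stop("need at least 2 samples")
  X <- t(lr[inBlock, , drop = FALSE])         # samples x probes
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  }
  if (sum(apply(X, 2, var)) == 0) stop("zero variance over the block")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  score <- pc$x[, 1]
  if (cor(score, rowMeans(X)) < 0) score <- -score
  structure(score, varExplained = pc$sdev[1]^2 / sum(pc$sdev^2))
}

#' Pairwise squared correlation between copy-number methods
#'
#' Symmetric matrix of squared Pearson correlations between the columns of
#' a sample x method estimate matrix; pairs sharing fewer than
#' \code{minShared} samples are \code{NA}.
#'
#' @param m numeric matrix, samples x methods.
#' @param minShared minimum paired samples per entry (default 3).
#' @return method x method r2 matrix with unit diagonal.
#' @export
methodConcordance <- function(m, minShared = 3) {
  stopifnot(is.matrix(m), ncol(m) >= 1)
  r2 <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))^2
  shared <- crossprod(!is.na(m))
  r2[shared < minShared] <- NA_real_
  diag(r2) <- 1
  r2
}

#' Integrate copy-number methods by principal components
#'
#' First principal component of the per-method standardized sample x
#' method matrix - a single per-sample figure reflecting copy number that
#' pools the methods' shared signal. Standardization makes the result
#' invariant to per-method affine rescaling. Constant methods are dropped
#' with a warning; missing values are mean-imputed within method. The
#' score is sign-oriented to correlate positively with the \code{ddpcr}
#' column when present (first column otherwise).
#'
#' @param m numeric matrix, samples x methods (>= 2 samples).
#' @param orientTo column name used for sign orientation.
#' @return named numeric vector of integrated scores (standardized scale).
#' @export
integrateMethods <- function(m, orientTo = "ddpcr") {
  stopifnot(is.matrix(m), nrow(m) >= 2)
  const <- apply(m, 2, function(x) var(x, na.rm = TRUE) == 0 ||
                                    all(is.na(x)))
  if (any(const)) {
    warning("dropping constant method(s): ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  if (ncol(m) == 0) stop("no non-constant method left")
  for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- mean(m[, j],
                                                          na.rm = TRUE)
  z <- scale(m)
  if (ncol(z) == 1) return(structure(z[, 1], names = rownames(m)))
  score <- prcomp(z, center = FALSE, scale. = FALSE)$x[, 1]
  ref <- if (orientTo %in% colnames(z)) z[, orientTo] else z[, 1]
  if (cor(score, ref) < 0) score <- -score
  names(score) <- rownames(m)
  score
}

#' Call integer copy numbers from an integrated score
#'
#' Maps the integrated score onto the anchor method's diploid scale by
#' least squares, then rounds to the nearest integer (ties round half away
#' from zero). ddPCR is the default anchor: as an absolute molecule-
#' counting method its estimates cluster about integer copy numbers.
#' Per-sample confidence is \code{1 - 2 * |mapped - round(mapped)|} (1 at
#' an integer, 0 halfway between two).
#'
#' @param score named numeric integrated score (e.g. from
#'   [integrateMethods()]).
#' @param m the sample x method matrix holding the anchor column.
#' @param anchorMethod anchor column name (default \code{"ddpcr"}).
#' @return data.frame with columns \code{sample}, \code{cn},
#'   \code{confidence}, \code{anchor}, \code{lowConfidence}.
#' @export
callIntegers <- function(score, m, anchorMethod = "ddpcr") {
  low <- FALSE
  if (!is.null(m) && anchorMethod %in% colnames(m)) {
    anchor <- m[names(score), anchorMethod]
    fit <- lm(anchor ~ score)
    mapped <- unname(coef(fit)[1]) + unname(coef(fit)[2]) * score
  } else {
    warning("anchor method '", anchorMethod,
            "' missing: rounding the raw score, flagged low-confidence")
    mapped <- score
    low <- TRUE
  }
  cn <- as.integer(roundHalfAwayFromZero(mapped))
  cn[cn < 0] <- 0L
  data.frame(sample = names(score), cn = cn,
             confidence = 1 - 2 * abs(mapped - roundHalfAwayFromZero(mapped)),
             anchor = if (low) NA_character_ else anchorMethod,
             lowConfidence = low, row.names = NULL)
}
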