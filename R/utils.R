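#' @importFrom methods new validObject is setClass setGeneric setMethod show
#' @importFrom stats lm coef prcomp rnorm runif rbinom rpois
#'   fisher.test dnorm
#' @importFrom utils head tail read.table write.table packageVersion
NULL

## All randomness flows from one top-level seed through named substreams so
## that e.g. the PRT noise draw does not shift when the cohort layout changes.
deriveSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629)
}

withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

## declared tie convention for integer copy-number calls
roundHalfAwayFromZero <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

configHash <- function(config) {
  rlang::hash(config)
}

## header comment lines stamped on every output file
fileHeader <- function(seed = NA, config = NULL) {
  c(sprintf("# defensinCNV %s", as.character(packageVersion("defensinCNV"))),
    sprintf("# seed: %s", ifelse(is.na(seed), "NA", as.character(seed))),
    sprintf("# config_hash: %s",
            if (is.null(config)) "NA" else configHash(config)))
}
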