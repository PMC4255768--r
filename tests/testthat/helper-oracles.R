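## Independent oracles used to cross-check package results. These stay
## deliberately naive (enumeration, closed forms, direct formulas) and
## share no code with the implementation paths they check.

## Two-sided Fisher exact p by full hypergeometric enumeration over all
## 2x2 tables with the observed margins: sum the probabilities of tables
## no more probable than the observed one.
fisherEnumOracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  aMin <- max(0, c1 - r2); aMax <- min(r1, c1)
  logP <- function(a)
    lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1)
  pObs <- logP(tab[1, 1])
  ps <- vapply(aMin:aMax, logP, numeric(1))
  sum(exp(ps)[ps <= pObs + 1e-7])
}

## Brute-force most-likely state path by enumerating every path (k^n).
viterbiEnumOracle <- function(values, means, sds, transProb, initProb) {
  k <- length(means); n <- length(values)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  trans <- matrix(transProb, k, k); diag(trans) <- 1 - (k - 1) * transProb
  lp <- log(initProb)[paths[, 1]] +
    dnorm(values[1], means[paths[, 1]], sds[paths[, 1]], log = TRUE)
  for (t in 2:n) {
    lp <- lp + log(trans[cbind(paths[, t - 1], paths[, t])]) +
      dnorm(values[t], means[paths[, t]], sds[paths[, t]], log = TRUE)
  }
  paths[which.max(lp), ]
}

## Gotoh global-alignment score with affine gaps (gap of length L costs
## open + L * extend), full DP table.
gotohScoreOracle <- function(a, b, match = 1, mismatch = -1, open = 5,
                             extend = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -open - (i - 1) * extend
  for (j in 2:(m + 1)) Iy[1, j] <- -open - (j - 1) * extend
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (a[i - 1] == b[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
    Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend)
    Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

## Direct-formula squared Pearson correlation (sum formulas, no cor()).
r2Oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- (n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2)
  num^2 / den
}

## Brute-force marker window: scan every (present, absent) lineage pair.
markerWindowOracle <- function(times, status) {
  pres <- times[status == "present"]; abs_ <- times[status == "absent"]
  if (!length(pres) || !length(abs_)) return(NULL)
  best <- c(0, Inf)
  for (p in pres) best[1] <- max(best[1], p)
  for (q in abs_) best[2] <- min(best[2], q)
  if (best[1] > best[2]) return("homoplasy")
  best
}

## Small deterministic test fixtures built in code.
tinyTrack <- function(values, spacing = 1000, chrom = "chrT") {
  n <- length(values)
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = (seq_len(n) - 1L) * spacing + 1L,
                            width = 50L))
  names(gr) <- sprintf("p%03d", seq_len(n))
  S4Vectors::mcols(gr)$r2 <- values
  S4Vectors::mcols(gr)$nUsed <- rep(10L, n)
  gr
}
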