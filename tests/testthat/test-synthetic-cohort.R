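test_that("probe tiling matches the requested density and is deterministic", {
  reg <- GRanges("chr8", IRanges(1, 10000))
  pr <- makeProbeSet(reg, meanSpacing = 1000, jitterFrac = 0)
  expect_length(pr, 10)
  expect_equal(start(pr) - 1L, seq(0, 9000, by = 1000))  # 0-based starts
  expect_false(anyDuplicated(names(pr)) > 0)
  expect_true(all(diff(start(pr)) > 0))

  # macaque-like density: 982 kb at 667-bp spacing ~ 1.5 probes/kb
  big <- GRanges("chr8", IRanges(1, 982000))
  prBig <- makeProbeSet(big, meanSpacing = 667, seed = 3)
  expect_equal(length(prBig), 1472, tolerance = 0.01)
  expect_equal(length(prBig) / (982000 / 1000), 1.5, tolerance = 0.01)

  expect_error(makeProbeSet(reg, meanSpacing = 0), "meanSpacing")
  expect_error(makeProbeSet(GRanges("chr8", IRanges(1, 100)),
                            meanSpacing = 1000), "twice")
  # identical seed => identical tiling
  expect_identical(makeProbeSet(big, 667, seed = 9),
                   makeProbeSet(big, 667, seed = 9))
})

test_that("cohort intensities follow the generative log2-ratio model", {
  cfg <- macaqueLocusConfig(seed = 11)

  # noise-free: in-block probes carry exactly log2(cn/2), others 0
  cfg0 <- cfg
  cfg0$noiseSd <- 0
  cfg0$decoys <- GRanges()
  co <- simulateCohort(cfg0)
  cn <- trueCopyNumber(co)
  inBlock <- overlapsAny(probes(co), truthBlock(co))
  for (s in seq_along(cn)) {
    expect_equal(unname(intensities(co)[inBlock, s]),
                 rep(unname(log2(cn[s] / 2)), sum(inBlock)))
    expect_equal(unname(intensities(co)[!inBlock, s]),
                 rep(0, sum(!inBlock)))
  }

  # cn = 2 everywhere, no noise => all zero
  cfg2 <- cfg0
  cfg2$cnRange <- c(2L, 2L)
  cfg2$decoyCnRange <- c(2L, 2L)
  expect_true(all(simulateCohort(cfg2) |> intensities() == 0))

  # noisy cohort: per-sample in-block mean within 3 standard errors of
  # log2(cn/2), checked against truth (Monte-Carlo consistency)
  coN <- simulateCohort(cfg)
  cnN <- trueCopyNumber(coN)
  inB <- overlapsAny(probes(coN), truthBlock(coN))
  se <- cfg$noiseSd / sqrt(sum(inB))
  for (s in seq_along(cnN))
    expect_lt(abs(mean(intensities(coN)[inB, s]) - log2(cnN[s] / 2)), 3 * se)

  # bit-reproducibility
  expect_identical(intensities(simulateCohort(cfg)),
                   intensities(simulateCohort(macaqueLocusConfig(seed = 11))))
  expect_false(identical(intensities(simulateCohort(cfg, seed = 12)),
                         intensities(coN)))
})

test_that("zero-copy samples are floored, not -Inf", {
  cfg <- humanLocusConfig(seed = 5)
  cfg$cnRange <- c(0L, 0L)
  cfg$noiseSd <- 0
  cfg$dropout <- NULL
  co <- simulateCohort(cfg)
  inB <- overlapsAny(probes(co), truthBlock(co))
  expect_true(all(is.finite(intensities(co))))
  expect_equal(unname(intensities(co)[inB, 1]),
               rep(log2(0.05 / 2.05), sum(inB)))
})

test_that("PRT simulation has the stated ratio expectation", {
  r0 <- simulatePRT(2, noiseCv = 0, sampleId = "a", seed = 1)
  expect_equal(prtRatios(r0), rep(1, 5))
  r6 <- simulatePRT(6, noiseCv = 0, sampleId = "a", seed = 1)
  expect_equal(prtRatios(r6), rep(3, 5))
  expect_error(simulatePRT(4, nReplicates = 0), "nReplicates")

  # law of large numbers: cn 4, cv 5%: grand mean of per-run means
  # within 1% of ratio 2.0
  means <- vapply(1:2000, function(i)
    mean(prtRatios(simulatePRT(4, noiseCv = 0.05, seed = i))), numeric(1))
  expect_lt(abs(mean(means) - 2) / 2, 0.01)
})

test_that("ddPCR simulation follows the Poisson loading model", {
  z <- simulateDdpcr(4, lambdaRef = 0, seed = 1)
  expect_true(all(z@nTestPositive == 0) && all(z@nRefPositive == 0))

  # cn 2: channels are exchangeable
  s2 <- simulateDdpcr(2, nDroplets = 50000, lambdaRef = 0.5,
                      nReplicates = 40, seed = 4)
  expect_equal(mean(s2@nTestPositive), mean(s2@nRefPositive),
               tolerance = 0.01)

  # extreme loading saturates and is flagged
  sat <- simulateDdpcr(8, nDroplets = 50, lambdaRef = 30, seed = 2)
  expect_true(any(sat@saturated))
})

test_that("haplotype generator plants recoverable labelled substitutions", {
  # no substitutions => four identical sequences
  h0 <- simulateParalogHaplotypes(0, 0, seed = 3)
  expect_length(unique(as.character(h0@sequences)), 1)

  # all-nonsynonymous paralog divergence round-trips through the
  # classifier on either haplotype
  h4 <- simulateParalogHaplotypes(4, 0, nonsynFracParalog = 1, seed = 5)
  for (hap in c("hapA", "hapB")) {
    d <- classifyNucDiffs(
      h4@sequences[h4@haplotype == hap & h4@position == "proximal"][[1]],
      h4@sequences[h4@haplotype == hap & h4@position == "distal"][[1]])
    expect_equal(c(d$nonsyn, d$syn), c(4, 0))
  }

  # a variant built with 4 nonsynonymous changes yields 4 amino-acid labels
  labs <- diffAA(
    h4@sequences[h4@haplotype == "hapA" & h4@position == "distal"][[1]],
    h4@sequences[h4@haplotype == "hapA" & h4@position == "proximal"][[1]])
  expect_length(labs, 4)
  expect_true(all(grepl("^[A-Z][0-9]+[A-Z]$", labs)))

  # requesting more substitutions than codons fails loudly
  expect_error(
    simulateParalogHaplotypes(80, 0, nonsynFracParalog = 1, nCodons = 10,
                              seed = 1),
    "available sites")

  # identical seed + config reproduce the set exactly
  expect_identical(
    as.character(simulateParalogHaplotypes(6, 4, 2/3, 1/4, seed = 8)@sequences),
    as.character(simulateParalogHaplotypes(6, 4, 2/3, 1/4, seed = 8)@sequences))
})
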