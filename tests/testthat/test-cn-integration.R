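test_that("block PC1 summarizes the shared copy-number signal", {
  cfg <- macaqueLocusConfig(seed = 51)
  cfg$noiseSd <- 0
  co <- simulateCohort(cfg)
  sc <- blockPC1(co, truthBlock(co))
  # noise-free: scores perfectly rank-correlated with truth
  expect_equal(cor(sc, trueCopyNumber(co), method = "spearman"), 1)

  # identical samples get identical scores
  lr <- matrix(rnorm(40), nrow = 20)
  lr <- cbind(lr[, 1], lr)
  gr <- GRanges("chrT", IRanges((0:19) * 100 + 1, width = 50))
  names(gr) <- rownames(lr) <- sprintf("p%02d", 1:20)
  colnames(lr) <- c("a", "b", "c")
  expect_equal(blockPC1(lr, GRanges("chrT", IRanges(1, 3000)), probes = gr)[["a"]],
               blockPC1(lr, GRanges("chrT", IRanges(1, 3000)), probes = gr)[["b"]])

  # near-rank-one matrix: PC1 explains > 99% of variance
  set.seed(9)
  sig <- outer(rnorm(30), rnorm(10))
  noisy <- sig + rnorm(300, sd = 0.01 * sd(sig))
  gr2 <- GRanges("chrT", IRanges((0:29) * 100 + 1, width = 50))
  names(gr2) <- rownames(noisy) <- sprintf("q%02d", 1:30)
  colnames(noisy) <- sprintf("S%02d", 1:10)
  sc2 <- blockPC1(noisy, GRanges("chrT", IRanges(1, 4000)), probes = gr2)
  expect_gt(attr(sc2, "varExplained"), 0.99)

  # zero variance is an error
  zed <- matrix(0, 5, 3, dimnames = list(sprintf("p%02d", 1:5), c("a","b","c")))
  gr3 <- GRanges("chrT", IRanges((0:4) * 100 + 1, width = 50))
  names(gr3) <- rownames(zed)
  expect_error(blockPC1(zed, GRanges("chrT", IRanges(1, 600)), probes = gr3),
               "variance")
})

test_that("method concordance is a symmetric sign-blind r2 matrix", {
  set.seed(3)
  x <- rnorm(16)
  m <- cbind(a = x, b = 2 * x + 1, c = -x, d = rnorm(16))
  cc <- methodConcordance(m)
  expect_equal(cc, t(cc))
  expect_equal(diag(cc), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cc["a", "b"], 1)
  expect_equal(cc["a", "c"], 1)     # anticorrelation: r2 is sign-blind
  expect_true(all(cc >= 0 & cc <= 1, na.rm = TRUE))

  # null expectation for independent methods: E[r2] = 1/(n-1)
  null <- replicate(400, methodConcordance(cbind(a = rnorm(16),
                                                 b = rnorm(16)))["a", "b"])
  expect_equal(mean(null), 1 / 15, tolerance = 0.25)

  # too few shared samples masks an entry
  m2 <- cbind(a = c(1, 2, NA, NA, NA), b = c(2, 1, NA, NA, NA))
  expect_true(is.na(methodConcordance(m2)["a", "b"]))
})

test_that("integration pools methods and is affine-invariant", {
  set.seed(11)
  truth <- sample(3:6, 16, replace = TRUE)
  m <- cbind(acgh = truth + rnorm(16, 0, 0.5),
             prt = truth + rnorm(16, 0, 0.4),
             ddpcr = truth + rnorm(16, 0, 0.3))
  rownames(m) <- sprintf("S%02d", 1:16)
  sc <- integrateMethods(m)

  # invariance to per-method affine rescaling
  m2 <- m
  m2[, "prt"] <- 10 * m2[, "prt"] - 4
  m2[, "acgh"] <- -0.1 + 0.25 * m2[, "acgh"]
  expect_equal(integrateMethods(m2), sc, tolerance = 1e-12)

  # two identical methods: score equals either, up to scale
  dup <- cbind(a = truth + 0.0, ddpcr = truth + 0.0)
  rownames(dup) <- rownames(m)
  expect_equal(abs(cor(integrateMethods(dup), truth)), 1)

  # single method: standardized values unchanged
  one <- m[, "ddpcr", drop = FALSE]
  expect_equal(unname(integrateMethods(one)),
               unname(scale(one)[, 1]))

  # constant method dropped with a warning
  mC <- cbind(m, flat = rep(5, 16))
  expect_warning(scC <- integrateMethods(mC), "constant")
  expect_equal(scC, sc, tolerance = 1e-12)
})

test_that("integrated PC1 usually beats the best single method", {
  set.seed(23)
  wins <- 0
  for (i in 1:200) {
    truth <- sample(3:6, 16, replace = TRUE)
    m <- cbind(acgh = truth + rnorm(16, 0, 0.6),
               prt = truth + rnorm(16, 0, 0.6),
               ddpcr = truth + rnorm(16, 0, 0.6))
    rownames(m) <- sprintf("S%02d", 1:16)
    sc <- integrateMethods(m)
    r2int <- cor(sc, truth)^2
    r2single <- max(apply(m, 2, function(v) cor(v, truth)^2))
    if (r2int >= r2single) wins <- wins + 1
  }
  expect_gte(wins / 200, 0.8)
})

test_that("integer calls anchor on ddPCR and round half away from zero", {
  cfg <- macaqueLocusConfig(seed = 61)
  cfg$noiseSd <- 0
  co <- simulateCohort(cfg)
  truth <- trueCopyNumber(co)
  sc <- blockPC1(co, truthBlock(co))
  m <- cbind(acgh = sc, ddpcr = as.numeric(truth))
  rownames(m) <- names(sc)
  calls <- callIntegers(integrateMethods(m), m)
  expect_identical(calls$cn, unname(as.integer(truth[calls$sample])))
  expect_true(all(calls$confidence > 0.7))

  # with methods linear in copy number the mapping is exact: confidence 1
  mLin <- cbind(prt = as.numeric(truth), ddpcr = as.numeric(truth))
  rownames(mLin) <- names(truth)
  callsLin <- callIntegers(integrateMethods(mLin), mLin)
  expect_identical(callsLin$cn, unname(as.integer(truth)))
  expect_equal(callsLin$confidence, rep(1, nrow(callsLin)),
               tolerance = 1e-6)

  # the declared tie rule: half-integers round away from zero
  expect_equal(defensinCNV:::roundHalfAwayFromZero(c(2.5, 3.5, -2.5)),
               c(3, 4, -3))
  sHalf <- c(a = 2.5, b = 3.5)
  mHalf <- cbind(ddpcr = c(a = 2.5, b = 3.5))
  cHalf <- callIntegers(sHalf, mHalf)
  expect_identical(cHalf$cn, c(3L, 4L))
  expect_equal(cHalf$confidence, c(0, 0), tolerance = 1e-9)

  # missing anchor: rounded raw score, flagged
  expect_warning(cNA <- callIntegers(c(a = 3.2, b = 4.9), NULL), "anchor")
  expect_true(all(cNA$lowConfidence))
  expect_identical(cNA$cn, c(3L, 5L))
})

test_that("confidence is lower for wrong calls than for correct ones", {
  set.seed(71)
  confW <- confC <- numeric(0)
  for (i in 1:60) {
    truth <- sample(3:6, 16, replace = TRUE)
    m <- cbind(acgh = truth + rnorm(16, 0, 0.6),
               prt = truth + rnorm(16, 0, 0.6),
               ddpcr = truth + rnorm(16, 0, 0.45))
    rownames(m) <- sprintf("S%02d", 1:16)
    calls <- callIntegers(integrateMethods(m), m)
    ok <- calls$cn == truth
    confC <- c(confC, calls$confidence[ok])
    confW <- c(confW, calls$confidence[!ok])
  }
  expect_gt(length(confW), 0)
  expect_lt(mean(confW), mean(confC))
})
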