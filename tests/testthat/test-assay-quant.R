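test_that("PRT copy number is the reference-scaled mean replicate ratio", {
  expect_equal(prtCopyNumber(PRTRun("a", rep(1, 5), rep(1, 5))), 2)
  expect_equal(prtCopyNumber(PRTRun("a", rep(1.5, 5), rep(1, 5))), 3)
  # arithmetic mean of (0.9, 1.1, 1.0, 1.2, 0.8) is exactly 1
  expect_equal(prtCopyNumber(PRTRun("a", c(0.9, 1.1, 1.0, 1.2, 0.8),
                                    rep(1, 5))), 2)
  # zero-reference replicate rejected, not propagated
  expect_equal(prtCopyNumber(PRTRun("a", c(1, 1, 7), c(1, 1, 0))), 2)
  expect_error(prtCopyNumber(PRTRun("a", c(1, 1), c(0, 0))), "rejected")
})

test_that("Poisson inversion recovers mean molecules per droplet", {
  expect_equal(ddpcrLambda(10000, 10000), 0)
  expect_equal(ddpcrLambda(round(exp(-1) * 1e7), 1e7), 1, tolerance = 1e-4)
  expect_equal(ddpcrLambda(3679, 10000), 1.0, tolerance = 1e-4)
  expect_error(ddpcrLambda(0, 10000), "saturated")
  expect_error(ddpcrLambda(20, 10), "exceed")
})

test_that("ddPCR copy number inverts both channels and applies QC", {
  # equal positive counts in both channels => diploid
  r <- DdpcrRun("a", 20000, 5000, 5000)
  expect_equal(as.numeric(ddpcrCopyNumber(r)), 2)

  # lambda_test = 2 * lambda_ref => cn 4
  lamR <- 0.4
  nd <- 50000
  r2 <- DdpcrRun("a", nd, round(nd * (1 - exp(-2 * lamR))),
                 round(nd * (1 - exp(-lamR))))
  expect_equal(as.numeric(ddpcrCopyNumber(r2)), 4, tolerance = 1e-3)

  # replicate at 9,500 droplets fails the strict >10,000 rule and is
  # excluded; the surviving replicate determines the estimate
  r3 <- DdpcrRun("a", c(9500, 20000), c(9000, 5000), c(2000, 5000))
  expect_equal(as.numeric(ddpcrCopyNumber(r3)), 2)
  expect_equal(attr(ddpcrCopyNumber(r3), "nUsed"), 1)
  expect_error(ddpcrCopyNumber(DdpcrRun("a", 9000, 100, 100)), "QC")

  # invariance to droplet-count scaling at fixed positive fractions
  a <- DdpcrRun("a", 20000, 6000, 4000)
  b <- DdpcrRun("a", 200000, 60000, 40000)
  expect_equal(as.numeric(ddpcrCopyNumber(a)), as.numeric(ddpcrCopyNumber(b)))
})

test_that("qPCR standard curve and efficiency follow least squares", {
  pts <- data.frame(log10Quantity = c(0, 1, 2),
                    ct = c(30, 26.6781, 23.3562))
  sc <- qpcrStandardCurve(pts)
  expect_equal(sc$slope, -3.3219, tolerance = 1e-4)
  expect_equal(sc$efficiency, 2, tolerance = 1e-3)
  expect_equal(sc$residuals, rep(0, 3), tolerance = 1e-9)
  expect_error(qpcrStandardCurve(data.frame(log10Quantity = c(1, 1),
                                            ct = c(20, 21))), "distinct")
})

test_that("qPCR copy number inverts the efficiency-corrected model", {
  curve <- data.frame(log10Quantity = 0:3, ct = 30 - 3.3219 * (0:3))
  cal <- QpcrRun("cal", ctTest = 25, ctRef = 25, curve, curve)
  # identical Cts and efficiencies, calibrator identical => diploid
  expect_equal(qpcrCopyNumber(cal, cal), 2)
  # one cycle earlier than the calibrator at efficiency 2 => one doubling
  s <- QpcrRun("s", ctTest = 24, ctRef = 25, curve, curve)
  expect_equal(qpcrCopyNumber(s, cal), 4, tolerance = 1e-3)
  expect_warning(u <- qpcrCopyNumber(s), "calibrator")
  expect_true(isTRUE(attr(u, "uncalibrated")))

  # invert a simulated cn = 3 sample with unequal efficiencies
  eT <- 1.9; eR <- 2.0
  mkCurve <- function(E) data.frame(log10Quantity = 0:3,
                                    ct = 28 - (0:3) / log10(E))
  ctFor <- function(cn, E, ct0) ct0 - log(cn / 2) / log(E)
  calib <- QpcrRun("cal", ctFor(2, eT, 25), ctFor(2, eR, 24),
                   mkCurve(eT), mkCurve(eR))
  samp <- QpcrRun("s", ctFor(3, eT, 25), ctFor(2, eR, 24),
                  mkCurve(eT), mkCurve(eR))
  expect_equal(qpcrCopyNumber(samp, calib), 3, tolerance = 1e-3)
})

test_that("estimators are consistent and monotone in true copy number", {
  # noise-free monotonicity across the diploid range
  prt <- vapply(2:7, function(cn)
    prtCopyNumber(simulatePRT(cn, noiseCv = 0, seed = 1)), numeric(1))
  expect_true(all(diff(prt) > 0))
  dd <- vapply(2:7, function(cn) {
    lam <- 0.5 * cn / 2
    as.numeric(ddpcrCopyNumber(DdpcrRun("a", 1e6,
                                        round(1e6 * (1 - exp(-lam))),
                                        round(1e6 * (1 - exp(-0.5))))))
  }, numeric(1))
  expect_true(all(diff(dd) > 0))
  expect_equal(dd, 2:7, tolerance = 5e-3)

  # Poisson inversion beats the naive positives-ratio estimator at high
  # loading (the digital advantage): the naive ratio saturates toward a
  # biased constant, so the fair comparison is squared error about truth
  set.seed(42)
  lamR <- 1.2; cn <- 5; lamT <- lamR * cn / 2; nd <- 20000
  tp <- rbinom(2000, nd, 1 - exp(-lamT))
  rp <- rbinom(2000, nd, 1 - exp(-lamR))
  inv <- 2 * (-log(1 - tp / nd)) / (-log(1 - rp / nd))
  naive <- 2 * tp / rp
  expect_lt(mean((inv - cn)^2), mean((naive - cn)^2))
  expect_lt(abs(mean(inv) - cn) / cn, 0.01)
})

test_that("anchor calibration maps estimates onto the integer scale", {
  v <- c(a = 1, b = 2, c = 3)
  expect_identical(calibrateToIntegerScale(v), v)
  # two exact anchors reproduce themselves under the affine map
  anchored <- calibrateToIntegerScale(c(a = 10, b = 20, c = 30),
                                      anchors = c(a = 2, c = 6))
  expect_equal(anchored[c("a", "c")], c(a = 2, c = 6))
  expect_equal(unname(anchored["b"]), 4)
  expect_warning(calibrateToIntegerScale(v, anchors = c(a = 2)), "anchors")

  # calibration reduces error on a systematically biased noisy cohort
  set.seed(7)
  truth <- sample(2:7, 40, replace = TRUE)
  names(truth) <- sprintf("s%02d", 1:40)
  raw <- 0.6 * truth + 1.3 + rnorm(40, 0, 0.1)
  names(raw) <- names(truth)
  cal <- calibrateToIntegerScale(raw, anchors = truth[c(1, 5, 9)])
  expect_lt(mean(abs(cal - truth)), mean(abs(raw - truth)))
})
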