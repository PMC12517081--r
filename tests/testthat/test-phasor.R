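test_that("theoretical phasors live on the universal semicircle", {
  acq <- testAcq()
  expect_equal(theoreticalPhasor(1e-9, acq), c(g = 1, s = 0), tolerance = 1e-6)
  p <- theoreticalPhasor(1e6, acq)
  expect_lt(sqrt(sum(p^2)), 1e-3)
  for (tau in c(0.1, 0.42, 1, 2.5, 4, 10)) {
    p <- theoreticalPhasor(tau, acq)
    expect_equal((p["g"] - 0.5)^2 + p["s"]^2, c(g = 0.25), tolerance = 1e-14)
  }
  # omega * tau = 1 sits at the semicircle apex
  apexTau <- 1 / angularFrequency(acq)
  expect_equal(theoreticalPhasor(apexTau, acq), c(g = 0.5, s = 0.5))
})

test_that("the discrete transform equals direct numerical integration", {
  acq <- testAcq(nBins = 64L)
  set.seed(31)
  cts <- rpois(64, modelDecay(50, 15, 0.42, 2.5, 1, acq))
  h <- DecayHistogram(cts, acq)
  got <- phasorTransform(h)
  want <- oraclePhasor(cts, binCenters(h), angularFrequency(acq))
  expect_equal(got, want, tolerance = 1e-12)

  # delta decay with its bin centred at t = 0 maps to (1, 0)
  hd <- DecayHistogram(c(1000, rep(0, 31)), acq,
                       binWidth = binWidth(acq), origin = -binWidth(acq) / 2)
  expect_equal(phasorTransform(hd), c(g = 1, s = 0))

  # intensity-weighted linearity: a mixture lands on the chord midpoint
  acqf <- AcquisitionConfig(nBins = 2048L, irfCenter = 0, irfFwhm = 0)
  y1 <- expectedClassDecay(PhotophysicsClass("cell", 0.42, 1, 1), acqf, 500)
  y2 <- expectedClassDecay(PhotophysicsClass("cell", 2.5, 1, 1), acqf, 500)
  p1 <- phasorTransform(DecayHistogram(y1, acqf))
  p2 <- phasorTransform(DecayHistogram(y2, acqf))
  pm <- phasorTransform(DecayHistogram(y1 + y2, acqf))
  expect_equal(pm, (p1 + p2) / 2, tolerance = 1e-12)

  expect_error(phasorTransform(DecayHistogram(rep(0, 64), acq)), "zero-bin")
})

test_that("calibration maps mono-exponential targets onto theory and guards reapplication", {
  acq <- testAcq(nBins = 256L)
  ref <- simulateRoiDecay(PhotophysicsClass("background", 4.0, 1, 1), acq,
                          1e6, seed = 41, poisson = FALSE)
  cal <- phasorCalibration(ref, tauRef = 4.0, acq = acq)
  # the correction reproduces the reference's theoretical point exactly
  z <- complex(real = cal@measuredG, imaginary = cal@measuredS) *
    complex(modulus = cal@modulation, argument = cal@phase)
  th <- theoreticalPhasor(4.0, acq)
  expect_lt(abs(z - complex(real = th["g"], imaginary = th["s"])), 1e-9)

  # independent mono-exponential target lands within 0.01 of theory
  stack <- array(0, c(2, 2, 256))
  tgt <- expectedClassDecay(PhotophysicsClass("cell", 1.5, 1, 1), acq, 1e4)
  for (i in 1:2) for (j in 1:2) stack[i, j, ] <- tgt
  fld <- calibratePhasor(phasorTransform(stack, acq), cal)
  cen <- phasorCentroid(fld)
  thT <- theoreticalPhasor(1.5, acq)
  expect_lt(sqrt(sum((cen - thT)^2)), 0.01)
  expect_true(isCalibrated(fld))
  expect_error(calibratePhasor(fld, cal), "twice")

  # a delta IRF with no offset needs (almost) no correction
  acq0 <- AcquisitionConfig(nBins = 4096L, irfCenter = 0, irfFwhm = 0)
  ref0 <- simulateRoiDecay(PhotophysicsClass("background", 4.0, 1, 1), acq0,
                           1e6, poisson = FALSE)
  cal0 <- phasorCalibration(ref0, tauRef = 4.0, acq = acq0)
  expect_equal(cal0@modulation, 1, tolerance = 0.01)
  expect_equal(cal0@phase, 0, tolerance = 0.01)
})

test_that("the masked median filter denoises without touching masked pixels", {
  acq <- testAcq(nBins = 16L)
  mk <- function(g) new("PhasorField", g = g, s = g,
                        intensity = matrix(100, nrow(g), ncol(g)),
                        mask = matrix(TRUE, nrow(g), ncol(g)),
                        calibrated = TRUE, harmonic = 1L, acq = acq)
  # constant field unchanged
  fc <- medianFilterPhasor(mk(matrix(0.4, 9, 9)), 4)
  expect_equal(phasorG(fc), matrix(0.4, 9, 9))
  # single outlier removed after one pass
  g <- matrix(0.4, 9, 9); g[5, 5] <- 5
  f1 <- medianFilterPhasor(mk(g), 1)
  expect_equal(phasorG(f1)[5, 5], 0.4)
  # variance decreases monotonically with iterations on a noisy field
  set.seed(51)
  gn <- matrix(0.5 + rnorm(64 * 64, 0, 0.05), 64, 64)
  vars <- vapply(0:4, function(it)
    var(as.vector(phasorG(medianFilterPhasor(mk(gn), it)))), 1)
  expect_true(all(diff(vars) < 0))
  # masked pixels are excluded from neighbourhoods and left untouched
  fm <- mk(g)
  fm@mask[5, 5] <- FALSE
  out <- medianFilterPhasor(fm, 1)
  expect_equal(phasorG(out)[5, 5], 5)      # untouched under the mask
  expect_equal(phasorG(out)[5, 6], 0.4)    # outlier never leaks in
})

test_that("intensity thresholding matches the generator's pixel census", {
  acq <- testAcq(nBins = 32L)
  scene <- buildScene("50x50", "M0", nCells = 4, pixelSize = 1.0, seed = 6)
  sim <- simulateTcspcStack(scene, acq, seed = 6)
  fld <- phasorTransform(sim$stack, acq)
  expect_equal(sum(keptMask(intensityThreshold(fld, 0))), sum(keptMask(fld)))
  expect_equal(sum(keptMask(intensityThreshold(fld, 1e9))), 0)
  # a threshold above background (10) but below the cell budget (1000)
  # keeps exactly the cell + scaffold pixels
  surv <- sum(keptMask(intensityThreshold(fld, 300)))
  census <- sim$sidecar$classCensus
  expect_equal(surv, census$cell + census$scaffold)
})

test_that("distance filtering separates scaffold from cell pixels", {
  acq <- testAcq(nBins = 64L)
  scene <- buildScene("50x50", "M0", nCells = 5, pixelSize = 1.0, seed = 8)
  sim <- simulateTcspcStack(scene, acq, seed = 8)
  ref <- simulateRoiDecay(PhotophysicsClass("background", 4, 1, 1), acq, 1e6,
                          seed = 9, poisson = FALSE)
  fld <- calibratePhasor(phasorTransform(sim$stack, acq), ref)
  fld <- medianFilterPhasor(fld, 4)
  cls <- classImage(scene)
  scaf <- phasorCentroid(local({f <- fld; f@mask <- f@mask & (cls == 2L); f}))

  # infinite radius: exclusion removes everything, inclusion keeps everything
  ex <- distanceFilter(fld, scaf, 1e9, mode = "exclude")
  expect_equal(sum(keptMask(ex)), 0)
  inc <- distanceFilter(fld, scaf, 1e9, mode = "include")
  expect_equal(keptMask(inc), keptMask(fld))

  f2 <- distanceFilter(fld, scaf, 0.25)
  expect_lte(sum(keptMask(f2)[cls == 2L]) / sum(cls == 2L), 0.01)
  expect_gte(sum(keptMask(f2)[cls == 1L]) / sum(keptMask(fld)[cls == 1L]), 0.95)
  # deterministic: same inputs, same mask
  f3 <- distanceFilter(fld, scaf, 0.25)
  expect_identical(keptMask(f2), keptMask(f3))

  expect_error(distanceFilter(fld, scaf, 0), "positive")
  un <- phasorTransform(sim$stack, acq)
  expect_error(distanceFilter(un, scaf, 0.25), "calibrated")
})

test_that("phasor centroids are means and track the bound fraction along the chord", {
  expect_equal(phasorCentroid(rbind(c(0.3, 0.4))), c(g = 0.3, s = 0.4))
  expect_equal(phasorCentroid(rbind(c(0.2, 0.1), c(0.6, 0.5))),
               c(g = 0.4, s = 0.3))

  acq <- testAcq(nBins = 256L)
  ref <- simulateRoiDecay(PhotophysicsClass("background", 4, 1, 1), acq, 1e6,
                          poisson = FALSE)
  pts <- lapply(c(0.3, 0.5, 0.7), function(fb) {
    y <- expectedClassDecay(PhotophysicsClass("cell", c(0.42, 2.5),
                                              c(1 - fb, fb), 1), acq, 1e5)
    stack <- array(y, c(1, 1, 256))
    phasorCentroid(calibratePhasor(phasorTransform(stack, acq), ref))
  })
  free <- theoreticalPhasor(0.42, acq); bound <- theoreticalPhasor(2.5, acq)
  # projection onto the chord moves monotonically toward the bound phasor
  chord <- (bound - free) / sqrt(sum((bound - free)^2))
  proj <- vapply(pts, function(p) sum((p - free) * chord), 1)
  expect_true(all(diff(proj) > 0))
  # and each mixture lies on the chord (collinearity residual)
  resid <- vapply(pts, function(p) {
    v <- p - free
    abs(v["g"] * chord["s"] - v["s"] * chord["g"])
  }, 1)
  expect_lt(max(resid), 0.02)
})
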