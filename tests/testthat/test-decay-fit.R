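test_that("the reconvolution forward model matches limits and the quadrature oracle", {
  acq <- AcquisitionConfig(nBins = 128L, irfCenter = 0, irfFwhm = 0)
  tc <- binCenters(acq)
  # delta IRF, single component: pure exponential at bin centres
  y <- modelDecay(3, 0, 1.7, 2, 0, acq)
  expect_equal(y, 3 * exp(-tc / 1.7) / (1 - exp(-period(acq) / 1.7)),
               tolerance = 1e-12)
  # no decay components: constant background
  expect_equal(modelDecay(0, 0, 1, 2, 4.5, acq), rep(4.5, 128))

  # Gaussian IRF vs adaptive quadrature on a grid of lifetimes and IRFs
  for (tau in c(0.42, 2.5, 6)) {
    for (fw in c(0.15, 0.4)) {
      acq2 <- AcquisitionConfig(nBins = 64L, irfCenter = 1.2, irfFwhm = fw)
      got <- modelDecay(1, 0, tau, tau + 1, 0, acq2)
      sigma <- fw / (2 * sqrt(2 * log(2)))
      want <- oracleFoldedConv(binCenters(acq2), tau, 1.2, sigma, period(acq2))
      expect_lt(max(abs(got - want) / want), 1e-8)
    }
  }

  expect_error(modelDecay(1, 0, 1, 2, 0, acq, binCenters = c(1, 20)),
               "beyond one repetition period")
})

test_that("amplitude-weighted mean lifetime follows the closed form", {
  expect_equal(meanLifetime(1, 0, 0.7, 2.5), 0.7)
  expect_equal(meanLifetime(1, 1, 0.42, 2.5), 1.46)
  expect_equal(meanLifetime(3, 1, 0.4, 2.0), 0.8)
  expect_error(meanLifetime(0, 0, 1, 2), "positive")
  # strictly increasing in the long-component amplitude share
  fracs <- seq(0.05, 0.95, by = 0.1)
  tm <- vapply(fracs, function(f) meanLifetime(1 - f, f, 0.42, 2.5), 1)
  expect_true(all(diff(tm) > 0))
})

test_that("noiseless bi-exponential fits recover the generator exactly", {
  acq <- AcquisitionConfig(nBins = 256L)
  truth <- c(alpha1 = 120, alpha2 = 30, tau1 = 0.42, tau2 = 2.5, C = 0.8)
  y <- modelDecay(truth["alpha1"], truth["alpha2"], truth["tau1"],
                  truth["tau2"], truth["C"], acq)
  fit <- fitBiexponential(DecayHistogram(y, acq), fixTau1 = NULL)
  p <- fitParams(fit)
  expect_lt(max(abs(p - truth) / truth), 1e-5)
  expect_lt(chiSquared(fit), 1e-12)
  expect_true(isConverged(fit))
  expect_lt(fit@tau1, fit@tau2)
})

test_that("Poisson fits at the ROI photon budget are calibrated and accurate", {
  acq <- AcquisitionConfig(nBins = 256L)
  cell <- defaultPhotophysics("M0")$cell
  tau2hat <- numeric(25); chi2 <- numeric(25)
  for (i in 1:25) {
    h <- simulateRoiDecay(cell, acq, totalPhotons = 1e5, seed = 100 + i)
    f <- fitBiexponential(h, fixTau1 = 0.42)
    tau2hat[i] <- f@tau2
    chi2[i] <- chiSquared(f)
  }
  # long lifetime within 10% (median), chi-squared calibrated around 1
  expect_lt(abs(median(tau2hat) - 2.5) / 2.5, 0.10)
  expect_gt(median(chi2), 0.8)
  expect_lt(median(chi2), 1.2)
})

test_that("fits flag degenerate and photon-starved inputs", {
  acq <- AcquisitionConfig(nBins = 64L)
  expect_error(fitBiexponential(DecayHistogram(rep(0, 64), acq)),
               "degenerate")
  y <- modelDecay(0.4, 0.1, 0.42, 2.5, 0, acq)  # ~60 photons
  expect_warning(fitBiexponential(DecayHistogram(rpois(64, y), acq)),
                 "fewer than 100 photons")
})

test_that("ROI aggregation conserves photons and is additive", {
  acq <- AcquisitionConfig(nBins = 32L)
  set.seed(21)
  stack <- array(rpois(8 * 8 * 32, 5), c(8, 8, 32))
  one <- matrix(FALSE, 8, 8); one[3, 4] <- TRUE
  expect_equal(counts(aggregateRoiDecay(stack, one, acq)), stack[3, 4, ])

  a <- matrix(FALSE, 8, 8); a[1:2, ] <- TRUE
  b <- matrix(FALSE, 8, 8); b[5:6, ] <- TRUE
  expect_equal(counts(aggregateRoiDecay(stack, a | b, acq)),
               counts(aggregateRoiDecay(stack, a, acq)) +
                 counts(aggregateRoiDecay(stack, b, acq)))

  # 2x spatial binning conserves totals over a block-aligned ROI
  all4 <- matrix(TRUE, 8, 8)
  h2 <- aggregateRoiDecay(stack, all4, acq, spatialBinning = 2L)
  expect_equal(nPhotons(h2), sum(stack))
  expect_error(aggregateRoiDecay(stack, matrix(FALSE, 8, 8), acq), "empty ROI")
})
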