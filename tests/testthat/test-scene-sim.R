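test_that("lattice pore counts match the analytic product formula", {
  # the large-pore design: 50x50x20 um pores filling 500x500x40 um
  sp <- ScaffoldSpec(c(50, 50, 20), c(500, 500, 40), beamThickness = 5)
  expect_equal(poreCount(sp), 200)
  lat <- buildScaffoldLattice(sp, pixelSize = 2.5, dims = "3d")
  expect_equal(lat$poreCount, 200)
  expect_equal(lat$poreCountRaster, 200)

  # single unit cell
  expect_equal(poreCount(ScaffoldSpec(c(1, 1, 1), c(1, 1, 1), 0.2)), 1)

  # small-pore design, single 28x28 layer
  sp2 <- ScaffoldSpec(c(15, 15, 15), c(420, 420, 15), beamThickness = 3)
  lat2 <- buildScaffoldLattice(sp2, pixelSize = 1.5, dims = "3d")
  expect_equal(lat2$poreCount, 784)
  expect_equal(lat2$poreCountRaster, 784)
  # the two-layer variant doubles it; raster and analytic stay consistent
  sp3 <- ScaffoldSpec(c(15, 15, 15), c(420, 420, 30), beamThickness = 3)
  lat3 <- buildScaffoldLattice(sp3, pixelSize = 3, dims = "3d")
  expect_equal(lat3$poreCountRaster, lat3$poreCount)
  expect_equal(lat3$poreCount, 2 * 784)
})

test_that("raster pore count equals the analytic count on random divisible specs", {
  set.seed(11)
  for (i in 1:10) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1); nz <- sample(1:3, 1)
    px <- sample(3:8, 1); py <- sample(3:8, 1); pz <- sample(3:8, 1)
    sp <- ScaffoldSpec(c(px, py, pz), c(nx * px, ny * py, nz * pz),
                       beamThickness = 1)
    lat <- buildScaffoldLattice(sp, pixelSize = 0.5, dims = "3d")
    expect_equal(lat$poreCountRaster, nx * ny * nz)
    expect_equal(lat$poreCount, nx * ny * nz)
  }
})

test_that("non-divisible scaffold dimensions are rejected naming the axis", {
  expect_error(ScaffoldSpec(c(50, 50, 20), c(510, 500, 40)), "axis.*x")
  expect_error(ScaffoldSpec(c(50, 50, 20), c(500, 500, 45)), "axis.*z")
})

test_that("cell mask generator honours shape parameters and determinism", {
  # one smooth isotropic cell is nearly circular
  one <- generateCellMasks(1, areaMean = 400, elongation = 1, protrusions = 0,
                           protrusionAmp = 0, frame = c(64L, 64L),
                           pixelSize = 1, areaCv = 0, seed = 5)
  expect_equal(max(one$masks), 1L)
  expect_gt(computeCircularity(one$polygons[[1]]), 0.97)

  # elongated population: Feret outruns the equivalent-circle diameter
  cm <- generateCellMasks(100, areaMean = 400, elongation = 3,
                          frame = c(512L, 512L), pixelSize = 1, seed = 7)
  expect_lt(abs(mean(cm$areas) - 400) / 400, 0.10)
  mt <- morphometryTable(cm$masks, 1, excludeBorder = FALSE)
  equivDiam <- 2 * sqrt(mt$area_um2 / pi)
  expect_gt(mean(mt$max_feret_um) / mean(equivDiam), 1.5)

  # determinism and non-overlap
  cm2 <- generateCellMasks(100, areaMean = 400, elongation = 3,
                           frame = c(512L, 512L), pixelSize = 1, seed = 7)
  expect_identical(cm$masks, cm2$masks)

  expect_error(generateCellMasks(20, areaMean = 400, frame = c(32L, 32L),
                                 pixelSize = 1, seed = 1, maxAttempts = 25L),
               "too small|crowded")
})

test_that("noiseless TCSPC stacks match the quadrature convolution oracle", {
  acq <- testAcq(nBins = 64L)
  # single-class, single-component scene
  classImg <- matrix(1L, 4, 4)
  masks <- matrix(0L, 4, 4); masks[2, 2] <- 1L
  gt <- list(background = PhotophysicsClass("background", 1, 1, 10),
             cell = PhotophysicsClass("cell", 2.2, 1, 1000),
             scaffold = PhotophysicsClass("scaffold", 3.5, 1, 5000))
  scene <- new("SyntheticScene", classImage = classImg, cellMasks = masks,
               groundTruth = gt, seed = 1L)
  sim <- simulateTcspcStack(scene, acq, seed = 1, poisson = FALSE)
  got <- sim$stack[1, 1, ]
  sigma <- irfFwhm(acq) / (2 * sqrt(2 * log(2)))
  oracle <- oracleFoldedConv(binCenters(acq), 2.2, irfCenter(acq), sigma,
                             period(acq))
  oracle <- oracle * 1000 / sum(oracle)
  expect_lt(max(abs(got - oracle) / oracle), 1e-10)
  # photon conservation is exact before Poisson sampling
  expect_equal(sum(got), 1000, tolerance = 1e-12)
})

test_that("Poisson sampling respects the class photon budget and the seed", {
  acq <- testAcq(nBins = 32L)
  classImg <- matrix(1L, 100, 100)  # 1e4 cell pixels
  scene <- new("SyntheticScene", classImage = classImg,
               cellMasks = matrix(0L, 100, 100),
               groundTruth = defaultPhotophysics("M0"), seed = 1L)
  sim <- simulateTcspcStack(scene, acq, seed = 9)
  perPixel <- sum(sim$stack) / 1e4
  expect_lt(abs(perPixel - 1000) / 1000, 0.02)
  sim2 <- simulateTcspcStack(scene, acq, seed = 9)
  expect_identical(sim$stack, sim2$stack)
  expect_false(identical(sim$stack, simulateTcspcStack(scene, acq, seed = 10)$stack))
})

test_that("a vanishing lifetime concentrates the decay in the IRF envelope", {
  acq <- testAcq(nBins = 256L)
  ph <- PhotophysicsClass("cell", binWidth(acq) / 100, 1, 1000)
  curve <- expectedClassDecay(ph, acq, 1000)
  tc <- binCenters(acq)
  env <- abs(tc - irfCenter(acq)) <= 3 * irfFwhm(acq)
  expect_gt(sum(curve[env]) / sum(curve), 0.99)
})

test_that("marker image generator recovers its own ground truth", {
  cm <- generateCellMasks(30, areaMean = 200, frame = c(256L, 256L),
                          pixelSize = 1, seed = 3)
  # null effect: corrected intensities match the M0 level
  sm <- simulateMarkerImages(cm$masks, meanM0 = 100, foldChange = 1,
                             noiseSd = 5, seed = 4)
  mm <- measureCellIntensities(sm$image, cm$masks)
  expect_lt(abs(mean(mm$corrected) - 100) / 100, 0.05)

  # no cells: background-subtracted means ~ 0 relative to signal scale
  empty <- simulateMarkerImages(matrix(0L, 64, 64), meanM0 = 100,
                                foldChange = 2, backgroundLevel = 7, seed = 5)
  bg <- matrix(FALSE, 64, 64); bg[1:32, ] <- TRUE
  m0 <- measureRoiIntensity(empty$image, !bg, bg)
  expect_lt(abs(m0$corrected), 1)

  expect_error(simulateMarkerImages(cm$masks, foldChange = 0), "foldChange")
  expect_error(simulateMarkerImages(cm$masks, noiseSd = -1), "noiseSd")
})

test_that("scene bundles round-trip through TIFF + JSON sidecar", {
  acq <- testAcq(nBins = 32L)
  scene <- buildScene("50x50", "M0", nCells = 3, pixelSize = 1.0, seed = 2)
  sim <- simulateTcspcStack(scene, acq, seed = 2)
  dir <- withr::local_tempdir()
  writeSceneBundle(sim, scene, dir)
  expect_identical(readTiffStack(file.path(dir, "stack.tif")), sim$stack + 0)
  expect_identical(readLabelTiff(file.path(dir, "cell_masks.tif")),
                   matrix(as.integer(cellMasks(scene)), nrow(cellMasks(scene))))
  sc <- readSceneSidecar(dir)
  expect_equal(sc$acquisition$nBins, 32)
  expect_equal(sc$groundTruth$cell$lifetimes, c(0.42, 2.5))
  acq2 <- acquisitionFromSidecar(sc)
  expect_equal(period(acq2), period(acq))
})
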