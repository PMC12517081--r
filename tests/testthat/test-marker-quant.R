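test_that("ROI intensity measurement subtracts background and rejects overlap", {
  img <- matrix(3, 10, 10)
  roi <- matrix(FALSE, 10, 10); roi[2:4, 2:4] <- TRUE
  bg <- matrix(FALSE, 10, 10); bg[7:9, 7:9] <- TRUE
  img[roi] <- 12
  m <- measureRoiIntensity(img, roi, bg)
  expect_equal(m$corrected, 9)
  # ROI drawn on background-level signal corrects to ~0
  m0 <- measureRoiIntensity(img, bg, local({b <- matrix(FALSE, 10, 10); b[1, ] <- TRUE; b}))
  expect_equal(m0$corrected, 0)
  expect_error(measureRoiIntensity(img, roi, roi), "overlap")
  expect_error(measureRoiIntensity(img, matrix(FALSE, 10, 10), bg), "empty ROI")
})

test_that("normalization to the reference closes to 1 and recovers folds", {
  set.seed(71)
  mkGroup <- function(ph, sub, mu, n = 120) {
    data.frame(phenotype = ph, substrate = sub, marker = "iNOS",
               corrected = rnorm(n, mu, 10))
  }
  df <- rbind(mkGroup("M0", "Flat", 100), mkGroup("M1", "Flat", 219),
              mkGroup("M0", "50x50", 100), mkGroup("M1", "50x50", 105))
  out <- normalizeToReference(df, "M0")
  # closure: the reference group's mean normalized value is exactly 1
  expect_equal(mean(out$normalized[out$phenotype == "M0" &
                                     out$substrate == "Flat"]), 1)
  # fold recovery within sampling error at n = 120
  expect_equal(mean(out$normalized[out$phenotype == "M1" &
                                     out$substrate == "Flat"]), 2.19,
               tolerance = 0.05)
  expect_equal(mean(out$normalized[out$phenotype == "M1" &
                                     out$substrate == "50x50"]), 1.05,
               tolerance = 0.05)
  # a condition with no matched reference is rejected by name
  bad <- rbind(df, mkGroup("M1", "15x15", 200))
  expect_error(normalizeToReference(bad, "M0"), "15x15")
})

test_that("full generator-to-quantification marker recovery stays within 5%", {
  cm <- generateCellMasks(120, areaMean = 120, frame = c(512L, 512L),
                          pixelSize = 1, seed = 72)
  sm <- simulateMarkerImages(cm$masks, meanM0 = 100, foldChange = 2.2,
                             noiseSd = 10, seed = 73)
  mm <- measureCellIntensities(sm$image, cm$masks)
  expect_equal(mean(mm$corrected), 220, tolerance = 220 * 0.05)
})

test_that("induction efficiency counts strictly-positive cells per image", {
  base <- data.frame(phenotype = "M0", substrate = "Flat", marker = "iNOS",
                     corrected = rep(10, 20), image_id = 1L)
  # all cells at exactly the reference mean: strict inequality gives 0%
  m1 <- rbind(base, data.frame(phenotype = "M1", substrate = "Flat",
                               marker = "iNOS", corrected = rep(10, 20),
                               image_id = 1L))
  expect_equal(inductionEfficiency(m1)$efficiency, 0)
  # half the cells above threshold
  m2 <- rbind(base, data.frame(phenotype = "M1", substrate = "Flat",
                               marker = "iNOS",
                               corrected = rep(c(5, 15), 50), image_id = 1L))
  expect_equal(inductionEfficiency(m2)$efficiency, 50)

  # recovery of a 70% positive fraction over 10 seeded images; the
  # positivity threshold (1.2x the M0 mean) separates the shifted
  # (3x) cells from the null cells
  effs <- numeric(10); truth <- numeric(10)
  for (i in 1:10) {
    cm <- generateCellMasks(40, areaMean = 100, frame = c(300L, 300L),
                            pixelSize = 1, seed = 80 + i)
    neg <- simulateMarkerImages(cm$masks, meanM0 = 100, foldChange = 1,
                                noiseSd = 5, seed = 180 + i)
    pos <- simulateMarkerImages(cm$masks, meanM0 = 100, foldChange = 3,
                                noiseSd = 5, positiveFraction = 0.7,
                                seed = 280 + i)
    m0 <- measureCellIntensities(neg$image, cm$masks, image_id = i)
    m0$phenotype <- "M0"
    mi <- measureCellIntensities(pos$image, cm$masks, image_id = i)
    mi$phenotype <- "M1"
    effs[i] <- inductionEfficiency(rbind(m0, mi), by = character(),
                                   threshold = 1.2)$efficiency
    truth[i] <- 100 * mean(pos$groundTruth$positive)
  }
  expect_lt(abs(mean(effs) - mean(truth)), 5)
  expect_lt(abs(mean(effs) - 70), 10)
  expect_true(all(effs >= 0 & effs <= 100))
})

test_that("group comparison picks the branch the data's normality dictates", {
  set.seed(74)
  # three identical groups: omnibus p = 1, nothing significant
  g <- rnorm(30)
  same <- compareGroups(rep(g, 3), rep(letters[1:3], each = 30))
  expect_gt(same@omnibusP, 0.99)
  expect_true(all(same@pairs$p_adj > 0.95))

  # 3-SD separation at n = 50 lands in the strongest significance band
  x <- c(rnorm(50), rnorm(50, 3))
  strong <- compareGroups(x, rep(c("a", "b"), each = 50))
  expect_equal(strong@testUsed, "ANOVA+Tukey")
  expect_lt(strong@pairs$p_adj[1], 1e-4)
  expect_equal(strong@pairs$stars[1], "****")

  # heavy tails force the non-parametric branch
  y <- c(rcauchy(40), rcauchy(40, 2))
  heavy <- compareGroups(y, rep(c("a", "b"), each = 40))
  expect_equal(heavy@testUsed, "KruskalWallis+Dunn")
  expect_false(all(heavy@normality))

  expect_error(compareGroups(rnorm(4), c("a", "a", "a", "b")), "n >= 3")
})

test_that("Dunn's test agrees with the Kruskal-Wallis picture on strong effects", {
  set.seed(75)
  v <- c(rexp(40), rexp(40) + 4, rexp(40))
  g <- rep(c("a", "b", "c"), each = 40)
  dn <- dunnTest(v, g)
  expect_equal(nrow(dn), 3)
  ab <- dn$p_adj[dn$group1 == "a" & dn$group2 == "b"]
  ac <- dn$p_adj[dn$group1 == "a" & dn$group2 == "c"]
  expect_lt(ab, 1e-4)
  expect_gt(ac, 0.05)
  expect_true(all(dn$p_adj >= 0 & dn$p_adj <= 1))
})

test_that("both branches keep their type-I error near the nominal level", {
  set.seed(76)
  nrep <- 300
  pPar <- numeric(nrep); pNon <- numeric(nrep)
  for (i in seq_len(nrep)) {
    vn <- rnorm(90)
    g <- rep(letters[1:3], each = 30)
    pPar[i] <- compareGroups(vn, g, branch = "parametric")@omnibusP
    vl <- rlnorm(90)
    pNon[i] <- compareGroups(vl, g, branch = "nonparametric")@omnibusP
  }
  expect_gt(mean(pPar < 0.05), 0.02)
  expect_lt(mean(pPar < 0.05), 0.08)
  expect_gt(mean(pNon < 0.05), 0.02)
  expect_lt(mean(pNon < 0.05), 0.08)
})
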