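#' Rasterize a scaffold pore lattice
#'
#' Renders the beam lattice of a \linkS4class{ScaffoldSpec} onto a pixel
#' grid: beams (scaffold class, value 2) lie along every lattice plane at
#' multiples of the pore pitch, pore interiors stay open (0). Returns both
#' the analytic pore count (the product formula
#' \eqn{(X/x)(Y/y)(Z/z)}) and the count recovered from the raster itself.
#'
#' Because the beams are full lattice planes, the open space is a Cartesian
#' product of open runs along each axis; the raster count is the product of
#' the per-axis open-run counts read off the rasterized volume.
#'
#' @param spec a \linkS4class{ScaffoldSpec}; construction already enforces
#'   that pore dimensions divide the overall dimensions.
#' @param pixelSize raster pixel size in micrometres.
#' @param dims "2d" for a single mid-height section (a matrix), "3d" for
#'   the full volume (used for pore counting).
#' @return list with \code{labels} (integer matrix or array; 2 = scaffold,
#'   0 = open), \code{poreCount} (analytic) and \code{poreCountRaster}.
#' @examples
#' sp <- ScaffoldSpec(c(50, 50, 20), c(500, 500, 40), beamThickness = 5)
#' lat <- buildScaffoldLattice(sp, pixelSize = 2.5, dims = "3d")
#' lat$poreCount # 200
#' @export
buildScaffoldLattice <- function(spec, pixelSize, dims = c("2d", "3d")) {
  dims <- match.arg(dims)
  stopifnot(is(spec, "ScaffoldSpec"), pixelSize > 0)
  validObject(spec)
  half <- max(spec@beamThickness / 2, pixelSize / 2)
  axisBeam <- function(extent, pitch) {
    centers <- (seq_len(round(extent / pixelSize)) - 0.5) * pixelSize
    lines <- seq(0, extent, by = pitch)
    sapply(centers, function(cc) any(abs(cc - lines) <= half))
  }
  bx <- axisBeam(spec@overallSize[1], spec@poreSize[1])
  by <- axisBeam(spec@overallSize[2], spec@poreSize[2])
  if (dims == "2d") {
    lab <- matrix(0L, length(by), length(bx))
    lab[by, ] <- 2L
    lab[, bx] <- 2L
  } else {
    bz <- axisBeam(spec@overallSize[3], spec@poreSize[3])
    lab <- array(0L, c(length(by), length(bx), length(bz)))
    lab[by, , ] <- 2L
    lab[, bx, ] <- 2L
    lab[, , bz] <- 2L
  }
  list(labels = lab, poreCount = poreCount(spec),
       poreCountRaster = rasterPoreCount(lab))
}

#' Count pores in a rasterized plane lattice
#'
#' Counts open runs along each axis of the raster and multiplies them; exact
#' for lattices whose beams are full planes (the open set is then a product
#' of 1-D open sets, so its connected components factorize by axis).
#'
#' @param labels matrix or 3-D array with 0 = open, 2 = scaffold.
#' @return integer pore count.
#' @export
rasterPoreCount <- function(labels) {
  nd <- length(dim(labels))
  runsAlong <- function(openProfile) {
    r <- rle(openProfile)
    sum(r$values)
  }
  if (nd == 2) {
    openRow <- apply(labels, 1, function(v) !all(v == 2L))
    openCol <- apply(labels, 2, function(v) !all(v == 2L))
    runsAlong(openRow) * runsAlong(openCol)
  } else {
    open1 <- apply(labels, 1, function(v) !all(v == 2L))
    open2 <- apply(labels, 2, function(v) !all(v == 2L))
    open3 <- apply(labels, 3, function(v) !all(v == 2L))
    runsAlong(open1) * runsAlong(open2) * runsAlong(open3)
  }
}

# Even-odd point-in-polygon test, vectorized over points.
.pointsInPolygon <- function(px, py, vx, vy) {
  inside <- rep(FALSE, length(px))
  nv <- length(vx)
  j <- nv
  for (i in seq_len(nv)) {
    denom <- vy[j] - vy[i]
    if (abs(denom) > 1e-300) {
      crosses <- ((vy[i] > py) != (vy[j] > py)) &
        (px < (vx[j] - vx[i]) * (py - vy[i]) / denom + vx[i])
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

# Smoothed random-star polygon in pixel units: harmonic perturbation of an
# ellipse, scaled to an exact target polygon area.
.starPolygon <- function(areaPx, elongation, protrusions, protrusionAmp,
                         nVertices = 96L) {
  th <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  r <- rep(1, nVertices)
  if (protrusions > 0 && protrusionAmp > 0)
    r <- r + protrusionAmp * cos(protrusions * th + runif(1, 0, 2 * pi))
  r <- r + 0.04 * cos(2 * th + runif(1, 0, 2 * pi))
  r <- pmax(r, 0.2)
  rot <- runif(1, 0, pi)
  x <- sqrt(elongation) * r * cos(th)
  y <- (1 / sqrt(elongation)) * r * sin(th)
  xr <- cos(rot) * x - sin(rot) * y
  yr <- sin(rot) * x + cos(rot) * y
  a <- abs(polygonArea(cbind(xr, yr)))
  k <- sqrt(areaPx / a)
  cbind(x = xr * k, y = yr * k)
}

#' Generate non-overlapping synthetic cell masks
#'
#' Places n smoothed random-star polygons (harmonic perturbations of an
#' ellipse, giving independent control of area, elongation and protrusion
#' count) into a frame, rasterizes them without overlap, and returns labelled
#' instance masks plus the generating polygons as ground truth.
#'
#' @param n number of cells (>= 1).
#' @param areaMean mean cell area in square micrometres.
#' @param elongation major/minor axis ratio of the underlying ellipse (1 =
#'   isotropic).
#' @param protrusions number of protrusion lobes (0 = smooth).
#' @param protrusionAmp relative protrusion amplitude.
#' @param frame integer c(rows, cols) of the target image.
#' @param pixelSize micrometres per pixel.
#' @param areaCv coefficient of variation of the per-cell target area.
#' @param allowed optional logical matrix of allowed pixels (e.g. pore
#'   interiors); cells must fall entirely inside it.
#' @param seed optional integer seed; identical seeds give identical masks.
#' @param maxAttempts placement attempts per cell before giving up.
#' @return list with \code{masks} (integer label matrix, 0 background,
#'   1..n per cell), \code{polygons} (list of vertex matrices, pixel
#'   coordinates) and \code{areas} (realized pixel-count areas, um^2).
#' @export
generateCellMasks <- function(n, areaMean = 400, elongation = 1,
                              protrusions = 4, protrusionAmp = 0.12,
                              frame = c(128L, 128L), pixelSize = 0.5,
                              areaCv = 0.15, allowed = NULL, seed = NULL,
                              maxAttempts = 500L) {
  stopifnot(n >= 1, areaMean > 0, elongation > 0, protrusionAmp >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  nr <- frame[1]; nc <- frame[2]
  occupied <- matrix(FALSE, nr, nc)
  masks <- matrix(0L, nr, nc)
  polygons <- vector("list", n)
  areas <- numeric(n)
  for (ci in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(maxAttempts)) {
      target <- max(areaMean * 0.25,
                    stats::rnorm(1, areaMean, areaCv * areaMean))
      poly <- .starPolygon(target / pixelSize^2, elongation, protrusions,
                           protrusionAmp)
      rx <- range(poly[, 1]); ry <- range(poly[, 2])
      if (diff(rx) >= nc - 2 || diff(ry) >= nr - 2) next
      cx <- runif(1, 1 - rx[1], nc - 1 - rx[2])
      cy <- runif(1, 1 - ry[1], nr - 1 - ry[2])
      vx <- poly[, 1] + cx; vy <- poly[, 2] + cy
      cols <- max(1L, floor(min(vx))):min(nc, ceiling(max(vx)))
      rows <- max(1L, floor(min(vy))):min(nr, ceiling(max(vy)))
      px <- rep(cols - 0.5, each = length(rows))
      py <- rep(rows - 0.5, length(cols))
      inside <- .pointsInPolygon(px, py, vx, vy)
      if (!any(inside)) next
      ridx <- rep(rows, length(cols))[inside]
      cidx <- rep(cols, each = length(rows))[inside]
      idx <- cbind(ridx, cidx)
      # 1-pixel separation margin against existing cells
      nbr <- expand.grid(dr = -1:1, dc = -1:1)
      clash <- FALSE
      for (k in seq_len(nrow(nbr))) {
        rr <- pmin(pmax(ridx + nbr$dr[k], 1L), nr)
        cc <- pmin(pmax(cidx + nbr$dc[k], 1L), nc)
        if (any(occupied[cbind(rr, cc)])) { clash <- TRUE; break }
      }
      if (clash) next
      if (!is.null(allowed) && !all(allowed[idx])) next
      masks[idx] <- ci
      occupied[idx] <- TRUE
      polygons[[ci]] <- cbind(x = vx, y = vy)
      areas[ci] <- nrow(idx) * pixelSize^2
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("could not place cell %d of %d: frame too small or too crowded",
                   ci, n))
  }
  list(masks = masks, polygons = polygons, areas = areas)
}

#' Default photophysics ground truth per macrophage phenotype
#'
#' Cell pixels are a two-component free/bound NAD(P)H mixture with the free
#' lifetime at 0.42 ns and the bound lifetime at 2.5 ns (mid-range of the
#' typical 2.0-3.0 ns enzyme-bound window). The bound intensity fraction
#' encodes the metabolic phenotype: 0.3 for glycolytic M1-like cells, 0.5
#' for unpolarized M0, 0.7 for oxidative M2-like cells. The scaffold is a
#' bright mono-exponential autofluorescence class (3.5 ns at five times the
#' cell photon budget); the background is dim.
#'
#' @param phenotype "M0", "M1" or "M2".
#' @param cellPhotons expected photons per cell pixel (default 1000).
#' @param boundFraction optional override of the bound intensity fraction.
#' @return named list of \linkS4class{PhotophysicsClass} for background,
#'   cell and scaffold.
#' @export
defaultPhotophysics <- function(phenotype = c("M0", "M1", "M2"),
                                cellPhotons = 1000,
                                boundFraction = NULL) {
  phenotype <- match.arg(phenotype)
  if (is.null(boundFraction))
    boundFraction <- c(M0 = 0.5, M1 = 0.3, M2 = 0.7)[[phenotype]]
  list(
    background = PhotophysicsClass("background", 1.0, 1, 10),
    cell = PhotophysicsClass("cell", c(0.42, 2.5),
                             c(1 - boundFraction, boundFraction),
                             cellPhotons),
    scaffold = PhotophysicsClass("scaffold", 3.5, 1, 5 * cellPhotons)
  )
}

#' Build a synthetic scene for one substrate/phenotype condition
#'
#' Composes a scaffold section (or a flat field), non-overlapping cell masks
#' confined to the open areas, and the ground-truth photophysics into a
#' \linkS4class{SyntheticScene}.
#'
#' @param substrate "Flat", "50x50" (50 um pores) or "15x15" (15 um pores).
#' @param phenotype macrophage phenotype, see [defaultPhotophysics()].
#' @param nCells number of cells to place.
#' @param pixelSize micrometres per pixel.
#' @param frameUm frame side in micrometres; must be divisible by the pore
#'   pitch for scaffold substrates. Defaults to 100 (Flat, 50x50) or 105
#'   (15x15).
#' @param cellArea mean cell area, um^2.
#' @param elongation,protrusions cell-shape parameters, see
#'   [generateCellMasks()].
#' @param photophysics ground-truth override; default
#'   \code{defaultPhotophysics(phenotype)}.
#' @param beamThickness scaffold beam thickness, um.
#' @param seed integer seed.
#' @return a \linkS4class{SyntheticScene}.
#' @export
buildScene <- function(substrate = c("Flat", "50x50", "15x15"),
                       phenotype = "M0", nCells = 8L, pixelSize = 0.5,
                       frameUm = NULL, cellArea = 250, elongation = 1.4,
                       protrusions = 4, photophysics = NULL,
                       beamThickness = 4, seed = 1L) {
  substrate <- match.arg(substrate)
  if (is.null(photophysics)) photophysics <- defaultPhotophysics(phenotype)
  set.seed(as.integer(seed))
  if (is.null(frameUm)) frameUm <- if (substrate == "15x15") 105 else 100
  frame <- rep(round(frameUm / pixelSize), 2L)
  if (substrate == "Flat") {
    classImg <- matrix(0L, frame[1], frame[2])
  } else {
    pore <- if (substrate == "50x50") c(50, 50, 20) else c(15, 15, 15)
    spec <- ScaffoldSpec(pore, c(frameUm, frameUm, pore[3]), beamThickness)
    classImg <- buildScaffoldLattice(spec, pixelSize, dims = "2d")$labels
  }
  allowed <- classImg == 0L
  cm <- generateCellMasks(nCells, areaMean = cellArea,
                          elongation = elongation, protrusions = protrusions,
                          frame = frame, pixelSize = pixelSize,
                          allowed = allowed,
                          seed = sample.int(.Machine$integer.max, 1))
  classImg[cm$masks > 0L] <- 1L
  scene <- new("SyntheticScene", classImage = classImg, cellMasks = cm$masks,
               groundTruth = photophysics, seed = as.integer(seed))
  attr(scene@cellMasks, "polygons") <- cm$polygons
  scene
}

#' Simulate a TCSPC time-resolved stack from a scene
#'
#' Every pixel receives the expectation of its class (two-component decay
#' convolved with the Gaussian IRF, folded over one repetition period,
#' scaled to the class photon budget) and is then Poisson-sampled per time
#' bin. With \code{poisson = FALSE} the noiseless expectation stack is
#' returned, which downstream oracle tests rely on.
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param acq an \linkS4class{AcquisitionConfig}.
#' @param seed integer seed for the photon noise.
#' @param poisson apply Poisson sampling (default TRUE).
#' @return list with \code{stack} (array rows x cols x bins) and
#'   \code{sidecar} (acquisition, exact generating parameters, seed and the
#'   per-class pixel census).
#' @export
simulateTcspcStack <- function(scene, acq, seed = 1L, poisson = TRUE) {
  stopifnot(is(scene, "SyntheticScene"), is(acq, "AcquisitionConfig"))
  set.seed(as.integer(seed))
  classImg <- classImage(scene)
  gt <- groundTruth(scene)
  d <- dim(classImg)
  nb <- nTimeBins(acq)
  flat <- matrix(0, prod(d), nb)
  codes <- c(background = 0L, cell = 1L, scaffold = 2L)
  census <- list()
  for (nm in names(codes)) {
    idx <- which(classImg == codes[[nm]])
    if (!length(idx)) next
    ph <- gt[[nm]]
    if (is.null(ph)) stop(sprintf("no ground truth for class '%s'", nm))
    if (ph@meanPhotons <= 0) stop("photon budget must be positive")
    curve <- expectedClassDecay(ph, acq, ph@meanPhotons)
    if (poisson) {
      flat[idx, ] <- matrix(
        stats::rpois(length(idx) * nb, rep(curve, each = length(idx))),
        length(idx), nb)
    } else {
      flat[idx, ] <- matrix(rep(curve, each = length(idx)), length(idx), nb)
    }
    census[[nm]] <- length(idx)
  }
  sidecar <- list(
    acquisition = list(repRate = repetitionRate(acq), nBins = nb,
                       pixelSize = pixelSize(acq), irfCenter = irfCenter(acq),
                       irfFwhm = irfFwhm(acq)),
    groundTruth = lapply(gt, function(p) list(
      label = p@label, lifetimes = p@lifetimes, fractions = p@fractions,
      meanPhotons = p@meanPhotons)),
    classCensus = census, seed = as.integer(seed), poisson = poisson,
    sceneSeed = scene@seed)
  list(stack = array(flat, c(d, nb)), sidecar = sidecar)
}

#' Simulate a single aggregated ROI decay histogram
#'
#' Convenience generator for fitting studies: the expected class decay scaled
#' to a total photon budget (e.g. ~1e3 photons/pixel times the ROI pixel
#' count), Poisson-sampled per bin.
#'
#' @param photophysics a \linkS4class{PhotophysicsClass}.
#' @param acq an \linkS4class{AcquisitionConfig}.
#' @param totalPhotons expected total photons in the ROI histogram.
#' @param seed optional integer seed.
#' @param poisson apply Poisson noise (default TRUE).
#' @return a \linkS4class{DecayHistogram}.
#' @export
simulateRoiDecay <- function(photophysics, acq, totalPhotons = 1e5,
                             seed = NULL, poisson = TRUE) {
  if (totalPhotons <= 0) stop("photon budget must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  curve <- expectedClassDecay(photophysics, acq, totalPhotons)
  cts <- if (poisson) stats::rpois(length(curve), curve) else curve
  DecayHistogram(cts, acq)
}

#' Simulate a marker-intensity image for labelled cells
#'
#' Each cell's mean marker level is drawn around \code{meanM0 * foldChange}
#' (positives) or \code{meanM0} (negatives, when \code{positiveFraction} < 1),
#' with additive between-cell noise; pixel shot noise and a flat background
#' are added on top. Ground truth (per-cell true mean and positivity) is
#' returned for recovery tests.
#'
#' @param cellMasks integer label matrix (0 = background).
#' @param meanM0 reference (M0) mean corrected intensity, a.u.
#' @param foldChange marker fold change over M0 (> 0).
#' @param noiseSd between-cell SD of the mean, a.u. (>= 0).
#' @param positiveFraction fraction of cells expressing the marker.
#' @param backgroundLevel flat background offset, a.u.
#' @param pixelNoiseSd per-pixel additive noise SD, a.u.
#' @param seed optional integer seed.
#' @return list with \code{image} (numeric matrix) and \code{groundTruth}
#'   (data.frame cell_id, true_mean, positive).
#' @export
simulateMarkerImages <- function(cellMasks, meanM0 = 100, foldChange = 1,
                                 noiseSd = 10, positiveFraction = 1,
                                 backgroundLevel = 5, pixelNoiseSd = 2,
                                 seed = NULL) {
  if (foldChange <= 0) stop("foldChange must be positive")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  stopifnot(positiveFraction >= 0, positiveFraction <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- dim(cellMasks)
  img <- backgroundLevel + matrix(stats::rnorm(prod(d), 0, pixelNoiseSd), d[1], d[2])
  ids <- setdiff(sort(unique(as.vector(cellMasks))), 0L)
  gt <- data.frame(cell_id = integer(), true_mean = numeric(),
                   positive = logical())
  for (id in ids) {
    positive <- stats::runif(1) < positiveFraction
    mu <- meanM0 * (if (positive) foldChange else 1) +
      stats::rnorm(1, 0, noiseSd)
    mu <- max(mu, 0)
    img[cellMasks == id] <- img[cellMasks == id] + mu
    gt <- rbind(gt, data.frame(cell_id = id, true_mean = mu,
                               positive = positive))
  }
  list(image = img, groundTruth = gt)
}
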