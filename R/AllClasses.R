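#' @useDynLib flimScaffold, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' TCSPC acquisition configuration
#'
#' Describes the time-resolved acquisition: laser repetition rate, number of
#' time bins spanning one repetition period, pixel size, and the Gaussian
#' instrument response function (IRF) used both to simulate and to fit decays.
#'
#' @slot repRate laser repetition rate in Hz.
#' @slot nBins number of TCSPC time bins spanning one period.
#' @slot pixelSize lateral pixel size in micrometres.
#' @slot irfCenter centre of the Gaussian IRF in ns.
#' @slot irfFwhm full width at half maximum of the Gaussian IRF in ns
#'   (0 selects a delta IRF).
#'
#' @details The repetition period is \eqn{T = 1/f} (12.5 ns at the default
#' 80 MHz) and the fundamental angular frequency used by the phasor transform
#' is \eqn{\omega = 2\pi f}.
#'
#' @export
setClass("AcquisitionConfig",
  representation(
    repRate = "numeric",
    nBins = "integer",
    pixelSize = "numeric",
    irfCenter = "numeric",
    irfFwhm = "numeric"
  )
)

setValidity("AcquisitionConfig", function(object) {
  msg <- character()
  if (length(object@repRate) != 1 || object@repRate <= 0)
    msg <- c(msg, "repRate must be a single positive number (Hz)")
  if (length(object@nBins) != 1 || object@nBins < 16L)
    msg <- c(msg, "nBins must be >= 16")
  if (object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be positive")
  if (object@irfFwhm < 0)
    msg <- c(msg, "irfFwhm must be >= 0")
  if (object@irfCenter < 0)
    msg <- c(msg, "irfCenter must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an acquisition configuration
#'
#' @param repRate laser repetition rate in Hz (default 80 MHz).
#' @param nBins number of time bins per period.
#' @param pixelSize pixel size in micrometres.
#' @param irfCenter Gaussian IRF centre in ns.
#' @param irfFwhm Gaussian IRF FWHM in ns; 0 gives a delta IRF.
#' @return an \linkS4class{AcquisitionConfig}.
#' @examples
#' acq <- AcquisitionConfig()
#' period(acq) # 12.5 ns at 80 MHz
#' @export
AcquisitionConfig <- function(repRate = 80e6, nBins = 256L, pixelSize = 0.5,
                              irfCenter = 1.0, irfFwhm = 0.25) {
  new("AcquisitionConfig", repRate = repRate, nBins = as.integer(nBins),
      pixelSize = pixelSize, irfCenter = irfCenter, irfFwhm = irfFwhm)
}

#' Scaffold lattice geometry
#'
#' A simple cuboidal pore lattice: identical rectangular pores separated by
#' beams, filling the overall volume exactly.
#'
#' @slot poreSize pore dimensions (x, y, z) in micrometres.
#' @slot overallSize overall scaffold dimensions (X, Y, Z) in micrometres.
#' @slot beamThickness beam thickness in micrometres.
#' @export
setClass("ScaffoldSpec",
  representation(
    poreSize = "numeric",
    overallSize = "numeric",
    beamThickness = "numeric"
  )
)

setValidity("ScaffoldSpec", function(object) {
  msg <- character()
  if (length(object@poreSize) != 3 || any(object@poreSize <= 0))
    msg <- c(msg, "poreSize must be three positive dimensions (x, y, z)")
  if (length(object@overallSize) != 3 || any(object@overallSize <= 0))
    msg <- c(msg, "overallSize must be three positive dimensions (X, Y, Z)")
  if (length(object@beamThickness) != 1 || object@beamThickness <= 0)
    msg <- c(msg, "beamThickness must be positive")
  if (length(msg) == 0) {
    ratio <- object@overallSize / object@poreSize
    bad <- abs(ratio - round(ratio)) > 1e-9
    if (any(bad)) {
      ax <- c("x", "y", "z")[bad]
      msg <- c(msg, sprintf(
        "pore dimensions must divide overall dimensions exactly; offending axis: %s",
        paste(ax, collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a scaffold lattice specification
#'
#' @param poreSize pore (x, y, z) in micrometres.
#' @param overallSize overall (X, Y, Z) in micrometres.
#' @param beamThickness beam thickness in micrometres.
#' @return a \linkS4class{ScaffoldSpec}.
#' @examples
#' sp <- ScaffoldSpec(c(50, 50, 20), c(500, 500, 40))
#' poreCount(sp) # 200
#' @export
ScaffoldSpec <- function(poreSize, overallSize, beamThickness = 2) {
  new("ScaffoldSpec", poreSize = as.numeric(poreSize),
      overallSize = as.numeric(overallSize),
      beamThickness = as.numeric(beamThickness))
}

#' Photophysics of a scene class
#'
#' Ground-truth emission model for one pixel class (background, cell or
#' scaffold): a mixture of mono-exponential lifetime components described by
#' their lifetimes and intensity (photon) fractions, plus the expected photon
#' budget per pixel.
#'
#' @slot label one of "background", "cell", "scaffold".
#' @slot lifetimes component lifetimes in ns.
#' @slot fractions intensity fractions per component; non-negative, sum to 1.
#' @slot meanPhotons expected photons per pixel.
#' @export
setClass("PhotophysicsClass",
  representation(
    label = "character",
    lifetimes = "numeric",
    fractions = "numeric",
    meanPhotons = "numeric"
  )
)

setValidity("PhotophysicsClass", function(object) {
  msg <- character()
  if (!object@label %in% c("background", "cell", "scaffold"))
    msg <- c(msg, "label must be one of 'background', 'cell', 'scaffold'")
  if (length(object@lifetimes) != length(object@fractions))
    msg <- c(msg, "lifetimes and fractions must have equal length")
  if (any(object@lifetimes <= 0))
    msg <- c(msg, "lifetimes must be positive")
  if (any(object@fractions < 0) || abs(sum(object@fractions) - 1) > 1e-9)
    msg <- c(msg, "fractions must be non-negative and sum to 1")
  if (identical(object@label, "scaffold") && sum(object@fractions > 0) != 1)
    msg <- c(msg, "scaffold class must be mono-exponential")
  if (length(object@meanPhotons) != 1 || object@meanPhotons <= 0)
    msg <- c(msg, "meanPhotons must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a photophysics class
#'
#' @param label class label.
#' @param lifetimes component lifetimes (ns).
#' @param fractions intensity fractions (sum to 1).
#' @param meanPhotons expected photons per pixel.
#' @return a \linkS4class{PhotophysicsClass}.
#' @export
PhotophysicsClass <- function(label, lifetimes, fractions, meanPhotons) {
  new("PhotophysicsClass", label = label, lifetimes = as.numeric(lifetimes),
      fractions = as.numeric(fractions), meanPhotons = as.numeric(meanPhotons))
}

#' A synthetic scene with ground truth
#'
#' Class-labelled image (0 = background, 1 = cell, 2 = scaffold), labelled
#' cell instance masks, and the generating photophysics per class. The anchor
#' of every downstream recovery test: all generating parameters are readable
#' from the object.
#'
#' @slot classImage integer matrix of pixel classes.
#' @slot cellMasks integer matrix; 0 outside cells, 1..n per cell instance.
#' @slot groundTruth named list of \linkS4class{PhotophysicsClass} keyed by
#'   class label.
#' @slot seed integer seed the scene was generated from.
#' @export
setClass("SyntheticScene",
  representation(
    classImage = "matrix",
    cellMasks = "matrix",
    groundTruth = "list",
    seed = "integer"
  )
)

setValidity("SyntheticScene", function(object) {
  msg <- character()
  if (!all(dim(object@classImage) == dim(object@cellMasks)))
    msg <- c(msg, "classImage and cellMasks must have identical dimensions")
  if (!all(object@classImage %in% 0:2))
    msg <- c(msg, "classImage values must be 0 (background), 1 (cell) or 2 (scaffold)")
  if (any(object@cellMasks > 0 & object@classImage != 1))
    msg <- c(msg, "cell instances must lie inside the cell class")
  present <- c("background", "cell", "scaffold")[1:3 %in% (unique(as.vector(object@classImage)) + 1)]
  missing <- setdiff(present, names(object@groundTruth))
  if (length(missing))
    msg <- c(msg, sprintf("groundTruth missing for class present in scene: %s",
                          paste(missing, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' A TCSPC decay histogram
#'
#' Photon counts per time bin for a pixel or an ROI, together with the bin
#' geometry and the acquisition it came from. The unit of decay fitting.
#'
#' @slot counts non-negative counts per time bin.
#' @slot binWidth bin width in ns.
#' @slot origin time of the leading edge of the first bin, ns.
#' @slot acq the \linkS4class{AcquisitionConfig}.
#' @export
setClass("DecayHistogram",
  representation(
    counts = "numeric",
    binWidth = "numeric",
    origin = "numeric",
    acq = "AcquisitionConfig"
  )
)

setValidity("DecayHistogram", function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be positive")
  span <- object@origin + length(object@counts) * object@binWidth
  if (span > period(object@acq) * (1 + 1e-9))
    msg <- c(msg, "bins must span at most one repetition period")
  if (length(msg)) msg else TRUE
})

#' Construct a decay histogram
#'
#' @param counts photon counts per bin.
#' @param acq acquisition configuration.
#' @param binWidth bin width in ns; defaults to one period / nBins(acq).
#' @param origin leading edge of the first bin in ns.
#' @return a \linkS4class{DecayHistogram}.
#' @export
DecayHistogram <- function(counts, acq, binWidth = period(acq) / nTimeBins(acq),
                           origin = 0) {
  new("DecayHistogram", counts = as.numeric(counts), binWidth = binWidth,
      origin = origin, acq = acq)
}

#' Result of a bi-exponential reconvolution fit
#'
#' Fitted amplitudes and lifetimes of the two NAD(P)H components, background,
#' the amplitude-weighted mean lifetime, reduced chi-squared, and convergence
#' metadata.
#'
#' @slot alpha1,alpha2 non-negative amplitudes of the short and long component.
#' @slot tau1,tau2 lifetimes in ns with tau1 < tau2.
#' @slot C background counts per bin.
#' @slot tauMean amplitude-weighted mean lifetime, ns.
#' @slot chi2 reduced chi-squared of the fit.
#' @slot fixed names of parameters held fixed during the fit.
#' @slot converged logical convergence flag.
#' @slot nIter number of optimizer iterations of the accepted start.
#' @export
setClass("BiExpFit",
  representation(
    alpha1 = "numeric", alpha2 = "numeric",
    tau1 = "numeric", tau2 = "numeric", background = "numeric",
    tauMean = "numeric", chi2 = "numeric",
    fixed = "character", converged = "logical", nIter = "integer"
  )
)

#' Per-pixel phasor field
#'
#' Per-pixel phasor coordinates (g, s), total intensity, and a keep-mask that
#' the filtering operations update. Pixels with zero intensity are masked from
#' the start.
#'
#' @slot g,s phasor coordinate matrices.
#' @slot intensity total photon counts per pixel.
#' @slot mask logical matrix, TRUE where the pixel is kept.
#' @slot calibrated TRUE once the fluorescein-style calibration was applied.
#' @slot harmonic harmonic of the transform (>= 1).
#' @slot acq the \linkS4class{AcquisitionConfig}.
#' @export
setClass("PhasorField",
  representation(
    g = "matrix", s = "matrix", intensity = "matrix", mask = "matrix",
    calibrated = "logical", harmonic = "integer", acq = "AcquisitionConfig"
  )
)

setValidity("PhasorField", function(object) {
  msg <- character()
  d <- dim(object@g)
  if (!all(dim(object@s) == d) || !all(dim(object@intensity) == d) ||
      !all(dim(object@mask) == d))
    msg <- c(msg, "g, s, intensity and mask must share dimensions")
  if (object@harmonic < 1L) msg <- c(msg, "harmonic must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Phasor calibration
#'
#' Complex correction mapping the measured phasor of a mono-exponential
#' reference dye onto its theoretical position on the universal semicircle.
#'
#' @slot tauRef reference lifetime in ns.
#' @slot measuredG,measuredS measured reference phasor.
#' @slot modulation modulation ratio of the correction.
#' @slot phase phase offset of the correction, radians.
#' @export
setClass("PhasorCalibration",
  representation(
    tauRef = "numeric", measuredG = "numeric", measuredS = "numeric",
    modulation = "numeric", phase = "numeric"
  )
)

#' Group comparison result
#'
#' Omnibus + post-hoc comparison following the normality-gated two-branch
#' scheme: Shapiro-Wilk per group, then either one-way ANOVA with Tukey's
#' post-hoc (all groups normal) or Kruskal-Wallis with Dunn's post-hoc.
#'
#' @slot testUsed "ANOVA+Tukey" or "KruskalWallis+Dunn".
#' @slot statistic omnibus test statistic.
#' @slot omnibusP omnibus p-value.
#' @slot pairs data.frame of pairwise comparisons with adjusted p-values and
#'   significance stars.
#' @slot normality named logical: Shapiro-Wilk pass (p >= alpha) per group.
#' @slot alpha significance level used throughout.
#' @export
setClass("GroupComparison",
  representation(
    testUsed = "character", statistic = "numeric", omnibusP = "numeric",
    pairs = "data.frame", normality = "logical", alpha = "numeric"
  )
)
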