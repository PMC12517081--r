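#' @name accessors
#' @title Accessors for flimScaffold classes
#' @description Small accessor generics: slot access stays behind functions.
#' @param object an object of the documented class.
#' @param x an object of the documented class.
NULL

#' @rdname accessors
#' @export
setGeneric("repetitionRate", function(object) standardGeneric("repetitionRate"))
#' @rdname accessors
#' @export
setMethod("repetitionRate", "AcquisitionConfig", function(object) object@repRate)

#' @rdname accessors
#' @export
setGeneric("nTimeBins", function(object) standardGeneric("nTimeBins"))
#' @rdname accessors
#' @export
setMethod("nTimeBins", "AcquisitionConfig", function(object) object@nBins)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "AcquisitionConfig", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setGeneric("period", function(object) standardGeneric("period"))

#' Repetition period in ns
#' @rdname accessors
#' @export
setMethod("period", "AcquisitionConfig", function(object) 1e9 / object@repRate)

#' @rdname accessors
#' @export
setGeneric("angularFrequency", function(object) standardGeneric("angularFrequency"))

#' Fundamental angular frequency in rad/ns
#' @rdname accessors
#' @export
setMethod("angularFrequency", "AcquisitionConfig",
          function(object) 2 * pi * object@repRate * 1e-9)

#' @rdname accessors
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))
#' @rdname accessors
#' @export
setMethod("binWidth", "AcquisitionConfig",
          function(object) period(object) / object@nBins)
#' @rdname accessors
#' @export
setMethod("binWidth", "DecayHistogram", function(object) object@binWidth)

#' Bin centres of the TCSPC window in ns
#' @rdname accessors
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setMethod("binCenters", "AcquisitionConfig", function(object) {
  (seq_len(object@nBins) - 0.5) * binWidth(object)
})
#' @rdname accessors
#' @export
setMethod("binCenters", "DecayHistogram", function(object) {
  object@origin + (seq_along(object@counts) - 0.5) * object@binWidth
})

#' @rdname accessors
#' @export
setGeneric("irfCenter", function(object) standardGeneric("irfCenter"))
#' @rdname accessors
#' @export
setMethod("irfCenter", "AcquisitionConfig", function(object) object@irfCenter)

#' @rdname accessors
#' @export
setGeneric("irfFwhm", function(object) standardGeneric("irfFwhm"))
#' @rdname accessors
#' @export
setMethod("irfFwhm", "AcquisitionConfig", function(object) object@irfFwhm)

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setMethod("counts", "DecayHistogram", function(object) object@counts)

#' Total photons in a histogram
#' @rdname accessors
#' @export
setGeneric("nPhotons", function(object) standardGeneric("nPhotons"))
#' @rdname accessors
#' @export
setMethod("nPhotons", "DecayHistogram", function(object) sum(object@counts))

#' @rdname accessors
#' @export
setGeneric("acquisition", function(object) standardGeneric("acquisition"))
#' @rdname accessors
#' @export
setMethod("acquisition", "DecayHistogram", function(object) object@acq)
#' @rdname accessors
#' @export
setMethod("acquisition", "PhasorField", function(object) object@acq)

#' Analytic pore count of a scaffold lattice
#' @rdname accessors
#' @export
setGeneric("poreCount", function(object) standardGeneric("poreCount"))
#' @rdname accessors
#' @export
setMethod("poreCount", "ScaffoldSpec", function(object) {
  prod(round(object@overallSize / object@poreSize))
})

#' Number of lattice layers (Z / pore z)
#' @rdname accessors
#' @export
setGeneric("nLayers", function(object) standardGeneric("nLayers"))
#' @rdname accessors
#' @export
setMethod("nLayers", "ScaffoldSpec", function(object) {
  round(object@overallSize[3] / object@poreSize[3])
})

#' @rdname accessors
#' @export
setGeneric("classImage", function(object) standardGeneric("classImage"))
#' @rdname accessors
#' @export
setMethod("classImage", "SyntheticScene", function(object) object@classImage)

#' @rdname accessors
#' @export
setGeneric("cellMasks", function(object) standardGeneric("cellMasks"))
#' @rdname accessors
#' @export
setMethod("cellMasks", "SyntheticScene", function(object) object@cellMasks)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "SyntheticScene", function(object) object@groundTruth)

#' Fit parameter accessors
#' @rdname accessors
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))
#' @rdname accessors
#' @export
setMethod("fitParams", "BiExpFit", function(object) {
  c(alpha1 = object@alpha1, alpha2 = object@alpha2,
    tau1 = object@tau1, tau2 = object@tau2, C = object@background)
})

#' Amplitude-weighted mean lifetime of a fit, ns
#' @rdname accessors
#' @export
setGeneric("tauMean", function(object) standardGeneric("tauMean"))
#' @rdname accessors
#' @export
setMethod("tauMean", "BiExpFit", function(object) object@tauMean)

#' Reduced chi-squared of a fit
#' @rdname accessors
#' @export
setGeneric("chiSquared", function(object) standardGeneric("chiSquared"))
#' @rdname accessors
#' @export
setMethod("chiSquared", "BiExpFit", function(object) object@chi2)

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setMethod("isConverged", "BiExpFit", function(object) object@converged)

#' Intensity fraction of the long (bound) component implied by a fit
#'
#' \eqn{f_2 = \alpha_2\tau_2 / (\alpha_1\tau_1 + \alpha_2\tau_2)}: the photon
#' fraction emitted by the bound-NAD(P)H component.
#' @rdname accessors
#' @export
setGeneric("boundFraction", function(object) standardGeneric("boundFraction"))
#' @rdname accessors
#' @export
setMethod("boundFraction", "BiExpFit", function(object) {
  num <- object@alpha2 * object@tau2
  num / (object@alpha1 * object@tau1 + num)
})

#' @rdname accessors
#' @export
setGeneric("phasorG", function(object) standardGeneric("phasorG"))
#' @rdname accessors
#' @export
setMethod("phasorG", "PhasorField", function(object) object@g)

#' @rdname accessors
#' @export
setGeneric("phasorS", function(object) standardGeneric("phasorS"))
#' @rdname accessors
#' @export
setMethod("phasorS", "PhasorField", function(object) object@s)

#' @rdname accessors
#' @export
setGeneric("intensityImage", function(object) standardGeneric("intensityImage"))
#' @rdname accessors
#' @export
setMethod("intensityImage", "PhasorField", function(object) object@intensity)

#' Keep-mask of a phasor field (TRUE = kept)
#' @rdname accessors
#' @export
setGeneric("keptMask", function(object) standardGeneric("keptMask"))
#' @rdname accessors
#' @export
setMethod("keptMask", "PhasorField", function(object) object@mask)

#' @rdname accessors
#' @export
setGeneric("isCalibrated", function(object) standardGeneric("isCalibrated"))
#' @rdname accessors
#' @export
setMethod("isCalibrated", "PhasorField", function(object) object@calibrated)

setMethod("show", "AcquisitionConfig", function(object) {
  cat(sprintf(
    "AcquisitionConfig: %.0f MHz (T = %.4g ns), %d bins (%.4g ns), %.3g um/px, IRF %g +- %g ns\n",
    object@repRate / 1e6, period(object), object@nBins, binWidth(object),
    object@pixelSize, object@irfCenter, object@irfFwhm))
})

setMethod("show", "ScaffoldSpec", function(object) {
  cat(sprintf(
    "ScaffoldSpec: %s um pores in %s um (%d pores, %d layer(s), beam %.3g um)\n",
    paste(object@poreSize, collapse = "x"),
    paste(object@overallSize, collapse = "x"),
    poreCount(object), nLayers(object), object@beamThickness))
})

setMethod("show", "SyntheticScene", function(object) {
  d <- dim(object@classImage)
  cat(sprintf(
    "SyntheticScene: %d x %d px, %d cell(s), classes: %s (seed %d)\n",
    d[1], d[2], max(object@cellMasks),
    paste(names(object@groundTruth), collapse = ", "), object@seed))
})

setMethod("show", "DecayHistogram", function(object) {
  cat(sprintf("DecayHistogram: %d bins x %.4g ns, %d photons\n",
              length(object@counts), object@binWidth, round(nPhotons(object))))
})

setMethod("show", "BiExpFit", function(object) {
  cat(sprintf(
    "BiExpFit: tau1 = %.4g ns, tau2 = %.4g ns, a1 = %.4g, a2 = %.4g, C = %.4g\n",
    object@tau1, object@tau2, object@alpha1, object@alpha2, object@background))
  cat(sprintf("  tau_mean = %.4g ns, reduced chi2 = %.4g, %s%s\n",
              object@tauMean, object@chi2,
              if (object@converged) "converged" else "NOT converged",
              if (length(object@fixed)) paste0(" (fixed: ",
                paste(object@fixed, collapse = ", "), ")") else ""))
})

setMethod("show", "PhasorField", function(object) {
  d <- dim(object@g)
  cat(sprintf("PhasorField: %d x %d px, %d kept, harmonic %d, %s\n",
              d[1], d[2], sum(object@mask), object@harmonic,
              if (object@calibrated) "calibrated" else "uncalibrated"))
})

setMethod("show", "PhasorCalibration", function(object) {
  cat(sprintf(
    "PhasorCalibration: tau_ref = %.3g ns, measured (%.4g, %.4g), modulation %.4g, phase %.4g rad\n",
    object@tauRef, object@measuredG, object@measuredS,
    object@modulation, object@phase))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison: %s, omnibus statistic %.4g, p = %.3g\n",
              object@testUsed, object@statistic, object@omnibusP))
  print(object@pairs, row.names = FALSE)
})
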