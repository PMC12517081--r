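#' Phasor transform of a decay or a time-resolved stack
#'
#' Maps each decay to its Fourier phasor coordinates at the (harmonic of the)
#' laser repetition frequency:
#' \eqn{g = \sum_t I(t)\cos(\omega t) / \sum_t I(t)},
#' \eqn{s = \sum_t I(t)\sin(\omega t) / \sum_t I(t)},
#' summed over bin centres (the discrete realization of the continuous
#' integrals), with \eqn{\omega = 2\pi\,\mathrm{harmonic}\,f}.
#'
#' @param x a \linkS4class{DecayHistogram} or a numeric array
#'   \code{[rows, cols, timebins]}.
#' @param acq the \linkS4class{AcquisitionConfig}; taken from the histogram
#'   when \code{x} is one.
#' @param harmonic integer harmonic (>= 1), default 1.
#' @return for a histogram, a named numeric \code{c(g =, s =)}; for a stack,
#'   a \linkS4class{PhasorField} in which all-zero pixels are masked.
#' @examples
#' acq <- AcquisitionConfig(irfCenter = 0, irfFwhm = 0, nBins = 4096L)
#' tau <- 1 / angularFrequency(acq) # omega * tau = 1
#' h <- DecayHistogram(modelDecay(1, 0, tau, tau * 2, 0, acq) , acq)
#' phasorTransform(h) # close to (0.5, 0.5)
#' @export
phasorTransform <- function(x, acq = NULL, harmonic = 1L) {
  harmonic <- as.integer(harmonic)
  stopifnot(harmonic >= 1L)
  if (is(x, "DecayHistogram")) {
    if (is.null(acq)) acq <- acquisition(x)
    cts <- counts(x)
    if (sum(cts) <= 0) stop("zero-bin histogram: phasor undefined")
    w <- angularFrequency(acq) * harmonic
    tc <- binCenters(x)
    tot <- sum(cts)
    return(c(g = sum(cts * cos(w * tc)) / tot,
             s = sum(cts * sin(w * tc)) / tot))
  }
  stopifnot(length(dim(x)) == 3, !is.null(acq))
  if (any(x < 0)) stop("counts must be non-negative")
  w <- angularFrequency(acq) * harmonic
  tc <- binCenters(acq)[seq_len(dim(x)[3])]
  npix <- prod(dim(x)[1:2])
  m <- matrix(x, nrow = npix, ncol = dim(x)[3])
  tot <- rowSums(m)
  gv <- as.vector(m %*% cos(w * tc))
  sv <- as.vector(m %*% sin(w * tc))
  keep <- tot > 0
  gv <- ifelse(keep, gv / pmax(tot, 1e-300), NA_real_)
  sv <- ifelse(keep, sv / pmax(tot, 1e-300), NA_real_)
  d <- dim(x)[1:2]
  new("PhasorField",
      g = matrix(gv, d[1], d[2]), s = matrix(sv, d[1], d[2]),
      intensity = matrix(tot, d[1], d[2]), mask = matrix(keep, d[1], d[2]),
      calibrated = FALSE, harmonic = harmonic, acq = acq)
}

#' Theoretical phasor of a mono-exponential lifetime
#'
#' The continuous-time limit of the transform:
#' \eqn{g = 1/(1+(\omega\tau)^2)}, \eqn{s = \omega\tau/(1+(\omega\tau)^2)}.
#' For every \eqn{\tau} the point lies exactly on the universal semicircle
#' \eqn{(g-1/2)^2 + s^2 = 1/4}.
#'
#' @param tau lifetime in ns (> 0).
#' @param acq the \linkS4class{AcquisitionConfig}.
#' @param harmonic integer harmonic, default 1.
#' @return named numeric \code{c(g =, s =)}.
#' @export
theoreticalPhasor <- function(tau, acq, harmonic = 1L) {
  stopifnot(tau > 0)
  wt <- angularFrequency(acq) * as.integer(harmonic) * tau
  c(g = 1 / (1 + wt^2), s = wt / (1 + wt^2))
}

#' Compute a phasor calibration from a mono-exponential reference
#'
#' A dye with a known mono-exponential decay (fluorescein in the original
#' protocol) maps instrument artefacts — IRF delay and demodulation — into a
#' single complex factor: the ratio of the theoretical phasor of
#' \code{tauRef} to the measured reference phasor. Its modulus is the
#' modulation correction, its argument the phase correction.
#'
#' @param reference a \linkS4class{DecayHistogram} or stack array of the
#'   reference dye (>= 1e4 total photons recommended).
#' @param tauRef reference lifetime in ns (default 4.0 ns, fluorescein).
#' @param acq acquisition (taken from the histogram if omitted).
#' @param harmonic integer harmonic.
#' @return a \linkS4class{PhasorCalibration}.
#' @export
phasorCalibration <- function(reference, tauRef = 4.0, acq = NULL,
                              harmonic = 1L) {
  if (is(reference, "DecayHistogram")) {
    if (is.null(acq)) acq <- acquisition(reference)
    meas <- phasorTransform(reference, acq, harmonic)
  } else {
    stopifnot(!is.null(acq))
    fld <- phasorTransform(reference, acq, harmonic)
    meas <- phasorCentroid(fld, weighted = TRUE)
  }
  zm <- complex(real = meas["g"], imaginary = meas["s"])
  if (Mod(zm) < 1e-12) stop("reference phasor at the origin: uncalibratable")
  th <- theoreticalPhasor(tauRef, acq, harmonic)
  zc <- complex(real = th["g"], imaginary = th["s"]) / zm
  new("PhasorCalibration", tauRef = tauRef,
      measuredG = unname(meas["g"]), measuredS = unname(meas["s"]),
      modulation = Mod(zc), phase = Arg(zc))
}

#' Calibrate a phasor field
#'
#' Applies the complex correction of a \linkS4class{PhasorCalibration}
#' (rotation by the phase offset, scaling by the modulation ratio) to every
#' pixel. A field can only be calibrated once; a second application is
#' refused by a guard.
#'
#' @param field a \linkS4class{PhasorField}.
#' @param calibration a \linkS4class{PhasorCalibration}, or a reference
#'   histogram/stack from which one is computed.
#' @param tauRef reference lifetime when \code{calibration} is raw data.
#' @return the calibrated \linkS4class{PhasorField}.
#' @export
calibratePhasor <- function(field, calibration, tauRef = 4.0) {
  stopifnot(is(field, "PhasorField"))
  if (isCalibrated(field))
    stop("field is already calibrated; refusing to apply calibration twice")
  if (!is(calibration, "PhasorCalibration"))
    calibration <- phasorCalibration(calibration, tauRef = tauRef,
                                     acq = acquisition(field),
                                     harmonic = field@harmonic)
  z <- complex(real = field@g, imaginary = field@s) *
    complex(modulus = calibration@modulation, argument = calibration@phase)
  field@g <- matrix(Re(z), nrow(field@g), ncol(field@g))
  field@s <- matrix(Im(z), nrow(field@s), ncol(field@s))
  field@calibrated <- TRUE
  field
}

#' Iterated masked 3x3 median filter of the phasor channels
#'
#' Median-filters the g and s channels independently (default four
#' iterations of a 3x3 kernel, the denoising used before thresholding);
#' masked pixels are excluded from every neighbourhood and the intensity
#' channel is left untouched. Windows shrink at the image border.
#'
#' @param field a \linkS4class{PhasorField}.
#' @param iterations number of filter passes (default 4).
#' @return the filtered \linkS4class{PhasorField}.
#' @export
medianFilterPhasor <- function(field, iterations = 4L) {
  stopifnot(is(field, "PhasorField"), iterations >= 0)
  if (iterations == 0L) return(field)
  keep <- field@mask
  g <- field@g; s <- field@s
  g[!keep] <- 0; s[!keep] <- 0  # values under the mask are never read
  field@g[keep] <- masked_median_cpp(g, keep, as.integer(iterations))[keep]
  field@s[keep] <- masked_median_cpp(s, keep, as.integer(iterations))[keep]
  field
}

#' Mask pixels below an intensity threshold
#'
#' @param field a \linkS4class{PhasorField}.
#' @param minCounts minimum total counts for a pixel to survive
#'   (the protocol used 50 for flat substrates, 120 and 150 for the
#'   small- and large-pore scaffolds).
#' @return the thresholded field; the number of surviving pixels is
#'   \code{sum(keptMask(field))}.
#' @export
intensityThreshold <- function(field, minCounts) {
  stopifnot(is(field, "PhasorField"), minCounts >= 0)
  field@mask <- field@mask & (field@intensity >= minCounts)
  field
}

#' Filter pixels by phasor distance from a reference point
#'
#' With \code{mode = "exclude"} (scaffold-rejection semantics) pixels within
#' \code{maxDistance} of the reference — typically the scaffold-class phasor
#' centroid — are removed and only pixels farther away are kept. With
#' \code{mode = "include"} only pixels within \code{maxDistance} of the
#' reference (e.g. a circular ROI around a cell population) are kept.
#'
#' @param field a calibrated \linkS4class{PhasorField}.
#' @param reference named numeric \code{c(g =, s =)}.
#' @param maxDistance Euclidean phasor-space distance threshold (> 0).
#' @param mode "exclude" (default) or "include".
#' @param requireCalibrated refuse uncalibrated fields (default TRUE).
#' @return the filtered field.
#' @export
distanceFilter <- function(field, reference, maxDistance,
                           mode = c("exclude", "include"),
                           requireCalibrated = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is(field, "PhasorField"))
  if (maxDistance <= 0) stop("maxDistance must be positive")
  if (requireCalibrated && !isCalibrated(field))
    stop("field must be calibrated before distance filtering")
  d2 <- (field@g - reference[["g"]])^2 + (field@s - reference[["s"]])^2
  inside <- !is.na(d2) & d2 <= maxDistance^2
  field@mask <- if (mode == "exclude") field@mask & !inside
                else field@mask & inside
  field
}

#' Centroid of a phasor cloud
#'
#' Mean (g, s) over the kept pixels, optionally intensity-weighted.
#'
#' @param x a \linkS4class{PhasorField}, or a two-column matrix / data.frame
#'   of (g, s) points.
#' @param weighted intensity-weight the mean (fields only), default FALSE.
#' @return named numeric \code{c(g =, s =)}.
#' @export
phasorCentroid <- function(x, weighted = FALSE) {
  if (is(x, "PhasorField")) {
    keep <- x@mask & !is.na(x@g)
    if (!any(keep)) stop("empty phasor cloud")
    w <- if (weighted) x@intensity[keep] else rep(1, sum(keep))
    return(c(g = sum(x@g[keep] * w) / sum(w),
             s = sum(x@s[keep] * w) / sum(w)))
  }
  x <- as.matrix(x)
  if (nrow(x) < 1) stop("empty phasor cloud")
  c(g = mean(x[, 1]), s = mean(x[, 2]))
}

#' Per-pixel phasor table of a field
#'
#' @param field a \linkS4class{PhasorField}.
#' @param keptOnly drop masked pixels (default FALSE).
#' @return data.frame with x (column), y (row), g, s, intensity, kept.
#' @export
phasorTable <- function(field, keptOnly = FALSE) {
  d <- dim(field@g)
  df <- data.frame(
    x = rep(seq_len(d[2]), each = d[1]),
    y = rep(seq_len(d[1]), d[2]),
    g = as.vector(field@g), s = as.vector(field@s),
    intensity = as.vector(field@intensity),
    kept = as.vector(field@mask))
  if (keptOnly) df <- df[df$kept, , drop = FALSE]
  df
}
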