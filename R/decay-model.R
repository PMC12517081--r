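#' Gaussian-IRF exponential convolution, periodically folded
#'
#' Closed-form convolution of a mono-exponential decay \eqn{e^{-t/\tau}}
#' (unit amplitude at t = 0) with a unit-area Gaussian IRF centred at
#' \code{t0} with standard deviation \code{sigma}, summed over all previous
#' excitation periods so that the long-lifetime tail wraps correctly around
#' the repetition window.
#'
#' @param t evaluation times in ns (within one period).
#' @param tau lifetime in ns.
#' @param t0 IRF centre in ns.
#' @param sigma IRF standard deviation in ns; 0 gives a delta IRF.
#' @param T repetition period in ns; Inf disables folding.
#' @return numeric vector of the folded convolved decay at \code{t}.
#' @keywords internal
foldedExpIrf <- function(t, tau, t0, sigma, T = Inf) {
  if (tau <= 0) stop("tau must be positive")
  one <- function(tt) {
    dt <- tt - t0
    if (sigma <= 0) {
      ifelse(dt >= 0, exp(-dt / tau), 0)
    } else {
      # log-domain exponentially-modified Gaussian; stable for large
      # sigma^2/tau^2 and far tails
      exp(sigma^2 / (2 * tau^2) - dt / tau +
            pnorm(sigma / tau - dt / sigma, lower.tail = FALSE, log.p = TRUE))
    }
  }
  if (!is.finite(T)) return(one(t))
  # wrap enough periods that the truncated tail is < 1e-14 of the total;
  # k = -1 adds the next pulse's Gaussian leading edge at the window end
  K <- max(0L, ceiling(tau * 33 / T))
  out <- numeric(length(t))
  for (k in -1:K) out <- out + one(t + k * T)
  out
}

#' Expected bi-exponential reconvolution decay per time bin
#'
#' The forward model of the TCSPC fit: the two-component decay
#' \eqn{\alpha_1 e^{-t/\tau_1} + \alpha_2 e^{-t/\tau_2}} convolved with the
#' acquisition's Gaussian IRF, folded over one repetition period, evaluated
#' per time bin, plus a constant background \code{C} per bin.
#'
#' @param alpha1,alpha2 non-negative component amplitudes.
#' @param tau1,tau2 component lifetimes in ns.
#' @param C constant background per bin.
#' @param acq an \linkS4class{AcquisitionConfig} (supplies bin layout and IRF).
#' @param binCenters optional bin-centre override in ns; must lie within one
#'   repetition period.
#' @param mode "midpoint" evaluates the closed-form convolution at bin
#'   centres; "integrate" integrates it over each bin (Gauss-Legendre,
#'   5 nodes per bin) and divides by the bin width.
#' @return numeric vector of expected counts per bin.
#' @examples
#' acq <- AcquisitionConfig(irfCenter = 0, irfFwhm = 0)
#' y <- modelDecay(1, 0, 2.5, 3, 0, acq)
#' @export
modelDecay <- function(alpha1, alpha2, tau1, tau2, C = 0, acq,
                       binCenters = NULL, mode = c("midpoint", "integrate")) {
  mode <- match.arg(mode)
  stopifnot(alpha1 >= 0, alpha2 >= 0, tau1 > 0, tau2 > 0, C >= 0)
  T <- period(acq)
  if (is.null(binCenters)) binCenters <- (seq_len(nTimeBins(acq)) - 0.5) * binWidth(acq)
  if (any(binCenters < 0) || any(binCenters > T))
    stop("bins extend beyond one repetition period")
  sigma <- irfFwhm(acq) / (2 * sqrt(2 * log(2)))
  t0 <- irfCenter(acq)
  f <- function(t) {
    out <- numeric(length(t))
    if (alpha1 > 0) out <- out + alpha1 * foldedExpIrf(t, tau1, t0, sigma, T)
    if (alpha2 > 0) out <- out + alpha2 * foldedExpIrf(t, tau2, t0, sigma, T)
    out
  }
  if (mode == "midpoint") {
    f(binCenters) + C
  } else {
    h <- if (length(binCenters) > 1) diff(binCenters[1:2]) else binWidth(acq)
    # 5-node Gauss-Legendre on [-h/2, h/2]
    gl_x <- c(-0.9061798459386640, -0.5384693101056831, 0,
              0.5384693101056831, 0.9061798459386640) * h / 2
    gl_w <- c(0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
              0.4786286704993665, 0.2369268850561891) / 2
    acc <- numeric(length(binCenters))
    for (i in seq_along(gl_x)) acc <- acc + gl_w[i] * f(binCenters + gl_x[i])
    acc + C
  }
}

#' Expected decay for a photophysics class, scaled to a photon budget
#'
#' Converts intensity fractions to model amplitudes (\eqn{\alpha_i \propto
#' f_i/\tau_i}, since the photon yield of component i is proportional to
#' \eqn{\alpha_i\tau_i}) and scales the folded, IRF-convolved expectation so
#' its bin sum equals \code{totalPhotons}.
#'
#' @param photophysics a \linkS4class{PhotophysicsClass}.
#' @param acq an \linkS4class{AcquisitionConfig}.
#' @param totalPhotons expected total photons in the histogram.
#' @return numeric vector of expected counts per bin (sums to
#'   \code{totalPhotons}).
#' @export
expectedClassDecay <- function(photophysics, acq, totalPhotons) {
  if (totalPhotons <= 0) stop("photon budget must be positive")
  taus <- photophysics@lifetimes
  fr <- photophysics@fractions
  keepc <- fr > 0
  taus <- taus[keepc]; fr <- fr[keepc]
  alphas <- fr / taus
  tc <- binCenters(acq)
  sigma <- irfFwhm(acq) / (2 * sqrt(2 * log(2)))
  out <- numeric(length(tc))
  for (i in seq_along(taus))
    out <- out + alphas[i] * foldedExpIrf(tc, taus[i], irfCenter(acq), sigma, period(acq))
  out * (totalPhotons / sum(out))
}

#' Amplitude-weighted mean fluorescence lifetime
#'
#' \eqn{\tau_{mean} = (\alpha_1\tau_1 + \alpha_2\tau_2)/(\alpha_1+\alpha_2)},
#' the metabolic readout of NAD(P)H FLIM: it grows with the bound-NAD(P)H
#' amplitude share.
#'
#' @param alpha1,alpha2 component amplitudes (or a \linkS4class{BiExpFit} as
#'   first argument).
#' @param tau1,tau2 component lifetimes in ns.
#' @return mean lifetime in ns.
#' @examples
#' meanLifetime(1, 1, 0.42, 2.5) # 1.46
#' @export
meanLifetime <- function(alpha1, alpha2 = NULL, tau1 = NULL, tau2 = NULL) {
  if (is(alpha1, "BiExpFit")) {
    f <- alpha1
    return(meanLifetime(f@alpha1, f@alpha2, f@tau1, f@tau2))
  }
  if (alpha1 < 0 || alpha2 < 0) stop("amplitudes must be non-negative")
  tot <- alpha1 + alpha2
  if (tot <= 0) stop("alpha1 + alpha2 must be positive")
  (alpha1 * tau1 + alpha2 * tau2) / tot
}
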