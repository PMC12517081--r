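# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: quadrature instead of closed forms,
# plain loops instead of vectorized algebra, O(n^2) scans instead of
# geometric algorithms.

# Numerical convolution of a periodically folded mono-exponential with a
# Gaussian IRF by adaptive quadrature (the folded tail is summed in closed
# geometric form, which is independent of the package's per-period sum).
oracleFoldedConv <- function(t, tau, t0, sigma, T) {
  vapply(t, function(tt) {
    integrand <- function(u) {
      dt <- (tt - u) %% T
      exp(-dt / tau) / (1 - exp(-T / tau)) * stats::dnorm(u, t0, sigma)
    }
    lo <- t0 - 12 * sigma; hi <- t0 + 12 * sigma
    # the folded decay jumps at u = tt; split the domain there so the
    # adaptive rule sees smooth pieces only
    cuts <- sort(unique(c(lo, hi, tt[tt > lo & tt < hi])))
    tot <- 0
    for (k in seq_len(length(cuts) - 1)) {
      tot <- tot + stats::integrate(integrand, cuts[k], cuts[k + 1],
                                    rel.tol = 1e-12, abs.tol = 0)$value
    }
    tot
  }, numeric(1))
}

# Direct rectangle-rule numerical integration of the phasor integrals over
# the histogram, written as an explicit loop.
oraclePhasor <- function(cts, tc, omega) {
  num_g <- 0; num_s <- 0; den <- 0
  for (i in seq_along(cts)) {
    num_g <- num_g + cts[i] * cos(omega * tc[i])
    num_s <- num_s + cts[i] * sin(omega * tc[i])
    den <- den + cts[i]
  }
  c(g = num_g / den, s = num_s / den)
}

# Brute-force maximum pairwise vertex distance.
oracleMaxFeret <- function(xy) {
  best <- 0
  n <- nrow(xy)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    if (d > best) best <- d
  }
  best
}

# Polygon area by kernel-fan triangulation with Heron's formula (valid for
# polygons star-shaped about the origin, as randomStar produces; no cross
# products shared with the shoelace path).
oracleStarArea <- function(xy) {
  cx <- 0; cy <- 0
  n <- nrow(xy)
  tot <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a <- sqrt((xy[i, 1] - cx)^2 + (xy[i, 2] - cy)^2)
    b <- sqrt((xy[j, 1] - cx)^2 + (xy[j, 2] - cy)^2)
    cc <- sqrt((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2)
    s <- (a + b + cc) / 2
    tot <- tot + sqrt(max(s * (s - a) * (s - b) * (s - cc), 0))
  }
  tot
}

# Regular polygon approximating a circle.
circlePolygon <- function(r = 1, n = 512L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = r * cos(th), y = r * sin(th))
}

# Random simple (star-shaped) polygon for geometry property tests.
randomStar <- function(n = 24L, rmin = 0.5, rmax = 2) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  cbind(x = r * cos(th), y = r * sin(th))
}

testAcq <- function(nBins = 128L, ...) AcquisitionConfig(nBins = nBins, ...)
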