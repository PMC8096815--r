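# Analytic model of per-frame tracking losses in nearest-neighbour linking,
# and the iteration that returns the radius achieving a target loss.

#' Effective squared jump distance between consecutive frames
#'
#' \eqn{\sigma^2(\tau_{tl}) = \sigma_0^2 + 4 D \tau_{tl}}: the mean squared
#' displacement between two detected positions of the same molecule, combining
#' the localization error of both detections and 2D diffusion.
#'
#' @param sigma0Sq squared localization error sigma_0^2 in um^2.
#' @param D diffusion coefficient in um^2/s.
#' @param tau frame-cycle time in seconds.
#' @return sigma^2 in um^2.
#' @export
effectiveSigmaSq <- function(sigma0Sq, D, tau) {
  stopifnot(sigma0Sq >= 0, D >= 0, tau >= 0)
  sigma0Sq + 4 * D * tau
}

#' Out-of-radius loss probability
#'
#' Probability that a detected jump exceeds the tracking radius,
#' \eqn{a_z = \exp(-s^2/\sigma^2) = \exp(-z)}, for the isotropic 2D density
#' \eqn{p(r) = \exp(-r^2/\sigma^2)/(\pi\sigma^2)}.
#'
#' @param s tracking radius in micrometres (>= 0).
#' @param sigmaSq effective squared jump distance in um^2.
#' @return probability.
#' @export
outOfRadiusProb <- function(s, sigmaSq) {
  stopifnot(s >= 0, sigmaSq > 0)
  exp(-s^2 / sigmaSq)
}

#' Erroneous-linking loss probability
#'
#' Small-density loss probability due to linking the track to a disturbing
#' molecule in close proximity, \eqn{a_{NN} = 0.76\,\pi\rho\sigma^2} with the
#' spot density \eqn{\rho} (detections per unit area per frame, in the same
#' area units as \eqn{\sigma^2}). The result is clipped to at most 1, and a
#' warning is issued when it exceeds 0.5 where the small-density expansion is
#' no longer valid.
#'
#' @param rho spot density in 1/um^2 per frame (>= 0).
#' @param sigmaSq effective squared jump distance in um^2.
#' @param coefficient dimensionless prefactor of \eqn{\pi\rho\sigma^2}
#'   (default 0.76; see [erroneousLinkCoefficient()] for a Monte-Carlo
#'   evaluation of the defining integral).
#' @return probability.
#' @export
erroneousLinkProb <- function(rho, sigmaSq, coefficient = 0.76) {
  stopifnot(rho >= 0, sigmaSq > 0)
  a <- coefficient * pi * rho * sigmaSq
  if (any(a > 0.5))
    warning("a_NN > 0.5: small-density expansion invalid at this density")
  pmin(a, 1)
}

#' Monte-Carlo evaluation of the erroneous-link integral
#'
#' Evaluates the constrained triple integral defining the erroneous-linking
#' loss at small density: two consecutive jumps \eqn{r_1, r_2} are drawn from
#' the isotropic 2D density with \eqn{E|r|^2 = \sigma^2 = 1}, the disturbing
#' spot \eqn{r_\#} uniformly in a window of half-width `window` (large
#' relative to sigma), and configurations with \eqn{|r_1| > |r_\#|} and
#' \eqn{|r_1 + r_2 - r_\#| > |r_2|} are counted. The returned value is the
#' loss probability divided by \eqn{\pi\rho\sigma^2}, i.e. the dimensionless
#' coefficient.
#'
#' @param nSamples Monte-Carlo sample count (default 1e7).
#' @param window half-width of the uniform window for the disturbing spot,
#'   in units of sigma.
#' @param seed integer seed.
#' @return list with `coefficient` and its standard error `se`.
#' @export
erroneousLinkCoefficient <- function(nSamples = 1e7, window = 8, seed = 1) {
  withSeed(seed, {
    chunk <- 1e6
    done <- 0; hits <- 0
    while (done < nSamples) {
      m <- min(chunk, nSamples - done)
      r1x <- stats::rnorm(m, 0, sqrt(0.5)); r1y <- stats::rnorm(m, 0, sqrt(0.5))
      r2x <- stats::rnorm(m, 0, sqrt(0.5)); r2y <- stats::rnorm(m, 0, sqrt(0.5))
      hx <- stats::runif(m, -window, window)
      hy <- stats::runif(m, -window, window)
      c1 <- (r1x^2 + r1y^2) > (hx^2 + hy^2)
      c2 <- ((r1x + r2x - hx)^2 + (r1y + r2y - hy)^2) > (r2x^2 + r2y^2)
      hits <- hits + sum(c1 & c2)
      done <- done + m
    }
    p <- hits / nSamples
    area <- (2 * window)^2
    list(coefficient = p * area / pi,
         se = area / pi * sqrt(p * (1 - p) / nSamples))
  })
}

#' Correlation of consecutive detected jumps
#'
#' Two consecutive detected jumps share the localization error of the middle
#' detection, which induces the negative correlation
#' \eqn{c = -\sigma_0^2 / (2\sigma^2)} per axis. For immobile molecules
#' (\eqn{\sigma^2 \to \sigma_0^2}) this approaches -1/2.
#'
#' @param sigma0Sq squared localization error in um^2.
#' @param sigmaSq effective squared jump distance in um^2.
#' @return correlation in (-1/2, 0].
#' @export
jumpCorrelation <- function(sigma0Sq, sigmaSq) {
  stopifnot(sigma0Sq >= 0, sigmaSq >= sigma0Sq)
  -sigma0Sq / (2 * sigmaSq)
}

#' Gap-frame recovery fraction
#'
#' Fraction \eqn{f = (a_z - a_{Gap})/a_z} of out-of-radius losses recovered
#' by allowing one gap frame. Conditional on the first jump \eqn{r_1} leaving
#' the radius, the track is recovered when the molecule returns inside the
#' radius and ends up closer to the track's last position than to the spot
#' that left (\eqn{|r_1 + r_2| < \min(s, |r_2|)}). The correlated bivariate
#' Gaussian integral over this region is evaluated by conditional Monte-Carlo
#' (sampling \eqn{|r_1|^2 = z\sigma^2 + \sigma^2\,\mathrm{Exp}(1)} exactly on
#' the out-of-radius event), which is accurate at all z; a fixed seed makes
#' it deterministic.
#'
#' @param z dimensionless squared radius \eqn{z = s^2/\sigma^2} (> 0).
#' @param c correlation of consecutive detected jumps, in (-1, 0].
#' @param nSamples Monte-Carlo sample count.
#' @param seed integer seed.
#' @return recovery fraction f in [0, 0.5] (up to Monte-Carlo error).
#' @export
gapRecoveryFraction <- function(z, c = -0.5, nSamples = 1e6, seed = 1) {
  stopifnot(z > 0, c > -1, c <= 0)
  withSeed(seed, {
    u2 <- z + stats::rexp(nSamples)
    ur <- sqrt(u2)
    th <- stats::runif(nSamples, 0, 2 * pi)
    ux <- ur * cos(th); uy <- ur * sin(th)
    sdv <- sqrt((1 - c^2) / 2)
    vx <- c * ux + stats::rnorm(nSamples, 0, sdv)
    vy <- c * uy + stats::rnorm(nSamples, 0, sdv)
    w2 <- (ux + vx)^2 + (uy + vy)^2
    mean(w2 < pmin(z, vx^2 + vy^2))
  })
}

#' Total per-frame tracking loss
#'
#' Composes the loss contributions into the overall per-frame probability of
#' losing the track of an immobile molecule:
#' \deqn{a_{tr} = a_{NN}(\rho) + a_z(s)\,(1 - f)\,(1 - a_{NN}(\rho))}
#' with \eqn{f = 0} when gap bridging is disabled.
#'
#' @param s tracking radius in micrometres.
#' @param sigmaSq effective squared jump distance in um^2.
#' @param rho spot density in 1/um^2 per frame.
#' @param gapEnabled whether one gap frame is allowed.
#' @param sigma0Sq squared localization error (needed for the jump
#'   correlation entering the gap integral; default: immobile regime,
#'   `sigma0Sq = sigmaSq`, c = -1/2).
#' @param coefficient erroneous-link prefactor (default 0.76).
#' @param nSamples samples for the gap integral.
#' @return list of class `"LossBudget"` with `s`, `z`, `rho`, `aZ`, `aNN`,
#'   `f`, `aGap` (unconditional final loss via the gap mechanism,
#'   \eqn{a_z(1-f)}) and `aTr`.
#' @export
totalLossProb <- function(s, sigmaSq, rho = 0, gapEnabled = TRUE,
                          sigma0Sq = sigmaSq, coefficient = 0.76,
                          nSamples = 2e5) {
  z <- s^2 / sigmaSq
  aZ <- outOfRadiusProb(s, sigmaSq)
  aNN <- erroneousLinkProb(rho, sigmaSq, coefficient)
  f <- if (gapEnabled && z > 0)
    gapRecoveryFraction(z, jumpCorrelation(sigma0Sq, sigmaSq), nSamples)
  else 0
  aGap <- aZ * (1 - f)
  aTr <- aNN + aGap * (1 - aNN)
  structure(list(s = s, z = z, rho = rho, aZ = aZ, aNN = aNN, f = f,
                 aGap = aGap, aTr = aTr),
            class = "LossBudget")
}

#' @export
print.LossBudget <- function(x, ...) {
  cat(sprintf(
    "LossBudget: s = %.4g um (z = %.3g)\n  a_z = %.4g  a_NN = %.4g  f = %.3g  a_Gap = %.4g  a_tr = %.4g\n",
    x$s, x$z, x$aZ, x$aNN, x$f, x$aGap, x$aTr))
  invisible(x)
}

# ratio of the radius-truncated mean squared jump to the true sigma^2:
# E[r^2 | r <= s] / sigma^2 for the isotropic 2D density.
truncatedSigmaBias <- function(z) {
  (1 - (1 + z) * exp(-z)) / (1 - exp(-z))
}

# invert the truncation bias: given the measured (truncated) mean squared
# jump and the radius, recover the underlying sigma^2.
sigmaSqFromTruncated <- function(sigmaSqMeas, s) {
  h <- function(ss) ss * truncatedSigmaBias(s^2 / ss) - sigmaSqMeas
  if (h(sigmaSqMeas) >= 0) return(sigmaSqMeas)
  upper <- sigmaSqMeas * 2
  while (h(upper) < 0 && upper < 1e6 * sigmaSqMeas) upper <- upper * 2
  stats::uniroot(h, c(sigmaSqMeas, upper), tol = 1e-12)$root
}

#' Minimum bound-track length for a condition
#'
#' Smallest number of frames n such that a freely diffusing molecule stays
#' within the tracking radius for n consecutive frames with probability below
#' `pFree`: each of the n - 1 jumps stays inside with probability
#' \eqn{1 - \exp(-z_{free})}, \eqn{z_{free} = s^2/(\sigma_0^2 + 4 D_{free}
#' \tau_{tl})}. At least 2 frames are always required.
#'
#' @param s tracking radius in micrometres.
#' @param sigma0Sq squared localization error in um^2.
#' @param dFree free diffusion coefficient in um^2/s.
#' @param tau frame-cycle time in seconds.
#' @param pFree admissible false-bound probability (default 1e-3).
#' @return integer number of frames.
#' @export
minBoundTrackLength <- function(s, sigma0Sq, dFree, tau, pFree = 1e-3) {
  zFree <- s^2 / effectiveSigmaSq(sigma0Sq, dFree, tau)
  pStay <- 1 - exp(-zFree)
  if (pStay <= 0) return(2L)
  # a radius so large that free molecules essentially never leave cannot
  # discriminate; cap at 1000 frames (longer than any practical movie)
  if (pStay >= 1 - 1e-12) return(1000L)
  n <- 1L + ceiling(log(pFree) / log(pStay))
  as.integer(max(2L, min(n, 1000L)))
}

#' Tracking radius achieving a target loss probability
#'
#' Iterates the fixed-point scheme that solves
#' \eqn{a_{tr} = a_{NN} + a_z (1-f)(1-a_{NN})} for the radius: at each step
#' the data are re-tracked with the current radius \eqn{s_i}, the mean
#' squared jump distance \eqn{\sigma^2(s_i)} of linked (non-gap) jumps is
#' measured, the target \eqn{\tilde z} is computed from the loss composition,
#' corrected for the radius truncation of the measured jump distribution by
#' \eqn{z_{i+1} = \tilde z\,(1 - e^{-\tilde z}) / (1 - (1+\tilde z)
#' e^{-\tilde z})}, and \eqn{s_{i+1} = \sqrt{\sigma^2(s_i)\, z_{i+1}}}. The
#' iteration stops when the relative change of s falls below `tol`.
#'
#' @param locs localization data.frame (`frame`, `x`, `y` in um).
#' @param tau frame-cycle time in seconds.
#' @param targetLoss desired per-frame tracking loss a_tr.
#' @param area observation area in um^2 (for the density estimate).
#' @param sigma0Sq squared localization error in um^2 (enters the jump
#'   correlation of the gap integral and the minimum-track-length rule).
#' @param dFree free diffusion coefficient for [minBoundTrackLength()].
#' @param gapEnabled whether tracking uses one gap frame.
#' @param rho spot density per um^2 per frame; estimated from `locs`/`area`
#'   when NULL.
#' @param s0 starting radius in um; when NULL a coarse pass starting from
#'   \eqn{3\sigma_0} expands to \eqn{3\sqrt{\hat\sigma^2}}.
#' @param tol relative-change stopping rule (default 1e-2).
#' @param maxIter iteration guard (default 100).
#' @param coefficient erroneous-link prefactor.
#' @param onUnreachable `"error"` stops when the target lies below the
#'   erroneous-link floor a_NN; `"min-loss"` instead returns the radius that
#'   would achieve the target out-of-radius loss alone, flagged.
#' @return list of class `"RadiusCalibration"`: `s`, `z`, `sigmaSqMeasured`,
#'   `sigmaSqTrue`, `rho`, `aNN`, `f`, `aTrPredicted`, `nMinBound`,
#'   `iterations`, `converged`, `unreachable`, `history`.
#' @export
radiusForLoss <- function(locs, tau, targetLoss, area, sigma0Sq = 0.0016,
                          dFree = 10, gapEnabled = TRUE, rho = NULL,
                          s0 = NULL, tol = 1e-2, maxIter = 100L,
                          coefficient = 0.76,
                          onUnreachable = c("error", "min-loss")) {
  onUnreachable <- match.arg(onUnreachable)
  stopifnot(targetLoss > 0, targetLoss < 1)
  if (is.null(rho))
    rho <- nrow(locs) / length(unique(locs$frame)) / area
  params <- function(s) trackingParams(s, maxGapFrames = as.integer(gapEnabled),
                                       minFramesBeforeGap = 2L)
  measure <- function(s) {
    ts <- nearestNeighbourLink(locs, params(s), frameCycleTime = tau)
    tr <- ts@tracks
    dx <- diff(tr$x); dy <- diff(tr$y)
    same <- diff(tr$track_id) == 0 & diff(tr$frame) == 1L
    r2 <- dx[same]^2 + dy[same]^2
    if (!length(r2)) return(NA_real_)
    mean(r2)
  }
  if (is.null(s0)) {
    s0 <- 3 * sqrt(sigma0Sq)
    for (k in 1:3) {
      m <- measure(s0)
      if (is.na(m)) break
      s0 <- 3 * sqrt(m)
    }
  }
  s <- s0
  hist <- numeric(0)
  converged <- FALSE
  unreachable <- FALSE
  sigMeas <- sigTrue <- aNN <- f <- z <- NA_real_
  for (i in seq_len(maxIter)) {
    sigMeas <- measure(s)
    if (is.na(sigMeas)) stop("no linked jumps at radius ", signif(s, 3), " um")
    sigTrue <- sigmaSqFromTruncated(sigMeas, s)
    aNN <- erroneousLinkProb(rho, sigTrue, coefficient)
    z <- s^2 / sigTrue
    f <- if (gapEnabled)
      gapRecoveryFraction(max(z, 1e-6), jumpCorrelation(min(sigma0Sq, sigTrue), sigTrue))
    else 0
    if (targetLoss <= aNN * 1.02) {
      unreachable <- TRUE
      if (onUnreachable == "error")
        stop("loss target unreachable at this density: a_NN = ", signif(aNN, 3))
      zt <- -log(targetLoss / (1 - f))
    } else {
      zt <- -log((targetLoss - aNN) / ((1 - aNN) * (1 - f)))
    }
    zt <- max(zt, 1e-3)
    zCorr <- zt * (1 - exp(-zt)) / (1 - (1 + zt) * exp(-zt))
    sNew <- sqrt(sigMeas * zCorr)
    hist <- c(hist, sNew)
    if (abs(sNew - s) / s < tol) {
      s <- sNew
      converged <- TRUE
      break
    }
    s <- sNew
  }
  nMin <- minBoundTrackLength(s, sigma0Sq, dFree, tau)
  budget <- totalLossProb(s, sigTrue, rho, gapEnabled,
                          min(sigma0Sq, sigTrue), coefficient)
  structure(list(s = s, z = s^2 / sigTrue, sigmaSqMeasured = sigMeas,
                 sigmaSqTrue = sigTrue, rho = rho, aNN = aNN, f = f,
                 aTrPredicted = budget$aTr, nMinBound = nMin,
                 iterations = length(hist), converged = converged,
                 unreachable = unreachable, history = hist),
            class = "RadiusCalibration")
}

#' @export
print.RadiusCalibration <- function(x, ...) {
  cat(sprintf(
    "RadiusCalibration: s = %.4g um (z = %.3g) after %d iteration(s)%s\n",
    x$s, x$z, x$iterations,
    if (x$unreachable) " [target below erroneous-link floor]" else ""))
  cat(sprintf("  sigma^2 = %.4g um^2 (measured %.4g), rho = %.4g /um^2, a_NN = %.4g\n",
              x$sigmaSqTrue, x$sigmaSqMeasured, x$rho, x$aNN))
  cat(sprintf("  predicted a_tr = %.4g, min bound-track length = %d frames\n",
              x$aTrPredicted, x$nMinBound))
  invisible(x)
}
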