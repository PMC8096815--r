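#' Gillespie event stream for binding, dissociation and photobleaching
#'
#' Simulates the event sequence of a chain of molecules using the Gillespie
#' direct method. A molecule is born in a binding state drawn from the
#' relative state frequencies; it carries two competing exponential clocks
#' (dissociation with the state's rate, photobleaching with `bleachRate`).
#' When either fires the molecule is replaced by a fresh one, so the stream
#' continues until `tMax`.
#'
#' @param states list of [bindingState()] objects.
#' @param bleachRate photobleaching rate in 1/s (use
#'   [bleachRateFromProb()] to convert a per-frame probability).
#' @param tMax end of the simulated time window in seconds.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return data.frame with columns `time` (strictly increasing event times in
#'   seconds), `kind` (`"dissociation"` or `"bleach"`) and `state` (index of
#'   the state the molecule was in).
#' @examples
#' ev <- gillespieEventTimes(list(bindingState(10, 1)), bleachRate = 0,
#'                           tMax = 1, seed = 1)
#' @export
gillespieEventTimes <- function(states, bleachRate = 0, tMax, seed = 1) {
  stopifnot(length(states) > 0, bleachRate >= 0, tMax > 0)
  rates <- vapply(states, `[[`, numeric(1), "dissociationRate")
  freqs <- vapply(states, `[[`, numeric(1), "relativeFrequency")
  if (all(rates + bleachRate <= 0)) stop("no events possible: all rates zero")
  withSeed(seed, {
    times <- numeric(0); kinds <- character(0); sts <- integer(0)
    t <- 0
    repeat {
      s <- sample.int(length(states), 1, prob = freqs)
      total <- rates[s] + bleachRate
      t <- t + stats::rexp(1, total)
      if (t > tMax) break
      kind <- if (stats::runif(1) < rates[s] / total) "dissociation" else "bleach"
      times <- c(times, t); kinds <- c(kinds, kind); sts <- c(sts, s)
    }
    data.frame(time = times, kind = kinds, state = sts)
  })
}

#' Convert a per-frame bleaching probability to a continuous rate
#'
#' The per-frame photobleaching probability `a` at frame-cycle time `tau` is
#' matched by the continuous rate \eqn{-\log(1 - a)/\tau}, so that the
#' Gillespie clock and the per-frame loss agree.
#'
#' @param a probability per frame in [0, 1).
#' @param tau frame-cycle time in seconds.
#' @return rate in 1/s.
#' @export
bleachRateFromProb <- function(a, tau) {
  stopifnot(a >= 0, a < 1, tau > 0)
  -log1p(-a) / tau
}

#' Simulate ground-truth trajectories for one time-lapse condition
#'
#' Molecules are maintained at a constant count: `moleculesPerFrame` chains
#' are started at time zero and whenever a molecule dissociates or bleaches a
#' replacement is born at that instant at a uniform random position with a
#' state drawn from the relative frequencies. Event times come from the
#' Gillespie direct method; positions are only evaluated at frame times, with
#' per-axis jump variance \eqn{2 D \tau_{tl}} for the bound-state diffusion
#' coefficient. Positions evolve unbounded; spots outside the field of view
#' are simply not rendered.
#'
#' @param scenario a [SimScenario-class].
#' @param conditionIndex which entry of `timelapseConditions` to simulate.
#' @param seed integer seed.
#' @return data.frame with one row per molecule per frame in which it is
#'   alive: columns `id`, `frame` (1-based), `t` (s), `x`, `y` (um), `state`,
#'   plus attributes `meta` (per-molecule state/birth/death/cause, including
#'   molecules too short-lived to appear in any frame) and `tau`.
#' @export
simulateTrajectories <- function(scenario, conditionIndex = 1, seed = 1) {
  stopifnot(is(scenario, "SimScenario"))
  if (length(scenario@states) == 0) stop("empty states list")
  tau <- scenario@timelapseConditions[conditionIndex]
  nF <- scenario@nFrames
  fov <- scenario@frameSize * scenario@pixelSizeUm
  tEnd <- (nF - 1) * tau
  rates <- vapply(scenario@states, `[[`, numeric(1), "dissociationRate")
  freqs <- vapply(scenario@states, `[[`, numeric(1), "relativeFrequency")
  dCoef <- vapply(scenario@states, `[[`, numeric(1), "diffusionCoeff")
  bleach <- if (scenario@bleachProbPerFrame > 0)
    bleachRateFromProb(scenario@bleachProbPerFrame, tau) else 0

  withSeed(seed, {
    accId <- list(); accFr <- list(); accX <- list(); accY <- list()
    accSt <- list(); k <- 0L
    mId <- integer(0); mSt <- integer(0); mBirth <- numeric(0)
    mDeath <- numeric(0); mCause <- character(0)
    id <- 0L
    for (chain in seq_len(scenario@moleculesPerFrame)) {
      tBirth <- 0
      repeat {
        id <- id + 1L
        s <- sample.int(length(scenario@states), 1, prob = freqs)
        total <- rates[s] + bleach
        dt <- stats::rexp(1, total)
        cause <- if (stats::runif(1) < rates[s] / total) "dissociation" else "bleach"
        tDeath <- tBirth + dt
        if (tDeath > tEnd) cause <- "end"
        # frames in which this molecule is visible
        f0 <- ceiling(tBirth / tau - 1e-9)
        f1 <- floor(min(tDeath, tEnd) / tau + 1e-9)
        if (f1 >= f0) {
          frames <- f0:f1
          n <- length(frames)
          x0 <- stats::runif(1, 0, fov); y0 <- stats::runif(1, 0, fov)
          sdJ <- sqrt(2 * dCoef[s] * tau)
          k <- k + 1L
          accId[[k]] <- rep.int(id, n)
          accFr[[k]] <- frames + 1L
          accX[[k]] <- x0 + c(0, cumsum(stats::rnorm(n - 1, 0, sdJ)))
          accY[[k]] <- y0 + c(0, cumsum(stats::rnorm(n - 1, 0, sdJ)))
          accSt[[k]] <- rep.int(s, n)
        }
        mId <- c(mId, id); mSt <- c(mSt, s); mBirth <- c(mBirth, tBirth)
        mDeath <- c(mDeath, min(tDeath, tEnd)); mCause <- c(mCause, cause)
        if (tDeath > tEnd) break
        tBirth <- tDeath
      }
    }
    fr <- unlist(accFr, use.names = FALSE)
    out <- data.frame(id = unlist(accId, use.names = FALSE), frame = fr,
                      t = (fr - 1L) * tau,
                      x = unlist(accX, use.names = FALSE),
                      y = unlist(accY, use.names = FALSE),
                      state = unlist(accSt, use.names = FALSE))
    attr(out, "meta") <- data.frame(id = mId, state = mSt, birth = mBirth,
                                    death = mDeath, cause = mCause)
    attr(out, "tau") <- tau
    out
  })
}

#' Coordinate-level detected localizations from ground-truth trajectories
#'
#' Adds the localization error of the detection step to true positions,
#' bypassing rendering and spot fitting. Each detected position receives an
#' independent Gaussian error with per-axis standard deviation
#' \eqn{\sigma_0/2}, so that the error contribution to the squared jump
#' distance between two detections is \eqn{\sigma_0^2} (matching
#' \eqn{\sigma^2 = \sigma_0^2 + 4 D \tau_{tl}}).
#'
#' @param traj output of [simulateTrajectories()].
#' @param sigma0 localization error sigma_0 in micrometres. The default
#'   0.010 um matches the sub-pixel fit precision of the package's detector
#'   at the standard rendering conditions (SNR 25, 1 px PSF, 0.16 um
#'   pixels).
#' @param pMiss probability that a detection is missed (default 0), to
#'   exercise gap bridging.
#' @param seed integer seed.
#' @return data.frame `frame`, `x`, `y` (um), `true_id`, `state`.
#' @export
detectedLocalizations <- function(traj, sigma0 = 0.010, pMiss = 0, seed = 1) {
  withSeed(seed, {
    n <- nrow(traj)
    keep <- if (pMiss > 0) stats::runif(n) >= pMiss else rep(TRUE, n)
    data.frame(frame = traj$frame[keep],
               x = traj$x[keep] + stats::rnorm(sum(keep), 0, sigma0 / 2),
               y = traj$y[keep] + stats::rnorm(sum(keep), 0, sigma0 / 2),
               true_id = traj$id[keep], state = traj$state[keep])
  })
}

# integrated Gaussian PSF: photon fraction per pixel via pnorm differences
renderSpot <- function(img, xPx, yPx, photons, psf) {
  H <- nrow(img); W <- ncol(img)
  r <- ceiling(4 * psf)
  i0 <- max(1, floor(yPx + 1 - r)); i1 <- min(H, ceiling(yPx + 1 + r))
  j0 <- max(1, floor(xPx + 1 - r)); j1 <- min(W, ceiling(xPx + 1 + r))
  if (i0 > i1 || j0 > j1) return(img)
  ii <- i0:i1; jj <- j0:j1
  # 1-based pixel i covers 0-based coordinates [i - 1.5, i - 0.5]
  fy <- stats::pnorm(ii - 0.5, yPx, psf) - stats::pnorm(ii - 1.5, yPx, psf)
  fx <- stats::pnorm(jj - 0.5, xPx, psf) - stats::pnorm(jj - 1.5, xPx, psf)
  img[ii, jj] <- img[ii, jj] + photons * outer(fy, fx)
  img
}

#' Render a synthetic movie from ground-truth trajectories
#'
#' Each visible molecule contributes an integrated 2D Gaussian of standard
#' deviation `psfWidth` centred at its sub-pixel position, with a total
#' photon count drawn from a lognormal distribution whose median is set so
#' that the median peak-pixel signal over the background standard deviation
#' equals the scenario SNR. The background is a uniform level plus uniform
#' noise plus a band-pass filtered (difference-of-Gaussians, sigmas 2 and 10
#' px) noise structure. Motion blur is not simulated.
#'
#' @param traj output of [simulateTrajectories()].
#' @param scenario the [SimScenario-class] used to generate `traj`.
#' @param seed integer seed; rendering is deterministic given (traj, seed).
#' @return a [SyntheticMovie-class].
#' @export
renderMovie <- function(traj, scenario, seed = 1) {
  stopifnot(is(scenario, "SimScenario"))
  if (scenario@psfWidth <= 0) stop("psfWidth must be > 0")
  H <- scenario@frameSize; W <- scenario@frameSize
  nF <- scenario@nFrames
  px <- scenario@pixelSizeUm
  psf <- scenario@psfWidth
  # median peak-pixel fraction of an integrated Gaussian centred on a pixel
  centreFrac <- (stats::pnorm(0.5, 0, psf) - stats::pnorm(-0.5, 0, psf))^2
  sigmaBg <- max(sqrt(scenario@backgroundNoise^2 / 3 +
                        scenario@structureAmplitude^2), 1)
  medPhotons <- scenario@snr * sigmaBg / centreFrac
  withSeed(seed, {
    stack <- array(0, c(H, W, nF))
    for (f in seq_len(nF)) {
      bg <- scenario@backgroundLevel +
        stats::runif(H * W, -scenario@backgroundNoise, scenario@backgroundNoise)
      frame <- matrix(bg, H, W)
      if (scenario@structureAmplitude > 0) {
        st <- matrix(stats::runif(H * W, -1, 1), H, W)
        st <- dogFilter(st, 2, 10)
        st <- st / max(stats::sd(st), 1e-12) * scenario@structureAmplitude
        frame <- frame + st
      }
      rows <- which(traj$frame == f)
      for (k in rows) {
        photons <- stats::rlnorm(1, log(medPhotons), scenario@lognormalShape)
        frame <- renderSpot(frame, traj$x[k] / px, traj$y[k] / px, photons, psf)
      }
      stack[, , f] <- frame
    }
    stack <- round(pmin(pmax(stack, 0), 65535))
    new("SyntheticMovie", stack = stack,
        frameCycleTime = attr(traj, "tau"),
        groundTruth = as.data.frame(traj), pixelSizeUm = px)
  })
}

# difference-of-Gaussians band-pass via separable convolution
dogFilter <- function(img, s1, s2) {
  gaussBlur(img, s1) - gaussBlur(img, s2)
}

gaussBlur <- function(img, sigma) {
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, 0, sigma)
  k <- k / sum(k)
  sepConvolve(img, k, k)
}
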