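# Survival-time distributions and the global inverse-Laplace dissociation
# rate spectrum (GRID-style), plus ITM bound fractions.

#' Build survival-time distributions per time-lapse condition
#'
#' For each condition, counts the number of tracks surviving at least t for
#' every observed duration t. Durations are track spans in seconds,
#' (frames - 1) x tau_tl; gap frames count toward the span.
#'
#' @param durationsByCondition named list: one numeric vector of track
#'   durations (seconds) per time-lapse condition; names are the frame-cycle
#'   times in seconds (or supply `taus`).
#' @param taus frame-cycle times, parallel to the list (default: parsed from
#'   names).
#' @param minFrames minimal track length in frames per condition (scalar or
#'   vector); shorter tracks are dropped.
#' @param nFramesMovie number of acquired frames per movie (scalar or
#'   vector), used by the spectrum fit to model the right-censoring of
#'   tracks born late in a movie; `Inf` disables the correction.
#' @param birthFrames optional list parallel to `durationsByCondition`
#'   giving the first frame of each track; when supplied, the censoring
#'   factor uses the empirical birth-frame distribution (assumption-free)
#'   instead of assuming uniform births.
#' @return list of class `"SurvivalSet"`: per condition `tau`, `t` (sorted
#'   unique durations), `n` (counts N(>= t)), `nTracks`, `minFrames`,
#'   `nFramesMovie`, `birthCdf`. Empty conditions are kept and flagged with
#'   `nTracks = 0`.
#' @export
buildSurvival <- function(durationsByCondition, taus = NULL, minFrames = 1L,
                          nFramesMovie = Inf, birthFrames = NULL) {
  if (is.null(taus)) taus <- as.numeric(names(durationsByCondition))
  stopifnot(length(taus) == length(durationsByCondition), !anyNA(taus))
  minFrames <- rep_len(as.integer(minFrames), length(taus))
  nFramesMovie <- rep_len(nFramesMovie, length(taus))
  out <- vector("list", length(taus))
  for (i in seq_along(taus)) {
    d <- durationsByCondition[[i]]
    frames <- round(d / taus[i]) + 1L
    keep <- frames >= minFrames[i]
    frames <- frames[keep]
    birthCdf <- NULL
    if (!is.null(birthFrames) && length(birthFrames[[i]]) && any(keep))
      birthCdf <- stats::ecdf(birthFrames[[i]][keep])
    if (!length(frames)) {
      out[[i]] <- list(tau = taus[i], t = numeric(0), n = integer(0),
                       nTracks = 0L, minFrames = minFrames[i],
                       nFramesMovie = nFramesMovie[i], birthCdf = NULL)
      next
    }
    tab <- table(frames)
    fr <- as.integer(names(tab))
    cnt <- rev(cumsum(rev(as.integer(tab))))
    out[[i]] <- list(tau = taus[i], t = (fr - 1L) * taus[i], n = cnt,
                     nTracks = length(frames), minFrames = minFrames[i],
                     nFramesMovie = nFramesMovie[i], birthCdf = birthCdf)
  }
  structure(out, class = "SurvivalSet")
}

#' @export
print.SurvivalSet <- function(x, ...) {
  cat("SurvivalSet with", length(x), "condition(s):\n")
  for (s in x)
    cat(sprintf("  tau = %g s: %d tracks, max duration %g s%s\n", s$tau,
                s$nTracks, if (s$nTracks) max(s$t) else NA,
                if (!s$nTracks) " [empty]" else ""))
  invisible(x)
}

# Design matrix of geometric decays for one condition: column k is
# beta_k^(j-1) for frame counts j, with beta_k = exp(-k tau) * (1 - a).
# Right-censoring of tracks born late in a finite movie deflates N(>= j) by
# P(birth frame <= F - j + 1); this uses the empirical birth-frame
# distribution when available, else assumes uniform births over F frames.
survivalDesign <- function(rateGrid, tau, frames, q, nFramesMovie = Inf,
                           birthCdf = NULL) {
  B <- outer(frames - 1L, log(q) - rateGrid * tau, function(n, lb) exp(n * lb))
  if (!is.null(birthCdf) && is.finite(nFramesMovie)) {
    B <- B * birthCdf(nFramesMovie - frames + 1)
  } else if (is.finite(nFramesMovie)) {
    B <- B * pmax(nFramesMovie - frames + 1, 0) / nFramesMovie
  }
  B
}

# Inner solver at fixed per-frame survival q = 1 - a: non-negative least
# squares of all normalized survival curves, iterating the per-condition
# normalization (which depends on the weights through the minimum track
# length) to a fixed point. A small ridge penalty keeps weights on rate
# components that are almost annihilated by the minimum-track-length
# depletion from blowing up.
fitWeightsAtQ <- function(survivals, rateGrid, q, nZIter = 4L, ridge = 0.02) {
  K <- length(rateGrid)
  conds <- Filter(function(s) s$nTracks > 0, survivals)
  ys <- lapply(conds, function(s) s$n / s$n[1])
  frames <- lapply(conds, function(s) as.integer(round(s$t / s$tau)) + 1L)
  B <- mapply(function(s, fr) survivalDesign(rateGrid, s$tau, fr, q,
                                             s$nFramesMovie, s$birthCdf),
              conds, frames, SIMPLIFY = FALSE)
  Bmin <- mapply(function(s, fr) survivalDesign(rateGrid, s$tau, fr[1], q,
                                                s$nFramesMovie, s$birthCdf),
                 conds, lapply(frames, `[`, 1), SIMPLIFY = FALSE)
  w <- rep(1 / K, K)
  pen <- diag(ridge, K)
  for (it in seq_len(nZIter)) {
    Z <- vapply(Bmin, function(bm) max(sum(bm * w), 1e-300), numeric(1))
    A <- rbind(do.call(rbind, B), pen)
    yy <- c(unlist(mapply(function(y, z) y * z, ys, Z, SIMPLIFY = FALSE)),
            numeric(K))
    w <- pracma::lsqnonneg(A, yy)$x
    if (sum(w) <= 0) { w <- rep(1 / K, K); break }
    w <- w / sum(w)
  }
  Z <- vapply(Bmin, function(bm) max(sum(bm * w), 1e-300), numeric(1))
  res <- 0
  for (i in seq_along(conds)) {
    m <- as.numeric(B[[i]] %*% w) / Z[i]
    res <- res + sum((ys[[i]] - m)^2)
  }
  list(w = w, rss = res)
}

#' Global dissociation-rate spectrum from survival distributions
#'
#' Fits all time-lapse survival distributions jointly with a mixture of
#' exponentials on a fixed grid of dissociation rates, each damped by a
#' shared per-frame loss probability a (photobleaching plus tracking loss):
#' \deqn{S_\tau(n) = \sum_k w_k\, e^{-k_k n \tau}\,(1-a)^n .}
#' Solving the inverse Laplace transform of the survival functions is cast
#' as a single non-negative minimization: for each candidate a, the weights
#' are obtained by non-negative least squares on the normalized survival
#' curves (normalization accounts for the per-condition minimum track
#' length); a is then found by a one-dimensional golden-section search.
#' Using at least two time-lapse conditions is recommended so the shared
#' per-frame loss is separable from the rates.
#'
#' @param survivals a `"SurvivalSet"` from [buildSurvival()].
#' @param rateGrid strictly increasing grid of dissociation rates in 1/s
#'   (default 60 log-spaced points over 1e-4..1e2).
#' @param lossInterval search interval for the per-frame loss a.
#' @param nZIter normalization fixed-point iterations of the inner solver.
#' @param ridge small L2 penalty on the weights (default 0.02), stabilizing
#'   components that the minimum-track-length depletion renders nearly
#'   unobservable.
#' @return a [RateSpectrum-class].
#' @export
gridSpectrum <- function(survivals, rateGrid = defaultRateGrid(),
                         lossInterval = c(0, 0.6), nZIter = 4L,
                         ridge = 0.02) {
  stopifnot(!is.unsorted(rateGrid, strictly = TRUE))
  if (!any(vapply(survivals, function(s) s$nTracks > 0, logical(1))))
    stop("all survival distributions are empty")
  obj <- function(a) fitWeightsAtQ(survivals, rateGrid, 1 - a, nZIter, ridge)$rss
  # coarse scan guards the golden-section refinement against local minima
  coarse <- seq(lossInterval[1] + 1e-3, min(lossInterval[2], 0.3), length.out = 16)
  vals <- vapply(coarse, obj, numeric(1))
  i <- which.min(vals)
  bracket <- c(coarse[max(1, i - 1)], coarse[min(length(coarse), i + 1)])
  opt <- stats::optimize(obj, bracket, tol = 1e-4)
  fit <- fitWeightsAtQ(survivals, rateGrid, 1 - opt$minimum, nZIter, ridge)
  new("RateSpectrum", rates = rateGrid, weights = fit$w,
      perFrameLoss = opt$minimum, resamples = matrix(0, 0, length(rateGrid)),
      residual = fit$rss)
}

#' Default dissociation-rate grid
#'
#' 60 log-spaced rates between 1e-4 and 1e2 1/s.
#' @param n number of grid points.
#' @param from,to grid limits in 1/s.
#' @return numeric vector.
#' @export
defaultRateGrid <- function(n = 60L, from = 1e-4, to = 1e2) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Resampled spectrum envelope
#'
#' Refits the spectrum on resamples that draw a fraction of the track
#' durations (without replacement, per condition) to estimate the
#' variability of the spectrum, as in the 499 x 80 percent resampling error
#' estimate.
#'
#' @param survivalsData named list of raw duration vectors per condition (as
#'   for [buildSurvival()]); resampling operates on durations, not on the
#'   binned counts.
#' @param taus,minFrames passed to [buildSurvival()].
#' @param nResamples number of resamples (default 499).
#' @param fraction fraction of durations drawn per condition (default 0.8).
#' @param seed integer seed; resampling is deterministic given the seed.
#' @param rateGrid rate grid.
#' @param refitLoss when FALSE (default) resamples reuse the full-data
#'   per-frame loss and only refit the weights, which is considerably
#'   faster; when TRUE the loss is refit per resample.
#' @return a [RateSpectrum-class] whose `resamples` slot holds one weight
#'   vector per row (0 rows when `nResamples = 0`).
#' @export
resampleSpectrum <- function(survivalsData, taus = NULL, minFrames = 1L,
                             nResamples = 499L, fraction = 0.8, seed = 1,
                             rateGrid = defaultRateGrid(), refitLoss = FALSE,
                             nFramesMovie = Inf) {
  full <- gridSpectrum(buildSurvival(survivalsData, taus, minFrames,
                                     nFramesMovie), rateGrid)
  if (nResamples <= 0) return(full)
  if (is.null(taus)) taus <- as.numeric(names(survivalsData))
  mat <- matrix(0, nResamples, length(rateGrid))
  withSeed(seed, {
    for (r in seq_len(nResamples)) {
      sub <- mapply(function(d, tau) {
        m <- floor(fraction * length(d))
        d[sample.int(length(d), m)]
      }, survivalsData, taus, SIMPLIFY = FALSE)
      sv <- buildSurvival(sub, taus, minFrames, nFramesMovie)
      if (refitLoss) {
        sp <- gridSpectrum(sv, rateGrid)
        mat[r, ] <- sp@weights
      } else {
        mat[r, ] <- fitWeightsAtQ(sv, rateGrid, 1 - full@perFrameLoss)$w
      }
    }
  })
  new("RateSpectrum", rates = rateGrid, weights = full@weights,
      perFrameLoss = full@perFrameLoss, resamples = mat,
      residual = full@residual)
}

#' Integrated cluster weights of a spectrum
#'
#' Sums the spectrum weights over user-supplied rate intervals, reported as
#' percentages.
#'
#' @param spectrum a [RateSpectrum-class].
#' @param intervals list of c(lower, upper) rate intervals in 1/s, or a
#'   2-column matrix.
#' @return numeric vector of percentages, one per interval.
#' @export
clusterWeights <- function(spectrum, intervals) {
  if (is.matrix(intervals))
    intervals <- split(intervals, seq_len(nrow(intervals)))
  vapply(intervals, function(iv) {
    100 * sum(spectrum@weights[spectrum@rates >= iv[1] & spectrum@rates <= iv[2]])
  }, numeric(1))
}

#' Detected clusters of a sparse spectrum
#'
#' Groups adjacent non-zero grid weights (separated by fewer than `gapPts`
#' empty grid points) into clusters and reports each cluster's mode (grid
#' rate of maximal weight) and total weight.
#'
#' @param spectrum a [RateSpectrum-class].
#' @param minWeight discard clusters with total weight below this (default
#'   0.01).
#' @param gapPts number of consecutive empty grid points that separates two
#'   clusters (default 3).
#' @return data.frame `mode` (1/s), `weight`.
#' @export
spectrumClusters <- function(spectrum, minWeight = 0.01, gapPts = 3L) {
  w <- spectrum@weights
  nz <- which(w > 1e-9)
  if (!length(nz)) return(data.frame(mode = numeric(0), weight = numeric(0)))
  grp <- cumsum(c(1, diff(nz) >= gapPts))
  modes <- weights <- numeric(0)
  for (g in unique(grp)) {
    ix <- nz[grp == g]
    tw <- sum(w[ix])
    if (tw < minWeight) next
    modes <- c(modes, spectrum@rates[ix[which.max(w[ix])]])
    weights <- c(weights, tw)
  }
  data.frame(mode = modes, weight = weights)
}

#' Which true rates are recovered by a spectrum
#'
#' A rate counts as recovered when a detected cluster mode lies within
#' `tolDecades` of it; each cluster can account for at most one rate
#' (greedy one-to-one matching by log-distance), so merged clusters do not
#' count as two recoveries.
#'
#' @param spectrum a [RateSpectrum-class].
#' @param trueRates numeric vector of ground-truth rates (1/s).
#' @param tolDecades half-width of the acceptance window in decades
#'   (default 0.5).
#' @param minWeight passed to [spectrumClusters()].
#' @return logical vector parallel to `trueRates`.
#' @export
recoveredRates <- function(spectrum, trueRates, tolDecades = 0.5,
                           minWeight = 0.01) {
  cl <- spectrumClusters(spectrum, minWeight)
  rec <- logical(length(trueRates))
  if (!nrow(cl)) return(rec)
  d <- abs(outer(log10(trueRates), log10(cl$mode), `-`))
  d[d > tolDecades] <- NA
  while (any(is.finite(d))) {
    ix <- which(d == min(d, na.rm = TRUE), arr.ind = TRUE)[1, ]
    rec[ix[1]] <- TRUE
    d[ix[1], ] <- NA
    d[, ix[2]] <- NA
  }
  rec
}

#' Bound fractions from interlaced time-lapse movies
#'
#' In interlaced time-lapse microscopy (ITM) two consecutive frames are
#' followed by a long dark period. Tracks surviving at least one dark period
#' are long bound, tracks persisting for two consecutive frames (within one
#' burst) are short bound, single detections are unbound. The bound fraction
#' and long-bound fraction are
#' \deqn{BF = N_{bound}/(N_{bound} + N_{unbound}), \quad
#'       BF_{long} = N_{long}/(N_{long} + N_{short}),}
#' computed per movie, as the mean over movies, and pooled over summed
#' counts.
#'
#' @param tracksets list of [TrackSet-class], one per ITM movie. Frame
#'   indices are consecutive acquisitions: frames 1,2 form burst 1, frames
#'   3,4 burst 2, and so on.
#' @param framesPerBurst acquisitions per burst (default 2).
#' @return list with `perMovie` (data.frame of counts and fractions),
#'   `mean` (mean BF/BF_long over movies) and `pooled`.
#' @export
itmBoundFractions <- function(tracksets, framesPerBurst = 2L) {
  per <- lapply(tracksets, function(ts) {
    tr <- ts@tracks
    if (!nrow(tr)) return(data.frame(nLong = 0L, nShort = 0L, nUnbound = 0L,
                                     bf = NA_real_, bfLong = NA_real_))
    burst <- (tr$frame - 1L) %/% framesPerBurst
    spanB <- tapply(burst, tr$track_id, function(b) max(b) - min(b))
    nDet <- tapply(tr$frame, tr$track_id, length)
    nLong <- sum(spanB >= 1)
    nShort <- sum(spanB == 0 & nDet >= 2)
    nUnbound <- sum(nDet == 1 & spanB == 0)
    data.frame(nLong = nLong, nShort = nShort, nUnbound = nUnbound,
               bf = (nLong + nShort) / max(nLong + nShort + nUnbound, 1),
               bfLong = if (nLong + nShort > 0) nLong / (nLong + nShort) else NA_real_)
  })
  per <- do.call(rbind, per)
  tot <- colSums(per[c("nLong", "nShort", "nUnbound")])
  pooled <- c(bf = unname((tot[1] + tot[2]) / max(sum(tot), 1)),
              bfLong = unname(if (tot[1] + tot[2] > 0) tot[1] / (tot[1] + tot[2]) else NA_real_))
  list(perMovie = per,
       mean = c(bf = mean(per$bf, na.rm = TRUE),
                bfLong = mean(per$bfLong, na.rm = TRUE)),
       pooled = pooled)
}
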