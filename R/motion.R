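# Mobility analyses: jump histograms, cumulative diffusion fits, MSD and
# confinement, jump angles, localization / jump-distance maps, intensity
# traces.

# consecutive-frame (non-gap) jumps of a TrackSet, optionally limited to the
# first `limit` jumps of each track
trackJumps <- function(ts, limit = Inf) {
  tr <- ts@tracks
  if (nrow(tr) < 2)
    return(data.frame(track_id = integer(0), dx = numeric(0), dy = numeric(0),
                      x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0)))
  same <- diff(tr$track_id) == 0 & diff(tr$frame) == 1L
  i <- which(same)
  jp <- data.frame(track_id = tr$track_id[i],
                   dx = tr$x[i + 1] - tr$x[i], dy = tr$y[i + 1] - tr$y[i],
                   x0 = tr$x[i], y0 = tr$y[i],
                   x1 = tr$x[i + 1], y1 = tr$y[i + 1])
  if (is.finite(limit)) {
    keep <- unlist(lapply(split(seq_len(nrow(jp)), jp$track_id),
                          function(ix) ix[seq_len(min(limit, length(ix)))]),
                   use.names = FALSE)
    jp <- jp[sort(keep), , drop = FALSE]
  }
  jp
}

#' Jump-distance histogram
#'
#' Histogram of all single-molecule jump distances between consecutive
#' frames; jumps across bridged gap frames are omitted. Limiting the jumps
#' per track (e.g. to 1) reduces the weight bias of long immobile tracks
#' over mobile ones.
#'
#' @param ts a [TrackSet-class].
#' @param binWidth histogram bin width Delta r in micrometres.
#' @param jumpsPerTrack maximal number of jumps per track (default all).
#' @return list `breaks`, `counts`, `jumps` (the raw distances, um).
#' @export
jumpHistogram <- function(ts, binWidth, jumpsPerTrack = Inf) {
  stopifnot(binWidth > 0)
  jp <- trackJumps(ts, jumpsPerTrack)
  r <- sqrt(jp$dx^2 + jp$dy^2)
  top <- max(r, binWidth)
  breaks <- seq(0, top + binWidth, by = binWidth)
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts, jumps = r)
}

#' Cumulative squared-displacement diffusion fit
#'
#' Fits the cumulative distribution of X = (dx^2 + dy^2)/(4 tau) with a two-
#' or three-component Brownian mixture whose last component is normalized
#' for the truncation of jump distances by the tracking radius:
#' \deqn{F(X) = A_1 (1 - e^{-X/D_1}) + \dots + (1 - \sum A_i)
#'   \frac{e^{-C_1/D_n} - e^{-X/D_n}}{e^{-C_1/D_n} - e^{-C_2/D_n}}}
#' with \eqn{C_1 = 0} and \eqn{C_2 = s^2/(4\tau)} set by the tracking
#' radius. The empirical distribution is evaluated at the sample quantiles
#' (no binning loss); 95 percent confidence intervals come from the fit
#' covariance.
#'
#' @param ts a [TrackSet-class], or a numeric vector of squared jump
#'   distances (um^2) via `jumpsSq`.
#' @param nComponents 2 or 3.
#' @param tau frame-cycle time in seconds (default: the TrackSet's).
#' @param C2 truncation bound on the X scale in um^2/s (default
#'   \eqn{s^2/(4\tau)} from the tracking radius; `Inf` disables truncation).
#' @param jumpsSq optional raw squared jump distances instead of `ts`.
#' @param jumpsPerTrack maximal jumps per track.
#' @return list of class `"DiffusionFit"`: `amplitudes`, `diffusionCoeffs`
#'   (um^2/s, ascending), `ci` (95 percent intervals), `adjR2`, `C2`, `n`.
#' @export
fitCumulativeJumps <- function(ts = NULL, nComponents = 2L, tau = NULL,
                               C2 = NULL, jumpsSq = NULL,
                               jumpsPerTrack = Inf) {
  if (is.null(jumpsSq)) {
    jp <- trackJumps(ts, jumpsPerTrack)
    jumpsSq <- jp$dx^2 + jp$dy^2
    if (is.null(tau)) tau <- ts@frameCycleTime
    if (is.null(C2)) C2 <- ts@params$trackingRadius^2 / (4 * tau)
  }
  stopifnot(nComponents %in% c(2L, 3L), tau > 0, length(jumpsSq) >= 10)
  if (is.null(C2)) C2 <- Inf
  X <- sort(jumpsSq) / (4 * tau)
  Femp <- seq_along(X) / length(X)
  trunc3 <- function(X, D) {
    if (is.finite(C2)) (1 - exp(-X / D)) / (1 - exp(-C2 / D))
    else 1 - exp(-X / D)
  }
  qs <- stats::quantile(X, c(0.3, 0.7, 0.95))
  df <- data.frame(X = X, Femp = Femp)
  if (nComponents == 2L) {
    fit <- minpack.lm::nlsLM(
      Femp ~ A1 * (1 - exp(-X / D1)) + (1 - A1) * trunc3(X, D2),
      data = df,
      start = list(A1 = 0.5, D1 = max(qs[1], 1e-6), D2 = max(qs[3], 1e-5)),
      lower = c(0, 1e-9, 1e-9), upper = c(1, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    fit <- minpack.lm::nlsLM(
      Femp ~ A1 * (1 - exp(-X / D1)) + A2 * (1 - exp(-X / D2)) +
        (1 - A1 - A2) * trunc3(X, D3),
      data = df,
      start = list(A1 = 0.3, A2 = 0.3, D1 = max(qs[1], 1e-6),
                   D2 = max(qs[2], 1e-5), D3 = max(qs[3], 1e-4)),
      lower = c(0, 0, 1e-9, 1e-9, 1e-9), upper = c(1, 1, Inf, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300))
  }
  p <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA, length(p)))
  nA <- nComponents - 1L
  A <- unname(p[seq_len(nA)]); A <- c(A, 1 - sum(A))
  D <- unname(p[nA + seq_len(nComponents)])
  o <- order(D)
  ciLow <- c(p - 1.96 * se)[c(seq_len(nA), nA + seq_len(nComponents))]
  ciHigh <- c(p + 1.96 * se)[c(seq_len(nA), nA + seq_len(nComponents))]
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((Femp - mean(Femp))^2)
  n <- length(X); k <- length(p)
  adjR2 <- 1 - (rss / (n - k - 1)) / (tss / (n - 1))
  structure(list(amplitudes = A[o], diffusionCoeffs = D[o],
                 ci = cbind(low = ciLow, high = ciHigh), adjR2 = adjR2,
                 C2 = C2, n = n),
            class = "DiffusionFit")
}

#' @export
print.DiffusionFit <- function(x, ...) {
  cat("DiffusionFit (", length(x$amplitudes), " components, n = ", x$n,
      " jumps, adj R^2 = ", signif(x$adjR2, 4), ")\n", sep = "")
  for (i in seq_along(x$amplitudes))
    cat(sprintf("  D%d = %.4g um^2/s  A%d = %.3f\n", i, x$diffusionCoeffs[i],
                i, x$amplitudes[i]))
  invisible(x)
}

#' Time-averaged mean squared displacement of one track
#'
#' Overlapping time-averaged MSD up to `maxLagFraction` of the track span
#' (bias/variance compromise). Gap-bridged frames have no localization and
#' are skipped pairwise.
#'
#' @param track data.frame with `frame`, `x`, `y` (one track).
#' @param tau frame-cycle time in seconds.
#' @param maxLagFraction largest lag as a fraction of the span (default 1/3).
#' @return data.frame `lag` (s), `msd` (um^2), `n` (pairs).
#' @export
msdCurve <- function(track, tau, maxLagFraction = 1 / 3) {
  fr <- track$frame
  span <- max(fr) - min(fr)
  maxLag <- max(1L, floor(span * maxLagFraction))
  lags <- seq_len(maxLag)
  msd <- nn <- numeric(length(lags))
  for (li in seq_along(lags)) {
    l <- lags[li]
    i <- match(fr + l, fr)
    ok <- !is.na(i)
    if (!any(ok)) next
    d2 <- (track$x[i[ok]] - track$x[ok])^2 + (track$y[i[ok]] - track$y[ok])^2
    msd[li] <- mean(d2); nn[li] <- sum(ok)
  }
  keep <- nn > 0
  data.frame(lag = lags[keep] * tau, msd = msd[keep], n = nn[keep])
}

#' Confinement-radius analysis of one track
#'
#' Fits the track's time-averaged MSD with a power law
#' \eqn{MSD = 4 D t^\alpha}; when \eqn{\alpha} is at or below
#' `alphaThreshold` the track is considered confined and the circular
#' confinement model
#' \deqn{MSD_{circle} = R^2 (1 - e^{-4 D^* t_{lag} / R^2}) + \mathrm{offset}}
#' is fitted for the confinement radius R, the local diffusion coefficient
#' D* and an offset absorbing the localization error.
#'
#' @param track data.frame with `frame`, `x`, `y` of one track (at least 5
#'   non-gap positions).
#' @param tau frame-cycle time in seconds.
#' @param alphaThreshold maximal alpha considered confined (default 0.7).
#' @return list of class `"ConfinementResult"`: `confined`, `alpha`, and for
#'   confined tracks `R` (um), `Dstar` (um^2/s), `offset` (um^2),
#'   `meanJumpDistance` (um).
#' @export
msdConfinement <- function(track, tau, alphaThreshold = 0.7) {
  stopifnot(nrow(track) >= 5)
  mc <- msdCurve(track, tau)
  if (nrow(mc) < 3) stop("track too short for MSD analysis")
  lf <- stats::lm(log(msd) ~ log(lag), data = mc[mc$msd > 0, ])
  alpha <- unname(stats::coef(lf)[2])
  jumps <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  out <- list(confined = alpha <= alphaThreshold, alpha = alpha,
              meanJumpDistance = mean(jumps))
  if (out$confined) {
    plateau <- max(mc$msd)
    fit <- tryCatch(minpack.lm::nlsLM(
      msd ~ R2 * (1 - exp(-4 * Ds * lag / R2)) + off, data = mc,
      start = list(R2 = plateau, Ds = plateau / (4 * mc$lag[1]), off = 0),
      lower = c(1e-12, 1e-12, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- stats::coef(fit)
      out$R <- sqrt(unname(p[["R2"]]))
      out$Dstar <- unname(p[["Ds"]])
      out$offset <- unname(p[["off"]])
    } else {
      out$confined <- NA
    }
  }
  structure(out, class = "ConfinementResult")
}

#' Angles between consecutive jumps
#'
#' For each pair of consecutive non-gap jumps within a track, the angle
#' between their direction vectors (inverse cosine of the scalar product of
#' the normalized vectors), in degrees within [0, 180]. Angles involving
#' jumps over gap frames are omitted.
#'
#' @param ts a [TrackSet-class].
#' @param nBins number of histogram bins over [0, 180] (default 18).
#' @return list `angles` (degrees), `breaks`, `counts`.
#' @export
jumpAngles <- function(ts, nBins = 18L) {
  tr <- ts@tracks
  n <- nrow(tr)
  if (n < 3) return(list(angles = numeric(0),
                         breaks = seq(0, 180, length.out = nBins + 1),
                         counts = integer(nBins)))
  c1 <- tr$track_id[1:(n - 2)] == tr$track_id[3:n] &
    tr$frame[2:(n - 1)] - tr$frame[1:(n - 2)] == 1L &
    tr$frame[3:n] - tr$frame[2:(n - 1)] == 1L
  i <- which(c1)
  v1x <- tr$x[i + 1] - tr$x[i]; v1y <- tr$y[i + 1] - tr$y[i]
  v2x <- tr$x[i + 2] - tr$x[i + 1]; v2y <- tr$y[i + 2] - tr$y[i + 1]
  n1 <- sqrt(v1x^2 + v1y^2); n2 <- sqrt(v2x^2 + v2y^2)
  ok <- n1 > 0 & n2 > 0
  cosA <- pmin(pmax((v1x * v2x + v1y * v2y)[ok] / (n1 * n2)[ok], -1), 1)
  ang <- acos(cosA) * 180 / pi
  breaks <- seq(0, 180, length.out = nBins + 1)
  counts <- graphics::hist(ang, breaks = breaks, plot = FALSE)$counts
  list(angles = ang, breaks = breaks, counts = counts)
}

#' Localization heat map
#'
#' 2D histogram of localization positions. `scale` > 1 divides the original
#' pixel into smaller bins (super-resolved map), `scale` < 1 merges pixels.
#'
#' @param locs data.frame with `x_px`, `y_px` (or `x`, `y` in um plus
#'   `pixelSizeUm`).
#' @param dims frame size c(H, W) in original pixels.
#' @param scale bin scale factor relative to the pixel size (default 1).
#' @param pixelSizeUm pixel size, used when only um columns are present.
#' @return integer matrix of counts (H*scale x W*scale).
#' @export
localizationMap <- function(locs, dims, scale = 1, pixelSizeUm = 0.16) {
  xs <- if ("x_px" %in% names(locs)) locs$x_px else locs$x / pixelSizeUm
  ys <- if ("y_px" %in% names(locs)) locs$y_px else locs$y / pixelSizeUm
  H <- round(dims[1] * scale); W <- round(dims[2] * scale)
  bi <- floor((ys + 0.5) * scale); bj <- floor((xs + 0.5) * scale)
  ok <- bi >= 0 & bi < H & bj >= 0 & bj < W
  m <- matrix(0L, H, W)
  if (any(ok)) {
    tab <- table(factor(bi[ok] * W + bj[ok], levels = 0:(H * W - 1)))
    m <- matrix(as.integer(tab), H, W, byrow = TRUE)
  }
  m
}

#' Jump-distance heat map
#'
#' For every non-gap jump a virtual line is drawn between start and end
#' position; every map bin touched by the line (supercover rasterization) is
#' assigned the jump distance. Bin values are the mean of all assigned jump
#' distances (bins without jumps are NA).
#'
#' @param ts a [TrackSet-class] with positions in um.
#' @param dims frame size c(H, W) in original pixels.
#' @param scale bin scale factor (default 1).
#' @param pixelSizeUm pixel size in um.
#' @return numeric matrix (mean jump distance per bin, um).
#' @export
jumpDistanceMap <- function(ts, dims, scale = 1, pixelSizeUm = 0.16) {
  jp <- trackJumps(ts)
  H <- round(dims[1] * scale); W <- round(dims[2] * scale)
  sumM <- matrix(0, H, W); cntM <- matrix(0L, H, W)
  for (k in seq_len(nrow(jp))) {
    r <- sqrt(jp$dx[k]^2 + jp$dy[k]^2)
    px <- supercoverPixels(jp$x0[k] / pixelSizeUm * scale,
                           jp$y0[k] / pixelSizeUm * scale,
                           jp$x1[k] / pixelSizeUm * scale,
                           jp$y1[k] / pixelSizeUm * scale)
    for (m in seq_len(nrow(px))) {
      i <- px[m, 2] + 1L; j <- px[m, 1] + 1L
      if (i >= 1 && i <= H && j >= 1 && j <= W) {
        sumM[i, j] <- sumM[i, j] + r
        cntM[i, j] <- cntM[i, j] + 1L
      }
    }
  }
  out <- sumM / cntM
  out[cntM == 0] <- NA_real_
  out
}

#' Intensity trace and kymographs of one track
#'
#' Mean intensity in a (2w+1) x (2w+1) pixel window around the spot centre
#' for every frame of the track, continued for `tail` frames after the last
#' detection with the window frozen at the last position (clipped at the
#' movie end). Kymographs are returned per spatial dimension: the window
#' strip around the track position with the other dimension maximum
#' projected.
#'
#' @param stack image array H x W x nFrames (or [SyntheticMovie-class]).
#' @param track data.frame `frame`, `x_px`, `y_px` (pixel coordinates).
#' @param halfWindow half window size in px (default 1, i.e. 3x3).
#' @param tail frames appended after the track end (default 20).
#' @return list `frame`, `intensity`, `kymoX` (nFrames x W), `kymoY`
#'   (nFrames x H).
#' @export
intensityTrace <- function(stack, track, halfWindow = 1L, tail = 20L) {
  if (is(stack, "SyntheticMovie")) stack <- stack@stack
  H <- dim(stack)[1]; W <- dim(stack)[2]; nF <- dim(stack)[3]
  f0 <- min(track$frame)
  fEnd <- min(max(track$frame) + tail, nF)
  framesOut <- f0:fEnd
  inten <- numeric(length(framesOut))
  kymoX <- matrix(NA_real_, length(framesOut), W)
  kymoY <- matrix(NA_real_, length(framesOut), H)
  lastX <- track$x_px[which.max(track$frame)]
  lastY <- track$y_px[which.max(track$frame)]
  for (k in seq_along(framesOut)) {
    f <- framesOut[k]
    row <- match(f, track$frame)
    xc <- if (!is.na(row)) track$x_px[row] else lastX
    yc <- if (!is.na(row)) track$y_px[row] else lastY
    i <- max(1, round(yc) + 1 - halfWindow):min(H, round(yc) + 1 + halfWindow)
    j <- max(1, round(xc) + 1 - halfWindow):min(W, round(xc) + 1 + halfWindow)
    inten[k] <- mean(stack[i, j, f])
    kymoX[k, ] <- apply(stack[i, , f, drop = FALSE], 2, max)
    kymoY[k, ] <- apply(stack[, j, f, drop = FALSE], 1, max)
  }
  list(frame = framesOut, intensity = inten, kymoX = kymoX, kymoY = kymoY)
}
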