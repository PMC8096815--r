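# Spot detection: a-trous wavelet enhancement, local-maximum candidate
# selection, sub-pixel 2D Gaussian refinement.

# Separable convolution with reflective boundary handling. kRow/kCol are odd
# symmetric kernels applied along rows (x) and columns (y).
sepConvolve <- function(img, kRow, kCol) {
  convAxis <- function(m, k) {
    r <- (length(k) - 1L) %/% 2L
    n <- nrow(m)
    idx <- seq(1L - r, n + r)
    idx <- ifelse(idx < 1L, 2L - idx, idx)        # mirror at the top edge
    idx <- ifelse(idx > n, 2L * n - idx, idx)     # mirror at the bottom edge
    idx <- pmin(pmax(idx, 1L), n)                 # clamp when r >= n
    padded <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * padded[(j - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  img <- convAxis(img, kCol)          # along columns (y)
  t(convAxis(t(img), kRow))           # along rows (x)
}

# B3-spline kernel of the a-trous decomposition, upsampled with 2^(level-1)-1
# zeros ("holes") between taps.
atrousKernel <- function(level) {
  base <- c(1, 4, 6, 4, 1) / 16
  if (level == 1L) return(base)
  gap <- 2^(level - 1L)
  k <- numeric(4L * gap + 1L)
  k[seq(1L, length(k), by = gap)] <- base
  k
}

#' A-trous wavelet spot-enhancement filter
#'
#' Computes the a-trous (stationary) B3-spline wavelet decomposition of the
#' image and combines the first `nLevels` detail planes. The combination is a
#' band-pass: the response to a constant image is zero and single-molecule
#' spots (about one pixel PSF sigma) are strongly enhanced relative to smooth
#' background. With `combine = "sum"` the filter is linear (the default);
#' `"prod"` multiplies the detail planes, which further suppresses noise but
#' is nonlinear.
#'
#' @param img numeric matrix (H x W), all values finite.
#' @param nLevels number of detail planes to combine (>= 1, default 2).
#' @param combine `"sum"` or `"prod"`.
#' @return filtered image, same dimensions as `img`.
#' @export
waveletFilter <- function(img, nLevels = 2L, combine = c("sum", "prod")) {
  combine <- match.arg(combine)
  stopifnot(is.matrix(img), nLevels >= 1)
  if (!all(is.finite(img))) stop("non-finite pixels in input image")
  approx <- img
  details <- vector("list", nLevels)
  for (lev in seq_len(nLevels)) {
    k <- atrousKernel(lev)
    nxt <- sepConvolve(approx, k, k)
    details[[lev]] <- approx - nxt
    approx <- nxt
  }
  if (combine == "sum") Reduce(`+`, details) else Reduce(`*`, details)
}

#' Robust threshold suggestion for the filtered image
#'
#' Suggests `k` times the median absolute deviation of the wavelet-filtered
#' image as a detection threshold. The suggestion is never applied silently;
#' pass the returned value to [detectCandidates()] explicitly.
#'
#' @param filtered wavelet-filtered image.
#' @param k multiplier (default 6).
#' @return threshold in filter-response units.
#' @export
suggestThreshold <- function(filtered, k = 6) {
  k * stats::mad(as.numeric(filtered))
}

#' Detect spot candidates as thresholded local maxima
#'
#' Returns strict 3x3 local maxima of the filtered image with response at or
#' above `threshold`, at least 2 px away from the image border, inside the
#' optional ROI mask. Candidates closer than 2 px to a brighter candidate are
#' merged into it (one PSF should yield one candidate). Output is sorted by
#' descending filter response.
#'
#' @param filtered wavelet-filtered image.
#' @param threshold detection threshold in filter-response units (> 0).
#' @param roiMask optional logical/0-1 matrix of the same size; candidates
#'   outside are dropped.
#' @param borderMargin minimal distance (px) of a candidate from the border.
#' @return data.frame `row`, `col` (0-based integer pixels), `value`.
#' @export
detectCandidates <- function(filtered, threshold, roiMask = NULL,
                             borderMargin = 2L) {
  stopifnot(threshold > 0)
  H <- nrow(filtered); W <- ncol(filtered)
  inner <- filtered[2:(H - 1), 2:(W - 1)]
  isMax <- inner >= threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    isMax <- isMax & (inner > filtered[2:(H - 1) + di, 2:(W - 1) + dj])
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  ri <- idx[, 1] + 1L; ci <- idx[, 2] + 1L       # back to full-image indices
  val <- filtered[cbind(ri, ci)]
  row0 <- ri - 1L; col0 <- ci - 1L               # 0-based
  keep <- row0 >= borderMargin & row0 <= H - 1L - borderMargin &
          col0 >= borderMargin & col0 <= W - 1L - borderMargin
  if (!is.null(roiMask)) keep <- keep & roiMask[cbind(ri, ci)] > 0
  row0 <- row0[keep]; col0 <- col0[keep]; val <- val[keep]
  o <- order(-val)
  row0 <- row0[o]; col0 <- col0[o]; val <- val[o]
  # merge candidates closer than 2 px, keeping the brighter one
  drop <- logical(length(val))
  for (i in seq_along(val)) {
    if (drop[i]) next
    if (i < length(val)) {
      later <- (i + 1):length(val)
      close <- (row0[later] - row0[i])^2 + (col0[later] - col0[i])^2 < 4
      drop[later[close]] <- TRUE
    }
  }
  data.frame(row = row0[!drop], col = col0[!drop], value = val[!drop])
}

#' Sub-pixel refinement by least-squares 2D Gaussian fit
#'
#' Fits amplitude * Gaussian(x0, y0, width) + background to the raw pixel
#' values in a window around a candidate (window clipped at image borders).
#' Coordinates are 0-based with the pixel centre at integer coordinates.
#'
#' @param img raw image matrix.
#' @param candidate one-row data.frame from [detectCandidates()] (or a list
#'   with `row`, `col`).
#' @param window fit window edge length in pixels (odd, default 7).
#' @param psfWidth initial width guess in pixels.
#' @return one-row data.frame `x`, `y` (0-based px), `amplitude`,
#'   `background`, `fit_width`. A rejected candidate (diverged fit,
#'   non-positive amplitude, or centre moved more than 2 px) yields a
#'   zero-row data.frame whose `"reason"` attribute states why.
#' @export
refineLocalization <- function(img, candidate, window = 7L, psfWidth = 1) {
  r <- (as.integer(window) - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  ri <- candidate$row + 1L; ci <- candidate$col + 1L   # 1-based
  ii <- max(1L, ri - r):min(H, ri + r)
  jj <- max(1L, ci - r):min(W, ci + r)
  z <- as.numeric(img[ii, jj])
  ys <- rep(ii - 1L, times = length(jj))
  xs <- rep(jj - 1L, each = length(ii))
  rejected <- function(why) {
    out <- data.frame(x = numeric(0), y = numeric(0), amplitude = numeric(0),
                      background = numeric(0), fit_width = numeric(0))
    attr(out, "reason") <- why
    out
  }
  bg0 <- min(z); a0 <- max(z) - bg0
  if (a0 <= 0) return(rejected("flat window"))
  df <- data.frame(z = z, xs = xs, ys = ys)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + a * exp(-((xs - x0)^2 + (ys - y0)^2) / (2 * w^2)),
      data = df,
      start = list(b = bg0, a = a0, x0 = candidate$col, y0 = candidate$row,
                   w = psfWidth),
      lower = c(-Inf, 0, candidate$col - r, candidate$row - r, 0.3),
      upper = c(Inf, Inf, candidate$col + r, candidate$row + r, 3 * window),
      control = minpack.lm::nls.lm.control(maxiter = 120)),
    error = function(e) e)
  if (inherits(fit, "error")) return(rejected(conditionMessage(fit)))
  p <- stats::coef(fit)
  if (p[["a"]] <= 0 ||
      abs(p[["x0"]] - candidate$col) > 2 || abs(p[["y0"]] - candidate$row) > 2)
    return(rejected("rejected fit"))
  data.frame(x = p[["x0"]], y = p[["y0"]], amplitude = p[["a"]],
             background = p[["b"]], fit_width = p[["w"]])
}

#' Detect and localize spots in a movie
#'
#' Runs wavelet filtering, candidate selection and Gaussian refinement on
#' every frame of an image stack.
#'
#' @param stack numeric array H x W x nFrames (or a [SyntheticMovie-class]).
#' @param threshold detection threshold in filter-response units; required.
#' @param roiMask optional ROI matrix.
#' @param pixelSizeUm pixel size for the micrometre coordinates.
#' @param nLevels,combine passed to [waveletFilter()].
#' @param window,psfWidth passed to [refineLocalization()].
#' @return data.frame `frame`, `x`, `y` (um), `x_px`, `y_px`, `amplitude`,
#'   `background`, `fit_width`.
#' @export
detectSpots <- function(stack, threshold, roiMask = NULL, pixelSizeUm = 0.16,
                        nLevels = 2L, combine = "sum", window = 7L,
                        psfWidth = 1) {
  if (is(stack, "SyntheticMovie")) {
    pixelSizeUm <- stack@pixelSizeUm
    stack <- stack@stack
  }
  nF <- dim(stack)[3]
  out <- vector("list", nF)
  for (f in seq_len(nF)) {
    img <- stack[, , f]
    filt <- waveletFilter(img, nLevels, combine)
    cand <- detectCandidates(filt, threshold, roiMask)
    if (nrow(cand) == 0) next
    locs <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand)))
      locs[[i]] <- refineLocalization(img, cand[i, ], window, psfWidth)
    locs <- do.call(rbind, locs)
    if (is.null(locs) || nrow(locs) == 0) next
    out[[f]] <- cbind(frame = f, locs)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      amplitude = numeric(0), background = numeric(0),
                      fit_width = numeric(0))
  data.frame(frame = res$frame, x = res$x * pixelSizeUm, y = res$y * pixelSizeUm,
             x_px = res$x, y_px = res$y, amplitude = res$amplitude,
             background = res$background, fit_width = res$fit_width)
}
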