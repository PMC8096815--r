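# Internal helpers.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so internal fixed-seed integrations do not disturb
# user-level reproducibility.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-stream sub-seed derived from a base seed; keeps stream i
# independent of how many draws earlier streams consumed. Kept below 2^31.
subSeed <- function(seed, i) {
  (as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483629
}

# Supercover line rasterization: all integer pixels (0-based) touched by the
# segment from (x0, y0) to (x1, y1) in pixel coordinates (pixel centres at
# integer coordinates, pixel (i, j) covers [i - 0.5, i + 0.5]).
supercoverPixels <- function(x0, y0, x1, y1) {
  # work in corner coordinates so pixel (i, j) covers [i, i + 1)
  xa <- x0 + 0.5; ya <- y0 + 0.5; xb <- x1 + 0.5; yb <- y1 + 0.5
  px <- floor(xa); py <- floor(ya)
  qx <- floor(xb); qy <- floor(yb)
  dx <- xb - xa; dy <- yb - ya
  n <- abs(qx - px) + abs(qy - py)
  out <- matrix(NA_real_, n + 1, 2)
  out[1, ] <- c(px, py)
  sx <- sign(dx); sy <- sign(dy)
  # parametric distances to next vertical / horizontal grid line
  tMaxX <- if (dx != 0) ((px + (sx > 0)) - xa) / dx else Inf
  tMaxY <- if (dy != 0) ((py + (sy > 0)) - ya) / dy else Inf
  tDeltaX <- if (dx != 0) abs(1 / dx) else Inf
  tDeltaY <- if (dy != 0) abs(1 / dy) else Inf
  k <- 1
  while (k <= n) {
    if (tMaxX < tMaxY) {
      px <- px + sx
      tMaxX <- tMaxX + tDeltaX
    } else {
      py <- py + sy
      tMaxY <- tMaxY + tDeltaY
    }
    k <- k + 1
    out[k, ] <- c(px, py)
  }
  out
}
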