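# Nearest-neighbour linking with optional one-frame gap bridging.

#' Link localizations into tracks (nearest-neighbour, optional gap frame)
#'
#' Model-free nearest-neighbour linking: for every pair of consecutive
#' frames, all candidate links (track last position, new spot) with distance
#' at or below the tracking radius are sorted by ascending distance and
#' assigned greedily, each track and spot used at most once — this realizes
#' symmetric nearest-neighbour matching with deterministic, order-independent
#' output (exact ties broken by lower track id, then lower spot index).
#' Spots that cannot be linked start new tracks. When `maxGapFrames = 1`, a
#' track with at least `minFramesBeforeGap` detections that found no match
#' may be continued by a spot two frames later within the tracking radius of
#' its last seen position; such gap candidates compete in the same greedy
#' pass, at their true Euclidean distance, with plain continuations and with
#' new-track creation.
#'
#' @param locs data.frame with columns `frame` (integer), `x`, `y`
#'   (micrometres); additional columns are preserved in the output through
#'   `loc_id`.
#' @param params a [trackingParams()] list.
#' @param frameCycleTime frame-cycle time tau_tl in seconds.
#' @param source optional movie identifier.
#' @return a [TrackSet-class]; `tracks(x)` has columns `track_id`, `frame`,
#'   `x`, `y`, `gap`, `loc_id`.
#' @export
nearestNeighbourLink <- function(locs, params, frameCycleTime = 1,
                                 source = "") {
  stopifnot(inherits(params, "TrackingParams"),
            all(c("frame", "x", "y") %in% names(locs)))
  s <- params$trackingRadius
  gap <- params$maxGapFrames
  minBG <- params$minFramesBeforeGap
  n <- nrow(locs)
  if (n && anyDuplicated(locs[c("frame", "x", "y")]))
    warning("duplicate localizations (same frame and coordinates); both kept")
  ord <- order(locs$frame)
  frame <- as.integer(locs$frame[ord]); x <- locs$x[ord]; y <- locs$y[ord]
  locId <- ord                                   # row index into input
  trackId <- integer(n)                          # assignment per localization
  gapFlag <- logical(n)
  # active track state (parallel vectors)
  aTid <- integer(0); aX <- numeric(0); aY <- numeric(0)
  aFrame <- integer(0); aN <- integer(0)
  nextTid <- 1L
  frames <- unique(frame)
  idxByFrame <- split(seq_len(n), frame)
  for (f in frames) {
    si <- idxByFrame[[as.character(f)]]
    # candidate tracks: matched last frame f-1, or gap-eligible from f-2
    cand <- which(aFrame == f - 1L |
                    (gap == 1L & aFrame == f - 2L & aN >= minBG))
    assignedSpot <- rep(NA_integer_, length(si))
    if (length(cand)) {
      dx <- outer(aX[cand], x[si], `-`)
      dy <- outer(aY[cand], y[si], `-`)
      d <- sqrt(dx * dx + dy * dy)
      ok <- which(d <= s, arr.ind = TRUE)
      if (nrow(ok)) {
        o <- order(d[ok], aTid[cand][ok[, 1]], ok[, 2])
        usedT <- logical(length(cand)); usedS <- logical(length(si))
        for (k in o) {
          ti <- ok[k, 1]; sj <- ok[k, 2]
          if (usedT[ti] || usedS[sj]) next
          usedT[ti] <- TRUE; usedS[sj] <- TRUE
          ai <- cand[ti]
          assignedSpot[sj] <- ai
        }
      }
    }
    for (j in seq_along(si)) {
      i <- si[j]
      ai <- assignedSpot[j]
      if (!is.na(ai)) {
        trackId[i] <- aTid[ai]
        gapFlag[i] <- (f - aFrame[ai]) == 2L
        aX[ai] <- x[i]; aY[ai] <- y[i]; aFrame[ai] <- f; aN[ai] <- aN[ai] + 1L
      } else {
        trackId[i] <- nextTid
        aTid <- c(aTid, nextTid); aX <- c(aX, x[i]); aY <- c(aY, y[i])
        aFrame <- c(aFrame, f); aN <- c(aN, 1L)
        nextTid <- nextTid + 1L
      }
    }
    # retire tracks that can no longer be continued
    alive <- aFrame >= f - gap
    aTid <- aTid[alive]; aX <- aX[alive]; aY <- aY[alive]
    aFrame <- aFrame[alive]; aN <- aN[alive]
  }
  tr <- data.frame(track_id = trackId, frame = frame, x = x, y = y,
                   gap = gapFlag, loc_id = locId)
  tr <- tr[order(tr$track_id, tr$frame), , drop = FALSE]
  rownames(tr) <- NULL
  new("TrackSet", tracks = tr, params = unclass(params),
      frameCycleTime = frameCycleTime, source = source)
}

#' Split tracks into bound and mobile classes
#'
#' A track is classified bound if it contains at least `minLen` successive
#' detections that all stay within `radius` of the running centroid of the
#' segment (each new detection is checked against the centroid of the
#' segment so far, then included).
#'
#' @param ts a [TrackSet-class].
#' @param minLen minimal number of successive detections within the area.
#' @param radius confinement radius in micrometres.
#' @return list with elements `bound` and `mobile`, each an integer vector of
#'   track ids.
#' @export
segmentBound <- function(ts, minLen, radius) {
  stopifnot(radius > 0, minLen >= 1)
  tr <- ts@tracks
  ids <- unique(tr$track_id)
  bound <- logical(length(ids))
  byTrack <- split(seq_len(nrow(tr)), tr$track_id)
  for (k in seq_along(ids)) {
    ix <- byTrack[[as.character(ids[k])]]
    xs <- tr$x[ix]; ys <- tr$y[ix]
    m <- length(xs)
    if (m < minLen) next
    for (i0 in seq_len(m - minLen + 1L)) {
      cx <- xs[i0]; cy <- ys[i0]; cnt <- 1L
      run <- 1L
      j <- i0 + 1L
      while (run < minLen && j <= m) {
        if (sqrt((xs[j] - cx / cnt)^2 + (ys[j] - cy / cnt)^2) > radius) break
        cx <- cx + xs[j]; cy <- cy + ys[j]; cnt <- cnt + 1L
        run <- run + 1L
        j <- j + 1L
      }
      if (run >= minLen) { bound[k] <- TRUE; break }
    }
  }
  list(bound = ids[bound], mobile = ids[!bound])
}

#' Track survival times
#'
#' Duration of each track in seconds: (frames spanned - 1) x tau_tl. Bridged
#' gap frames lie inside the span and therefore count toward the duration,
#' preserving the temporal information of recovered tracks.
#'
#' @param ts a [TrackSet-class].
#' @param minFrames keep only tracks spanning at least this many frames.
#' @return numeric vector of durations in seconds (one per retained track).
#' @export
trackSurvivalTimes <- function(ts, minFrames = 1L) {
  trackDurationTable(ts, minFrames)$duration
}

#' Track durations with birth frames
#'
#' Like [trackSurvivalTimes()] but also reports the first frame of each
#' track, which the spectrum fit uses to model right-censoring by the movie
#' end from the empirical birth-frame distribution.
#'
#' @inheritParams trackSurvivalTimes
#' @return data.frame `duration` (s), `birthFrame`.
#' @export
trackDurationTable <- function(ts, minFrames = 1L) {
  tr <- ts@tracks
  if (!nrow(tr))
    return(data.frame(duration = numeric(0), birthFrame = integer(0)))
  first <- tapply(tr$frame, tr$track_id, min)
  last <- tapply(tr$frame, tr$track_id, max)
  spans <- last - first + 1L
  keep <- spans >= minFrames
  data.frame(duration = as.numeric(spans[keep] - 1L) * ts@frameCycleTime,
             birthFrame = as.integer(first[keep]))
}

#' Empirical per-frame tracking loss from ground truth
#'
#' Follows each ground-truth molecule through the produced track fragments:
#' starting from the fragment containing the molecule's first detection, it
#' repeatedly jumps to the fragment containing the next detection after the
#' current fragment's end. Each jump before the end of the observation is one
#' loss event; every frame-to-frame transition in which the current fragment
#' could have been continued is one trial. Recovered gap frames stay inside a
#' fragment and are not counted as losses. Orphan fragments created by a
#' recovered loss are skipped by the walk.
#'
#' @param ts a [TrackSet-class] whose `tracks` retain `loc_id`.
#' @param trueId vector mapping input localization rows to ground-truth
#'   molecule ids (same order as the `locs` passed to the linker).
#' @return list with `losses`, `trials` and the per-frame loss `aHat`.
#' @export
empiricalLossPerFrame <- function(ts, trueId) {
  tr <- ts@tracks
  tid <- trueId[tr$loc_id]
  losses <- 0L; trials <- 0L
  lastFrameByTrack <- tapply(tr$frame, tr$track_id, max)
  for (mol in unique(tid)) {
    ix <- which(tid == mol)
    ix <- ix[order(tr$frame[ix])]
    fr <- tr$frame[ix]
    trk <- tr$track_id[ix]
    molEnd <- fr[length(fr)]
    cur <- trk[1]
    k <- 1L
    while (k <= length(ix)) {
      curEnd <- lastFrameByTrack[[as.character(cur)]]
      # transitions attributed to this fragment
      covered <- fr >= fr[k] & fr <= curEnd
      nxt <- which(fr > curEnd)
      if (!length(nxt)) {
        trials <- trials + sum(covered) - 1L
        break
      }
      # fragment ended before the molecule did: one loss
      trials <- trials + sum(covered)
      losses <- losses + 1L
      k <- nxt[1]
      cur <- trk[k]
    }
  }
  list(losses = losses, trials = trials,
       aHat = if (trials > 0) losses / trials else NA_real_)
}
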