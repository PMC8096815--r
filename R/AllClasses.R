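#' @import methods
NULL

#' Binding-state parameterization
#'
#' One kinetic state of a chromatin-binding molecule: its dissociation rate,
#' the probability that a newly bound molecule is in this state, and the
#' apparent diffusion coefficient while bound.
#'
#' @param dissociationRate dissociation rate constant in 1/s (> 0).
#' @param relativeFrequency probability that a binding event enters this state.
#' @param diffusionCoeff apparent diffusion coefficient while in this state,
#'   in um^2/s.
#' @return a `list` with class `"BindingState"`.
#' @export
bindingState <- function(dissociationRate, relativeFrequency, diffusionCoeff = 1e-3) {
  stopifnot(dissociationRate > 0, relativeFrequency >= 0, relativeFrequency <= 1,
            diffusionCoeff >= 0)
  structure(list(dissociationRate = dissociationRate,
                 relativeFrequency = relativeFrequency,
                 diffusionCoeff = diffusionCoeff),
            class = "BindingState")
}

#' SimScenario: full parameterization of a synthetic time-lapse experiment
#'
#' Holds everything needed to generate ground-truth trajectories and rendered
#' movies: the kinetic states, photobleaching probability per frame, the set
#' of time-lapse conditions, movie geometry and rendering parameters.
#'
#' @slot moleculesPerFrame target number of visible molecules per frame.
#' @slot states list of [bindingState()] objects; frequencies must sum to 1.
#' @slot bleachProbPerFrame probability per frame that the label bleaches.
#' @slot timelapseConditions frame-cycle times tau_tl in seconds.
#' @slot exposureTime camera exposure in seconds (informational; motion blur
#'   is not simulated).
#' @slot nFrames number of acquired frames per movie.
#' @slot frameSize movie width/height in pixels (square frames).
#' @slot psfWidth Gaussian PSF standard deviation in pixels.
#' @slot pixelSizeUm pixel size in micrometres.
#' @slot snr peak spot signal over background standard deviation.
#' @slot dBound apparent diffusion coefficient of bound molecules (um^2/s).
#' @slot dFree diffusion coefficient of freely diffusing molecules (um^2/s);
#'   used for the minimum bound-track-length rule.
#' @slot lognormalShape shape (sdlog) of the lognormal photon-count
#'   distribution of rendered spots.
#' @slot backgroundLevel mean camera background in counts.
#' @slot backgroundNoise half-width of the uniform background noise (counts).
#' @slot structureAmplitude standard deviation of the band-pass filtered
#'   background structure (counts).
#' @export
setClass("SimScenario",
  representation(moleculesPerFrame = "numeric", states = "list",
                 bleachProbPerFrame = "numeric", timelapseConditions = "numeric",
                 exposureTime = "numeric", nFrames = "integer",
                 frameSize = "integer", psfWidth = "numeric",
                 pixelSizeUm = "numeric", snr = "numeric",
                 dBound = "numeric", dFree = "numeric",
                 lognormalShape = "numeric", backgroundLevel = "numeric",
                 backgroundNoise = "numeric", structureAmplitude = "numeric"))

setValidity("SimScenario", function(object) {
  msg <- character()
  if (object@moleculesPerFrame <= 0) msg <- c(msg, "moleculesPerFrame must be > 0")
  if (length(object@states) == 0) msg <- c(msg, "at least one binding state required")
  fr <- vapply(object@states, `[[`, numeric(1), "relativeFrequency")
  if (abs(sum(fr) - 1) > 1e-9) msg <- c(msg, "state frequencies must sum to 1")
  if (any(object@timelapseConditions <= 0)) msg <- c(msg, "frame-cycle times must be > 0")
  if (object@bleachProbPerFrame < 0 || object@bleachProbPerFrame > 1)
    msg <- c(msg, "bleachProbPerFrame must be in [0, 1]")
  if (object@nFrames <= 0 || object@frameSize <= 0)
    msg <- c(msg, "nFrames and frameSize must be positive")
  if (object@psfWidth <= 0) msg <- c(msg, "psfWidth must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation scenario
#'
#' @param moleculesPerFrame,states,bleachProbPerFrame,timelapseConditions
#'   see the class documentation ([SimScenario-class]).
#' @param exposureTime,nFrames,frameSize,psfWidth,pixelSizeUm,snr,dBound,dFree
#'   movie geometry and rendering parameters.
#' @param lognormalShape,backgroundLevel,backgroundNoise,structureAmplitude
#'   rendering parameters with defaults; all configurable.
#' @return a [SimScenario-class] object.
#' @examples
#' sc <- simScenario(moleculesPerFrame = 5,
#'                   states = list(bindingState(0.2, 1)),
#'                   bleachProbPerFrame = 0.01,
#'                   timelapseConditions = c(0.05, 1))
#' @export
simScenario <- function(moleculesPerFrame, states, bleachProbPerFrame,
                        timelapseConditions, exposureTime = 0.05,
                        nFrames = 400L, frameSize = 100L, psfWidth = 1,
                        pixelSizeUm = 0.16, snr = 25, dBound = 1e-3,
                        dFree = 10, lognormalShape = 0.3,
                        backgroundLevel = 100, backgroundNoise = 17,
                        structureAmplitude = 2) {
  new("SimScenario", moleculesPerFrame = moleculesPerFrame, states = states,
      bleachProbPerFrame = bleachProbPerFrame,
      timelapseConditions = timelapseConditions, exposureTime = exposureTime,
      nFrames = as.integer(nFrames), frameSize = as.integer(frameSize),
      psfWidth = psfWidth, pixelSizeUm = pixelSizeUm, snr = snr,
      dBound = dBound, dFree = dFree, lognormalShape = lognormalShape,
      backgroundLevel = backgroundLevel, backgroundNoise = backgroundNoise,
      structureAmplitude = structureAmplitude)
}

#' Standard simulated study scenarios
#'
#' Returns the parameterizations used throughout the validation simulations:
#' scenario 1 is a single immortal, non-bleaching immobile molecule (loss-curve
#' validation); scenarios 2 and 3 are five-state binding kinetics with
#' photobleaching at low and variable density, respectively.
#'
#' @param i scenario number (1, 2 or 3).
#' @param moleculesPerFrame override for the molecule count (used for the
#'   density scan of scenario 3; default 50).
#' @return a [SimScenario-class] object.
#' @export
tableScenario <- function(i, moleculesPerFrame = NULL) {
  fiveStates <- list(
    bindingState(3e-3, 0.03), bindingState(2e-2, 0.06),
    bindingState(0.2, 0.130), bindingState(1.3, 0.26), bindingState(10, 0.52))
  sc <- switch(as.character(i),
    "1" = simScenario(1, list(bindingState(1e-15, 1)), 0,
                      c(0.05, 1, 5), nFrames = 500L),
    "2" = simScenario(5, fiveStates, 0.01, c(0.05, 0.3, 1.5, 5), nFrames = 400L),
    "3" = simScenario(if (is.null(moleculesPerFrame)) 50 else moleculesPerFrame,
                      fiveStates, 0.01, c(0.05, 0.3, 1.5, 5), nFrames = 400L),
    stop("unknown scenario: ", i))
  sc
}

setMethod("show", "SimScenario", function(object) {
  cat("SimScenario:", object@moleculesPerFrame, "molecules/frame,",
      length(object@states), "state(s)\n")
  cat("  rates (1/s): ",
      paste(signif(vapply(object@states, `[[`, numeric(1), "dissociationRate"), 3),
            collapse = ", "), "\n", sep = "")
  cat("  bleach/frame:", object@bleachProbPerFrame,
      " tau_tl (s):", paste(object@timelapseConditions, collapse = ", "), "\n")
  cat("  ", object@nFrames, " frames of ", object@frameSize, "x",
      object@frameSize, " px (", object@pixelSizeUm, " um/px), SNR ",
      object@snr, "\n", sep = "")
})

#' SyntheticMovie: rendered frames plus ground truth
#'
#' @slot stack numeric array H x W x nFrames of non-negative counts.
#' @slot frameCycleTime frame-cycle time tau_tl in seconds.
#' @slot groundTruth data.frame of per-frame true molecule positions
#'   (columns id, frame, t, x, y, state).
#' @slot pixelSizeUm pixel size in micrometres.
#' @export
setClass("SyntheticMovie",
  representation(stack = "array", frameCycleTime = "numeric",
                 groundTruth = "data.frame", pixelSizeUm = "numeric"))

setValidity("SyntheticMovie", function(object) {
  if (length(dim(object@stack)) != 3) return("stack must be H x W x nFrames")
  if (any(object@stack < 0)) return("pixel values must be >= 0")
  TRUE
})

setMethod("show", "SyntheticMovie", function(object) {
  d <- dim(object@stack)
  cat("SyntheticMovie: ", d[3], " frames of ", d[1], "x", d[2],
      " px, tau_tl = ", object@frameCycleTime, " s, ",
      length(unique(object@groundTruth$id)), " ground-truth molecules\n", sep = "")
})

#' Tracking parameters
#'
#' @param trackingRadius maximum linking distance in micrometres.
#' @param maxGapFrames 0 (no bridging) or 1 (bridge a single missed frame).
#' @param minFramesBeforeGap detections a track needs before it may bridge a
#'   gap (default 2).
#' @param minTrackLengthBound minimum number of frames spanned for a track to
#'   enter the bound/survival analysis.
#' @return a `list` with class `"TrackingParams"`.
#' @export
trackingParams <- function(trackingRadius, maxGapFrames = 1L,
                           minFramesBeforeGap = 2L, minTrackLengthBound = 2L) {
  stopifnot(trackingRadius > 0, maxGapFrames %in% c(0L, 1L),
            minFramesBeforeGap >= 1, minTrackLengthBound >= 1)
  structure(list(trackingRadius = trackingRadius,
                 maxGapFrames = as.integer(maxGapFrames),
                 minFramesBeforeGap = as.integer(minFramesBeforeGap),
                 minTrackLengthBound = as.integer(minTrackLengthBound)),
            class = "TrackingParams")
}

#' TrackSet: linked single-molecule tracks
#'
#' The central container for linking results. `tracks` has one row per
#' localization with columns `track_id`, `frame` (1-based), `x`, `y`
#' (micrometres), `gap` (TRUE when the link to the previous detection bridged
#' one missed frame) and `loc_id` (row index into the input localization
#' table, so external annotations can be joined back).
#'
#' @slot tracks data.frame as described above.
#' @slot params `TrackingParams` list used to produce the tracks.
#' @slot frameCycleTime frame-cycle time tau_tl in seconds.
#' @slot source identifier of the source movie (may be "").
#' @export
setClass("TrackSet",
  representation(tracks = "data.frame", params = "list",
                 frameCycleTime = "numeric", source = "character"))

setValidity("TrackSet", function(object) {
  tr <- object@tracks
  need <- c("track_id", "frame", "x", "y", "gap")
  if (!all(need %in% names(tr))) return("tracks must have track_id, frame, x, y, gap")
  if (nrow(tr) && anyDuplicated(tr[c("track_id", "frame")]))
    return("a track may contain at most one localization per frame")
  if (object@frameCycleTime <= 0) return("frameCycleTime must be > 0")
  TRUE
})

#' @describeIn TrackSet-class number of tracks.
#' @param x,object a `TrackSet`.
#' @export
setMethod("length", "TrackSet", function(x) length(unique(x@tracks$track_id)))

#' Accessors for TrackSet
#'
#' `tracks()` returns the per-localization data.frame, `trackingRadius()` the
#' linking radius in micrometres and `frameCycleTime()` the frame-cycle time
#' in seconds.
#'
#' @param x a [TrackSet-class].
#' @return see description.
#' @export
tracks <- function(x) x@tracks

#' @rdname tracks
#' @export
trackingRadius <- function(x) x@params$trackingRadius

#' @rdname tracks
#' @export
frameCycleTime <- function(x) x@frameCycleTime

setMethod("show", "TrackSet", function(object) {
  cat("TrackSet: ", length(object), " tracks, ", nrow(object@tracks),
      " localizations, tau_tl = ", object@frameCycleTime,
      " s, radius = ", object@params$trackingRadius, " um\n", sep = "")
})

#' RateSpectrum: weights on a grid of dissociation rates
#'
#' Result of the global inverse-Laplace fit of survival-time distributions.
#' Weights are non-negative and sum to one; `perFrameLoss` is the shared
#' per-frame loss probability (photobleaching plus tracking loss) recovered by
#' the fit. `resamples` optionally holds one resampled spectrum per row.
#'
#' @slot rates strictly increasing rate grid in 1/s.
#' @slot weights non-negative weights summing to 1.
#' @slot perFrameLoss fitted combined per-frame loss probability.
#' @slot resamples matrix (nResamples x nRates) of resampled weight vectors.
#' @slot residual final residual sum of squares of the fit.
#' @export
setClass("RateSpectrum",
  representation(rates = "numeric", weights = "numeric",
                 perFrameLoss = "numeric", resamples = "matrix",
                 residual = "numeric"))

setValidity("RateSpectrum", function(object) {
  if (is.unsorted(object@rates, strictly = TRUE)) return("rates must be strictly increasing")
  if (any(object@weights < -1e-12)) return("weights must be non-negative")
  if (abs(sum(object@weights) - 1) > 1e-6) return("weights must sum to 1")
  if (object@perFrameLoss < 0 || object@perFrameLoss > 1)
    return("perFrameLoss must be in [0, 1]")
  TRUE
})

#' Accessors for RateSpectrum
#' @param x a [RateSpectrum-class].
#' @return numeric vector / scalar.
#' @export
rates <- function(x) x@rates

#' @rdname rates
#' @export
spectrumWeights <- function(x) x@weights

#' @rdname rates
#' @export
perFrameLoss <- function(x) x@perFrameLoss

setMethod("show", "RateSpectrum", function(object) {
  nz <- which(object@weights > 1e-6)
  cat("RateSpectrum: ", length(object@rates), " grid points, per-frame loss ",
      signif(object@perFrameLoss, 3), "\n", sep = "")
  if (length(nz)) {
    cat("  non-zero weights:\n")
    for (i in nz)
      cat(sprintf("    %10.3g 1/s  %6.2f%%\n", object@rates[i],
                  100 * object@weights[i]))
  }
})
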