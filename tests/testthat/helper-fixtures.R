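# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no stored data.

# a single-frame ground-truth table usable by renderMovie()
spotFrameTraj <- function(xUm, yUm, tau = 0.05) {
  n <- length(xUm)
  traj <- data.frame(id = seq_len(n), frame = rep(1L, n), t = rep(0, n),
                     x = xUm, y = yUm, state = rep(1L, n))
  attr(traj, "tau") <- tau
  traj
}

# scenario for rendering isolated test frames
renderScenario <- function(frameSize = 40L, nFrames = 1L, snr = 25) {
  simScenario(1, list(bindingState(1e-15, 1)), 0, 0.05, nFrames = nFrames,
              frameSize = frameSize, snr = snr)
}

# an immobile noiseless track data.frame
immobileTrack <- function(nFrames, x = 1, y = 1, startFrame = 1L) {
  data.frame(track_id = 1L, frame = startFrame + seq_len(nFrames) - 1L,
             x = x, y = y, gap = FALSE, loc_id = seq_len(nFrames))
}

# wrap a tracks data.frame into a TrackSet
asTrackSet <- function(tr, radius = 1, tau = 1, gap = 1L) {
  methods::new("TrackSet", tracks = tr,
               params = unclass(trackingParams(radius, maxGapFrames = gap)),
               frameCycleTime = tau, source = "")
}

# Brownian track with localization noise, in um
brownianTrack <- function(nFrames, D, tau, sigma0 = 0, x0 = 0, y0 = 0) {
  sdJ <- sqrt(2 * D * tau)
  x <- x0 + cumsum(c(0, rnorm(nFrames - 1, 0, sdJ)))
  y <- y0 + cumsum(c(0, rnorm(nFrames - 1, 0, sdJ)))
  if (sigma0 > 0) {
    x <- x + rnorm(nFrames, 0, sigma0 / 2)
    y <- y + rnorm(nFrames, 0, sigma0 / 2)
  }
  data.frame(track_id = 1L, frame = seq_len(nFrames), x = x, y = y,
             gap = FALSE, loc_id = seq_len(nFrames))
}

# durations (in seconds) drawn from the survival model
# S(n frames) = sum_k w_k (exp(-k tau) (1-a))^(n-1), returned as a sample of
# exact expected counts (noise-free), for estimator tests
modelDurations <- function(rates, weights, a, tau, nFramesMax = 400L,
                           nTracks = 1e5) {
  n <- seq_len(nFramesMax)
  S <- vapply(n, function(j)
    sum(weights * exp(-rates * tau * (j - 1)) * (1 - a)^(j - 1)), numeric(1))
  cnt <- round(nTracks * S)
  pmfc <- -diff(c(cnt, 0))
  keep <- pmfc > 0
  rep((n[keep] - 1) * tau, times = pmfc[keep])
}
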