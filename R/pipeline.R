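# End-to-end coordinate-level validation pipelines: simulate a scenario,
# calibrate tracking radii for a target loss, track, and infer the
# dissociation-rate spectrum.

#' Simulate coordinate-level localizations for every time-lapse condition
#'
#' Runs the Gillespie trajectory simulator for each condition of a scenario
#' and converts ground truth to detected localizations with localization
#' noise, bypassing rendering.
#'
#' @param scenario a [SimScenario-class].
#' @param sigma0 localization error in um. The default 0.010 um is the
#'   localization error the package's own detector delivers at the standard
#'   rendering conditions (SNR 25, 1 px PSF, 0.16 um pixels), so
#'   coordinate-level studies emulate what rendered-and-fitted movies give.
#' @param nMovies independent movies per condition (default 1).
#' @param seed base seed; per-movie seeds are derived deterministically.
#' @return list with one element per condition: `tau`, `movies` (list of
#'   localization data.frames with `frame`, `x`, `y`, `true_id`, `state`).
#' @export
simulateStudy <- function(scenario, sigma0 = 0.010, nMovies = 1L, seed = 1) {
  lapply(seq_along(scenario@timelapseConditions), function(ci) {
    movies <- lapply(seq_len(nMovies), function(m) {
      sd1 <- subSeed(seed, ci * 1000 + m)
      traj <- simulateTrajectories(scenario, ci, seed = sd1)
      detectedLocalizations(traj, sigma0 = sigma0, seed = subSeed(sd1, 7))
    })
    list(tau = scenario@timelapseConditions[ci], movies = movies)
  })
}

#' Calibrate, track and collect survival times for one simulated study
#'
#' For each time-lapse condition the tracking radius is calibrated to the
#' target per-frame loss with [radiusForLoss()] (using the first movie),
#' all movies are tracked with the calibrated radius (one gap frame
#' allowed), and track durations of tracks spanning at least the
#' condition's minimum bound-track length are collected.
#'
#' @param study output of [simulateStudy()].
#' @param scenario the [SimScenario-class] that produced it.
#' @param targetLoss desired per-frame tracking loss (default 0.01).
#' @param sigma0 localization error in um used for the simulation.
#' @param onUnreachable passed to [radiusForLoss()] (default "min-loss" so
#'   density scans proceed past the erroneous-link floor).
#' @return list per condition: `tau`, `calibration`, `tracksets`,
#'   `durations` (s), `minFrames`.
#' @export
calibrateAndTrack <- function(study, scenario, targetLoss = 0.01,
                              sigma0 = 0.010, onUnreachable = "min-loss") {
  area <- (scenario@frameSize * scenario@pixelSizeUm)^2
  nF <- scenario@nFrames
  lapply(study, function(cond) {
    # calibrate on all movies, concatenated with frame offsets so the
    # empirical sigma^2(s_i) re-tracking sees the full data set
    calLocs <- do.call(rbind, lapply(seq_along(cond$movies), function(m) {
      lc <- cond$movies[[m]]
      lc$frame <- lc$frame + (m - 1L) * (nF + 1L)
      lc
    }))
    cal <- radiusForLoss(calLocs, cond$tau, targetLoss, area,
                         sigma0Sq = sigma0^2, dFree = scenario@dFree,
                         onUnreachable = onUnreachable)
    params <- trackingParams(cal$s, maxGapFrames = 1L, minFramesBeforeGap = 2L,
                             minTrackLengthBound = cal$nMinBound)
    tss <- lapply(cond$movies, nearestNeighbourLink, params = params,
                  frameCycleTime = cond$tau)
    dt <- do.call(rbind, lapply(tss, trackDurationTable,
                                minFrames = cal$nMinBound))
    list(tau = cond$tau, calibration = cal, tracksets = tss,
         durations = dt$duration, birthFrames = dt$birthFrame,
         minFrames = cal$nMinBound)
  })
}

#' Dissociation-rate spectrum of a simulated scenario
#'
#' Convenience pipeline: simulate all conditions at coordinate level,
#' calibrate tracking radii for the target loss, track, build survival
#' distributions and fit the global rate spectrum.
#'
#' @inheritParams simulateStudy
#' @inheritParams calibrateAndTrack
#' @param rateGrid rate grid for [gridSpectrum()].
#' @return list `spectrum` ([RateSpectrum-class]), `conditions` (the
#'   [calibrateAndTrack()] output), `survivals`.
#' @export
scenarioSpectrum <- function(scenario, targetLoss = 0.01, sigma0 = 0.010,
                             nMovies = 1L, seed = 1,
                             rateGrid = defaultRateGrid()) {
  study <- simulateStudy(scenario, sigma0, nMovies, seed)
  conds <- calibrateAndTrack(study, scenario, targetLoss, sigma0)
  durs <- lapply(conds, `[[`, "durations")
  taus <- vapply(conds, `[[`, numeric(1), "tau")
  minF <- vapply(conds, `[[`, integer(1), "minFrames")
  sv <- buildSurvival(durs, taus, minF, nFramesMovie = scenario@nFrames,
                      birthFrames = lapply(conds, `[[`, "birthFrames"))
  list(spectrum = gridSpectrum(sv, rateGrid), conditions = conds,
       survivals = sv)
}

#' Density limit of rate-spectrum recovery
#'
#' Scans the simulated spot density and reports, for each density, whether
#' all ground-truth dissociation-rate clusters are recovered (cluster mode
#' within half a decade of the true rate), and the largest density at which
#' they all are.
#'
#' @param densities spot densities in spots per pixel (default 0.0005 to
#'   0.005 in 0.0005 steps).
#' @param targetLoss calibrated per-frame tracking loss (default 0.01).
#' @param sigma0 localization error in um.
#' @param nMoviesRef movies per condition at the reference density 0.0025;
#'   other densities use movies proportional to 1/density (floor 2) so
#'   every scan point carries comparable track statistics.
#' @param seed base seed.
#' @param tolDecades cluster acceptance half-width in decades.
#' @return list `table` (data.frame density, nMovies, nRecovered,
#'   allRecovered), `maxDensity` (largest density with all clusters
#'   recovered, NA if none).
#' @export
densityLimitScan <- function(densities = seq(5e-4, 5e-3, by = 5e-4),
                             targetLoss = 0.01, sigma0 = 0.010,
                             nMoviesRef = 4L, seed = 1, tolDecades = 0.5) {
  trueRates <- c(3e-3, 2e-2, 0.2, 1.3, 10)
  rows <- lapply(seq_along(densities), function(i) {
    dens <- densities[i]
    nm <- max(2L, as.integer(round(nMoviesRef * 0.0025 / dens)))
    sc <- tableScenario(3, moleculesPerFrame = dens * 100^2)
    res <- scenarioSpectrum(sc, targetLoss, sigma0, nm,
                            seed = subSeed(seed, i))
    rec <- recoveredRates(res$spectrum, trueRates, tolDecades)
    data.frame(density = dens, nMovies = nm, nRecovered = sum(rec),
               allRecovered = all(rec))
  })
  tab <- do.call(rbind, rows)
  ok <- tab$density[tab$allRecovered]
  list(table = tab, maxDensity = if (length(ok)) max(ok) else NA_real_)
}
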