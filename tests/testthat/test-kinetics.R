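# Survival distributions, the global rate-spectrum fit, resampling, cluster
# weights and ITM bound fractions.

test_that("survival counting is a right-continuous counting function", {
  sv <- buildSurvival(list(c(1, 1, 2, 5)), taus = 1)[[1]]
  expect_identical(sv$t, c(1, 2, 5))
  expect_identical(sv$n, c(4L, 2L, 1L))
  expect_identical(sv$nTracks, 4L)
  # empty condition kept and flagged
  sv2 <- buildSurvival(list(numeric(0), 3), taus = c(1, 2))
  expect_identical(sv2[[1]]$nTracks, 0L)
  expect_identical(sv2[[2]]$nTracks, 1L)
})

test_that("exponential survival has the right log-slope", {
  set.seed(1)
  k <- 0.2; tau <- 0.5
  durations <- (rgeom(1e4, 1 - exp(-k * tau))) * tau
  sv <- buildSurvival(list(durations), taus = tau)[[1]]
  keep <- sv$n >= 30
  fit <- lm(log(sv$n[keep]) ~ sv$t[keep])
  expect_lt(abs(-coef(fit)[2] - k) / k, 0.10)
})

test_that("the global fit inverts model-generated survivals", {
  rates <- c(0.02, 1.5)
  wts <- c(0.35, 0.65)
  a <- 0.015
  taus <- c(0.05, 0.5, 2)
  durs <- lapply(taus, function(tau)
    modelDurations(rates, wts, a, tau, nTracks = 2e5))
  sp <- gridSpectrum(buildSurvival(durs, taus))
  expect_lt(abs(perFrameLoss(sp) - a), 0.004)
  rec <- recoveredRates(sp, rates, tolDecades = 0.25)
  expect_true(all(rec))
  cw <- clusterWeights(sp, list(c(0.02 / 3, 0.02 * 3), c(0.5, 4.5)))
  expect_lt(abs(cw[1] - 35), 6)
  expect_lt(abs(cw[2] - 65), 6)
  # weights are non-negative and normalized
  expect_true(all(spectrumWeights(sp) >= 0))
  expect_equal(sum(spectrumWeights(sp)), 1)
})

test_that("refitting a spectrum-regenerated single-rate input is a fixed point", {
  k <- 0.2; a <- 0.01
  taus <- c(0.1, 1)
  durs <- lapply(taus, function(tau) modelDurations(k, 1, a, tau))
  # the ridge deliberately spreads mass over near-duplicate columns, so the
  # exact fixed-point property is assessed with the plain objective
  sp1 <- gridSpectrum(buildSurvival(durs, taus), ridge = 0)
  # regenerate survivals from the fitted spectrum and refit
  nz <- spectrumWeights(sp1) > 1e-8
  durs2 <- lapply(taus, function(tau)
    modelDurations(rates(sp1)[nz], spectrumWeights(sp1)[nz],
                   perFrameLoss(sp1), tau))
  sp2 <- gridSpectrum(buildSurvival(durs2, taus), ridge = 0)
  expect_lt(sum(abs(spectrumWeights(sp2) - spectrumWeights(sp1))), 0.02)
  expect_lt(abs(perFrameLoss(sp2) - perFrameLoss(sp1)), 1e-3)
})

test_that("resampling is deterministic, sized and stable", {
  k <- 0.5; a <- 0.02
  taus <- c(0.1, 1)
  durs <- lapply(taus, function(tau)
    modelDurations(k, 1, a, tau, nTracks = 3000))
  # no resamples: empty envelope
  sp0 <- resampleSpectrum(durs, taus, nResamples = 0L)
  expect_identical(nrow(sp0@resamples), 0L)
  spA <- resampleSpectrum(durs, taus, nResamples = 25L, seed = 7)
  spB <- resampleSpectrum(durs, taus, nResamples = 25L, seed = 7)
  expect_identical(spA@resamples, spB@resamples)
  expect_identical(nrow(spA@resamples), 25L)
  # every resampled spectrum is a normalized non-negative weight vector
  expect_true(all(spA@resamples >= 0))
  expect_equal(unname(rowSums(spA@resamples)), rep(1, 25))
  # median resampled spectrum close to the full-data spectrum
  med <- apply(spA@resamples, 2, median)
  expect_lt(0.5 * sum(abs(med / sum(med) - spectrumWeights(spA))), 0.1)
})

test_that("cluster weights integrate to 100% and vanish on empty intervals", {
  durs <- lapply(c(0.1, 1), function(tau) modelDurations(0.5, 1, 0.02, tau))
  sp <- gridSpectrum(buildSurvival(durs, c(0.1, 1)))
  expect_equal(unname(clusterWeights(sp, list(c(1e-5, 1e3)))), 100)
  expect_identical(unname(clusterWeights(sp, list(c(50, 60)))), 0)
})

test_that("ITM bound fractions follow the counting definitions", {
  # construct tracks: 10 long bound (survive a dark period = appear in two
  # bursts), 30 short bound (two frames within a burst), 60 single
  mkTracks <- function(nLong, nShort, nSingle) {
    rows <- list(); id <- 0L
    for (i in seq_len(nLong)) {
      id <- id + 1L
      rows[[length(rows) + 1L]] <- data.frame(track_id = id,
                                              frame = c(1L, 2L, 3L),
                                              x = i, y = 0, gap = FALSE)
    }
    for (i in seq_len(nShort)) {
      id <- id + 1L
      rows[[length(rows) + 1L]] <- data.frame(track_id = id, frame = c(1L, 2L),
                                              x = 10 + i, y = 5, gap = FALSE)
    }
    for (i in seq_len(nSingle)) {
      id <- id + 1L
      rows[[length(rows) + 1L]] <- data.frame(track_id = id, frame = 1L,
                                              x = 50 + i, y = 9, gap = FALSE)
    }
    tr <- do.call(rbind, rows)
    tr$loc_id <- seq_len(nrow(tr))
    asTrackSet(tr)
  }
  res <- itmBoundFractions(list(mkTracks(10, 30, 60)))
  expect_equal(unname(res$pooled["bf"]), 0.4)
  expect_equal(unname(res$pooled["bfLong"]), 0.25)
  # all single detections: bound fraction zero
  res0 <- itmBoundFractions(list(mkTracks(0, 0, 20)))
  expect_equal(unname(res0$pooled["bf"]), 0)
})

test_that("ITM classification recovers a known long-bound fraction", {
  # molecules bound long (survive the dark period) vs short with known mix
  set.seed(2)
  pLong <- 0.3
  nMol <- 800
  rows <- list()
  for (i in seq_len(nMol)) {
    long <- runif(1) < pLong
    fr <- if (long) c(1L, 2L, 3L) else c(1L, 2L)
    rows[[i]] <- data.frame(track_id = i, frame = fr, x = 100 * runif(1),
                            y = 100 * runif(1), gap = FALSE)
  }
  tr <- do.call(rbind, rows)
  tr$loc_id <- seq_len(nrow(tr))
  res <- itmBoundFractions(list(asTrackSet(tr)))
  se <- sqrt(pLong * (1 - pLong) / nMol)
  expect_lt(abs(res$pooled["bfLong"] - pLong), 3 * se)
})
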