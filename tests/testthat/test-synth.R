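# Gillespie event stream, trajectory simulation and movie rendering.

test_that("Gillespie waiting times are exponential with the total rate", {
  k <- 10
  ev <- gillespieEventTimes(list(bindingState(k, 1)), bleachRate = 0,
                            tMax = 1200, seed = 1)
  waits <- diff(c(0, ev$time))
  n <- length(waits)
  expect_gt(n, 5e3)
  # mean waiting time = 1/k within 3 s.e.m.
  expect_lt(abs(mean(waits) - 1 / k), 3 * sd(waits) / sqrt(n))
  # full-distribution check against Exp(k)
  ks <- suppressWarnings(ks.test(waits, "pexp", k))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(diff(ev$time) > 0))
})

test_that("per-frame bleaching probability is reproduced by the converted rate", {
  a <- 0.01; tau <- 1
  rate <- bleachRateFromProb(a, tau)
  expect_equal(exp(-rate * tau), 1 - a)
  n <- 1e4
  set.seed(2)
  bleachedWithinFrame <- rexp(n, rate) < tau
  se <- sqrt(a * (1 - a) / n)
  expect_lt(abs(mean(bleachedWithinFrame) - a), 3 * se)
})

test_that("event kinds are drawn proportionally to the individual rates", {
  ev <- gillespieEventTimes(list(bindingState(3, 1)), bleachRate = 1,
                            tMax = 2500, seed = 3)
  pDiss <- mean(ev$kind == "dissociation")
  se <- sqrt(0.75 * 0.25 / nrow(ev))
  expect_lt(abs(pDiss - 0.75), 3 * se)
})

test_that("all rates zero is an error", {
  expect_error(gillespieEventTimes(list(structure(list(dissociationRate = 0,
                                                       relativeFrequency = 1,
                                                       diffusionCoeff = 0),
                                                  class = "BindingState")),
                                   bleachRate = 0, tMax = 1, seed = 1),
               "no events possible")
})

test_that("the immortal-molecule scenario produces no events over the movie", {
  # dissociation and bleach rates of 1e-15/s: probability of any event in
  # 500 frames x 5 s is ~2.5e-12
  sc1 <- tableScenario(1)
  expect_equal(sc1@bleachProbPerFrame, 0)
  nEvents <- 0L
  for (s in 1:50) {
    traj <- simulateTrajectories(sc1, 3, seed = s)
    nEvents <- nEvents + (length(unique(traj$id)) - 1L)
  }
  expect_identical(nEvents, 0L)
})

test_that("zero diffusion keeps positions identical across frames", {
  sc <- simScenario(3, list(bindingState(1e-15, 1, diffusionCoeff = 0)), 0,
                    1, nFrames = 20L)
  traj <- simulateTrajectories(sc, 1, seed = 4)
  for (id in unique(traj$id)) {
    sub <- traj[traj$id == id, ]
    expect_equal(diff(range(sub$x)), 0)
    expect_equal(diff(range(sub$y)), 0)
  }
})

test_that("frame-to-frame jump variance is 4 D tau and scales linearly in tau", {
  sc2 <- tableScenario(2)
  D <- sc2@dBound
  msdOverTau <- vapply(c(1L, 3L), function(ci) {
    # conditions 0.05 s and 5 s of a dedicated scenario
    sc <- simScenario(60, list(bindingState(1e-15, 1)), 0, c(0.05, 1, 5),
                      nFrames = 200L)
    traj <- simulateTrajectories(sc, ci, seed = 10 + ci)
    jumps2 <- unlist(lapply(split(traj[c("x", "y")], traj$id), function(s)
      diff(s$x)^2 + diff(s$y)^2))
    mean(jumps2) / sc@timelapseConditions[ci]
  }, numeric(1))
  # both estimates of 4D agree with truth within 5%
  expect_lt(abs(msdOverTau[1] - 4 * D) / (4 * D), 0.05)
  expect_lt(abs(msdOverTau[2] - 4 * D) / (4 * D), 0.05)
})

test_that("state at birth follows the relative frequencies (Table scenario 2)", {
  sc2 <- tableScenario(2)
  freqs <- vapply(sc2@states, `[[`, numeric(1), "relativeFrequency")
  births <- integer(0)
  for (s in 1:6) {
    traj <- simulateTrajectories(sc2, 2, seed = 40 + s)
    births <- c(births, attr(traj, "meta")$state)
  }
  n <- length(births)
  expect_gt(n, 1e3)
  for (k in seq_along(freqs)) {
    p <- mean(births == k)
    se <- sqrt(freqs[k] * (1 - freqs[k]) / n)
    expect_lt(abs(p - freqs[k]), 3 * se + 1e-9)
  }
})

test_that("empty states list errors and molecule count stays constant", {
  sc <- tableScenario(2)
  sc@states <- list()
  expect_error(simulateTrajectories(sc, 1, seed = 1))
  sc2 <- tableScenario(2)
  traj <- simulateTrajectories(sc2, 4, seed = 6)
  perFrame <- table(traj$frame)
  expect_true(all(perFrame == sc2@moleculesPerFrame))
})

test_that("rendering an empty scene yields pure background with ~0 detections", {
  sc <- renderScenario(frameSize = 100L)
  traj <- spotFrameTraj(numeric(0), numeric(0))
  mov <- renderMovie(traj, sc, seed = 7)
  img <- mov@stack[, , 1]
  expect_true(all(img >= 0))
  filt <- waveletFilter(img)
  cand <- detectCandidates(filt, suggestThreshold(filt))
  expect_lte(nrow(cand), 2)
})

test_that("a rendered immobile molecule peaks at its position", {
  sc <- renderScenario(frameSize = 100L)
  mov <- renderMovie(spotFrameTraj(0.16 * 50, 0.16 * 50), sc, seed = 8)
  wm <- which(mov@stack[, , 1] == max(mov@stack[, , 1]), arr.ind = TRUE)
  expect_lte(abs(wm[1, 1] - 1L - 50), 1)   # row (y), 0-based
  expect_lte(abs(wm[1, 2] - 1L - 50), 1)   # col (x)
})

test_that("scenario-1 rendering matches the declared geometry", {
  sc1 <- tableScenario(1)
  traj <- simulateTrajectories(sc1, 1, seed = 9)
  mov <- renderMovie(traj, sc1, seed = 9)
  expect_identical(dim(mov@stack), c(100L, 100L, 500L))
  expect_equal(mov@pixelSizeUm, 0.16)
})

test_that("rendering is deterministic given trajectories and seed", {
  sc <- renderScenario()
  traj <- spotFrameTraj(0.16 * c(10, 25), 0.16 * c(12, 30))
  m1 <- renderMovie(traj, sc, seed = 11)
  m2 <- renderMovie(traj, sc, seed = 11)
  expect_identical(m1@stack, m2@stack)
  m3 <- renderMovie(traj, sc, seed = 12)
  expect_false(identical(m1@stack, m3@stack))
})

test_that("detected localizations carry the configured error variance", {
  sc <- simScenario(50, list(bindingState(1e-15, 1, diffusionCoeff = 0)), 0,
                    1, nFrames = 400L)
  traj <- simulateTrajectories(sc, 1, seed = 13)
  sigma0 <- 0.04
  locs <- detectedLocalizations(traj, sigma0 = sigma0, seed = 14)
  # squared jump of an immobile molecule = sum of two localization errors
  jumps2 <- unlist(lapply(split(locs[c("x", "y")], locs$true_id), function(s)
    diff(s$x)^2 + diff(s$y)^2))
  expect_lt(abs(mean(jumps2) - sigma0^2) / sigma0^2,
            3 * sqrt(2 / length(jumps2)))
})
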