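# Jump histograms, cumulative diffusion fits, confinement, angles, maps and
# intensity traces.

test_that("jump histograms conserve counts and respect the per-track limit", {
  tr <- immobileTrack(10)
  h <- jumpHistogram(asTrackSet(tr), binWidth = 0.05)
  expect_identical(sum(h$counts), 9L)
  expect_identical(h$counts[1], 9L)   # all jumps in the first bin
  # two tracks, limit one jump per track
  tr2 <- rbind(tr, transform(immobileTrack(6, x = 5), track_id = 2L))
  h2 <- jumpHistogram(asTrackSet(tr2), binWidth = 0.05, jumpsPerTrack = 1)
  expect_identical(sum(h2$counts), 2L)
  # jumps across gap frames are omitted
  trG <- data.frame(track_id = 1L, frame = c(1, 2, 4), x = c(0, 0.1, 0.2),
                    y = 0, gap = c(FALSE, FALSE, TRUE), loc_id = 1:3)
  hG <- jumpHistogram(asTrackSet(trG), binWidth = 0.05)
  expect_identical(sum(hG$counts), 1L)
})

test_that("the jump-distance mode matches the Rayleigh prediction", {
  set.seed(1)
  D <- 1; tau <- 0.05
  tr <- brownianTrack(20000, D, tau)
  h <- jumpHistogram(asTrackSet(tr, tau = tau), binWidth = 0.04)
  mode <- h$breaks[which.max(h$counts)] + 0.02
  expect_lt(abs(mode - sqrt(2 * D * tau)), 0.06)   # within 1.5 bins
})

test_that("single-population diffusion is recovered within 10%", {
  set.seed(2)
  D <- 0.5; tau <- 0.05
  C2 <- 1.5
  X <- rexp(1e4, 1 / D)
  X <- X[X < C2][1:8000]
  fit <- fitCumulativeJumps(nComponents = 2L, tau = tau, C2 = C2,
                            jumpsSq = X * 4 * tau)
  Dhat <- fit$diffusionCoeffs[which.max(fit$amplitudes)]
  expect_lt(abs(Dhat - D) / D, 0.10)
  expect_gt(fit$adjR2, 0.99)
})

test_that("two-population mixtures recover D and A with the truncation term", {
  set.seed(3)
  tau <- 0.05
  D1 <- 0.01; D2 <- 1.0; A1 <- 0.4
  s <- 0.7
  C2 <- s^2 / (4 * tau)
  n <- 1e4
  comp <- runif(n) < A1
  X <- ifelse(comp, rexp(n, 1 / D1), rexp(n, 1 / D2))
  X <- X[X < C2]
  fit <- fitCumulativeJumps(nComponents = 2L, tau = tau, C2 = C2,
                            jumpsSq = X * 4 * tau)
  expect_lt(abs(fit$diffusionCoeffs[1] - D1) / D1, 0.15)
  expect_lt(abs(fit$diffusionCoeffs[2] - D2) / D2, 0.15)
  # the truncated-and-refit amplitude refers to jumps below C2; convert the
  # simulated truth accordingly
  A1trunc <- A1 / (A1 + (1 - A1) * (1 - exp(-C2 / D2)))
  expect_lt(abs(fit$amplitudes[1] - A1trunc), 0.05)
  # omitting the truncation term inflates the fast coefficient
  fitNo <- fitCumulativeJumps(nComponents = 2L, tau = tau, C2 = Inf,
                              jumpsSq = X * 4 * tau)
  expect_lt(fitNo$diffusionCoeffs[2], D2)  # censored tail biases D down
})

test_that("the truncation normalization reduces to the plain mixture as C2 grows", {
  set.seed(4)
  X <- rexp(5000, 1)
  f1 <- fitCumulativeJumps(nComponents = 2L, tau = 0.05, C2 = 1e6,
                           jumpsSq = X * 0.2)
  f2 <- fitCumulativeJumps(nComponents = 2L, tau = 0.05, C2 = Inf,
                           jumpsSq = X * 0.2)
  expect_lt(abs(f1$diffusionCoeffs[2] - f2$diffusionCoeffs[2]) /
              f2$diffusionCoeffs[2], 0.01)
})

test_that("confined tracks yield the disc radius; free tracks are rejected", {
  # reflected Brownian motion in a disc of radius R
  R <- 0.2
  set.seed(5)
  simDisc <- function(n, D, tau) {
    x <- 0; y <- 0
    xs <- numeric(n); ys <- numeric(n)
    sub <- 20                      # fine steps per frame for the reflection
    sd_ <- sqrt(2 * D * tau / sub)
    for (i in seq_len(n)) {
      for (k in seq_len(sub)) {
        x <- x + rnorm(1, 0, sd_); y <- y + rnorm(1, 0, sd_)
        r <- sqrt(x^2 + y^2)
        if (r > R) { x <- x * (2 * R - r) / r; y <- y * (2 * R - r) / r }
      }
      xs[i] <- x; ys[i] <- y
    }
    data.frame(track_id = 1L, frame = seq_len(n), x = xs, y = ys,
               gap = FALSE, loc_id = seq_len(n))
  }
  tr <- simDisc(1000, D = 0.05, tau = 0.05)
  res <- msdConfinement(tr, tau = 0.05)
  expect_true(isTRUE(res$confined))
  expect_lt(abs(res$R - R) / R, 0.2)
  # free diffusion: alpha ~ 1, above the threshold
  set.seed(6)
  free <- brownianTrack(800, D = 0.5, tau = 0.05)
  resF <- msdConfinement(free, tau = 0.05)
  expect_gt(resF$alpha, 0.7)
  expect_false(isTRUE(resF$confined))
})

test_that("jump angles handle collinear, reversal and isotropic cases", {
  fwd <- data.frame(track_id = 1L, frame = 1:3, x = c(1, 2, 3), y = 0,
                    gap = FALSE, loc_id = 1:3)
  expect_equal(jumpAngles(asTrackSet(fwd))$angles, 0)
  rev_ <- data.frame(track_id = 1L, frame = 1:3, x = c(0, 1, 0), y = 0,
                     gap = FALSE, loc_id = 1:3)
  expect_equal(jumpAngles(asTrackSet(rev_))$angles, 180)
  # gap-adjacent angles are omitted
  gappy <- data.frame(track_id = 1L, frame = c(1, 2, 4, 5),
                      x = c(0, 1, 2, 3), y = 0, gap = FALSE, loc_id = 1:4)
  # both angle candidates involve the jump across the missing frame 3
  expect_identical(length(jumpAngles(asTrackSet(gappy))$angles), 0L)
  # Brownian tracks give uniform angles (isotropy)
  set.seed(7)
  tr <- brownianTrack(30000, D = 1, tau = 0.05)
  ja <- jumpAngles(asTrackSet(tr, tau = 0.05), nBins = 12L)
  # account for the sin-free 2D angle distribution: uniform on [0, 180]
  cs <- chisq.test(ja$counts)
  expect_gt(cs$p.value, 0.01)
})

test_that("localization maps count detections and conserve totals on rescale", {
  locs <- data.frame(x_px = c(5.1, 5.2, 4.9, 10.4), y_px = c(7, 7.1, 6.8, 2))
  m1 <- localizationMap(locs, dims = c(20, 20), scale = 1)
  expect_identical(sum(m1), 4L)
  expect_identical(m1[8, 6], 3L)           # row y=7, col x=5 (1-based)
  m2 <- localizationMap(locs, dims = c(20, 20), scale = 2)
  expect_identical(sum(m2), 4L)
})

test_that("the jump map assigns the jump distance to every touched pixel", {
  tr <- data.frame(track_id = 1L, frame = 1:2, x = 0.16 * c(2, 7),
                   y = 0.16 * c(3, 3), gap = FALSE, loc_id = 1:2)
  jm <- jumpDistanceMap(asTrackSet(tr), dims = c(12, 12), scale = 1,
                        pixelSizeUm = 0.16)
  L <- 0.16 * 5
  touched <- which(!is.na(jm))
  expect_identical(length(touched), 6L)    # pixels x = 2..7 on row y = 3
  expect_true(all(abs(jm[touched] - L) < 1e-12))
})

test_that("intensity traces drop to background after bleaching and clip at movie end", {
  sc <- renderScenario(frameSize = 30L, nFrames = 12L)
  # molecule visible in frames 1..6 only
  traj <- data.frame(id = 1L, frame = 1:6, t = (0:5) * 0.05,
                     x = 0.16 * 14, y = 0.16 * 16, state = 1L)
  attr(traj, "tau") <- 0.05
  sc@nFrames <- 12L
  mov <- renderMovie(traj, sc, seed = 8)
  track <- data.frame(frame = 1:6, x_px = 14, y_px = 16)
  trc <- intensityTrace(mov, track, tail = 20L)
  expect_identical(trc$frame, 1:12)        # clipped at the movie end
  during <- mean(trc$intensity[1:6])
  after <- mean(trc$intensity[7:12])
  expect_gt(during, after + 5 * sd(trc$intensity[7:12]))
  expect_identical(dim(trc$kymoX), c(12L, 30L))
})
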