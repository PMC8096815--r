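# Tracking-loss theory: effective jump variance, out-of-radius loss,
# erroneous linking, gap recovery, total loss and the radius iteration.

test_that("effective sigma^2 composes localization error and diffusion", {
  expect_identical(effectiveSigmaSq(0.0016, 0, 1), 0.0016)
  expect_identical(effectiveSigmaSq(0, 1e-3, 5), 0.02)
  # Monte-Carlo: detected jumps of an immobile molecule with loc noise
  set.seed(1)
  n <- 1e5
  sigma0 <- 0.04
  jump2 <- (rnorm(n, 0, sigma0 / 2) - rnorm(n, 0, sigma0 / 2))^2 +
    (rnorm(n, 0, sigma0 / 2) - rnorm(n, 0, sigma0 / 2))^2
  expect_lt(abs(mean(jump2) - sigma0^2) / sigma0^2, 0.02)
})

test_that("out-of-radius probability is exp(-z)", {
  expect_identical(outOfRadiusProb(0, 1), 1)
  expect_equal(outOfRadiusProb(1, 1), exp(-1))
  # sampling oracle: isotropic 2D Gaussian with E[r^2] = sigma^2
  set.seed(2)
  n <- 1e6
  sigmaSq <- 0.01
  r2 <- rnorm(n, 0, sqrt(sigmaSq / 2))^2 + rnorm(n, 0, sqrt(sigmaSq / 2))^2
  for (s in sqrt(sigmaSq) * c(0.5, 1, 1.8)) {
    p <- mean(r2 > s^2)
    a <- outOfRadiusProb(s, sigmaSq)
    expect_lt(abs(p - a), 3 * sqrt(a * (1 - a) / n))
  }
})

test_that("erroneous-link probability is linear in density with the 0.76 prefactor", {
  expect_identical(erroneousLinkProb(0, 1), 0)
  expect_equal(erroneousLinkProb(0.01, 1), 0.76 * pi * 0.01)
  expect_equal(erroneousLinkProb(1, 0.01), 0.76 * pi * 0.01)
  expect_warning(erroneousLinkProb(100, 0.01), "small-density")
})

test_that("the Monte-Carlo integral oracle matches its semi-analytic value", {
  # the constrained triple integral, reduced exactly to a circle-overlap
  # (lens) area average, evaluates to 0.8183; the sampling oracle must agree
  res <- erroneousLinkCoefficient(nSamples = 2e6, seed = 3)
  expect_lt(abs(res$coefficient - 0.8183), 3 * res$se + 0.003)
})

test_that("gap recovery agrees with the explicit 6-D error-model oracle", {
  # sample g1, g2, g3 (localization errors) and h1, h2 (diffusion jumps)
  # explicitly; r1 = h1 - g1 + g2, r2 = h2 - g2 + g3
  z <- 1; cc <- -0.1
  s0sq <- -2 * cc          # sigma^2 = 1 => sigma0^2 = -2c
  hsq <- 1 + 2 * cc
  n <- 4e5
  set.seed(4)
  g <- function() cbind(rnorm(n, 0, sqrt(s0sq / 4)), rnorm(n, 0, sqrt(s0sq / 4)))
  h <- function() cbind(rnorm(n, 0, sqrt(hsq / 2)), rnorm(n, 0, sqrt(hsq / 2)))
  g1 <- g(); g2 <- g(); g3 <- g(); h1 <- h(); h2 <- h()
  r1 <- h1 - g1 + g2; r2 <- h2 - g2 + g3
  out <- rowSums(r1^2) > z
  rec <- rowSums((r1 + r2)^2) < pmin(z, rowSums(r2^2))
  fOracle <- sum(rec & out) / sum(out)
  f <- gapRecoveryFraction(z, cc, nSamples = 1e6, seed = 5)
  se <- sqrt(fOracle * (1 - fOracle) / sum(out))
  expect_lt(abs(f - fOracle), 3 * se + 0.002)
  # the derived correlation of consecutive detected jumps
  expect_equal(jumpCorrelation(s0sq, 1), cc)
  expect_lt(abs(cor(r1[, 1], r2[, 1]) - cc), 0.01)
})

test_that("gap recovery never exceeds one half and vanishes at large z", {
  for (cc in c(0, -0.25, -0.5)) {
    for (z in c(0.1, 1, 5, 10)) {
      f <- gapRecoveryFraction(z, cc, nSamples = 2e5, seed = 6)
      expect_gte(f, 0)
      expect_lte(f, 0.5 + 0.005)
    }
  }
  # absolute recovered probability a_z * f -> 0 as z -> infinity
  expect_lt(outOfRadiusProb(sqrt(30), 1) *
              gapRecoveryFraction(30, -0.5, 2e5, seed = 7), 2e-13)
})

test_that("all loss components are probabilities and compose per the model", {
  set.seed(8)
  for (i in 1:20) {
    sigmaSq <- runif(1, 1e-4, 0.05)
    s <- runif(1, 0.3, 4) * sqrt(sigmaSq)
    rho <- runif(1, 0, 0.2)
    lb <- totalLossProb(s, sigmaSq, rho, gapEnabled = i %% 2 == 0,
                        sigma0Sq = runif(1, 0, sigmaSq), nSamples = 2e4)
    for (p in c(lb$aZ, lb$aNN, lb$aGap, lb$aTr)) {
      expect_gte(p, 0); expect_lte(p, 1)
    }
    expect_gte(lb$aTr, lb$aNN - 1e-12)
    expect_lte(lb$aGap, lb$aZ + 1e-12)
    expect_equal(lb$aTr, lb$aNN + lb$aGap * (1 - lb$aNN))
  }
  # rho = 0 and gap disabled reduces to exp(-z)
  lb0 <- totalLossProb(0.2, 0.01, 0, gapEnabled = FALSE)
  expect_equal(lb0$aTr, exp(-0.2^2 / 0.01))
})

test_that("the truncation correction approaches 1 at large z", {
  corr <- function(z) z * (1 - exp(-z)) / (1 - (1 + z) * exp(-z))
  expect_gt(corr(1) / 1, 1.5)
  expect_lt(abs(corr(30) / 30 - 1), 1e-10)
})

test_that("the radius iteration hits the loss target on synthetic data", {
  sc <- tableScenario(1)
  tau <- 1
  target <- 0.03
  locsL <- lapply(1:25, function(m) {
    traj <- simulateTrajectories(sc, 2, seed = 800 + m)
    lc <- detectedLocalizations(traj, 0.04, seed = 900 + m)
    lc$frame <- lc$frame + (m - 1L) * 501L
    lc
  })
  locs <- do.call(rbind, locsL)
  area <- (100 * 0.16)^2
  cal <- radiusForLoss(locs, tau, target, area, sigma0Sq = 0.04^2)
  expect_true(cal$converged)
  # fixed-point residual: the predicted loss at the returned radius matches
  # the target
  expect_lt(abs(cal$aTrPredicted - target), 1e-3)
  # the recovered sigma^2 matches the known ground truth within a few %
  truth <- effectiveSigmaSq(0.04^2, sc@dBound, tau)
  expect_lt(abs(cal$sigmaSqTrue - truth) / truth, 0.05)
})

test_that("an unreachable loss target errors unless the fallback is chosen", {
  set.seed(9)
  locs <- data.frame(frame = rep(1:40, each = 60),
                     x = runif(2400, 0, 16), y = runif(2400, 0, 16))
  # rho = 60 / 256 um^-2; with sigma^2 ~ 0.0016 the floor is ~9e-4, so a
  # target well below it must error
  expect_error(suppressWarnings(
    radiusForLoss(locs, 0.05, 5e-4, area = 256, sigma0Sq = 0.04^2,
                  onUnreachable = "error")), "unreachable")
  cal <- suppressWarnings(
    radiusForLoss(locs, 0.05, 5e-4, area = 256, sigma0Sq = 0.04^2,
                  onUnreachable = "min-loss"))
  expect_true(cal$unreachable)
  expect_gt(cal$s, 0)
})

test_that("the minimum bound-track length shrinks with the frame-cycle time", {
  n005 <- minBoundTrackLength(0.1, 0.0016, 10, 0.05)
  n5 <- minBoundTrackLength(0.43, 0.0016, 10, 9)
  expect_gte(n005, n5)
  expect_gte(n5, 2L)
  # an over-large radius cannot discriminate free molecules at all
  expect_identical(minBoundTrackLength(10, 0.0016, 10, 0.05), 1000L)
})

test_that("the gap integral is conservative when the localization error dominates", {
  # consecutive detected jumps of a surviving track are conditioned on the
  # previous jump having stayed inside the radius; when sigma0^2 is a large
  # fraction of sigma^2 this strengthens the effective anti-correlation and
  # the tracker recovers MORE gaps than the unconditional integral predicts
  sc1 <- tableScenario(1)
  sigma0 <- 0.04                       # sigma0^2 / sigma^2 = 0.89 at 0.05 s
  tau <- 0.05
  sigmaSq <- effectiveSigmaSq(sigma0^2, sc1@dBound, tau)
  s <- sqrt(1 * sigmaSq)
  L <- 0L; Tr <- 0L
  for (m in 1:12) {
    traj <- simulateTrajectories(sc1, 1, seed = 300 + m)
    locs <- detectedLocalizations(traj, sigma0, seed = 400 + m)
    ts <- nearestNeighbourLink(locs, trackingParams(s, 1L, 2L), tau)
    el <- empiricalLossPerFrame(ts, locs$true_id)
    L <- L + el$losses; Tr <- Tr + el$trials
  }
  aHat <- L / Tr
  th <- totalLossProb(s, sigmaSq, 1 / 256, TRUE, sigma0^2)$aTr
  se <- sqrt(th * (1 - th) / Tr)
  expect_lt(aHat, th)                  # prediction is an upper bound here
  expect_gt((th - aHat) / se, 3)       # and measurably so
})
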