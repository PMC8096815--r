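# sptkit

Single-molecule tracking for fluorescence time-lapse microscopy, with a
calibrated treatment of tracking errors.

When a fluorescently labelled molecule (say, a transcription factor bound to
chromatin) is imaged frame by frame, its track ends for one of three
reasons: the molecule actually dissociates, the dye photobleaches, or the
*tracker* loses it — because the apparent jump exceeded the tracking radius
or because a neighbouring molecule was linked instead. Only the first
carries kinetic information; the other two blur every residence-time
estimate built on track durations. `sptkit` implements the full pipeline —
spot detection, nearest-neighbour linking with one-frame gap bridging,
survival-time analysis and a global dissociation-rate spectrum — together
with an analytic model of the per-frame tracking loss that lets you *choose*
the loss probability and obtain the tracking radius that achieves it, for
every time-lapse condition.

## The loss model

For an immobile molecule detected with localization error σ₀ and apparent
diffusion coefficient D at frame-cycle time τ, the effective squared jump
distance between consecutive detections is

    σ²(τ) = σ₀² + 4 D τ,

and the per-frame probability that the jump leaves the tracking radius s is
`a_z = exp(−z)` with `z = s²/σ²`. Erroneous links to a neighbouring
detection at spot density ρ contribute `a_NN = 0.76·π·ρ·σ²`. Allowing one
gap frame recovers a fraction `f ≤ 1/2` of the out-of-radius losses
(a correlated bivariate Gaussian integral over the recovery geometry,
evaluated by conditional Monte-Carlo), giving the total per-frame loss

    a_tr = a_NN + a_z · (1 − f) · (1 − a_NN).

`radiusForLoss()` inverts this for s by re-tracking the data at each
iterate, measuring the (radius-truncated) mean squared jump, and applying
the exact truncation correction — so the returned radius achieves the
requested loss on *your* data. Because the tracking loss is then constant
per frame across all time-lapse conditions, it can be corrected jointly
with photobleaching by the survival-time fit.

A Gillespie-based simulator (`simulateTrajectories()`, `renderMovie()`)
generates ground-truth trajectories and rendered movies with multiple
binding states, photobleaching, lognormal spot intensities and structured
background, and backs every quantitative claim in the test suite.

## Worked example

Simulate a five-state time-lapse experiment (5 molecules per 100×100 px
frame, dissociation rates 0.003–10 s⁻¹, 1% photobleaching per frame,
frame-cycle times 0.05/0.3/1.5/5 s), calibrate the tracking radius of each
condition to a 1% per-frame loss, track, and infer the rate spectrum:

```r
library(sptkit)
scenario <- tableScenario(2)
study  <- simulateStudy(scenario, nMovies = 2L, seed = 42)
conds  <- calibrateAndTrack(study, scenario, targetLoss = 0.01)
conds[[1]]$calibration
#> RadiusCalibration: s = 0.03662 um (z = 4.47) after 3 iteration(s)
#>   sigma^2 = 0.0002997 um^2 (measured 0.0002847), rho = 0.01953 /um^2, a_NN = 1.397e-05
#>   predicted a_tr = 0.009897, min bound-track length = 2 frames
```

The calibrated radii grow with the frame-cycle time (36.6, 77.1, 166,
301 nm here) exactly so that each condition keeps the same 1% loss per
frame. Collecting track durations into survival distributions and fitting
them globally:

```r
sv <- buildSurvival(lapply(conds, `[[`, "durations"),
                    vapply(conds, `[[`, numeric(1), "tau"),
                    vapply(conds, `[[`, integer(1), "minFrames"),
                    nFramesMovie = 400,
                    birthFrames = lapply(conds, `[[`, "birthFrames"))
spec <- gridSpectrum(sv)
spec
#> RateSpectrum: 60 grid points, per-frame loss 0.0223
#>   non-zero weights:
#>        0.00335 1/s    2.12%
#>        0.00424 1/s    3.85%
#>        ...
#>           39.2 1/s   13.99%
```

The fitted per-frame loss 0.0223 combines the 1% bleaching with the 1%
calibrated tracking loss (1 − 0.99² ≈ 0.0199) plus residual losses. Four of
the five rate clusters sit on the ground truth; the fastest state
(10 s⁻¹, lasting ~2 frames even at the shortest lapse) comes back as a
smeared block of weight at 24–100 s⁻¹ — resolving rates at the edge of the
observable window is the hard part of this inverse problem, and
`spectrumClusters()` / `recoveredRates()` make such calls explicit rather
than hiding them.

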