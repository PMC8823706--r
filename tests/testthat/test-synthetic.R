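test_that("rotation profile reproduces the printed stimulus extremes", {
  p <- makeRotationProfile(90, 7)
  v <- profileVelocity(p)
  expect_equal(max(abs(v)), 2 * pi * 90 / 7, tolerance = 1e-3)
  expect_equal(max(abs(profilePosition(p))), 90, tolerance = 1e-6)
  # starts and ends at rest, returns to the starting position
  expect_equal(v[1L], 0)
  expect_equal(v[length(v)], 0)
  expect_lt(abs(profilePosition(p)[length(v)]), 1e-6)

  cw <- makeRotationProfile(direction = "CW")
  ccw <- makeRotationProfile(direction = "CCW")
  expect_equal(profileVelocity(cw), -profileVelocity(ccw))

  z <- makeRotationProfile(0, 7)
  expect_true(all(profileVelocity(z) == 0))
  expect_true(all(profilePosition(z) == 0))
})

test_that("trajectory statistics match open-field assumptions and seeds", {
  tr <- simulateTrajectory(1200, seed = 1)
  gt <- attr(tr, "groundTruth")
  expect_gte(mean(abs(gt$ahv) <= 200), 0.95)
  expect_true(all(abs(sqrt(tr$body_x^2 + tr$body_y^2)) <= 46))
  tr2 <- simulateTrajectory(1200, seed = 1)
  expect_identical(tr, tr2)

  frozen <- simulateTrajectory(60, seed = 2, ahvSd = 0, speedSd = 0,
                               speedMean = 0)
  k <- computeKinematics(frozen)
  expect_true(all(abs(ahv(k)) < 1e-9, na.rm = TRUE))
  expect_lt(diff(range(headDirection(k))), 1e-9)
})

test_that("tuned-spike generator obeys the Poisson count oracle", {
  fx <- cachedKin(duration = 1000, seed = 13)
  sp <- simulateTunedSpikes(fx$kin, neuronSpec(baselineRate = 5), seed = 3)
  # refractory thinning removes ~ rate * refractory of spikes
  expect_lt(abs(nSpikes(sp) - 5000), 4 * sqrt(5000) + 0.005 * 5000)

  empty <- simulateTunedSpikes(fx$kin, neuronSpec(baselineRate = 0),
                               seed = 3)
  expect_identical(nSpikes(empty), 0L)

  expect_error(simulateTunedSpikes(fx$kin,
                                   neuronSpec(baselineRate = 600)),
               "500 Hz")

  tuned <- simulateTunedSpikes(fx$kin,
                               neuronSpec(baselineRate = 2,
                                          ahvGainRight = 0.2), seed = 4)
  cv <- tuningCurve(tuned, fx$kin, "ahv")
  hi <- cv$bin_center > 40
  lo <- cv$bin_center > 0 & cv$bin_center < 20
  expect_gt(mean(cv$rate[hi], na.rm = TRUE),
            mean(cv$rate[lo], na.rm = TRUE))
})

test_that("rotation sessions interleave the full condition grid deterministically", {
  specs <- lapply(1:2, function(u)
    list(baseline = 5,
         speedGain = list(vestibular = 0, vestibular_visual = 0,
                          visual = 0)))
  sess <- simulateRotationSession(specs, 10, seed = 6)
  expect_identical(nrow(sess$trials), 60L)
  expect_true(all(table(sess$trials$condition, sess$trials$direction) == 10))
  sess2 <- simulateRotationSession(specs, 10, seed = 6)
  expect_identical(spikeTimes(sess$spikes[[1L]]),
                   spikeTimes(sess2$spikes[[1L]]))

  # zero gains: per-condition mean rates statistically indistinguishable
  r <- trialRates(sess$spikes[[1L]], sess$trials)
  p <- summary(stats::aov(r ~ sess$trials$condition))[[1L]][1, "Pr(>F)"]
  expect_gt(p, 0.01)
})

test_that("coupled-pair generator plants a transmission peak at the set delay", {
  cp <- simulateCoupledPair(10, 10, 2, 0.2, 300, seed = 8)
  g <- computeCCG(cp$a, cp$b)
  peakBin <- which(abs(g$lags - 2) < 1e-9)
  baseBins <- which(abs(g$lags) > 10)
  expect_gt(g$counts[peakBin], mean(g$counts[baseBins]) +
              6 * sqrt(mean(g$counts[baseBins])))

  ind <- simulateCoupledPair(10, 10, 2, 0, 300, seed = 9)
  gi <- computeCCG(ind$a, ind$b)
  expect_lt(gi$counts[peakBin], mean(gi$counts[baseBins]) +
              5 * sqrt(mean(gi$counts[baseBins])))

  inh <- simulateCoupledPair(20, 20, 1.5, 0.6, 300, seed = 10,
                             type = "inhibitory", windowMs = 2.5)
  gh <- computeCCG(inh$a, inh$b)
  trough <- gh$lags >= 2 & gh$lags <= 3.5
  base <- mean(gh$counts[abs(gh$lags) > 10])
  expect_lt(mean(gh$counts[trough]), 0.75 * base)
})

test_that("waveform library ground truth and zero-jitter identity hold", {
  lib0 <- simulateWaveformLibrary(nPairs = 4, nDistractors = 2,
                                  jitter = list(amplitude = 0, shape = 0,
                                                isi = 0, channel = 0),
                                  seed = 5, duration = 120)
  expect_identical(nrow(lib0$truth), 4L)
  for (i in seq_len(4)) {
    expect_equal(waveformMatrix(lib0$free$waveforms[[lib0$truth$free_id[i]]]),
                 waveformMatrix(lib0$fix$waveforms[[lib0$truth$fix_id[i]]]))
  }
})

test_that("simulated go/no-go observers behave as specified", {
  perfect <- simulateGoNoGoSession(c(30, 80), nBlocks = 3, threshold = 0,
                                   slope = 0, lapse = 0, seed = 2)
  accP <- scoreSession(perfect)
  expect_true(all(accP$accuracy == 100))

  guess <- simulateGoNoGoSession(rep(c(30, 80), each = 1), nBlocks = 25,
                                 threshold = 1e6, slope = 10, seed = 3)
  accG <- scoreSession(guess)
  expect_lt(abs(mean(accG$accuracy) - 50), 7)

  mc <- simulateGoNoGoSession(c(20, 30), nBlocks = 40, threshold = 15,
                              slope = 3, seed = 4)
  accs <- scoreSession(mc)
  a10 <- mean(accs$accuracy[accs$peak_splus == 20])
  a20 <- mean(accs$accuracy[accs$peak_splus == 30])
  expect_lt(a10, a20)
})
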