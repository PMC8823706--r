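test_that("proportional difference follows its closed form", {
  expect_equal(proportionalDifference(10, 10), 1)
  expect_equal(proportionalDifference(10, 20), 0)
  expect_equal(proportionalDifference(10, 30), 0)
  expect_equal(proportionalDifference(10, 5), 0.5)
  expect_equal(proportionalDifference(0, 0), 1)
  expect_equal(proportionalDifference(0, 3), 0)
})

test_that("histogram intersection matches hand computation", {
  expect_equal(histogramIntersection(c(0.2, 0.8), c(0.2, 0.8)), 1)
  expect_equal(histogramIntersection(c(1, 0), c(0, 1)), 0)
  expect_equal(histogramIntersection(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)),
               (0.25 + 0.25) / (0.5 + 0.5 + 0.5))
  h1 <- isiHistogram(SpikeTrain(c(0.1, 0.2, 0.4)))
  h2 <- h1; h2$edges <- h2$edges * 2
  expect_error(histogramIntersection(h1, h2), "edges")
})

test_that("local features are exact on a constructed waveform", {
  si <- 1e6 / 30000
  w <- rep(0, 121)
  w[49] <- -80            # trough
  w[40] <- 6              # first positive peak before the trough
  w[64] <- 25             # second positive peak: 15 samples after trough
  wf <- UnitWaveform(matrix(w, 1), channelPositions = 0)
  lf <- extractLocalFeatures(wf)
  expect_equal(lf$A, 6)
  expect_equal(lf$B, 25)
  expect_equal(lf$C, 15 * si)
  expect_equal(lf$D, -80)

  flipped <- UnitWaveform(matrix(abs(w) + 1, 1), channelPositions = 0)
  lfF <- extractLocalFeatures(flipped)
  expect_true("atypical_no_trough" %in% lfF$flags)
})

test_that("DTW alignment and global features behave on controlled pairs", {
  x <- ahvtools:::waveformTemplate(100, 120, 400, 0.35)
  al <- dtwAlign(x, x)
  expect_equal(al$distance, 0)
  expect_equal(al$pathLength, length(x))
  expect_identical(al$index1, al$index2)

  wfX <- UnitWaveform(matrix(x, 1), channelPositions = 0)
  gSame <- globalFeatures(wfX, wfX)
  expect_equal(gSame$wfDifference, 0)
  expect_equal(gSame$wfCorr, 1)
  expect_equal(gSame$wfIntersection, 1)
  expect_equal(gSame$dtwScale, 1)

  wfScaled <- UnitWaveform(matrix(1.2 * x, 1), channelPositions = 0)
  gSc <- globalFeatures(wfX, wfScaled)
  expect_gt(gSc$wfCorr, 1 - 1e-6)
  expect_lt(gSc$wfIntersection, 1)

  stretched <- stats::approx(seq_along(x), x,
                             xout = seq(1, length(x), length.out = 150))$y
  alS <- dtwAlign(x, stretched, radius = 40)
  expect_lt(length(x) / alS$pathLength, 1)

  flat <- UnitWaveform(matrix(rep(-1, 121), 1), channelPositions = 0)
  expect_error(globalFeatures(wfX, flat), "flat")
})

test_that("weighted similarity score equals its hand-computed arithmetic", {
  m <- list(fPeak2 = 0.9, fT2pDur = 0.8, fT2pAmp = 0.7, fP2tAmp = 0.6,
            wfIntersection = 0.5, wfDifference = 0.2, wfCorr = 0.95,
            dtwScale = 0.9, isiCorr = 0.85, isiIntersection = 0.75)
  hand <- (1 / 9) * sqrt(0.9^2 + 0.8^2 + 0.7^2 + 0.6^2) +
    (4 / 9) * sqrt(0.5^2 + 0.8^2 + 0.95^2 + 0.9^2) +
    (4 / 9) * sqrt(0.85^2 + 0.75^2)
  expect_equal(similarityScore(m), hand)
  expect_error(similarityScore(m[-1L]), "missing")
  zero <- lapply(m, function(x) 0)
  zero$wfDifference <- 1; zero$dtwScale <- 1e9
  expect_lt(similarityScore(zero), 1e-6)
})

test_that("matching a session against itself returns the identity mapping", {
  lib <- simulateWaveformLibrary(nPairs = 6, nDistractors = 0, seed = 3,
                                 duration = 150)
  m <- matchUnits(lib$fix, lib$fix)
  expect_identical(m$free_id, m$fix_id)
  expect_true(all(m$accepted))
  expect_true(all(m$chk_isi_corr & m$chk_local & m$chk_wf_corr &
                    m$chk_wf_diff))
})

test_that("a Free unit claimed twice goes to the higher-scoring Fix unit", {
  lib <- simulateWaveformLibrary(nPairs = 1, nDistractors = 0, seed = 4,
                                 duration = 150)
  fix <- lib$fix
  # second Fix unit: strongly rescaled copy competing for the same Free
  # unit; it still claims the same best match but at a lower score
  w <- waveformMatrix(fix$waveforms[[1L]])
  pert <- UnitWaveform(w * 1.4,
                       channelPositions = channelPositions(
                         fix$waveforms[[1L]]), unitId = "fix99")
  fix$spikes$fix99 <- SpikeTrain(spikeTimes(fix$spikes[[1L]]) + 0.0005,
                                 unitId = "fix99")
  fix$waveforms$fix99 <- pert
  m <- matchUnits(fix, lib$free)
  winner <- m[!is.na(m$free_id), ]
  expect_identical(nrow(winner), 1L)
  expect_identical(winner$fix_id, "fix01")
  expect_identical(m$reason[m$fix_id == "fix99"], "conflict")
})

test_that("increasing jitter lowers mean true-pair similarity", {
  meanScore <- function(amp) {
    mean(vapply(1:3, function(s) {
      lib <- simulateWaveformLibrary(
        nPairs = 6, nDistractors = 0,
        jitter = list(amplitude = amp, shape = amp / 2, isi = amp,
                      channel = 1), seed = s, duration = 150)
      m <- matchUnits(lib$fix, lib$free)
      mean(m$score, na.rm = TRUE)
    }, numeric(1)))
  }
  expect_gt(meanScore(0.01), meanScore(0.4))
})

test_that("accepted pairs always satisfy every printed threshold", {
  lib <- simulateWaveformLibrary(nPairs = 10, nDistractors = 5, seed = 6,
                                 duration = 150)
  m <- matchUnits(lib$fix, lib$free)
  acc <- m[m$accepted, ]
  expect_true(all(acc$chk_isi_corr & acc$chk_local & acc$chk_wf_corr &
                    acc$chk_wf_diff))
})
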