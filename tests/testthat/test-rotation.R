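test_that("rotation modulation index follows its definition exactly", {
  # regular trains with known rates: 10 Hz baseline, 12.9 Hz during trials
  trials <- data.frame(trial_id = 1:5, condition = "vestibular",
                       direction = "CW",
                       t_onset = seq(100, 500, by = 100),
                       t_offset = seq(110, 510, by = 100),
                       profile_id = "CW")
  times <- sort(unique(c(
    seq(0.05, 600, by = 0.1),
    unlist(lapply(trials$t_onset, function(o)
      seq(o + 0.017, o + 10, by = 10 / 29))))))
  ev <- evokedResponse(SpikeTrain(times), trials, "CW")
  expect_equal(ev$rateBase, 10, tolerance = 0.01)
  expect_equal(ev$rateRot, 12.9, tolerance = 0.01)
  expect_equal(ev$modulationIndex, 0.29, tolerance = 0.01)

  # identical rates: index 0; doubled rate: index 1
  flat <- evokedResponse(SpikeTrain(seq(0.05, 600, by = 0.1)), trials, "CW")
  expect_equal(flat$modulationIndex, 0, tolerance = 0.01)
  dbl <- sort(c(seq(0.05, 600, by = 0.1),
                unlist(lapply(trials$t_onset, function(o)
                  seq(o + 0.013, o + 10, by = 0.1)))))
  evD <- evokedResponse(SpikeTrain(dbl), trials, "CW")
  expect_equal(evD$modulationIndex, 1, tolerance = 0.02)
})

test_that("the modulation index is invariant to rate scaling", {
  sess <- cachedRotationSession()
  tv <- sess$trials
  ev1 <- evokedResponse(sess$spikes[[1L]], tv, "CW")
  # interleave a copy of every spike: rates double everywhere
  t2 <- sort(c(spikeTimes(sess$spikes[[1L]]),
               spikeTimes(sess$spikes[[1L]]) + 1e-4))
  ev2 <- evokedResponse(SpikeTrain(t2), tv, "CW")
  expect_equal(ev2$modulationIndex, ev1$modulationIndex, tolerance = 1e-6)
})

test_that("direction selectivity AUC equals pair counting and its landmarks", {
  expect_equal(directionSelectivity(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  expect_equal(directionSelectivity(c(5, 6, 7), c(1, 2, 3))$auc, 1)
  expect_equal(directionSelectivity(c(3, 5, 7), c(2, 4, 6))$auc, 6 / 9)
  set.seed(3)
  for (i in 1:5) {
    cw <- stats::rpois(12, 8); ccw <- stats::rpois(15, 6)
    expect_equal(directionSelectivity(cw, ccw)$auc, bruteAUC(cw, ccw))
  }
})

test_that("rotation tuning recovers gain modulation and calibrates on flat cells", {
  sess <- cachedRotationSession()
  tv <- sess$trials
  rt <- rotationTuning(sess$spikes[[1L]], tv, sess$profiles, nPerm = 200,
                       seed = 2)
  expect_true(rt$isVelocityModulated)
  expect_gt(max(rt$scoreCW, rt$scoreCCW), 0.7)

  # constant-rate unit: Pearson r of a flat curve is NA, not modulated
  flat <- SpikeTrain(seq(0.05, max(tv$t_offset) + 5, by = 0.1))
  rf <- rotationTuning(flat, tv, sess$profiles, nPerm = 100, seed = 3)
  expect_false(isTRUE(rf$isVelocityModulated) &&
                 max(rf$scoreCW, rf$scoreCCW, na.rm = TRUE) > 0.99)
})

test_that("active/passive comparison detects shared tuning and flags flat curves", {
  fx <- cachedKin()
  spec <- neuronSpec(baselineRate = 3, ahvGainRight = 0.15,
                     ahvGainLeft = 0.08)
  sp <- simulateTunedSpikes(fx$kin, spec, seed = 4)
  act <- classifyAHV(sp, fx$kin, nPerm = 50, seed = 5)
  sess <- cachedRotationSession()
  rt <- rotationTuning(sess$spikes[[1L]], sess$trials, sess$profiles,
                       nPerm = 50, seed = 6)
  # same generating ramp on both sides: correlated curves
  cmp <- compareActivePassive(act, rt, nPerm = 200, seed = 7)
  expect_false(cmp$undefined)
  expect_length(cmp$active, length(cmp$passive))

  flatCurve <- rt
  flatCurve$curve$rate <- rep(1, nrow(flatCurve$curve))
  cf <- compareActivePassive(act, flatCurve, nPerm = 50, seed = 8)
  expect_true(cf$undefined)
  expect_false(cf$similar)
})

test_that("rate heatmaps are normalised, baseline-subtracted and lossless", {
  sess <- cachedRotationSession()
  tv <- sess$trials
  hm <- buildRateHeatmap(sess$spikes[1:2], tv, sess$profiles,
                         type = "speed")
  expect_identical(nrow(hm), 4L)
  expect_true(all(hm <= 1 + 1e-9, na.rm = TRUE))

  const <- list(flat = SpikeTrain(seq(0.05, max(tv$t_offset) + 20,
                                      by = 0.1), unitId = "flat"))
  hmF <- buildRateHeatmap(const, tv, sess$profiles, type = "temporal",
                          binWidth = 1)
  expect_lt(max(abs(hmF), na.rm = TRUE), 0.15)

  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(hm, f, sep = "\t", col.names = NA)
  back <- as.matrix(utils::read.table(f, sep = "\t", header = TRUE,
                                      row.names = 1, check.names = FALSE))
  hmPlain <- hm
  attr(hmPlain, "sortKey") <- NULL
  expect_equal(unname(back), unname(hmPlain), tolerance = 1e-12)
})

test_that("eye-movement events are recovered from injected saccades", {
  set.seed(9)
  n <- 4800
  drift <- 0.4 * sin(2 * pi * seq_len(n) / 1600)
  x <- cumsum(stats::rnorm(n, 0, 0.001)) + drift
  onsets <- seq(300, 4500, length.out = 10)
  signs <- rep(c(1, -1), 5)
  for (i in seq_along(onsets)) {
    k <- round(onsets[i])
    x[k:n] <- x[k:n] + signs[i] * 0.12
  }
  ev <- detectEyeEvents(x)
  expect_identical(nrow(ev$events), 10L)
  got <- ifelse(ev$events$direction == "nasal", 1, -1)
  expect_identical(got, signs)
  ev2 <- detectEyeEvents(x)
  expect_identical(ev$events, ev2$events)

  slow <- detectEyeEvents(drift)
  expect_identical(nrow(slow$events), 0L)
})

test_that("eye modulation flags event-locked units and degenerate input", {
  set.seed(10)
  on <- seq(5, 295, by = 5)
  ev <- list(events = data.frame(
    t_onset = on, t_peak = on + 0.02,
    direction = rep(c("nasal", "temporal"), length.out = length(on)),
    amplitude = stats::runif(length(on), 0.5, 3)),
    sd = 1, fs = 40)
  base <- sort(stats::runif(1500) * 300)
  extra <- unlist(lapply(seq_len(nrow(ev$events)), function(i) {
    e <- ev$events[i, ]
    nsp <- stats::rpois(1, 4 * e$amplitude)
    e$t_onset + stats::runif(nsp, 0, 0.25)
  }))
  locked <- SpikeTrain(sort(unique(c(base, extra))))
  r <- eyeModulation(locked, ev)
  expect_true(r$modulated)

  indep <- SpikeTrain(base)
  r0 <- eyeModulation(indep, ev)
  expect_false(r0$undefined)

  none <- list(events = ev$events[0, ], sd = 1, fs = 40)
  rn <- eyeModulation(locked, none)
  expect_true(rn$undefined)
})
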