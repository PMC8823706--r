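test_that("spike-shift null preserves counts and is seed-reproducible", {
  fx <- cachedKin()
  sp <- simulateTunedSpikes(fx$kin, neuronSpec(baselineRate = 4), seed = 2)
  n1 <- spikeShiftNull(sp, length, nPerm = 20, seed = 3)
  expect_true(all(n1 == nSpikes(sp)))
  s1 <- spikeShiftNull(sp, function(t) mean(diff(t)), nPerm = 50, seed = 4)
  s2 <- spikeShiftNull(sp, function(t) mean(diff(t)), nPerm = 50, seed = 4)
  expect_identical(s1, s2)
  expect_error(spikeShiftNull(SpikeTrain(c(1, 2, 30)), length, 5, 1), "40 s")
})

test_that("AHV classification recovers gain, subtype and slope", {
  fx <- cachedKin()
  right <- simulateTunedSpikes(fx$kin,
                               neuronSpec(baselineRate = 2,
                                          ahvGainRight = 0.2), seed = 5)
  rr <- classifyAHV(right, fx$kin, nPerm = 200, seed = 6)
  expect_true(rr$isAHV)
  expect_identical(rr$subtype, "unidirectional_right")
  expect_lt(abs(rr$slopeRight - 0.2) / 0.2, 0.25)

  both <- simulateTunedSpikes(fx$kin,
                              neuronSpec(baselineRate = 2,
                                         ahvGainRight = 0.15,
                                         ahvGainLeft = 0.15), seed = 7)
  rb <- classifyAHV(both, fx$kin, nPerm = 200, seed = 8)
  expect_identical(rb$subtype, "bidirectional")
  expect_true(all(rb$curve$occupancy >= 0))
  expect_true(all(abs(rb$curve$bin_center) <= 80))

  # frame-wise score domain agrees on a strongly tuned unit
  fw <- classifyAHV(right, fx$kin, nPerm = 100, seed = 9,
                    scoreDomain = "framewise")
  expect_true(fw$isAHV)
  expect_identical(fw$subtype, "unidirectional_right")
})

test_that("speed classification recovers positive and negative tuning", {
  fx <- cachedKin()
  pos <- simulateTunedSpikes(fx$kin,
                             neuronSpec(baselineRate = 2, speedGain = 0.5),
                             seed = 9)
  rp <- classifySpeed(pos, fx$kin, nPerm = 200, seed = 10)
  expect_true(rp$isSpeed)
  expect_identical(rp$sign, 1)

  neg <- simulateTunedSpikes(fx$kin,
                             neuronSpec(baselineRate = 8, speedGain = -0.3),
                             seed = 11)
  rn <- classifySpeed(neg, fx$kin, nPerm = 200, seed = 12)
  expect_true(rn$isSpeed)
  expect_identical(rn$sign, -1)
})

test_that("HD classification applies the conjunctive two-epoch rule", {
  fx <- cachedKin()
  pool <- lapply(1:3, function(u)
    simulateTunedSpikes(fx$kin, neuronSpec(baselineRate = 5),
                        seed = 20 + u, unitId = paste0("n", u)))
  pn <- populationHDNull(pool, fx$kin, nPerm = 100, seed = 13)
  tuned <- simulateTunedSpikes(fx$kin,
                               neuronSpec(baselineRate = 5,
                                          hdPreferred = 120,
                                          hdConcentration = 2), seed = 14)
  rt <- classifyHD(tuned, fx$kin, pn)
  expect_true(rt$isHD)
  expect_length(rt$passesEpoch, 2L)
  expect_identical(rt$epochSource, "halves")

  flat <- pool[[1L]]
  rf <- classifyHD(flat, fx$kin, pn)
  expect_false(rf$isHD)
  # conjunction: forcing one epoch to fail fails the cell
  expect_true(all(rt$passesEpoch))
  expect_false(all(c(rt$passesEpoch[1L], FALSE)) && rf$isHD)
})

test_that("stability index separates tuned from untuned units", {
  fx <- cachedKin()
  tuned <- simulateTunedSpikes(fx$kin,
                               neuronSpec(baselineRate = 2,
                                          ahvGainRight = 0.25,
                                          ahvGainLeft = 0.25), seed = 15)
  st <- stabilityIndex(tuned, fx$kin, "ahv", nPerm = 100, seed = 16)
  expect_true(st$stable)
  expect_gt(st$rHalves, 0.6)
})

test_that("theta index flags rhythmic but not Poisson firing", {
  dur <- 300
  tt <- seq(0, dur, by = 0.001)
  set.seed(17)
  rate <- 10 * (1 + 0.8 * sin(2 * pi * 8 * tt))
  spk <- tt[stats::runif(length(tt)) < rate * 0.001]
  th <- thetaIndex(SpikeTrain(spk), duration = dur)
  expect_true(th$isTheta)
  expect_gt(th$thetaIndex, 5)
  expect_lt(abs(th$thetaPeakHz - 8), 1)

  set.seed(18)
  pois <- SpikeTrain(sort(stats::runif(3000) * dur))
  tp <- thetaIndex(pois, duration = dur)
  expect_false(tp$isTheta)

  single <- suppressWarnings(thetaIndex(SpikeTrain(c(1, 600)),
                                        duration = 601))
  expect_true(is.na(single$thetaIndex) || !single$isTheta)
})

test_that("rate filter applies the strict < 0.5 Hz exclusion rule", {
  mk <- function(rate) SpikeTrain(seq(0.5, 99.5,
                                      length.out = max(2, rate * 100)))
  sets <- filterAnalysisUnits(list(lo = mk(0.4), mid = mk(0.5),
                                   hi = mk(0.6)), duration = 100)
  expect_setequal(names(sets$retained), c("mid", "hi"))
  expect_identical(names(sets$excluded), "lo")
  expect_true("below_min_rate" %in% unitFlags(sets$excluded[[1L]]))
})
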