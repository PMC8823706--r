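test_that("spike data survives a write/read round trip to 1 microsecond", {
  lib <- simulateWaveformLibrary(nPairs = 3, nDistractors = 0, seed = 4,
                                 duration = 100)
  dir <- withr::local_tempdir()
  writeSpikeData(lib$fix$spikes, dir, lib$fix$waveforms,
                 lib$fix$channelPositions)
  back <- loadSpikeData(dir, minSpikes = 1)
  expect_setequal(names(back$spikes), names(lib$fix$spikes))
  for (id in names(back$spikes)) {
    expect_lt(max(abs(spikeTimes(back$spikes[[id]]) -
                        spikeTimes(lib$fix$spikes[[id]]))), 1e-6)
    expect_equal(waveformMatrix(back$waveforms[[id]]),
                 waveformMatrix(lib$fix$waveforms[[id]]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("curation flags units below the spike-count minimum without dropping them", {
  spikes <- list(a = SpikeTrain(seq(0.1, 100, length.out = 1200), "a", 1L),
                 b = SpikeTrain(seq(0.1, 100, length.out = 500), "b", 1L),
                 c = SpikeTrain(seq(0.1, 100, length.out = 950), "c", 1L))
  dir <- withr::local_tempdir()
  writeSpikeData(spikes, dir)
  back <- loadSpikeData(dir)
  expect_length(back$spikes, 3L)
  expect_identical(unitFlags(back$spikes[["b"]]), "below_min_spikes")
  expect_length(unitFlags(back$spikes[["a"]]), 0L)
  expect_length(unitFlags(back$spikes[["c"]]), 0L)
})

test_that("missing files and inconsistent unit ids are fatal with names", {
  dir <- withr::local_tempdir()
  expect_error(loadSpikeData(dir), "spike_times.csv")
  spikes <- list(a = SpikeTrain(seq(0.1, 50, by = 0.5), "a", 1L))
  writeSpikeData(spikes, dir)
  st <- utils::read.csv(file.path(dir, "spike_times.csv"))
  st$unit_id <- "zz"
  utils::write.csv(st, file.path(dir, "spike_times.csv"), row.names = FALSE)
  expect_error(loadSpikeData(dir, minSpikes = 1), "zz")
})

test_that("tracking loader interpolates low-likelihood frames linearly", {
  dir <- withr::local_tempdir()
  tr <- data.frame(t = (0:9) / 40,
                   left_x = 1:10, left_y = 0, right_x = 1:10 + 1,
                   right_y = 2, body_x = seq(0, 9, 1), body_y = 0,
                   left_lik = 0.99, right_lik = 0.99, body_lik = 0.99)
  f <- file.path(dir, "tr.csv")
  utils::write.csv(tr, f, row.names = FALSE)
  t1 <- loadTracking(f)
  expect_identical(nrow(t1), 10L)
  expect_false(any(t1$interpolated))

  tr2 <- tr
  tr2$left_lik[5] <- 0.1
  tr2$left_x[5] <- 999
  utils::write.csv(tr2, f, row.names = FALSE)
  t2 <- loadTracking(f)
  expect_true(t2$interpolated[5])
  expect_equal(t2$left_x[5], (tr$left_x[4] + tr$left_x[6]) / 2)

  tr3 <- tr[c(2, 1, 3:10), ]
  utils::write.csv(tr3, f, row.names = FALSE)
  expect_error(loadTracking(f), "increasing")
})

test_that("pipeline is deterministic, complete, and rejects unknown keys", {
  cfg <- list(synthetic = list(duration = 90, n_units = 2),
              tuning = list(n_perm = 30),
              rotation = list(n_trials = 2),
              behavior = list(n_blocks = 2))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- runPipeline(cfg, d1, seed = 5)
  s2 <- runPipeline(cfg, d2, seed = 5)
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d2, "summary.json")))
  expect_true(all(c("tuning", "rotation", "roc", "connectivity",
                    "behavior") %in% names(s1)))
  expect_true(file.exists(file.path(d1, "pipeline.log")))
  expect_error(runPipeline(list(ahv_bnis = 6), d1), "ahv_bnis")
  expect_error(runPipeline(list(tuning = list(nperm = 2)), d1), "nperm")
})
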