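test_that("binned CCG equals the brute-force double loop", {
  set.seed(1)
  ta <- sort(stats::runif(400) * 50)
  tb <- sort(stats::runif(500) * 50)
  g <- suppressWarnings(computeCCG(SpikeTrain(ta), SpikeTrain(tb)))
  expect_equal(g$counts, bruteCCG(ta, tb))
})

test_that("CCG(a,b) at +lag equals CCG(b,a) at -lag exactly", {
  set.seed(2)
  ta <- sort(stats::runif(600) * 80)
  tb <- sort(stats::runif(700) * 80)
  ab <- suppressWarnings(computeCCG(SpikeTrain(ta), SpikeTrain(tb)))
  ba <- suppressWarnings(computeCCG(SpikeTrain(tb), SpikeTrain(ta)))
  expect_equal(ab$counts, rev(ba$counts))
})

test_that("the autocorrelation case is dominated by the zero-lag bin", {
  set.seed(3)
  t0 <- sort(stats::runif(1000) * 100)
  g <- computeCCG(SpikeTrain(t0), SpikeTrain(t0))
  expect_identical(which.max(g$counts), which(g$lags == 0))
  expect_gte(g$counts[g$lags == 0], 1000)
})

test_that("connection detection recovers planted synaptic structure", {
  exc <- simulateCoupledPair(10, 10, 2, 0.2, 600, seed = 4)
  expect_identical(detectConnection(computeCCG(exc$a, exc$b))$label,
                   "excitatory")
  inh <- simulateCoupledPair(20, 20, 1.5, 0.5, 1200, seed = 5,
                             type = "inhibitory", windowMs = 2.5)
  expect_identical(detectConnection(computeCCG(inh$a, inh$b))$label,
                   "inhibitory")
  ind <- simulateCoupledPair(10, 10, 2, 0, 600, seed = 6)
  expect_identical(detectConnection(computeCCG(ind$a, ind$b))$label,
                   "none")
})

test_that("cell-type clustering separates feature blobs with stable naming", {
  set.seed(7)
  narrow <- data.frame(peak2_over_trough = stats::rnorm(25, 0.55, 0.05),
                       trough_to_peak_us = stats::rnorm(25, 250, 25))
  wide <- data.frame(peak2_over_trough = stats::rnorm(25, 0.25, 0.05),
                     trough_to_peak_us = stats::rnorm(25, 650, 60))
  feats <- rbind(narrow, wide)
  truth <- rep(c("narrow", "wide"), each = 25)
  for (s in c(1, 99)) {
    lab <- classifyCelltype(feats, seed = s)
    expect_identical(as.character(lab), truth)
  }
  dup <- feats[rep(1, 12), ]
  expect_error(classifyCelltype(dup), "degenerate")
})

test_that("class agreement scores the expected correspondence", {
  km <- c("wide", "wide", "narrow", "narrow", "wide")
  ccg <- c("excitatory", "excitatory", "inhibitory", "none", "inhibitory")
  res <- classAgreement(km, ccg)
  expect_identical(res$nTyped, 4L)
  expect_equal(res$overlap, 3 / 4)
  expect_equal(classAgreement(km, rep("none", 5))$nTyped, 0L)
})
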