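mkSession <- function(lickPlus, lickMinus, block = 1) {
  data.frame(block = block, trial = 1:20,
             stimulus = rep(c("S+", "S-"), each = 10),
             peak_splus = 30, peak_sminus = 10, condition = "vestibular",
             lick_bins = c(lickPlus, lickMinus))
}

test_that("block scoring implements the lick-bin rules and accuracy formula", {
  allCorrect <- mkSession(rep(3, 10), rep(0, 10))
  expect_equal(scoreSession(allCorrect)$accuracy, 100)

  alwaysLick <- mkSession(rep(4, 10), rep(4, 10))
  expect_equal(scoreSession(alwaysLick)$accuracy, 50)

  mixed <- mkSession(c(rep(3, 8), 1, 0), c(rep(0, 7), rep(2, 3)))
  sc <- scoreSession(mixed)
  expect_equal(sc$pct_splus, 80)
  expect_equal(sc$pct_sminus, 70)
  expect_equal(sc$accuracy, 75)

  # exactly 2 lick bins counts as a response (S+ correct, S- incorrect)
  boundary <- mkSession(rep(2, 10), rep(2, 10))
  expect_equal(scoreSession(boundary)$accuracy, 50)

  incomplete <- mkSession(rep(3, 10), rep(0, 10))[1:15, ]
  sc2 <- scoreSession(rbind(incomplete, mkSession(rep(3, 10), rep(0, 10),
                                                  block = 2)))
  expect_identical(nrow(sc2), 1L)
  expect_length(attr(sc2, "excluded"), 1L)
})

test_that("lick binning counts distinct 250-ms bins after the peak", {
  expect_identical(binLickTimes(c(16.2, 16.21, 16.6, 20)), 3L)
  expect_identical(binLickTimes(numeric(0)), 0L)
  expect_identical(binLickTimes(c(10, 15)), 0L)  # before the peak
})

test_that("training criterion requires 80% over 5 blocks and 20 blocks total", {
  acc <- c(rep(70, 15), rep(81, 5))
  expect_true(criterionCheck(acc))
  expect_false(criterionCheck(c(rep(70, 15), rep(79, 5))))
  expect_false(criterionCheck(rep(85, 4)))
  expect_false(criterionCheck(rep(85, 19)))
  expect_true(criterionCheck(rep(85, 20)))
})

test_that("psychometric fits recover step midpoints and flag flat data", {
  d <- c(5, 10, 20, 30, 45, 70)
  step <- c(50, 50, 50, 100, 100, 100)
  fit <- fitPsychometric(d, step)
  expect_true(fit$converged)
  expect_gt(fit$midpoint, 20)
  expect_lt(fit$midpoint, 30)

  flat <- fitPsychometric(d, rep(50, 6))
  expect_true(flat$flat)
  expect_true(is.na(flat$midpoint))
  expect_error(fitPsychometric(c(5, 5, 10), c(50, 50, 60)), "distinct")
})

test_that("turn angles are exact on lines and circles and shift under circling", {
  tv <- seq(0, 10, by = 0.025)
  line <- data.frame(t = tv, body_x = tv * 5, body_y = 2)
  expect_true(all(abs(turnAngleDistribution(line)) < 1e-9))

  # constant-curvature circle: constant step angle = 360 / steps per lap
  th <- seq(0, 4 * pi, length.out = 401)
  circ <- data.frame(t = seq_along(th), body_x = 10 * cos(th),
                     body_y = 10 * sin(th))
  ta <- turnAngleDistribution(circ)
  expect_lt(diff(range(ta)), 1e-6)
  expect_equal(abs(ta[1L]), 360 / 200, tolerance = 1e-6)

  set.seed(1)
  straightish <- data.frame(t = tv, body_x = tv * 5 +
                              stats::rnorm(length(tv), 0, 0.05),
                            body_y = stats::rnorm(length(tv), 0, 0.05))
  circling <- data.frame(t = seq_along(th),
                         body_x = 10 * cos(th) + stats::rnorm(401, 0, 0.05),
                         body_y = 10 * sin(th) + stats::rnorm(401, 0, 0.05))
  p <- suppressWarnings(stats::ks.test(
    turnAngleDistribution(straightish, 0.05),
    turnAngleDistribution(circling, 0.05))$p.value)
  expect_lt(p, 0.01)
})
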