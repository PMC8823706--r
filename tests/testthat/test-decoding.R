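test_that("pseudo-population construction preserves label marginals", {
  set.seed(1)
  pool <- lapply(1:15, function(i)
    list(rates = list(CW = stats::rnorm(12, 5), CCW = stats::rnorm(12, 5))))
  tm <- buildPseudopopulation(pool, 10, seed = 2)
  expect_identical(dim(tm$rates), c(10L, 20L))
  expect_true(all(table(tm$labels) == 10))
  tm2 <- buildPseudopopulation(pool, 10, seed = 2)
  expect_identical(tm$rates, tm2$rates)

  # without replacement at pool size: every unit appears exactly once
  tmA <- buildPseudopopulation(pool, 15, seed = 3, replace = FALSE)
  cwMeans <- round(rowMeans(tmA$rates[, tmA$labels == "CW"]), 6)
  expect_identical(length(unique(cwMeans)), 15L)

  short <- c(pool, list(list(rates = list(CW = stats::rnorm(5),
                                          CCW = stats::rnorm(12)))))
  expect_warning(buildPseudopopulation(short, 5, seed = 4), "excluding")
})

test_that("a linearly separable toy population decodes perfectly", {
  pool <- lapply(1:4, function(i)
    list(rates = list(CW = 10 + stats::runif(10, 0, 0.1),
                      CCW = 2 + stats::runif(10, 0, 0.1))))
  tm <- buildPseudopopulation(pool, 2, seed = 5)
  res <- ldaDecode(tm)
  expect_equal(res$accuracy, 1)
  expect_identical(res$nTrials, 20L)
})

test_that("shrinkage LDA agrees with MASS::lda when well conditioned", {
  skip_if_not_installed("MASS")
  set.seed(6)
  pool <- lapply(1:3, function(i)
    list(rates = list(CW = stats::rnorm(30, 6), CCW = stats::rnorm(30, 4))))
  tm <- buildPseudopopulation(pool, 3, seed = 7, nPerClass = 30)
  mine <- ldaDecode(tm)
  x <- t(tm$rates)
  ref <- MASS::lda(x, grouping = tm$labels)
  refPred <- as.character(stats::predict(ref, x)$class)
  # resubstitution predictions from the full-data fit largely agree with
  # cross-validated shrinkage-LDA predictions on separable data
  expect_gt(mean(refPred == mine$predictions), 0.85)
})

test_that("decoding is at chance for label-shuffled populations", {
  accs <- vapply(1:6, function(s) {
    set.seed(100 + s)
    pool <- lapply(1:20, function(i)
      list(rates = list(CW = stats::rnorm(10, 5),
                        CCW = stats::rnorm(10, 5))))
    ldaDecode(buildPseudopopulation(pool, 15, seed = s))$accuracy
  }, numeric(1))
  n <- 6 * 20
  expect_lt(abs(mean(accs) - 0.5), 3 * sqrt(0.25 / n) + 0.02)
})

test_that("grouped binary decoders cover the multiclass label set", {
  set.seed(11)
  pool <- lapply(1:10, function(i) list(rates = list(
    CW_dark = stats::rnorm(10, 8), CCW_dark = stats::rnorm(10, 4),
    CW_vis = stats::rnorm(10, 9), CCW_vis = stats::rnorm(10, 3))))
  tm <- buildPseudopopulation(pool, 8, seed = 12)
  g <- c(CW_dark = "dark", CCW_dark = "dark",
         CW_vis = "vis", CCW_vis = "vis")
  r <- ldaDecode(tm, groupBy = g)
  expect_identical(length(r$predictions), length(tm$labels))
  expect_gt(r$accuracy, 0.9)
  # within-group predictions never leak labels from another group
  expect_true(all(g[r$predictions] == g[tm$labels]))
})

test_that("bootstrap curves are seed-deterministic", {
  set.seed(8)
  pool <- lapply(1:12, function(i)
    list(rates = list(CW = stats::rnorm(10, 7),
                      CCW = stats::rnorm(10, 5))))
  b1 <- bootstrapDecoding(pool, c(4, 8), nBoot = 3, seed = 9)
  b2 <- bootstrapDecoding(pool, c(4, 8), nBoot = 3, seed = 9)
  expect_identical(b1, b2)
  expect_identical(b1$n_neurons, c(4L, 8L))
})

test_that("simultaneous decoding enforces minimum population sizes", {
  set.seed(10)
  mk <- function(n) {
    pool <- lapply(seq_len(n), function(i)
      list(rates = list(CW = stats::rnorm(10, 6),
                        CCW = stats::rnorm(10, 5))))
    tm <- buildPseudopopulation(pool, n, seed = 1, replace = FALSE)
    tm$provenance <- "real-simultaneous"
    tm
  }
  sessions <- list(small = mk(9), ok = mk(10))
  res <- simultaneousDecode(sessions, "direction")
  expect_identical(res$excluded, "small")
  expect_identical(names(res$results), "ok")
})
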