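# Cached synthetic fixtures shared across test files (built once per run).

.fixtures <- new.env(parent = emptyenv())

cachedKin <- function(duration = 300, seed = 11, ...) {
  key <- paste("kin", duration, seed, sep = "_")
  if (is.null(.fixtures[[key]])) {
    tr <- simulateTrajectory(duration, seed = seed, ...)
    .fixtures[[key]] <- list(tracking = tr, kin = computeKinematics(tr),
                             truth = attr(tr, "groundTruth"))
  }
  .fixtures[[key]]
}

cachedRotationSession <- function(key = "default", nUnits = 4,
                                  dirGain = 0.06, speedGain = 0.05,
                                  nTrials = 10, seed = 21,
                                  conditions = "vestibular") {
  key <- paste("rot", key, sep = "_")
  if (is.null(.fixtures[[key]])) {
    specs <- lapply(seq_len(nUnits), function(u)
      list(baseline = 5,
           speedGain = stats::setNames(as.list(rep(speedGain,
                                                   length(conditions))),
                                       conditions),
           dirGain = stats::setNames(as.list(rep(dirGain,
                                                 length(conditions))),
                                     conditions)))
    .fixtures[[key]] <- simulateRotationSession(
      specs, nTrials, seed = seed, conditions = conditions)
  }
  .fixtures[[key]]
}

# direction-labelled rate pool from a rotation session (rotation window)
sessionDirectionPool <- function(sess, window = c(3.5, 7)) {
  tv <- sess$trials
  lapply(sess$spikes, function(sp) list(rates = list(
    CW = trialRates(sp, tv[tv$direction == "CW", ], window),
    CCW = trialRates(sp, tv[tv$direction == "CCW", ], window))))
}

# brute-force AUC by pair counting (independent oracle)
bruteAUC <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# brute-force CCG by double loop (independent oracle)
bruteCCG <- function(ta, tb, binMs = 0.5, maxLagMs = 50) {
  edges <- seq(-maxLagMs - binMs / 2, maxLagMs + binMs / 2, by = binMs)
  counts <- numeric(length(edges) - 1L)
  for (a in ta) {
    lag <- (tb - a) * 1000
    lag <- lag[lag >= edges[1L] & lag <= edges[length(edges)]]
    for (l in lag) {
      i <- findInterval(l, edges, rightmost.closed = TRUE)
      counts[i] <- counts[i] + 1
    }
  }
  counts
}

# rigid-rotation tracking table: head turning at a constant clockwise rate
rigidRotationTracking <- function(rateDegS, duration = 30, fps = 40,
                                  theta0 = 90) {
  tv <- seq(0, duration, by = 1 / fps)
  th <- (theta0 - rateDegS * tv) * pi / 180  # heading, math convention
  d <- 1
  data.frame(t = tv,
             left_x = -d * sin(th), left_y = d * cos(th),
             right_x = d * sin(th), right_y = -d * cos(th),
             body_x = 0, body_y = 0, interpolated = FALSE)
}
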