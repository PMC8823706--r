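# Single-cell discrimination: rectified ROC AUCs with DeLong confidence
# intervals for rotation speed and direction.

#' AUC with DeLong confidence interval
#'
#' Mid-rank (Mann-Whitney) AUC for \code{pos} versus \code{neg} samples
#' with the DeLong variance estimate and a normal-approximation CI
#' clipped to [0, 1]. When every value is tied the variance is zero and
#' the degenerate CI is flagged.
#'
#' @param pos,neg numeric samples (>= 2 each).
#' @param level confidence level (default 0.99).
#' @return list(auc, low, high, degenerate).
#' @export
delongCI <- function(pos, neg, level = 0.99) {
  if (length(pos) < 2L || length(neg) < 2L)
    stopf("need >= 2 samples per class")
  auc <- rankAUC(pos, neg)
  if (stats::sd(c(pos, neg)) == 0)
    return(list(auc = auc, low = auc, high = auc, degenerate = TRUE))
  r <- pROC::roc(response = c(rep(1L, length(pos)), rep(0L, length(neg))),
                 predictor = c(pos, neg), levels = c(0L, 1L),
                 direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(
    pROC::ci.auc(r, conf.level = level, method = "delong")))
  list(auc = auc, low = max(ci[1L], 0), high = min(ci[3L], 1),
       degenerate = FALSE)
}

# one rectified ROC comparison
rocComparison <- function(pos, neg, label, level = 0.99, window = NA_real_) {
  d <- delongCI(pos, neg, level)
  rect <- d$auc >= 0.5
  aucR <- max(d$auc, 1 - d$auc)
  lowR <- if (rect) d$low else 1 - d$high
  highR <- if (rect) d$high else 1 - d$low
  structure(list(comparison = label, auc = d$auc, aucRectified = aucR,
                 ciLow = d$low, ciHigh = d$high,
                 ciLowRectified = lowR, ciHighRectified = highR,
                 significant = !d$degenerate && is.finite(lowR) &&
                   lowR > 0.5,
                 degenerate = d$degenerate, window = window),
            class = "ROCResult")
}

#' Per-trial firing rates by rotation-speed bin
#'
#' For each trial, the firing rate (spike count over dwell time) within
#' each 5-deg/s bin of absolute rotation velocity. Column names give the
#' bin's peak speed (5, 10, ..., 80 deg/s).
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param trials trial table.
#' @param profiles named profile list.
#' @param binWidth bin width, deg/s.
#' @param maxSpeed maximum speed, deg/s.
#' @return trials x bins numeric matrix (NA where a bin was not visited).
#' @export
speedBinRates <- function(spikes, trials, profiles, binWidth = 5,
                          maxSpeed = 80) {
  edges <- seq(0, maxSpeed, by = binWidth)
  nb <- length(edges) - 1L
  times <- spikeTimes(spikes)
  out <- matrix(NA_real_, nrow(trials), nb,
                dimnames = list(NULL, edges[-1L]))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    pr <- profiles[[tr$profile_id]]
    pt <- profileTime(pr); dt <- stats::median(diff(pt))
    sp <- abs(profileVelocity(pr))
    bi <- findInterval(sp, edges, rightmost.closed = TRUE)
    okb <- bi >= 1L & bi <= nb
    dwell <- tabulate(bi[okb], nbins = nb) * dt
    st <- times[times >= tr$t_onset & times < tr$t_offset]
    cnt <- numeric(nb)
    if (length(st)) {
      sv <- abs(trialVelocity(st, tr, profiles))
      sb <- findInterval(sv, edges, rightmost.closed = TRUE)
      cnt <- tabulate(sb[sb >= 1L & sb <= nb], nbins = nb)
    }
    out[i, dwell > 0] <- cnt[dwell > 0] / dwell[dwell > 0]
  }
  out
}

#' Speed-discrimination ROC curves for one unit
#'
#' Compares the per-trial firing-rate distribution of the speed bin
#' peaking at 10 deg/s against each successive bin (peaks 15 to 80
#' deg/s; 14 comparisons), each with a rectified AUC and a 99% DeLong
#' CI. A comparison is significant when the rectified CI lower bound
#' exceeds 0.5; empty bins are skipped (recorded with NA).
#'
#' @param rateMatrix trials x speed-bin matrix from [speedBinRates()].
#' @param refPeak reference bin peak speed, deg/s (default 10).
#' @param level CI level (default 0.99).
#' @return list of \code{"ROCResult"} (named \code{"10_vs_15"} ...);
#'   attribute \code{"skipped"} lists comparisons with empty bins.
#' @export
speedROC <- function(rateMatrix, refPeak = 10, level = 0.99) {
  peaks <- as.numeric(colnames(rateMatrix))
  ref <- rateMatrix[, which(peaks == refPeak)]
  targets <- peaks[peaks > refPeak]
  out <- list(); skipped <- character(0)
  for (pk in targets) {
    lab <- sprintf("%g_vs_%g", refPeak, pk)
    cmp <- rateMatrix[, which(peaks == pk)]
    ok <- is.finite(ref) & is.finite(cmp)
    if (sum(ok) < 2L || stats::sd(c(ref[ok], cmp[ok])) == 0 &&
        length(unique(c(ref[ok], cmp[ok]))) == 0L) {
      skipped <- c(skipped, lab)
      next
    }
    out[[lab]] <- rocComparison(cmp[ok], ref[ok], lab, level)
  }
  attr(out, "skipped") <- skipped
  out
}

#' Direction-discrimination ROC for one unit
#'
#' Compares CW versus CCW trial firing rates. The sinusoidal stimulus
#' moves in its labelled direction only during the initial half-cycle,
#' so the \code{"full"} rotation window is that half-cycle (3.5 s for
#' the 7-s stimulus); \code{"onset"} uses the first 500 ms.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param trials trial table.
#' @param window \code{"full"} (entire rotation window) or \code{"onset"}
#'   (first 500 ms of the rotation).
#' @param rotationOnsetS start of the directional rotation relative to
#'   trial onset (the entry-ramp duration; 3.5 s for the default
#'   stimulus).
#' @param rotationWindowS length of the full rotation window, seconds.
#' @param level CI level.
#' @return A \code{"ROCResult"}.
#' @export
directionROC <- function(spikes, trials, window = c("full", "onset"),
                         rotationOnsetS = 3.5, rotationWindowS = 3.5,
                         level = 0.99) {
  window <- match.arg(window)
  win <- rotationOnsetS + (if (window == "onset") c(0, 0.5)
                           else c(0, rotationWindowS))
  cw <- trialRates(spikes, trials[trials$direction == "CW", ], win)
  ccw <- trialRates(spikes, trials[trials$direction == "CCW", ], win)
  rocComparison(cw, ccw, "CW_vs_CCW", level,
                window = if (window == "onset") 0.5 else rotationWindowS)
}
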