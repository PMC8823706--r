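# Head-fixed rotation analysis: velocity tuning with bin-shuffle nulls,
# evoked-response statistics, direction selectivity, active/passive tuning
# comparison, rate heatmaps and pupil event analysis.

#' Per-trial firing rates
#'
#' Mean firing rate of one unit within a window of each trial.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param trials trial table with \code{t_onset}, \code{t_offset}.
#' @param window numeric(2), seconds relative to trial onset (default the
#'   whole trial).
#' @return Numeric vector, Hz, one entry per trial row.
#' @export
trialRates <- function(spikes, trials, window = NULL) {
  times <- spikeTimes(spikes)
  vapply(seq_len(nrow(trials)), function(i) {
    a <- trials$t_onset[i]; b <- trials$t_offset[i]
    if (!is.null(window)) { b <- min(b, a + window[2L]); a <- a + window[1L] }
    sum(times >= a & times < b) / (b - a)
  }, numeric(1))
}

# signed stimulus velocity at given times within a trial
trialVelocity <- function(tt, trial, profiles) {
  pr <- profiles[[trial$profile_id]]
  stats::approx(profileTime(pr), profileVelocity(pr), xout = tt - trial$t_onset,
                rule = 2)$y
}

#' Rotation-velocity tuning of one unit
#'
#' Trial-averaged firing rate as a function of signed rotation velocity
#' (5 deg/s bins over +-80 deg/s): total spikes in each velocity bin over
#' all trials divided by the total dwell time. CW and CCW velocity scores
#' are the |Pearson r| between binned rate and velocity on the positive
#' and negative sides; each is compared with the 95th percentile of a
#' null obtained by shuffling the rates across velocity bins.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param trials trial table (rows to analyse; filter by condition first).
#' @param profiles named list of \linkS4class{VelocityProfile} keyed by
#'   \code{profile_id}.
#' @param binWidth bin width, deg/s.
#' @param maxSpeed velocity range bound, deg/s.
#' @param nPerm bin-shuffle permutations (default 1000).
#' @param seed RNG seed.
#' @return list of class \code{"RotationTuningResult"}: curve
#'   (\code{bin_center, occupancy, count, rate}), \code{scoreCW},
#'   \code{scoreCCW}, null 95th percentiles and
#'   \code{isVelocityModulated}.
#' @export
rotationTuning <- function(spikes, trials, profiles, binWidth = 5,
                           maxSpeed = 80, nPerm = 1000, seed = 1) {
  edges <- seq(-maxSpeed, maxSpeed, by = binWidth)
  nb <- length(edges) - 1L
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  occ <- numeric(nb); cnt <- numeric(nb)
  times <- spikeTimes(spikes)
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    pr <- profiles[[tr$profile_id]]
    pt <- profileTime(pr); dt <- stats::median(diff(pt))
    v <- profileVelocity(pr)
    bi <- findInterval(v, edges, rightmost.closed = TRUE)
    okb <- bi >= 1L & bi <= nb
    occ <- occ + tabulate(bi[okb], nbins = nb) * dt
    st <- times[times >= tr$t_onset & times < tr$t_offset]
    if (length(st)) {
      sv <- trialVelocity(st, tr, profiles)
      sb <- findInterval(sv, edges, rightmost.closed = TRUE)
      cnt <- cnt + tabulate(sb[sb >= 1L & sb <= nb], nbins = nb)
    }
  }
  rate <- ifelse(occ > 0, cnt / occ, NA_real_)
  curve <- data.frame(bin_center = centers, occupancy = occ, count = cnt,
                      rate = rate)
  sideScore <- function(r) {
    cw <- centers > 0 & occ > 0
    ccw <- centers < 0 & occ > 0
    c(cw = abs(safeCor(r[cw], centers[cw])),
      ccw = abs(safeCor(r[ccw], abs(centers[ccw]))))
  }
  obs <- sideScore(rate)
  set.seed(seed)
  vis <- which(occ > 0)
  null <- t(vapply(seq_len(nPerm), function(p) {
    r <- rate
    r[vis] <- r[vis][sample.int(length(vis))]
    sideScore(r)
  }, numeric(2)))
  n95 <- apply(null, 2L, stats::quantile, probs = 0.95, na.rm = TRUE)
  # cell-level threshold from the per-permutation maximum score (5%
  # calibrated test of "either velocity score exceeds the null")
  thr <- stats::quantile(pmax(null[, 1L], null[, 2L], na.rm = TRUE),
                         0.95, na.rm = TRUE, names = FALSE)
  structure(list(unitId = unitId(spikes), curve = curve,
                 scoreCW = obs[["cw"]], scoreCCW = obs[["ccw"]],
                 null95CW = n95[["cw"]], null95CCW = n95[["ccw"]],
                 null95Max = thr,
                 isVelocityModulated =
                   (!is.na(obs[["cw"]]) && obs[["cw"]] > thr) ||
                   (!is.na(obs[["ccw"]]) && obs[["ccw"]] > thr)),
            class = "RotationTuningResult")
}

#' Rotation-evoked response of one unit
#'
#' Compares trial firing rates during rotation with the immediately
#' preceding stationary period of the same duration (paired Wilcoxon
#' signed-rank test), and reports the rotation modulation index
#' \code{|Rrot - Rbase| / Rbase} computed from trial-averaged rates
#' (undefined and flagged when the baseline rate is 0).
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param trials trial table.
#' @param direction \code{"CW"} or \code{"CCW"} (rows with this direction
#'   label are analysed).
#' @return list of class \code{"EvokedResponse"}: \code{rateRot},
#'   \code{rateBase}, \code{pValue}, \code{modulationIndex},
#'   \code{undefined}, \code{direction}.
#' @export
evokedResponse <- function(spikes, trials, direction = "CW") {
  tr <- trials[trials$direction == direction, , drop = FALSE]
  if (!nrow(tr)) stopf("no trials with direction %s", direction)
  dur <- tr$t_offset - tr$t_onset
  rot <- trialRates(spikes, tr)
  baseTr <- data.frame(t_onset = tr$t_onset - dur, t_offset = tr$t_onset)
  base <- trialRates(spikes, baseTr)
  p <- tryCatch(stats::wilcox.test(rot, base, paired = TRUE,
                                   exact = FALSE)$p.value,
                error = function(e) NA_real_)
  rBar <- mean(rot); bBar <- mean(base)
  undef <- bBar == 0
  structure(list(unitId = unitId(spikes), rateRot = rBar, rateBase = bBar,
                 trialRatesRot = rot, trialRatesBase = base, pValue = p,
                 modulationIndex = if (undef) NA_real_ else
                   abs(rBar - bBar) / bBar,
                 undefined = undef, direction = direction),
            class = "EvokedResponse")
}

#' Direction-selectivity index
#'
#' Area under the ROC curve comparing the distributions of CW and CCW
#' trial firing rates (mid-rank convention). Values range over [0, 1] and
#' are not rectified: 0.5 means no selectivity.
#'
#' @param ratesCW,ratesCCW per-trial firing rates, Hz.
#' @return list of class \code{"DirectionSelectivity"} with \code{auc}.
#' @export
directionSelectivity <- function(ratesCW, ratesCCW) {
  if (length(ratesCW) < 2L || length(ratesCCW) < 2L)
    stopf("need at least 2 trials per direction")
  structure(list(auc = rankAUC(ratesCW, ratesCCW),
                 nCW = length(ratesCW), nCCW = length(ratesCCW)),
            class = "DirectionSelectivity")
}

#' Compare active (open-field) and passive (rotation) velocity tuning
#'
#' The active AHV tuning curve (6 deg/s grid) is linearly interpolated
#' onto the passive 5 deg/s bin centers within the overlapping velocity
#' range, and the Pearson correlation between the matched rates is
#' compared with the 95th percentile of a null obtained by shuffling the
#' active rates across bins (1000 permutations). A flat curve on either
#' side leaves r undefined and the cell not similarly tuned (flagged).
#'
#' @param ahvResult an \code{"AHVTuningResult"} from [classifyAHV()].
#' @param rotResult a \code{"RotationTuningResult"} from
#'   [rotationTuning()].
#' @param nPerm permutations.
#' @param seed RNG seed.
#' @param method \code{"interp"} (linear interpolation, default) or
#'   \code{"nearest"} bin matching.
#' @return list of class \code{"ActivePassiveComparison"}: matched rate
#'   pairs, \code{r}, \code{null95}, \code{similar}, \code{undefined}.
#' @export
compareActivePassive <- function(ahvResult, rotResult, nPerm = 1000,
                                 seed = 1, method = c("interp", "nearest")) {
  method <- match.arg(method)
  ac <- ahvResult$curve; pc <- rotResult$curve
  aSel <- ac$occupancy > 0 & !is.na(ac$rate)
  pSel <- pc$occupancy > 0 & !is.na(pc$rate)
  lo <- max(min(ac$bin_center[aSel]), min(pc$bin_center[pSel]))
  hi <- min(max(ac$bin_center[aSel]), max(pc$bin_center[pSel]))
  tgt <- pc$bin_center[pSel & pc$bin_center >= lo & pc$bin_center <= hi]
  passive <- pc$rate[match(tgt, pc$bin_center)]
  mapActive <- function(rates) {
    if (method == "interp")
      stats::approx(ac$bin_center[aSel], rates[aSel], xout = tgt, rule = 1)$y
    else rates[aSel][vapply(tgt, function(v)
      which.min(abs(ac$bin_center[aSel] - v)), integer(1))]
  }
  active <- mapActive(ac$rate)
  r <- safeCor(active, passive)
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(p) {
    sh <- ac$rate
    sh[aSel] <- sh[aSel][sample.int(sum(aSel))]
    safeCor(mapActive(sh), passive)
  }, numeric(1))
  n95 <- stats::quantile(null, 0.95, na.rm = TRUE, names = FALSE)
  undef <- is.na(r)
  structure(list(unitId = ahvResult$unitId, active = active,
                 passive = passive, binCenters = tgt, r = r, null95 = n95,
                 similar = !undef && r > n95, undefined = undef),
            class = "ActivePassiveComparison")
}

#' Normalised, baseline-subtracted rate heatmap
#'
#' Builds per-unit display rows: the trial-averaged firing rate binned
#' either in time (200-ms bins) or rotation speed (5 deg/s bins, CW and
#' CCW as consecutive rows), normalised to the peak rate, with the median
#' (normalised) rate of the preceding stationary period subtracted. Rows
#' are ordered by direction-selectivity AUC (temporal) or mean speed
#' correlation (speed).
#'
#' @param spikesList named list of \linkS4class{SpikeTrain}.
#' @param trials trial table.
#' @param profiles named profile list.
#' @param type \code{"speed"} or \code{"temporal"}.
#' @param binWidth deg/s (speed) or seconds (temporal).
#' @return A numeric matrix with informative dimnames, ordered rows, and
#'   a \code{"sortKey"} attribute.
#' @export
buildRateHeatmap <- function(spikesList, trials, profiles,
                             type = c("speed", "temporal"),
                             binWidth = if (type[1L] == "speed") 5 else 0.2) {
  type <- match.arg(type)
  dur <- max(trials$t_offset - trials$t_onset)
  rows <- list(); key <- numeric(0)
  for (id in names(spikesList)) {
    sp <- spikesList[[id]]
    times <- spikeTimes(sp)
    baseTr <- data.frame(t_onset = trials$t_onset - (trials$t_offset -
                                                       trials$t_onset),
                         t_offset = trials$t_onset)
    baseMed <- stats::median(trialRates(sp, baseTr))
    if (type == "temporal") {
      edges <- seq(0, dur, by = binWidth)
      nb <- length(edges) - 1L
      acc <- matrix(0, nrow(trials), nb)
      for (i in seq_len(nrow(trials))) {
        st <- times[times >= trials$t_onset[i] & times < trials$t_offset[i]] -
          trials$t_onset[i]
        acc[i, ] <- tabulate(findInterval(st, edges,
                                          rightmost.closed = TRUE),
                             nbins = nb) / binWidth
      }
      row <- colMeans(acc)
      pk <- max(row)
      row <- if (pk > 0) row / pk else row
      rows[[id]] <- row - (if (pk > 0) baseMed / pk else baseMed)
      cw <- trials$direction == "CW"
      key[id] <- rankAUC(trialRates(sp, trials[cw, ]),
                         trialRates(sp, trials[!cw, ]))
    } else {
      rt <- rotationTuning(sp, trials, profiles, binWidth = binWidth,
                           nPerm = 2, seed = 1)
      cv <- rt$curve
      neg <- cv$bin_center < 0; pos <- cv$bin_center > 0
      mk <- function(sel, rev = FALSE) {
        r <- cv$rate[sel]
        if (rev) r <- rev(r)
        r
      }
      both <- c(mk(pos), mk(neg, rev = TRUE))
      pk <- max(both, na.rm = TRUE)
      sc <- function(r) {
        r <- if (pk > 0) r / pk else r
        r - (if (pk > 0) baseMed / pk else baseMed)
      }
      rows[[paste0(id, "_CW")]] <- sc(mk(pos))
      rows[[paste0(id, "_CCW")]] <- sc(mk(neg, rev = TRUE))
      key[id] <- mean(c(rt$scoreCW, rt$scoreCCW), na.rm = TRUE)
    }
  }
  m <- do.call(rbind, rows)
  ord <- order(key, decreasing = TRUE)
  units <- names(key)[ord]
  rowSel <- if (type == "temporal") units
  else as.vector(rbind(paste0(units, "_CW"), paste0(units, "_CCW")))
  m <- m[rowSel, , drop = FALSE]
  attr(m, "sortKey") <- key[ord]
  m
}

#' Detect rapid eye-movement events in a pupil-position trace
#'
#' Pupil velocity is the central derivative of horizontal position,
#' median-filtered (50-ms window); samples exceeding the outlier cut-off
#' are removed, low-frequency fluctuations are subtracted with lowess
#' smoothing (span 0.01), and events are runs where the residual velocity
#' magnitude exceeds \code{threshSd} times its SD. Direction is taken
#' from the velocity sign (positive = nasal).
#'
#' @param pupilX horizontal pupil position, mm.
#' @param fs sampling rate, Hz (default 40).
#' @param outlierCut velocity outlier threshold, mm/s (default 20).
#' @param span lowess span (default 0.01).
#' @param threshSd detection threshold in residual SDs (default 2.5).
#' @param medianMs median-filter width, ms.
#' @return list of class \code{"EyeEventSeries"}: \code{events}
#'   data.frame (\code{t_onset, t_peak, direction, amplitude}), the
#'   residual-velocity trace and its SD.
#' @export
detectEyeEvents <- function(pupilX, fs = 40, outlierCut = 20, span = 0.01,
                            threshSd = 2.5, medianMs = 50) {
  n <- length(pupilX)
  if (n * span < 2) stopf("trace shorter than the lowess span")
  dt <- 1 / fs
  v <- c(0, (pupilX[-(1:2)] - pupilX[seq_len(n - 2L)]) / (2 * dt), 0)
  k <- round(medianMs / 1000 * fs)
  if (k %% 2 == 0) k <- k + 1L
  v <- as.numeric(stats::runmed(v, max(k, 1L)))
  out <- abs(v) > outlierCut
  if (any(out)) {
    good <- which(!out)
    v[out] <- stats::approx(good, v[good], xout = which(out), rule = 2)$y
  }
  tv <- (seq_len(n) - 1L) * dt
  trend <- stats::lowess(tv, v, f = span)$y
  resid <- v - trend
  s <- stats::sd(resid)
  hot <- abs(resid) > threshSd * s
  events <- data.frame(t_onset = numeric(0), t_peak = numeric(0),
                       direction = character(0), amplitude = numeric(0),
                       stringsAsFactors = FALSE)
  if (any(hot)) {
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (g in which(r$values)) {
      idx <- starts[g]:ends[g]
      pk <- idx[which.max(abs(resid[idx]))]
      events[nrow(events) + 1L, ] <- list(
        tv[idx[1L]], tv[pk],
        if (resid[pk] > 0) "nasal" else "temporal", abs(resid[pk]))
    }
  }
  structure(list(events = events, residual = resid, sd = s, fs = fs),
            class = "EyeEventSeries")
}

#' Eye-movement modulation of one unit
#'
#' Counts spikes around each eye-movement event (default 75 ms before to
#' 250 ms after onset), builds 25-ms average rate histograms per
#' direction, and flags the unit as modulated if its per-event firing
#' rate is significantly correlated (Pearson test) with event amplitude
#' in either direction.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param events an \code{"EyeEventSeries"}.
#' @param window numeric(2), seconds around event onset.
#' @param binMs histogram bin width, ms.
#' @param alpha significance level (default 0.05).
#' @return list: per-direction r, p, histograms, \code{modulated},
#'   \code{undefined} (no events).
#' @export
eyeModulation <- function(spikes, events, window = c(-0.075, 0.25),
                          binMs = 25, alpha = 0.05) {
  ev <- events$events
  if (!nrow(ev))
    return(list(unitId = unitId(spikes), modulated = FALSE,
                undefined = TRUE))
  times <- spikeTimes(spikes)
  winDur <- diff(window)
  edges <- seq(window[1L], window[2L], by = binMs / 1000)
  res <- list()
  for (d in c("nasal", "temporal")) {
    sub <- ev[ev$direction == d, , drop = FALSE]
    if (nrow(sub) < 3L) {
      res[[d]] <- list(r = NA_real_, p = NA_real_, n = nrow(sub))
      next
    }
    rates <- vapply(sub$t_onset, function(t0)
      sum(times >= t0 + window[1L] & times < t0 + window[2L]) / winDur,
      numeric(1))
    hist <- rowMeans(vapply(sub$t_onset, function(t0) {
      rel <- times[times >= t0 + window[1L] & times < t0 + window[2L]] - t0
      tabulate(findInterval(rel, edges, rightmost.closed = TRUE),
               nbins = length(edges) - 1L) / (binMs / 1000)
    }, numeric(length(edges) - 1L)))
    ct <- tryCatch(stats::cor.test(rates, sub$amplitude),
                   error = function(e) list(estimate = NA, p.value = NA))
    res[[d]] <- list(r = unname(ct$estimate), p = ct$p.value,
                     n = nrow(sub), hist = hist)
  }
  ps <- vapply(res, function(x) x$p, numeric(1))
  list(unitId = unitId(spikes), byDirection = res,
       modulated = any(!is.na(ps) & ps < alpha), undefined = FALSE)
}
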