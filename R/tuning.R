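# Open-field tuning classification: occupancy-weighted tuning curves,
# spike-time-shift permutation nulls, HD/AHV/speed labels, stability and
# theta indices.

# default bin edges; the AHV grid keeps whole bins inside [-maxAHV, maxAHV]
ahvBinEdges <- function(maxAHV = 80, width = 6) {
  half <- floor(maxAHV / width) * width
  seq(-half, half, by = width)
}
speedBinEdges <- function(maxSpeed = 20, width = 1) seq(0, maxSpeed, by = width)
hdBinEdges <- function(width = 6) seq(0, 360, by = width)

#' Occupancy-weighted tuning curve
#'
#' Bins a frame-wise covariate, accumulates dwell time and spike counts per
#' bin, and returns the rate as total spikes over total time per bin. Bins
#' with zero occupancy have rate NA (they are excluded from correlations,
#' never zero-filled).
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param kin a \linkS4class{KinematicSeries}.
#' @param variable frame-wise covariate: \code{"ahv"}, \code{"speed"} or
#'   \code{"hd"}.
#' @param binEdges bin edges (defaults: 6 deg/s over +-80, 1 cm/s up to 20,
#'   6 deg over the circle).
#' @param include optional logical frame mask.
#' @return data.frame \code{bin_center, occupancy, count, rate}.
#' @export
tuningCurve <- function(spikes, kin, variable = c("ahv", "speed", "hd"),
                        binEdges = NULL, include = NULL) {
  variable <- match.arg(variable)
  ctx <- frameContext(kin, variable, binEdges, include)
  counts <- countsPerFrame(spikeTimes(spikes), ctx$t0, ctx$dt, ctx$nFrames)
  curveFromCounts(ctx, counts)
}

# precompute the frame->bin mapping used by curves and permutation nulls
frameContext <- function(kin, variable, binEdges = NULL, include = NULL) {
  tv <- frameTimes(kin)
  dt <- stats::median(diff(tv))
  vals <- switch(variable,
                 ahv = ahv(kin), speed = speed(kin),
                 hd = headDirection(kin))
  if (is.null(binEdges))
    binEdges <- switch(variable, ahv = ahvBinEdges(),
                       speed = speedBinEdges(), hd = hdBinEdges())
  ok <- !is.na(vals) & vals >= binEdges[1L] & vals <= binEdges[length(binEdges)]
  if (!is.null(include)) ok <- ok & include
  idx <- findInterval(vals, binEdges, rightmost.closed = TRUE)
  idx[!ok] <- NA_integer_
  nb <- length(binEdges) - 1L
  occ <- tabulate(idx[ok], nbins = nb) * dt
  list(t0 = tv[1L], dt = dt, nFrames = length(tv), binIdx = idx, ok = ok,
       nBins = nb, centers = (binEdges[-1L] + binEdges[-length(binEdges)]) / 2,
       occupancy = occ,
       duration = tv[length(tv)] - tv[1L] + dt)
}

curveFromCounts <- function(ctx, counts) {
  cnt <- numeric(ctx$nBins)
  sel <- ctx$ok & counts > 0
  if (any(sel)) {
    agg <- rowsum(counts[sel], ctx$binIdx[sel])
    cnt[as.integer(rownames(agg))] <- agg[, 1L]
  }
  rate <- ifelse(ctx$occupancy > 0, cnt / ctx$occupancy, NA_real_)
  data.frame(bin_center = ctx$centers, occupancy = ctx$occupancy,
             count = cnt, rate = rate)
}

# AHV statistics from a curve: |r| and slope per turn direction. Bins
# with less than minOcc seconds of dwell are excluded from correlations
# and fits: their rate estimates are dominated by counting noise.
ahvStats <- function(curve, minOcc = 1) {
  right <- curve$bin_center > 0 & curve$occupancy >= minOcc
  left <- curve$bin_center < 0 & curve$occupancy >= minOcc
  rR <- safeCor(curve$rate[right], curve$bin_center[right])
  rL <- safeCor(curve$rate[left], abs(curve$bin_center[left]))
  slopeOf <- function(sel, x) {
    if (sum(sel) < 3L) return(NA_real_)
    stats::coef(stats::lm(curve$rate[sel] ~ x))[2L]
  }
  c(scoreRight = abs(rR), scoreLeft = abs(rL),
    signRight = sign(rR), signLeft = sign(rL),
    slopeRight = unname(slopeOf(right, curve$bin_center[right])),
    slopeLeft = unname(slopeOf(left, abs(curve$bin_center[left]))))
}

# mean Rayleigh vector length of a binned rate vector (rate-weighted)
hdVectorLengthRate <- function(rate, centers) {
  sel <- !is.na(rate)
  w <- rate[sel]
  if (!sum(w)) return(NA_real_)
  th <- centers[sel] * pi / 180
  sqrt(sum(w * cos(th))^2 + sum(w * sin(th))^2) / sum(w)
}

hdVectorLength <- function(curve)
  hdVectorLengthRate(ifelse(curve$occupancy > 0, curve$rate, NA_real_),
                     curve$bin_center)

# Rayleigh test p-value (Zar approximation) for vector length R and n obs
rayleighP <- function(R, n) {
  if (is.na(R) || n < 1) return(NA_real_)
  Rn <- n * R
  Z <- Rn^2 / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  min(max(p, 0), 1)
}

#' Spike-time-shift permutation null
#'
#' For each permutation the whole spike sequence is circularly shifted by a
#' uniform random offset between 20 s and the recording duration minus
#' 20 s, and the statistic recomputed on the shifted train. This preserves
#' the spike count and autostructure while breaking the alignment with
#' behaviour.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param statistic function taking a numeric vector of (shifted) spike
#'   times and returning a scalar.
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param duration recording length, seconds (default: last spike time).
#' @return Numeric vector of \code{nPerm} null statistics; permutations on
#'   which the statistic is not finite are NA (warned when > 1% missing).
#' @export
spikeShiftNull <- function(spikes, statistic, nPerm = 1000, seed = 1,
                           duration = NULL) {
  times <- spikeTimes(spikes)
  if (is.null(duration)) duration <- max(times)
  if (duration <= 40) stopf("recording length must exceed 40 s")
  set.seed(seed)
  shifts <- stats::runif(nPerm, 20, duration - 20)
  out <- vapply(shifts, function(s) {
    v <- statistic(sort((times + s) %% duration))
    if (is.finite(v)) v else NA_real_
  }, numeric(1))
  if (mean(is.na(out)) > 0.01)
    warnf("statistic missing on %.1f%% of permutations",
          100 * mean(is.na(out)))
  out
}

# shared fast permutation engine: one circular shift produces one binned
# rate vector from which all requested statistics are computed. statFuns
# receive the bare per-bin rate vector (NA where unoccupied).
tuningNull <- function(spikes, ctx, nPerm, seed, duration, statFuns) {
  times <- spikeTimes(spikes)
  set.seed(seed)
  shifts <- stats::runif(nPerm, 20, duration - 20)
  out <- matrix(NA_real_, nPerm, length(statFuns),
                dimnames = list(NULL, names(statFuns)))
  okIdx <- which(ctx$ok)
  grp <- ctx$binIdx[okIdx]
  occPos <- ctx$occupancy > 0
  rate0 <- rep(NA_real_, ctx$nBins)
  for (p in seq_len(nPerm)) {
    st <- (times + shifts[p]) %% duration
    counts <- countsPerFrame(st, ctx$t0, ctx$dt, ctx$nFrames)
    cnt <- numeric(ctx$nBins)
    csel <- counts[okIdx]
    nz <- csel > 0
    if (any(nz)) {
      agg <- rowsum(csel[nz], grp[nz])
      cnt[as.integer(rownames(agg))] <- agg[, 1L]
    }
    rate <- rate0
    rate[occPos] <- cnt[occPos] / ctx$occupancy[occPos]
    for (j in seq_along(statFuns)) out[p, j] <- statFuns[[j]](rate)
  }
  out
}

#' Classify AHV tuning of one unit
#'
#' Builds the AHV tuning curve (6 deg/s bins over +-80 deg/s; positive =
#' rightward/clockwise turns), computes separate right- and left-turn AHV
#' scores (|Pearson r| between binned firing rate and angular speed) and
#' linear-fit slopes, and compares them with a per-cell spike-shift null.
#' No speed floor is applied. A unit is AHV tuned if either score exceeds
#' the 95th percentile of the null distribution of the cell's AHV score
#' (the per-shuffle maximum of the two sides, so the cell-level test is
#' calibrated at 5%); per-side null percentiles are also reported.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param kin a \linkS4class{KinematicSeries}.
#' @param nPerm permutations for the null (default 1000).
#' @param seed RNG seed.
#' @param maxAHV tuning-curve range, deg/s.
#' @param binWidth bin width, deg/s.
#' @param minOccupancy minimum dwell time (s) for a bin to enter the
#'   correlation and fit; sparser bins carry counting-noise rate
#'   estimates (default 1 s).
#' @return list of class \code{"AHVTuningResult"}: curve, scores, slopes,
#'   null 95th percentiles, \code{isAHV}, \code{subtype}
#'   (unidirectional_right / unidirectional_left / bidirectional / none)
#'   and per-direction correlation signs.
#' @export
classifyAHV <- function(spikes, kin, nPerm = 1000, seed = 1, maxAHV = 80,
                        binWidth = 6, minOccupancy = 1,
                        scoreDomain = c("binned", "framewise")) {
  scoreDomain <- match.arg(scoreDomain)
  if (scoreDomain == "framewise")
    return(classifyAHVFramewise(spikes, kin, nPerm, seed, maxAHV))
  ctx <- frameContext(kin, "ahv", ahvBinEdges(maxAHV, binWidth))
  counts <- countsPerFrame(spikeTimes(spikes), ctx$t0, ctx$dt, ctx$nFrames)
  curve <- curveFromCounts(ctx, counts)
  obs <- ahvStats(curve, minOccupancy)
  # right and left nulls share the same shifted trains
  right <- ctx$centers > 0 & ctx$occupancy >= minOccupancy
  left <- ctx$centers < 0 & ctx$occupancy >= minOccupancy
  cR <- ctx$centers[right]; cL <- abs(ctx$centers[left])
  nulls <- tuningNull(
    spikes, ctx, nPerm, seed, ctx$duration,
    list(right = function(rate) abs(safeCor(rate[right], cR)),
         left = function(rate) abs(safeCor(rate[left], cL))))
  n95R <- stats::quantile(nulls[, "right"], 0.95, na.rm = TRUE, names = FALSE)
  n95L <- stats::quantile(nulls[, "left"], 0.95, na.rm = TRUE, names = FALSE)
  # classification threshold: 95th percentile of the per-shuffle maximum
  # score, so that "either score exceeds the null" is calibrated at 5%
  # for the cell rather than per side
  nullMax <- pmax(nulls[, "right"], nulls[, "left"], na.rm = TRUE)
  thr <- stats::quantile(nullMax, 0.95, na.rm = TRUE, names = FALSE)
  passR <- !is.na(obs[["scoreRight"]]) && obs[["scoreRight"]] > thr
  passL <- !is.na(obs[["scoreLeft"]]) && obs[["scoreLeft"]] > thr
  subtype <- if (passR && passL) "bidirectional"
  else if (passR) "unidirectional_right"
  else if (passL) "unidirectional_left" else "none"
  structure(list(unitId = unitId(spikes), curve = curve,
                 scoreRight = obs[["scoreRight"]],
                 scoreLeft = obs[["scoreLeft"]],
                 slopeRight = obs[["slopeRight"]],
                 slopeLeft = obs[["slopeLeft"]],
                 signRight = obs[["signRight"]],
                 signLeft = obs[["signLeft"]],
                 null95Right = n95R, null95Left = n95L, null95Max = thr,
                 nullRight = nulls[, "right"], nullLeft = nulls[, "left"],
                 isAHV = passR || passL, subtype = subtype),
            class = "AHVTuningResult")
}

#' Classify locomotion-speed tuning of one unit
#'
#' Speed tuning curve at 1 cm/s bins up to 20 cm/s (higher speeds are
#' excluded); the speed score is the |Pearson r| between binned rate and
#' speed, compared with the 95th percentile of a per-cell spike-shift
#' null. Negative-sign tuning is allowed and reported.
#'
#' @inheritParams classifyAHV
#' @param maxSpeed upper speed cut-off, cm/s.
#' @param binWidth bin width, cm/s.
#' @return list of class \code{"SpeedTuningResult"}: curve, score, sign,
#'   null95, null draws, \code{isSpeed}.
#' @export
classifySpeed <- function(spikes, kin, nPerm = 1000, seed = 1,
                          maxSpeed = 20, binWidth = 1, minOccupancy = 1) {
  ctx <- frameContext(kin, "speed", speedBinEdges(maxSpeed, binWidth))
  counts <- countsPerFrame(spikeTimes(spikes), ctx$t0, ctx$dt, ctx$nFrames)
  curve <- curveFromCounts(ctx, counts)
  sel <- curve$occupancy >= minOccupancy
  r <- safeCor(curve$rate[sel], curve$bin_center[sel])
  centers <- ctx$centers[sel]
  nulls <- tuningNull(spikes, ctx, nPerm, seed, ctx$duration,
                      list(speed = function(rate)
                        abs(safeCor(rate[sel], centers))))[, 1L]
  n95 <- stats::quantile(nulls, 0.95, na.rm = TRUE, names = FALSE)
  structure(list(unitId = unitId(spikes), curve = curve, score = abs(r),
                 sign = sign(r), null95 = n95, null = nulls,
                 isSpeed = !is.na(r) && abs(r) > n95),
            class = "SpeedTuningResult")
}

#' Pooled population null for head-direction classification
#'
#' Spike-shift null of the mean Rayleigh vector length pooled over all
#' recorded units (the HD criterion threshold is the 99th percentile of
#' this pooled distribution).
#'
#' @param spikesList list of \linkS4class{SpikeTrain}.
#' @param kin a \linkS4class{KinematicSeries}.
#' @param nPerm permutations per cell (default 1000).
#' @param seed RNG seed.
#' @param speedFloor frames below this locomotion speed (cm/s) are excluded.
#' @return Numeric vector of pooled null vector lengths.
#' @export
populationHDNull <- function(spikesList, kin, nPerm = 1000, seed = 1,
                             speedFloor = 1.5) {
  include <- speed(kin) >= speedFloor
  ctx <- frameContext(kin, "hd", hdBinEdges(), include = include)
  centers <- ctx$centers
  res <- lapply(seq_along(spikesList), function(i)
    tuningNull(spikesList[[i]], ctx, nPerm, childSeed(seed, i),
               ctx$duration,
               list(vl = function(rate)
                 hdVectorLengthRate(rate, centers)))[, 1L])
  unlist(res, use.names = FALSE)
}

#' Classify head-direction tuning of one unit
#'
#' HD tuning curves at 6-degree bins with frames below the locomotion-speed
#' floor excluded. A unit is HD tuned only if, in both recording epochs,
#' (1) the binned firing-rate distribution is non-uniform (Rayleigh p <
#' 0.01) and (2) the mean Rayleigh vector length exceeds the 99th
#' percentile of the pooled population null.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param kin a \linkS4class{KinematicSeries}.
#' @param populationNull pooled null vector lengths from
#'   [populationHDNull()].
#' @param epochs list of two logical frame masks defining the epochs;
#'   \code{NULL} splits the session into halves (recorded in the result as
#'   \code{epochSource = "halves"}).
#' @param speedFloor locomotion-speed floor, cm/s (default 1.5).
#' @param alpha Rayleigh significance level (default 0.01).
#' @return list of class \code{"HDTuningResult"}: per-epoch curves, vector
#'   lengths, Rayleigh p values, pass flags, coverage flags and \code{isHD}.
#' @export
classifyHD <- function(spikes, kin, populationNull, epochs = NULL,
                       speedFloor = 1.5, alpha = 0.01) {
  tv <- frameTimes(kin)
  if (is.null(epochs)) {
    half <- tv <= stats::median(tv)
    epochs <- list(half, !half)
    epochSource <- "halves"
  } else epochSource <- "supplied"
  thr <- stats::quantile(populationNull, 0.99, na.rm = TRUE, names = FALSE)
  fast <- speed(kin) >= speedFloor
  res <- lapply(epochs, function(ep) {
    ctx <- frameContext(kin, "hd", hdBinEdges(), include = ep & fast)
    counts <- countsPerFrame(spikeTimes(spikes), ctx$t0, ctx$dt, ctx$nFrames)
    curve <- curveFromCounts(ctx, counts)
    vl <- hdVectorLength(curve)
    nSpk <- sum(counts[ctx$ok & !is.na(ctx$binIdx)])
    coverage <- mean(curve$occupancy > 0)
    list(curve = curve, vectorLength = vl,
         rayleighP = rayleighP(vl, nSpk),
         unreliable = coverage < 0.5, coverage = coverage)
  })
  passes <- vapply(res, function(e)
    !is.na(e$vectorLength) && !is.na(e$rayleighP) &&
      e$rayleighP < alpha && e$vectorLength > thr, logical(1))
  structure(list(unitId = unitId(spikes), epochs = res,
                 vectorLength = vapply(res, `[[`, numeric(1), "vectorLength"),
                 rayleighP = vapply(res, `[[`, numeric(1), "rayleighP"),
                 passesEpoch = passes, nullThreshold = thr,
                 unreliable = any(vapply(res, `[[`, logical(1), "unreliable")),
                 epochSource = epochSource,
                 isHD = all(passes)),
            class = "HDTuningResult")
}

#' Half-session tuning stability index
#'
#' Pearson correlation between the tuning curves of the two half-sessions,
#' compared against a null in which the spikes of each half are
#' independently circularly shifted (20 s to half duration minus 20 s).
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param kin a \linkS4class{KinematicSeries}.
#' @param modality \code{"ahv"} or \code{"speed"}.
#' @param nPerm shift permutations (default 1000).
#' @param seed RNG seed.
#' @return list of class \code{"StabilityResult"}: \code{rHalves},
#'   \code{null95}, null draws and \code{stable}.
#' @export
stabilityIndex <- function(spikes, kin, modality = c("ahv", "speed"),
                           nPerm = 1000, seed = 1) {
  modality <- match.arg(modality)
  tv <- frameTimes(kin)
  mid <- stats::median(tv)
  ctx1 <- frameContext(kin, modality, include = tv <= mid)
  ctx2 <- frameContext(kin, modality, include = tv > mid)
  times <- spikeTimes(spikes)
  halfCurve <- function(ctx, t) curveFromCounts(
    ctx, countsPerFrame(t, ctx$t0, ctx$dt, ctx$nFrames))
  corCurves <- function(c1, c2) {
    sel <- c1$occupancy >= 0.5 & c2$occupancy >= 0.5
    abs(safeCor(c1$rate[sel], c2$rate[sel]))
  }
  rObs <- corCurves(halfCurve(ctx1, times), halfCurve(ctx2, times))
  t1 <- times[times <= mid]; t2 <- times[times > mid] - mid
  halfDur <- mid - tv[1L]
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(p) {
    s1 <- (t1 + stats::runif(1, 20, halfDur - 20)) %% halfDur
    s2 <- (t2 + stats::runif(1, 20, halfDur - 20)) %% halfDur
    corCurves(halfCurve(ctx1, sort(s1)),
              halfCurve(ctx2, sort(s2) + mid))
  }, numeric(1))
  n95 <- stats::quantile(null, 0.95, na.rm = TRUE, names = FALSE)
  structure(list(unitId = unitId(spikes), rHalves = rObs, null95 = n95,
                 null = null, stable = !is.na(rObs) && rObs > n95),
            class = "StabilityResult")
}

#' Theta-rhythmicity index of a spike train
#'
#' Spike-train autocorrelogram (1-ms bins, +-500 ms) with the zero-lag peak
#' equalised to the maximum of the remaining bins and the mean subtracted;
#' the power spectrum is the squared FFT magnitude after zero-padding to
#' 2^16 samples, smoothed with a 2-Hz mean window. The theta index is the
#' ratio of the 5-11 Hz peak to the mean power between 0 and 50 Hz; a unit
#' is theta-modulated if the index is at least 5.
#'
#' @param spikes a \linkS4class{SpikeTrain} (>= 900 spikes recommended;
#'   fewer produces a warning).
#' @param duration recording length, seconds (default: last spike time).
#' @return list of class \code{"ThetaResult"}: \code{thetaIndex},
#'   \code{thetaPeakHz}, \code{isTheta}, \code{degenerate} flag, and the
#'   processed autocorrelogram.
#' @export
thetaIndex <- function(spikes, duration = NULL) {
  times <- spikeTimes(spikes)
  if (length(times) < 900)
    warnf("theta index computed on %d spikes (< 900)", length(times))
  if (is.null(duration)) duration <- max(times) + 1e-3
  nb <- ceiling(duration * 1000)
  counts <- countsPerFrame(times, 0, 1e-3, nb)
  m <- 2^ceiling(log2(nb + 501))
  f <- stats::fft(c(counts, numeric(m - nb)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE)) / m
  acg <- c(rev(ac[2:501]), ac[1:501])  # lags -500 .. 500 ms
  centre <- 501L
  mx <- max(acg[-centre])
  acg[centre] <- mx
  proc <- acg - mean(acg)
  if (max(abs(proc)) == 0)
    return(structure(list(unitId = unitId(spikes), thetaIndex = NA_real_,
                          thetaPeakHz = NA_real_, isTheta = FALSE,
                          degenerate = TRUE, acg = proc),
                     class = "ThetaResult"))
  nfft <- 2^16
  pw <- Mod(stats::fft(c(proc, numeric(nfft - length(proc)))))^2
  freq <- (seq_len(nfft) - 1L) * (1000 / nfft)
  smoothWidth <- max(1L, round(2 / (1000 / nfft)))
  pwS <- slideMean(pw[freq <= 60], smoothWidth)
  fS <- freq[freq <= 60]
  thetaBand <- fS >= 5 & fS <= 11
  peak <- max(pwS[thetaBand])
  base <- mean(pwS[fS <= 50])
  idx <- if (base > 0) peak / base else NA_real_
  structure(list(unitId = unitId(spikes), thetaIndex = idx,
                 thetaPeakHz = fS[thetaBand][which.max(pwS[thetaBand])],
                 isTheta = !is.na(idx) && idx >= 5, degenerate = FALSE,
                 acg = proc),
            class = "ThetaResult")
}

#' Filter units by mean firing rate
#'
#' Retains units whose whole-session mean rate is at least \code{minRate}
#' Hz (the exclusion rule is "< minRate"); excluded units keep a flag, and
#' both sets are returned so nothing is silently dropped.
#'
#' @param spikesList list of \linkS4class{SpikeTrain}.
#' @param duration session length, seconds.
#' @param minRate exclusion threshold, Hz (default 0.5).
#' @return list(retained, excluded) of SpikeTrain lists.
#' @export
filterAnalysisUnits <- function(spikesList, duration, minRate = 0.5) {
  rates <- vapply(spikesList, function(s) nSpikes(s) / duration, numeric(1))
  keep <- rates >= minRate
  excluded <- lapply(spikesList[!keep], function(s) {
    s@flags <- unique(c(s@flags, "below_min_rate"))
    s
  })
  list(retained = spikesList[keep], excluded = excluded)
}

# frame-wise score domain: correlate per-frame rate with per-frame AHV
# directly instead of through the binned curve (config switch; scores are
# systematically lower because frame noise is not averaged out)
classifyAHVFramewise <- function(spikes, kin, nPerm, seed, maxAHV) {
  tv <- frameTimes(kin)
  dt <- stats::median(diff(tv))
  av <- ahv(kin)
  okR <- !is.na(av) & av > 0 & av <= maxAHV
  okL <- !is.na(av) & av < 0 & av >= -maxAHV
  n <- length(tv)
  score <- function(counts) {
    r <- counts / dt
    c(right = abs(safeCor(r[okR], av[okR])),
      left = abs(safeCor(r[okL], -av[okL])))
  }
  times <- spikeTimes(spikes)
  obs <- score(countsPerFrame(times, tv[1L], dt, n))
  duration <- tv[n] - tv[1L] + dt
  set.seed(seed)
  shifts <- stats::runif(nPerm, 20, duration - 20)
  nulls <- t(vapply(shifts, function(s)
    score(countsPerFrame((times + s) %% duration, tv[1L], dt, n)),
    numeric(2)))
  thr <- stats::quantile(pmax(nulls[, 1L], nulls[, 2L], na.rm = TRUE),
                         0.95, na.rm = TRUE, names = FALSE)
  passR <- !is.na(obs[["right"]]) && obs[["right"]] > thr
  passL <- !is.na(obs[["left"]]) && obs[["left"]] > thr
  structure(list(unitId = unitId(spikes), curve = NULL,
                 scoreRight = obs[["right"]], scoreLeft = obs[["left"]],
                 slopeRight = NA_real_, slopeLeft = NA_real_,
                 signRight = NA_real_, signLeft = NA_real_,
                 null95Right = stats::quantile(nulls[, 1L], 0.95,
                                               na.rm = TRUE, names = FALSE),
                 null95Left = stats::quantile(nulls[, 2L], 0.95,
                                              na.rm = TRUE, names = FALSE),
                 null95Max = thr,
                 nullRight = nulls[, 1L], nullLeft = nulls[, 2L],
                 isAHV = passR || passL,
                 subtype = if (passR && passL) "bidirectional"
                 else if (passR) "unidirectional_right"
                 else if (passL) "unidirectional_left" else "none",
                 scoreDomain = "framewise"),
            class = "AHVTuningResult")
}
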