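# Putative cell-type assignment from waveform shape and monosynaptic
# connection detection from cross-correlograms.

#' Waveform features for cell-type classification
#'
#' The two spike-shape metrics used to separate narrow- from
#' wide-spiking units: the height of the second positive peak relative
#' to the trough magnitude, and the trough-to-peak duration.
#'
#' @param wf a \linkS4class{UnitWaveform}.
#' @return list(peak2OverTrough, troughToPeakUs).
#' @export
waveformFeatures <- function(wf) {
  lf <- extractLocalFeatures(wf)
  list(peak2OverTrough = if (lf$D < 0) lf$B / abs(lf$D) else NA_real_,
       troughToPeakUs = lf$C)
}

#' Classify units as narrow or wide spiking
#'
#' K-means clustering (k = 2) on standardised waveform features; the
#' cluster with the smaller mean trough-to-peak duration is labelled
#' \code{"narrow"}, making the naming independent of initialisation.
#'
#' @param features data.frame with columns \code{peak2_over_trough},
#'   \code{trough_to_peak_us} (>= 10 rows).
#' @param seed RNG seed for the k-means initialisation.
#' @param nstart k-means restarts.
#' @return factor of \code{"narrow"}/\code{"wide"} per row, with the
#'   fitted centres (original units) as attribute \code{"centers"}.
#' @export
classifyCelltype <- function(features, seed = 1, nstart = 10) {
  x <- as.matrix(features[, c("peak2_over_trough", "trough_to_peak_us")])
  if (nrow(x) < 10L) stopf("need >= 10 units for cell-type clustering")
  if (any(apply(x, 2L, stats::sd) == 0))
    stopf("degenerate features: no variance to cluster")
  z <- scale(x)
  set.seed(seed)
  km <- stats::kmeans(z, centers = 2L, nstart = nstart)
  meanT2P <- tapply(x[, "trough_to_peak_us"], km$cluster, mean)
  narrowCluster <- as.integer(names(which.min(meanT2P)))
  lab <- factor(ifelse(km$cluster == narrowCluster, "narrow", "wide"),
                levels = c("narrow", "wide"))
  centers <- km$centers * matrix(attr(z, "scaled:scale"), 2L, 2L,
                                 byrow = TRUE) +
    matrix(attr(z, "scaled:center"), 2L, 2L, byrow = TRUE)
  attr(lab, "centers") <- centers
  lab
}

#' Spike-train cross-correlogram
#'
#' Counts of B-spike lags relative to each A spike in 0.5-ms bins
#' spanning -50 to +50 ms (bins centred on multiples of 0.5 ms).
#'
#' @param a,b \linkS4class{SpikeTrain}s (a warning is issued below 900
#'   spikes).
#' @param binMs bin width, ms.
#' @param maxLagMs maximum lag, ms.
#' @return list of class \code{"CCG"}: \code{lags} (bin centres, ms),
#'   \code{counts}, \code{nA}, \code{nB}, \code{duration}.
#' @export
computeCCG <- function(a, b, binMs = 0.5, maxLagMs = 50) {
  ta <- spikeTimes(a); tb <- spikeTimes(b)
  if (!length(ta) || !length(tb)) stopf("empty spike train")
  if (length(ta) < 900 || length(tb) < 900)
    warnf("CCG computed with < 900 spikes in at least one train")
  half <- (maxLagMs + binMs / 2) / 1000
  lo <- findInterval(ta - half, tb)
  hi <- findInterval(ta + half, tb)
  nPer <- hi - lo
  aRep <- rep(ta, nPer)
  bIdx <- sequence(nPer, from = lo + 1L)
  lagMs <- (tb[bIdx] - aRep) * 1000
  nb <- 2L * round(maxLagMs / binMs) + 1L
  edges <- seq(-maxLagMs - binMs / 2, maxLagMs + binMs / 2, by = binMs)
  counts <- tabulate(findInterval(lagMs, edges, rightmost.closed = TRUE),
                     nbins = nb)
  structure(list(lags = (edges[-1L] + edges[-length(edges)]) / 2,
                 counts = counts, nA = length(ta), nB = length(tb),
                 duration = max(ta[length(ta)], tb[length(tb)])),
            class = "CCG")
}

#' Detect a putative monosynaptic connection in a CCG
#'
#' The baseline of each bin is a Fourier-smoothed version of the CCG: the
#' centre +-1 ms (which carries the monosynaptic shoulder) is first
#' replaced by interpolation, then only the lowest-frequency Fourier
#' components are retained (a gentle low-pass; the cut-off is expressed
#' as the number of harmonics kept across the 100-ms window). A
#' confidence band is the 0.0001-99.9999 percentile of the Poisson
#' distribution at each bin's baseline. Within the 1.5-4 ms window after
#' the centre bin, an excitatory connection requires at least two bins
#' above the upper band, an inhibitory one at least three bins below the
#' lower band.
#'
#' @param ccg a \code{"CCG"}.
#' @param windowMs outlier-detection window after zero lag, ms.
#' @param nHarmonics Fourier components kept for the baseline (default
#'   5).
#' @param bandQuantiles lower/upper Poisson percentiles.
#' @param minBinsPeak,minBinsTrough bin criteria.
#' @param contiguous require the significant bins to be contiguous
#'   (default FALSE: bins may lie anywhere in the window).
#' @return list of class \code{"CCGResult"}: baseline, bands, per-bin
#'   significance, \code{label} (excitatory / inhibitory / none),
#'   \code{flagged}.
#' @export
detectConnection <- function(ccg, windowMs = c(1.5, 4), nHarmonics = 5,
                             bandQuantiles = c(1e-6, 1 - 1e-6),
                             minBinsPeak = 2, minBinsTrough = 3,
                             contiguous = FALSE) {
  cnt <- ccg$counts
  lags <- ccg$lags
  n <- length(cnt)
  # exclude the centre region (zero-lag shoulder and the candidate
  # monosynaptic window itself) from baseline fitting, so a genuine peak
  # or trough cannot inflate its own baseline
  centre <- abs(lags) <= max(1, windowMs[2L]) + 1e-9
  fit <- cnt
  fit[centre] <- stats::approx(which(!centre), cnt[!centre],
                               xout = which(centre), rule = 2)$y
  f <- stats::fft(fit)
  keep <- c(seq_len(nHarmonics + 1L), seq(n - nHarmonics + 1L, n))
  f[-keep] <- 0
  base <- pmax(Re(stats::fft(f, inverse = TRUE)) / n, 0)
  upper <- stats::qpois(bandQuantiles[2L], base)
  lower <- stats::qpois(bandQuantiles[1L], base)
  win <- lags >= windowMs[1L] & lags <= windowMs[2L]
  flagged <- any(base[win] <= 0)
  sigHigh <- win & cnt > upper
  sigLow <- win & cnt < lower
  nSig <- function(sig, need) {
    k <- sum(sig)
    if (!contiguous || k < need) return(k)
    r <- rle(sig[win])
    max(c(0, r$lengths[r$values]))
  }
  label <- if (flagged) "none"
  else if (nSig(sigHigh, minBinsPeak) >= minBinsPeak) "excitatory"
  else if (nSig(sigLow, minBinsTrough) >= minBinsTrough) "inhibitory"
  else "none"
  structure(list(lags = lags, counts = cnt, baseline = base,
                 bandLow = lower, bandHigh = upper,
                 significantHigh = which(sigHigh),
                 significantLow = which(sigLow),
                 label = label, flagged = flagged),
            class = "CCGResult")
}

#' Agreement between waveform classes and CCG connection types
#'
#' Fraction of CCG-typed units whose k-means waveform class matches the
#' expected correspondence (excitatory = wide, inhibitory = narrow).
#'
#' @param kmeansLabels factor/character of \code{"narrow"}/\code{"wide"}
#'   per unit.
#' @param ccgLabels character of \code{"excitatory"}/\code{"inhibitory"}/
#'   \code{"none"} per unit (typed units only are scored).
#' @return list(overlap, nTyped).
#' @export
classAgreement <- function(kmeansLabels, ccgLabels) {
  typed <- ccgLabels %in% c("excitatory", "inhibitory")
  if (!any(typed)) return(list(overlap = NA_real_, nTyped = 0L))
  expected <- ifelse(ccgLabels[typed] == "excitatory", "wide", "narrow")
  list(overlap = mean(as.character(kmeansLabels)[typed] == expected),
       nTyped = sum(typed))
}
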