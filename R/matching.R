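# Cross-session single-unit matching: ISI-shape, local and global waveform
# similarity metrics, weighted score, candidate/conflict resolution and
# acceptance thresholds.

#' Proportional difference similarity
#'
#' \code{F(x, y) = max(0, 1 - |(x - y) / x|)}: 1 for identical values,
#' falling to 0 once y deviates from x by 100% or more. By documented
#' convention \code{F(0, 0) = 1} and \code{F(0, y != 0) = 0}.
#'
#' @param x reference value (the "Fix" feature).
#' @param y comparison value (the "Free" feature).
#' @return Similarity in [0, 1].
#' @export
proportionalDifference <- function(x, y) {
  if (x == 0) return(if (y == 0) 1 else 0)
  max(0, 1 - abs((x - y) / x))
}

#' Inter-spike-interval relative-frequency histogram
#'
#' ISI histogram over the whole recording on log-spaced bins (default 50
#' bins from 1 ms to 10 s); frequencies sum to 1.
#'
#' @param spikes a \linkS4class{SpikeTrain}.
#' @param binEdges bin edges, seconds.
#' @return list(edges, freq, nIntervals).
#' @export
isiHistogram <- function(spikes,
                         binEdges = exp(seq(log(1e-3), log(10),
                                            length.out = 51))) {
  isi <- diff(spikeTimes(spikes))
  isi <- isi[isi >= binEdges[1L] & isi <= binEdges[length(binEdges)]]
  cnt <- tabulate(findInterval(isi, binEdges, rightmost.closed = TRUE),
                  nbins = length(binEdges) - 1L)
  list(edges = binEdges,
       freq = if (sum(cnt)) cnt / sum(cnt) else cnt + 0,
       nIntervals = length(isi))
}

#' Histogram intersection ratio
#'
#' \code{sum(min(h1, h2)) / sum(max(h1, h2))} over bins: 1 for identical
#' histograms, 0 for disjoint ones. Histograms must share bin edges.
#'
#' @param h1,h2 histograms as returned by [isiHistogram()] (or plain
#'   numeric frequency vectors of equal length).
#' @return Intersection ratio in [0, 1].
#' @export
histogramIntersection <- function(h1, h2) {
  if (is.list(h1)) {
    if (!isTRUE(all.equal(h1$edges, h2$edges)))
      stopf("histogram bin edges do not match")
    h1 <- h1$freq; h2 <- h2$freq
  }
  if (length(h1) != length(h2)) stopf("histogram lengths do not match")
  den <- sum(pmax(h1, h2))
  if (den == 0) return(1)
  sum(pmin(h1, h2)) / den
}

# peak-channel waveform re-centred on its trough within the 4-ms window;
# resampled to 30 kHz when recorded at another rate
peakWindow <- function(wf, nPre = 48L, nPost = 72L) {
  w <- waveformMatrix(wf)[peakChannel(wf), ]
  si <- sampleInterval(wf)
  target <- 1e6 / 30000
  if (abs(si - target) > 1e-9) {
    tOrig <- (seq_along(w) - 1L) * si
    w <- stats::approx(tOrig, w, xout = seq(0, max(tOrig), by = target))$y
    si <- target
  }
  tr <- which.min(w)
  idx <- (tr - nPre):(tr + nPost)
  out <- numeric(length(idx))
  inb <- idx >= 1L & idx <= length(w)
  out[inb] <- w[idx[inb]]
  out
}

#' Local spike-shape features
#'
#' From the peak-channel mean waveform: A, amplitude of the first positive
#' peak preceding the trough (microvolts; 0 and flagged when absent); B,
#' amplitude of the second positive peak after the trough; C,
#' trough-to-peak duration (microseconds); D, trough amplitude.
#'
#' @param wf a \linkS4class{UnitWaveform}.
#' @return list(A, B, C, D, flags).
#' @export
extractLocalFeatures <- function(wf) {
  w <- peakWindow(wf)
  si <- 1e6 / 30000
  tr <- which.min(w)
  flags <- character(0)
  if (w[tr] >= 0) flags <- c(flags, "atypical_no_trough")
  pre <- w[seq_len(tr - 1L)]
  A <- if (length(pre) && max(pre) > 0) max(pre) else 0
  if (A == 0) flags <- c(flags, "no_pre_trough_peak")
  post <- w[(tr + 1L):length(w)]
  B <- max(post)
  C <- which.max(post) * si
  list(A = A, B = B, C = C, D = w[tr], flags = flags)
}

#' Dynamic time warping of two waveforms
#'
#' Classic dynamic-programming DTW with a Sakoe-Chiba band, returning the
#' optimal alignment path (diagonal steps preferred on ties, so identical
#' inputs give the identity path).
#'
#' @param x,y numeric vectors.
#' @param radius band half-width, samples (default 3).
#' @return list(index1, index2, distance, pathLength).
#' @export
dtwAlign <- function(x, y, radius = 3) {
  n <- length(x); m <- length(y)
  band <- max(radius, abs(n - m)) + 1L
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    jlo <- max(1L, i - band); jhi <- min(m, i + band)
    for (j in jlo:jhi) {
      D[i + 1L, j + 1L] <- abs(x[i] - y[j]) +
        min(D[i, j], D[i, j + 1L], D[i + 1L, j])
    }
  }
  i <- n; j <- m
  p1 <- integer(0); p2 <- integer(0)
  while (i >= 1L && j >= 1L) {
    p1 <- c(i, p1); p2 <- c(j, p2)
    if (i == 1L && j == 1L) break
    steps <- c(D[i, j], D[i, j + 1L], D[i + 1L, j])  # diag, up, left
    k <- which.min(steps)
    if (k == 1L) { i <- i - 1L; j <- j - 1L }
    else if (k == 2L) i <- i - 1L
    else j <- j - 1L
  }
  list(index1 = p1, index2 = p2, distance = D[n + 1L, m + 1L],
       pathLength = length(p1))
}

#' Global waveform-similarity features
#'
#' Compares the whole 4-ms peak-channel waveforms of a Fix/Free pair:
#' amplitude-histogram intersection (3-uV bins), and three DTW-based
#' metrics computed along the optimal warping path — maximum pointwise
#' distance normalised by the Fix peak-to-trough amplitude
#' (\code{wfDifference}), Pearson correlation of the warped waveforms
#' (\code{wfCorr}), and the DTW scale factor (original length / warped
#' length), which penalises excessive warping.
#'
#' @param wfFix,wfFree \linkS4class{UnitWaveform}s.
#' @param binUv amplitude-histogram bin width, microvolts.
#' @param radius DTW band half-width, samples.
#' @param normalizeBy \code{"fix"} (default) or \code{"free"}: whose
#'   peak-to-trough amplitude normalises the waveform difference.
#' @return list(wfIntersection, wfDifference, wfCorr, dtwScale).
#' @export
globalFeatures <- function(wfFix, wfFree, binUv = 3, radius = 3,
                           normalizeBy = c("fix", "free")) {
  normalizeBy <- match.arg(normalizeBy)
  rawX <- waveformMatrix(wfFix)[peakChannel(wfFix), ]
  rawY <- waveformMatrix(wfFree)[peakChannel(wfFree), ]
  if (stats::sd(rawX) == 0 || stats::sd(rawY) == 0)
    stopf("degenerate flat waveform; pair skipped")
  x <- peakWindow(wfFix); y <- peakWindow(wfFree)
  rng <- range(c(x, y))
  edges <- seq(floor(rng[1L] / binUv) * binUv,
               ceiling(rng[2L] / binUv) * binUv + binUv, by = binUv)
  hx <- tabulate(findInterval(x, edges), nbins = length(edges) - 1L)
  hy <- tabulate(findInterval(y, edges), nbins = length(edges) - 1L)
  inter <- histogramIntersection(hx / sum(hx), hy / sum(hy))
  # warp on shape (amplitude-normalised waveforms) so a pure amplitude
  # scaling does not distort the alignment path; metrics are then taken
  # on the original signals along that path
  al <- dtwAlign(x / (max(x) - min(x)), y / (max(y) - min(y)),
                 radius = radius)
  w1 <- x[al$index1]; w2 <- y[al$index2]
  p2t <- if (normalizeBy == "fix") max(x) - min(x) else max(y) - min(y)
  list(wfIntersection = inter,
       wfDifference = max(abs(w1 - w2)) / p2t,
       wfCorr = safeCor(w1, w2),
       dtwScale = length(x) / al$pathLength)
}

#' Weighted similarity score
#'
#' Combines the three metric categories as
#' \code{W_local * ||local||_2 + W_global * ||global||_2 + W_ISI *
#' ||isi||_2} with empirical weights (1/9, 4/9, 4/9). Every component is
#' mapped to similarity orientation before norming: the waveform
#' difference enters as \code{1 - min(d, 1)}, the DTW scale as
#' \code{min(s, 1/s)}, and correlations are clipped at 0.
#'
#' @param metrics list with elements \code{fPeak2, fT2pDur, fT2pAmp,
#'   fP2tAmp, wfIntersection, wfDifference, wfCorr, dtwScale, isiCorr,
#'   isiIntersection} (as built by [computeSimilarity()]).
#' @param weights numeric(3) category weights (local, global, isi).
#' @return The weighted score (scalar).
#' @export
similarityScore <- function(metrics, weights = c(1, 4, 4) / 9) {
  need <- c("fPeak2", "fT2pDur", "fT2pAmp", "fP2tAmp", "wfIntersection",
            "wfDifference", "wfCorr", "dtwScale", "isiCorr",
            "isiIntersection")
  miss <- setdiff(need, names(metrics))
  if (length(miss) || any(vapply(metrics[need], function(v)
    is.null(v) || is.na(v), logical(1))))
    stopf("missing similarity component(s): %s",
          paste(c(miss, need[vapply(metrics[need], function(v)
            is.null(v) || is.na(v), logical(1))]), collapse = ", "))
  l2 <- function(v) sqrt(sum(v^2))
  local <- c(metrics$fPeak2, metrics$fT2pDur, metrics$fT2pAmp,
             metrics$fP2tAmp)
  global <- c(metrics$wfIntersection, 1 - min(metrics$wfDifference, 1),
              max(metrics$wfCorr, 0),
              min(metrics$dtwScale, 1 / metrics$dtwScale))
  isi <- c(max(metrics$isiCorr, 0), metrics$isiIntersection)
  sum(weights * c(l2(local), l2(global), l2(isi)))
}

#' Full similarity metric set for one Fix/Free pair
#'
#' @param fixSpikes,freeSpikes \linkS4class{SpikeTrain}s.
#' @param fixWf,freeWf \linkS4class{UnitWaveform}s.
#' @param radius DTW band half-width.
#' @param normalizeBy see [globalFeatures()].
#' @return list of all components plus \code{weightedScore} and the local
#'   feature sets.
#' @export
computeSimilarity <- function(fixSpikes, freeSpikes, fixWf, freeWf,
                              radius = 3, normalizeBy = "fix") {
  lf <- extractLocalFeatures(fixWf)
  lr <- extractLocalFeatures(freeWf)
  hf <- isiHistogram(fixSpikes)
  hr <- isiHistogram(freeSpikes)
  gf <- globalFeatures(fixWf, freeWf, radius = radius,
                       normalizeBy = normalizeBy)
  m <- list(fPeak2 = proportionalDifference(lf$B, lr$B),
            fT2pDur = proportionalDifference(lf$C, lr$C),
            fT2pAmp = proportionalDifference(lf$B - lf$D, lr$B - lr$D),
            fP2tAmp = proportionalDifference(lf$A - lf$D, lr$A - lr$D),
            wfIntersection = gf$wfIntersection,
            wfDifference = gf$wfDifference,
            wfCorr = gf$wfCorr, dtwScale = gf$dtwScale,
            isiCorr = safeCor(hf$freq, hr$freq),
            isiIntersection = histogramIntersection(hf, hr),
            localFix = lf, localFree = lr)
  m$weightedScore <- similarityScore(m)
  m
}

#' Match single units between a Fix and a Free session
#'
#' For each Fix unit, candidate Free units are those whose peak channel
#' lies within the allowed vertical distance and whose whole-session mean
#' firing rate differs by no more than a factor of
#' \code{rateRatioMax}. The candidate with the highest weighted
#' similarity score is the best potential match; a Free unit claimed by
#' several Fix units is assigned only to the one with the highest score.
#' Finally the acceptance thresholds are applied: ISI histogram
#' correlation > 0.7, all four local features > 0.7, waveform correlation
#' > 0.95 and waveform difference < 0.3.
#'
#' @param fix,free session lists with elements \code{spikes},
#'   \code{waveforms} (named by unit) as returned by [loadSpikeData()] or
#'   [simulateWaveformLibrary()].
#' @param maxChannelDistance maximum vertical peak-channel separation,
#'   micrometers (40 for the 8-neighbour probe, 50 for the 4-neighbour
#'   probe).
#' @param rateRatioMax firing-rate ratio cap (default 20).
#' @param thresholds named list overriding the acceptance thresholds
#'   \code{isiCorr, localF, wfCorr, wfDifference}.
#' @param radius DTW band half-width.
#' @param normalizeBy see [globalFeatures()].
#' @return data.frame with one row per Fix unit: \code{fix_id, free_id,
#'   score}, each threshold check, \code{accepted} and \code{reason}
#'   (\code{""}, \code{"no_candidates"}, \code{"conflict"} or
#'   \code{"threshold"}).
#' @export
matchUnits <- function(fix, free, maxChannelDistance = 40,
                       rateRatioMax = 20, thresholds = list(),
                       radius = 3, normalizeBy = "fix") {
  thr <- utils::modifyList(list(isiCorr = 0.7, localF = 0.7, wfCorr = 0.95,
                                wfDifference = 0.3), thresholds)
  durOf <- function(sess) max(vapply(sess$spikes, function(s)
    if (nSpikes(s)) max(spikeTimes(s)) else 0, numeric(1)))
  dFix <- durOf(fix); dFree <- durOf(free)
  posOf <- function(sess, id) {
    w <- sess$waveforms[[id]]
    channelPositions(w)[peakChannel(w)]
  }
  fixIds <- names(fix$spikes); freeIds <- names(free$spikes)
  rateFix <- vapply(fixIds, function(i) nSpikes(fix$spikes[[i]]) / dFix,
                    numeric(1))
  rateFree <- vapply(freeIds, function(i) nSpikes(free$spikes[[i]]) / dFree,
                     numeric(1))
  posFix <- vapply(fixIds, function(i) posOf(fix, i), numeric(1))
  posFree <- vapply(freeIds, function(i) posOf(free, i), numeric(1))

  best <- data.frame(fix_id = fixIds, free_id = NA_character_,
                     score = NA_real_, reason = "", stringsAsFactors = FALSE)
  metricsList <- vector("list", length(fixIds))
  names(metricsList) <- fixIds
  for (fi in seq_along(fixIds)) {
    cand <- freeIds[abs(posFree - posFix[fi]) <= maxChannelDistance &
                      pmax(rateFree / rateFix[fi],
                           rateFix[fi] / rateFree) <= rateRatioMax]
    if (!length(cand)) { best$reason[fi] <- "no_candidates"; next }
    sims <- lapply(cand, function(ci)
      tryCatch(computeSimilarity(fix$spikes[[fixIds[fi]]],
                                 free$spikes[[ci]],
                                 fix$waveforms[[fixIds[fi]]],
                                 free$waveforms[[ci]], radius = radius,
                                 normalizeBy = normalizeBy),
               error = function(e) NULL))
    keep <- !vapply(sims, is.null, logical(1))
    cand <- cand[keep]; sims <- sims[keep]
    if (!length(cand)) { best$reason[fi] <- "no_candidates"; next }
    scores <- vapply(sims, `[[`, numeric(1), "weightedScore")
    k <- which.max(scores)
    best$free_id[fi] <- cand[k]
    best$score[fi] <- scores[k]
    metricsList[[fi]] <- sims[[k]]
  }

  # conflict resolution: a Free unit goes to its highest-scoring claimant
  for (fid in unique(stats::na.omit(best$free_id))) {
    claim <- which(best$free_id %in% fid)
    if (length(claim) > 1L) {
      lose <- claim[-which.max(best$score[claim])]
      best$free_id[lose] <- NA_character_
      best$reason[lose] <- "conflict"
      metricsList[lose] <- list(NULL)
    }
  }

  checks <- data.frame(chk_isi_corr = NA, chk_local = NA, chk_wf_corr = NA,
                       chk_wf_diff = NA)
  out <- cbind(best, checks[rep(1L, nrow(best)), , drop = FALSE])
  rownames(out) <- NULL
  out$accepted <- FALSE
  for (fi in seq_len(nrow(out))) {
    m <- metricsList[[fi]]
    if (is.null(m)) next
    out$chk_isi_corr[fi] <- m$isiCorr > thr$isiCorr
    out$chk_local[fi] <- min(m$fPeak2, m$fT2pDur, m$fT2pAmp,
                             m$fP2tAmp) > thr$localF
    out$chk_wf_corr[fi] <- m$wfCorr > thr$wfCorr
    out$chk_wf_diff[fi] <- m$wfDifference < thr$wfDifference
    ok <- out$chk_isi_corr[fi] && out$chk_local[fi] &&
      out$chk_wf_corr[fi] && out$chk_wf_diff[fi]
    out$accepted[fi] <- ok
    if (!ok) out$reason[fi] <- "threshold"
  }
  attr(out, "metrics") <- metricsList
  out
}
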