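# Go/no-go rotation-discrimination scoring, psychometric fitting,
# training-criterion checks and lesion turning-angle quantification.

#' Bin lick timestamps into post-peak lick bins
#'
#' Counts the number of 250-ms bins containing at least one lick between
#' the stimulus velocity peak (16.1 s from rotation onset by default)
#' and stimulus end (32.2 s).
#'
#' @param lickTimes lick timestamps, seconds from trial onset.
#' @param peakTime velocity-peak time, s.
#' @param endTime stimulus end, s.
#' @param binS bin width, s.
#' @return Integer count of lick-containing bins.
#' @export
binLickTimes <- function(lickTimes, peakTime = 16.1, endTime = 32.2,
                         binS = 0.25) {
  edges <- seq(peakTime, endTime, by = binS)
  idx <- findInterval(lickTimes, edges, rightmost.closed = TRUE)
  length(unique(idx[idx >= 1L & idx < length(edges)]))
}

#' Score a go/no-go session
#'
#' A correct S+ response is licking in two or more 250-ms bins after the
#' velocity peak; a correct S- response is licking in fewer than two.
#' Block discrimination accuracy is the mean of the percentage of
#' correct S+ and correct S- trials. Incomplete blocks (not 10 S+ and
#' 10 S-) are excluded and listed.
#'
#' @param session session data.frame from [simulateGoNoGoSession()] (or
#'   the same layout: \code{block, stimulus, peak_splus, peak_sminus,
#'   condition, lick_bins}).
#' @param lickCriterion minimum lick bins for an S+ response (default
#'   2).
#' @return data.frame per block: \code{block, peak_splus, peak_sminus,
#'   condition, pct_splus, pct_sminus, accuracy}; excluded blocks in
#'   attribute \code{"excluded"}.
#' @export
scoreSession <- function(session, lickCriterion = 2) {
  key <- interaction(session$block, session$peak_splus,
                     session$peak_sminus, session$condition, drop = TRUE)
  out <- list(); excluded <- character(0)
  for (k in levels(key)) {
    tr <- session[key == k, , drop = FALSE]
    nP <- sum(tr$stimulus == "S+"); nM <- sum(tr$stimulus == "S-")
    if (nP != 10L || nM != 10L) { excluded <- c(excluded, k); next }
    lick <- tr$lick_bins >= lickCriterion
    pctP <- 100 * mean(lick[tr$stimulus == "S+"])
    pctM <- 100 * mean(!lick[tr$stimulus == "S-"])
    out[[k]] <- data.frame(block = tr$block[1L],
                           peak_splus = tr$peak_splus[1L],
                           peak_sminus = tr$peak_sminus[1L],
                           condition = tr$condition[1L],
                           pct_splus = pctP, pct_sminus = pctM,
                           accuracy = (pctP + pctM) / 2,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res[order(res$peak_splus, res$block), ]
}

#' Fit a psychometric curve to discrimination accuracies
#'
#' Four-parameter logistic fit of block accuracy (percent) against the
#' absolute peak-speed difference, with the floor bounded at 50% (chance
#' in the go/no-go task). The discrimination threshold is reported as
#' the speed difference at the curve midpoint.
#'
#' @param dSpeed absolute S+/S- peak-speed differences, deg/s (>= 4
#'   distinct values).
#' @param accuracy accuracies, percent.
#' @return list of class \code{"PsychometricFit"}: \code{floor},
#'   \code{ceiling}, \code{midpoint} (deg/s), \code{slope},
#'   \code{fitted}, \code{converged}, \code{flat} (slope ~ 0: threshold
#'   undefined).
#' @export
fitPsychometric <- function(dSpeed, accuracy) {
  if (length(unique(dSpeed)) < 4L)
    stopf("need >= 4 distinct speed differences")
  df <- data.frame(d = dSpeed, a = accuracy)
  rng <- diff(range(df$a))
  if (rng < 2) {
    return(structure(list(floor = mean(df$a), ceiling = mean(df$a),
                          midpoint = NA_real_, slope = 0,
                          fitted = rep(mean(df$a), nrow(df)),
                          converged = TRUE, flat = TRUE),
                     class = "PsychometricFit"))
  }
  sigmoid <- function(p, d) p[1L] + (p[2L] - p[1L]) /
    (1 + exp(-(d - p[3L]) / p[4L]))
  start <- c(fl = max(50, min(df$a)), ce = max(df$a),
             mid = stats::median(df$d), sl = diff(range(df$d)) / 8)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start,
                       lower = c(50, 50, 0, 1e-3),
                       upper = c(100, 100, max(df$d) * 2, 100),
                       fn = function(p) df$a - sigmoid(p, df$d),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info < 1 || fit$info > 4)
    return(structure(list(floor = NA_real_, ceiling = NA_real_,
                          midpoint = NA_real_, slope = NA_real_,
                          fitted = rep(NA_real_, nrow(df)),
                          converged = FALSE, flat = FALSE),
                     class = "PsychometricFit"))
  cf <- fit$par
  structure(list(floor = unname(cf["fl"]), ceiling = unname(cf["ce"]),
                 midpoint = unname(cf["mid"]), slope = unname(cf["sl"]),
                 fitted = sigmoid(cf, df$d), converged = TRUE,
                 flat = unname(cf["ce"] - cf["fl"]) < 2),
            class = "PsychometricFit")
}

#' Training-progression criterion
#'
#' A mouse advances to the next stimulus pair once it has performed at
#' least \code{minBlocks} blocks and its mean accuracy over at least
#' \code{nConsecutive} consecutive blocks reaches \code{criterion}.
#'
#' @param blockAccuracies block accuracies in order, percent.
#' @param criterion accuracy criterion, percent (default 80).
#' @param nConsecutive consecutive-block window (default 5).
#' @param minBlocks minimum total blocks (default 20).
#' @return TRUE (advance) or FALSE (hold).
#' @export
criterionCheck <- function(blockAccuracies, criterion = 80,
                           nConsecutive = 5, minBlocks = 20) {
  n <- length(blockAccuracies)
  if (n < minBlocks || n < nConsecutive) return(FALSE)
  runMeans <- vapply(seq_len(n - nConsecutive + 1L), function(i)
    mean(blockAccuracies[i:(i + nConsecutive - 1L)]), numeric(1))
  any(runMeans >= criterion)
}

#' Turning-angle distribution of a trajectory
#'
#' The signed change of travel direction computed from three consecutive
#' frames of the body centroid; steps shorter than the displacement
#' floor are excluded (tracking jitter). Positive angles are clockwise
#' turns. Two distributions (e.g. pre- and post-lesion) can be compared
#' with [stats::ks.test()].
#'
#' @param tracking tracking table with \code{body_x}, \code{body_y}.
#' @param displacementFloor minimum step length, cm (default 0.1).
#' @param maxDistance optional path-distance cap, cm: only steps until
#'   the cumulative distance reaches this value are used.
#' @return Numeric vector of turn angles, degrees in (-180, 180].
#' @export
turnAngleDistribution <- function(tracking, displacementFloor = 0.1,
                                  maxDistance = NULL) {
  dx <- diff(tracking$body_x); dy <- diff(tracking$body_y)
  len <- sqrt(dx^2 + dy^2)
  if (!is.null(maxDistance)) {
    cum <- cumsum(len)
    keepN <- which(cum <= maxDistance)
    dx <- dx[keepN]; dy <- dy[keepN]; len <- len[keepN]
  }
  ang <- atan2(dy, dx) * 180 / pi
  ok <- len[-length(len)] >= displacementFloor & len[-1L] >= displacementFloor
  turns <- -circDiff(ang[-1L], ang[-length(ang)])  # positive = clockwise
  turns[ok]
}
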