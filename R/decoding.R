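# Population decoding: pseudo-population assembly, shrinkage linear
# discriminant analysis with balanced leave-one-per-class-out
# cross-validation, and bootstrap population-size curves.

#' Assemble a pseudo-population trial matrix
#'
#' Samples units from a pool and allocates trial simultaneity within each
#' stimulus class: every unit contributes exactly \code{nPerClass} trials
#' per class, independently permuted, so the label marginals are exact by
#' construction. Units lacking enough trials in any class are excluded
#' with a warning.
#'
#' @param pool list of units; each unit is a list with element
#'   \code{rates}, a named list mapping class label to a numeric vector
#'   of per-trial firing rates.
#' @param nNeurons population size.
#' @param seed RNG seed.
#' @param nPerClass trials per class (default 10).
#' @param replace sample units with replacement (default TRUE; FALSE with
#'   \code{nNeurons} equal to the pool size gives a permutation of the
#'   pool).
#' @return list of class \code{"TrialMatrix"}: \code{rates} (neurons x
#'   trials), \code{labels} (class per trial), \code{provenance}.
#' @export
buildPseudopopulation <- function(pool, nNeurons, seed = 1, nPerClass = 10,
                                  replace = TRUE) {
  classes <- names(pool[[1L]]$rates)
  ok <- vapply(pool, function(u)
    all(classes %in% names(u$rates)) &&
      all(vapply(u$rates[classes], length, 1L) >= nPerClass), logical(1))
  if (!all(ok)) {
    warnf("excluding %d unit(s) lacking %d trials per class",
          sum(!ok), nPerClass)
    pool <- pool[ok]
  }
  set.seed(seed)
  pick <- sample.int(length(pool), nNeurons, replace = replace)
  labels <- rep(classes, each = nPerClass)
  rates <- matrix(NA_real_, nNeurons, length(labels))
  for (i in seq_along(pick)) {
    u <- pool[[pick[i]]]
    rates[i, ] <- unlist(lapply(classes, function(cl)
      sample(u$rates[[cl]], nPerClass)), use.names = FALSE)
  }
  structure(list(rates = rates, labels = labels, provenance = "pseudo"),
            class = "TrialMatrix")
}

# Ledoit-Wolf analytic shrinkage of a covariance toward the
# average-variance identity; x is the (already centred) n x p data matrix
lwShrinkCov <- function(x) {
  n <- nrow(x); p <- ncol(x)
  S <- crossprod(x) / n
  m <- sum(diag(S)) / p
  d2 <- sum((S - diag(m, p))^2) / p
  if (d2 == 0) return(list(sigma = S, lambda = 0))
  b2bar <- 0
  for (i in seq_len(n)) {
    xi <- x[i, ]
    b2bar <- b2bar + sum((tcrossprod(xi) - S)^2)
  }
  b2bar <- b2bar / (n^2 * p)
  b2 <- min(b2bar, d2)
  lambda <- b2 / d2
  list(sigma = (1 - lambda) * S + diag(lambda * m, p), lambda = lambda)
}

#' Linear-discriminant decoding with shrinkage
#'
#' Balanced cross-validated LDA: each fold holds out exactly one trial
#' per class (54/6 train/test splits for six 10-trial classes, 18/2 for
#' two). Firing rates are z-scored per neuron using training-fold
#' statistics; the pooled within-class covariance is regularised by
#' analytic (Ledoit-Wolf) shrinkage toward the average-variance
#' identity; classes have equal priors. Accuracy is correct over
#' correct-plus-incorrect held-out trials.
#'
#' @param tm a \code{"TrialMatrix"}.
#' @param groupBy optional named character vector mapping each class
#'   label to a group: instead of one multiclass problem, a separate
#'   decoder is trained within each group (e.g. one binary
#'   direction decoder per experimental condition) and the accuracy is
#'   aggregated over all held-out trials.
#' @return list of class \code{"DecodingResult"}: \code{accuracy},
#'   \code{nNeurons}, \code{nTrials}, \code{predictions},
#'   \code{shrinkage} (mean intensity over folds).
#' @export
ldaDecode <- function(tm, groupBy = NULL) {
  if (!is.null(groupBy)) {
    groups <- unique(groupBy[tm$labels])
    preds <- character(length(tm$labels))
    shr <- numeric(0)
    for (g in groups) {
      sel <- groupBy[tm$labels] == g
      sub <- structure(list(rates = tm$rates[, sel, drop = FALSE],
                            labels = tm$labels[sel],
                            provenance = tm$provenance),
                       class = "TrialMatrix")
      r <- ldaDecode(sub)
      preds[sel] <- r$predictions
      shr <- c(shr, r$shrinkage)
    }
    return(structure(list(accuracy = mean(preds == tm$labels),
                          nNeurons = nrow(tm$rates),
                          nTrials = length(tm$labels),
                          predictions = preds, labels = tm$labels,
                          shrinkage = mean(shr)),
                     class = "DecodingResult"))
  }
  rates <- tm$rates
  labels <- tm$labels
  classes <- unique(labels)
  perClass <- table(labels)
  if (any(perClass < 2L)) stopf("every class needs >= 2 trials")
  if (length(unique(perClass)) != 1L)
    stopf("classes must be balanced")
  k <- unname(perClass[1L])
  # fold f holds out the f-th trial of each class
  foldOf <- integer(length(labels))
  for (cl in classes) foldOf[labels == cl] <- seq_len(k)
  preds <- character(length(labels))
  lams <- numeric(k)
  for (f in seq_len(k)) {
    test <- foldOf == f
    xtr <- t(rates[, !test, drop = FALSE])
    ytr <- labels[!test]
    mu <- colMeans(xtr); sd0 <- apply(xtr, 2L, stats::sd)
    sd0[sd0 == 0] <- 1
    z <- sweep(sweep(xtr, 2L, mu), 2L, sd0, "/")
    centred <- z
    means <- matrix(0, length(classes), ncol(z))
    for (ci in seq_along(classes)) {
      sel <- ytr == classes[ci]
      means[ci, ] <- colMeans(z[sel, , drop = FALSE])
      centred[sel, ] <- sweep(z[sel, , drop = FALSE], 2L, means[ci, ])
    }
    sh <- lwShrinkCov(centred)
    lams[f] <- sh$lambda
    ch <- tryCatch(chol(sh$sigma), error = function(e) NULL)
    if (is.null(ch)) ch <- chol(sh$sigma + diag(1e-6, ncol(z)))
    W <- backsolve(ch, forwardsolve(t(ch), t(means)))  # sigma^-1 mu_k
    zte <- sweep(sweep(t(rates[, test, drop = FALSE]), 2L, mu), 2L, sd0, "/")
    disc <- zte %*% W - matrix(colSums(t(means) * W) / 2,
                               sum(test), length(classes), byrow = TRUE)
    preds[test] <- classes[max.col(disc, ties.method = "first")]
  }
  structure(list(accuracy = mean(preds == labels),
                 nNeurons = nrow(rates), nTrials = length(labels),
                 predictions = preds, labels = labels,
                 shrinkage = mean(lams)),
            class = "DecodingResult")
}

#' Bootstrap decoding-accuracy curve over population sizes
#'
#' For each population size, units are sampled with replacement into
#' \code{nBoot} pseudo-populations, each decoded with [ldaDecode()]; the
#' mean accuracy and bootstrap IQR are reported per size.
#'
#' @param pool unit pool (see [buildPseudopopulation()]).
#' @param sizes integer vector of population sizes.
#' @param nBoot bootstrap samples per size (default 1000).
#' @param seed RNG seed.
#' @param nPerClass trials per class.
#' @return data.frame \code{n_neurons, accuracy, iqr_low, iqr_high,
#'   n_boot}.
#' @export
bootstrapDecoding <- function(pool, sizes, nBoot = 1000, seed = 1,
                              nPerClass = 10) {
  out <- lapply(sizes, function(nn) {
    acc <- vapply(seq_len(nBoot), function(b) {
      tm <- buildPseudopopulation(pool, nn,
                                  seed = childSeed(seed, nn * 100003 + b),
                                  nPerClass = nPerClass)
      ldaDecode(tm)$accuracy
    }, numeric(1))
    q <- stats::quantile(acc, c(0.25, 0.75), names = FALSE)
    data.frame(n_neurons = as.integer(nn), accuracy = mean(acc),
               iqr_low = q[1L],
               iqr_high = q[2L], n_boot = nBoot)
  })
  do.call(rbind, out)
}

#' Decode from simultaneously recorded populations
#'
#' Applies [ldaDecode()] to each session population that meets the
#' minimum size for the task (10 neurons for direction, 20 for speed);
#' smaller sessions are excluded and listed.
#'
#' @param sessions named list of \code{"TrialMatrix"} objects with
#'   provenance \code{"real-simultaneous"}.
#' @param task \code{"direction"} or \code{"speed"}.
#' @param minNeurons named minimum sizes (default direction 10, speed
#'   20).
#' @return list(results, excluded).
#' @export
simultaneousDecode <- function(sessions, task = c("direction", "speed"),
                               minNeurons = c(direction = 10, speed = 20)) {
  task <- match.arg(task)
  need <- minNeurons[[task]]
  sizes <- vapply(sessions, function(s) nrow(s$rates), integer(1))
  keep <- sizes >= need
  list(results = lapply(sessions[keep], ldaDecode),
       excluded = names(sessions)[!keep])
}
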