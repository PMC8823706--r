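#' Neuron specification for the tuned-spike generator
#'
#' Bundles the ground-truth tuning parameters of one simulated unit. The
#' firing-rate model is
#' \code{rate(t) = max(0, baseline + gR * max(AHV, 0) + gL * max(-AHV, 0) +
#' gS * speed) * m(HD)} where \code{m} is a von Mises modulation with mean 1
#' over uniform heading (\code{hdConcentration = 0} means no HD tuning).
#'
#' @param baselineRate baseline firing rate, Hz.
#' @param ahvGainRight,ahvGainLeft gain for rightward (clockwise, positive
#'   AHV) and leftward head turns, Hz per (deg/s); signed.
#' @param speedGain locomotion-speed gain, Hz per (cm/s); signed.
#' @param hdPreferred preferred head direction, degrees.
#' @param hdConcentration von Mises concentration (dimensionless, >= 0).
#' @param refractoryMs absolute refractory dead time, ms.
#' @return A list of class \code{"NeuronSpec"}.
#' @export
neuronSpec <- function(baselineRate = 5, ahvGainRight = 0, ahvGainLeft = 0,
                       speedGain = 0, hdPreferred = 0, hdConcentration = 0,
                       refractoryMs = 1) {
  stopifnot(baselineRate >= 0, hdConcentration >= 0, refractoryMs >= 0)
  structure(list(baselineRate = baselineRate, ahvGainRight = ahvGainRight,
                 ahvGainLeft = ahvGainLeft, speedGain = speedGain,
                 hdPreferred = hdPreferred,
                 hdConcentration = hdConcentration,
                 refractoryMs = refractoryMs), class = "NeuronSpec")
}

#' Simulate an open-field tracking trajectory
#'
#' Heading is generated by integrating a mean-reverting (Ornstein-Uhlenbeck)
#' angular-velocity process; the body follows a speed-modulated walk confined
#' to a circular arena, and ear positions are placed at fixed offsets
#' perpendicular to the heading. Statistics emulate mouse open-field data:
#' AHV mostly within +-80 deg/s, speeds 0-20 cm/s, 40 frames/s.
#'
#' @param duration session length, seconds (>= 60).
#' @param seed RNG seed.
#' @param fps frame rate, frames/s (default 40).
#' @param ahvSd stationary SD of angular velocity, deg/s (default 40; 0 gives
#'   a constant heading).
#' @param ahvTau relaxation time of the AHV process, s.
#' @param speedMean,speedSd,speedTau locomotion-speed process parameters,
#'   cm/s and s (speed is clipped at 0).
#' @param arenaDiameter arena diameter, cm (default 92).
#' @param earOffset half ear separation, cm.
#' @return A tracking-table data.frame with columns \code{t, left_x, left_y,
#'   right_x, right_y, body_x, body_y, interpolated}, plus a
#'   \code{"groundTruth"} attribute (data.frame \code{t, heading, ahv, speed})
#'   holding the generating kinematics.
#' @export
simulateTrajectory <- function(duration, seed = 1, fps = 40, ahvSd = 40,
                               ahvTau = 0.5, speedMean = 8, speedSd = 4,
                               speedTau = 1, arenaDiameter = 92,
                               earOffset = 1) {
  if (duration < 60) stopf("duration must be >= 60 s")
  set.seed(seed)
  dt <- 1 / fps
  n <- floor(duration * fps)
  tv <- (seq_len(n) - 1L) * dt

  # OU angular velocity, positive = clockwise/rightward
  a <- exp(-dt / ahvTau)
  omega <- numeric(n)
  if (ahvSd > 0) {
    inc <- ahvSd * sqrt(1 - a^2)
    z <- stats::rnorm(n)
    for (k in 2:n) omega[k] <- omega[k - 1L] * a + inc * z[k]
  }
  heading <- wrap360(-cumsum(c(0, omega[-n]) * dt))

  # OU speed clipped at zero
  b <- exp(-dt / speedTau)
  spd <- rep(speedMean, n)
  if (speedSd > 0) {
    inc <- speedSd * sqrt(1 - b^2)
    z <- stats::rnorm(n)
    for (k in 2:n)
      spd[k] <- speedMean + (spd[k - 1L] - speedMean) * b + inc * z[k]
    spd <- pmax(spd, 0)
  }

  # body walk in heading direction, reflected into the arena
  rad <- heading * pi / 180
  R <- arenaDiameter / 2 - 3
  bx <- numeric(n); by <- numeric(n)
  for (k in 2:n) {
    bx[k] <- bx[k - 1L] + spd[k] * dt * cos(rad[k])
    by[k] <- by[k - 1L] + spd[k] * dt * sin(rad[k])
    r <- sqrt(bx[k]^2 + by[k]^2)
    if (r > R) { bx[k] <- bx[k] * R / r; by[k] <- by[k] * R / r }
  }
  # true speed after confinement
  spdTrue <- c(0, sqrt(diff(bx)^2 + diff(by)^2) / dt)

  # head centre ahead of body; ears perpendicular to heading
  hx <- bx + 2 * cos(rad); hy <- by + 2 * sin(rad)
  lx <- hx - earOffset * sin(rad); ly <- hy + earOffset * cos(rad)
  rx <- hx + earOffset * sin(rad); ry <- hy - earOffset * cos(rad)

  tr <- data.frame(t = tv, left_x = lx, left_y = ly, right_x = rx,
                   right_y = ry, body_x = bx, body_y = by,
                   interpolated = FALSE)
  attr(tr, "groundTruth") <- data.frame(t = tv, heading = heading,
                                        ahv = omega, speed = spdTrue)
  tr
}

# frame-wise rate vector for a NeuronSpec on a KinematicSeries (Hz)
specRate <- function(kin, spec) {
  av <- ahv(kin); av[is.na(av)] <- 0
  sp <- speed(kin); sp[is.na(sp)] <- 0
  r <- spec$baselineRate + spec$ahvGainRight * pmax(av, 0) +
    spec$ahvGainLeft * pmax(-av, 0) + spec$speedGain * sp
  r <- pmax(r, 0)
  if (spec$hdConcentration > 0) {
    k <- spec$hdConcentration
    d <- (headDirection(kin) - spec$hdPreferred) * pi / 180
    r <- r * exp(k * cos(d)) / besselI(k, 0)
  }
  r
}

# draw an inhomogeneous Poisson train from a piecewise-constant rate,
# then enforce an absolute refractory dead time
drawPoissonTrain <- function(rate, t0, dt, refractoryS) {
  counts <- stats::rpois(length(rate), rate * dt)
  idx <- rep.int(seq_along(rate), counts)
  if (!length(idx)) return(numeric(0))
  times <- sort(t0 + (idx - 1L) * dt + stats::runif(length(idx)) * dt)
  if (refractoryS > 0 && length(times) > 1L) {
    keep <- logical(length(times))
    last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= refractoryS) { keep[i] <- TRUE; last <- times[i] }
    }
    times <- times[keep]
  }
  times
}

#' Simulate a tuned spike train on a kinematic series
#'
#' Inhomogeneous Poisson spiking with the rate model of [neuronSpec()],
#' thinned by an absolute refractory dead time.
#'
#' @param kin a \linkS4class{KinematicSeries} covering the session.
#' @param spec a \code{NeuronSpec}.
#' @param seed RNG seed.
#' @param unitId identifier for the returned train.
#' @return A \linkS4class{SpikeTrain}.
#' @export
simulateTunedSpikes <- function(kin, spec, seed = 1, unitId = "sim") {
  set.seed(seed)
  rate <- specRate(kin, spec)
  if (max(rate) > 500)
    stopf("instantaneous rate %.1f Hz exceeds 500 Hz: unphysiological spec",
          max(rate))
  tv <- frameTimes(kin)
  dt <- stats::median(diff(tv))
  times <- drawPoissonTrain(rate, tv[1L], dt, spec$refractoryMs / 1000)
  SpikeTrain(times, unitId = unitId)
}

#' Build the passive-rotation stimulus profile
#'
#' One full sinusoidal period of platform position (amplitude
#' \code{peakDisplacement}, period 7 s by default) flanked by
#' half-sinusoid ramps of the same period that move the platform from
#' rest to the sinusoid's starting extreme and back, so position and
#' velocity start and end at zero and the net displacement is zero. Peak
#' velocity is \code{2 * pi * peakDisplacement / period} (80.8 deg/s for
#' the default 90 deg / 7 s stimulus), reached during the main sinusoid.
#' For a \code{"CW"} stimulus the main rotation moves clockwise during
#' its first half-cycle (the 3.5-s "rotation window" used by direction
#' analyses, starting at \code{period / 2} after profile onset).
#'
#' @param peakDisplacement position amplitude, degrees (default 90).
#' @param period sinusoid period, seconds (default 7).
#' @param direction \code{"CW"} (clockwise first) or \code{"CCW"}.
#' @param dt profile sample spacing, seconds.
#' @return A \linkS4class{VelocityProfile} of duration \code{2 * period}
#'   (ramp, full period, ramp).
#' @export
makeRotationProfile <- function(peakDisplacement = 90, period = 7,
                                direction = c("CW", "CCW"), dt = 0.005) {
  direction <- match.arg(direction)
  if (peakDisplacement < 0) stopf("peakDisplacement must be >= 0")
  A <- peakDisplacement
  w <- 2 * pi / period
  tv <- seq(0, 2 * period, by = dt)
  pos <- numeric(length(tv)); vel <- numeric(length(tv))
  ramp <- tv <= period / 2
  pos[ramp] <- -(A / 2) * (1 - cos(w * tv[ramp]))
  vel[ramp] <- -(A / 2) * w * sin(w * tv[ramp])
  main <- tv > period / 2 & tv <= 3 * period / 2
  tm <- tv[main] - period / 2
  pos[main] <- -A * cos(w * tm)
  vel[main] <- A * w * sin(w * tm)
  exit <- tv > 3 * period / 2
  te <- tv[exit] - 3 * period / 2
  pos[exit] <- -(A / 2) * (1 + cos(w * te))
  vel[exit] <- (A / 2) * w * sin(w * te)
  if (direction == "CCW") { pos <- -pos; vel <- -vel }
  vel[c(1L, length(vel))] <- 0
  new("VelocityProfile", t = tv, position = pos, velocity = vel)
}

#' Build a go/no-go discrimination stimulus profile
#'
#' A symmetric, smooth (Gaussian-bump) velocity profile of fixed duration
#' whose peak velocity occurs at the midpoint (16.1 s for the default 32.2-s
#' stimulus) and whose integrated displacement is \code{displacement}
#' degrees, so stimuli with different peak speeds share onset, offset and
#' area under the curve.
#'
#' @param peakVelocity peak rotation speed, deg/s.
#' @param duration stimulus duration, seconds (default 32.2).
#' @param displacement total rotation, degrees (default 90).
#' @param direction \code{"CW"} or \code{"CCW"}.
#' @param dt sample spacing, seconds.
#' @return A \linkS4class{VelocityProfile}.
#' @export
makeDiscriminationProfile <- function(peakVelocity, duration = 32.2,
                                      displacement = 90,
                                      direction = c("CW", "CCW"), dt = 0.01) {
  direction <- match.arg(direction)
  stopifnot(peakVelocity > 0, duration > 0)
  tv <- seq(0, duration, by = dt)
  w <- displacement / (peakVelocity * sqrt(2 * pi))
  g <- exp(-((tv - duration / 2) / w)^2 / 2)
  edge <- g[1L]
  vel <- peakVelocity * (g - edge) / (1 - edge)
  vel <- pmax(vel, 0)
  sgn <- if (direction == "CW") 1 else -1
  vel <- sgn * vel
  pos <- cumsum(c(0, (vel[-1L] + vel[-length(vel)]) / 2 * dt))
  new("VelocityProfile", t = tv, position = pos, velocity = vel)
}

#' Simulate a head-fixed passive-rotation session
#'
#' Generates pseudo-randomly interleaved rotation trials under the three
#' experimental conditions (vestibular, vestibular + visual, visual) for a
#' set of simulated units. Each unit's rate during a trial is
#' \code{max(0, baseline + speedGain[cond] * |v(t)| + dirGain[cond] * v(t))},
#' so condition-specific gains can emulate visual gain enhancement; between
#' trials units fire at baseline.
#'
#' @param specs list of per-unit parameter lists with elements
#'   \code{baseline} (Hz), \code{speedGain} and \code{dirGain} (named numeric
#'   per condition, Hz per (deg/s)).
#' @param nTrialsPerCondition trials per condition x direction cell (>= 2).
#' @param seed RNG seed.
#' @param conditions condition labels.
#' @param profile a \linkS4class{VelocityProfile} (default the 90 deg / 7 s
#'   stimulus).
#' @param stationaryRange range of the stationary inter-trial period,
#'   seconds; the lower bound must exceed the profile duration so every
#'   trial has a baseline window of equal length.
#' @return list(spikes, trials, profiles, specs): spike trains, the trial
#'   table (\code{trial_id, condition, direction, t_onset, t_offset,
#'   profile_id}), and the CW/CCW profiles.
#' @export
simulateRotationSession <- function(specs, nTrialsPerCondition = 10, seed = 1,
                                    conditions = c("vestibular",
                                                   "vestibular_visual",
                                                   "visual"),
                                    profile = makeRotationProfile(),
                                    stationaryRange = c(15, 30)) {
  if (nTrialsPerCondition < 2) stopf("need >= 2 trials per condition cell")
  set.seed(seed)
  dur <- max(profileTime(profile))
  if (stationaryRange[1L] < dur)
    warnf("stationary period shorter than the rotation; baseline windows will overlap previous trials")
  grid <- expand.grid(condition = conditions, direction = c("CW", "CCW"),
                      rep = seq_len(nTrialsPerCondition),
                      stringsAsFactors = FALSE)
  grid <- grid[sample.int(nrow(grid)), c("condition", "direction")]
  nTr <- nrow(grid)
  iti <- stats::runif(nTr, stationaryRange[1L], stationaryRange[2L])
  onset <- cumsum(iti) + c(0, cumsum(rep(dur, nTr - 1L)))
  trials <- data.frame(trial_id = seq_len(nTr), condition = grid$condition,
                       direction = grid$direction, t_onset = onset,
                       t_offset = onset + dur,
                       profile_id = grid$direction,
                       stringsAsFactors = FALSE)
  sessionEnd <- trials$t_offset[nTr] + 10

  # session rate grid
  dt <- 0.01
  tg <- seq(0, sessionEnd, by = dt)
  vProf <- stats::approx(profileTime(profile), profileVelocity(profile),
                         xout = seq(0, dur, by = dt), rule = 2)$y
  spikes <- vector("list", length(specs))
  for (u in seq_along(specs)) {
    sp <- specs[[u]]
    rate <- rep(sp$baseline, length(tg))
    for (i in seq_len(nTr)) {
      idx <- which(tg >= trials$t_onset[i] & tg < trials$t_offset[i])
      v <- vProf[pmin(seq_along(idx), length(vProf))]
      if (trials$direction[i] == "CCW") v <- -v
      cond <- trials$condition[i]
      rate[idx] <- pmax(0, sp$baseline +
                          sp$speedGain[[cond]] * abs(v) +
                          (if (!is.null(sp$dirGain)) sp$dirGain[[cond]] else 0) * v)
    }
    set.seed(childSeed(seed, u))
    spikes[[u]] <- SpikeTrain(drawPoissonTrain(rate, 0, dt, 0.001),
                              unitId = sprintf("sim%03d", u))
  }
  names(spikes) <- vapply(spikes, unitId, "")
  list(spikes = spikes, trials = trials,
       profiles = list(CW = profile,
                       CCW = {
                         p <- profile
                         p@velocity <- -p@velocity
                         p@position <- -p@position
                         p
                       }),
       specs = specs)
}

# smooth biphasic waveform template on the 4-ms, 30-kHz grid (121 samples,
# trough at sample 49); parameters in microvolts / microseconds
waveformTemplate <- function(troughAmp, troughSd, t2pDur, peak2Frac,
                             preFrac = 0.08, preLag = 200, preSd = 90) {
  grid <- (seq_len(121L) - 49L) * (1e6 / 30000)  # -1600 .. +2400 us
  peakSd <- t2pDur / 2.2
  w <- -troughAmp * exp(-grid^2 / (2 * troughSd^2)) +
    peak2Frac * troughAmp * exp(-(grid - t2pDur)^2 / (2 * peakSd^2)) +
    preFrac * troughAmp * exp(-(grid + preLag)^2 / (2 * preSd^2))
  w
}

# place a single-channel template onto a probe with Gaussian spatial decay
spreadWaveform <- function(w, peakCh, positions, spatialSd = 35) {
  decay <- exp(-(positions - positions[peakCh])^2 / (2 * spatialSd^2))
  outer(decay, w)
}

# gamma-ISI spike train of given mean rate (Hz) and shape, length duration
gammaTrain <- function(rate, shape, duration) {
  n <- max(10L, ceiling(rate * duration * 1.5))
  isi <- stats::rgamma(n, shape = shape, rate = shape * rate)
  tt <- cumsum(isi)
  tt[tt < duration]
}

#' Simulate a Fix/Free waveform library with ground-truth matches
#'
#' Builds paired recording sessions for testing cross-session unit matching:
#' each "Fix" unit has a "Free" counterpart whose waveform is an
#' amplitude/shape-jittered copy placed on the same or a neighbouring
#' channel, and whose spike train is re-drawn from a perturbed gamma-ISI
#' process. Distractor units with physiologically distinct spike shapes
#' (trough-to-peak durations differing by >= 35% from every Fix unit) are
#' added to the Free session.
#'
#' @param nPairs number of true Fix/Free pairs.
#' @param nDistractors number of unmatched Free-only units.
#' @param jitter list with elements \code{amplitude} (relative SD of the
#'   amplitude scale), \code{shape} (relative SD of added shape noise),
#'   \code{isi} (relative SD of ISI-parameter perturbation), \code{channel}
#'   (maximum channel displacement, rows). Defaults emulate a stable chronic
#'   recording a few hours apart.
#' @param seed RNG seed.
#' @param nChannels probe channels (20-um vertical pitch).
#' @param duration session length used for ISI statistics, seconds.
#' @return list(fix, free, truth): each session is a list with
#'   \code{spikes}, \code{waveforms}, \code{channelPositions}; \code{truth}
#'   is a data.frame \code{fix_id, free_id} of the injective ground-truth
#'   mapping.
#' @export
simulateWaveformLibrary <- function(nPairs = 20, nDistractors = 20,
                                    jitter = list(amplitude = 0.05,
                                                  shape = 0.02, isi = 0.05,
                                                  channel = 1),
                                    seed = 1, nChannels = 32,
                                    duration = 400) {
  set.seed(seed)
  positions <- seq_len(nChannels) * 20
  names(positions) <- seq_len(nChannels)

  troughAmp <- stats::runif(nPairs, 60, 150)
  troughSd <- stats::runif(nPairs, 90, 160)
  t2p <- stats::runif(nPairs, 250, 750)
  p2frac <- stats::runif(nPairs, 0.2, 0.5)
  chans <- sample(3:(nChannels - 2), nPairs, replace = TRUE)
  shape <- stats::runif(nPairs, 1.5, 4)
  rate <- stats::runif(nPairs, 2, 10)

  fixSpikes <- list(); fixWf <- list()
  freeSpikes <- list(); freeWf <- list()
  for (i in seq_len(nPairs)) {
    idF <- sprintf("fix%02d", i)
    w <- waveformTemplate(troughAmp[i], troughSd[i], t2p[i], p2frac[i])
    fixWf[[idF]] <- UnitWaveform(spreadWaveform(w, chans[i], positions),
                                 channelPositions = positions, unitId = idF)
    fixSpikes[[idF]] <- SpikeTrain(gammaTrain(rate[i], shape[i], duration),
                                   unitId = idF)
    idR <- sprintf("free%02d", i)
    ampScale <- 1 + stats::rnorm(1) * jitter$amplitude
    noise <- if (jitter$shape > 0)
      slideMean(stats::rnorm(121L), 7L) * jitter$shape * troughAmp[i]
    else 0
    w2 <- ampScale * w + noise
    ch2 <- chans[i] + sample(seq(-jitter$channel, jitter$channel), 1L)
    ch2 <- min(max(ch2, 1L), nChannels)
    freeWf[[idR]] <- UnitWaveform(spreadWaveform(w2, ch2, positions),
                                  channelPositions = positions, unitId = idR)
    pert <- function(x) x * (1 + stats::rnorm(1) * jitter$isi)
    freeSpikes[[idR]] <- SpikeTrain(
      gammaTrain(max(pert(rate[i]), 0.2), max(pert(shape[i]), 1), duration),
      unitId = idR)
  }

  # distractors: trough-to-peak duration kept >= 35% away from every pair
  d <- 0L
  while (d < nDistractors) {
    cand <- stats::runif(1, 150, 950)
    if (min(abs(cand - t2p) / t2p) < 0.35) next
    d <- d + 1L
    idD <- sprintf("distr%02d", d)
    w <- waveformTemplate(stats::runif(1, 60, 150), stats::runif(1, 90, 160),
                          cand, stats::runif(1, 0.2, 0.5))
    chD <- sample(seq_len(nChannels), 1L)
    freeWf[[idD]] <- UnitWaveform(spreadWaveform(w, chD, positions),
                                  channelPositions = positions, unitId = idD)
    freeSpikes[[idD]] <- SpikeTrain(
      gammaTrain(stats::runif(1, 2, 10), stats::runif(1, 1.5, 4), duration),
      unitId = idD)
  }

  list(fix = list(spikes = fixSpikes, waveforms = fixWf,
                  channelPositions = positions),
       free = list(spikes = freeSpikes, waveforms = freeWf,
                   channelPositions = positions),
       truth = data.frame(fix_id = sprintf("fix%02d", seq_len(nPairs)),
                          free_id = sprintf("free%02d", seq_len(nPairs)),
                          stringsAsFactors = FALSE))
}

#' Simulate a synaptically coupled spike-train pair
#'
#' Unit B fires its own Poisson spikes; in the excitatory variant each A
#' spike additionally triggers a B spike at \code{delayMs} (plus jitter)
#' with probability \code{pTransmission}; the inhibitory variant instead
#' deletes B spikes within a window after each A spike with that
#' probability.
#'
#' @param rateA,rateB baseline Poisson rates, Hz.
#' @param delayMs synaptic delay, ms (0 < delay < 50).
#' @param pTransmission transmission (or deletion) probability in [0, 1].
#' @param duration recording length, seconds.
#' @param seed RNG seed.
#' @param type \code{"excitatory"} or \code{"inhibitory"}.
#' @param jitterMs SD of transmission-delay jitter, ms.
#' @param windowMs width of the inhibitory deletion window, ms.
#' @return list(a, b) of \linkS4class{SpikeTrain}.
#' @export
simulateCoupledPair <- function(rateA = 10, rateB = 10, delayMs = 2,
                                pTransmission = 0.2, duration = 600,
                                seed = 1, type = c("excitatory",
                                                   "inhibitory"),
                                jitterMs = 0.2, windowMs = 3) {
  type <- match.arg(type)
  stopifnot(pTransmission >= 0, pTransmission <= 1,
            delayMs > 0, delayMs < 50)
  set.seed(seed)
  aT <- cumsum(stats::rexp(ceiling(rateA * duration * 1.3) + 10, rateA))
  aT <- aT[aT < duration]
  bT <- cumsum(stats::rexp(ceiling(rateB * duration * 1.3) + 10, rateB))
  bT <- bT[bT < duration]
  if (type == "excitatory") {
    trig <- aT[stats::runif(length(aT)) < pTransmission]
    extra <- trig + delayMs / 1000 + stats::rnorm(length(trig)) * jitterMs / 1000
    bT <- sort(c(bT, extra[extra > 0 & extra < duration]))
  } else {
    trig <- aT[stats::runif(length(aT)) < pTransmission]
    if (length(trig)) {
      lo <- findInterval(trig + delayMs / 1000 - 1e-9, bT)
      hi <- findInterval(trig + (delayMs + windowMs) / 1000, bT)
      del <- unlist(Map(function(l, h) if (h > l) (l + 1L):h else integer(0),
                        lo, hi))
      if (length(del)) bT <- bT[-unique(del)]
    }
  }
  bT <- bT[!duplicated(round(bT, 7))]
  list(a = SpikeTrain(aT, unitId = "A"), b = SpikeTrain(bT, unitId = "B"))
}

# expected block accuracy of the simulated observer at speed difference d
observerAccuracy <- function(d, threshold, slope, lapse) {
  if (slope <= 0) {
    a <- ifelse(d > threshold, 1 - lapse, 0.5)
  } else {
    L0 <- stats::plogis(-threshold / slope)
    L <- stats::plogis((d - threshold) / slope)
    a <- 0.5 + (0.5 - lapse) * (L - L0) / (1 - L0)
  }
  pmin(pmax(a, 0), 1)
}

#' Simulate a go/no-go rotation-discrimination session
#'
#' A simulated observer performs blocks of 20 trials (10 S+ / 10 S- in
#' pseudo-random order) for each stimulus pair. The observer's probability
#' of a correct response follows a logistic psychometric function of the
#' peak-speed difference |S+ - S-| with the given threshold (midpoint),
#' slope and lapse rate; licking is reported as the number of 250-ms lick
#' bins after the velocity peak (correct S+ responses produce >= 2 bins).
#'
#' @param stimulusPairs data.frame with columns \code{peak_splus,
#'   peak_sminus} (deg/s), or a numeric vector of S+ peaks with S- fixed at
#'   10 deg/s.
#' @param nBlocks blocks per pair.
#' @param threshold psychometric midpoint, deg/s.
#' @param slope psychometric slope, deg/s (0 = step observer).
#' @param lapse lapse rate in [0, 0.5).
#' @param condition label attached to all trials.
#' @param seed RNG seed.
#' @return A session data.frame with one row per trial: \code{block, trial,
#'   stimulus, peak_splus, peak_sminus, condition, lick_bins}.
#' @export
simulateGoNoGoSession <- function(stimulusPairs, nBlocks = 5, threshold = 15,
                                  slope = 3, lapse = 0.02,
                                  condition = "vestibular", seed = 1) {
  if (is.numeric(stimulusPairs))
    stimulusPairs <- data.frame(peak_splus = stimulusPairs, peak_sminus = 10)
  set.seed(seed)
  out <- list()
  for (p in seq_len(nrow(stimulusPairs))) {
    d <- abs(stimulusPairs$peak_splus[p] - stimulusPairs$peak_sminus[p])
    acc <- observerAccuracy(d, threshold, slope, lapse)
    for (b in seq_len(nBlocks)) {
      stim <- sample(rep(c("S+", "S-"), each = 10L))
      correct <- stats::runif(20L) < acc
      lick <- ifelse(stim == "S+",
                     ifelse(correct, 2L + stats::rpois(20L, 1),
                            stats::rbinom(20L, 1L, 0.5)),
                     ifelse(correct, stats::rbinom(20L, 1L, 0.5),
                            2L + stats::rpois(20L, 1)))
      out[[length(out) + 1L]] <- data.frame(
        block = b, trial = seq_len(20L), stimulus = stim,
        peak_splus = stimulusPairs$peak_splus[p],
        peak_sminus = stimulusPairs$peak_sminus[p],
        condition = condition, lick_bins = as.integer(lick),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
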