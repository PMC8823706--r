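#' @import methods
NULL

#' SpikeTrain: spike times of one isolated unit
#'
#' Container for the spike times of a single curated unit, in seconds from
#' session start. Times are strictly ascending and non-negative; this is the
#' universal input to every analysis stage.
#'
#' @slot unitId character(1), opaque unit identifier.
#' @slot times numeric, strictly ascending spike times in seconds.
#' @slot peakChannel integer(1), channel index with the largest-amplitude
#'   mean waveform (NA when unknown).
#' @slot flags character, curation flags attached by filters (e.g.
#'   \code{"below_min_spikes"}); curation never silently drops a unit.
#'
#' @export
setClass("SpikeTrain",
  representation(
    unitId = "character",
    times = "numeric",
    peakChannel = "integer",
    flags = "character"
  ),
  prototype(unitId = NA_character_, times = numeric(0),
            peakChannel = NA_integer_, flags = character(0))
)

setValidity("SpikeTrain", function(object) {
  msg <- character(0)
  t <- object@times
  if (length(object@unitId) != 1L)
    msg <- c(msg, "unitId must be length 1")
  if (anyNA(t))
    msg <- c(msg, "spike times must not contain NA")
  else {
    if (length(t) && t[1L] < 0)
      msg <- c(msg, "spike times must be non-negative")
    if (is.unsorted(t, strictly = TRUE))
      msg <- c(msg, "spike times must be strictly ascending (no duplicates)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpikeTrain
#'
#' @param times numeric spike times, seconds from session start.
#' @param unitId unit identifier (coerced to character).
#' @param peakChannel integer channel index of the largest waveform, or NA.
#' @param flags character vector of curation flags.
#' @return A \linkS4class{SpikeTrain}.
#' @examples
#' st <- SpikeTrain(c(0.1, 0.5, 1.2), unitId = "u1")
#' nSpikes(st)
#' @export
SpikeTrain <- function(times, unitId = "unit", peakChannel = NA_integer_,
                       flags = character(0)) {
  new("SpikeTrain", unitId = as.character(unitId),
      times = as.numeric(times),
      peakChannel = as.integer(peakChannel), flags = flags)
}

#' UnitWaveform: mean multi-channel spike waveform
#'
#' Mean extracellular spike waveform of one unit across probe channels, in
#' microvolts, with channel geometry. The analysis window spans 4 ms around
#' the trough on the peak channel.
#'
#' @slot unitId character(1) unit identifier.
#' @slot samples numeric matrix, channels x time samples, microvolts.
#' @slot sampleInterval numeric(1), microseconds between samples.
#' @slot channelPositions numeric, vertical position of each channel row,
#'   micrometers.
#' @slot peakChannel integer(1), row index attaining the most negative sample.
#'
#' @export
setClass("UnitWaveform",
  representation(
    unitId = "character",
    samples = "matrix",
    sampleInterval = "numeric",
    channelPositions = "numeric",
    peakChannel = "integer"
  )
)

setValidity("UnitWaveform", function(object) {
  msg <- character(0)
  s <- object@samples
  if (!is.numeric(s) || !length(s))
    msg <- c(msg, "samples must be a non-empty numeric matrix")
  if (length(object@channelPositions) != nrow(s))
    msg <- c(msg, "channelPositions must have one entry per channel row")
  pc <- object@peakChannel
  if (length(pc) != 1L || is.na(pc) || pc < 1L || pc > nrow(s))
    msg <- c(msg, "peakChannel out of range")
  else if (abs(min(s[pc, ]) - min(s)) > 1e-9)
    msg <- c(msg, "peakChannel must attain the most negative sample")
  if (object@sampleInterval <= 0)
    msg <- c(msg, "sampleInterval must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a UnitWaveform
#'
#' @param samples channels x time numeric matrix, microvolts.
#' @param sampleInterval sample spacing, microseconds (default 100/3, i.e.
#'   30 kHz).
#' @param channelPositions vertical channel positions, micrometers.
#' @param unitId unit identifier.
#' @param peakChannel channel attaining the minimum sample; computed when
#'   missing.
#' @return A \linkS4class{UnitWaveform}.
#' @export
UnitWaveform <- function(samples, sampleInterval = 1e6 / 30000,
                         channelPositions = seq_len(nrow(samples)) * 20,
                         unitId = "unit", peakChannel = NULL) {
  samples <- as.matrix(samples)
  if (is.null(peakChannel))
    peakChannel <- as.integer(which.min(apply(samples, 1L, min)))
  new("UnitWaveform", unitId = as.character(unitId), samples = samples,
      sampleInterval = as.numeric(sampleInterval),
      channelPositions = as.numeric(channelPositions),
      peakChannel = as.integer(peakChannel))
}

#' VelocityProfile: stimulus position and velocity trace
#'
#' The position (degrees) and velocity (degrees/s) of one rotation stimulus,
#' sampled on a regular grid relative to stimulus onset. Velocity is the
#' derivative of position; profiles start and end at zero velocity.
#'
#' @slot t numeric, seconds relative to stimulus onset.
#' @slot position numeric, platform (or grating) position, degrees.
#' @slot velocity numeric, degrees/s; positive = clockwise.
#'
#' @export
setClass("VelocityProfile",
  representation(t = "numeric", position = "numeric", velocity = "numeric")
)

setValidity("VelocityProfile", function(object) {
  msg <- character(0)
  n <- length(object@t)
  if (length(object@position) != n || length(object@velocity) != n)
    msg <- c(msg, "t, position and velocity must have equal length")
  if (n > 1L && is.unsorted(object@t, strictly = TRUE))
    msg <- c(msg, "t must be strictly increasing")
  if (n > 2L) {
    dt <- diff(object@t)
    dnum <- diff(object@position) / dt
    vmid <- (object@velocity[-1L] + object@velocity[-n]) / 2
    scale <- max(abs(object@velocity), 1)
    if (max(abs(dnum - vmid)) > 0.05 * scale + 1e-6)
      msg <- c(msg, "velocity must be the derivative of position (within 5%)")
    if (abs(object@velocity[1L]) > 1e-6 * scale ||
        abs(object@velocity[n]) > 1e-6 * scale)
      msg <- c(msg, "profile must start and end at zero velocity")
  }
  if (length(msg)) msg else TRUE
})

#' KinematicSeries: frame-wise head kinematics
#'
#' Per-frame head direction, angular head velocity and locomotion speed
#' derived from a tracking table. Head direction is in [0, 360) degrees;
#' AHV is signed with positive values for rightward/clockwise head turns.
#'
#' @slot t numeric, frame timestamps, seconds.
#' @slot headDirection numeric, degrees in [0, 360).
#' @slot ahv numeric, degrees/s, positive = clockwise; NA over the first
#'   derivative window.
#' @slot speed numeric, cm/s, non-negative.
#'
#' @export
setClass("KinematicSeries",
  representation(t = "numeric", headDirection = "numeric",
                 ahv = "numeric", speed = "numeric")
)

setValidity("KinematicSeries", function(object) {
  msg <- character(0)
  n <- length(object@t)
  if (length(object@headDirection) != n || length(object@ahv) != n ||
      length(object@speed) != n)
    msg <- c(msg, "all series must share the frame grid length")
  hd <- object@headDirection
  if (any(hd < 0 | hd >= 360, na.rm = TRUE))
    msg <- c(msg, "headDirection must lie in [0, 360)")
  if (any(object@speed < 0, na.rm = TRUE))
    msg <- c(msg, "speed must be non-negative")
  if (any(is.infinite(object@ahv)))
    msg <- c(msg, "ahv must be finite or NA")
  if (length(msg)) msg else TRUE
})
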