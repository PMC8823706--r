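#' Accessors for ahvtools S4 classes
#'
#' Accessor generics for \linkS4class{SpikeTrain}, \linkS4class{UnitWaveform},
#' \linkS4class{VelocityProfile} and \linkS4class{KinematicSeries}. Slots are
#' never accessed directly by user code.
#'
#' @param x an ahvtools object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("unitId", function(x) standardGeneric("unitId"))
#' @rdname accessors
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))
#' @rdname accessors
#' @export
setGeneric("peakChannel", function(x) standardGeneric("peakChannel"))
#' @rdname accessors
#' @export
setGeneric("unitFlags", function(x) standardGeneric("unitFlags"))
#' @rdname accessors
#' @export
setGeneric("waveformMatrix", function(x) standardGeneric("waveformMatrix"))
#' @rdname accessors
#' @export
setGeneric("sampleInterval", function(x) standardGeneric("sampleInterval"))
#' @rdname accessors
#' @export
setGeneric("channelPositions", function(x) standardGeneric("channelPositions"))
#' @rdname accessors
#' @export
setGeneric("profileTime", function(x) standardGeneric("profileTime"))
#' @rdname accessors
#' @export
setGeneric("profilePosition", function(x) standardGeneric("profilePosition"))
#' @rdname accessors
#' @export
setGeneric("profileVelocity", function(x) standardGeneric("profileVelocity"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("headDirection", function(x) standardGeneric("headDirection"))
#' @rdname accessors
#' @export
setGeneric("ahv", function(x) standardGeneric("ahv"))
#' @rdname accessors
#' @export
setGeneric("speed", function(x) standardGeneric("speed"))

#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("unitId", "SpikeTrain", function(x) x@unitId)
#' @rdname accessors
#' @export
setMethod("nSpikes", "SpikeTrain", function(x) length(x@times))
#' @rdname accessors
#' @export
setMethod("peakChannel", "SpikeTrain", function(x) x@peakChannel)
#' @rdname accessors
#' @export
setMethod("unitFlags", "SpikeTrain", function(x) x@flags)

#' @rdname accessors
#' @export
setMethod("unitId", "UnitWaveform", function(x) x@unitId)
#' @rdname accessors
#' @export
setMethod("waveformMatrix", "UnitWaveform", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("sampleInterval", "UnitWaveform", function(x) x@sampleInterval)
#' @rdname accessors
#' @export
setMethod("channelPositions", "UnitWaveform", function(x) x@channelPositions)
#' @rdname accessors
#' @export
setMethod("peakChannel", "UnitWaveform", function(x) x@peakChannel)

#' @rdname accessors
#' @export
setMethod("profileTime", "VelocityProfile", function(x) x@t)
#' @rdname accessors
#' @export
setMethod("profilePosition", "VelocityProfile", function(x) x@position)
#' @rdname accessors
#' @export
setMethod("profileVelocity", "VelocityProfile", function(x) x@velocity)

#' @rdname accessors
#' @export
setMethod("frameTimes", "KinematicSeries", function(x) x@t)
#' @rdname accessors
#' @export
setMethod("headDirection", "KinematicSeries", function(x) x@headDirection)
#' @rdname accessors
#' @export
setMethod("ahv", "KinematicSeries", function(x) x@ahv)
#' @rdname accessors
#' @export
setMethod("speed", "KinematicSeries", function(x) x@speed)

setMethod("show", "SpikeTrain", function(object) {
  n <- length(object@times)
  dur <- if (n) max(object@times) else 0
  cat(sprintf("SpikeTrain '%s': %d spikes over %.1f s (mean %.2f Hz)",
              object@unitId, n, dur, if (dur > 0) n / dur else 0))
  if (!is.na(object@peakChannel))
    cat(sprintf(", peak channel %d", object@peakChannel))
  if (length(object@flags))
    cat(sprintf("\n  flags: %s", paste(object@flags, collapse = ", ")))
  cat("\n")
})

setMethod("show", "UnitWaveform", function(object) {
  cat(sprintf(
    "UnitWaveform '%s': %d channels x %d samples @ %.1f kHz, peak channel %d\n",
    object@unitId, nrow(object@samples), ncol(object@samples),
    1e3 / object@sampleInterval, object@peakChannel))
})

setMethod("show", "VelocityProfile", function(object) {
  cat(sprintf(
    "VelocityProfile: %.2f s, peak |velocity| %.1f deg/s, displacement %.1f deg\n",
    diff(range(object@t)), max(abs(object@velocity)),
    max(abs(object@position))))
})

setMethod("show", "KinematicSeries", function(object) {
  ok <- !is.na(object@ahv)
  cat(sprintf(
    "KinematicSeries: %d frames over %.1f s; AHV sd %.1f deg/s, median speed %.1f cm/s\n",
    length(object@t), diff(range(object@t)),
    stats::sd(object@ahv[ok]), stats::median(object@speed, na.rm = TRUE)))
})
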