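#' Read a spike-sorter-style session directory
#'
#' Loads curated single units from a directory of plain-text sorter output:
#' \code{spike_times.csv} (\code{unit_id,time_s}), \code{cluster_info.csv}
#' (\code{unit_id,peak_channel,sample_interval_us}), \code{waveforms.csv}
#' (long format \code{unit_id,channel,sample,value_uv}) and
#' \code{channel_positions.csv} (\code{channel,y_um}). Units failing the
#' minimum spike-count curation rule are flagged, never dropped.
#'
#' @param path directory containing the four tables.
#' @param minSpikes curation threshold; units with fewer spikes are flagged
#'   \code{"below_min_spikes"} (default 900).
#' @return A list with \code{spikes} (named list of \linkS4class{SpikeTrain}),
#'   \code{waveforms} (named list of \linkS4class{UnitWaveform}) and
#'   \code{channelPositions} (numeric, micrometers, named by channel).
#' @seealso [writeSpikeData()] for the inverse writer.
#' @export
loadSpikeData <- function(path, minSpikes = 900) {
  need <- c("spike_times.csv", "cluster_info.csv", "waveforms.csv",
            "channel_positions.csv")
  for (f in need) {
    if (!file.exists(file.path(path, f)))
      stopf("missing required file '%s' in %s", f, path)
  }
  st <- utils::read.csv(file.path(path, "spike_times.csv"),
                        colClasses = c(unit_id = "character"))
  ci <- utils::read.csv(file.path(path, "cluster_info.csv"),
                        colClasses = c(unit_id = "character"))
  wf <- utils::read.csv(file.path(path, "waveforms.csv"),
                        colClasses = c(unit_id = "character"))
  cp <- utils::read.csv(file.path(path, "channel_positions.csv"))

  ids <- sort(unique(ci$unit_id))
  bad <- setdiff(unique(c(st$unit_id, wf$unit_id)), ids)
  bad <- c(bad, setdiff(ids, unique(st$unit_id)))
  if (length(bad))
    stopf("unit ids inconsistent between tables: %s",
          paste(sort(unique(bad)), collapse = ", "))

  pos <- cp$y_um[order(cp$channel)]
  names(pos) <- sort(cp$channel)

  spikes <- list(); waves <- list()
  for (id in ids) {
    row <- ci[ci$unit_id == id, , drop = FALSE]
    times <- sort(st$time_s[st$unit_id == id])
    flags <- character(0)
    if (length(times) < minSpikes) flags <- "below_min_spikes"
    spikes[[id]] <- SpikeTrain(times, unitId = id,
                               peakChannel = as.integer(row$peak_channel),
                               flags = flags)
    w <- wf[wf$unit_id == id, , drop = FALSE]
    if (nrow(w)) {
      chans <- sort(unique(w$channel))
      nsamp <- max(w$sample)
      m <- matrix(0, length(chans), nsamp)
      m[cbind(match(w$channel, chans), w$sample)] <- w$value_uv
      waves[[id]] <- UnitWaveform(
        m, sampleInterval = row$sample_interval_us,
        channelPositions = pos[as.character(chans)], unitId = id)
    }
  }
  list(spikes = spikes, waveforms = waves, channelPositions = pos)
}

#' Write a session directory in the format read by loadSpikeData
#'
#' Times are written with microsecond precision so a write/read round trip is
#' lossless to 1 microsecond.
#'
#' @param spikes named list of \linkS4class{SpikeTrain}.
#' @param waveforms named list of \linkS4class{UnitWaveform} (may be empty).
#' @param channelPositions numeric vector of vertical positions, micrometers,
#'   named by channel index.
#' @param path output directory (created if absent).
#' @return \code{path}, invisibly.
#' @export
writeSpikeData <- function(spikes, path, waveforms = list(),
                           channelPositions = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  st <- do.call(rbind, lapply(spikes, function(s)
    data.frame(unit_id = unitId(s), time_s = sprintf("%.6f", spikeTimes(s)))))
  utils::write.csv(st, file.path(path, "spike_times.csv"), row.names = FALSE,
                   quote = FALSE)
  ci <- do.call(rbind, lapply(spikes, function(s) {
    w <- waveforms[[unitId(s)]]
    data.frame(unit_id = unitId(s), peak_channel = peakChannel(s),
               n_spikes = nSpikes(s),
               sample_interval_us =
                 if (!is.null(w)) sampleInterval(w) else NA_real_)
  }))
  utils::write.csv(ci, file.path(path, "cluster_info.csv"), row.names = FALSE,
                   quote = FALSE)
  wf <- do.call(rbind, lapply(waveforms, function(w) {
    m <- waveformMatrix(w)
    data.frame(unit_id = unitId(w),
               channel = rep(seq_len(nrow(m)), ncol(m)),
               sample = rep(seq_len(ncol(m)), each = nrow(m)),
               value_uv = as.vector(m))
  }))
  if (is.null(wf))
    wf <- data.frame(unit_id = character(0), channel = integer(0),
                     sample = integer(0), value_uv = numeric(0))
  utils::write.csv(wf, file.path(path, "waveforms.csv"), row.names = FALSE,
                   quote = FALSE)
  if (is.null(channelPositions)) {
    nch <- max(c(1L, vapply(waveforms, function(w) nrow(waveformMatrix(w)),
                            1L)))
    channelPositions <- seq_len(nch) * 20
    names(channelPositions) <- seq_len(nch)
  }
  utils::write.csv(
    data.frame(channel = as.integer(names(channelPositions)),
               y_um = as.numeric(channelPositions)),
    file.path(path, "channel_positions.csv"), row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tracking CSV into a tracking table
#'
#' Expects columns \code{t}, \code{left_x,left_y,right_x,right_y,
#' body_x,body_y} (centimeters, arena frame) and optional per-point
#' likelihood columns \code{left_lik,right_lik,body_lik}. Frames where any
#' likelihood falls below \code{likelihoodFloor} have their coordinates
#' replaced by linear interpolation between neighbouring good frames and are
#' flagged in the logical \code{interpolated} column.
#'
#' @param path CSV file path.
#' @param likelihoodFloor tracker-confidence floor below which a frame is
#'   interpolated (default 0.9).
#' @return A data.frame tracking table (nominal 40 frames/s).
#' @export
loadTracking <- function(path, likelihoodFloor = 0.9) {
  tr <- utils::read.csv(path)
  if (!"t" %in% names(tr)) stopf("tracking CSV lacks a 't' column")
  if (is.unsorted(tr$t, strictly = TRUE))
    stopf("tracking timestamps must be strictly increasing")
  coord <- intersect(c("left_x", "left_y", "right_x", "right_y",
                       "body_x", "body_y"), names(tr))
  lik <- intersect(c("left_lik", "right_lik", "body_lik", "likelihood"),
                   names(tr))
  bad <- if (length(lik))
    apply(tr[lik] < likelihoodFloor, 1L, any) else rep(FALSE, nrow(tr))
  if (any(bad)) {
    good <- which(!bad)
    if (length(good) < 2L) stopf("too few high-likelihood frames")
    for (cc in coord)
      tr[[cc]][bad] <- stats::approx(tr$t[good], tr[[cc]][good],
                                     xout = tr$t[bad], rule = 2)$y
  }
  tr$interpolated <- bad
  tr[setdiff(names(tr), lik)]
}

#' Write a tracking table as CSV
#'
#' @param tracking data.frame as returned by [loadTracking()] or
#'   [simulateTrajectory()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeTracking <- function(tracking, path) {
  utils::write.csv(tracking, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
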