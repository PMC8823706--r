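#' Derive head kinematics from a tracking table
#'
#' Head direction is the angle between the horizontal axis and the line
#' perpendicular to the axis joining the ears (the facing direction). The
#' heading series is smoothed with a sliding circular mean (unit-vector
#' averaging, 50 ms default); AHV at each frame is the circular heading
#' change over a trailing derivative window (200 ms default) divided by the
#' window length, with positive values for rightward/clockwise turns.
#' Locomotion speed is the frame-to-frame body displacement divided by the
#' frame interval, mean-filtered with the same smoothing width.
#'
#' @param tracking tracking table as returned by [loadTracking()] or
#'   [simulateTrajectory()].
#' @param smoothMs sliding-mean width, ms.
#' @param derivWindowMs trailing AHV derivative window, ms.
#' @return A \linkS4class{KinematicSeries}; AHV is NA over the first
#'   derivative window.
#' @export
computeKinematics <- function(tracking, smoothMs = 50, derivWindowMs = 200) {
  tv <- tracking$t
  n <- length(tv)
  dt <- stats::median(diff(tv))
  if ((n - 1) * dt <= derivWindowMs / 1000)
    stopf("tracking duration shorter than the AHV derivative window")

  # facing direction: ear axis (left - right) rotated -90 degrees
  vx <- tracking$left_x - tracking$right_x
  vy <- tracking$left_y - tracking$right_y
  hd <- wrap360(atan2(-vx, vy) * 180 / pi)

  width <- max(1L, round(smoothMs / 1000 / dt))
  hdS <- slideMeanCircular(hd, width)

  lag <- max(1L, round(derivWindowMs / 1000 / dt))
  u <- unwrapDeg(hdS)
  dAng <- c(rep(NA_real_, lag), u[(lag + 1L):n] - u[seq_len(n - lag)])
  av <- -dAng / (lag * dt)  # heading angle increases CCW; AHV positive = CW

  sp <- c(0, sqrt(diff(tracking$body_x)^2 + diff(tracking$body_y)^2) / dt)
  sp <- pmax(slideMean(sp, width), 0)

  new("KinematicSeries", t = tv, headDirection = hdS, ahv = av, speed = sp)
}
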