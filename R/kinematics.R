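#' Per-sample velocity and acceleration of a gaze recording
#'
#' Positions are pre-smoothed with a centred moving average (7 ms at
#' 1000 Hz, scaled to the sampling rate) and differentiated with a 5-point
#' central difference; speed is the Euclidean norm of the horizontal and
#' vertical velocities and acceleration its first difference. Samples
#' within the blink padding (50 ms on each side of a flagged run) are
#' masked to NA, as are edge samples where the stencils are incomplete.
#'
#' @param recording list with \code{samples} (time_ms, x_deg, y_deg, blink)
#'   and \code{sampling_rate}.
#' @param smooth_ms moving-average width in ms.
#' @param blink_pad_ms padding masked around blinks, ms.
#' @return list: time_ms, xs, ys (smoothed positions), vx, vy (deg/s),
#'   speed (deg/s), accel (deg/s^2), dt_ms.
#' @export
compute_kinematics <- function(recording, smooth_ms = 7,
                               blink_pad_ms = 50) {
  s <- recording$samples
  if (nrow(s) < 5) stop("recording too short for kinematics (< 5 samples)")
  fs <- recording$sampling_rate
  dt <- 1000 / fs
  w <- max(1L, round(smooth_ms * fs / 1000))
  if (w %% 2 == 0) w <- w + 1L
  ma <- function(v) if (w == 1) v else
    as.numeric(stats::filter(v, rep(1 / w, w), sides = 2))
  xs <- ma(s$x_deg); ys <- ma(s$y_deg)
  d5 <- function(v) {
    n <- length(v)
    out <- rep(NA_real_, n)
    i <- 3:(n - 2)
    out[i] <- (v[i - 2] - 8 * v[i - 1] + 8 * v[i + 1] - v[i + 2]) / (12 * dt)
    out * 1000            # deg/ms -> deg/s
  }
  vx <- d5(xs); vy <- d5(ys)
  speed <- sqrt(vx^2 + vy^2)
  accel <- c(NA, diff(speed)) / dt * 1000
  ## mask blink padding
  if (any(s$blink == 1)) {
    r <- rle(s$blink == 1)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    pad <- ceiling(blink_pad_ms / dt)
    for (k in which(r$values)) {
      idx <- max(1, starts[k] - pad):min(nrow(s), ends[k] + pad)
      speed[idx] <- NA; accel[idx] <- NA; vx[idx] <- NA; vy[idx] <- NA
    }
  }
  list(time_ms = s$time_ms, xs = xs, ys = ys, vx = vx, vy = vy,
       speed = speed, accel = accel, dt_ms = dt)
}

#' Detect saccades in a gaze recording
#'
#' A sample is a saccade candidate when its speed is at least 60 deg/s, or
#' at least 22 deg/s with acceleration magnitude at least 3800 deg/s^2.
#' Thresholding runs on a more heavily smoothed velocity trace
#' (\code{detect_smooth_ms}), which keeps tracker noise below the
#' thresholds; the boundaries of every candidate run are then refined
#' outward to the surrounding 22 deg/s crossings of the standard
#' (\code{smooth_ms = 7}) kinematics, where amplitude and peak velocity are
#' also measured, so event boundaries and kinematic measurements retain
#' millisecond accuracy on clean data. Runs separated by less than 20 ms
#' are merged (suppressing dynamic-overshoot double counts) and events with
#' amplitude of 1 degree or less are discarded.
#'
#' @param recording a gaze recording (see [compute_kinematics()]).
#' @param v_main main velocity threshold, deg/s.
#' @param v_low secondary velocity threshold and boundary criterion, deg/s.
#' @param a_thresh acceleration threshold, deg/s^2.
#' @param min_amplitude events with amplitude <= this are discarded, deg.
#' @param merge_gap_ms candidate runs closer than this are merged.
#' @param detect_smooth_ms smoothing window of the thresholding trace.
#' @param kin optional precomputed [compute_kinematics()] result.
#' @return data frame: onset, offset (ms), amplitude (deg), peak_velocity,
#'   peak_acceleration, direction (sign of horizontal displacement),
#'   start_x, end_x, start_y, end_y. Empty when nothing is detected.
#' @export
detect_saccades <- function(recording, v_main = 60, v_low = 22,
                            a_thresh = 3800, min_amplitude = 1,
                            merge_gap_ms = 20, detect_smooth_ms = 21,
                            kin = NULL) {
  if (is.null(kin)) kin <- compute_kinematics(recording)
  kd <- compute_kinematics(recording, smooth_ms = detect_smooth_ms)
  spd <- kd$speed; acd <- kd$accel
  cand <- (spd >= v_main) | (spd >= v_low & abs(acd) >= a_thresh)
  cand[is.na(cand)] <- FALSE
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      amplitude = numeric(0), peak_velocity = numeric(0),
                      peak_acceleration = numeric(0), direction = numeric(0),
                      start_x = numeric(0), end_x = numeric(0),
                      start_y = numeric(0), end_y = numeric(0))
  if (!any(cand)) return(empty)
  sp <- kin$speed; ac <- kin$accel
  r <- rle(cand)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  on <- starts[r$values]; off <- ends[r$values]
  above <- !is.na(sp) & sp >= v_low
  n <- length(sp)
  ## refine boundaries on the lightly smoothed speed: collapse each run to
  ## its speed peak, then expand outward until the three samples beyond the
  ## boundary all sit below v_low (noise tolerance)
  look <- function(i, dir) {
    idx <- i + dir * (1:3)
    idx <- idx[idx >= 1 & idx <= n]
    length(idx) > 0 && any(above[idx])
  }
  for (k in seq_along(on)) {
    seg <- sp[on[k]:off[k]]
    pk <- if (all(is.na(seg))) which.max(spd[on[k]:off[k]]) else
      which.max(seg)
    on[k] <- off[k] <- on[k] + pk - 1
    while (on[k] > 1 && look(on[k], -1)) on[k] <- on[k] - 1
    while (off[k] < n && look(off[k], 1)) off[k] <- off[k] + 1
  }
  ## merge events with small gaps
  gap <- ceiling(merge_gap_ms / kin$dt_ms)
  keep_on <- on[1]; keep_off <- off[1]
  if (length(on) > 1) for (k in 2:length(on)) {
    last <- length(keep_off)
    if (on[k] - keep_off[last] < gap) keep_off[last] <- max(keep_off[last],
                                                            off[k])
    else { keep_on <- c(keep_on, on[k]); keep_off <- c(keep_off, off[k]) }
  }
  pos <- function(v, i) ifelse(is.na(kin[[v]][i]),
                               recording$samples[[sub("s$", "_deg", v)]][i],
                               kin[[v]][i])
  x1 <- pos("xs", keep_on); x2 <- pos("xs", keep_off)
  y1 <- pos("ys", keep_on); y2 <- pos("ys", keep_off)
  amp <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  pv <- mapply(function(a, b) max(sp[a:b], na.rm = TRUE), keep_on, keep_off)
  pa <- mapply(function(a, b) suppressWarnings(
    max(abs(ac[a:b]), na.rm = TRUE)), keep_on, keep_off)
  out <- data.frame(onset = kin$time_ms[keep_on],
                    offset = kin$time_ms[keep_off], amplitude = amp,
                    peak_velocity = pv, peak_acceleration = pa,
                    direction = sign(x2 - x1), start_x = x1, end_x = x2,
                    start_y = y1, end_y = y2)
  out <- out[out$amplitude > min_amplitude & is.finite(out$amplitude), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect blinks from the blink flag
#'
#' Returns contiguous flagged runs; runs whose padded extents (50 ms by
#' default) touch or overlap are merged.
#'
#' @param recording a gaze recording.
#' @param pad_ms padding in ms applied on each side.
#' @return data frame: onset, offset (core extent, ms), pad_onset,
#'   pad_offset (padded extent).
#' @export
detect_blinks <- function(recording, pad_ms = 50) {
  s <- recording$samples
  if (is.null(s$blink)) stop("recording has no blink flags")
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      pad_onset = numeric(0), pad_offset = numeric(0))
  if (!any(s$blink == 1)) return(empty)
  r <- rle(s$blink == 1)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  on <- s$time_ms[starts[r$values]]; off <- s$time_ms[ends[r$values]]
  ## merge runs whose padded intervals overlap
  m_on <- on[1]; m_off <- off[1]
  if (length(on) > 1) for (k in 2:length(on)) {
    last <- length(m_off)
    if (on[k] - pad_ms <= m_off[last] + pad_ms) m_off[last] <- off[k]
    else { m_on <- c(m_on, on[k]); m_off <- c(m_off, off[k]) }
  }
  data.frame(onset = m_on, offset = m_off, pad_onset = m_on - pad_ms,
             pad_offset = m_off + pad_ms)
}
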