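## target position schedule from TARGET_ON messages
.target_schedule <- function(messages) {
  m <- messages[grepl("^TARGET_ON", messages$event), , drop = FALSE]
  if (!nrow(m)) stop("no TARGET_ON messages found")
  xy <- do.call(rbind, lapply(strsplit(m$event, " "), function(p)
    as.numeric(p[2:3])))
  data.frame(time_ms = m$time_ms, x = xy[, 1], y = xy[, 2])
}

#' Fixation-task summary
#'
#' Computes the fixation spatial error as the root mean square Euclidean
#' distance between gaze and the current target over fixation periods
#' (runs of at least 100 ms without saccades or padded blinks), and the
#' saccade and blink rates as event counts over the task duration.
#'
#' @param recording a gaze recording of the fixation task.
#' @param task the [task_spec()] (used for validation only).
#' @param min_fix_ms minimum fixation-period duration.
#' @return one-row data frame: spatial_error_rmse (deg), saccade_rate (/s),
#'   blink_rate (/s), analyzed_s. The RMSE is NA when no fixation period
#'   reaches the minimum duration.
#' @export
summarize_fixation_task <- function(recording, task = task_spec("fixation"),
                                    min_fix_ms = 100) {
  s <- recording$samples
  dur_s <- (max(s$time_ms) - min(s$time_ms)) / 1000
  sacc <- detect_saccades(recording)
  blinks <- detect_blinks(recording)
  excl <- rep(FALSE, nrow(s))
  mark <- function(a, b) {
    idx <- s$time_ms >= a & s$time_ms <= b
    excl[idx] <<- TRUE
  }
  for (i in seq_len(nrow(sacc))) mark(sacc$onset[i], sacc$offset[i])
  for (i in seq_len(nrow(blinks))) mark(blinks$pad_onset[i],
                                        blinks$pad_offset[i])
  ## refoveation grace after each target jump: gaze only counts against the
  ## new target once the first subsequent saccade has landed
  sched <- .target_schedule(recording$messages)
  for (tc in sched$time_ms[-1]) {
    nxt <- sacc$offset[sacc$onset >= tc]
    grace_end <- if (length(nxt)) min(min(nxt), tc + 800) else tc + 400
    mark(tc, grace_end)
  }
  excl <- excl | is.na(s$x_deg)
  dt <- 1000 / recording$sampling_rate
  r <- rle(!excl)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  fix_idx <- integer(0)
  for (k in which(r$values & r$lengths * dt >= min_fix_ms))
    fix_idx <- c(fix_idx, starts[k]:ends[k])
  rmse <- NA_real_
  if (length(fix_idx)) {
    seg <- findInterval(s$time_ms[fix_idx], sched$time_ms)
    d2 <- (s$x_deg[fix_idx] - sched$x[seg])^2 +
      (s$y_deg[fix_idx] - sched$y[seg])^2
    rmse <- sqrt(mean(d2))
  }
  data.frame(spatial_error_rmse = rmse,
             saccade_rate = nrow(sacc) / dur_s,
             blink_rate = nrow(blinks) / dur_s,
             analyzed_s = length(fix_idx) * dt / 1000)
}

#' Smooth-pursuit summary
#'
#' Velocity gain: for every complete half-cycle of target motion (between
#' consecutive target extremes), the mean horizontal eye velocity over
#' pursuit-classified samples (speed below 30 deg/s in runs of at least
#' 50 ms) within the middle two temporal quarters of the half-cycle is
#' divided by the mean target velocity over the same samples; the gain is
#' the average of these per-half-cycle ratios, in percent. The saccade rate
#' is the detected saccade count over the task duration.
#'
#' @param recording a gaze recording of the pursuit task.
#' @param task the pursuit [task_spec()] (amplitude, frequency, cycles,
#'   lead-in).
#' @param spem_v velocity ceiling for pursuit classification, deg/s.
#' @param spem_min_ms minimum duration of a pursuit run, ms.
#' @return one-row data frame: velocity_gain (percent; NA without a single
#'   complete half-cycle), saccade_rate (/s), n_half_cycles.
#' @export
summarize_spem_task <- function(recording, task = task_spec("spem"),
                                spem_v = 30, spem_min_ms = 50,
                                pursuit_smooth_ms = 41) {
  s <- recording$samples
  sacc <- detect_saccades(recording)
  dur_s <- (max(s$time_ms) - min(s$time_ms)) / 1000
  lead <- task$lead_in * 1000
  A <- task$amplitude; f <- task$frequency
  v_tgt <- function(tms) ifelse(
    tms < lead, 0,
    A * 2 * pi * f / 1000 * cos(2 * pi * f * (tms - lead) / 1000) * 1000)
  ## pursuit velocity from a wider smoothing window: pursuit is an order of
  ## magnitude slower than saccades, so the heavier low-pass is unbiased at
  ## 0.5 Hz but keeps sample noise well under the 30 deg/s ceiling
  kin <- compute_kinematics(recording, smooth_ms = pursuit_smooth_ms)
  ## pursuit classification: slow samples in sufficiently long runs,
  ## outside detected saccades
  slow <- !is.na(kin$speed) & kin$speed < spem_v
  for (i in seq_len(nrow(sacc))) {
    idx <- s$time_ms >= sacc$onset[i] - 10 & s$time_ms <= sacc$offset[i] + 10
    slow[idx] <- FALSE
  }
  dt <- kin$dt_ms
  r <- rle(slow)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  spem_ok <- rep(FALSE, nrow(s))
  for (k in which(r$values & r$lengths * dt >= spem_min_ms))
    spem_ok[starts[k]:ends[k]] <- TRUE
  ## half-cycles between target extremes
  half_ms <- 1000 / (2 * f)
  first_ext <- lead + half_ms / 2
  n_half <- 2 * task$cycles - 1
  gains <- rep(NA_real_, n_half)
  for (h in seq_len(n_half)) {
    h0 <- first_ext + (h - 1) * half_ms
    w0 <- h0 + half_ms / 4; w1 <- h0 + 3 * half_ms / 4
    idx <- which(s$time_ms >= w0 & s$time_ms < w1 & spem_ok)
    if (length(idx) < 10) next
    ve <- mean(kin$vx[idx]); vt <- mean(v_tgt(s$time_ms[idx]))
    if (abs(vt) < 1) next
    gains[h] <- ve / vt
  }
  data.frame(velocity_gain = if (all(is.na(gains))) NA_real_ else
    100 * mean(gains, na.rm = TRUE),
    saccade_rate = nrow(sacc) / dur_s,
    n_half_cycles = sum(!is.na(gains)))
}

#' Parse saccade-task trials from the message log
#'
#' Cuts the recording into trials at TRIAL_START markers; within a trial,
#' the centre TARGET_ON is the fixation onset, the peripheral TARGET_ON the
#' target onset, and the target offset follows after the task's target
#' duration. Practice trials (the first \code{n_practice}) are excluded
#' from scoring. Incomplete trailing trials are dropped with a warning.
#'
#' @param recording a gaze recording of a prosaccade or antisaccade task.
#' @param task the [task_spec()].
#' @return data frame: trial, side, t_fix_on, t_target_on, t_target_off.
#' @export
parse_trials <- function(recording, task) {
  m <- recording$messages
  starts <- m[grepl("^TRIAL_START", m$event), , drop = FALSE]
  if (!nrow(starts)) stop("message log contains no TRIAL_START markers")
  tgt <- .target_schedule(m)
  t_max <- max(recording$samples$time_ms)
  out <- list()
  for (i in seq_len(nrow(starts))) {
    k <- as.integer(sub("TRIAL_START ", "", starts$event[i]))
    t0 <- starts$time_ms[i]
    t1 <- if (i < nrow(starts)) starts$time_ms[i + 1] else Inf
    per <- tgt[tgt$time_ms >= t0 & tgt$time_ms < t1 & tgt$x != 0, ,
               drop = FALSE]
    ctr <- tgt[tgt$time_ms >= t0 & tgt$time_ms < t1 & tgt$x == 0 &
                 tgt$y == 0, , drop = FALSE]
    if (!nrow(per) || !nrow(ctr)) {
      warning(sprintf("trial %d incomplete; dropped", k))
      next
    }
    t_on <- per$time_ms[1]
    t_off <- t_on + task$target_dur * 1000
    if (t_off > t_max) {
      warning(sprintf("trial %d truncated by end of recording; dropped", k))
      next
    }
    out[[length(out) + 1]] <- data.frame(
      trial = k, side = ifelse(per$x[1] < 0, "left", "right"),
      t_fix_on = ctr$time_ms[1], t_target_on = t_on, t_target_off = t_off,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (task$n_practice > 0) {
    ord <- order(res$t_fix_on)
    res$practice <- seq_along(ord)[order(ord)] <= task$n_practice
  } else res$practice <- FALSE
  res
}

#' Validate one saccade-task trial
#'
#' A trial is valid when the central fixation started at least 100 ms
#' before target onset, was no more than 3 degrees off the fixation point,
#' no saccade or blink occurred during the pre-target fixation window, the
#' initial saccade had a latency of at least 80 ms and ended before the
#' target timed out. Invalid trials carry one machine-readable reason.
#'
#' @param trial one row of [parse_trials()] output.
#' @param saccades detected saccades of the session.
#' @param blinks detected blinks of the session.
#' @param recording the gaze recording.
#' @param fix_window_ms required pre-target fixation duration.
#' @param max_fix_offset maximum fixation offset from centre, degrees.
#' @param min_latency_ms anticipatory-saccade floor.
#' @return list: valid flag, reason (empty when valid), initial (row index
#'   into \code{saccades} of the initial saccade, NA otherwise).
#' @export
validate_trial <- function(trial, saccades, blinks, recording,
                           fix_window_ms = 100, max_fix_offset = 3,
                           min_latency_ms = 80) {
  t_on <- trial$t_target_on; t_off <- trial$t_target_off
  w0 <- t_on - fix_window_ms
  fail <- function(reason) list(valid = FALSE, reason = reason,
                                initial = NA_integer_)
  if (nrow(blinks) &&
      any(blinks$pad_onset <= t_on & blinks$pad_offset >= w0))
    return(fail("blink_in_fixation"))
  if (nrow(saccades)) {
    ## a saccade landing inside the window: fixation started too late
    if (any(saccades$offset >= w0 & saccades$onset < w0))
      return(fail("late_fixation"))
    if (any(saccades$onset >= w0 & saccades$onset < t_on))
      return(fail("saccade_in_fixation"))
  }
  s <- recording$samples
  idx <- s$time_ms >= w0 & s$time_ms < t_on & !is.na(s$x_deg)
  if (!any(idx)) return(fail("blink_in_fixation"))
  if (sqrt(mean(s$x_deg[idx])^2 + mean(s$y_deg[idx])^2) > max_fix_offset)
    return(fail("off_fixation"))
  cand <- which(saccades$onset >= t_on & saccades$onset < t_off)
  if (!length(cand)) return(fail("no_saccade"))
  ini <- cand[which.min(saccades$onset[cand])]
  if (saccades$onset[ini] - t_on < min_latency_ms)
    return(fail("anticipatory"))
  if (saccades$offset[ini] > t_off) return(fail("initial_saccade_too_late"))
  list(valid = TRUE, reason = "", initial = ini)
}

#' Score one valid saccade-task trial
#'
#' Left-side trials are mirrored to a canonical rightward frame so a single
#' code path scores both sides. Latency is the initial-saccade onset minus
#' target onset; amplitude gain is the initial-saccade amplitude over the
#' target eccentricity (percent); spatial error is the absolute distance of
#' the landing position from the required position (target for prosaccades,
#' mirror position for antisaccades) over the eccentricity (percent);
#' amplitude-adjusted peak velocity is peak velocity divided by amplitude.
#' On antisaccade direction errors, the trial is corrected when a later
#' saccade heading toward the mirror side crosses the midline before target
#' offset.
#'
#' @param trial one row of [parse_trials()] output.
#' @param val the [validate_trial()] result for that trial.
#' @param saccades detected saccades of the session.
#' @param task "prosaccade" or "antisaccade".
#' @param eccentricity target eccentricity, degrees.
#' @return one-row data frame of trial metrics.
#' @export
score_saccade_trial <- function(trial, val, saccades, task,
                                eccentricity = 9.63) {
  stopifnot(isTRUE(val$valid))
  anti <- task == "antisaccade"
  mirror <- trial$side == "left"
  flip <- function(v) if (mirror) -v else v
  ini <- saccades[val$initial, ]
  disp <- flip(ini$end_x - ini$start_x)
  dir_ok <- if (anti) disp < 0 else disp > 0
  required_x <- if (anti) -eccentricity else eccentricity
  land <- flip(ini$end_x)
  corrected <- NA
  if (anti && !dir_ok) {
    later <- saccades[saccades$onset > ini$offset &
                        saccades$onset < trial$t_target_off, , drop = FALSE]
    corrected <- FALSE
    if (nrow(later)) {
      lx0 <- flip(later$start_x); lx1 <- flip(later$end_x)
      corrected <- any(lx1 < lx0 & lx1 <= 0)
    }
  }
  data.frame(trial = trial$trial, side = trial$side,
             latency = ini$onset - trial$t_target_on,
             amplitude = ini$amplitude,
             amplitude_gain = 100 * ini$amplitude / eccentricity,
             spatial_error = 100 * abs(land - required_x) / eccentricity,
             peak_velocity = ini$peak_velocity,
             adj_peak_velocity = ini$peak_velocity / ini$amplitude,
             direction_correct = dir_ok, corrected = corrected,
             stringsAsFactors = FALSE)
}

#' Detect, validate and score all trials of a saccade-task recording
#'
#' @param recording a prosaccade or antisaccade gaze recording.
#' @param task the [task_spec()].
#' @return per-trial metrics data frame with validity columns; practice
#'   trials excluded.
#' @export
process_saccade_session <- function(recording, task) {
  if (is.character(task)) task <- task_spec(task)
  trials <- parse_trials(recording, task)
  trials <- trials[!trials$practice, , drop = FALSE]
  saccades <- detect_saccades(recording)
  blinks <- detect_blinks(recording)
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    val <- validate_trial(tr, saccades, blinks, recording)
    if (val$valid) {
      sc <- score_saccade_trial(tr, val, saccades, task$task)
      cbind(sc, valid = TRUE, invalid_reason = "")
    } else data.frame(trial = tr$trial, side = tr$side, latency = NA_real_,
                      amplitude = NA_real_, amplitude_gain = NA_real_,
                      spatial_error = NA_real_, peak_velocity = NA_real_,
                      adj_peak_velocity = NA_real_,
                      direction_correct = NA, corrected = NA, valid = FALSE,
                      invalid_reason = val$reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.mean_if <- function(x, n_min) if (length(x) >= n_min) mean(x) else NA_real_

#' Aggregate per-trial metrics into the per-subject outcome summary
#'
#' Prosaccade and antisaccade outcomes are means over valid trials with a
#' directionally correct initial saccade and require at least
#' \code{min_trials} such trials; the direction error rate requires at
#' least \code{min_trials} valid (not necessarily correct) trials; the
#' correction rate is reported only for subjects with at least
#' \code{min_errors} direction errors of whom at least one was corrected.
#' Subjects with at least \code{min_errors} errors and no correction at all
#' have all antisaccade outcomes set absent. Antisaccade costs are present
#' only when both latencies are. Absent outcomes are NA, never zero.
#'
#' @param fixation,spem one-row summaries from the respective task
#'   functions (optional).
#' @param pro,anti per-trial metrics from [process_saccade_session()]
#'   (optional).
#' @param min_trials minimum valid-and-correct trial count.
#' @param min_errors minimum direction errors for the correction rate.
#' @return one-row data frame with the 16 eye-movement outcomes and
#'   valid-trial counts.
#' @export
aggregate_subject <- function(fixation = NULL, spem = NULL, pro = NULL,
                              anti = NULL, min_trials = 7, min_errors = 5) {
  out <- data.frame(
    fixation_spatial_error = NA_real_, fixation_saccade_rate = NA_real_,
    fixation_blink_rate = NA_real_, spem_velocity_gain = NA_real_,
    spem_saccade_rate = NA_real_,
    prosaccade_latency = NA_real_, prosaccade_amplitude_gain = NA_real_,
    prosaccade_spatial_error = NA_real_,
    prosaccade_peak_velocity = NA_real_,
    prosaccade_adj_peak_velocity = NA_real_,
    antisaccade_latency = NA_real_, antisaccade_amplitude_gain = NA_real_,
    antisaccade_spatial_error = NA_real_,
    antisaccade_peak_velocity = NA_real_,
    antisaccade_adj_peak_velocity = NA_real_,
    antisaccade_costs = NA_real_, antisaccade_error_rate = NA_real_,
    antisaccade_correction_rate = NA_real_,
    n_valid_pro = NA_integer_, n_valid_correct_pro = NA_integer_,
    n_valid_anti = NA_integer_, n_valid_correct_anti = NA_integer_,
    n_errors_anti = NA_integer_)
  if (!is.null(fixation)) {
    out$fixation_spatial_error <- fixation$spatial_error_rmse
    out$fixation_saccade_rate <- fixation$saccade_rate
    out$fixation_blink_rate <- fixation$blink_rate
  }
  if (!is.null(spem)) {
    out$spem_velocity_gain <- spem$velocity_gain
    out$spem_saccade_rate <- spem$saccade_rate
  }
  fill <- function(tab, prefix, n_min) {
    ok <- tab$valid & tab$direction_correct
    ok[is.na(ok)] <- FALSE
    for (m in c("latency", "amplitude_gain", "spatial_error",
                "peak_velocity", "adj_peak_velocity")) {
      col <- paste0(prefix, "_", sub("^adj_peak_velocity$",
                                     "adj_peak_velocity", m))
      out[[col]] <<- .mean_if(tab[[m]][ok], n_min)
    }
    sum(ok)
  }
  if (!is.null(pro)) {
    out$n_valid_pro <- sum(pro$valid)
    out$n_valid_correct_pro <- fill(pro, "prosaccade", min_trials)
  }
  if (!is.null(anti)) {
    valid <- anti$valid
    err <- valid & !anti$direction_correct
    out$n_valid_anti <- sum(valid)
    out$n_errors_anti <- sum(err, na.rm = TRUE)
    n_err <- out$n_errors_anti
    corrected <- anti$corrected[err]
    disqualified <- n_err >= min_errors &&
      !any(corrected, na.rm = TRUE)
    if (!disqualified) {
      out$n_valid_correct_anti <- fill(anti, "antisaccade", min_trials)
      if (out$n_valid_anti >= min_trials)
        out$antisaccade_error_rate <- 100 * n_err / out$n_valid_anti
      if (n_err >= min_errors && any(corrected, na.rm = TRUE))
        out$antisaccade_correction_rate <- 100 * mean(corrected)
    } else {
      out$n_valid_correct_anti <- sum(valid & anti$direction_correct,
                                      na.rm = TRUE)
    }
  }
  if (!is.na(out$antisaccade_latency) && !is.na(out$prosaccade_latency))
    out$antisaccade_costs <- out$antisaccade_latency - out$prosaccade_latency
  out
}
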