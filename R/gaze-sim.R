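#' Gaze simulation configuration
#'
#' Parameters of the synthetic oculomotor plant. Saccades are synthesized
#' with a raised-cosine velocity profile whose peak follows the main
#' sequence V_peak = V_max (1 - exp(-A / c)); with the defaults (V_max =
#' 600 deg/s, c = 10 deg) a 9.63 degree saccade peaks near 370 deg/s,
#' within the range reported for healthy adults at that eccentricity.
#' Saccade latencies are truncated-normal with a floor at 80 ms, so no
#' synthetic saccade is anticipatory by construction; antisaccades add
#' \code{anti_latency_shift} to the mean (the antisaccade cost). Blinks are
#' gaps of flagged samples whose positions are unusable; event detection
#' pads them by 50 ms on each side.
#'
#' @param sampling_rate Hz.
#' @param noise_sd per-axis Gaussian position noise, degrees.
#' @param blink_rate blink events per minute.
#' @param latency_mean,latency_sd saccade latency distribution, ms.
#' @param latency_floor truncation floor of the latency distribution, ms;
#'   lower it explicitly to synthesize anticipatory saccades for negative
#'   tests.
#' @param anti_latency_shift added to the latency mean on correct
#'   antisaccade trials, ms.
#' @param direction_error_prob probability an antisaccade trial starts with
#'   a reflexive saccade toward the target.
#' @param correction_prob probability a direction error is followed by a
#'   corrective saccade toward the mirror position.
#' @param main_sequence named vector (v_max deg/s, amp_constant deg).
#' @param pursuit_gain eye/target velocity ratio during smooth pursuit.
#' @param catchup_rate catch-up saccades per second during pursuit.
#' @param gain_mean,gain_sd saccadic amplitude gain distribution
#'   (landing position = gain x goal position).
#' @param seed integer seed.
#' @export
gaze_sim_config <- function(sampling_rate = 1000, noise_sd = 0.05,
                            blink_rate = 3, latency_mean = 190,
                            latency_sd = 28, latency_floor = 80,
                            anti_latency_shift = 90,
                            direction_error_prob = 0.3,
                            correction_prob = 0.95,
                            main_sequence = c(v_max = 600,
                                              amp_constant = 10),
                            pursuit_gain = 0.8, catchup_rate = 1.5,
                            gain_mean = 0.96, gain_sd = 0.03, seed = 1L) {
  stopifnot(sampling_rate > 0, noise_sd >= 0, blink_rate >= 0,
            direction_error_prob >= 0, direction_error_prob <= 1,
            correction_prob >= 0, correction_prob <= 1,
            all(main_sequence > 0), pursuit_gain >= 0)
  structure(list(sampling_rate = sampling_rate, noise_sd = noise_sd,
                 blink_rate = blink_rate, latency_mean = latency_mean,
                 latency_sd = latency_sd, latency_floor = latency_floor,
                 anti_latency_shift = anti_latency_shift,
                 direction_error_prob = direction_error_prob,
                 correction_prob = correction_prob,
                 main_sequence = main_sequence,
                 pursuit_gain = pursuit_gain, catchup_rate = catchup_rate,
                 gain_mean = gain_mean, gain_sd = gain_sd,
                 seed = as.integer(seed)), class = "gaze_sim_config")
}

#' Task geometry specification
#'
#' Target geometry of the four oculomotor tasks: fixation (centre 5 s, then
#' four eccentric 10 s epochs at 9.63 degrees with 5 s centre returns),
#' smooth pursuit (sinusoid between +-9.63 degrees at 0.5 Hz, ten full
#' cycles after a 1 s centre lead-in), and the prosaccade/antisaccade step
#' tasks (30 trials, centre fixation 1-2 s uniform, target step to
#' x = +-9.63 degrees for 1 s, 15 times per side; the antisaccade task has
#' six practice trials first).
#'
#' @param task one of "fixation", "spem", "prosaccade", "antisaccade".
#' @param ... overrides of the geometry fields.
#' @export
task_spec <- function(task = c("fixation", "spem", "prosaccade",
                               "antisaccade"), ...) {
  task <- match.arg(task)
  base <- switch(task,
    fixation = list(center_dur = 5, ecc_dur = 10, return_dur = 5,
                    eccentricity = 9.63),
    spem = list(amplitude = 9.63, frequency = 0.5, cycles = 10,
                lead_in = 1),
    prosaccade = list(n_trials = 30L, n_practice = 0L,
                      fixation_range = c(1, 2), target_dur = 1,
                      eccentricity = 9.63),
    antisaccade = list(n_trials = 30L, n_practice = 6L,
                       fixation_range = c(1, 2), target_dur = 1,
                       eccentricity = 9.63))
  structure(utils::modifyList(c(list(task = task), base), list(...)),
            class = "task_spec")
}

## main-sequence kinematics of one synthetic saccade; times in ms
.saccade_kinematics <- function(amplitude, ms) {
  vp <- ms[["v_max"]] * (1 - exp(-amplitude / ms[["amp_constant"]]))
  dur <- 2 * amplitude / vp * 1000
  ## time from movement start until the raised-cosine velocity reaches
  ## 22 deg/s -- the convention used for ground-truth onsets/offsets
  t22 <- if (vp > 44) dur / (2 * pi) * acos(1 - 44 / vp) else 0
  list(peak_velocity = vp, duration = dur, t_margin = t22)
}

## raised-cosine displacement fraction for phase u in [0,1]
.rc_disp <- function(u) u - sin(2 * pi * u) / (2 * pi)

## fill x/y traces from a table of non-overlapping saccade segments
.rasterize <- function(tms, seg, x0 = 0, y0 = 0) {
  x <- rep(NA_real_, length(tms)); y <- x
  px <- x0; py <- y0; pe <- -Inf
  if (nrow(seg)) seg <- seg[order(seg$t_start), , drop = FALSE]
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    hold <- tms >= pe & tms < s$t_start
    x[hold] <- px; y[hold] <- py
    mov <- tms >= s$t_start & tms < s$t_start + s$dur
    u <- (tms[mov] - s$t_start) / s$dur
    f <- .rc_disp(u)
    x[mov] <- s$x0 + (s$x1 - s$x0) * f
    y[mov] <- s$y0 + (s$y1 - s$y0) * f
    px <- s$x1; py <- s$y1; pe <- s$t_start + s$dur
  }
  tail <- tms >= pe
  x[tail] <- px; y[tail] <- py
  list(x = x, y = y)
}

.rtrunc_norm <- function(n, mean, sd, lower = 80) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

## draw blinks over [0, t_end] ms; returns onset/offset table
.draw_blinks <- function(t_end, rate_per_min) {
  if (rate_per_min <= 0) return(data.frame(onset = numeric(0),
                                           offset = numeric(0)))
  n <- stats::rpois(1, rate_per_min * t_end / 60000)
  if (n == 0) return(data.frame(onset = numeric(0), offset = numeric(0)))
  on <- sort(stats::runif(n, 0, t_end))
  off <- pmin(on + stats::runif(n, 100, 300), t_end)
  keep <- c(TRUE, on[-1] > off[-n] + 150)   # drop overlapping blinks
  data.frame(onset = on[keep], offset = off[keep])
}

#' Simulate one gaze-recording session
#'
#' Generates a full 1000 Hz (configurable) gaze recording for one of the
#' four oculomotor tasks, together with a ground-truth log of every
#' synthesized event. Saccades use a raised-cosine velocity profile on the
#' main sequence; ground-truth onsets and offsets are logged at the
#' 22 deg/s crossings of the noiseless velocity profile (the same
#' convention the detector uses for event boundaries), and ground-truth
#' amplitudes are the programmed displacements.
#'
#' @param task a [task_spec()] or a task name.
#' @param gsim a [gaze_sim_config()].
#' @param subject_params named list of per-subject overrides of any
#'   \code{gsim} field (e.g. \code{latency_mean}, \code{pursuit_gain}).
#' @param seed integer seed (defaults to the config seed).
#' @return list with \code{recording} (samples data frame \code{time_ms,
#'   x_deg, y_deg, blink}; messages data frame \code{time_ms, event};
#'   \code{sampling_rate}) and \code{truth} (saccades, blinks, trials,
#'   generating parameters).
#' @export
simulate_gaze_session <- function(task, gsim = gaze_sim_config(),
                                  subject_params = list(),
                                  seed = gsim$seed) {
  if (is.character(task)) task <- task_spec(task)
  stopifnot(inherits(task, "task_spec"), inherits(gsim, "gaze_sim_config"))
  g <- utils::modifyList(gsim, subject_params)
  set.seed(seed)
  out <- switch(task$task,
                fixation = .sim_fixation(task, g),
                spem = .sim_spem(task, g),
                prosaccade = .sim_saccade_task(task, g),
                antisaccade = .sim_saccade_task(task, g))
  dt <- 1000 / g$sampling_rate
  tms <- seq(0, out$t_end - dt, by = dt)
  tr <- .rasterize(tms, out$segments)
  if (!is.null(out$overlay_x)) tr$x <- tr$x + out$overlay_x(tms)
  blinks <- .draw_blinks(out$t_end, g$blink_rate)
  blink_flag <- rep(0L, length(tms))
  for (i in seq_len(nrow(blinks))) {
    idx <- tms >= blinks$onset[i] & tms <= blinks$offset[i]
    blink_flag[idx] <- 1L
    tr$x[idx] <- NA; tr$y[idx] <- NA
  }
  if (g$noise_sd > 0) {
    ok <- blink_flag == 0L
    tr$x[ok] <- tr$x[ok] + stats::rnorm(sum(ok), 0, g$noise_sd)
    tr$y[ok] <- tr$y[ok] + stats::rnorm(sum(ok), 0, g$noise_sd)
  }
  samples <- data.frame(time_ms = tms, x_deg = tr$x, y_deg = tr$y,
                        blink = blink_flag)
  truth <- out$truth
  truth$blinks <- blinks
  if (!is.null(truth$trials) && nrow(blinks)) {
    tt <- truth$trials
    for (i in seq_len(nrow(tt))) {
      w0 <- tt$t_target_on[i] - 100
      w1 <- min(tt$t_target_on[i] + tt$latency[i] + 120, tt$t_target_off[i])
      if (any(blinks$onset <= w1 + 50 & blinks$offset >= w0 - 50))
        tt$valid[i] <- FALSE
    }
    truth$trials <- tt
  }
  list(recording = list(samples = samples, messages = out$messages,
                        sampling_rate = g$sampling_rate),
       truth = truth)
}

.sim_fixation <- function(task, g) {
  ecc <- task$eccentricity
  pos <- list(c(0, ecc), c(0, -ecc), c(-ecc, 0), c(ecc, 0))
  pos <- pos[sample.int(4)]
  sched <- list(list(xy = c(0, 0), dur = task$center_dur * 1000))
  for (p in pos) {
    sched <- c(sched, list(list(xy = p, dur = task$ecc_dur * 1000)),
               list(list(xy = c(0, 0), dur = task$return_dur * 1000)))
  }
  t <- 0; msgs <- list(); segs <- list(); sacc <- list()
  cur <- c(0, 0)
  for (s in sched) {
    msgs[[length(msgs) + 1]] <- data.frame(
      time_ms = t, event = sprintf("TARGET_ON %.2f %.2f", s$xy[1], s$xy[2]))
    if (any(s$xy != cur)) {
      lat <- .rtrunc_norm(1, g$latency_mean, g$latency_sd,
                          g$latency_floor)
      amp <- sqrt(sum((s$xy - cur)^2))
      kin <- .saccade_kinematics(amp, g$main_sequence)
      t0 <- t + lat
      segs[[length(segs) + 1]] <- data.frame(
        t_start = t0, dur = kin$duration, x0 = cur[1], y0 = cur[2],
        x1 = s$xy[1], y1 = s$xy[2])
      sacc[[length(sacc) + 1]] <- data.frame(
        t_on = t0 + kin$t_margin, t_off = t0 + kin$duration - kin$t_margin,
        amplitude = amp, peak_velocity = kin$peak_velocity,
        direction = sign(s$xy[1] - cur[1]), trial = NA_integer_,
        role = "fixation_jump")
      cur <- s$xy
    }
    t <- t + s$dur
  }
  list(t_end = t, segments = do.call(rbind, segs),
       messages = do.call(rbind, msgs),
       truth = list(saccades = do.call(rbind, sacc), trials = NULL,
                    params = list(task = "fixation")))
}

.sim_spem <- function(task, g) {
  lead <- task$lead_in * 1000
  t_end <- lead + task$cycles / task$frequency * 1000
  A <- task$amplitude; f <- task$frequency; gain <- g$pursuit_gain
  target_x <- function(tms) ifelse(tms < lead, 0,
                                   A * sin(2 * pi * f * (tms - lead) / 1000))
  ## catch-up saccades: step the positional offset back onto the target
  segs <- data.frame(t_start = numeric(0), dur = numeric(0), x0 = numeric(0),
                     y0 = numeric(0), x1 = numeric(0), y1 = numeric(0))
  sacc <- list()
  off_t <- c(0); off_v <- c(0)   # offset changepoints
  if (g$catchup_rate > 0 && gain < 1) {
    n <- stats::rpois(1, g$catchup_rate * (t_end - lead) / 1000)
    times <- sort(stats::runif(n, lead + 500, t_end - 200))
    cur_off <- 0
    for (tt in times) {
      new_off <- (1 - gain) * target_x(tt)
      amp <- abs(new_off - cur_off)
      if (amp < 0.2) next
      kin <- .saccade_kinematics(amp, g$main_sequence)
      segs <- rbind(segs, data.frame(t_start = tt, dur = kin$duration,
                                     x0 = cur_off, y0 = 0, x1 = new_off,
                                     y1 = 0))
      sacc[[length(sacc) + 1]] <- data.frame(
        t_on = tt + kin$t_margin, t_off = tt + kin$duration - kin$t_margin,
        amplitude = amp, peak_velocity = kin$peak_velocity,
        direction = sign(new_off - cur_off), trial = NA_integer_,
        role = "catchup")
      cur_off <- new_off
    }
  }
  msgs <- data.frame(time_ms = c(0, lead),
                     event = c("TARGET_ON 0.00 0.00", "PURSUIT_START"))
  list(t_end = t_end, segments = segs, messages = msgs,
       overlay_x = function(tms) gain * target_x(tms),
       truth = list(saccades = if (length(sacc)) do.call(rbind, sacc) else
         NULL, trials = NULL,
         params = list(task = "spem", velocity_gain = gain,
                       amplitude = A, frequency = f, lead_in = lead)))
}

.sim_saccade_task <- function(task, g) {
  anti <- task$task == "antisaccade"
  n_all <- task$n_trials + task$n_practice
  sides <- c(sample(c(-1, 1), task$n_practice, replace = TRUE),
             sample(rep(c(-1, 1), task$n_trials / 2)))
  ecc <- task$eccentricity
  t <- 0; msgs <- list(); segs <- list(); sacc <- list(); trials <- list()
  add_seg <- function(t0, dur, x0, x1)
    segs[[length(segs) + 1]] <<- data.frame(t_start = t0, dur = dur,
                                            x0 = x0, y0 = 0, x1 = x1, y1 = 0)
  add_sacc <- function(t0, kin, amp, dir, trial, role)
    sacc[[length(sacc) + 1]] <<- data.frame(
      t_on = t0 + kin$t_margin, t_off = t0 + kin$duration - kin$t_margin,
      amplitude = amp, peak_velocity = kin$peak_velocity, direction = dir,
      trial = trial, role = role)
  msg <- function(tm, ev)
    msgs[[length(msgs) + 1]] <<- data.frame(time_ms = tm, event = ev)

  for (k in seq_len(n_all)) {
    practice <- k <= task$n_practice
    side <- sides[k]
    fix_dur <- stats::runif(1, task$fixation_range[1] * 1000,
                            task$fixation_range[2] * 1000)
    t_fix <- t
    msg(t_fix, sprintf("TRIAL_START %d", k))
    msg(t_fix, "TARGET_ON 0.00 0.00")
    t_on <- t_fix + fix_dur
    t_off <- t_on + task$target_dur * 1000
    msg(t_on, sprintf("TARGET_ON %.2f 0.00", side * ecc))

    err <- anti && stats::runif(1) < g$direction_error_prob
    lat <- .rtrunc_norm(1, g$latency_mean +
                          if (anti && !err) g$anti_latency_shift else 0,
                        g$latency_sd, g$latency_floor)
    goal <- if (!anti || err) side * ecc else -side * ecc
    gn <- min(max(stats::rnorm(1, g$gain_mean, g$gain_sd), 0.7), 1.25)
    land <- gn * goal
    kin <- .saccade_kinematics(abs(land), g$main_sequence)
    t0 <- t_on + lat
    add_seg(t0, kin$duration, 0, land)
    add_sacc(t0, kin, abs(land), sign(land), k, "primary")
    cur <- land
    prev_end <- t0 + kin$duration

    corrected <- NA
    if (err) {
      corrected <- FALSE
      if (stats::runif(1) < g$correction_prob) {
        c_lat <- stats::runif(1, 130, 280)
        gn2 <- min(max(stats::rnorm(1, g$gain_mean, g$gain_sd), 0.7), 1.25)
        land2 <- gn2 * (-side * ecc)
        amp2 <- abs(land2 - cur)
        kin2 <- .saccade_kinematics(amp2, g$main_sequence)
        c0 <- prev_end + c_lat
        add_seg(c0, kin2$duration, cur, land2)
        add_sacc(c0, kin2, amp2, sign(land2 - cur), k, "corrective")
        if (c0 + kin2$duration <= t_off) corrected <- TRUE
        cur <- land2
        prev_end <- c0 + kin2$duration
      }
    }
    ## return to centre after target offset
    r0 <- max(t_off + .rtrunc_norm(1, g$latency_mean, g$latency_sd,
                                   g$latency_floor),
              prev_end + 60)
    kin3 <- .saccade_kinematics(abs(cur), g$main_sequence)
    add_seg(r0, kin3$duration, cur, 0)
    add_sacc(r0, kin3, abs(cur), sign(-cur), k, "return")

    valid <- lat + kin$duration <= task$target_dur * 1000
    trials[[k]] <- data.frame(
      trial = k, practice = practice, side = ifelse(side < 0, "left",
                                                    "right"),
      t_fix_on = t_fix, t_target_on = t_on, t_target_off = t_off,
      latency = lat, direction_error = err, corrected = corrected,
      valid = valid, stringsAsFactors = FALSE)
    msg(t_off, sprintf("TRIAL_END %d", k))
    t <- t_off
  }
  t <- t + 600   # tail so the last return saccade completes
  list(t_end = t, segments = do.call(rbind, segs),
       messages = do.call(rbind, msgs),
       truth = list(saccades = do.call(rbind, sacc),
                    trials = do.call(rbind, trials),
                    params = list(task = task$task,
                                  direction_error_prob =
                                    g$direction_error_prob,
                                  correction_prob = g$correction_prob)))
}
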