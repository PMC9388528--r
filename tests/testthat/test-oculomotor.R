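test_that("kinematics recover constant, linear and saccadic motion", {
  ## constant position: zero velocity everywhere it is defined
  rec <- make_recording(rep(2, 500))
  k <- compute_kinematics(rec)
  expect_equal(max(abs(k$speed), na.rm = TRUE), 0)
  ## linear ramp x = 10 deg/s
  rec2 <- make_recording(10 * seq(0, 0.499, by = 0.001))
  k2 <- compute_kinematics(rec2)
  expect_equal(stats::median(k2$speed, na.rm = TRUE), 10, tolerance = 1e-6)
  ## a programmed 400 deg/s raised-cosine peak is measured within 2%
  amp <- 10.986   # amplitude whose main-sequence peak is 400 deg/s
  x <- inject_saccade(800, 300, amp, 400)
  k3 <- compute_kinematics(make_recording(x))
  expect_lt(abs(max(k3$speed, na.rm = TRUE) - 400) / 400, 0.02)
  expect_error(compute_kinematics(make_recording(rep(0, 3))), "short")
})

test_that("saccade detection obeys its thresholds sharply", {
  ## flat noisy trace at sigma = 0.05 deg: nothing detected
  set.seed(40)
  rec <- make_recording(rnorm(5000, 0, 0.05), rnorm(5000, 0, 0.05))
  expect_equal(nrow(detect_saccades(rec)), 0)
  ## one planted 9.63 deg saccade: one event, tight onset and amplitude
  x <- inject_saccade(1500, 500, 9.63, 600 * (1 - exp(-0.963)))
  det <- detect_saccades(make_recording(x))
  expect_equal(nrow(det), 1)
  expect_equal(det$amplitude, 9.63, tolerance = 0.05 * 9.63)
  ## 0.8 deg microsaccade with an 80 deg/s peak: amplitude-filtered out
  x2 <- inject_saccade(1000, 400, 0.8, 80)
  expect_equal(nrow(detect_saccades(make_recording(x2))), 0)
  ## sustained 59 deg/s with sub-threshold acceleration: never an event;
  ## sustained 60 deg/s with amplitude > 1 deg: always one
  ramp <- function(v_peak, a_slope) {
    dt <- 0.001
    v <- c(rep(0, 300), seq(0, v_peak, by = a_slope * dt),
           rep(v_peak, 120))
    v <- c(v, rev(v), rep(0, 300))
    cumsum(v) * dt
  }
  expect_equal(nrow(detect_saccades(make_recording(ramp(59, 3799)))), 0)
  ## 60.001 rather than 60 exactly: cumsum/difference round-trip noise
  ## sits at machine epsilon and must not flip the >= comparison
  expect_equal(nrow(detect_saccades(make_recording(ramp(60.001, 3799)))), 1)
})

test_that("blink runs are padded and merged", {
  b <- rep(0L, 2000)
  expect_equal(nrow(detect_blinks(make_recording(rep(0, 2000), blink = b))),
               0)
  b[501:620] <- 1L
  one <- detect_blinks(make_recording(rep(0, 2000), blink = b))
  expect_equal(nrow(one), 1)
  expect_equal(one$offset - one$onset, 119)
  expect_equal(one$pad_onset, one$onset - 50)
  ## two runs 10 ms apart merge once padded
  b2 <- rep(0L, 2000)
  b2[501:600] <- 1L; b2[611:700] <- 1L
  two <- detect_blinks(make_recording(rep(0, 2000), blink = b2))
  expect_equal(nrow(two), 1)
  expect_equal(two$offset, 699)
})

test_that("fixation summary measures spatial error and event rates", {
  msgs <- data.frame(time_ms = 0, event = "TARGET_ON 0.00 0.00")
  ## gaze pinned to the target: zero error, zero rates
  pin <- summarize_fixation_task(make_recording(rep(0, 20000),
                                                messages = msgs))
  expect_equal(pin$spatial_error_rmse, 0)
  expect_equal(pin$saccade_rate, 0)
  expect_equal(pin$blink_rate, 0)
  ## constant 1 degree offset
  off <- summarize_fixation_task(make_recording(rep(1, 20000),
                                                messages = msgs))
  expect_equal(off$spatial_error_rmse, 1, tolerance = 1e-9)
  ## isotropic noise sigma per axis: RMSE -> sigma * sqrt(2)
  set.seed(42)
  s <- 0.05
  nz <- summarize_fixation_task(make_recording(rnorm(60000, 0, s),
                                               rnorm(60000, 0, s),
                                               messages = msgs))
  expect_equal(nz$spatial_error_rmse, s * sqrt(2), tolerance = 0.05 * s)
})

test_that("pursuit velocity gain is the eye/target velocity ratio", {
  ## eye trace identical to the target: 100%
  spec <- task_spec("spem")
  tms <- seq(0, 20999)
  tgt <- ifelse(tms < 1000, 0,
                9.63 * sin(2 * pi * 0.5 * (tms - 1000) / 1000))
  ident <- summarize_spem_task(make_recording(tgt), spec)
  expect_equal(ident$velocity_gain, 100, tolerance = 0.2)
  ## stationary eye: 0%
  still <- summarize_spem_task(make_recording(rep(0, 21000)), spec)
  expect_equal(still$velocity_gain, 0, tolerance = 1e-6)
  ## eye velocity at 0.8 x target throughout: 80%
  att <- summarize_spem_task(make_recording(0.8 * tgt), spec)
  expect_equal(att$velocity_gain, 80, tolerance = 0.5)
  ## too short for a single half-cycle: absent
  shrt <- summarize_spem_task(make_recording(tgt[1:1400]), spec)
  expect_true(is.na(shrt$velocity_gain))
})

test_that("trial parsing finds scored trials and flags truncation", {
  g <- gaze_sim_config(noise_sd = 0, blink_rate = 0, seed = 43)
  pro <- simulate_gaze_session("prosaccade", g)
  tp <- parse_trials(pro$recording, task_spec("prosaccade"))
  expect_equal(nrow(tp), 30)
  expect_equal(sum(tp$practice), 0)
  expect_equal(sum(tp$side == "left"), 15)
  anti <- simulate_gaze_session("antisaccade", g)
  ta <- parse_trials(anti$recording, task_spec("antisaccade"))
  expect_equal(nrow(ta), 36)
  expect_equal(sum(ta$practice), 6)
  expect_equal(nrow(ta[!ta$practice, ]), 30)
  ## truncated recording: fewer trials, with a warning
  cut <- pro$recording
  t_cut <- tp$t_target_off[12] + 100
  cut$samples <- cut$samples[cut$samples$time_ms <= t_cut, ]
  cut$messages <- cut$messages[cut$messages$time_ms <= t_cut, ]
  expect_warning(tc <- parse_trials(cut, task_spec("prosaccade")),
                 "truncated|incomplete")
  expect_equal(nrow(tc), 12)
  expect_error(parse_trials(list(samples = cut$samples,
                                 messages = data.frame(time_ms = 0,
                                                       event = "X")),
                            task_spec("prosaccade")), "TRIAL_START")
})

test_that("trial validation reports machine-readable reasons", {
  g <- gaze_sim_config(noise_sd = 0.02, blink_rate = 0, seed = 44)
  s <- simulate_gaze_session("prosaccade", g)
  rec <- s$recording
  sacc <- detect_saccades(rec)
  blk <- detect_blinks(rec)
  trials <- parse_trials(rec, task_spec("prosaccade"))
  v1 <- validate_trial(trials[1, ], sacc, blk, rec)
  expect_true(v1$valid)
  expect_equal(v1$reason, "")
  ## fixation 4 degrees off centre at target onset
  rec_off <- rec
  w <- rec_off$samples$time_ms >= trials$t_target_on[1] - 100 &
    rec_off$samples$time_ms < trials$t_target_on[1]
  rec_off$samples$x_deg[w] <- rec_off$samples$x_deg[w] + 4
  ## saccade list from the unperturbed trace: the offset is a pure gaze
  ## displacement, not an eye movement
  v2 <- validate_trial(trials[1, ], sacc, blk, rec_off)
  expect_false(v2$valid)
  expect_equal(v2$reason, "off_fixation")
  ## blink inside the fixation window invalidates a valid trial
  rec_blk <- rec
  bw <- rec_blk$samples$time_ms >= trials$t_target_on[2] - 60 &
    rec_blk$samples$time_ms < trials$t_target_on[2] - 20
  rec_blk$samples$blink[bw] <- 1L
  v3 <- validate_trial(trials[2, ], sacc, detect_blinks(rec_blk), rec_blk)
  expect_false(v3$valid)
  expect_equal(v3$reason, "blink_in_fixation")
  ## anticipatory initial saccade (floor lowered deliberately)
  ga <- gaze_sim_config(noise_sd = 0, blink_rate = 0, latency_mean = 50,
                        latency_sd = 5, latency_floor = 30, seed = 45)
  sa <- simulate_gaze_session("prosaccade", ga)
  tma <- process_saccade_session(sa$recording, task_spec("prosaccade"))
  expect_true(all(tma$invalid_reason[!tma$valid] == "anticipatory"))
  expect_gt(sum(!tma$valid), 25)
})

test_that("trial scoring follows the task geometry", {
  sacc <- data.frame(onset = 1200, offset = 1250, amplitude = 9.63,
                     peak_velocity = 370, peak_acceleration = 2e4,
                     direction = 1, start_x = 0, end_x = 9.63,
                     start_y = 0, end_y = 0)
  trial <- data.frame(trial = 1, side = "right", t_fix_on = 0,
                      t_target_on = 1000, t_target_off = 2000)
  val <- list(valid = TRUE, reason = "", initial = 1)
  sc <- score_saccade_trial(trial, val, sacc, "prosaccade")
  expect_equal(sc$latency, 200)
  expect_equal(sc$amplitude_gain, 100)
  expect_equal(sc$spatial_error, 0)
  expect_true(sc$direction_correct)
  expect_equal(sc$adj_peak_velocity, 370 / 9.63)
  ## antisaccade: the same rightward saccade is a direction error, and a
  ## later midline-crossing return marks it corrected
  sacc2 <- rbind(sacc, data.frame(onset = 1500, offset = 1560,
                                  amplitude = 12, peak_velocity = 400,
                                  peak_acceleration = 2e4, direction = -1,
                                  start_x = 9.63, end_x = -3,
                                  start_y = 0, end_y = 0))
  sc2 <- score_saccade_trial(trial, val, sacc2, "antisaccade")
  expect_false(sc2$direction_correct)
  expect_true(sc2$corrected)
  ## without the return it stays uncorrected
  sc3 <- score_saccade_trial(trial, val, sacc, "antisaccade")
  expect_false(sc3$direction_correct)
  expect_false(sc3$corrected)
  ## a leftward initial saccade is the correct antisaccade response
  sacc4 <- sacc
  sacc4$end_x <- -9.63; sacc4$direction <- -1
  sc4 <- score_saccade_trial(trial, val, sacc4, "antisaccade")
  expect_true(sc4$direction_correct)
  expect_equal(sc4$spatial_error, 0)
  ## gain/error duality for a centre-origin horizontal saccade
  sacc5 <- sacc
  sacc5$end_x <- 0.85 * 9.63; sacc5$amplitude <- 0.85 * 9.63
  sc5 <- score_saccade_trial(trial, val, sacc5, "prosaccade")
  expect_equal(sc5$spatial_error, abs(sc5$amplitude_gain - 100),
               tolerance = 1e-9)
})

test_that("subject aggregation enforces the trial-count rules", {
  ## 6 valid-and-correct prosaccade trials: outcome absent
  pro6 <- do.call(rbind, lapply(1:6, metric_row))
  agg6 <- aggregate_subject(pro = pro6)
  expect_true(is.na(agg6$prosaccade_latency))
  expect_equal(agg6$n_valid_correct_pro, 6)
  pro7 <- do.call(rbind, lapply(1:7, metric_row))
  expect_equal(aggregate_subject(pro = pro7)$prosaccade_latency, 200)
  ## 10 valid antisaccade trials, 4 errors (all corrected): error rate
  ## 40%, correction rate absent under the >= 5 errors rule
  anti <- rbind(do.call(rbind, lapply(1:6, metric_row)),
                do.call(rbind, lapply(7:10, function(i)
                  metric_row(i, direction_correct = FALSE,
                             corrected = TRUE))))
  agg <- aggregate_subject(anti = anti)
  expect_equal(agg$antisaccade_error_rate, 40)
  expect_true(is.na(agg$antisaccade_correction_rate))
  ## >= 5 errors, all corrected: correction rate 100
  anti5 <- rbind(do.call(rbind, lapply(1:10, metric_row)),
                 do.call(rbind, lapply(11:15, function(i)
                   metric_row(i, direction_correct = FALSE,
                              corrected = TRUE))))
  expect_equal(aggregate_subject(anti = anti5)$antisaccade_correction_rate,
               100)
  ## >= 5 errors and no correction at all: antisaccade outcomes withheld
  anti0 <- rbind(do.call(rbind, lapply(1:10, metric_row)),
                 do.call(rbind, lapply(11:15, function(i)
                   metric_row(i, direction_correct = FALSE,
                              corrected = FALSE))))
  agg0 <- aggregate_subject(anti = anti0)
  expect_true(is.na(agg0$antisaccade_latency))
  expect_true(is.na(agg0$antisaccade_error_rate))
  expect_true(is.na(agg0$antisaccade_correction_rate))
  ## costs appear only when both latencies exist
  both <- aggregate_subject(pro = pro7,
                            anti = do.call(rbind, lapply(1:8, function(i)
                              metric_row(i, latency = 290))))
  expect_equal(both$antisaccade_costs, 90)
  expect_true(is.na(aggregate_subject(anti = anti5)$antisaccade_costs))
})

test_that("subject-level error rate tracks the planted probability", {
  set.seed(46)
  p <- 0.25
  n_subj <- 40
  rates <- vapply(seq_len(n_subj), function(i) {
    s <- simulate_gaze_session(
      "antisaccade", gaze_sim_config(noise_sd = 0.05, blink_rate = 0,
                                     direction_error_prob = p,
                                     seed = 4600 + i))
    tm <- process_saccade_session(s$recording, task_spec("antisaccade"))
    sum(tm$valid & !tm$direction_correct) / sum(tm$valid)
  }, numeric(1))
  se <- sqrt(p * (1 - p) / (n_subj * 30))
  expect_lt(abs(mean(rates) - p), 3 * se)
})
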