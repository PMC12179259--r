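# Synthetic multi-participant in-lab sessions with a known latent-MET
# mapping, so every pipeline stage is exercisable without recorded data.
# A session emulates a supervised protocol: 12 activities spanning
# sedentary to vigorous intensity, 5 minutes each with 5-minute seated
# rests in between, 20 Hz 6-axis IMU, and breath-by-breath gas exchange
# generated so the Weir/MET chain recovers the latent MET of each
# activity up to per-breath noise.

#' Default in-lab activity protocol
#'
#' Twelve activities (three per intensity class) in an order that
#' disperses exertion. Latent MET values follow measured-calorimetry
#' levels for these activity types in adults with obesity, which for
#' light activities sit well below compendium assignments (standing near
#' 1.4 MET rather than 1.8), so the non-sedentary MET distribution has
#' support near the resting rate just as criterion measurements do. The
#' latent MET of each non-sedentary activity is a strictly increasing
#' function of its motion amplitude (`amp = 0.13 * (MET - 1)` g), so
#' signal dispersion is the informative intensity cue; sedentary
#' activities move at most 0.02 g. Motion
#' frequencies sit inside the 0.3--8 Hz band of human movement (e.g.
#' stepping at 30 steps/min = 0.5 Hz, fast walking near 2 Hz). Set
#' `met_driver = "frequency"` for a variant in which amplitude is held
#' constant across non-sedentary activities and MET instead increases
#' with motion frequency (exercising the dominant-frequency feature).
#'
#' @param duration_s Activity duration, seconds (default 300).
#' @param rest_s Rest duration between activities, seconds (default 300).
#' @param met_driver `"amplitude"` (default) or `"frequency"`.
#' @return List of class `synthetic_protocol` with the activity table,
#'   `rest_s` and the driver.
#' @export
default_protocol <- function(duration_s = 300, rest_s = 300,
                             met_driver = c("amplitude", "frequency")) {
  met_driver <- match.arg(met_driver)
  act <- data.frame(
    label = c("computer", "walking slowly", "walking normally", "standing",
              "squats", "reading", "general aerobics", "sweeping",
              "push-ups", "walking fast", "lying down", "step test"),
    intensity = c("sedentary", "light", "moderate", "light", "moderate",
                  "sedentary", "vigorous", "light", "moderate", "vigorous",
                  "sedentary", "vigorous"),
    motion_freq = c(1.5, 1.4, 1.8, 0.7, 0.7, 0.8, 2.0, 1.0, 0.8, 2.2, 0.5,
                    0.5),
    latent_met = c(1.3, 2.5, 3.2, 1.4, 4.5, 1.2, 6.5, 2.0, 3.5, 5.5, 1.0,
                   7.5))
  sed <- act$intensity == "sedentary"
  act$motion_amp <- 0.13 * (act$latent_met - 1)
  act$motion_amp[sed] <- 0.004 + 0.004 * (act$latent_met[sed] - 1) /
    max(act$latent_met[sed] - 1, 0.1)
  if (met_driver == "frequency") {
    act$motion_amp[!sed] <- 0.3
    act$motion_freq[!sed] <- 0.5 + 0.35 * (act$latent_met[!sed] - 1)
  }
  act$duration_s <- duration_s
  stopifnot(all(act$latent_met >= 1),
            all(act$motion_amp[sed] <= 0.02))
  structure(list(activities = act, rest_s = rest_s, met_driver = met_driver),
            class = "synthetic_protocol")
}

#' Generate one synthetic in-lab session
#'
#' Per activity the acceleration is a gravity unit vector plus a
#' sinusoid of the activity's amplitude and frequency (split across the
#' horizontal axes with a phase offset, and at half amplitude vertically)
#' plus white Gaussian noise; the gyroscope moves analogously, scaled to
#' deg/s. Breaths arrive at `breath_rate` Hz and carry
#' `VO2 = (latent MET + N(0, sigma_met)) * 3.5 * weight / 1000` L/min
#' (so the Weir/MET ground-truth chain recovers the latent MET) with
#' VCO2 at a respiratory exchange ratio of 0.85. Rest periods sit at
#' 1 MET and sedentary-level motion but are not annotated as activities.
#' Demographics are drawn from ranges typical of an adult cohort with
#' BMI >= 30. Fully reproducible from `participant_seed`.
#'
#' @param protocol A [default_protocol()].
#' @param participant_seed Integer seed for this participant.
#' @param participant_id Identifier; default derived from the seed.
#' @param fs IMU sampling rate, Hz (default 20).
#' @param noise_sd Accelerometer noise SD, g (default 0.01).
#' @param sigma_met Per-breath MET noise SD (default 0.1).
#' @param breath_rate Breaths per second (default 0.25, a typical adult
#'   respiratory rate).
#' @param handedness `"right"` or `"left"`.
#' @return List of class `wm_session` with elements `imu`
#'   ([imu_recording()]), `calorimetry` ([calorimetry_trace()]),
#'   `annotations` ([activity_annotations()]), `demographics` (one-row
#'   [demographics()]) and `latent` (per-sample latent MET).
#' @export
generate_session <- function(protocol = default_protocol(), participant_seed,
                             participant_id = sprintf("P%03d",
                                                      participant_seed %% 1000L),
                             fs = 20, noise_sd = 0.01, sigma_met = 0.1,
                             breath_rate = 0.25,
                             handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  set.seed(participant_seed)

  age <- round(stats::runif(1, 25, 60))
  sex <- sample(c("female", "male"), 1)
  height <- round(stats::runif(1, if (sex == "female") 152 else 163,
                               if (sex == "female") 175 else 188), 1)
  bmi_draw <- stats::runif(1, 30, 42)
  weight <- round(bmi_draw * (height / 100)^2, 1)
  demo <- demographics(participant_id, age, sex, height, weight)

  act <- protocol$activities
  n_act <- nrow(act)
  rest_s <- protocol$rest_s
  # timeline blocks: activity, rest, activity, ... (no trailing rest)
  blocks <- list()
  t_cursor <- 0
  ann_rows <- list()
  for (i in seq_len(n_act)) {
    blocks[[length(blocks) + 1L]] <-
      list(start = t_cursor, dur = act$duration_s[[i]],
           amp = act$motion_amp[[i]], freq = act$motion_freq[[i]],
           met = act$latent_met[[i]])
    ann_rows[[length(ann_rows) + 1L]] <-
      data.frame(label = act$label[[i]], intensity = act$intensity[[i]],
                 start_s = t_cursor, end_s = t_cursor + act$duration_s[[i]])
    t_cursor <- t_cursor + act$duration_s[[i]]
    if (i < n_act && rest_s > 0) {
      blocks[[length(blocks) + 1L]] <-
        list(start = t_cursor, dur = rest_s, amp = 0.005, freq = 0.4,
             met = 1.0)
      t_cursor <- t_cursor + rest_s
    }
  }
  ann <- do.call(rbind, ann_rows)
  annotations <- activity_annotations(ann$label, ann$intensity, ann$start_s,
                                      ann$end_s)

  total_s <- t_cursor
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1L) / fs
  latent <- numeric(n)
  ax <- stats::rnorm(n, 0, noise_sd)
  ay <- stats::rnorm(n, 0, noise_sd)
  az <- 1 + stats::rnorm(n, 0, noise_sd)   # gravity on z
  gx <- stats::rnorm(n, 0, 1)
  gy <- stats::rnorm(n, 0, 1)
  gz <- stats::rnorm(n, 0, 1)
  for (b in blocks) {
    i <- which(t >= b$start & t < b$start + b$dur)
    phase <- stats::runif(1, 0, 2 * pi)
    s1 <- sin(2 * pi * b$freq * t[i] + phase)
    s2 <- sin(2 * pi * b$freq * t[i] + phase + pi / 3)
    ax[i] <- ax[i] + b$amp * s1
    ay[i] <- ay[i] + b$amp * s2
    az[i] <- az[i] + 0.5 * b$amp * s1
    gx[i] <- gx[i] + 60 * b$amp * s2
    gy[i] <- gy[i] + 60 * b$amp * s1
    gz[i] <- gz[i] + 30 * b$amp * s2
    latent[i] <- b$met
  }
  imu <- imu_recording(data.frame(t = t, ax = ax, ay = ay, az = az,
                                  gx = gx, gy = gy, gz = gz),
                       participant_id, handedness, fs)

  breath_t <- seq(0, total_s, by = 1 / breath_rate)
  breath_met <- latent[pmin(n, floor(breath_t * fs) + 1L)] +
    stats::rnorm(length(breath_t), 0, sigma_met)
  vo2 <- pmax(0, breath_met) * 3.5 * weight / 1000
  vco2 <- 0.85 * vo2
  calorimetry <- calorimetry_trace(breath_t, vo2, vco2)

  structure(list(imu = imu, calorimetry = calorimetry,
                 annotations = annotations, demographics = demo,
                 latent = data.frame(t = t, met = latent),
                 protocol = protocol, sigma_met = sigma_met,
                 seed = participant_seed),
            class = "wm_session")
}

#' @export
print.wm_session <- function(x, ...) {
  cat(sprintf("<wm_session> %s: %d IMU samples, %d breaths, %d activities\n",
              attr(x$imu, "participant_id"), nrow(x$imu),
              nrow(x$calorimetry), nrow(x$annotations)))
  invisible(x)
}

#' Generate a synthetic multi-participant cohort
#'
#' @param n_participants Number of participants (default 10).
#' @param protocol A [default_protocol()].
#' @param seed Master integer seed; participant seeds are derived as
#'   `seed * 1000 + i`.
#' @param ... Passed to [generate_session()] (`noise_sd`, `sigma_met`,
#'   ...).
#' @return List with `sessions` (list of `wm_session`) and `demographics`
#'   (combined [demographics()] table).
#' @export
generate_cohort <- function(n_participants = 10, protocol = default_protocol(),
                            seed = 1L, ...) {
  sessions <- lapply(seq_len(n_participants), function(i) {
    generate_session(protocol, participant_seed = seed * 1000L + i,
                     participant_id = sprintf("P%03d", i), ...)
  })
  demo <- do.call(rbind, lapply(sessions, `[[`, "demographics"))
  class(demo) <- c("demographics", "data.frame")
  list(sessions = sessions, demographics = demo)
}

#' Windows with ground-truth METs from one session
#'
#' The standard preparation chain: mirror left-hand recordings, convert
#' calorimetry to a per-sample MET series on the IMU clock, mask the
#' first `trim_s` seconds of each activity, segment annotation-bounded
#' windows, and attach aggregated MET labels.
#'
#' @param session A `wm_session` (or any list with `imu`, `calorimetry`,
#'   `annotations`, `demographics`).
#' @param window_s Window length, seconds.
#' @param overlap Overlap fraction (default 0.5).
#' @param trim_s Activity head trim, seconds (default 120).
#' @param aggregation MET aggregation rule (default `"mean"`).
#' @return A labelled [window_set()].
#' @export
windows_from_session <- function(session, window_s, overlap = 0.5,
                                 trim_s = 120, aggregation = "mean") {
  rec <- mirror_left_hand(session$imu)
  met <- calorimetry_to_met_series(session$calorimetry, session$demographics,
                                   clock_t = rec$t)
  mask <- trim_activity_head(rec$t, session$annotations, trim_s)
  ws <- segment_windows(rec, window_s, overlap = overlap,
                        annotations = session$annotations, mask = mask)
  attach_met_labels(ws, met, aggregation = aggregation)
}

#' Windows pooled over several sessions
#' @param sessions List of sessions.
#' @param window_s,overlap,trim_s,aggregation See [windows_from_session()].
#' @return A combined labelled [window_set()].
#' @export
windows_from_sessions <- function(sessions, window_s, overlap = 0.5,
                                  trim_s = 120, aggregation = "mean") {
  c_window_sets(lapply(sessions, windows_from_session, window_s = window_s,
                       overlap = overlap, trim_s = trim_s,
                       aggregation = aggregation))
}

#' Generate a paired free-living MET series with planted disagreements
#'
#' Series A is a piecewise-constant minute-level MET pattern alternating
#' rest and activity bouts; series B equals A plus Gaussian disagreement
#' noise `N(mu, sigma)` plus planted excursions of
#' `excursion_sd_mult * sigma` (default 5 SD, which exceeds the
#' +/- 1.96 SD limits of agreement by construction) at the requested
#' minute indices -- positive indices plant overestimation of A relative
#' to B... (the excursion is added to A), negative sizes plant
#' underestimation.
#'
#' @param n_minutes Series length (>= 3).
#' @param seed Integer seed.
#' @param mu,sigma Disagreement mean and SD (defaults 0 and 0.2 MET).
#' @param excursion_idx Integer minute indices receiving planted
#'   excursions.
#' @param excursion_sd_mult Excursion size in units of `sigma` (signed;
#'   default +5).
#' @return List with `a` and `b` (`met_series` data frames at 1-minute
#'   resolution) and `excursion_idx`.
#' @export
generate_free_living_pair <- function(n_minutes, seed = 1L, mu = 0,
                                      sigma = 0.2,
                                      excursion_idx = integer(0),
                                      excursion_sd_mult = 5) {
  if (n_minutes < 3) wm_contract_error("n_minutes must be >= 3")
  set.seed(seed)
  # alternating bouts of rest and activity, 5-30 min long
  met <- numeric(0)
  level_rest <- TRUE
  while (length(met) < n_minutes) {
    len <- sample(5:30, 1)
    lvl <- if (level_rest) stats::runif(1, 1, 1.4) else stats::runif(1, 1.5, 6)
    met <- c(met, rep(lvl, len))
    level_rest <- !level_rest
  }
  a <- met[seq_len(n_minutes)]
  b <- a - (stats::rnorm(n_minutes, mu, sigma))
  if (length(excursion_idx)) {
    if (any(excursion_idx < 1 | excursion_idx > n_minutes))
      wm_contract_error("excursion_idx out of range")
    a[excursion_idx] <- a[excursion_idx] + excursion_sd_mult * sigma
  }
  t <- (seq_len(n_minutes) - 1) * 60
  list(a = structure(data.frame(t = t, met = a),
                     class = c("met_series", "data.frame")),
       b = structure(data.frame(t = t, met = b),
                     class = c("met_series", "data.frame")),
       excursion_idx = excursion_idx)
}
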