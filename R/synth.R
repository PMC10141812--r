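# Synthetic session generator: a neutral face template animated with
# seeded temporally-correlated jitter, Poisson blinks, utterance-locked
# mouth opening, gaze/head drift and an AR(1) pulse, with configurable
# deception-window effects. Stands in for unavailable human-subject
# recordings; emits the same three file formats the readers consume.

#' Neutral 68-point face template (plus 56-point eye model)
#'
#' A plausible frontal face in a 1280x720 image (pixel coordinates, y
#' down): jaw ellipse, arched brows, nasal bridge of length 30 px, 6-point
#' eye rings, 12/8-point mouth rings, and an eye-model layout consistent
#' with the semantic indices of [openface_dialect()].
#'
#' @return list with `face` (68 x 2), `eye` (56 x 2), `eye_center_y`,
#'   `mouth_center_y`.
#' @export
face_template <- function() {
  fx <- numeric(68); fy <- numeric(68)
  # jaw P0..P16
  tt <- seq(-1, 1, length.out = 17)
  fx[1:17] <- 640 + 100 * sin(tt * pi / 2)
  fy[1:17] <- 340 + 140 * cos(tt * pi / 2)
  # brows P17..P21 (right), P22..P26 (left)
  fx[18:22] <- seq(555, 615, length.out = 5)
  fy[18:22] <- c(304, 298, 296, 297, 300)
  fx[23:27] <- seq(665, 725, length.out = 5)
  fy[23:27] <- c(300, 297, 296, 298, 304)
  # nose P27..P35
  fx[28:31] <- 640
  fy[28:31] <- seq(310, 355, length.out = 4)
  fx[32:36] <- seq(620, 660, length.out = 5)
  fy[32:36] <- c(368, 370, 372, 370, 368)
  # eyes P36..P41 (right), P42..P47 (left)
  ex_r <- c(565, 580, 600, 615, 600, 580)
  ey_r <- c(330, 322, 322, 330, 338, 338)
  fx[37:42] <- ex_r; fy[37:42] <- ey_r
  fx[43:48] <- ex_r + 100; fy[43:48] <- ey_r
  # mouth outer P48..P59, inner P60..P67
  fx[49:60] <- c(600, 612, 626, 640, 654, 668, 680, 668, 654, 640, 626, 612)
  fy[49:60] <- c(420, 412, 408, 406, 408, 412, 420, 428, 432, 434, 432, 428)
  fx[61:68] <- c(610, 625, 640, 655, 670, 655, 640, 625)
  fy[61:68] <- c(420, 419, 418.5, 419, 420, 421, 421.5, 421)

  # 56-point eye model: 20-point lid ring + 8-point iris ring per eye
  ex <- numeric(56); ey <- numeric(56)
  phi <- pi + (0:19 - 8) * pi / 6
  ex[1:20] <- 590 + 25 * cos(phi)
  ey[1:20] <- 330 + 8 * sin(phi)
  psi <- 2 * pi * (0:7) / 8
  ex[21:28] <- 590 + 6 * cos(psi)
  ey[21:28] <- 330 + 6 * sin(psi)
  ex[29:56] <- ex[1:28] + 100
  ey[29:56] <- ey[1:28]
  list(face = cbind(fx, fy), eye = cbind(ex, ey),
       eye_center_y = 330, mouth_center_y = 420)
}

#' Synthetic-session configuration
#'
#' Defaults state the emulated world: 10-minute sessions at the 30 fps
#' recording rate, ~30 free-speech utterances of 5-15 s (half deceptive),
#' a 15 blinks/min baseline tripled inside deception windows, a 70 bpm
#' pulse with AR(1) noise whose variance is quadrupled inside deception
#' windows, about one missing pulse sample per thousand, and smooth
#' (AR(1), sd 1 px) landmark jitter. Effect sizes of 1 (multipliers) or 0
#' (shifts) switch an effect off.
#'
#' @param duration_s session length (seconds).
#' @param fps video frame rate.
#' @param n_utterances number of utterances.
#' @param fraction_deceptive fraction of utterances that are deceptive.
#' @param utterance_length_s length range (min, max) in seconds.
#' @param blink_rate_base baseline blink rate (blinks/minute).
#' @param blink_rate_deception_multiplier blink-rate multiplier inside
#'   deception windows.
#' @param mouth_area_shift fractional mouth-size shift inside deception
#'   windows.
#' @param gaze_shift_sd sd (radians) of the sustained gaze offset drawn
#'   per deception window.
#' @param pulse_base baseline pulse (bpm).
#' @param pulse_noise_sd sd of the AR(1) pulse innovations (bpm).
#' @param pulse_variance_deception_multiplier pulse-variance multiplier
#'   inside deception windows.
#' @param landmark_jitter_sd stationary sd (pixels) of the AR(1) landmark
#'   jitter (common-mode translation; the per-landmark tracking residual
#'   is 0.25 of it).
#' @param jitter_ar AR(1) coefficient of the jitter (per frame).
#' @param lid_drift_sd stationary sd of the slow binocular lid-aperture
#'   drift (fraction of the open-eye extent; 0 = lids steady).
#' @param mouth_open_scale inner-mouth vertical opening factor while
#'   speaking (1 = mouth never opens).
#' @param missing_pulse_rate probability a 1 Hz pulse sample is missing.
#' @param seed generator seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(duration_s = 600, fps = 30, n_utterances = 30,
                         fraction_deceptive = 0.5,
                         utterance_length_s = c(5, 15),
                         blink_rate_base = 15,
                         blink_rate_deception_multiplier = 3,
                         mouth_area_shift = 0.3,
                         gaze_shift_sd = 0.1,
                         pulse_base = 70, pulse_noise_sd = 1.5,
                         pulse_variance_deception_multiplier = 4,
                         landmark_jitter_sd = 1, jitter_ar = 0.95,
                         lid_drift_sd = 0.18,
                         mouth_open_scale = 6,
                         missing_pulse_rate = 0.001,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$duration_s > 0, cfg$fps > 0,
            cfg$fraction_deceptive >= 0, cfg$fraction_deceptive <= 1,
            cfg$blink_rate_base >= 0, cfg$pulse_noise_sd >= 0,
            cfg$landmark_jitter_sd >= 0, cfg$missing_pulse_rate >= 0)
  structure(cfg, class = "synth_config")
}

#' A configuration with every deception effect switched off
#'
#' The null world: stationary behavior with labels still assigned around
#' deceptive onsets, so positive and negative frames are distributionally
#' identical. Utterance-locked mouth opening is also suppressed
#' (`mouth_open_scale = 1`): onset-locked labeling plus undersampling
#' would otherwise make window structure itself predictive.
#'
#' @param ... overrides passed to [synth_config()].
#' @return a `synth_config`.
#' @export
null_synth_config <- function(...) {
  synth_config(blink_rate_deception_multiplier = 1, mouth_area_shift = 0,
               gaze_shift_sd = 0, pulse_variance_deception_multiplier = 1,
               mouth_open_scale = 1, ...)
}

pack_utterances <- function(cfg) {
  n <- cfg$n_utterances
  lead <- 4; min_gap <- 2; tail_margin <- 6
  lens <- runif(n, cfg$utterance_length_s[1], cfg$utterance_length_s[2])
  slack <- cfg$duration_s - lead - tail_margin - sum(lens) - min_gap * (n - 1)
  if (slack < 0)
    stop_dd("cannot pack %d utterances of %g-%g s into %g s", n,
            cfg$utterance_length_s[1], cfg$utterance_length_s[2],
            cfg$duration_s, class = "deceptrf_config_error")
  w <- runif(n); w <- w / sum(w)
  gaps <- c(lead, rep(min_gap, n - 1)) + slack * w
  onsets <- cumsum(gaps) + c(0, cumsum(lens))[1:n]
  n_dec <- round(n * cfg$fraction_deceptive)
  deceptive <- rep(FALSE, n)
  deceptive[sample(n, n_dec)] <- TRUE
  data.frame(onset_s = onsets, end_s = onsets + lens, deceptive = deceptive)
}

ar1_matrix <- function(n, ncol, rho, sd_stat) {
  if (sd_stat == 0) return(matrix(0, n, ncol))
  innov <- matrix(rnorm(n * ncol, 0, sd_stat * sqrt(1 - rho^2)), n, ncol)
  innov[1, ] <- rnorm(ncol, 0, sd_stat)
  apply(innov, 2, function(e) as.numeric(stats::filter(e, rho, "recursive")))
}

#' Simulate one synthetic session
#'
#' Generates the aligned landmark/pulse/annotation streams with the
#' configured deception-window effects and the ground truth needed to
#' verify downstream recovery. With `dir` given, the three input files
#' (canonical dialects) plus a ground-truth JSON are written.
#'
#' @param config a [synth_config()].
#' @param dir optional output directory for the four files.
#' @return list with `session` (a `session_recording`), `pulse` (the 1 Hz
#'   series), `truth` (labels, blink starts, utterances, window flags) and
#'   `paths` (when `dir` is given).
#' @export
simulate_session <- function(config = synth_config(), dir = NULL) {
  cfg <- config
  withr::with_seed(cfg$seed, {
    n <- as.integer(round(cfg$duration_s * cfg$fps))
    t <- (seq_len(n) - 1) / cfg$fps
    tpl <- face_template()

    ann <- pack_utterances(cfg)
    labels <- make_labels(ann, n, cfg$fps)
    win <- labels == 1L
    speaking <- rep(FALSE, n)
    for (i in seq_len(nrow(ann)))
      speaking <- speaking | (t >= ann$onset_s[i] & t < ann$end_s[i])

    # blinks: per-frame Bernoulli thinning of a Poisson process whose rate
    # is multiplied inside deception windows; 8-frame refractory period
    rate <- cfg$blink_rate_base / 60 / cfg$fps *
      ifelse(win, cfg$blink_rate_deception_multiplier, 1)
    cand <- which(runif(n) < rate)
    blink_starts <- integer(0)
    last <- -10L
    for (s in cand) {
      if (s > last + 8L && s <= n - 4L) {
        blink_starts <- c(blink_starts, s)
        last <- s
      }
    }
    e <- rep(1, n)
    prof <- c(0.15, 0.02, 0.02, 0.15)
    for (s in blink_starts) e[s:(s + 3L)] <- pmin(e[s:(s + 3L)], prof)
    # slow binocular lid-aperture drift (squinting, lid droop): an OU
    # process with ~11 s correlation time, so below-Q1 "closure"
    # excursions of the eye area are long and few per 3 s window and the
    # fast blink dips stand out as distinct episodes
    aperture <- pmax(0.4, 1 + as.numeric(ar1_matrix(n, 1, 0.997,
                                                    cfg$lid_drift_sd)))
    e <- e * aperture

    # mouth opening while speaking; scaled further inside deception windows
    m_in <- ifelse(speaking, cfg$mouth_open_scale, 1)
    m_in <- m_in * (1 + cfg$mouth_area_shift * win)
    m_out <- 1 + (m_in - 1) * 0.15

    # gaze and head pose: slow AR(1) wander at naturalistic amplitude
    # (people look around; ~0.08 rad stationary sd), plus sustained
    # per-window gaze offsets drawn with sd gaze_shift_sd
    gaze <- ar1_matrix(n, 2, 0.995, 0.08)
    if (cfg$gaze_shift_sd > 0) {
      for (i in which(ann$deceptive)) {
        idx <- t >= ann$onset_s[i] - 3 & t < ann$onset_s[i] + 5
        gaze[idx, 1] <- gaze[idx, 1] + rnorm(1, 0, cfg$gaze_shift_sd)
        gaze[idx, 2] <- gaze[idx, 2] + rnorm(1, 0, cfg$gaze_shift_sd)
      }
    }
    pose <- ar1_matrix(n, 3, 0.995, 0.03)

    # landmark jitter: mostly common-mode face translation (head
    # micro-motion, sd landmark_jitter_sd, leaves areas and distances
    # unchanged) plus a small fast per-landmark tracking residual
    common <- ar1_matrix(n, 2, cfg$jitter_ar, cfg$landmark_jitter_sd)
    res_sd <- 0.25 * cfg$landmark_jitter_sd
    # rho 0.85: landmark trackers smooth temporally, so the residual is
    # not white at 30 fps
    jf <- ar1_matrix(n, 136, 0.85, res_sd)
    je <- ar1_matrix(n, 112, 0.85, res_sd)
    jf[, 1:68] <- jf[, 1:68] + common[, 1]
    jf[, 69:136] <- jf[, 69:136] + common[, 2]
    je[, 1:56] <- je[, 1:56] + common[, 1]
    je[, 57:112] <- je[, 57:112] + common[, 2]

    one <- rep(1, n)
    face_x <- outer(one, tpl$face[, 1]) + jf[, 1:68]
    face_y0 <- outer(one, tpl$face[, 2])
    # eye closure: scale y-offsets from the eye centerline
    eye_cols <- 37:48
    off <- outer(one, tpl$face[eye_cols, 2] - tpl$eye_center_y)
    face_y0[, eye_cols] <- tpl$eye_center_y + off * e
    # mouth opening: scale y-offsets from the mouth centerline
    outer_cols <- 49:60; inner_cols <- 61:68
    face_y0[, outer_cols] <- tpl$mouth_center_y +
      outer(one, tpl$face[outer_cols, 2] - tpl$mouth_center_y) * m_out
    face_y0[, inner_cols] <- tpl$mouth_center_y +
      outer(one, tpl$face[inner_cols, 2] - tpl$mouth_center_y) * m_in
    face_y <- face_y0 + jf[, 69:136]

    eye_x <- outer(one, tpl$eye[, 1]) + je[, 1:56]
    eye_y <- tpl$eye_center_y +
      outer(one, tpl$eye[, 2] - tpl$eye_center_y) * e + je[, 57:112]

    frames <- new_landmark_frames(
      frame_index = seq_len(n) - 1L, timestamp = t,
      confidence = rep(0.98, n), success = rep(TRUE, n),
      face_x = face_x, face_y = face_y, eye_x = eye_x, eye_y = eye_y,
      gaze = gaze, pose = pose
    )

    # 1 Hz pulse: AR(1) noise whose innovation sd drifts slowly
    # (log-AR(1), heart-rate variability is nonstationary) and is
    # multiplied by sqrt(variance multiplier) inside deception windows
    secs <- 0:ceiling(cfg$duration_s)
    z <- as.numeric(ar1_matrix(length(secs), 1, 0.98, 0.25))
    sd_s <- cfg$pulse_noise_sd * exp(z) *
      ifelse(vapply(secs, function(s) {
        any(ann$deceptive & s >= ann$onset_s - 3 & s < ann$onset_s + 5)
      }, logical(1)), sqrt(cfg$pulse_variance_deception_multiplier), 1)
    r <- numeric(length(secs))
    phi <- 0.5
    r[1] <- rnorm(1, 0, sd_s[1])
    for (s in seq_along(secs)[-1]) r[s] <- phi * r[s - 1] + rnorm(1, 0, sd_s[s])
    bpm <- cfg$pulse_base + r
    miss <- runif(length(secs)) < cfg$missing_pulse_rate
    bpm[miss] <- NA_real_
    pulse <- structure(data.frame(timestamp = as.numeric(secs), bpm = bpm),
                       class = c("pulse_series", "data.frame"))

    ppf <- align_pulse_to_frames(pulse, n, cfg$fps, mode = "step")
    session <- session_recording(frames, ppf, ann, fps = cfg$fps)

    truth <- list(labels = as.integer(labels),
                  blink_starts = blink_starts,
                  utterances = ann,
                  n_missing_pulse = sum(miss),
                  effects = list(
                    blink = cfg$blink_rate_deception_multiplier != 1,
                    mouth = cfg$mouth_area_shift != 0,
                    gaze = cfg$gaze_shift_sd != 0,
                    pulse = cfg$pulse_variance_deception_multiplier != 1))

    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(landmarks = file.path(dir, "landmarks.csv"),
                    pulse = file.path(dir, "pulse.csv"),
                    annotations = file.path(dir, "annotations.json"),
                    ground_truth = file.path(dir, "ground_truth.json"))
      write_openface_csv(frames, paths$landmarks)
      write_pulse_csv(pulse, paths$pulse)
      write_annotations(ann, paths$annotations)
      write_json_artifact(list(labels = truth$labels,
                               blink_starts = truth$blink_starts,
                               utterances = ann,
                               n_missing_pulse = truth$n_missing_pulse),
                          paths$ground_truth)
    }
    list(session = session, pulse = pulse, truth = truth, paths = paths)
  })
}

#' Generate a role-play holdout session set
#'
#' Same generator with mildly perturbed effect sizes and a shifted seed,
#' emulating a second recording context (role-played interviews) scored by
#' an already-trained model.
#'
#' @param config the training-session [synth_config()].
#' @param shift named list of multiplicative perturbations applied to
#'   effect fields (e.g. `list(pulse_variance_deception_multiplier =
#'   0.9)`); an empty list reuses the training effect sizes.
#' @param seed_offset added to the seed (default 1000).
#' @param dir optional output directory.
#' @return as [simulate_session()].
#' @export
make_role_play_set <- function(config, shift = list(), seed_offset = 1000L,
                               dir = NULL) {
  cfg <- config
  for (nm in names(shift)) {
    if (!nm %in% names(cfg))
      stop_dd("unknown config field '%s' in shift", nm,
              class = "deceptrf_config_error")
    cfg[[nm]] <- cfg[[nm]] * shift[[nm]]
  }
  cfg$seed <- cfg$seed + seed_offset
  simulate_session(cfg, dir = dir)
}
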