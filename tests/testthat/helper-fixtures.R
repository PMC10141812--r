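# fixtures built in code: a rigid template face repeated over n frames,
# plus small writable sessions

template_frames <- function(n = 3, fps = 30, transform = identity) {
  tpl <- face_template()
  face <- transform(tpl$face)
  eye <- transform(tpl$eye)
  one <- rep(1, n)
  deceptrf:::new_landmark_frames(
    frame_index = seq_len(n) - 1L, timestamp = (seq_len(n) - 1) / fps,
    confidence = rep(0.98, n), success = rep(TRUE, n),
    face_x = outer(one, face[, 1]), face_y = outer(one, face[, 2]),
    eye_x = outer(one, eye[, 1]), eye_y = outer(one, eye[, 2]),
    gaze = matrix(0, n, 2), pose = matrix(0, n, 3)
  )
}

tiny_session <- function(n = 90, fps = 30, bpm = 70,
                         annotations = data.frame(onset_s = numeric(0),
                                                  end_s = numeric(0),
                                                  deceptive = logical(0))) {
  session_recording(template_frames(n, fps), rep(bpm, n), annotations,
                    fps = fps)
}

write_landmark_fixture <- function(path, n = 3, fps = 30) {
  write_openface_csv(template_frames(n, fps), path)
  path
}

# small fast generator config for module tests (not the stated world;
# the acceptance suite runs the defaults)
small_cfg <- function(seed = 1, ...) {
  synth_config(duration_s = 120, n_utterances = 6, seed = seed, ...)
}

# random simple (convex) polygon around a circle, for area oracles
random_convex_polygon <- function(k) {
  ang <- sort(runif(k, 0, 2 * pi))
  r <- runif(1, 0.5, 3)
  cbind(r * cos(ang) + rnorm(1, 0, 2), r * sin(ang) + rnorm(1, 0, 2))
}

# fan-triangulation area oracle (signed triangles from vertex 1)
fan_area <- function(pts) {
  pts <- unname(as.matrix(pts))
  k <- nrow(pts)
  s <- 0
  for (i in 2:(k - 1)) {
    s <- s + ((pts[i, 1] - pts[1, 1]) * (pts[i + 1, 2] - pts[1, 2]) -
              (pts[i + 1, 1] - pts[1, 1]) * (pts[i, 2] - pts[1, 2])) / 2
  }
  abs(s)
}
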