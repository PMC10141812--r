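#' Default landmark-CSV dialect map
#'
#' Column-name mapping for the OpenFace 2.0 output dialect, plus the
#' semantic indices of the 56-point eye model used by the eye features
#' (aspect ratio and iris offsets). Eye-model points are indexed E0..E55
#' separately from the 68 face points P0..P67 because the published
#' eye-landmark figure reuses small numbers for a different point set;
#' this mapping binds both.
#'
#' @param fps expected video frame rate (frames/second), default 30.
#' @return a list with entries `frame`, `timestamp`, `confidence`,
#'   `success`, `face_x`, `face_y`, `eye_x`, `eye_y`, `gaze`, `pose`
#'   (column names) and `eye_idx` (semantic 0-based eye-model indices per
#'   side: `outer`, `top`, `inner`, `bottom`, `iris`).
#' @export
openface_dialect <- function(fps = 30) {
  list(
    frame = "frame", timestamp = "timestamp",
    confidence = "confidence", success = "success",
    face_x = sprintf("x_%d", 0:67), face_y = sprintf("y_%d", 0:67),
    eye_x = sprintf("eye_lmk_x_%d", 0:55),
    eye_y = sprintf("eye_lmk_y_%d", 0:55),
    gaze = c("gaze_angle_x", "gaze_angle_y"),
    pose = c("pose_Rx", "pose_Ry", "pose_Rz"),
    eye_idx = list(
      right = list(outer = 8L, top = 11L, inner = 14L, bottom = 17L,
                   iris = c(23L, 27L)),
      left  = list(inner = 36L, top = 39L, outer = 42L, bottom = 45L,
                   iris = c(51L, 55L))
    ),
    fps = fps
  )
}

new_landmark_frames <- function(frame_index, timestamp, confidence, success,
                                face_x, face_y, eye_x, eye_y, gaze, pose) {
  structure(list(
    frame_index = as.integer(frame_index), timestamp = as.numeric(timestamp),
    confidence = as.numeric(confidence), success = as.logical(success),
    face_x = face_x, face_y = face_y, eye_x = eye_x, eye_y = eye_y,
    gaze = gaze, pose = pose
  ), class = "landmark_frames")
}

#' @export
length.landmark_frames <- function(x) length(x$frame_index)

#' @export
`[.landmark_frames` <- function(x, i) {
  new_landmark_frames(
    x$frame_index[i], x$timestamp[i], x$confidence[i], x$success[i],
    x$face_x[i, , drop = FALSE], x$face_y[i, , drop = FALSE],
    x$eye_x[i, , drop = FALSE], x$eye_y[i, , drop = FALSE],
    x$gaze[i, , drop = FALSE], x$pose[i, , drop = FALSE]
  )
}

#' @export
print.landmark_frames <- function(x, ...) {
  cat(sprintf("<landmark_frames> %d frames, %d flagged as tracking failures\n",
              length(x), sum(!x$success)))
  invisible(x)
}

check_numeric_cols <- function(dt, cols, path) {
  for (cn in cols) {
    col <- dt[[cn]]
    if (is.numeric(col) || is.logical(col)) next
    suppressWarnings(num <- as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & nzchar(trimws(col)))
    if (length(bad) > 0)
      stop_dd("non-numeric value '%s' in column '%s' at data row %d of %s",
              col[bad[1]], cn, bad[1], path, class = "deceptrf_parse_error")
    data.table::set(dt, j = cn, value = num)
  }
  invisible(dt)
}

#' Read a facial-landmark CSV
#'
#' Reads one video's per-frame landmark table in the OpenFace 2.0 output
#' dialect (configurable through `dialect`). Rows with `success = 0`
#' (tracking failure) are retained and flagged; feature extraction later
#' marks them missing.
#'
#' @param path CSV file path.
#' @param dialect column mapping, see [openface_dialect()].
#' @param fps if non-NULL, validate `timestamp == frame_index / fps`
#'   to within 1e-6 s.
#' @return a `landmark_frames` object (ordered frame sequence).
#' @export
read_openface_csv <- function(path, dialect = openface_dialect(), fps = NULL) {
  if (!file.exists(path))
    stop_dd("landmark file not found: %s", path, class = "deceptrf_io_error")
  dt <- data.table::fread(path, header = TRUE, data.table = TRUE)
  needed <- c(dialect$frame, dialect$timestamp, dialect$confidence,
              dialect$success, dialect$face_x, dialect$face_y,
              dialect$eye_x, dialect$eye_y, dialect$gaze, dialect$pose)
  missing_cols <- setdiff(needed, names(dt))
  if (length(missing_cols) > 0)
    stop_dd("missing required column '%s' in %s", missing_cols[1], path,
            class = "deceptrf_format_error")
  check_numeric_cols(dt, needed, path)
  fi <- dt[[dialect$frame]]
  if (length(fi) > 1 && any(diff(fi) <= 0))
    stop_dd("frame indices not strictly increasing in %s", path,
            class = "deceptrf_format_error")
  ts <- dt[[dialect$timestamp]]
  if (!is.null(fps)) {
    if (any(abs(ts - fi / fps) > 1e-6))
      stop_dd("timestamps inconsistent with frame_index/fps in %s", path,
              class = "deceptrf_format_error")
  }
  new_landmark_frames(
    frame_index = fi, timestamp = ts,
    confidence = dt[[dialect$confidence]],
    success = dt[[dialect$success]] != 0,
    face_x = as.matrix(dt[, dialect$face_x, with = FALSE]),
    face_y = as.matrix(dt[, dialect$face_y, with = FALSE]),
    eye_x = as.matrix(dt[, dialect$eye_x, with = FALSE]),
    eye_y = as.matrix(dt[, dialect$eye_y, with = FALSE]),
    gaze = as.matrix(dt[, dialect$gaze, with = FALSE]),
    pose = as.matrix(dt[, dialect$pose, with = FALSE])
  )
}

#' Write a facial-landmark CSV in the canonical dialect
#'
#' @param frames a `landmark_frames` object.
#' @param path output CSV path.
#' @param dialect column mapping, see [openface_dialect()].
#' @return `path`, invisibly.
#' @export
write_openface_csv <- function(frames, path, dialect = openface_dialect()) {
  dt <- data.table::data.table(
    frames$frame_index, frames$timestamp, frames$confidence,
    as.integer(frames$success)
  )
  data.table::setnames(dt, c(dialect$frame, dialect$timestamp,
                             dialect$confidence, dialect$success))
  add <- function(m, nms) for (j in seq_along(nms))
    data.table::set(dt, j = nms[j], value = m[, j])
  add(frames$gaze, dialect$gaze)
  add(frames$pose, dialect$pose)
  add(frames$face_x, dialect$face_x)
  add(frames$face_y, dialect$face_y)
  add(frames$eye_x, dialect$eye_x)
  add(frames$eye_y, dialect$eye_y)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a 1 Hz pulse-rate CSV
#'
#' Two columns, `timestamp` (seconds) and `bpm`; empty bpm cells are kept
#' as missing markers (`NA`).
#'
#' @param path CSV path.
#' @return a data.frame with columns `timestamp`, `bpm` (class
#'   `pulse_series`).
#' @export
read_pulse_csv <- function(path) {
  if (!file.exists(path))
    stop_dd("pulse file not found: %s", path, class = "deceptrf_io_error")
  dt <- data.table::fread(path, header = TRUE, data.table = TRUE,
                          colClasses = list(numeric = 1:2))
  if (!all(c("timestamp", "bpm") %in% names(dt)))
    stop_dd("pulse CSV must have columns 'timestamp,bpm' (%s)", path,
            class = "deceptrf_format_error")
  ts <- dt$timestamp
  if (length(ts) > 1 && any(diff(ts) <= 0))
    stop_dd("pulse timestamps not strictly increasing in %s", path,
            class = "deceptrf_format_error")
  bpm <- dt$bpm
  if (any(!is.na(bpm) & (bpm <= 20 | bpm >= 250)))
    stop_dd("pulse values outside the plausible (20, 250) bpm range in %s",
            path, class = "deceptrf_format_error")
  structure(data.frame(timestamp = ts, bpm = bpm),
            class = c("pulse_series", "data.frame"))
}

#' Write a pulse-rate CSV
#'
#' @param pulse data.frame with `timestamp`, `bpm` columns (NA bpm allowed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pulse_csv <- function(pulse, path) {
  data.table::fwrite(data.table::as.data.table(pulse[c("timestamp", "bpm")]),
                     path)
  invisible(path)
}

#' Read utterance annotations (JSON)
#'
#' A JSON list of objects `{onset_s, end_s, deceptive}` giving, for each
#' utterance, the time the subject opened their mouth, the end of the
#' utterance, and whether it was deceptive.
#'
#' @param path JSON path.
#' @return data.frame with columns `onset_s`, `end_s`, `deceptive`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    stop_dd("annotation file not found: %s", path, class = "deceptrf_io_error")
  ann <- jsonlite::fromJSON(path)
  ann <- as.data.frame(ann)
  if (!all(c("onset_s", "end_s", "deceptive") %in% names(ann)))
    stop_dd("annotations need fields onset_s, end_s, deceptive (%s)", path,
            class = "deceptrf_format_error")
  if (any(ann$onset_s >= ann$end_s))
    stop_dd("annotation with onset >= end in %s", path,
            class = "deceptrf_format_error")
  ann[c("onset_s", "end_s", "deceptive")]
}

#' Write utterance annotations (JSON)
#'
#' @param annotations data.frame with `onset_s`, `end_s`, `deceptive`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  jsonlite::write_json(annotations, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Align a 1 Hz pulse series to video frames
#'
#' `step` mode (default) assigns each frame the pulse sample with the
#' greatest timestamp not exceeding the frame time; `linear` interpolates
#' between consecutive samples at the frame timestamp (`frame_index /
#' fps`). Frames whose covering sample (either interpolation endpoint in
#' linear mode) is missing carry `NA`.
#'
#' @param pulse data.frame with `timestamp`, `bpm` (see [read_pulse_csv()]).
#' @param n_frames number of video frames.
#' @param fps frames per second.
#' @param mode `"step"` or `"linear"`.
#' @return numeric vector of length `n_frames` (bpm per frame, NA where
#'   missing).
#' @export
align_pulse_to_frames <- function(pulse, n_frames, fps,
                                  mode = c("step", "linear")) {
  mode <- match.arg(mode)
  stopifnot(n_frames >= 1, fps > 0)
  ts <- pulse$timestamp
  bpm <- pulse$bpm
  duration <- (n_frames - 1) / fps
  # coverage: one trailing sample interval of slack is tolerated
  if (max(ts) < duration - 1)
    stop_dd("pulse series (last sample %.3f s) does not cover the %.3f s session",
            max(ts), duration, class = "deceptrf_coverage_error")
  if (min(ts) > 0)
    stop_dd("pulse series starts after the session (first sample %.3f s)",
            min(ts), class = "deceptrf_coverage_error")
  t_frame <- (seq_len(n_frames) - 1) / fps
  idx <- findInterval(t_frame, ts)        # greatest sample timestamp <= t
  idx[idx < 1] <- 1L
  if (mode == "step") {
    return(bpm[idx])
  }
  # linear: interpolate between covering sample and the next; hold the last
  nxt <- pmin(idx + 1L, length(ts))
  w <- ifelse(nxt == idx, 0, (t_frame - ts[idx]) / (ts[nxt] - ts[idx]))
  w <- pmin(pmax(w, 0), 1)
  out <- (1 - w) * bpm[idx] + w * bpm[nxt]
  out[is.na(bpm[idx]) | is.na(bpm[nxt])] <- NA_real_
  out
}

#' Bundle one session's aligned streams
#'
#' @param frames `landmark_frames` sequence.
#' @param pulse_per_frame bpm per frame (same length as `frames`).
#' @param annotations utterance annotation data.frame.
#' @param fps frames per second (default 30, the recording rate).
#' @return a `session_recording` object.
#' @export
session_recording <- function(frames, pulse_per_frame, annotations, fps = 30) {
  stopifnot(fps > 0)
  if (length(pulse_per_frame) != length(frames))
    stop_dd("pulse_per_frame length (%d) != number of frames (%d)",
            length(pulse_per_frame), length(frames),
            class = "deceptrf_format_error")
  structure(list(frames = frames, pulse_per_frame = pulse_per_frame,
                 annotations = annotations, fps = fps),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %d frames @ %g fps (%.1f s), %d utterances (%d deceptive)\n",
              length(x$frames), x$fps, length(x$frames) / x$fps,
              nrow(x$annotations), sum(x$annotations$deceptive)))
  invisible(x)
}

#' Read a full session from its three files
#'
#' @param landmarks_path landmark CSV path.
#' @param pulse_path pulse CSV path.
#' @param annotations_path annotation JSON path.
#' @param fps frames per second.
#' @param dialect landmark-CSV dialect map.
#' @param pulse_mode pulse-to-frame alignment mode.
#' @return a `session_recording`.
#' @export
read_session <- function(landmarks_path, pulse_path, annotations_path,
                         fps = 30, dialect = openface_dialect(fps),
                         pulse_mode = "step") {
  frames <- read_openface_csv(landmarks_path, dialect, fps = fps)
  pulse <- read_pulse_csv(pulse_path)
  ann <- read_annotations(annotations_path)
  ppf <- align_pulse_to_frames(pulse, length(frames), fps, mode = pulse_mode)
  session_recording(frames, ppf, ann, fps = fps)
}
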