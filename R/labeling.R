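# Per-frame deception labels from utterance annotations.

#' Per-frame deception labels
#'
#' A frame at time `t = frame_index / fps` is positive iff it falls in
#' `[onset - pre_s, onset + post_s)` of any deceptive utterance (half-open
#' at frame resolution, so an unclipped window spans exactly `(pre_s +
#' post_s) * fps` frames). Overlapping deceptive windows union; truthful
#' utterances and deceptive speech beyond `post_s` are negative. The
#' positive window takes precedence over any overlapping truthful
#' utterance.
#'
#' @param annotations data.frame with `onset_s`, `end_s`, `deceptive`.
#' @param n_frames number of frames in the session.
#' @param fps frames per second.
#' @param pre_s seconds before onset included (default 3).
#' @param post_s seconds after onset included (default 5).
#' @return integer vector (0/1) of length `n_frames`, with attribute
#'   `provenance`: index of the first deceptive annotation covering each
#'   positive frame (0 for negatives).
#' @export
make_labels <- function(annotations, n_frames, fps, pre_s = 3, post_s = 5) {
  stopifnot(n_frames >= 1, fps > 0)
  duration <- n_frames / fps
  dec <- which(annotations$deceptive)
  bad <- dec[annotations$onset_s[dec] < 0 | annotations$onset_s[dec] > duration]
  if (length(bad) > 0)
    stop_dd("deceptive onset %.3f s outside the [0, %.3f s] session",
            annotations$onset_s[bad[1]], duration,
            class = "deceptrf_annotation_error")
  t <- (seq_len(n_frames) - 1) / fps
  labels <- integer(n_frames)
  provenance <- integer(n_frames)
  eps <- 1e-9
  for (i in dec) {
    onset <- annotations$onset_s[i]
    inside <- t >= onset - pre_s - eps & t < onset + post_s - eps
    labels[inside] <- 1L
    provenance[inside & provenance == 0L] <- i
  }
  attr(labels, "provenance") <- provenance
  labels
}

#' Attach labels to a feature table
#'
#' @param features feature table (one row per frame).
#' @param labels 0/1 vector from [make_labels()].
#' @return data.frame `features` plus a `label` column.
#' @export
label_dataset <- function(features, labels) {
  if (nrow(features) != length(labels))
    stop_dd("label count (%d) does not match row count (%d)",
            length(labels), nrow(features), class = "deceptrf_format_error")
  out <- features
  out$label <- as.integer(labels)
  attr(out, "fps") <- attr(features, "fps")
  attr(out, "provenance") <- attr(labels, "provenance")
  out
}
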