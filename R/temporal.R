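# Rolling-variance and event-count features over the per-frame series.

#' Centered rolling variance
#'
#' Population variance over a centered window of `2 * half_width_s * fps +
#' 1` frames, truncated at the edges of the series. Missing values are
#' excluded from their windows; a window with fewer than two present
#' values yields NA. Implemented with cumulative sums (O(n)), centering
#' the series first for numerical stability.
#'
#' @param series per-frame numeric vector (NA allowed).
#' @param half_width_s window half-width in seconds (> 0); the facial
#'   features use 3 s (6 s total), the pulse 10 s (20 s total).
#' @param fps frames per second.
#' @return per-frame variance vector, same length as `series`.
#' @export
rolling_variance <- function(series, half_width_s, fps) {
  if (length(series) == 0)
    stop_dd("rolling_variance: empty series", class = "deceptrf_argument_error")
  stopifnot(half_width_s > 0, fps > 0)
  n <- length(series)
  h <- as.integer(round(half_width_s * fps))
  ok <- !is.na(series)
  mu <- if (any(ok)) mean(series[ok]) else 0
  xs <- ifelse(ok, series - mu, 0)
  cs <- c(0, cumsum(xs))
  cs2 <- c(0, cumsum(xs^2))
  cn <- c(0, cumsum(ok))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  S <- cs[hi + 1L] - cs[lo]
  S2 <- cs2[hi + 1L] - cs2[lo]
  m <- cn[hi + 1L] - cn[lo]
  v <- rep(NA_real_, n)
  good <- m >= 2
  v[good] <- pmax(S2[good] / m[good] - (S[good] / m[good])^2, 0)
  v
}

#' Closure threshold (first quartile)
#'
#' First quartile (linear-interpolation convention) of all present values
#' of an area series over the entire session; areas below it are treated
#' as "closed".
#'
#' @param series per-frame area values (NA allowed).
#' @return Q1 in the units of `series`.
#' @export
closure_threshold <- function(series) {
  present <- series[!is.na(series)]
  if (length(present) < 4)
    stop_dd("closure_threshold needs at least 4 present values, got %d",
            length(present), class = "deceptrf_argument_error")
  q_linear(present, 0.25)
}

#' Count closure episodes in a trailing window
#'
#' For each frame t, the number of below-threshold episodes (maximal runs
#' of consecutive frames with value < threshold) that intersect the
#' trailing window `(t - window_s * fps, t]`. An episode straddling the
#' window edge counts once. NA values never start or extend an episode.
#'
#' @param series per-frame values.
#' @param threshold closure threshold (finite).
#' @param window_s trailing window length in seconds (default 3).
#' @param fps frames per second.
#' @return integer vector of per-frame episode counts.
#' @export
count_closure_episodes <- function(series, threshold, window_s = 3, fps) {
  stopifnot(is.finite(threshold), fps > 0, window_s > 0)
  below <- !is.na(series) & series < threshold
  n <- length(below)
  starts <- which(diff(c(FALSE, below)) == 1L)
  ends <- which(diff(c(below, FALSE)) == -1L)
  w <- as.integer(round(window_s * fps))
  t <- seq_len(n)
  n_started <- findInterval(t, starts)       # episodes with start <= t
  n_closed <- findInterval(t - w, ends)      # episodes fully before window
  as.integer(n_started - n_closed)
}

#' Feature-table column conventions
#'
#' @return list recording the pinned numerical conventions (variance type,
#'   quantile rule, window sizes) embedded in feature-table sidecars.
#' @export
feature_conventions <- function() {
  list(variance = "population", quantile = "linear (type 7)",
       facial_variance_half_width_s = 3, pulse_variance_half_width_s = 10,
       closure_window_s = 3, closure_rule = "area < session Q1")
}

#' Build the per-frame feature table of a session
#'
#' Columns: all static geometric features, the rolling variance of every
#' facial feature (+/- 3 s), the pulse variance (+/- 10 s), blink counts
#' (per eye and merged over the mean eye area; trailing 3 s) and the
#' mouth-closure count (inner mouth area; trailing 3 s), in a fixed order.
#' Missing values propagate; nothing is imputed. Closure thresholds are
#' the first quartile of each area over the entire session (a deliberate,
#' documented use of global statistics before any train/test split).
#'
#' @param session a `session_recording`.
#' @param eye_idx semantic eye-model indices.
#' @param L_convention nasal-bridge convention.
#' @param facial_var_s,pulse_var_s variance window half-widths (seconds).
#' @param closure_window_s trailing event-count window (seconds).
#' @return data.frame with one row per frame and attributes `fps`,
#'   `conventions`.
#' @export
build_feature_table <- function(session,
                                eye_idx = openface_dialect()$eye_idx,
                                L_convention = "midpoint",
                                facial_var_s = 3, pulse_var_s = 10,
                                closure_window_s = 3) {
  fps <- session$fps
  static <- extract_static_features(session$frames, session$pulse_per_frame,
                                    eye_idx, L_convention)
  facial_cols <- setdiff(names(static), "pulse")
  vars <- lapply(static[facial_cols], rolling_variance,
                 half_width_s = facial_var_s, fps = fps)
  names(vars) <- paste0("var_", facial_cols)
  var_pulse <- rolling_variance(static$pulse, pulse_var_s, fps)

  count_of <- function(series) {
    thr <- closure_threshold(series)
    count_closure_episodes(series, thr, closure_window_s, fps)
  }
  blink_r <- count_of(static$eye_area_r)
  blink_l <- count_of(static$eye_area_l)
  blink_m <- count_of((static$eye_area_r + static$eye_area_l) / 2)
  mouth_closed <- count_of(static$mouth_area_in)

  out <- cbind(static, as.data.frame(vars), var_pulse = var_pulse,
               blink_count_r = blink_r, blink_count_l = blink_l,
               blink_count = blink_m, mouth_closed_count = mouth_closed)
  attr(out, "fps") <- fps
  attr(out, "conventions") <- feature_conventions()
  out
}

#' Names of the event-count feature columns
#'
#' Integer-valued columns exempt from quartile-fence outlier removal by
#' default (fences on small counts would delete the high-count deception
#' frames the counts exist to flag).
#'
#' @return character vector of column names.
#' @export
count_feature_names <- function() {
  c("blink_count_r", "blink_count_l", "blink_count", "mouth_closed_count")
}

#' Write a feature table with a JSON conventions sidecar
#'
#' @param features feature table from [build_feature_table()].
#' @param path output CSV path; the sidecar goes to `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  data.table::fwrite(data.table::as.data.table(features), path)
  meta <- c(attr(features, "conventions") %||% feature_conventions(),
            list(fps = attr(features, "fps")))
  write_json_artifact(meta, paste0(path, ".meta.json"))
  invisible(path)
}
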