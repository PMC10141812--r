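# Per-frame geometric features. Landmarks are in image coordinates
# (pixels, y grows downward). Distances are normalized by the nasal-bridge
# length L and areas by L^2 so that features are invariant to uniform
# scaling and translation of the face in the image.

# vectorized shoelace over rows: px, py are n x k matrices, one polygon
# per row, vertices in stored order, closed cyclically
shoelace_rows <- function(px, py) {
  k <- ncol(px)
  nxt <- c(2:k, 1)
  0.5 * abs(rowSums((px - px[, nxt, drop = FALSE]) *
                    (py + py[, nxt, drop = FALSE])))
}

#' Polygon area (shoelace formula)
#'
#' Absolute area of the polygon traversed in the stored vertex order and
#' closed cyclically; collinear input gives 0.
#'
#' @param points numeric matrix, one vertex per row (x, y), at least 3 rows.
#' @return area in squared input units.
#' @export
polygon_area <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3)
    stop_dd("polygon_area needs at least 3 points, got %d", nrow(points),
            class = "deceptrf_argument_error")
  shoelace_rows(matrix(points[, 1], nrow = 1), matrix(points[, 2], nrow = 1))
}

# 0-based face-point index -> column
fp <- function(i) i + 1L

#' Nasal-bridge length L
#'
#' The normalization scale: by default the distance between the midpoint of
#' the inner brow ends (P21, P22) and the midpoint of the upper inner eye
#' corners (P39, P42). The alternative convention averages the two vertical
#' segment lengths |P21-P39| and |P22-P42|; both agree on axis-aligned
#' rectangles.
#'
#' @param face_points 68 x 2 matrix of face landmarks.
#' @param convention `"midpoint"` (default) or `"pairmean"`.
#' @return L in pixels (> 0).
#' @export
nasal_bridge_length <- function(face_points, convention = c("midpoint", "pairmean")) {
  convention <- match.arg(convention)
  p <- function(i) face_points[fp(i), ]
  L <- if (convention == "midpoint") {
    sqrt(sum(((p(21) + p(22)) / 2 - (p(39) + p(42)) / 2)^2))
  } else {
    (sqrt(sum((p(21) - p(39))^2)) + sqrt(sum((p(22) - p(42))^2))) / 2
  }
  if (!is.finite(L) || L <= 0)
    stop_dd("degenerate face: nasal-bridge length is zero",
            class = "deceptrf_degenerate_face")
  L
}

# rowwise Euclidean distance between two 0-based face points
dist_rows <- function(fx, fy, i, j) {
  sqrt((fx[, fp(i)] - fx[, fp(j)])^2 + (fy[, fp(i)] - fy[, fp(j)])^2)
}

#' Eyebrow tilt (least-squares slope)
#'
#' Ordinary least-squares slope of y on x through the five brow points.
#' Image coordinates (y down), so the sign is flipped versus visual
#' intuition; this is documented, not corrected.
#'
#' @param brow_points 5 x 2 matrix.
#' @return slope (dimensionless), NA if all x equal (vertical brow).
#' @export
eyebrow_tilt <- function(brow_points) {
  x <- brow_points[, 1]; y <- brow_points[, 2]
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(NA_real_)
  sum((x - mean(x)) * (y - mean(y))) / sxx
}

#' Brow-eye distance
#'
#' Mean of the four Euclidean distances between the listed brow/eyelid
#' point pairs, divided by L.
#'
#' @param brow_pairs list of 4 point pairs; each pair is a 2 x 2 matrix
#'   (brow point row, eye point row).
#' @param L nasal-bridge length.
#' @return L-normalized distance.
#' @export
brow_eye_distance <- function(brow_pairs, L) {
  d <- vapply(brow_pairs, function(pr) sqrt(sum((pr[1, ] - pr[2, ])^2)),
              numeric(1))
  mean(d) / L
}

#' Inter-brow area
#'
#' Shoelace area of the quadrilateral over (P21, P22, P42, P39) traversed
#' in convex order, divided by L^2.
#'
#' @param face_points 68 x 2 matrix.
#' @param L nasal-bridge length.
#' @return L^2-normalized area.
#' @export
inter_brow_area <- function(face_points, L) {
  idx <- fp(c(21, 22, 42, 39))
  polygon_area(face_points[idx, , drop = FALSE]) / L^2
}

#' Eye area
#'
#' Shoelace area of the six-point eye ring (P36..P41 right, P42..P47
#' left), divided by L^2; 0 when the eye is closed (collinear points).
#'
#' @param face_points 68 x 2 matrix.
#' @param side `"right"` or `"left"`.
#' @param L nasal-bridge length.
#' @return L^2-normalized area.
#' @export
eye_area <- function(face_points, side = c("right", "left"), L) {
  side <- match.arg(side)
  idx <- if (side == "right") fp(36:41) else fp(42:47)
  polygon_area(face_points[idx, , drop = FALSE]) / L^2
}

#' Aspect ratio from a vertical/horizontal extent pair
#'
#' @param l_v vertical extent (designated landmark pair distance).
#' @param l_h horizontal extent.
#' @return `l_v / l_h`; NA when `l_h` is 0.
#' @export
aspect_ratio <- function(l_v, l_h) {
  ifelse(l_h > 0, l_v / l_h, NA_real_)
}

#' Iris offsets
#'
#' Horizontal offset: distance from the eye's inner corner to the iris
#' center (midpoint of the two iris points); vertical offset: distance
#' from the eye's top point to the iris center. Both divided by L.
#'
#' @param eye_points 56 x 2 eye-model matrix.
#' @param side `"right"` or `"left"`.
#' @param L nasal-bridge length.
#' @param eye_idx semantic eye-model indices (see [openface_dialect()]).
#' @return named numeric vector `c(horizontal, vertical)`.
#' @export
iris_offsets <- function(eye_points, side = c("right", "left"), L,
                         eye_idx = openface_dialect()$eye_idx) {
  side <- match.arg(side)
  ix <- eye_idx[[side]]
  ep <- function(i) eye_points[i + 1L, ]
  center <- (ep(ix$iris[1]) + ep(ix$iris[2])) / 2
  c(horizontal = sqrt(sum((center - ep(ix$inner))^2)) / L,
    vertical = sqrt(sum((center - ep(ix$top))^2)) / L)
}

#' Mouth area
#'
#' Shoelace area of the inner 8-point ring (P60..P67) or outer 12-point
#' ring (P48..P59), divided by L^2.
#'
#' @param face_points 68 x 2 matrix.
#' @param ring `"inner"` or `"outer"`.
#' @param L nasal-bridge length.
#' @return L^2-normalized area.
#' @export
mouth_area <- function(face_points, ring = c("inner", "outer"), L) {
  ring <- match.arg(ring)
  idx <- if (ring == "inner") fp(60:67) else fp(48:59)
  polygon_area(face_points[idx, , drop = FALSE]) / L^2
}

#' Mouth-corner raise
#'
#' `(y_h - y_v) / y_v` where `y_v` is the sum of the y-coordinates of the
#' top (P51) and bottom (P57) mouth points and `y_h` the sum for the two
#' mouth corners (P48, P54). Computed in image coordinates (y down); the
#' published sign reading (positive = corners raised) is kept.
#'
#' @param face_points 68 x 2 matrix.
#' @return dimensionless value; NA when `y_v` is 0.
#' @export
mouth_corner_raise <- function(face_points) {
  y <- face_points[, 2]
  y_v <- y[fp(51)] + y[fp(57)]
  y_h <- y[fp(48)] + y[fp(54)]
  if (y_v == 0) return(NA_real_)
  (y_h - y_v) / y_v
}

angle_deg <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  acos(pmin(pmax(sum(u * v) / (nu * nv), -1), 1)) * 180 / pi
}

#' Mouth angle
#'
#' Mean of the two mouth-corner angles: at P48 between segments to P49 and
#' P59, and at P54 between segments to P53 and P55, in degrees.
#'
#' @param face_points 68 x 2 matrix.
#' @return mean corner angle in 0..180 degrees; NA on zero-length
#'   segments.
#' @export
mouth_angle <- function(face_points) {
  p <- function(i) face_points[fp(i), ]
  a1 <- angle_deg(p(49) - p(48), p(59) - p(48))
  a2 <- angle_deg(p(53) - p(54), p(55) - p(54))
  (a1 + a2) / 2
}

#' Canonical static feature column order
#'
#' The 25 raw per-frame features: brow tilt/distance, inter-brow and eye
#' areas, eye aspect ratios, iris offsets, mouth geometry, gaze, head
#' rotation and pulse.
#'
#' @return character vector of column names.
#' @export
static_feature_names <- function() {
  c("brow_tilt_r", "brow_tilt_l", "brow_eye_dist_r", "brow_eye_dist_l",
    "inter_brow_area", "eye_area_r", "eye_area_l", "ear_r", "ear_l",
    "iris_offset_h_r", "iris_offset_v_r", "iris_offset_h_l",
    "iris_offset_v_l", "mouth_area_in", "mouth_area_out",
    "mouth_aspect_in", "mouth_aspect_out", "mouth_corner_raise",
    "mouth_angle", "gaze_h", "gaze_v", "head_pitch", "head_yaw",
    "head_roll", "pulse")
}

# vectorized static-feature extraction over all frames; returns a
# data.frame with one row per frame (NA rows for tracking failures or
# degenerate nasal bridge)
extract_static_features <- function(frames, pulse_per_frame,
                                    eye_idx = openface_dialect()$eye_idx,
                                    L_convention = "midpoint") {
  fx <- frames$face_x; fy <- frames$face_y
  ex <- frames$eye_x; ey <- frames$eye_y
  n <- length(frames)

  mid_xy <- function(i, j) list(x = (fx[, fp(i)] + fx[, fp(j)]) / 2,
                                y = (fy[, fp(i)] + fy[, fp(j)]) / 2)
  L <- if (L_convention == "midpoint") {
    a <- mid_xy(21, 22); b <- mid_xy(39, 42)
    sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
  } else {
    (dist_rows(fx, fy, 21, 39) + dist_rows(fx, fy, 22, 42)) / 2
  }

  tilt_rows <- function(cols) {
    X <- fx[, fp(cols), drop = FALSE]; Y <- fy[, fp(cols), drop = FALSE]
    xc <- X - rowMeans(X); yc <- Y - rowMeans(Y)
    sxx <- rowSums(xc^2)
    ifelse(sxx > 0, rowSums(xc * yc) / sxx, NA_real_)
  }

  bed <- function(pairs) {
    d <- 0
    for (pr in pairs) d <- d + dist_rows(fx, fy, pr[1], pr[2])
    d / length(pairs) / L
  }

  poly_rows <- function(cols) {
    shoelace_rows(fx[, fp(cols), drop = FALSE], fy[, fp(cols), drop = FALSE])
  }

  edist_rows <- function(i, j) {
    sqrt((ex[, i + 1L] - ex[, j + 1L])^2 + (ey[, i + 1L] - ey[, j + 1L])^2)
  }
  iris_rows <- function(ix) {
    cx <- (ex[, ix$iris[1] + 1L] + ex[, ix$iris[2] + 1L]) / 2
    cy <- (ey[, ix$iris[1] + 1L] + ey[, ix$iris[2] + 1L]) / 2
    list(h = sqrt((cx - ex[, ix$inner + 1L])^2 + (cy - ey[, ix$inner + 1L])^2) / L,
         v = sqrt((cx - ex[, ix$top + 1L])^2 + (cy - ey[, ix$top + 1L])^2) / L)
  }
  ir <- iris_rows(eye_idx$right); il <- iris_rows(eye_idx$left)

  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)

  y_v <- fy[, fp(51)] + fy[, fp(57)]
  y_h <- fy[, fp(48)] + fy[, fp(54)]

  angle_rows <- function(ax, ay, bx, by) {
    # angle between row vectors (ax,ay) and (bx,by), degrees
    na <- sqrt(ax^2 + ay^2); nb <- sqrt(bx^2 + by^2)
    ok <- na > 0 & nb > 0
    out <- rep(NA_real_, length(ax))
    cosv <- pmin(pmax((ax * bx + ay * by)[ok] / (na * nb)[ok], -1), 1)
    out[ok] <- acos(cosv) * 180 / pi
    out
  }
  vx <- function(i, j) fx[, fp(j)] - fx[, fp(i)]
  vy <- function(i, j) fy[, fp(j)] - fy[, fp(i)]
  ang <- (angle_rows(vx(48, 49), vy(48, 49), vx(48, 59), vy(48, 59)) +
          angle_rows(vx(54, 53), vy(54, 53), vx(54, 55), vy(54, 55))) / 2

  feat <- data.frame(
    brow_tilt_r = tilt_rows(17:21),
    brow_tilt_l = tilt_rows(22:26),
    brow_eye_dist_r = bed(list(c(18, 36), c(19, 37), c(20, 38), c(21, 39))),
    brow_eye_dist_l = bed(list(c(22, 42), c(23, 43), c(24, 44), c(25, 45))),
    inter_brow_area = poly_rows(c(21, 22, 42, 39)) / L^2,
    eye_area_r = poly_rows(36:41) / L^2,
    eye_area_l = poly_rows(42:47) / L^2,
    ear_r = ratio(edist_rows(eye_idx$right$top, eye_idx$right$bottom),
                  edist_rows(eye_idx$right$outer, eye_idx$right$inner)),
    ear_l = ratio(edist_rows(eye_idx$left$top, eye_idx$left$bottom),
                  edist_rows(eye_idx$left$inner, eye_idx$left$outer)),
    iris_offset_h_r = ir$h, iris_offset_v_r = ir$v,
    iris_offset_h_l = il$h, iris_offset_v_l = il$v,
    mouth_area_in = poly_rows(60:67) / L^2,
    mouth_area_out = poly_rows(48:59) / L^2,
    mouth_aspect_in = ratio(dist_rows(fx, fy, 62, 66),
                            dist_rows(fx, fy, 60, 64)),
    mouth_aspect_out = ratio(dist_rows(fx, fy, 51, 57),
                             dist_rows(fx, fy, 48, 54)),
    mouth_corner_raise = ifelse(y_v != 0, (y_h - y_v) / y_v, NA_real_),
    mouth_angle = ang,
    gaze_h = frames$gaze[, 1], gaze_v = frames$gaze[, 2],
    head_pitch = frames$pose[, 1], head_yaw = frames$pose[, 2],
    head_roll = frames$pose[, 3],
    pulse = as.numeric(pulse_per_frame)
  )
  bad <- !frames$success | !is.finite(L) | L <= 0
  if (any(bad)) feat[bad, ] <- NA_real_
  feat[static_feature_names()]
}

#' Extract the static feature vector of a single frame
#'
#' Computes every per-frame geometric feature (brow tilt and distance,
#' inter-brow and eye areas, eye aspect ratios, iris offsets, mouth areas,
#' aspects, corner raise and angle), passes gaze, head rotation and pulse
#' through unchanged, and normalizes lengths by L and areas by L^2.
#'
#' @param frame a single-frame `landmark_frames` object (subset with `[`).
#' @param pulse_bpm the frame's pulse value (bpm, NA allowed).
#' @param eye_idx semantic eye-model indices.
#' @param L_convention nasal-bridge convention, see
#'   [nasal_bridge_length()].
#' @return named numeric vector (one value per feature; NA marks missing).
#' @export
extract_frame_features <- function(frame, pulse_bpm,
                                   eye_idx = openface_dialect()$eye_idx,
                                   L_convention = "midpoint") {
  df <- extract_static_features(frame, pulse_bpm, eye_idx, L_convention)
  unlist(df[1, ])
}
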