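test_that("polygon_area handles canonical shapes and rejects degenerate input", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(square), 1.0)

  ang <- 2 * pi * (0:5) / 6
  hexagon <- cbind(cos(ang), sin(ang))
  expect_equal(polygon_area(hexagon), 3 * sqrt(3) / 2, tolerance = 1e-12)

  collinear <- cbind(1:4, 2 * (1:4))
  expect_equal(polygon_area(collinear), 0)

  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))),
               class = "deceptrf_argument_error")
})

test_that("polygon_area agrees with a fan-triangulation oracle on random hexagons", {
  set.seed(101)
  for (i in 1:200) {
    pts <- random_convex_polygon(6)
    expect_equal(polygon_area(pts), fan_area(pts), tolerance = 1e-9)
  }
})

test_that("nasal bridge length follows both conventions", {
  face <- face_template()$face
  face[22, ] <- c(-1, 0)  # P21
  face[23, ] <- c(1, 0)   # P22
  face[40, ] <- c(-1, 3)  # P39
  face[43, ] <- c(1, 3)   # P42
  expect_equal(nasal_bridge_length(face), 3)
  expect_equal(nasal_bridge_length(face, "pairmean"), 3)

  face[c(22, 23, 40, 43), 1] <- 0
  face[c(22, 23, 40, 43), 2] <- 0
  expect_error(nasal_bridge_length(face), class = "deceptrf_degenerate_face")
})

test_that("eyebrow tilt is the least-squares slope", {
  flat <- cbind(1:5, rep(2, 5))
  expect_equal(eyebrow_tilt(flat), 0)
  steep <- cbind(1:5, 2 * (1:5) + 1)
  expect_equal(eyebrow_tilt(steep), 2)
  vertical <- cbind(rep(3, 5), 1:5)
  expect_true(is.na(eyebrow_tilt(vertical)))

  # closed-form oracle on noisy points
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(5)
    oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_equal(eyebrow_tilt(cbind(x, y)), oracle, tolerance = 1e-9)
  }
})

test_that("brow-eye distance averages the four pair distances over L", {
  pairs <- lapply(c(1, 2, 3, 4), function(d) rbind(c(0, 0), c(0, d)))
  expect_equal(brow_eye_distance(pairs, L = 1), 2.5)
  pairs2 <- lapply(1:4, function(i) rbind(c(i, 0), c(i, 2)))
  expect_equal(brow_eye_distance(pairs2, L = 2), 1.0)
})

test_that("inter-brow area uses convex traversal and normalizes by L^2", {
  face <- face_template()$face
  L <- 2
  face[22, ] <- c(0, 0); face[23, ] <- c(L, 0)
  face[43, ] <- c(L, L); face[40, ] <- c(0, L)
  expect_equal(inter_brow_area(face, L), 1.0)

  face[c(22, 23, 43, 40), 2] <- 0  # collinear
  expect_equal(inter_brow_area(face, L), 0)
})

test_that("eye area is zero for a closed eye and matches the oracle otherwise", {
  face <- face_template()$face
  expect_gt(eye_area(face, "right", L = 30), 0)
  expect_equal(eye_area(face, "right", L = 30),
               fan_area(face[37:42, ]) / 900, tolerance = 1e-12)
  face[37:42, 2] <- 330  # collapse to a line
  expect_equal(eye_area(face, "right", L = 30), 0)
})

test_that("aspect ratios follow l_v / l_h with missing on zero width", {
  expect_equal(aspect_ratio(2, 2), 1)
  expect_equal(aspect_ratio(0, 5), 0)
  expect_equal(aspect_ratio(3, 6), 0.5)
  expect_true(is.na(aspect_ratio(1, 0)))
})

test_that("iris offsets measure distance from corner and top to the iris center", {
  eye <- face_template()$eye
  idx <- openface_dialect()$eye_idx
  # corner at origin, iris points at (2,0) and (4,0): center (3,0), offset 3
  eye[idx$right$inner + 1, ] <- c(0, 0)
  eye[idx$right$iris[1] + 1, ] <- c(2, 0)
  eye[idx$right$iris[2] + 1, ] <- c(4, 0)
  eye[idx$right$top + 1, ] <- c(3, 0)  # iris center on the top point
  off <- iris_offsets(eye, "right", L = 1)
  expect_equal(unname(off["horizontal"]), 3)
  expect_equal(unname(off["vertical"]), 0)

  # random layouts against direct Euclidean recomputation
  set.seed(11)
  for (i in 1:10) {
    eye[] <- rnorm(112, 500, 40)
    ctr <- (eye[idx$left$iris[1] + 1, ] + eye[idx$left$iris[2] + 1, ]) / 2
    oracle_h <- sqrt(sum((ctr - eye[idx$left$inner + 1, ])^2)) / 30
    oracle_v <- sqrt(sum((ctr - eye[idx$left$top + 1, ])^2)) / 30
    off <- iris_offsets(eye, "left", L = 30)
    expect_equal(unname(off), c(oracle_h, oracle_v), tolerance = 1e-9)
  }
})

test_that("mouth corner raise follows the printed arithmetic", {
  face <- face_template()$face
  face[52, 2] <- 10   # P51 top
  face[58, 2] <- 30   # P57 bottom
  face[49, 2] <- 20   # P48
  face[55, 2] <- 20   # P54
  expect_equal(mouth_corner_raise(face), 0)

  face[49, 2] <- 15; face[55, 2] <- 15
  expect_equal(mouth_corner_raise(face), -0.25)
})

test_that("mouth angle averages the two corner angles in degrees", {
  face <- face_template()$face
  # perpendicular segments at both corners
  face[49, ] <- c(0, 0); face[50, ] <- c(1, 0); face[60, ] <- c(0, 1)
  face[55, ] <- c(10, 0); face[54, ] <- c(11, 0); face[56, ] <- c(10, 1)
  expect_equal(mouth_angle(face), 90)

  # collinear opposite rays
  face[50, ] <- c(1, 0); face[60, ] <- c(-1, 0)
  face[54, ] <- c(11, 0); face[56, ] <- c(9, 0)
  expect_equal(mouth_angle(face), 180)
})

test_that("frame features are symmetric on the template and finite", {
  frames <- template_frames(1)
  feat <- extract_frame_features(frames[1], pulse_bpm = 70)
  expect_true(all(is.finite(feat)))
  expect_equal(feat[["eye_area_r"]], feat[["eye_area_l"]], tolerance = 1e-12)
  expect_equal(feat[["ear_r"]], feat[["ear_l"]], tolerance = 1e-12)
  expect_identical(unname(feat["pulse"]), 70)
})

test_that("normalized features are invariant to translation and uniform scaling", {
  # a perturbed, asymmetric face so the invariances are non-trivial
  set.seed(3)
  wobble <- matrix(rnorm(68 * 2, 0, 2), 68, 2)
  ewobble <- matrix(rnorm(56 * 2, 0, 0.5), 56, 2)
  make <- function(s, dx, dy) {
    template_frames(1, transform = function(m) {
      w <- if (nrow(m) == 68) wobble else ewobble
      cbind((m[, 1] + w[, 1]) * s + dx, (m[, 2] + w[, 2]) * s + dy)
    })[1]
  }
  base <- extract_frame_features(make(1, 0, 0), 70)
  # mouth_corner_raise is normalized by an absolute y-sum (the published
  # formula), so it is scale-invariant but NOT translation-invariant;
  # it is excluded from the translation check below
  trans_cols <- setdiff(names(base), "mouth_corner_raise")

  scaled <- extract_frame_features(make(2, 0, 0), 70)
  expect_equal(scaled, base, tolerance = 1e-9)

  shifted <- extract_frame_features(make(1, 100, 100), 70)
  expect_equal(shifted[trans_cols], base[trans_cols], tolerance = 1e-9)

  for (i in 1:10) {
    s <- runif(1, 0.2, 5); dx <- runif(2, -400, 400)
    moved <- extract_frame_features(make(s, dx[1], dx[2]), 70)
    expect_equal(moved[trans_cols], base[trans_cols], tolerance = 1e-9)
    expect_equal(extract_frame_features(make(s, 0, 0), 70)[["mouth_corner_raise"]],
                 base[["mouth_corner_raise"]], tolerance = 1e-9)
  }
})

test_that("tracking failures and degenerate faces mark the frame missing", {
  frames <- template_frames(2)
  frames$success[2] <- FALSE
  df <- deceptrf:::extract_static_features(frames, c(70, 70))
  expect_false(anyNA(df[1, ]))
  expect_true(all(is.na(df[2, ])))
})
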