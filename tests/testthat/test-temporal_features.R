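test_that("rolling variance matches hand arithmetic and handles edges", {
  expect_equal(rolling_variance(rep(4.2, 50), 1, 10), rep(0, 50))

  s <- c(0, 0, 0, 6, 0, 0, 0)
  v <- rolling_variance(s, half_width_s = 1, fps = 1)
  expect_equal(v[4], 8.0)            # population var of (0, 6, 0)
  expect_equal(v[1], 0)              # truncated edge window (0, 0)
  expect_equal(v[3], var(c(0, 0, 6)) * 2 / 3)

  expect_error(rolling_variance(numeric(0), 1, 30),
               class = "deceptrf_argument_error")
})

test_that("rolling variance equals direct per-window recomputation", {
  set.seed(21)
  s <- rnorm(400, 10, 3)
  s[sample(400, 25)] <- NA
  fps <- 10; hw <- 0.7
  got <- rolling_variance(s, hw, fps)
  h <- round(hw * fps)
  for (i in seq_along(s)) {
    w <- s[max(1, i - h):min(length(s), i + h)]
    w <- w[!is.na(w)]
    oracle <- if (length(w) >= 2) mean((w - mean(w))^2) else NA_real_
    expect_equal(got[i], oracle, tolerance = 1e-9)
  }
})

test_that("rolling variance is non-negative and shift-invariant", {
  set.seed(8)
  for (i in 1:10) {
    s <- rnorm(300, 0, runif(1, 0.1, 50))
    v <- rolling_variance(s, 0.5, 30)
    expect_true(all(v >= 0, na.rm = TRUE))
    expect_equal(rolling_variance(s + 123.456, 0.5, 30), v, tolerance = 1e-9)
  }
})

test_that("closure threshold is the linear-convention first quartile", {
  expect_equal(closure_threshold(1:8), 2.75)
  expect_equal(closure_threshold(rep(7, 10)), 7)
  expect_equal(closure_threshold(c(0, 0, 0, 100)), 0)
  expect_error(closure_threshold(c(1, 2, NA, NA)),
               class = "deceptrf_argument_error")
})

test_that("episode counts match construction and the run-length oracle", {
  fps <- 30
  s <- rep(1, 300)
  expect_equal(count_closure_episodes(s, 0.5, 3, fps), rep(0L, 300))

  # two separated 5-frame dips fully inside the trailing window
  s[100:104] <- 0; s[150:154] <- 0
  cnt <- count_closure_episodes(s, 0.5, 3, fps)
  expect_identical(cnt[160], 2L)
  expect_identical(cnt[99], 0L)
  expect_identical(cnt[105], 1L)
  # an episode straddling the window edge counts once, then drops out
  expect_identical(cnt[103 + 90], 2L)  # window (103, 193] still touches 104
  expect_identical(cnt[104 + 90], 1L)  # window (104, 194] no longer does

  # run-length-encoding oracle on random binary dip patterns
  set.seed(31)
  for (rep in 1:20) {
    s <- as.numeric(runif(200) > 0.3)
    w <- sample(5:50, 1)
    got <- count_closure_episodes(s, 0.5, w / fps, fps)
    r <- rle(s < 0.5)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    starts <- starts[r$values]; ends <- ends[r$values]
    for (t in sample(200, 25)) {
      oracle <- sum(starts <= t & ends > t - w)
      expect_identical(got[t], as.integer(oracle))
    }
  }
})

test_that("episode counts are monotone in the window length", {
  set.seed(32)
  s <- rnorm(500)
  thr <- closure_threshold(s)
  prev <- rep(0L, 500)
  for (w_s in c(0.5, 1, 2, 4)) {
    cnt <- count_closure_episodes(s, thr, w_s, 30)
    expect_true(all(cnt >= prev))
    prev <- cnt
  }
})

test_that("the feature table has one row per frame and deterministic columns", {
  sim <- simulate_session(synth_config(duration_s = 60, n_utterances = 3,
                                       seed = 2))
  ft <- build_feature_table(sim$session)
  expect_identical(nrow(ft), 1800L)
  expect_identical(names(ft)[1:25], static_feature_names())
  expect_identical(names(ft)[26], "var_brow_tilt_r")
  expect_true(all(c("var_pulse", count_feature_names()) %in% names(ft)))
  # variance columns non-negative
  for (cn in grep("^var_", names(ft), value = TRUE)) {
    expect_true(all(ft[[cn]] >= 0, na.rm = TRUE), label = cn)
  }
  # missing pulse propagates into var_pulse windows, never imputed
  expect_identical(anyNA(ft$pulse), anyNA(sim$session$pulse_per_frame))
})

test_that("scripted blinks are recovered exactly on clean data", {
  cfg <- synth_config(duration_s = 60, n_utterances = 3,
                      landmark_jitter_sd = 0, lid_drift_sd = 0,
                      mouth_open_scale = 1, seed = 9)
  sim <- simulate_session(cfg)
  k <- length(sim$truth$blink_starts)
  expect_gt(k, 0)
  ft <- build_feature_table(sim$session)
  thr <- closure_threshold(ft$eye_area_r)
  cnt <- count_closure_episodes(ft$eye_area_r, thr,
                                window_s = 60, fps = 30)
  expect_identical(cnt[length(cnt)], as.integer(k))

  # blink-count columns are all zero when no blinks are scripted
  cfg0 <- synth_config(duration_s = 60, n_utterances = 3,
                       blink_rate_base = 0, landmark_jitter_sd = 0,
                       lid_drift_sd = 0, mouth_open_scale = 1, seed = 9)
  ft0 <- build_feature_table(simulate_session(cfg0)$session)
  expect_true(all(ft0$blink_count_r == 0))
  expect_true(all(ft0$blink_count == 0))
})

test_that("the conventions sidecar is written alongside the table", {
  sim <- simulate_session(synth_config(duration_s = 40, n_utterances = 1,
                                       utterance_length_s = c(3, 6), seed = 3))
  ft <- build_feature_table(sim$session)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  expect_identical(meta$variance, "population")
  expect_equal(meta$fps, 30)
  back <- data.table::fread(path)
  expect_identical(nrow(back), nrow(ft))
})
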