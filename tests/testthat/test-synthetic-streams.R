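test_that("session_config validates its invariants", {
  expect_error(session_config(trial_duration = 0), "positive")
  expect_error(session_config(eeg_rate = -1), "positive")
  expect_error(
    session_config(attention_schedule = data.frame(onset = 59, duration = 5, level = 1)),
    "within"
  )
  expect_error(
    session_config(attention_schedule = data.frame(onset = 1, duration = 2, level = 1.5)),
    "level"
  )
})

test_that("same seed gives bit-identical streams, different seeds differ", {
  cfg <- session_config(seed = 7, trial_duration = 20, n_trials = 1)
  a <- gen_eeg(cfg)
  b <- gen_eeg(cfg)
  expect_identical(a$stream$uv, b$stream$uv)
  expect_identical(a$truth$artifacts, b$truth$artifacts)
  g1 <- gen_gaze(cfg)
  g2 <- gen_gaze(cfg)
  expect_identical(g1$stream$x_deg, g2$stream$x_deg)
  expect_identical(g1$truth$fixations, g2$truth$fixations)
  other <- gen_eeg(session_config(seed = 8, trial_duration = 20, n_trials = 1))
  expect_false(identical(a$stream$uv, other$stream$uv))
})

test_that("empty schedule and zero artifact rates give a stationary clean stream", {
  cfg <- clean_config(1, duration = 20, attention_schedule = no_episodes())
  e <- gen_eeg(cfg)
  expect_equal(nrow(e$truth$episodes), 0)
  expect_equal(nrow(e$truth$artifacts), 0)
  # stationary band powers: beta/(alpha+theta) of first vs second half agree
  fs <- 512
  r_half <- vapply(list(1:(10 * fs), (10 * fs + 1):(20 * fs)), function(idx) {
    bp <- band_powers(welch_psd(e$stream$uv[idx], fs))
    bp$beta / (bp$alpha + bp$theta)
  }, numeric(1))
  expect_lt(abs(diff(r_half)) / mean(r_half), 0.25)
})

test_that("artifact injection honesty: every interval exceeds its threshold", {
  cfg <- session_config(seed = 3, trial_duration = 120, n_trials = 1,
                        attention_schedule = no_episodes(),
                        artifact_rates = c(blinks = 10, muscle = 5))
  e <- gen_eeg(cfg)
  arts <- e$truth$artifacts
  expect_gt(nrow(arts), 0)
  fs <- 512
  for (i in seq_len(nrow(arts))) {
    idx <- round(arts$onset[i] * fs):round((arts$onset[i] + arts$duration[i]) * fs)
    w <- e$stream$uv[idx]
    if (arts$kind[i] == "blink") expect_gt(max(abs(w)), 100)
    if (arts$kind[i] == "muscle") expect_gt(max(abs(diff(w))), 50)
  }
})

test_that("attention level maps monotonically onto the band-power ratio", {
  # one level per stream, ratio from an independent periodogram
  levels <- seq(0.05, 0.95, length.out = 10)
  ratios <- vapply(levels, function(lv) {
    cfg <- clean_config(
      11, duration = 20,
      attention_schedule = data.frame(onset = 0, duration = 20, level = lv)
    )
    x <- gen_eeg(cfg)$stream$uv
    sp <- oracle_welch(x, 512)
    df <- sp$freq[2] - sp$freq[1]
    bp <- function(lo, hi) sum(sp$psd[sp$freq >= lo & sp$freq < hi]) * df
    bp(12, 30) / (bp(8, 12) + bp(4, 8))
  }, numeric(1))
  expect_gt(cor(levels, ratios, method = "spearman"), 0.9)
})

test_that("gaze generator matches its stated observation model", {
  cfg <- session_config(seed = 2, trial_duration = 90, n_trials = 1)
  g <- gen_gaze(cfg)
  resid <- g$stream$x_deg - g$truth$true_gaze$x_deg
  expect_gt(length(resid), 1e4)
  expect_gt(sd(resid), 0.45)
  expect_lt(sd(resid), 0.55)
  # zero-noise override on a single target: constant trace at its direction
  one <- session_config(seed = 2, trial_duration = 5, n_trials = 1,
                        gaze_noise_sd = 0, gaze_dropout_rate = 0,
                        scene_spec = data.frame(id = 1, x = 0.1, y = 0, z = 0.6))
  gz <- gen_gaze(one)
  dir <- atan2(0.1, 0.6) * 180 / pi
  expect_equal(unique(round(gz$stream$x_deg, 9)), round(dir, 9))
  expect_true(all(gz$stream$valid))
})

test_that("controller reaches follow the minimum-jerk closed form", {
  # peak speed of a 1-s reach of 0.4 m is 1.875 * 0.4 / 1 = 0.75 m/s
  cfg <- session_config(seed = 1, trial_duration = 10, n_trials = 1)
  # reach starts at the left hand's home pose to avoid a teleport
  reach <- data.frame(hand = "left", onset = 2, duration = 1,
                      x0 = -0.25, y0 = -0.30, z0 = 0.40,
                      x1 = 0.15, y1 = -0.30, z1 = 0.40)
  p <- gen_controllers(cfg, reaches = reach)
  v <- sqrt(diff(p$stream$lx)^2 + diff(p$stream$ly)^2 + diff(p$stream$lz)^2) *
    cfg$pose_rate
  expect_equal(max(v), 1.875 * 0.4, tolerance = 1e-3)
  # straight reach: path length equals displacement
  seg <- p$stream$t >= 2 & p$stream$t <= 3
  path <- sum(abs(diff(p$stream$lx[seg])))
  expect_equal(path, 0.4, tolerance = 1e-3)
  # stationary outside reaches
  before <- p$stream$t < 2
  expect_equal(var(p$stream$lx[before]), 0)
})

test_that("session write/read round-trips and enforces its error contracts", {
  cfg <- session_config(seed = 4, trial_duration = 5, n_trials = 1)
  td <- simulate_trial(cfg)
  d <- withr::local_tempdir()
  write_session(td, d)
  back <- read_session(d)
  expect_equal(back$eeg$uv, td$eeg$uv, tolerance = 1e-12)
  expect_equal(back$gaze$x_deg, td$gaze$x_deg, tolerance = 1e-12)
  expect_equal(back$pose$rx, td$pose$rx, tolerance = 1e-12)
  expect_equal(attr(back$eeg, "rate"), 512)
  n_truth <- nrow(td$truth$episodes) + nrow(td$truth$artifacts) +
    nrow(td$truth$fixations) + nrow(td$truth$reaches)
  expect_equal(nrow(back$events), n_truth)
  # refusal to clobber
  expect_error(write_session(td, d), "refusing")
  expect_silent(write_session(td, d, overwrite = TRUE))
  # missing sidecar is a named format error
  file.remove(file.path(d, "sub-01", "sub-01_task-trimanual_run-01_gaze.json"))
  expect_error(read_session(d), "sidecar")
})
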