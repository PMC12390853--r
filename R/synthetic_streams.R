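# Seeded synthetic multimodal session streams. The signal model is stated
# once and kept fixed: a 1/f (pink) noise floor plus three narrow-band
# oscillators with slow random phase jitter; attention episodes boost the
# beta oscillator and suppress alpha proportionally to episode level; blink
# and muscle artifacts are injected from templates that exceed the detection
# thresholds with margin.

pink_noise <- function(n, sd) {
  if (sd <= 0 || n == 0) return(numeric(n))
  w <- rnorm(n)
  spec <- fft(w)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f) # two-sided frequency index
  amp <- c(0, 1 / sqrt(f[-1])) # 1/f power
  x <- Re(fft(spec * amp, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

band_oscillator <- function(t, centre, amplitude, jitter_sd = 0.05) {
  n <- length(t)
  phase <- 2 * pi * centre * t + cumsum(rnorm(n, 0, jitter_sd))
  amplitude * sin(phase)
}

schedule_level <- function(t, schedule) {
  lev <- numeric(length(t))
  if (nrow(schedule) == 0) return(lev)
  for (i in seq_len(nrow(schedule))) {
    idx <- t >= schedule$onset[i] & t < schedule$onset[i] + schedule$duration[i]
    lev[idx] <- pmax(lev[idx], schedule$level[i])
  }
  lev
}

#' Generate a synthetic single-channel EEG trial
#'
#' EEG (microvolts) = pink-noise floor + theta/alpha/beta oscillators. During
#' attention episodes of level L the beta amplitude is scaled by
#' `(1 + 2 L)` (a level-1.0 episode triples it) and alpha by `(1 - 0.5 L)`,
#' so the beta/(alpha+theta) power ratio rises monotonically with L. Blink artifacts are 300 ms raised-cosine
#' deflections peaking at 150 uV; muscle bursts are 150 ms white-noise bursts
#' (SD 40 uV) rescaled if necessary so at least one sample-to-sample gradient
#' exceeds 55 uV/sample. All injected events are recorded in the returned
#' ground truth.
#'
#' @param config a [session_config()].
#' @param trial trial index (>= 1); each trial draws an independent derived
#'   seed so the whole session is reproducible from `config$seed`.
#' @return list with elements `stream` (a [sample_stream()] with columns
#'   `t`, `uv`) and `truth` (episodes + artifact intervals).
#' @export
gen_eeg <- function(config, trial = 1) {
  stopifnot(inherits(config, "session_config"))
  withr::with_seed(sub_seed(config$seed, 100 + trial), {
    fs <- config$eeg_rate
    dur <- config$trial_duration
    n <- round(fs * dur)
    t <- (seq_len(n) - 1) / fs
    lev <- schedule_level(t, config$attention_schedule)
    x <- pink_noise(n, config$noise_sd)
    bp <- config$band_params
    for (i in seq_len(nrow(bp))) {
      amp <- rep(bp$amplitude[i], n)
      if (bp$band[i] == "beta") amp <- amp * (1 + 2 * lev)
      if (bp$band[i] == "alpha") amp <- amp * (1 - 0.5 * lev)
      x <- x + band_oscillator(t, bp$centre[i], 1, jitter_sd = 0.05) * amp
    }
    arts <- inject_artifacts(x, fs, dur, config$artifact_rates)
    x <- arts$x
    stream <- sample_stream(data.frame(t = t, uv = x), "eeg", fs, "uV")
    truth <- ground_truth(
      episodes = config$attention_schedule,
      artifacts = arts$intervals
    )
    list(stream = stream, truth = truth)
  })
}

inject_artifacts <- function(x, fs, dur, rates) {
  n <- length(x)
  intervals <- data.frame(kind = character(0), onset = numeric(0), duration = numeric(0))
  place_events <- function(k, width) {
    # uniform onsets, kept clear of the ends and of each other
    if (k <= 0) return(numeric(0))
    onsets <- sort(runif(k, 0.5, dur - width - 0.5))
    keep <- c(TRUE, diff(onsets) > width + 0.6)
    onsets[keep]
  }
  blink_w <- 0.3
  n_blink <- rpois(1, rates[["blinks"]] * dur / 60)
  for (on in place_events(n_blink, blink_w)) {
    idx <- round(on * fs) + seq_len(round(blink_w * fs))
    idx <- idx[idx <= n]
    tpl <- 150 * 0.5 * (1 - cos(2 * pi * seq_along(idx) / length(idx)))
    x[idx] <- x[idx] + tpl
    # guarantee the amplitude threshold is exceeded after superposition
    if (max(abs(x[idx])) <= 100) x[idx] <- x[idx] + (101 - max(abs(x[idx])))
    intervals <- rbind(intervals, data.frame(kind = "blink", onset = on, duration = blink_w))
  }
  muscle_w <- 0.15
  n_mus <- rpois(1, rates[["muscle"]] * dur / 60)
  for (on in place_events(n_mus, muscle_w)) {
    idx <- round(on * fs) + seq_len(round(muscle_w * fs))
    idx <- idx[idx <= n]
    burst <- rnorm(length(idx), 0, 40)
    g <- max(abs(diff(burst)))
    if (g < 55) burst <- burst * 55 / g
    x[idx] <- x[idx] + burst
    intervals <- rbind(intervals, data.frame(kind = "muscle", onset = on, duration = muscle_w))
  }
  list(x = x, intervals = intervals[order(intervals$onset), , drop = FALSE])
}

# scene sphere positions expressed as viewing directions (deg) from the
# cyclopean origin
target_directions <- function(scene_spec) {
  az <- atan2(scene_spec$x, scene_spec$z) * 180 / pi
  el <- atan2(scene_spec$y, sqrt(scene_spec$x^2 + scene_spec$z^2)) * 180 / pi
  data.frame(id = scene_spec$id, az = az, el = el)
}

#' Generate a synthetic gaze trial
#'
#' A fixation-saccade process over the scene targets: fixation durations are
#' gamma-distributed (mean ~0.35 s), saccades are 40 ms linear transitions.
#' The observed gaze equals the true gaze plus independent per-axis Gaussian
#' noise (SD `config$gaze_noise_sd` degrees); short dropout runs are flagged
#' invalid.
#'
#' @inheritParams gen_eeg
#' @return list with `stream` (columns `t`, `x_deg`, `y_deg`, `valid`) and
#'   `truth` (fixation intervals with true target ids and directions).
#' @export
gen_gaze <- function(config, trial = 1) {
  stopifnot(inherits(config, "session_config"))
  if (nrow(config$scene_spec) == 0) stop("scene_spec must be non-empty")
  withr::with_seed(sub_seed(config$seed, 200 + trial), {
    fs <- config$gaze_rate
    dur <- config$trial_duration
    n <- round(fs * dur)
    t <- (seq_len(n) - 1) / fs
    dirs <- target_directions(config$scene_spec)
    k <- nrow(dirs)
    # build fixation sequence
    fix <- data.frame(onset = numeric(0), duration = numeric(0), target = integer(0))
    now <- 0
    cur <- sample.int(k, 1)
    sacc <- 0.04
    while (now < dur) {
      d <- min(max(rgamma(1, shape = 4, scale = 0.0875), 0.1), 1.5)
      fix <- rbind(fix, data.frame(onset = now, duration = min(d, dur - now), target = cur))
      now <- now + d + sacc
      cur <- if (k > 1) sample(setdiff(seq_len(k), cur), 1) else cur
    }
    # piecewise true trajectory
    key_t <- c(rbind(fix$onset, fix$onset + fix$duration))
    key_x <- c(rbind(dirs$az[fix$target], dirs$az[fix$target]))
    key_y <- c(rbind(dirs$el[fix$target], dirs$el[fix$target]))
    tx <- approx(key_t, key_x, xout = t, rule = 2)$y
    ty <- approx(key_t, key_y, xout = t, rule = 2)$y
    ox <- tx + rnorm(n, 0, config$gaze_noise_sd)
    oy <- ty + rnorm(n, 0, config$gaze_noise_sd)
    valid <- rep(TRUE, n)
    n_drop <- round(config$gaze_dropout_rate * n / 12) # runs of ~12 samples (100 ms)
    if (n_drop > 0) {
      starts <- sample.int(n - 12, n_drop)
      for (s in starts) valid[s:(s + 11)] <- FALSE
    }
    stream <- sample_stream(
      data.frame(t = t, x_deg = ox, y_deg = oy, valid = valid),
      "gaze", fs, "deg"
    )
    truth <- ground_truth(fixations = cbind(fix,
      az = dirs$az[fix$target], el = dirs$el[fix$target]
    ))
    truth$true_gaze <- data.frame(t = t, x_deg = tx, y_deg = ty)
    list(stream = stream, truth = truth)
  })
}

#' Minimum-jerk position profile
#'
#' Normalised minimum-jerk displacement `s(tau) = 10 tau^3 - 15 tau^4 +
#' 6 tau^5`; the peak speed of a reach of length `d` over duration `T` is
#' `1.875 d / T`.
#'
#' @param tau normalised time in \[0, 1\].
#' @export
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Generate synthetic controller pose streams
#'
#' Two hand channels ("left", "right") in workspace metres. Hands rest at
#' fixed home positions and perform minimum-jerk reaches: by default each
#' hand reaches to its sphere and then carries it toward a shifted position.
#'
#' @inheritParams gen_eeg
#' @param reaches optional data.frame (hand, onset, duration, x0, y0, z0,
#'   x1, y1, z1) overriding the default reach schedule.
#' @return list with `stream` (wide format: `t`, `lx..lz`, `rx..rz`) and
#'   `truth` (reach segments).
#' @export
gen_controllers <- function(config, trial = 1, reaches = NULL) {
  stopifnot(inherits(config, "session_config"))
  fs <- config$pose_rate
  dur <- config$trial_duration
  n <- round(fs * dur)
  t <- (seq_len(n) - 1) / fs
  home <- list(
    left = c(-0.25, -0.30, 0.40),
    right = c(0.25, -0.30, 0.40)
  )
  if (is.null(reaches)) {
    sp <- config$scene_spec
    mk <- function(hand, tid, on1, on2) {
      p0 <- home[[hand]]
      p1 <- as.numeric(sp[sp$id == tid, c("x", "y", "z")])
      p2 <- p1 + c(0.10, 0.05, 0)
      rbind(
        data.frame(hand = hand, onset = on1, duration = 1.0,
                   x0 = p0[1], y0 = p0[2], z0 = p0[3], x1 = p1[1], y1 = p1[2], z1 = p1[3]),
        data.frame(hand = hand, onset = on2, duration = 1.5,
                   x0 = p1[1], y0 = p1[2], z0 = p1[3], x1 = p2[1], y1 = p2[2], z1 = p2[3])
      )
    }
    reaches <- rbind(
      mk("left", config$scene_spec$id[1], 2, 6),
      mk("right", config$scene_spec$id[2], 2.5, 6.5)
    )
    reaches <- reaches[reaches$onset + reaches$duration <= dur, , drop = FALSE]
  }
  pos <- list(
    left = matrix(home$left, n, 3, byrow = TRUE),
    right = matrix(home$right, n, 3, byrow = TRUE)
  )
  for (hand in names(pos)) {
    hr <- reaches[reaches$hand == hand, , drop = FALSE]
    hr <- hr[order(hr$onset), , drop = FALSE]
    for (i in seq_len(nrow(hr))) {
      p0 <- as.numeric(hr[i, c("x0", "y0", "z0")])
      p1 <- as.numeric(hr[i, c("x1", "y1", "z1")])
      tau <- (t - hr$onset[i]) / hr$duration[i]
      s <- min_jerk(tau)
      seg <- tau >= 0
      pos[[hand]][seg, ] <- rep(p0, each = sum(seg)) +
        outer(s[seg], p1 - p0)
    }
  }
  stream <- sample_stream(
    data.frame(
      t = t,
      lx = pos$left[, 1], ly = pos$left[, 2], lz = pos$left[, 3],
      rx = pos$right[, 1], ry = pos$right[, 2], rz = pos$right[, 3]
    ),
    "pose", fs, "m"
  )
  list(stream = stream, truth = ground_truth(reaches = reaches[c("hand", "onset", "duration")]))
}

#' Simulate a full synthetic trial (all three modalities)
#'
#' @inheritParams gen_eeg
#' @return list with `eeg`, `gaze`, `pose` stream objects, merged `truth`
#'   and the `config`.
#' @export
simulate_trial <- function(config, trial = 1) {
  e <- gen_eeg(config, trial)
  g <- gen_gaze(config, trial)
  p <- gen_controllers(config, trial)
  truth <- ground_truth(
    episodes = e$truth$episodes, artifacts = e$truth$artifacts,
    fixations = g$truth$fixations, reaches = p$truth$reaches
  )
  truth$true_gaze <- g$truth$true_gaze
  list(eeg = e$stream, gaze = g$stream, pose = p$stream, truth = truth, config = config)
}

fmt_num <- function(x) {
  if (is.numeric(x)) format(x, digits = 15, trim = TRUE, scientific = FALSE) else x
}

write_tsv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_num), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a trial to disk in a BIDS-inspired layout
#'
#' Produces `sub-XX/sub-XX_task-trimanual_run-YY_{eeg,gaze,pose}.tsv`, JSON
#' sidecars carrying rate/units/column metadata, and an events TSV with one
#' row per ground-truth interval. Round-trips losslessly (to numeric
#' precision) through [read_session()].
#'
#' @param trial_data result of [simulate_trial()].
#' @param out_dir output directory root.
#' @param sub,run subject and run indices used in file names.
#' @param overwrite if `FALSE` (default), refuse to write into an existing
#'   non-empty subject directory.
#' @export
write_session <- function(trial_data, out_dir, sub = 1, run = 1, overwrite = FALSE) {
  stub <- sprintf("sub-%02d", sub)
  dir <- file.path(out_dir, stub)
  base <- file.path(dir, sprintf("%s_task-trimanual_run-%02d", stub, run))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    existing <- list.files(dir, pattern = sprintf("run-%02d", run))
    if (length(existing) > 0) stop("refusing to overwrite existing session files in ", dir)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  streams <- list(eeg = trial_data$eeg, gaze = trial_data$gaze, pose = trial_data$pose)
  for (nm in names(streams)) {
    s <- streams[[nm]]
    df <- as.data.frame(s)
    if (nm == "pose") {
      # long format per the interface: t, hand, x, y, z
      df <- rbind(
        data.frame(t = df$t, hand = "left", x = df$lx, y = df$ly, z = df$lz),
        data.frame(t = df$t, hand = "right", x = df$rx, y = df$ry, z = df$rz)
      )
      df <- df[order(df$hand, df$t), ]
    }
    write_tsv(df, paste0(base, "_", nm, ".tsv"))
    sidecar <- list(
      SamplingFrequency = attr(s, "rate"), Units = attr(s, "units"),
      Channel = attr(s, "channel"), Columns = names(df), StartTime = s$t[1]
    )
    jsonlite::write_json(sidecar, paste0(base, "_", nm, ".json"), auto_unbox = TRUE, digits = NA)
  }
  ev <- truth_to_events(trial_data$truth)
  write_tsv(ev, paste0(base, "_events.tsv"))
  jsonlite::write_json(
    list(seed = trial_data$config$seed, trial_duration = trial_data$config$trial_duration,
         n_trials = trial_data$config$n_trials),
    paste0(base, "_session.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(base)
}

truth_to_events <- function(truth) {
  ev <- data.frame(onset = numeric(0), duration = numeric(0),
                   event_type = character(0), value = character(0))
  if (nrow(truth$episodes)) {
    ev <- rbind(ev, data.frame(onset = truth$episodes$onset, duration = truth$episodes$duration,
                               event_type = "attention", value = as.character(truth$episodes$level)))
  }
  if (nrow(truth$artifacts)) {
    ev <- rbind(ev, data.frame(onset = truth$artifacts$onset, duration = truth$artifacts$duration,
                               event_type = truth$artifacts$kind, value = ""))
  }
  if (nrow(truth$fixations)) {
    ev <- rbind(ev, data.frame(onset = truth$fixations$onset, duration = truth$fixations$duration,
                               event_type = "fixation", value = as.character(truth$fixations$target)))
  }
  if (nrow(truth$reaches)) {
    ev <- rbind(ev, data.frame(onset = truth$reaches$onset, duration = truth$reaches$duration,
                               event_type = "reach", value = truth$reaches$hand))
  }
  ev[order(ev$onset), , drop = FALSE]
}

#' Read a written session back from disk
#'
#' @param dir output root used by [write_session()].
#' @param sub,run subject and run indices.
#' @return list with `eeg`, `gaze`, `pose` streams and the `events` table.
#' @export
read_session <- function(dir, sub = 1, run = 1) {
  stub <- sprintf("sub-%02d", sub)
  base <- file.path(dir, stub, sprintf("%s_task-trimanual_run-%02d", stub, run))
  out <- list()
  for (nm in c("eeg", "gaze", "pose")) {
    tsv <- paste0(base, "_", nm, ".tsv")
    side <- paste0(base, "_", nm, ".json")
    if (!file.exists(tsv)) stop("missing stream file: ", tsv)
    if (!file.exists(side)) stop("missing JSON sidecar for '", nm, "' stream: ", side)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    df <- utils::read.table(tsv, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    if (nm == "pose") {
      left <- df[df$hand == "left", ]
      right <- df[df$hand == "right", ]
      df <- data.frame(t = left$t, lx = left$x, ly = left$y, lz = left$z,
                       rx = right$x, ry = right$y, rz = right$z)
    }
    out[[nm]] <- sample_stream(df, meta$Channel, meta$SamplingFrequency, meta$Units)
  }
  ev <- paste0(base, "_events.tsv")
  if (!file.exists(ev)) stop("missing events file: ", ev)
  out$events <- utils::read.table(ev, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  out
}
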