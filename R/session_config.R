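#' Session configuration for the synthetic multimodal generator
#'
#' Bundles every knob that determines a synthetic recording session. The seed
#' fully determines all generated streams: two configs that compare equal
#' produce byte-identical sessions.
#'
#' @param seed integer RNG seed; all per-stream seeds are derived from it.
#' @param trial_duration trial length in seconds. 60 s is the protocol
#'   default; a 30 s manipulation-period variant is supported by simply
#'   passing `trial_duration = 30`.
#' @param n_trials number of trials in the session.
#' @param eeg_rate,gaze_rate,pose_rate sampling rates in Hz (512 / 120 / 90).
#' @param attention_schedule data.frame with columns `onset` (s), `duration`
#'   (s) and `level` (0-1): episodes of elevated attentional engagement
#'   during which the beta oscillator is boosted and alpha suppressed.
#' @param artifact_rates named numeric, events per minute for `blinks` and
#'   `muscle` bursts. The defaults (4 blinks/min, 1 burst/min) reflect the
#'   suppressed blink rate typical of visually demanding VR tasks.
#' @param band_params data.frame (band, centre, amplitude): centre frequency
#'   (Hz) and baseline amplitude (uV) of the theta/alpha/beta oscillators.
#' @param noise_sd standard deviation (uV) of the 1/f background noise.
#' @param gaze_noise_sd per-axis gaze observation noise SD in degrees
#'   (0.5 deg, matching the assumed observation model).
#' @param gaze_dropout_rate fraction of gaze samples lost to tracking
#'   dropout (flagged invalid).
#' @param scene_spec data.frame (id, x, y, z, radius) of scene spheres in
#'   metres; defaults to the three-sphere equilateral layout.
#' @param n_distractors count of distractor objects in the scene.
#' @return object of class `session_config`.
#' @export
session_config <- function(seed = 1L,
                           trial_duration = 60,
                           n_trials = 20,
                           eeg_rate = 512,
                           gaze_rate = 120,
                           pose_rate = 90,
                           attention_schedule = default_attention_schedule(trial_duration),
                           artifact_rates = c(blinks = 4, muscle = 1),
                           band_params = default_band_params(),
                           noise_sd = 8,
                           gaze_noise_sd = 0.5,
                           gaze_dropout_rate = 0.02,
                           scene_spec = scene()$spheres,
                           n_distractors = 0) {
  if (trial_duration <= 0) stop("trial_duration must be positive")
  if (any(c(eeg_rate, gaze_rate, pose_rate) <= 0)) {
    stop("sampling rates must be positive")
  }
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (nrow(attention_schedule) > 0) {
    bad <- attention_schedule$onset < 0 |
      attention_schedule$onset + attention_schedule$duration > trial_duration |
      attention_schedule$level < 0 | attention_schedule$level > 1
    if (any(bad)) stop("attention episodes must lie within [0, trial_duration] with level in [0, 1]")
  }
  if (any(artifact_rates < 0)) stop("artifact rates must be non-negative")
  cfg <- list(
    seed = as.integer(seed), trial_duration = trial_duration,
    n_trials = as.integer(n_trials), eeg_rate = eeg_rate,
    gaze_rate = gaze_rate, pose_rate = pose_rate,
    attention_schedule = attention_schedule,
    artifact_rates = artifact_rates, band_params = band_params,
    noise_sd = noise_sd, gaze_noise_sd = gaze_noise_sd,
    gaze_dropout_rate = gaze_dropout_rate,
    scene_spec = scene_spec, n_distractors = n_distractors
  )
  class(cfg) <- "session_config"
  cfg
}

#' @export
print.session_config <- function(x, ...) {
  cat("session_config: seed", x$seed, "|", x$n_trials, "trials x",
      x$trial_duration, "s | rates", x$eeg_rate, "/", x$gaze_rate, "/",
      x$pose_rate, "Hz |", nrow(x$attention_schedule), "attention episodes\n")
  invisible(x)
}

#' Default attention episode schedule
#'
#' Episodes of 4 s at level 1.0, every 20 s starting at t = 6 s - three per
#' 60-s trial. This is the "stated world" the detection tests are run
#' against: strong, well-separated engagement periods occupying a minority
#' of the trial.
#'
#' @param trial_duration trial length (s).
#' @export
default_attention_schedule <- function(trial_duration = 60) {
  if (trial_duration < 12) {
    return(data.frame(onset = numeric(0), duration = numeric(0), level = numeric(0)))
  }
  onsets <- seq(6, trial_duration - 6, by = 20)
  data.frame(onset = onsets, duration = 4, level = 1)
}

#' @rdname session_config
#' @export
default_band_params <- function() {
  data.frame(
    band = c("theta", "alpha", "beta"),
    centre = c(6, 10, 20),
    amplitude = c(7, 9, 5)
  )
}

#' Timestamped uniformly sampled channel data
#'
#' Thin data.frame wrapper carrying rate/units metadata. The first column is
#' always `t` (seconds); remaining columns are channel values.
#'
#' @param data data.frame whose first column is `t`.
#' @param channel channel name ("eeg", "gaze", "pose", ...).
#' @param rate sampling rate in Hz.
#' @param units unit string ("uV", "deg", "m").
#' @export
sample_stream <- function(data, channel, rate, units) {
  stopifnot(is.data.frame(data), names(data)[1] == "t")
  if (nrow(data) > 1) {
    dt <- diff(data$t)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing")
    if (max(abs(dt - 1 / rate)) > 1e-6 / rate) {
      stop("timestamps must be uniform at the declared rate")
    }
  }
  structure(data,
    channel = channel, rate = rate, units = units,
    class = c("sample_stream", "data.frame")
  )
}

#' @export
print.sample_stream <- function(x, ...) {
  cat(sprintf(
    "<sample_stream '%s': %d samples @ %g Hz [%s], t = %.3f..%.3f s>\n",
    attr(x, "channel"), nrow(x), attr(x, "rate"), attr(x, "units"),
    x$t[1], x$t[nrow(x)]
  ))
  invisible(x)
}

stream_rate <- function(s) attr(s, "rate")
stream_duration <- function(s) nrow(s) / attr(s, "rate")

# ground truth container: the oracle for every detection test
ground_truth <- function(episodes = NULL, artifacts = NULL,
                         fixations = NULL, reaches = NULL) {
  gt <- list(
    episodes = episodes %||% data.frame(onset = numeric(0), duration = numeric(0), level = numeric(0)),
    artifacts = artifacts %||% data.frame(kind = character(0), onset = numeric(0), duration = numeric(0)),
    fixations = fixations %||% data.frame(onset = numeric(0), duration = numeric(0), target = integer(0)),
    reaches = reaches %||% data.frame(hand = character(0), onset = numeric(0), duration = numeric(0))
  )
  for (nm in names(gt)) {
    if (nrow(gt[[nm]]) && any(gt[[nm]]$duration < 0)) stop("negative interval in ground truth")
  }
  class(gt) <- "ground_truth"
  gt
}
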