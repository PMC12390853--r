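# Three-tier false-trigger mitigation: temporal persistence (300 ms above
# threshold, quality < 150 resets the timer), quality-scaled thresholds
# (x1.2 below quality 100, disabled below 50), contextual outlier rejection
# (2.5 sigma against a 60-s buffer), plus the artifact blanking gate and a
# refractory period after accepted events.

#' Gate configuration
#'
#' @param base_threshold activation threshold on the 0-100 attention scale.
#' @param hold_time required persistence above threshold (s).
#' @param quality_reset quality below which the persistence timer resets.
#' @param quality_degrade quality below which the threshold is scaled by
#'   `degrade_factor`.
#' @param quality_disable quality below which activation is disabled.
#' @param degrade_factor threshold multiplier in the degraded-quality band.
#' @param context_sigma rejection bound in buffer standard deviations.
#' @param context_window historical buffer span (s).
#' @param context_min_history minimum buffer span (s) before the context
#'   tier is enforced; shorter buffers pass with an audit flag.
#' @param blanking artifact blanking duration (s) (used by the generator of
#'   blanking intervals; kept here for reference).
#' @param refractory dead time after an accepted activation (s).
#' @export
gate_config <- function(base_threshold = 80, hold_time = 0.3,
                        quality_reset = 150, quality_degrade = 100,
                        quality_disable = 50, degrade_factor = 1.2,
                        context_sigma = 2.5, context_window = 60,
                        context_min_history = 10, blanking = 0.5,
                        refractory = 1.0) {
  stopifnot(
    quality_disable < quality_degrade, quality_degrade < quality_reset,
    quality_reset <= 200, hold_time > 0
  )
  structure(
    list(
      base_threshold = base_threshold, hold_time = hold_time,
      quality_reset = quality_reset, quality_degrade = quality_degrade,
      quality_disable = quality_disable, degrade_factor = degrade_factor,
      context_sigma = context_sigma, context_window = context_window,
      context_min_history = context_min_history, blanking = blanking,
      refractory = refractory
    ),
    class = "gate_config"
  )
}

#' Quality-scaled effective activation threshold
#'
#' Below quality 50 control is disabled (returned as `Inf`); between 50 and
#' 100 the base threshold is raised by 20%; otherwise the base threshold
#' applies unchanged. Vectorised over `quality`.
#'
#' @param base base threshold (0-100 scale).
#' @param quality signal quality index in \[0, 200\].
#' @param cfg a [gate_config()].
#' @export
effective_threshold <- function(base, quality, cfg = gate_config()) {
  stopifnot(all(quality >= 0 & quality <= 200))
  ifelse(quality < cfg$quality_disable, Inf,
    ifelse(quality < cfg$quality_degrade, base * cfg$degrade_factor, base)
  )
}

#' Tier 1: temporal consistency check
#'
#' A persistence timer starts when attention first exceeds the effective
#' threshold; a candidate is emitted at the first frame at or after
#' `t_start + hold_time` with the run unbroken. Any frame below threshold,
#' with quality under `quality_reset`, or in the disabled state resets the
#' timer. At most one candidate is emitted per unbroken run.
#'
#' @param attention attention values on the 0-100 scale.
#' @param quality quality indices on the same 8 Hz clock.
#' @param t frame times (s).
#' @param cfg a [gate_config()].
#' @param use_quality_tier if `FALSE` the threshold is not quality-scaled
#'   (tier 2 disabled); the tier-1 `quality_reset` rule always applies.
#' @return data.frame of candidates: `time`, `attention`, `eff_threshold`,
#'   `run_start`.
#' @export
temporal_consistency <- function(attention, quality, t, cfg = gate_config(),
                                 use_quality_tier = TRUE) {
  thr <- if (use_quality_tier) {
    effective_threshold(cfg$base_threshold, quality, cfg)
  } else {
    rep(cfg$base_threshold, length(attention))
  }
  ok <- is.finite(thr) & attention > thr & quality >= cfg$quality_reset
  cand <- data.frame(time = numeric(0), attention = numeric(0),
                     eff_threshold = numeric(0), run_start = numeric(0))
  run_start <- NA_real_
  fired <- FALSE
  for (i in seq_along(ok)) {
    if (ok[i]) {
      if (is.na(run_start)) {
        run_start <- t[i]
        fired <- FALSE
      }
      if (!fired && t[i] >= run_start + cfg$hold_time) {
        cand <- rbind(cand, data.frame(
          time = t[i], attention = attention[i],
          eff_threshold = thr[i], run_start = run_start
        ))
        fired <- TRUE
      }
    } else {
      run_start <- NA_real_
      fired <- FALSE
    }
  }
  cand
}

#' Tier 3: contextual outlier validation
#'
#' Rejects a candidate whose attention deviates more than `context_sigma`
#' standard deviations from the mean of the trailing (up to 60-s) history
#' buffer. Blanked frames are excluded from the buffer. Buffers spanning
#' less than `context_min_history` seconds pass with a `context_unchecked`
#' flag, as do zero-variance buffers.
#'
#' @param time,attention candidate time and attention value.
#' @param history data.frame with `t`, `attention` and a logical `blanked`
#'   column (the feature trace).
#' @param cfg a [gate_config()].
#' @return list: `accept`, `z`, `context_unchecked`.
#' @export
contextual_validate <- function(time, attention, history, cfg = gate_config()) {
  buf <- history[history$t < time & history$t >= time - cfg$context_window &
                   !history$blanked & is.finite(history$attention), , drop = FALSE]
  if (nrow(buf) < 2 || diff(range(buf$t)) < cfg$context_min_history) {
    return(list(accept = TRUE, z = NA_real_, context_unchecked = TRUE))
  }
  s <- stats::sd(buf$attention)
  if (s == 0) {
    return(list(accept = TRUE, z = NA_real_, context_unchecked = TRUE))
  }
  z <- abs(attention - mean(buf$attention)) / s
  list(accept = z <= cfg$context_sigma, z = z, context_unchecked = FALSE)
}

#' Artifact blanking gate
#'
#' @param time candidate time (s).
#' @param blanking data.frame of `onset`, `offset` intervals (sorted).
#' @return `TRUE` if the candidate passes (is outside every interval).
#' @export
blanking_gate <- function(time, blanking) {
  !any(time >= blanking$onset & time < blanking$offset)
}

#' Full activation cascade
#'
#' Composes the tiers: temporal persistence, quality-scaled thresholds,
#' contextual validation, artifact blanking, and a refractory period after
#' each accepted event. Every candidate carries its complete audit trail;
#' every rejected candidate names the rejecting tier.
#'
#' The context tier compares the *physical* baseline-normalised attention
#' (`attention` column) against its trailing buffer - the percentile-scaled
#' `attention100` has a uniform marginal by construction, which would make
#' a sigma-based outlier rule vacuous. The blanking tier rejects candidates
#' at frames whose analysis window touches a blanking interval (the
#' `blanked` flag), a stricter superset of the raw 500 ms intervals.
#'
#' @param features a [feature_stream()] trace; an `attention100` column is
#'   added via [scale_attention()] if absent. Blanking intervals are taken
#'   from the `"blanking"` attribute unless supplied.
#' @param cfg a [gate_config()].
#' @param tiers character subset of `c("quality", "context", "blanking")`
#'   to enable beyond the always-on temporal tier (used for cascade
#'   ablation studies).
#' @param blanking optional data.frame of blanking intervals.
#' @return data.frame of `activation_events`: `time`, `attention`,
#'   `eff_threshold`, `quality`, `z_context`, `context_unchecked`,
#'   `accepted`, `reject_tier`.
#' @export
detect_activations <- function(features, cfg = gate_config(),
                               tiers = c("quality", "context", "blanking"),
                               blanking = NULL) {
  if (is.null(features$attention100)) features <- scale_attention(features)
  blanking <- blanking %||% attr(features, "blanking") %||%
    data.frame(onset = numeric(0), offset = numeric(0))
  cand <- temporal_consistency(
    features$attention100, features$quality, features$t, cfg,
    use_quality_tier = "quality" %in% tiers
  )
  n <- nrow(cand)
  ev <- data.frame(
    time = cand$time, attention = cand$attention,
    eff_threshold = cand$eff_threshold,
    quality = if (n) features$quality[match(cand$time, features$t)] else numeric(0),
    z_context = NA_real_[seq_len(n)],
    context_unchecked = logical(n),
    accepted = logical(n), reject_tier = NA_character_[seq_len(n)]
  )
  hist_df <- data.frame(t = features$t, attention = features$attention,
                        blanked = features$blanked)
  last_accept <- -Inf
  for (i in seq_len(n)) {
    ti <- ev$time[i]
    fi <- match(ti, features$t)
    if (cfg$refractory > 0 && ti - last_accept < cfg$refractory) {
      ev$reject_tier[i] <- "refractory"
      next
    }
    if ("context" %in% tiers) {
      cv <- contextual_validate(ti, features$attention[fi], hist_df, cfg)
      ev$z_context[i] <- cv$z
      ev$context_unchecked[i] <- cv$context_unchecked
      if (!cv$accept) {
        ev$reject_tier[i] <- "context"
        next
      }
    }
    if ("blanking" %in% tiers &&
        (isTRUE(features$blanked[fi]) || !blanking_gate(ti, blanking))) {
      ev$reject_tier[i] <- "blanking"
      next
    }
    ev$accepted[i] <- TRUE
    last_accept <- ti
  }
  class(ev) <- c("activation_events", "data.frame")
  ev
}

#' Episode-level detection summary against ground truth
#'
#' An episode counts as detected when at least one accepted activation
#' falls inside it (with `slack` seconds of tolerance at the tail for the
#' persistence delay); accepted activations outside every episode count as
#' false activations.
#'
#' @param events a [detect_activations()] result.
#' @param episodes ground-truth episode data.frame (`onset`, `duration`).
#' @param duration session duration in seconds (for the per-minute rate).
#' @param slack tail tolerance (s); defaults to the 2-s analysis window,
#'   since a trailing-window frame that long after the episode still sees
#'   episode content.
#' @return list: `tpr`, `false_per_min`, `n_detected`, `n_episodes`.
#' @export
episode_detection <- function(events, episodes, duration, slack = 2) {
  acc <- events$time[events$accepted]
  hit <- function(on, dur) any(acc >= on & acc <= on + dur + slack)
  det <- if (nrow(episodes)) {
    mapply(hit, episodes$onset, episodes$duration)
  } else {
    logical(0)
  }
  in_any <- if (nrow(episodes)) {
    vapply(acc, function(a) any(a >= episodes$onset & a <= episodes$onset + episodes$duration + slack), logical(1))
  } else {
    rep(FALSE, length(acc))
  }
  list(
    tpr = if (length(det)) mean(det) else NA_real_,
    false_per_min = sum(!in_any) / (duration / 60),
    n_detected = sum(det), n_episodes = length(det)
  )
}
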