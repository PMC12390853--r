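test_that("effective threshold follows the quality-scaling rules", {
  expect_equal(effective_threshold(80, 120), 80)
  expect_equal(effective_threshold(80, 90), 96)
  expect_identical(effective_threshold(80, 40), Inf) # disabled
  # boundaries: 50 is degraded (not disabled), 100 is nominal
  expect_equal(effective_threshold(80, 50), 96)
  expect_equal(effective_threshold(80, 100), 80)
  expect_error(effective_threshold(80, 250), "quality")
  # monotone: lower quality never lowers the threshold
  q <- seq(200, 50, by = -1)
  thr <- effective_threshold(80, q)
  expect_true(all(diff(thr) >= 0))
  expect_true(all(is.infinite(effective_threshold(80, seq(0, 49)))))
})

test_that("temporal consistency emits one candidate per sustained run", {
  t <- seq(0, 5, by = 0.125)
  att <- rep(0, length(t))
  qual <- rep(200, length(t))
  att[t >= 1 & t < 1.4] <- 85 # 400 ms above threshold
  cand <- temporal_consistency(att, qual, t)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$time, 1.375) # first frame at/after t0 + 300 ms
  expect_equal(cand$run_start, 1)
  # quality dip below 150 inside the run resets the timer
  qual2 <- qual
  qual2[t == 1.25] <- 140
  expect_equal(nrow(temporal_consistency(att, qual2, t)), 0)
  # attention below threshold never triggers
  expect_equal(nrow(temporal_consistency(rep(79, length(t)), qual, t)), 0)
  # a long run still yields a single candidate
  att3 <- rep(90, length(t))
  expect_equal(nrow(temporal_consistency(att3, qual, t)), 1)
})

test_that("contextual validation applies the 2.5-sigma rule", {
  t <- seq(0, 20, by = 0.125)
  hist <- data.frame(
    t = t,
    attention = rep(c(66, 74), length.out = length(t)), # mean 70, sd ~ 4
    blanked = FALSE
  )
  buf <- hist[hist$t < 20.1, ]
  r81 <- contextual_validate(20.1, 81, hist)
  expect_false(r81$accept)
  expect_equal(r81$z, abs(81 - mean(buf$attention)) / sd(buf$attention),
               tolerance = 1e-9)
  expect_gt(r81$z, 2.5)
  r79 <- contextual_validate(20.1, 79, hist)
  expect_true(r79$accept)
  expect_lt(r79$z, 2.5)
  # short buffer: pass-through with audit flag
  short <- hist[hist$t > 15, ]
  rs <- contextual_validate(20.1, 200, short)
  expect_true(rs$accept)
  expect_true(rs$context_unchecked)
  # zero-variance buffer: accept with audit flag
  flat <- data.frame(t = t, attention = 50, blanked = FALSE)
  rf <- contextual_validate(20.1, 90, flat)
  expect_true(rf$accept)
  expect_true(rf$context_unchecked)
})

test_that("blanking gate blocks candidates inside intervals", {
  iv <- data.frame(onset = 5.0, offset = 5.5)
  expect_false(blanking_gate(5.3, iv))
  expect_true(blanking_gate(5.6, iv))
  expect_true(blanking_gate(5.3, iv[0, ]))
})

test_that("cascade: quality-40 sessions produce zero events", {
  t <- seq(2, 60, by = 0.125)
  fx <- data.frame(
    t = t, attention = 3, attention100 = 95, quality = 40,
    blanked = FALSE, ratio_raw = 1
  )
  ev <- detect_activations(fx, blanking = data.frame(onset = numeric(0), offset = numeric(0)))
  expect_equal(sum(ev$accepted), 0)
})

test_that("audit completeness: every rejected candidate names its tier", {
  cfg <- session_config(seed = 13, trial_duration = 120, n_trials = 1)
  fx <- scale_attention(feature_stream(gen_eeg(cfg)$stream))
  ev <- detect_activations(fx)
  rej <- ev[!ev$accepted, ]
  expect_true(all(!is.na(rej$reject_tier)))
  expect_true(all(rej$reject_tier %in% c("refractory", "context", "blanking")))
  acc <- ev[ev$accepted, ]
  expect_true(all(is.na(acc$reject_tier)))
  # blanking completeness: no accepted event on a blanked frame
  expect_false(any(fx$blanked[match(acc$time, fx$t)]))
})

test_that("cascade dominance and artifact monotonicity", {
  cfg <- gate_config(refractory = 0)
  for (seed in c(31, 32)) {
    sc <- session_config(seed = seed, trial_duration = 90, n_trials = 1)
    fx <- scale_attention(feature_stream(gen_eeg(sc)$stream))
    full <- detect_activations(fx, cfg)
    for (sub in list(c("quality"), c("quality", "context"), c("quality", "blanking"))) {
      subset_ev <- detect_activations(fx, cfg, tiers = sub)
      expect_true(all(full$time[full$accepted] %in% subset_ev$time[subset_ev$accepted]))
    }
    # adding an artifact interval never increases accepted events
    extra <- rbind(attr(fx, "blanking"), data.frame(onset = 45, offset = 60))
    fewer <- detect_activations(fx, cfg, blanking = extra)
    expect_lte(sum(fewer$accepted), sum(full$accepted))
  }
})

test_that("episode detection summarises against ground truth", {
  ev <- data.frame(time = c(7, 30, 55), accepted = c(TRUE, TRUE, TRUE))
  eps <- data.frame(onset = c(6, 26), duration = c(4, 4))
  d <- episode_detection(ev, eps, duration = 60)
  expect_equal(d$tpr, 1)
  expect_equal(d$false_per_min, 1)
  none <- episode_detection(ev[0, ], eps, 60)
  expect_equal(none$tpr, 0)
})
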