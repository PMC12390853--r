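test_that("artifact detection follows the amplitude/gradient/variance rules", {
  fs <- 512
  x <- numeric(fs * 6)
  x[fs * 2 + 2] <- 120 # one sample at +120 uV (t ~ 2.002 s)
  tspike <- (fs * 2 + 1) / fs
  res <- detect_artifacts(make_stream(x, fs))
  hit <- res$flags[res$flags$start <= tspike & res$flags$end > tspike, ]
  expect_true(all(hit$blink))
  expect_equal(nrow(res$blanking), 1)
  # a 500 ms blank from the offending sample (the spike also trips the
  # gradient rule one sample earlier, so the merged width may gain 1/fs)
  width <- res$blanking$offset - res$blanking$onset
  expect_gte(width, 0.5)
  expect_lte(width, 0.5 + 2 / fs)
  expect_true(res$blanking$onset <= tspike && res$blanking$offset >= tspike)

  y <- numeric(fs * 6)
  y[fs * 3 + 0:1] <- c(30, -30) # adjacent samples differ by 60 uV
  resy <- detect_artifacts(make_stream(y, fs))
  hity <- resy$flags[resy$flags$start <= 3 & resy$flags$end > 3, ]
  expect_true(any(hity$muscle)) # flagged in the window containing the pair
  expect_false(any(resy$flags$blink))

  z <- detect_artifacts(make_stream(numeric(fs * 6), fs))
  expect_false(any(z$flags$blink | z$flags$muscle | z$flags$poor_contact))
  expect_equal(nrow(z$blanking), 0)

  empty <- detect_artifacts(make_stream(numeric(0), fs))
  expect_equal(nrow(empty$flags), 0)
})

test_that("band-pass design matches the reference Butterworth coefficients", {
  # frozen from an independent filter-design implementation
  # (4th-order band-pass, 4-40 Hz at 512 Hz)
  co <- butter_bandpass(4, 4, 40, 512)
  b_ref <- c(0.00141968399008381, 0, -0.00567873596033522, 0,
             0.00851810394050284, 0, -0.00567873596033522, 0,
             0.00141968399008381)
  a_ref <- c(1, -6.766063674930017, 20.134904686304555, -34.44484026148404,
             37.06825808471774, -25.705258100096234, 11.218692389954965,
             -2.8174135342186104, 0.31172060914968275)
  expect_equal(co$b, b_ref, tolerance = 1e-12)
  expect_equal(co$a, a_ref, tolerance = 1e-12)
})

test_that("bandpass_detrend attenuates stop-band, preserves pass-band", {
  fs <- 512
  t <- (0:(fs * 20 - 1)) / fs
  mid <- (fs * 5):(fs * 15)
  slow <- bandpass_detrend(make_stream(sin(2 * pi * 0.5 * t), fs))
  expect_lt(20 * log10(max(abs(slow$uv[mid]))), -40)
  pass <- bandpass_detrend(make_stream(sin(2 * pi * 10 * t), fs))
  expect_equal(max(abs(pass$uv[mid])), 1, tolerance = 0.05)
  const <- bandpass_detrend(make_stream(rep(5, fs * 4), fs))
  expect_lt(max(abs(const$uv)), 1e-6)
  expect_error(bandpass_detrend(make_stream(numeric(10), fs)), "warm-up")
  expect_error(bandpass_detrend(make_stream(numeric(512), 64)), "128")
})

test_that("welch_psd satisfies Parseval and the error contract", {
  fs <- 512
  t <- (0:(fs * 8 - 1)) / fs
  sp <- welch_psd(3 * sin(2 * pi * 10 * t), fs)
  df <- sp$freq[2] - sp$freq[1]
  expect_equal(sp$freq[which.max(sp$psd)], 10, tolerance = df)
  expect_equal(sum(sp$psd) * df, 9 / 2, tolerance = 0.05 * 9 / 2)
  set.seed(42)
  w <- rnorm(fs * 8, sd = 2)
  spw <- welch_psd(w, fs)
  expect_equal(sum(spw$psd) * df, 4, tolerance = 0.4)
  expect_equal(sum(welch_psd(numeric(512), fs)$psd), 0)
  expect_error(welch_psd(numeric(100), fs), "at least")
})

test_that("welch_psd equals the independent periodogram oracle", {
  set.seed(9)
  fs <- 512
  x <- rnorm(fs * 2) + sin(2 * pi * 11 * (0:(fs * 2 - 1)) / fs)
  ours <- welch_psd(x, fs)
  ref <- oracle_welch(x, fs)
  expect_equal(ours$freq, ref$freq)
  expect_lt(max(abs(ours$psd - ref$psd) / (ref$psd + 1e-30)), 1e-6)
})

test_that("band powers integrate half-open bands and scale quadratically", {
  fs <- 512
  t <- (0:(fs * 4 - 1)) / fs
  bp10 <- band_powers(welch_psd(sin(2 * pi * 10 * t), fs))
  expect_gt(bp10$alpha, 0)
  expect_lt(bp10$theta / bp10$alpha, 1e-3)
  # the Hamming main lobe leaks into the adjacent 12 Hz bin, so beta is
  # small but not exactly zero
  expect_lt(bp10$beta / bp10$alpha, 0.2)
  bp20 <- band_powers(welch_psd(sin(2 * pi * 20 * t), fs))
  expect_gt(bp20$beta / (bp20$alpha + bp20$theta + 1e-12), 1e3)
  # amplitude x2 -> every band power x4
  x <- rnorm(fs * 4)
  b1 <- band_powers(welch_psd(x, fs))
  b2 <- band_powers(welch_psd(2 * x, fs))
  for (nm in names(b1)) expect_equal(b2[[nm]], 4 * b1[[nm]], tolerance = 1e-10)
})

test_that("attention metric arithmetic, baseline handling and errors", {
  bp <- list(theta = 4, alpha = 6, beta = 10)
  res <- attention_metric(bp, baseline_state(), t = 0)
  expect_equal(res$ratio_raw, 1.0)
  expect_equal(res$attention, 1.0) # empty baseline self-normalises
  res2 <- attention_metric(list(theta = 4, alpha = 6, beta = 20),
                           res$baseline, t = 1)
  expect_equal(res2$attention, 2.0)
  expect_error(attention_metric(list(theta = 0, alpha = 0, beta = 5),
                                baseline_state()), "undefined")
  # history expiry beyond the 30-s window
  st <- baseline_state()
  for (tt in seq(0, 40, by = 1)) st <- trimanus:::baseline_push(st, tt, tt)
  expect_true(all(st$t > 40 - 30))
})

test_that("quality index maps flagged fraction onto 0-200", {
  wins <- seq(0, 9)
  expect_equal(quality_index(numeric(0), wins, t = 9), 200)
  expect_equal(quality_index(wins, wins, t = 9), 0)
  expect_equal(quality_index(wins[1:5], wins, t = 9), 100)
})

test_that("feature frames obey the 8 Hz contract and respond to episodes", {
  cfg <- clean_config(21, duration = 40, attention_schedule = no_episodes())
  fx <- feature_stream(gen_eeg(cfg)$stream)
  expect_equal(unique(round(diff(fx$t), 9)), 0.125)
  expect_equal(ncol(fx) - 2, 10) # t + 10 features + blanked flag
  # stationary stream: attention hovers near 1 once the baseline is filled
  late <- fx$attention[fx$t > 32]
  expect_lt(sd(late), 0.2)
  expect_equal(mean(late), 1, tolerance = 0.2)
  # scale invariance of the attention metric under signal rescaling
  # (factor 0.5 keeps both streams clear of the absolute artifact
  # thresholds, which are intentionally scale-dependent)
  s <- gen_eeg(clean_config(22, duration = 10, attention_schedule = no_episodes()))$stream
  s3 <- s
  s3$uv <- s3$uv * 0.5
  f1 <- feature_stream(s)
  f3 <- feature_stream(s3)
  expect_lt(max(abs(f1$attention - f3$attention)), 1e-9)
  expect_lt(max(abs(f1$ratio_raw - f3$ratio_raw)), 1e-9)
  # conservation: band sum never exceeds total 4-40 Hz power
  tot <- vapply(seq_len(nrow(f1)), function(i) {
    idx <- (round((f1$t[i] - 2) * 512) + 1):round(f1$t[i] * 512)
    band_powers(welch_psd(bandpass_detrend(s)$uv[idx], 512))$total
  }, numeric(1))
  expect_true(all(f1$theta + f1$alpha + f1$beta <= tot + 1e-9))
  # an injected episode lifts attention above 1.3
  cfg2 <- clean_config(
    23, duration = 40,
    attention_schedule = data.frame(onset = 20, duration = 6, level = 0.5)
  )
  f2 <- feature_stream(gen_eeg(cfg2)$stream)
  expect_gt(max(f2$attention[f2$t >= 22 & f2$t <= 26]), 1.3)
})

test_that("epoch segmentation matches the bookkeeping convention", {
  expect_equal(segment_epochs(60)$n_epochs, 32)
  expect_equal(20 * segment_epochs(60)$n_epochs, 640)
  expect_equal(segment_epochs(3.75)$n_epochs, 2)
  s <- make_stream(rnorm(512 * 4), 512)
  seg <- segment_epochs(s)
  expect_equal(seg$n_epochs, 3)
  expect_true(all(vapply(seg$epochs, length, numeric(1)) == round(3.75 * 512)))
  # final epoch zero-padded: tail beyond the stream is exactly zero
  last <- seg$epochs[[3]]
  expect_true(all(last[(round((4 - 3.75) * 512) + 100):length(last)] == 0))
  expect_error(segment_epochs(2), "shorter")
})

test_that("ERD percent change follows its definition", {
  expect_equal(erd_percent(1, 1), 0)
  expect_equal(erd_percent(0.577, 1), -42.3)
  expect_equal(erd_percent(2, 1), 100)
  expect_error(erd_percent(1, 0), "zero baseline")
  # time course on a constructed amplitude drop in the alpha band
  fs <- 512
  t <- (0:(fs * 20 - 1)) / fs
  amp <- ifelse(t < 10, 1, sqrt(0.577))
  x <- amp * sin(2 * pi * 10 * t)
  erd <- spectrogram_erd(make_stream(x, fs), band = c(8, 12), baseline = c(0, 10))
  late <- erd$erd[erd$t > 12]
  expect_equal(mean(late), -42.3, tolerance = 1.5)
  expect_error(
    spectrogram_erd(make_stream(numeric(fs * 20), fs), c(8, 12), c(0, 10)),
    "zero baseline"
  )
})
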