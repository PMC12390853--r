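# Independent oracles, deliberately coded without reusing package internals.

# Welch estimate built from plain single-segment periodograms; must agree
# with welch_psd() when the segmentation is identical.
oracle_welch <- function(x, fs, nfft = 256, overlap = 0.5) {
  hop <- round(nfft * (1 - overlap))
  idx0 <- seq(1, length(x) - nfft + 1, by = hop)
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(nfft - 1)) / (nfft - 1))
  U <- fs * sum(win^2)
  half <- nfft %/% 2 + 1
  psum <- rep(0, half)
  for (i0 in idx0) {
    seg <- x[i0:(i0 + nfft - 1)]
    seg <- seg - mean(seg)
    X <- fft(seg * win)[seq_len(half)]
    pg <- (Re(X)^2 + Im(X)^2) / U
    pg[-c(1, half)] <- 2 * pg[-c(1, half)]
    psum <- psum + pg
  }
  list(freq = (seq_len(half) - 1) * fs / nfft, psd = psum / length(idx0))
}

# Batch maximum-a-posteriori smoother for a scalar linear-Gaussian model,
# solved as one weighted least-squares problem over (x0, x1, ..., xn).
oracle_batch_filter <- function(a, h, q, r, x0, p0, z) {
  n <- length(z)
  rows <- 1 + n + n
  M <- matrix(0, rows, n + 1)
  b <- numeric(rows)
  M[1, 1] <- 1 / sqrt(p0); b[1] <- x0 / sqrt(p0)
  for (t in seq_len(n)) {
    M[1 + t, t] <- -a / sqrt(q); M[1 + t, t + 1] <- 1 / sqrt(q)
    M[1 + n + t, t + 1] <- h / sqrt(r); b[1 + n + t] <- z[t] / sqrt(r)
  }
  sol <- qr.solve(M, b)
  sol[n + 1] # posterior mean of the final state
}

# power of a two-sided paired t test from the noncentral t distribution
oracle_paired_power <- function(delta_sd, n, alpha) {
  tc <- qt(1 - alpha / 2, n - 1)
  ncp <- delta_sd * sqrt(n)
  1 - pt(tc, n - 1, ncp = ncp) + pt(-tc, n - 1, ncp = ncp)
}

# clean EEG config helpers
no_episodes <- function() {
  data.frame(onset = numeric(0), duration = numeric(0), level = numeric(0))
}

clean_config <- function(seed, duration = 60, ...) {
  session_config(
    seed = seed, trial_duration = duration, n_trials = 1,
    artifact_rates = c(blinks = 0, muscle = 0), ...
  )
}

make_stream <- function(x, fs = 512, channel = "eeg", units = "uV") {
  sample_stream(data.frame(t = (seq_along(x) - 1) / fs, uv = x),
                channel, fs, units)
}
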