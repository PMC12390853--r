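# Single-channel EEG feature pipeline: artifact gating -> zero-phase 4-40 Hz
# Butterworth + 500 ms moving-average detrend -> Welch band powers ->
# baseline-normalised beta/(alpha+theta) attention metric, emitted as a
# 10-dimensional feature frame at 8 Hz.

#' Detect amplitude/gradient/variance artifacts
#'
#' Scans the raw stream in 2-s windows with 50% overlap. A window is flagged
#' as `blink` when any sample exceeds +/- 100 uV, `muscle` when any
#' sample-to-sample gradient exceeds 50 uV/sample, and `poor_contact` when
#' the window SD exceeds 35 uV. Every flag opens a 500 ms blanking interval
#' starting at the first offending sample; overlapping intervals are merged.
#'
#' @param stream raw EEG [sample_stream()] (uV).
#' @param amp_thresh,grad_thresh,sd_thresh detection thresholds.
#' @param win,overlap window length (s) and fractional overlap.
#' @param blank blanking duration (s) opened by each flag.
#' @return list with `flags` (per-window logical flags) and `blanking`
#'   (merged data.frame of `onset`, `offset` in seconds).
#' @export
detect_artifacts <- function(stream, amp_thresh = 100, grad_thresh = 50,
                             sd_thresh = 35, win = 2, overlap = 0.5,
                             blank = 0.5) {
  x <- stream$uv
  fs <- stream_rate(stream)
  n <- length(x)
  step <- win * (1 - overlap)
  empty <- list(
    flags = data.frame(start = numeric(0), end = numeric(0),
                       blink = logical(0), muscle = logical(0), poor_contact = logical(0)),
    blanking = data.frame(onset = numeric(0), offset = numeric(0))
  )
  if (n == 0) return(empty)
  starts <- seq(0, n / fs - win, by = step)
  if (length(starts) == 0) return(empty)
  t0 <- stream$t[1]
  flags <- data.frame(start = starts + t0, end = starts + win + t0,
                      blink = FALSE, muscle = FALSE, poor_contact = FALSE)
  onsets <- numeric(0)
  for (i in seq_along(starts)) {
    idx <- (round(starts[i] * fs) + 1):min(round((starts[i] + win) * fs), n)
    w <- x[idx]
    off <- integer(0)
    if (any(abs(w) > amp_thresh)) {
      flags$blink[i] <- TRUE
      off <- c(off, idx[which(abs(w) > amp_thresh)[1]])
    }
    g <- abs(diff(w))
    if (any(g > grad_thresh)) {
      flags$muscle[i] <- TRUE
      off <- c(off, idx[which(g > grad_thresh)[1]])
    }
    if (stats::sd(w) > sd_thresh) {
      flags$poor_contact[i] <- TRUE
      off <- c(off, idx[1])
    }
    if (length(off)) onsets <- c(onsets, stream$t[off])
  }
  blanking <- merge_intervals(data.frame(onset = onsets, offset = onsets + blank))
  list(flags = flags, blanking = blanking)
}

merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv$onset), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    j <- nrow(out)
    if (iv$onset[i] <= out$offset[j]) {
      out$offset[j] <- max(out$offset[j], iv$offset[i])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

in_intervals <- function(t, iv) {
  if (nrow(iv) == 0) return(rep(FALSE, length(t)))
  res <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv))) {
    res <- res | (t >= iv$onset[i] & t < iv$offset[i])
  }
  res
}

#' Band-pass filter and detrend an EEG stream
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass, default
#' 4-40 Hz, followed by subtraction of a 500 ms centred moving average to
#' remove residual slow drift. A causal single-pass mode is available for
#' latency studies.
#'
#' @param stream raw EEG [sample_stream()]; rate must be >= 128 Hz.
#' @param lo,hi band edges (Hz).
#' @param order Butterworth prototype order.
#' @param detrend_win moving-average window (s).
#' @param causal if `TRUE`, use a single forward pass instead of
#'   forward-backward filtering.
#' @return filtered [sample_stream()].
#' @export
bandpass_detrend <- function(stream, lo = 4, hi = 40, order = 4,
                             detrend_win = 0.5, causal = FALSE) {
  fs <- stream_rate(stream)
  if (fs < 128) stop("sampling rate must be >= 128 Hz")
  coef <- butter_bandpass(order, lo, hi, fs)
  x <- stream$uv
  npad <- 3 * (max(length(coef$a), length(coef$b)) - 1)
  if (length(x) <= npad) {
    stop("stream shorter than filter warm-up (", npad, " samples)")
  }
  y <- if (causal) iir_filter(coef$b, coef$a, x) else filtfilt(coef$b, coef$a, x)
  y <- y - centered_ma(y, round(detrend_win * fs))
  out <- stream
  out$uv <- y
  out
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: 256-point Hamming-tapered segments with
#' 50% overlap, per-segment mean removal, one-sided density scaling
#' (uV^2/Hz), so the integral of the PSD equals the signal power.
#'
#' @param x numeric vector or a [sample_stream()] window.
#' @param fs sampling rate (Hz); taken from the stream if omitted.
#' @param nfft segment/FFT length.
#' @param overlap fractional segment overlap.
#' @return data.frame with columns `freq`, `psd` (class `welch_psd`).
#' @export
welch_psd <- function(x, fs = NULL, nfft = 256, overlap = 0.5) {
  if (inherits(x, "sample_stream")) {
    fs <- stream_rate(x)
    x <- x$uv
  }
  if (is.null(fs)) stop("fs required")
  n <- length(x)
  if (n < nfft) stop("window must contain at least ", nfft, " samples")
  step <- round(nfft * (1 - overlap))
  starts <- seq(1, n - nfft + 1, by = step)
  w <- hamming_window(nfft)
  scale <- 1 / (fs * sum(w^2))
  nf <- nfft %/% 2 + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- fft(seg)[1:nf]
    p <- Mod(sp)^2 * scale
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)] # one-sided
    acc <- acc + p
  }
  out <- data.frame(freq = (0:(nf - 1)) * fs / nfft, psd = acc / length(starts))
  class(out) <- c("welch_psd", "data.frame")
  out
}

#' Integrate a PSD over the canonical EEG bands
#'
#' Rectangular integration over half-open intervals \[lo, hi): theta 4-8 Hz,
#' alpha 8-12 Hz, beta 12-30 Hz, plus the total 4-40 Hz power.
#'
#' @param spectrum a [welch_psd()] result.
#' @param bands named list of `c(lo, hi)` band edges.
#' @return named list of band powers (uV^2), class `band_powers`.
#' @export
band_powers <- function(spectrum,
                        bands = list(theta = c(4, 8), alpha = c(8, 12),
                                     beta = c(12, 30), total = c(4, 40))) {
  if (max(spectrum$freq) < 30) stop("spectrum must cover 4-30 Hz")
  df <- spectrum$freq[2] - spectrum$freq[1]
  bp <- lapply(bands, function(b) {
    sum(spectrum$psd[spectrum$freq >= b[1] & spectrum$freq < b[2]]) * df
  })
  class(bp) <- "band_powers"
  bp
}

#' Rolling 30-s baseline of the raw attention ratio
#'
#' @param window history span in seconds.
#' @export
baseline_state <- function(window = 30) {
  structure(list(t = numeric(0), ratio = numeric(0), window = window),
            class = "baseline_state")
}

baseline_mean <- function(state) {
  if (length(state$ratio) == 0) NA_real_ else mean(state$ratio)
}

baseline_push <- function(state, t, ratio) {
  state$t <- c(state$t, t)
  state$ratio <- c(state$ratio, ratio)
  keep <- state$t > t - state$window
  state$t <- state$t[keep]
  state$ratio <- state$ratio[keep]
  state
}

#' Baseline-normalised attention metric
#'
#' `ratio_raw = beta / (alpha + theta)`; `attention = ratio_raw / mean` of
#' the 30-s rolling baseline (artifact-blanked frames excluded upstream).
#' With an empty baseline the frame self-normalises to 1. The baseline is
#' updated *after* the read, so a frame never normalises against itself.
#'
#' @param bp a [band_powers()] result.
#' @param baseline a [baseline_state()].
#' @param t frame time (s), used for history expiry.
#' @return list with `ratio_raw`, `attention` and the updated `baseline`.
#' @export
attention_metric <- function(bp, baseline, t = 0) {
  denom <- bp$alpha + bp$theta
  if (denom <= 0) stop("undefined attention ratio: alpha + theta must be positive")
  ratio <- bp$beta / denom
  m <- baseline_mean(baseline)
  attention <- if (is.na(m) || m <= 0) 1 else ratio / m
  baseline <- baseline_push(baseline, t, ratio)
  list(ratio_raw = ratio, attention = attention, baseline = baseline)
}

#' Signal quality index on the 0-200 scale
#'
#' `200 * (1 - fraction of flagged 2-s windows within the trailing 10 s)`,
#' clamped to \[0, 200\]. Higher is better.
#'
#' @param flag_times window start times that carried any artifact flag.
#' @param window_times all window start times considered so far.
#' @param t current time (s).
#' @param span history span (s).
#' @export
quality_index <- function(flag_times, window_times, t, span = 10) {
  recent <- window_times > t - span & window_times <= t
  if (!any(recent)) return(200)
  frac <- sum(flag_times > t - span & flag_times <= t) / sum(recent)
  max(0, min(200, 200 * (1 - frac)))
}

#' Full EEG feature pipeline at 8 Hz
#'
#' Composes artifact detection, band-pass/detrend filtering, Welch band
#' powers, the baseline-normalised attention metric, the quality index and
#' the zero-crossing rate into the 10-dimensional feature frame sequence.
#' Each frame at time `t` summarises the trailing 2-s window; frames are
#' spaced 125 ms apart. Band-power derivatives are first differences of
#' consecutive frames divided by the frame spacing.
#'
#' @param stream raw EEG [sample_stream()].
#' @param frame_rate frame emission rate (Hz).
#' @param win analysis window (s).
#' @param baseline_window rolling baseline span (s).
#' @return data.frame (class `feature_frames`) with columns `t`, `theta`,
#'   `alpha`, `beta`, `d_theta`, `d_alpha`, `d_beta`, `ratio_raw`,
#'   `attention`, `quality`, `zcr` and a `blanked` bookkeeping flag; the
#'   artifact blanking intervals ride along as attribute `"blanking"`.
#' @export
feature_stream <- function(stream, frame_rate = 8, win = 2, baseline_window = 30) {
  dur <- stream_duration(stream)
  if (dur < win) stop("stream must be at least ", win, " s long")
  fs <- stream_rate(stream)
  art <- detect_artifacts(stream)
  filt <- bandpass_detrend(stream)
  t0 <- stream$t[1]
  frame_t <- seq(t0 + win, t0 + dur, by = 1 / frame_rate)
  flagged <- art$flags$start[art$flags$blink | art$flags$muscle | art$flags$poor_contact]
  base <- baseline_state(baseline_window)
  nfr <- length(frame_t)
  # a frame is blanked when its trailing analysis window touches any
  # blanking interval: the frame itself may lie past the 500 ms blank, but
  # its window content is still artifact-contaminated
  blanked <- rep(FALSE, nfr)
  if (nrow(art$blanking)) {
    for (k in seq_len(nrow(art$blanking))) {
      blanked <- blanked | (frame_t >= art$blanking$onset[k] &
                              frame_t - win < art$blanking$offset[k])
    }
  }
  out <- data.frame(
    t = frame_t, theta = NA_real_, alpha = NA_real_, beta = NA_real_,
    d_theta = 0, d_alpha = 0, d_beta = 0, ratio_raw = NA_real_,
    attention = NA_real_, quality = NA_real_, zcr = NA_real_,
    blanked = blanked
  )
  for (i in seq_len(nfr)) {
    tf <- frame_t[i]
    idx <- (round((tf - win - t0) * fs) + 1):round((tf - t0) * fs)
    seg <- filt$uv[idx]
    bp <- band_powers(welch_psd(seg, fs))
    out$theta[i] <- bp$theta
    out$alpha[i] <- bp$alpha
    out$beta[i] <- bp$beta
    ratio <- bp$beta / (bp$alpha + bp$theta)
    m <- baseline_mean(base)
    out$ratio_raw[i] <- ratio
    out$attention[i] <- if (is.na(m) || m <= 0) 1 else ratio / m
    if (!out$blanked[i]) base <- baseline_push(base, tf, ratio)
    out$quality[i] <- quality_index(flagged, art$flags$start, tf)
    out$zcr[i] <- sum(diff(sign(seg)) != 0) / win / 2
  }
  step <- 1 / frame_rate
  if (nfr > 1) {
    out$d_theta[-1] <- diff(out$theta) / step
    out$d_alpha[-1] <- diff(out$alpha) / step
    out$d_beta[-1] <- diff(out$beta) / step
  }
  structure(out,
    blanking = art$blanking, frame_rate = frame_rate,
    class = c("feature_frames", "data.frame")
  )
}

#' Rescale normalised attention to the 0-100 e-Sense-like scale
#'
#' Percentile calibration: `attention100` is 100 times the empirical CDF of
#' the baseline-normalised attention over a calibration run (by default the
#' feature trace itself, excluding blanked frames). This makes the
#' activation threshold of 80 coincide with the 80th percentile of the
#' calibration attention distribution, mirroring how personalised
#' thresholds are calibrated in practice.
#'
#' @param features a [feature_stream()] result.
#' @param calibration feature frames to calibrate the distribution on.
#' @export
scale_attention <- function(features, calibration = features) {
  a <- calibration$attention[!calibration$blanked & is.finite(calibration$attention)]
  if (length(a) < 2 || diff(range(a)) == 0) {
    features$attention100 <- rep(50, nrow(features))
    return(features)
  }
  F <- stats::ecdf(a)
  features$attention100 <- 100 * F(features$attention)
  features
}

#' Segment a trial into overlapping epochs
#'
#' Epochs of `epoch_len` seconds start every `epoch_len * (1 - overlap)`
#' seconds from 0 while the start lies inside the trial; the final partial
#' epoch is zero-padded. With the defaults a 60-s trial yields 32 epochs
#' (`ceiling(duration / step)`), hence 640 across a 20-trial session.
#'
#' @param x a [sample_stream()] or a duration in seconds.
#' @param epoch_len epoch length (s), default 3.75.
#' @param overlap fractional overlap, default 0.5.
#' @param taper apply a Hamming taper to each epoch's samples.
#' @return list with `starts`, `n_epochs`, and (when `x` is a stream)
#'   `epochs`: a list of tapered, zero-padded sample vectors.
#' @export
segment_epochs <- function(x, epoch_len = 3.75, overlap = 0.5, taper = TRUE) {
  dur <- if (inherits(x, "sample_stream")) stream_duration(x) else as.numeric(x)
  if (dur < epoch_len) stop("trial shorter than one epoch")
  step <- epoch_len * (1 - overlap)
  starts <- seq(0, by = step, length.out = ceiling(dur / step))
  starts <- starts[starts < dur]
  out <- list(starts = starts, n_epochs = length(starts),
              epoch_len = epoch_len, step = step)
  if (inherits(x, "sample_stream")) {
    fs <- stream_rate(x)
    nsamp <- round(epoch_len * fs)
    w <- if (taper) hamming_window(nsamp) else rep(1, nsamp)
    vals <- x[[2]]
    out$epochs <- lapply(starts, function(s) {
      idx <- (round(s * fs) + 1):(round(s * fs) + nsamp)
      seg <- vals[idx[idx <= length(vals)]]
      seg <- c(seg, numeric(nsamp - length(seg))) # zero-pad final epoch
      seg * w
    })
  }
  out
}

#' Event-related (de)synchronisation time course
#'
#' Short-time band power `P(t)` relative to its mean over a baseline
#' interval: `ERD%(t) = 100 (P(t) - P_ref) / P_ref`. Negative values are
#' desynchronisation (ERD), positive synchronisation (ERS).
#'
#' @param stream raw or filtered EEG [sample_stream()].
#' @param band `c(lo, hi)` band of interest (Hz).
#' @param baseline `c(t0, t1)` baseline interval (s); should be
#'   artifact-free.
#' @param win,step short-time window length and hop (s).
#' @return data.frame with `t`, `power`, `erd`.
#' @export
spectrogram_erd <- function(stream, band = c(8, 12), baseline,
                            win = 1, step = 0.125) {
  fs <- stream_rate(stream)
  dur <- stream_duration(stream)
  t0 <- stream$t[1]
  centers <- seq(t0 + win / 2, t0 + dur - win / 2, by = step)
  nfft <- min(256, round(win * fs))
  pw <- vapply(centers, function(tc) {
    idx <- (round((tc - win / 2 - t0) * fs) + 1):round((tc + win / 2 - t0) * fs)
    sp <- welch_psd(stream[[2]][idx], fs, nfft = nfft)
    df <- sp$freq[2] - sp$freq[1]
    sum(sp$psd[sp$freq >= band[1] & sp$freq < band[2]]) * df
  }, numeric(1))
  ref_idx <- centers >= baseline[1] & centers <= baseline[2]
  if (!any(ref_idx)) stop("baseline interval contains no analysis windows")
  p_ref <- mean(pw[ref_idx])
  if (p_ref <= 0) stop("zero baseline power")
  data.frame(t = centers, power = pw, erd = 100 * (pw - p_ref) / p_ref)
}

#' Percent change of band power relative to a reference
#'
#' Convenience closed form used when constructing ERD examples:
#' `100 * (p - p_ref) / p_ref`.
#' @param p,p_ref band powers.
#' @export
erd_percent <- function(p, p_ref) {
  if (any(p_ref <= 0)) stop("zero baseline power")
  100 * (p - p_ref) / p_ref
}
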