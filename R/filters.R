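# Minimal IIR design machinery: Butterworth band-pass via the analog
# prototype -> lowpass-to-bandpass transform -> bilinear transform, the same
# construction used by the classic DSP references. Only what the EEG pipeline
# needs is implemented; this is not a general filter-design toolbox.

# polynomial with given roots, ascending order of z^-1 coefficients
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' Returns transfer-function coefficients for a zero-DC band-pass filter of
#' the given analog-prototype order (the digital filter has order
#' `2 * order`). Uses frequency pre-warping and the bilinear transform, so
#' coefficients match the conventional scipy/MATLAB `butter` design.
#'
#' @param order analog prototype order (4 gives the standard "4th-order"
#'   band-pass used for EEG conditioning).
#' @param lo,hi band edges in Hz.
#' @param fs sampling rate in Hz.
#' @return list with numerator `b` and denominator `a` (with `a[1] == 1`).
#' @export
butter_bandpass <- function(order, lo, hi, fs) {
  if (!(lo > 0 && hi > lo && hi < fs / 2)) {
    stop("band edges must satisfy 0 < lo < hi < fs/2")
  }
  fs2 <- 2 * fs
  wlo <- fs2 * tan(pi * lo / fs)
  whi <- fs2 * tan(pi * hi / fs)
  bw <- whi - wlo
  w0 <- sqrt(wlo * whi)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # LHP poles, |p|=1
  pb <- proto * bw / 2
  poles <- c(pb + sqrt(pb^2 - w0^2), pb - sqrt(pb^2 - w0^2))
  zeros <- rep(0 + 0i, order)
  gain <- bw^order
  # bilinear transform
  zd <- (fs2 + zeros) / (fs2 - zeros)
  pd <- (fs2 + poles) / (fs2 - poles)
  gd <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  zd <- c(zd, rep(-1 + 0i, length(poles) - length(zeros)))
  b <- Re(poly_from_roots(zd)) * gd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a / a[1])
}

iir_filter <- function(b, a, x, zi = NULL) {
  .iir_filter_cpp(as.numeric(b), as.numeric(a), as.numeric(x), zi)
}

# steady-state initial filter state for a unit-step input (direct form II
# transposed); removes start-up transients when scaled by the first sample
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  comp <- rbind(-a[-1] / a[1], cbind(diag(1, n - 2), 0))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(comp), B)
}

#' Zero-phase filtering (forward-backward)
#'
#' Applies the filter twice, once forward and once reversed, which cancels
#' phase distortion and squares the magnitude response. Ends are padded with
#' odd reflections and each pass starts from the step steady-state initial
#' conditions, so edge transients are suppressed even for filters with slow
#' poles.
#'
#' @param b,a transfer-function coefficients.
#' @param x numeric signal.
#' @export
filtfilt <- function(b, a, x) {
  npad <- 3 * (max(length(a), length(b)) - 1)
  n <- length(x)
  if (n <= npad) stop("signal shorter than filter warm-up (", npad, " samples)")
  ext <- c(
    2 * x[1] - x[(npad + 1):2],
    x,
    2 * x[n] - x[(n - 1):(n - npad)]
  )
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- rev(iir_filter(b, a, y, zi * y[1]))
  y[(npad + 1):(npad + n)]
}

# centred moving average with shrinking windows at the edges
centered_ma <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  half <- floor(k / 2)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}
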