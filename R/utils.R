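# Internal helpers shared across modules.

# Zero-phase band-pass via the squared Butterworth magnitude response applied
# in the frequency domain. Equivalent to an ideal forward-backward pass of the
# analog prototype; numerically robust even when lo/fs is tiny (0.01 Hz on a
# 60 s record), where recursive filtfilt realizations fail to settle.
fft_bandpass <- function(x, fs, lo, hi, order_lo = 2L, order_hi = 4L) {
  # reflect-pad so the circular FFT sees no boundary discontinuity
  npad <- min(length(x) - 1L, round(2 * fs))
  xp <- c(rev(x[seq_len(npad) + 1L]), x, x[length(x) - seq_len(npad)])
  n <- length(xp)
  f <- seq(0L, n - 1L) * fs / n
  f <- pmin(f, fs - f)              # fold to [0, fs/2]
  hp <- ifelse(f == 0, 0, 1 / (1 + (lo / pmax(f, .Machine$double.xmin))^(2 * order_lo)))
  lp <- 1 / (1 + (f / hi)^(2 * order_hi))
  out <- Re(stats::fft(stats::fft(xp) * hp * lp, inverse = TRUE)) / n
  out[npad + seq_along(x)]
}

# Derive a per-record seed from a global seed, staying inside 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) + 7919 * as.double(k)) %% 2147483629)
}

# Welch power spectral density: mean of Hann-windowed modified periodograms.
welch_psd <- function(x, fs, seg_sec = 2, overlap = 0.5) {
  nseg <- round(seg_sec * fs)
  if (length(x) < nseg) nseg <- length(x)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  u <- sum(w^2)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2 / (u * fs)
  }
  nf <- floor(nseg / 2) + 1L
  tibble::tibble(
    freq = (seq_len(nf) - 1L) * fs / nseg,
    power = (acc / length(starts))[seq_len(nf)]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
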