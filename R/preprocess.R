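#' Zero-phase band-pass filter for single-lead ECG
#'
#' Removes baseline drift and high-frequency noise with passband
#' `[lo, hi]` Hz (defaults 0.01--50 Hz). The filter is realized in the
#' frequency domain with the squared Butterworth magnitude response, which is
#' exactly zero-phase and removes DC completely; attenuation one octave
#' outside the passband exceeds 20 dB at the default orders.
#'
#' @param x Numeric voltage series (mV).
#' @param fs Sampling rate (Hz); must exceed `2 * hi`.
#' @param lo,hi Band edges in Hz.
#' @param order_lo,order_hi Butterworth orders of the high-pass and low-pass
#'   prototypes.
#' @return Filtered series, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, lo = 0.01, hi = 50,
                            order_lo = 2L, order_hi = 4L) {
  if (fs <= 2 * hi) stopf("invalid rate: fs (%g) must exceed 2*hi (%g)", fs, 2 * hi)
  fft_bandpass(x, fs, lo, hi, order_lo, order_hi)
}

#' Place R-wave fiducial markers at points of maximum absolute derivative
#'
#' Candidate beats are found by thresholding the absolute first difference at
#' `threshold_frac` of its 99th percentile; samples above threshold are
#' clustered, the fiducial of each cluster is the sample of maximum absolute
#' derivative, and a refractory period is enforced between fiducials.
#'
#' @param x Filtered voltage series.
#' @param fs Sampling rate (Hz).
#' @param threshold_frac Fraction of the 99th percentile of `|diff(x)|` used
#'   as detection threshold.
#' @param refractory Minimum spacing between fiducials, seconds.
#' @param min_beats Minimum number of beats required.
#' @return Integer vector of 1-based fiducial sample indices.
#' @export
detect_fiducials <- function(x, fs, threshold_frac = 0.4, refractory = 0.25,
                             min_beats = 5L) {
  d <- abs(diff(x))
  thr <- threshold_frac * stats::quantile(d, 0.99, names = FALSE)
  cand <- which(d > thr)
  refr <- round(refractory * fs)
  if (length(cand) == 0) stopf("insufficient beats: 0 detected (need >= %d)", min_beats)
  # cluster candidates separated by less than the refractory period
  brk <- c(0L, which(diff(cand) > refr), length(cand))
  fid <- integer(0)
  for (k in seq_len(length(brk) - 1L)) {
    grp <- cand[(brk[k] + 1L):brk[k + 1L]]
    fid <- c(fid, grp[which.max(d[grp])])
  }
  # enforce refractory between successive fiducials (keep the earlier one)
  keep <- c(TRUE, diff(fid) > refr)
  while (!all(keep)) {
    fid <- fid[keep]
    keep <- c(TRUE, diff(fid) > refr)
  }
  if (length(fid) < min_beats) {
    stopf("insufficient beats: %d detected (need >= %d)", length(fid), min_beats)
  }
  as.integer(fid)
}

#' Build the average QRST template
#'
#' Averages all complete beat windows (`pre` seconds before to `post` seconds
#' after each fiducial) pointwise. Beats whose window would cross the signal
#' boundary are excluded from the average.
#'
#' @param x Filtered voltage series.
#' @param fiducials Fiducial indices from [detect_fiducials()].
#' @param fs Sampling rate (Hz).
#' @param pre,post Window extent before/after the fiducial, seconds.
#' @return A `qrst_template`: list with `samples`, `pre_offset`, `post_offset`
#'   (offsets in samples).
#' @export
build_template <- function(x, fiducials, fs, pre = 0.12, post = 0.45,
                           align = 0.02) {
  if (length(fiducials) < 5) stopf("need at least 5 fiducials, got %d", length(fiducials))
  pre_n <- round(pre * fs)
  post_n <- round(post * fs)
  ok <- fiducials - pre_n >= 1L & fiducials + post_n <= length(x)
  if (!any(ok)) stopf("no complete beat windows inside the signal")
  grab <- function(fids) {
    vapply(fids, function(f) x[(f - pre_n):(f + post_n)],
           numeric(pre_n + post_n + 1L))
  }
  tmpl <- rowMeans(grab(fiducials[ok]))
  # Refinement pass: derivative-based fiducials jitter by a sample or two
  # when fibrillatory waves perturb the slope maximum, which smears the
  # average; re-align each beat to the provisional template at integer lags
  # before re-averaging.
  if (align > 0) {
    fid2 <- vapply(fiducials[ok], function(f) {
      as.integer(f) + best_lag(x, f, tmpl, pre_n, post_n, round(align * fs))
    }, numeric(1))
    ok2 <- fid2 - pre_n >= 1L & fid2 + post_n <= length(x)
    if (any(ok2)) tmpl <- rowMeans(grab(fid2[ok2]))
  }
  structure(list(samples = tmpl, pre_offset = pre_n, post_offset = post_n,
                 align_n = round(align * fs)),
            class = "qrst_template")
}

# Integer lag in [-max_lag, max_lag] maximizing the correlation between the
# beat window at fiducial f (shifted by the lag) and the template.
best_lag <- function(x, f, tmpl, pre_n, post_n, max_lag) {
  lags <- (-max_lag):max_lag
  cors <- vapply(lags, function(l) {
    a <- f + l - pre_n
    b <- f + l + post_n
    if (a < 1L || b > length(x)) return(-Inf)
    w <- x[a:b]
    if (stats::sd(w) == 0) return(-Inf)
    stats::cor(w, tmpl)
  }, numeric(1))
  if (all(!is.finite(cors))) return(0L)
  as.integer(lags[which.max(cors)])
}

#' Correlate each beat with the QRST template
#'
#' Each beat window is first re-aligned to the template at integer lags
#' within the template's alignment range (so that detector jitter of a
#' sample or two is not mistaken for a morphology change), then scored by
#' Pearson correlation.
#'
#' @param x Filtered voltage series.
#' @param fiducials Fiducial indices.
#' @param template A `qrst_template` from [build_template()].
#' @return A `beat_set` tibble with columns `fiducial` (alignment-refined)
#'   and `correlation` (Pearson r of the beat window with the template;
#'   boundary-truncated beats get `-Inf` and are always excluded downstream).
#' @export
score_beats <- function(x, fiducials, template) {
  al <- template$align_n %||% 0L
  scored <- lapply(fiducials, function(f) {
    a <- f - template$pre_offset
    b <- f + template$post_offset
    if (a < 1L || b > length(x)) return(list(f = f, r = -Inf))
    lag <- if (al > 0) best_lag(x, f, template$samples, template$pre_offset,
                                template$post_offset, al) else 0L
    a <- a + lag
    b <- b + lag
    if (a < 1L || b > length(x)) return(list(f = f, r = -Inf))
    w <- x[a:b]
    if (stats::sd(w) == 0) return(list(f = f, r = -Inf))
    list(f = f + lag, r = stats::cor(w, template$samples))
  })
  out <- tibble::tibble(fiducial = vapply(scored, function(s) as.integer(s$f), integer(1)),
                        correlation = vapply(scored, `[[`, numeric(1), "r"))
  class(out) <- c("beat_set", class(out))
  attr(out, "pre_offset") <- template$pre_offset
  attr(out, "post_offset") <- template$post_offset
  out
}

#' Select consistent-morphology segments by correlation gating
#'
#' Finds maximal runs of consecutive beats whose template correlation exceeds
#' `threshold`, converts each run to the sample range from the first retained
#' beat's window start to the last retained beat's window end, and discards
#' runs shorter than `min_duration` seconds.
#'
#' @param beats A `beat_set` from [score_beats()].
#' @param fs Sampling rate (Hz).
#' @param threshold Correlation gate (default 0.90).
#' @param min_duration Minimum segment length in seconds.
#' @return Tibble with columns `start_index`, `end_index` (1-based, inclusive).
#' @export
select_segments <- function(beats, fs, threshold = 0.90, min_duration = 10) {
  good <- beats$correlation > threshold
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pre_n <- attr(beats, "pre_offset")
  post_n <- attr(beats, "post_offset")
  out <- tibble::tibble(start_index = integer(0), end_index = integer(0))
  for (k in which(r$values)) {
    s <- beats$fiducial[starts[k]] - pre_n
    e <- beats$fiducial[ends[k]] + post_n
    if (e - s + 1L >= round(min_duration * fs)) {
      out <- tibble::add_row(out, start_index = as.integer(s), end_index = as.integer(e))
    }
  }
  out
}

#' Cancel ventricular activity by average beat subtraction
#'
#' For each beat with a complete window, fits `a * template + c` to the beat
#' by least squares (scale and offset) and subtracts the fit. Beats are
#' processed in temporal order on the running signal, so overlapping windows
#' at short RR intervals are handled sequentially. Samples outside every beat
#' window pass through unchanged.
#'
#' @param x Filtered voltage series.
#' @param beats A `beat_set` (only its fiducials and window geometry are used).
#' @param template A `qrst_template`.
#' @return Estimated atrial-activity series, same length as `x`.
#' @export
cancel_qrst <- function(x, beats, template) {
  tmpl <- template$samples
  vt <- stats::var(tmpl)
  if (vt == 0) stopf("singular fit: template has zero variance")
  tmpl_c <- tmpl - mean(tmpl)
  denom <- sum(tmpl_c^2)
  aa <- x
  for (f in beats$fiducial) {
    a0 <- f - template$pre_offset
    b0 <- f + template$post_offset
    if (a0 < 1L || b0 > length(x)) next
    w <- aa[a0:b0]
    a <- sum((w - mean(w)) * tmpl_c) / denom
    c0 <- mean(w) - a * mean(tmpl)
    aa[a0:b0] <- w - (a * tmpl + c0)
  }
  aa
}

#' Excess (Fisher) kurtosis
#'
#' `m4 / m2^2 - 3` with biased sample moments. Negative for sub-Gaussian,
#' sinusoid-like signals (a pure sinusoid gives -1.5), which is why a low
#' value indicates a clean fibrillatory excerpt free of ventricular residue.
#'
#' @param x Numeric series of length >= 4 with nonzero variance.
#' @return Scalar excess kurtosis.
#' @export
excess_kurtosis <- function(x) {
  if (length(x) < 4) stopf("need at least 4 samples")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stopf("zero variance")
  mean((x - m)^4) / m2^2 - 3
}

#' Pick the minimum-kurtosis excerpt
#'
#' Slides a `duration`-second window at `stride`-second steps within each
#' eligible segment and returns the window with the lowest excess kurtosis
#' (ties broken by earliest start).
#'
#' @param aa Estimated atrial-activity series.
#' @param segments Tibble from [select_segments()].
#' @param fs Sampling rate (Hz).
#' @param duration Excerpt length in seconds (default 10).
#' @param stride Search stride in seconds (default 1).
#' @param source_id Identifier carried into the result.
#' @return An `aa_segment`: list with `samples` (length `duration * fs`
#'   exactly), `fs`, `start_index`, `kurtosis`, `source_id`.
#' @export
pick_excerpt <- function(aa, segments, fs, duration = 10, stride = 1,
                         source_id = "record") {
  n_win <- round(duration * fs)
  best <- NULL
  for (k in seq_len(nrow(segments))) {
    s <- segments$start_index[k]
    e <- segments$end_index[k]
    if (e - s + 1L < n_win) next
    for (st in seq(s, e - n_win + 1L, by = round(stride * fs))) {
      kur <- excess_kurtosis(aa[st:(st + n_win - 1L)])
      if (is.null(best) || kur < best$kurtosis) {
        best <- list(start = st, kurtosis = kur)
      }
    }
  }
  if (is.null(best)) stopf("no clean segment of at least %g s available", duration)
  structure(
    list(samples = aa[best$start:(best$start + n_win - 1L)], fs = fs,
         start_index = best$start, kurtosis = best$kurtosis,
         source_id = source_id),
    class = "aa_segment"
  )
}

#' @export
print.aa_segment <- function(x, ...) {
  cat(sprintf("<aa_segment %s>  %.0f s @ %g Hz, start %d, excess kurtosis %.3f\n",
              x$source_id, length(x$samples) / x$fs, x$fs, x$start_index, x$kurtosis))
  invisible(x)
}

#' Extract the atrial-activity excerpt from a raw record
#'
#' Runs the full preprocessing chain: band-pass filtering, fiducial
#' detection, template construction, correlation gating, average beat
#' subtraction and kurtosis-based excerpt selection. With `gate = FALSE` the
#' correlation gate and kurtosis search are bypassed and a seeded random
#' `duration`-second window of the cancelled signal is returned instead
#' (useful to quantify how much the quality gating matters).
#'
#' @param record An `ecg_record` (or list with `samples` and `fs`).
#' @param threshold Correlation gate passed to [select_segments()].
#' @param duration,stride Excerpt search parameters, seconds.
#' @param gate Apply correlation gating and kurtosis selection?
#' @param seed Seed for the random window when `gate = FALSE`.
#' @param ... Passed to [detect_fiducials()].
#' @return An `aa_segment` with a `report` attribute: list with `n_beats`,
#'   `pct_low_cor`, `n_segments`, `segment_lengths_s`, `kurtosis`.
#' @export
extract_aa <- function(record, threshold = 0.90, duration = 10, stride = 1,
                       gate = TRUE, seed = 1L, ...) {
  fs <- record$fs
  filt <- bandpass_filter(record$samples, fs)
  fid <- detect_fiducials(filt, fs, ...)
  tmpl <- build_template(filt, fid, fs)
  beats <- score_beats(filt, fid, tmpl)
  aa <- cancel_qrst(filt, beats, tmpl)
  finite <- is.finite(beats$correlation)
  pct_low <- 100 * mean(beats$correlation[finite] <= threshold)
  if (gate) {
    segs <- select_segments(beats, fs, threshold = threshold, min_duration = duration)
    seg_out <- pick_excerpt(aa, segs, fs, duration = duration, stride = stride,
                            source_id = record$record_id %||% "record")
  } else {
    n_win <- round(duration * fs)
    if (length(aa) < n_win) stopf("record shorter than %g s", duration)
    st <- withr::with_seed(seed, sample.int(length(aa) - n_win + 1L, 1L))
    seg_out <- structure(
      list(samples = aa[st:(st + n_win - 1L)], fs = fs, start_index = st,
           kurtosis = excess_kurtosis(aa[st:(st + n_win - 1L)]),
           source_id = record$record_id %||% "record"),
      class = "aa_segment"
    )
    segs <- tibble::tibble(start_index = integer(0), end_index = integer(0))
  }
  attr(seg_out, "report") <- list(
    n_beats = nrow(beats),
    pct_low_cor = pct_low,
    n_segments = nrow(segs),
    segment_lengths_s = if (nrow(segs)) (segs$end_index - segs$start_index + 1) / fs else numeric(0),
    kurtosis = seg_out$kurtosis
  )
  seg_out
}

#' Correlation between an extracted excerpt and the generator's ground truth
#'
#' Only meaningful for synthetic records, which carry the true fibrillatory
#' component. The truth is band-passed the same way as the signal before
#' comparison so that the score reflects extraction quality, not filter
#' shape.
#'
#' @param record An `ecg_record` with `truth_aa`.
#' @param segment An `aa_segment` extracted from that record.
#' @return Pearson correlation between the excerpt and the co-located truth.
#' @export
aa_truth_correlation <- function(record, segment) {
  if (is.null(record$truth_aa)) stopf("record carries no ground-truth atrial activity")
  idx <- segment$start_index:(segment$start_index + length(segment$samples) - 1L)
  truth <- bandpass_filter(record$truth_aa, record$fs)[idx]
  stats::cor(segment$samples, truth)
}
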