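#' Configuration for the synthetic AF-ECG generator
#'
#' Bundles every knob of the single-lead atrial-fibrillation ECG simulator.
#' Records are built as a quasi-periodic QRST train with irregular RR
#' intervals, plus fibrillatory waves (a harmonic "sawtooth" series with a
#' random-walk phase, mixed with band-limited noise), sinusoidal baseline
#' wander and white measurement noise. The two organization knobs
#' (`phase_jitter_sd`, `broadband_frac`) control how narrowband the f-waves
#' are; class presets map AF-Free to organized values and AF-Relapse to
#' disorganized values (see [synthesize_record()]).
#'
#' @param fs Sampling rate in Hz.
#' @param duration Record length in seconds.
#' @param n_per_class Records per class generated by [synthesize_cohort()].
#' @param f0 Dominant atrial frequency in Hz (typical AF f-waves sit near 6 Hz).
#' @param f0_sd Per-record spread of the dominant rate in Hz; each record draws
#'   its own rate from `N(f0, f0_sd)` clipped to 4--9 Hz so the AFR comparator
#'   is informative but imperfect.
#' @param n_harmonics Number of harmonics in the f-wave series (amplitude of
#'   harmonic `h` falls off as `1/h`, the usual sawtooth surrogate).
#' @param fwave_amp Fundamental f-wave amplitude in mV.
#' @param phase_jitter_sd Standard deviation, in radians per sample, of the
#'   cumulative random-walk phase added to the f-wave (organization knob).
#' @param am_depth,am_freq Amplitude modulation of the harmonic f-wave
#'   component (depth as a fraction of the carrier, frequency in Hz);
#'   fibrillatory waves wax and wane on a respiratory time scale.
#' @param broadband_frac Fraction of total f-wave power drawn from band-limited
#'   (3--12 Hz) Gaussian noise (organization knob), in `[0, 1]`.
#' @param rr_mean,rr_sd Mean and sd of the RR interval in seconds. Intervals
#'   are Gaussian, floored at 0.3 s.
#' @param qrst_amp R-wave peak amplitude in mV.
#' @param wander_amp,wander_freq Baseline wander amplitude (mV) and frequency (Hz).
#' @param noise_sd White measurement-noise sd in mV.
#' @param altbeat_prob Probability that a beat uses the widened
#'   alternate QRST morphology (exercises the correlation gate).
#' @param seed Integer seed; every derived record seed is a deterministic
#'   function of it.
#'
#' @return A `synth_config` list.
#' @seealso [synthesize_record()], [synthesize_cohort()], [make_fwave()]
#' @export
#' @examples
#' cfg <- synth_config(duration = 10, n_per_class = 2)
#' cohort <- synthesize_cohort(cfg)
#' cohort
synth_config <- function(fs = 250, duration = 60, n_per_class = 20,
                         f0 = 6.2, f0_sd = 0.3, n_harmonics = 3,
                         fwave_amp = 0.05, phase_jitter_sd = 0.01,
                         broadband_frac = 0.1, am_depth = 0.8, am_freq = 0.25,
                         rr_mean = 0.8, rr_sd = 0.15,
                         qrst_amp = 1.0,
                         wander_amp = 0.01, wander_freq = 0.3,
                         noise_sd = 0.005, altbeat_prob = 0.05,
                         seed = 1L) {
  if (fs <= 0) stopf("fs must be positive")
  if (duration <= 0) stopf("duration must be positive")
  if (broadband_frac < 0 || broadband_frac > 1) stopf("broadband_frac must lie in [0, 1]")
  if (altbeat_prob < 0 || altbeat_prob >= 1) stopf("altbeat_prob must lie in [0, 1)")
  if (!(rr_mean > rr_sd) || rr_sd < 0) stopf("need rr_mean > rr_sd >= 0")
  structure(
    list(fs = fs, duration = duration, n_per_class = n_per_class,
         f0 = f0, f0_sd = f0_sd, n_harmonics = n_harmonics,
         fwave_amp = fwave_amp, phase_jitter_sd = phase_jitter_sd,
         broadband_frac = broadband_frac, am_depth = am_depth,
         am_freq = am_freq, rr_mean = rr_mean, rr_sd = rr_sd,
         qrst_amp = qrst_amp, wander_amp = wander_amp,
         wander_freq = wander_freq, noise_sd = noise_sd,
         altbeat_prob = altbeat_prob, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Organization presets keyed by class label (0 = AF-Free/organized,
# 1 = AF-Relapse/disorganized). The dominant-rate offset makes AFR a usable
# but weak predictor, as observed clinically.
class_preset <- function(label) {
  if (label == 0) {
    list(phase_jitter_sd = 0.01, broadband_frac = 0.1, f0 = 6.2)
  } else {
    list(phase_jitter_sd = 0.2, broadband_frac = 0.6, f0 = 6.6)
  }
}

#' Generate a synthetic fibrillatory wave
#'
#' Builds the atrial (f-wave) component alone: a sum over harmonics
#' `h = 1..n_harmonics` of `(fwave_amp/h) * sin(2*pi*h*f0*t + h*phi(t))`, where
#' `phi` is a cumulative Gaussian random-walk phase with per-sample sd
#' `phase_jitter_sd`, amplitude-modulated at `am_freq` with depth `am_depth`,
#' mixed with band-limited (3--12 Hz) Gaussian noise
#' carrying `broadband_frac` of the power. The output is zero-mean and its
#' mean-square power is rescaled to the pure-sawtooth power
#' `sum_h (fwave_amp/h)^2 / 2` regardless of the organization knobs.
#'
#' @param config A [synth_config()].
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @return Numeric vector of length `round(fs * duration)`, in mV.
#' @export
make_fwave <- function(config, seed = NULL) {
  if (config$n_harmonics < 1) stopf("n_harmonics must be >= 1")
  gen <- function() {
    n <- round(config$fs * config$duration)
    t <- (seq_len(n) - 1) / config$fs
    p_target <- sum((config$fwave_amp / seq_len(config$n_harmonics))^2) / 2
    if (p_target == 0) return(numeric(n))
    phi <- cumsum(stats::rnorm(n, 0, config$phase_jitter_sd))
    harm <- numeric(n)
    for (h in seq_len(config$n_harmonics)) {
      harm <- harm + (config$fwave_amp / h) * sin(2 * pi * h * config$f0 * t + h * phi)
    }
    if ((config$am_depth %||% 0) > 0) {
      harm <- harm * (1 + config$am_depth *
                        sin(2 * pi * config$am_freq * t + stats::runif(1, 0, 2 * pi)))
    }
    harm <- harm * sqrt((1 - config$broadband_frac) * p_target / max(mean(harm^2), 1e-300))
    out <- harm
    if (config$broadband_frac > 0) {
      bb <- fft_bandpass(stats::rnorm(n), config$fs, 3, 12, order_lo = 4L, order_hi = 4L)
      bb <- bb * sqrt(config$broadband_frac * p_target / max(mean(bb^2), 1e-300))
      out <- out + bb
    }
    out <- out - mean(out)
    out * sqrt(p_target / max(mean(out^2), 1e-300))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate irregular beat onset times
#'
#' RR intervals are drawn from a Gaussian with mean `rr_mean` and sd `rr_sd`,
#' floored at 0.3 s (physiological ventricular refractoriness), and summed
#' into onset times covering `[0, duration)`. The first onset is at 0 s.
#'
#' @inheritParams make_fwave
#' @return Numeric vector of beat onset times in seconds.
#' @export
make_rr_series <- function(config, seed = NULL) {
  if (config$rr_mean <= 0) stopf("rr_mean must be positive")
  gen <- function() {
    n_max <- ceiling(config$duration / 0.3) + 2L
    rr <- pmax(0.3, stats::rnorm(n_max, config$rr_mean, config$rr_sd))
    onsets <- c(0, cumsum(rr))
    onsets[onsets < config$duration]
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Sum-of-Gaussians QRST shape evaluated on a sample grid relative to the
# R peak (time 0). The alternate morphology is widened with a shifted T wave,
# mimicking an aberrantly conducted beat.
qrst_shape <- function(fs, qrst_amp, alternate = FALSE) {
  t <- seq(-0.10, 0.42, by = 1 / fs)
  # V1-like rS-with-inverted-T morphology; component areas nearly cancel so
  # the AC-coupled beat train sits on a negligible pedestal.
  comp <- if (!alternate) {
    list(c(-0.10, -0.035, 0.010), c(1.00, 0.000, 0.012),
         c(-0.35, 0.035, 0.012), c(-0.20, 0.250, 0.050))
  } else {
    list(c(-0.10, -0.045, 0.020), c(0.80, 0.000, 0.026),
         c(-0.50, 0.060, 0.025), c(-0.20, 0.330, 0.080))
  }
  y <- numeric(length(t))
  for (g in comp) y <- y + g[1] * exp(-(t - g[2])^2 / (2 * g[3]^2))
  list(t = t, y = y * qrst_amp)
}

#' Synthesize one single-lead AF ECG record
#'
#' Assembles QRST train + f-waves + baseline wander + white noise. The f-wave
#' component alone is stored as `truth_aa`, so atrial-activity extraction can
#' be scored against ground truth. When `apply_preset` is `TRUE` the
#' organization knobs and dominant rate are overridden by the class preset
#' for `label` (0 = organized/AF-Free, 1 = disorganized/AF-Relapse) and the
#' record draws its own dominant rate from `N(f0, f0_sd)` clipped to 4--9 Hz.
#'
#' @param config A [synth_config()].
#' @param label Class label: 0 (AF-Free), 1 (AF-Relapse), or `NA` (unknown).
#' @param seed Integer seed for this record.
#' @param record_id Identifier string.
#' @param apply_preset Override organization knobs from the class preset?
#' @return An `ecg_record`: list with `samples` (mV), `fs`, `record_id`,
#'   `label`, `truth_aa`, `beat_times` (s), `alt_beats` (logical flags for
#'   alternate-morphology beats), and `f0_used` (Hz).
#' @export
synthesize_record <- function(config, label = NA, seed = config$seed,
                              record_id = "synth-001",
                              apply_preset = !is.na(label)) {
  cfg <- config
  if (apply_preset) {
    if (!label %in% c(0, 1)) stopf("label must be 0 or 1 when apply_preset = TRUE")
    cfg[names(class_preset(label))] <- class_preset(label)
  }
  withr::with_seed(seed, {
    n <- round(cfg$fs * cfg$duration)
    t <- (seq_len(n) - 1) / cfg$fs
    onsets <- make_rr_series(cfg)
    alt <- stats::runif(length(onsets)) < cfg$altbeat_prob
    cfg$f0 <- min(9, max(4, stats::rnorm(1, cfg$f0, cfg$f0_sd)))
    aa <- make_fwave(cfg)
    qrst <- numeric(n)
    shapes <- list(qrst_shape(cfg$fs, cfg$qrst_amp, FALSE),
                   qrst_shape(cfg$fs, cfg$qrst_amp, TRUE))
    for (b in seq_along(onsets)) {
      sh <- shapes[[1 + alt[b]]]
      idx <- round(onsets[b] * cfg$fs) + 1L + round(sh$t * cfg$fs)
      keep <- idx >= 1L & idx <= n
      qrst[idx[keep]] <- qrst[idx[keep]] + sh$y[keep]
    }
    wander <- cfg$wander_amp * sin(2 * pi * cfg$wander_freq * t)
    noise <- if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else numeric(n)
    structure(
      list(samples = qrst + aa + wander + noise, fs = cfg$fs,
           record_id = record_id, label = label, truth_aa = aa,
           beat_times = onsets, alt_beats = alt, f0_used = cfg$f0),
      class = "ecg_record"
    )
  })
}

#' Synthesize a balanced labelled cohort
#'
#' Generates `2 * n_per_class` records with alternating labels. Record seeds
#' are derived deterministically from `config$seed` and the record index, so
#' growing `n_per_class` only appends records at the tail.
#'
#' @param config A [synth_config()].
#' @return A tibble with columns `record_id`, `label`, `seed`, `f0_used`, and
#'   a list-column `record` of `ecg_record` objects.
#' @export
synthesize_cohort <- function(config) {
  if (config$n_per_class < 1) stopf("n_per_class must be >= 1")
  idx <- seq_len(2L * config$n_per_class)
  labels <- (idx + 1L) %% 2L  # 0, 1, 0, 1, ...
  purrr::map2_dfr(idx, labels, function(i, lab) {
    sd_i <- derive_seed(config$seed, i)
    id <- sprintf("synth-%03d-%s", i, if (lab == 0) "free" else "relapse")
    rec <- synthesize_record(config, label = lab, seed = sd_i, record_id = id)
    tibble::tibble(record_id = id, label = lab, seed = sd_i,
                   f0_used = rec$f0_used, record = list(rec))
  })
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s>  %.1f s @ %g Hz, label = %s\n",
              x$record_id, length(x$samples) / x$fs, x$fs,
              if (is.na(x$label)) "unknown" else x$label))
  invisible(x)
}

#' Tabular view of an ECG record
#'
#' @param x An `ecg_record`.
#' @param ... Unused.
#' @return A tibble with `time_s`, `mV`, and (when ground truth is present)
#'   `truth_aa`.
#' @export
as_tibble.ecg_record <- function(x, ...) {
  out <- tibble::tibble(time_s = (seq_along(x$samples) - 1) / x$fs, mV = x$samples)
  if (!is.null(x$truth_aa)) out$truth_aa <- x$truth_aa
  out
}

#' Write / read an ECG record as two-column CSV with a JSON sidecar
#'
#' The CSV holds `time_s, mV`; the sidecar `<path>.json` records the sampling
#' rate, label, seed and generator configuration for provenance.
#'
#' @param record An `ecg_record`.
#' @param path Output CSV path.
#' @param config Optional [synth_config()] echoed into the sidecar.
#' @param seed Optional seed echoed into the sidecar.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path, config = NULL, seed = NULL) {
  utils::write.csv(as_tibble.ecg_record(record)[, c("time_s", "mV")],
                   path, row.names = FALSE)
  side <- list(fs = record$fs, record_id = record$record_id,
               label = record$label, seed = seed,
               config = if (!is.null(config)) unclass(config))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ecg_csv
#' @param fs Sampling rate in Hz; if `NULL`, inferred from the sidecar or the
#'   time column.
#' @export
read_ecg_csv <- function(path, fs = NULL) {
  d <- utils::read.csv(path)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
  if (is.null(fs)) fs <- side$fs %||% (1 / stats::median(diff(d$time_s)))
  structure(
    list(samples = d$mV, fs = fs,
         record_id = side$record_id %||% basename(path),
         label = side$label %||% NA, truth_aa = NULL),
    class = "ecg_record"
  )
}
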