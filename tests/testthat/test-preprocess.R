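fs <- 250

test_that("band-pass removes DC, keeps the f-wave band, rejects high frequencies", {
  t <- seq(0, 60, by = 1 / fs)
  expect_lt(max(abs(bandpass_filter(rep(1, length(t)), fs))), 1e-3)
  mid <- 3000:12000
  expect_equal(max(abs(bandpass_filter(sin(2 * pi * 10 * t), fs)[mid])), 1,
               tolerance = 0.05)
  expect_lt(max(abs(bandpass_filter(sin(2 * pi * 100 * t), fs)[mid])), 0.1)
  expect_error(bandpass_filter(rnorm(100), fs = 80), "invalid rate")
})

test_that("stopband attenuation exceeds 20 dB one octave outside the passband", {
  t <- seq(0, 600, by = 1 / fs)   # long record so 0.005 Hz completes cycles
  mid <- 50000:100000
  a100 <- max(abs(bandpass_filter(sin(2 * pi * 100 * t), fs)[mid]))
  expect_lt(20 * log10(a100), -20)
  a005 <- max(abs(bandpass_filter(sin(2 * pi * 0.005 * t), fs)[mid]))
  expect_lt(20 * log10(a005), -20)
})

test_that("fiducials land on every beat of a regular record", {
  rec <- synthesize_record(synth_config(duration = 30, rr_mean = 1, rr_sd = 0,
                                        altbeat_prob = 0),
                           label = 0, seed = 5, record_id = "t")
  fid <- detect_fiducials(bandpass_filter(rec$samples, fs), fs)
  expect_true(length(fid) %in% c(29, 30))
  expect_true(all(abs(diff(fid) - fs) <= 0.01 * fs))
})

test_that("a record without ventricular activity yields the insufficient-beats error", {
  rec <- synthesize_record(synth_config(duration = 30, qrst_amp = 0, am_depth = 0),
                           label = 0, seed = 3, record_id = "t")
  expect_error(detect_fiducials(bandpass_filter(rec$samples, fs), fs),
               "insufficient beats")
})

test_that("fiducials of normal beats sit within 20 ms of the true R peaks", {
  for (sd in 4:6) {
    rec <- synthesize_record(synth_config(duration = 30), label = sd %% 2,
                             seed = sd, record_id = "t")
    fid <- detect_fiducials(bandpass_filter(rec$samples, fs), fs)
    on <- round(rec$beat_times * fs) + 1
    nearest <- vapply(fid, function(x) which.min(abs(on - x)), integer(1))
    offs_ms <- (fid - on[nearest]) / fs * 1000
    normal <- !rec$alt_beats[nearest]
    expect_true(all(abs(offs_ms[normal]) <= 20))
    expect_equal(length(fid), length(on))
  }
})

test_that("template equals a single beat for identical noise-free beats", {
  rec <- synthesize_record(synth_config(duration = 30, rr_mean = 1, rr_sd = 0,
                                        altbeat_prob = 0, fwave_amp = 0,
                                        wander_amp = 0, noise_sd = 0),
                           label = 0, seed = 5, record_id = "t")
  x <- rec$samples  # unfiltered: beats are exactly identical
  fid <- round(rec$beat_times * fs) + 1
  fid <- fid[fid - 30 >= 1 & fid + 112 <= length(x)]
  tmpl <- build_template(x, fid, fs)
  beat <- x[(fid[3] - tmpl$pre_offset):(fid[3] + tmpl$post_offset)]
  expect_equal(tmpl$samples, beat, tolerance = 1e-12)
  expect_error(build_template(x, fid[1], fs), "at least 5 fiducials")
})

test_that("averaging suppresses additive noise at the root-n rate", {
  set.seed(31)
  beat <- qrst_ref <- afmp:::qrst_shape(fs, 1)$y
  n_beats <- 100
  gap <- 260
  x <- numeric(n_beats * gap + 200)
  fid <- integer(n_beats)
  for (k in seq_len(n_beats)) {
    at <- (k - 1) * gap + 50
    x[at:(at + length(beat) - 1)] <- beat
    fid[k] <- at + round(0.10 * fs)  # R peak position inside the shape
  }
  noise_sd <- 0.05
  xn <- x + rnorm(length(x), 0, noise_sd)
  tmpl <- build_template(xn, fid, fs, align = 0)
  clean <- build_template(x, fid, fs, align = 0)
  expect_true(all(abs(tmpl$samples - clean$samples) < 3 * noise_sd / sqrt(n_beats) * 3))
})

test_that("beat scoring is exact for template copies and their negation", {
  pre <- round(0.12 * fs); post <- round(0.45 * fs)
  len <- pre + post + 1
  shp <- afmp:::qrst_shape(fs, 1)$y
  tmpl_shape <- c(shp, numeric(len - length(shp)))
  x <- numeric(5 * 400)
  fids <- integer(0)
  for (k in 1:5) {
    at <- (k - 1) * 400 + 100
    sgn <- if (k == 3) -1 else 1
    x[at:(at + len - 1)] <- sgn * tmpl_shape[seq_len(len)]
    fids <- c(fids, at + pre)
  }
  tmpl <- structure(list(samples = tmpl_shape[seq_len(len)], pre_offset = pre,
                         post_offset = post, align_n = 0L),
                    class = "qrst_template")
  sc <- score_beats(x, fids, tmpl)
  expect_equal(sc$correlation[c(1, 2, 4, 5)], rep(1, 4), tolerance = 1e-12)
  expect_equal(sc$correlation[3], -1, tolerance = 1e-12)
})

test_that("alternate-morphology beats fall below the 90% correlation gate", {
  rec <- synthesize_record(synth_config(duration = 60, altbeat_prob = 0.2),
                           label = 0, seed = 9, record_id = "t")
  filt <- bandpass_filter(rec$samples, fs)
  fid <- detect_fiducials(filt, fs)
  tmpl <- build_template(filt, fid, fs)
  sc <- score_beats(filt, fid, tmpl)
  on <- round(rec$beat_times * fs) + 1
  is_alt <- rec$alt_beats[vapply(sc$fiducial, function(x) which.min(abs(on - x)),
                                 integer(1))]
  fin <- is.finite(sc$correlation)
  expect_true(all(sc$correlation[is_alt & fin] < 0.9))
  expect_gt(mean(sc$correlation[!is_alt & fin] > 0.9), 0.8)
})

test_that("segment gating matches a hand-rolled run-length scan", {
  mk_beats <- function(cors, spacing = 200) {
    b <- tibble::tibble(fiducial = seq_along(cors) * spacing, correlation = cors)
    class(b) <- c("beat_set", class(b))
    attr(b, "pre_offset") <- 30L
    attr(b, "post_offset") <- 112L
    b
  }
  b1 <- mk_beats(rep(0.95, 20))
  expect_equal(nrow(select_segments(b1, fs, min_duration = 10)), 1)

  b2 <- mk_beats(c(.95, .95, .5, .95, .95, .95))
  segs <- select_segments(b2, fs, min_duration = 0)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$start_index[2], 4 * 200 - 30)

  set.seed(12)
  for (rep in 1:20) {
    cors <- runif(40, 0.5, 1)
    segs <- select_segments(mk_beats(cors), fs, threshold = 0.9, min_duration = 0)
    runs <- rle(cors > 0.9)
    expect_equal(nrow(segs), sum(runs$values & runs$lengths >= 1))
  }
})

test_that("average beat subtraction cancels a pure template train exactly", {
  p <- preprocessed_record()
  pre <- p$tmpl$pre_offset; post <- p$tmpl$post_offset
  x <- numeric(6 * 400)
  fids <- integer(0)
  for (k in 1:6) {
    at <- (k - 1) * 400 + 100
    amp <- if (k == 2) 2 else 1   # scaling must be fitted per beat
    x[at:(at + pre + post)] <- amp * p$tmpl$samples
    fids <- c(fids, at + pre)
  }
  beats <- tibble::tibble(fiducial = fids, correlation = rep(1, 6))
  aa <- cancel_qrst(x, beats, p$tmpl)
  expect_lt(max(abs(aa)), 1e-8 * max(abs(p$tmpl$samples)))

  flat <- structure(list(samples = rep(1, pre + post + 1), pre_offset = pre,
                         post_offset = post), class = "qrst_template")
  expect_error(cancel_qrst(x, beats, flat), "zero variance")
})

test_that("cancellation recovers a known f-wave to within a third of its RMS", {
  cfg <- synth_config(duration = 60, seed = 5, noise_sd = 0, wander_amp = 0,
                      altbeat_prob = 0)
  rec <- synthesize_record(cfg, label = 0, seed = 5, record_id = "t")
  filt <- bandpass_filter(rec$samples, fs)
  fid <- detect_fiducials(filt, fs)
  tmpl <- build_template(filt, fid, fs)
  beats <- score_beats(filt, fid, tmpl)
  aa <- cancel_qrst(filt, beats, tmpl)
  truth <- bandpass_filter(rec$truth_aa, fs)
  inwin <- rep(FALSE, length(filt))
  for (f in beats$fiducial[is.finite(beats$correlation)]) {
    if (f - tmpl$pre_offset >= 1 && f + tmpl$post_offset <= length(filt)) {
      inwin[(f - tmpl$pre_offset):(f + tmpl$post_offset)] <- TRUE
    }
  }
  err <- (aa - truth)[inwin]
  expect_lt(sd(err), 0.30 * sd(truth[inwin]))
  # and the ventricular component itself is almost entirely gone
  qrst_only <- filt - truth
  expect_lt(mean((aa - truth)[inwin]^2), 0.01 * mean(qrst_only[inwin]^2))
})

test_that("excess kurtosis matches closed forms", {
  x <- sin(2 * pi * seq(0, 1000 - 1 / fs, by = 1 / fs))
  expect_equal(excess_kurtosis(x), -1.5, tolerance = 0.01)
  set.seed(77)
  expect_equal(excess_kurtosis(rnorm(1e5)), 0, tolerance = 0.1)
  expect_error(excess_kurtosis(rep(2, 100)), "zero variance")
  expect_error(excess_kurtosis(c(1, 2)), "at least 4")
})

test_that("the excerpt picker avoids spiky windows and returns exact lengths", {
  set.seed(5)
  aa <- rnorm(40 * fs, 0, 0.05)
  aa[seq(25 * fs, 26 * fs)] <- aa[seq(25 * fs, 26 * fs)] + rt(fs + 1, df = 2) * 0.4
  segs <- tibble::tibble(start_index = 1L, end_index = length(aa))
  pick <- pick_excerpt(aa, segs, fs, duration = 10, stride = 1)
  expect_equal(length(pick$samples), 10 * fs)
  # oracle: enumerate all windows, every burst-containing one must be worse
  starts <- seq(1, length(aa) - 10 * fs + 1, by = fs)
  kur <- vapply(starts, function(s) excess_kurtosis(aa[s:(s + 10 * fs - 1)]),
                numeric(1))
  expect_equal(pick$start_index, starts[which.min(kur)])
  burst_windows <- starts[starts <= 26 * fs & starts + 10 * fs - 1 >= 25 * fs]
  expect_true(all(pick$kurtosis <
                    kur[starts %in% burst_windows]))

  single <- tibble::tibble(start_index = 101L, end_index = 100L + 10L * fs)
  p2 <- pick_excerpt(aa, single, fs)
  expect_identical(p2$samples, aa[101:(100 + 10 * fs)])
  expect_error(pick_excerpt(aa, tibble::tibble(start_index = 1L, end_index = 50L), fs),
               "no clean segment")
})

test_that("the full extraction chain reports and recovers the atrial activity", {
  p <- preprocessed_record()
  seg <- extract_aa(p$rec)
  rep <- attr(seg, "report")
  expect_equal(length(seg$samples), 10 * fs)
  expect_gte(rep$n_segments, 1)
  expect_equal(rep$n_beats, length(p$fid))
  expect_gt(aa_truth_correlation(p$rec, seg), 0.8)
})
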