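# Independent brute-force oracles and shared fixtures.

# Exhaustive greedy matching pursuit: recomputes every inner product by a
# naive dot-product loop at every iteration. Deliberately independent of the
# package's update machinery.
oracle_greedy <- function(x, dict, iters) {
  res <- x - mean(x)
  out <- vector("list", iters)
  for (m in seq_len(iters)) {
    best <- NULL
    for (key in names(dict$atoms)) {
      a <- dict$atoms[[key]]
      ips <- vapply(seq_len(a$n_shifts),
                    function(T) sum(res[T:(T + a$len - 1)] * a$w), numeric(1))
      Tb <- which.max(abs(ips))
      if (is.null(best) || abs(ips[Tb]) > abs(best$ip)) {
        best <- list(key = key, T = Tb, ip = ips[Tb])
      }
    }
    a <- dict$atoms[[best$key]]
    res[best$T:(best$T + a$len - 1)] <- res[best$T:(best$T + a$len - 1)] - best$ip * a$w
    out[[m]] <- best
  }
  out
}

# Exact two-sided Mann-Whitney P by enumeration of all C(n, nA) labelings.
oracle_mwu_exact <- function(a, b) {
  na <- length(a)
  n <- na + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  us <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Pairwise-comparison probability (rank form of the AUC).
oracle_auc_pairs <- function(labels, scores) {
  p1 <- scores[labels == 1]
  p0 <- scores[labels == 0]
  tot <- 0
  for (v in p1) tot <- tot + sum(v > p0) + 0.5 * sum(v == p0)
  tot / (length(p1) * length(p0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Memoized expensive fixtures shared across test files.
.fixtures <- new.env(parent = emptyenv())

default_run <- function() {
  if (is.null(.fixtures$run)) {
    .fixtures$run <- suppressWarnings(run_all(pipeline_config()))
  }
  .fixtures$run
}

small_pipeline_config <- function(out_dir = NULL) {
  pipeline_config(
    synth = synth_config(n_per_class = 3, duration = 50, seed = 42),
    max_iter = 150L, seed = 42, out_dir = out_dir
  )
}

# A 60 s default-preset record plus its preprocessing chain, reused by
# several preprocessing tests.
preprocessed_record <- function() {
  if (is.null(.fixtures$prep)) {
    rec <- synthesize_record(synth_config(duration = 60, seed = 7), label = 0,
                             seed = 42, record_id = "fix-01")
    filt <- bandpass_filter(rec$samples, rec$fs)
    fid <- detect_fiducials(filt, rec$fs)
    tmpl <- build_template(filt, fid, rec$fs)
    beats <- score_beats(filt, fid, tmpl)
    .fixtures$prep <- list(rec = rec, filt = filt, fid = fid,
                           tmpl = tmpl, beats = beats)
  }
  .fixtures$prep
}
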