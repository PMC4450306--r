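#' Greedy matching-pursuit decomposition
#'
#' Iteratively selects the atom with the largest absolute inner product with
#' the running residue, records the signed expansion coefficient
#' `b_m = <R, A>`, and updates `R <- R - b_m * A`. Ties are broken
#' deterministically by family order, then scale, then shift. The signal is
#' mean-removed before decomposition.
#'
#' Stopping: with `use_fixed_M = TRUE` (the default) the pursuit runs for
#' `max_iter` iterations; otherwise it stops as soon as
#' `|b_m| / |b_1| < coeff_ratio_stop`. Either way it stops early if the
#' residue is exhausted (`b_m == 0`).
#'
#' The default engine (`method = "fast"`) updates inner products
#' incrementally from precomputed atom cross-correlation tables, touching
#' only shifts whose support overlaps the subtracted atom; `method =
#' "direct"` recomputes every inner product each iteration. Both give the
#' same pursuit to floating-point accuracy.
#'
#' @param x Numeric series of length `dict$signal_length`; must be nonzero
#'   and free of NA.
#' @param dict An [build_dictionary()] dictionary.
#' @param max_iter Fixed number of iterations `M` (default 1000).
#' @param coeff_ratio_stop Ratio threshold for the alternative stopping rule.
#' @param use_fixed_M Use the fixed-`M` rule (`TRUE`) or the coefficient-ratio
#'   rule (`FALSE`)?
#' @param method `"fast"` or `"direct"`.
#' @return An `mp_result`: list with `selections` (tibble: `iter`, `wavelet`,
#'   `scale`, `shift`, `coeff`, `residual_energy`), `residue` (final residual
#'   series), `energy_trace` (residual energy after each iteration), `b1`,
#'   `M_done`, and `dict_info`.
#' @export
#' @examples
#' d <- build_dictionary(64, fs = 250, scales = 0:2)
#' x <- 3 * c(d$atoms$coif1_s1$w, numeric(64 - d$atoms$coif1_s1$len))
#' r <- mp_decompose(x, d, max_iter = 1)
#' tidy(r)
mp_decompose <- function(x, dict, max_iter = 1000L, coeff_ratio_stop = 0.05,
                         use_fixed_M = TRUE, method = c("fast", "direct")) {
  method <- match.arg(method)
  if (anyNA(x)) stopf("input contains NA")
  if (length(x) != dict$signal_length) {
    stopf("signal length %d != dictionary signal length %d",
          length(x), dict$signal_length)
  }
  if (max_iter < 1) stopf("max_iter must be >= 1")
  if (coeff_ratio_stop <= 0 || coeff_ratio_stop >= 1) {
    stopf("coeff_ratio_stop must lie in (0, 1)")
  }
  if (sum(x^2) == 0) stopf("zero signal cannot be decomposed")

  res <- x - mean(x)
  e0 <- sum(res^2)
  keys <- names(dict$atoms)
  ip <- all_inner_products(res, dict)
  gram <- if (method == "fast") atom_gram(dict) else NULL

  sel_key <- character(max_iter)
  sel_shift <- integer(max_iter)
  sel_coeff <- numeric(max_iter)
  energy <- numeric(max_iter)
  b1 <- NA_real_
  m_done <- 0L
  e_run <- e0

  for (m in seq_len(max_iter)) {
    best_val <- -1
    best_k <- 0L
    best_t <- 0L
    for (k in seq_along(keys)) {
      tk <- which.max(abs(ip[[k]]))
      vk <- abs(ip[[k]][tk])
      if (vk > best_val) {
        best_val <- vk
        best_k <- k
        best_t <- tk
      }
    }
    b <- ip[[best_k]][best_t]
    if (b == 0) break
    key <- keys[best_k]
    a <- dict$atoms[[key]]
    res[best_t:(best_t + a$len - 1L)] <-
      res[best_t:(best_t + a$len - 1L)] - b * a$w
    e_run <- e_run - b^2
    m_done <- m
    sel_key[m] <- key
    sel_shift[m] <- best_t
    sel_coeff[m] <- b
    energy[m] <- max(e_run, 0)
    if (m == 1L) b1 <- abs(b)

    if (method == "fast") {
      gp <- gram[[key]]
      for (k in seq_along(keys)) {
        aq <- dict$atoms[[keys[k]]]
        t_lo <- max(1L, best_t - aq$len + 1L)
        t_hi <- min(aq$n_shifts, best_t + a$len - 1L)
        if (t_lo > t_hi) next
        idx <- t_lo:t_hi
        ip[[k]][idx] <- ip[[k]][idx] - b * gp[[keys[k]]][idx - best_t + aq$len]
      }
    } else {
      ip <- all_inner_products(res, dict)
    }

    if (!use_fixed_M && abs(b) / b1 < coeff_ratio_stop) break
  }

  keep <- seq_len(m_done)
  fam <- vapply(dict$atoms[sel_key[keep]], `[[`, character(1), "family")
  scl <- vapply(dict$atoms[sel_key[keep]], `[[`, integer(1), "scale")
  structure(
    list(
      selections = tibble::tibble(
        iter = keep, wavelet = unname(fam), scale = unname(scl),
        shift = sel_shift[keep], coeff = sel_coeff[keep],
        residual_energy = energy[keep]
      ),
      residue = res, energy_trace = energy[keep], b1 = b1, M_done = m_done,
      dict_info = list(families = dict$families, scales = dict$scales,
                       signal_length = dict$signal_length, fs = dict$fs)
    ),
    class = "mp_result"
  )
}

#' @export
print.mp_result <- function(x, ...) {
  cat(sprintf("<mp_result>  %d iterations, |b1| = %.4g, residual energy = %.4g\n",
              x$M_done, x$b1, x$energy_trace[x$M_done]))
  invisible(x)
}

#' Reconstruct the signal contribution of a subset of (wavelet, scale) pairs
#'
#' Sums `b_m * A` over all selections whose (wavelet, scale) pair is in
#' `which`. Passing every pair reproduces `x - mean(x) - residue`.
#'
#' @param result An `mp_result`.
#' @param dict The dictionary used for the decomposition.
#' @param which Character vector of atom keys like `"coif1_s0"`, or a data
#'   frame with `wavelet` and `scale` columns.
#' @return Numeric series of length `dict$signal_length`.
#' @export
reconstruct_subset <- function(result, dict, which) {
  if (is.data.frame(which)) {
    which <- sprintf("%s_s%d", which$wavelet, which$scale)
  }
  out <- numeric(dict$signal_length)
  sel <- result$selections
  keys <- sprintf("%s_s%d", sel$wavelet, sel$scale)
  for (m in base::which(keys %in% which)) {
    a <- dict$atoms[[keys[m]]]
    t0 <- sel$shift[m]
    out[t0:(t0 + a$len - 1L)] <- out[t0:(t0 + a$len - 1L)] + sel$coeff[m] * a$w
  }
  out
}
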