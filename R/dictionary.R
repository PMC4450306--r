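# Base quadrature-mirror filters (decomposition low-pass taps; standard
# published constants). The wavelet atom at scale 0 is the reconstruction
# high-pass rec_hi[k] = (-1)^k dec_lo[k], unit-normalized.
.wavelet_filters <- list(
  coif1 = c(-0.015655728135791993, -0.07273261951252645, 0.38486484686485778,
            0.85257202021160039, 0.33789766245748182, -0.07273261951252645),
  sym2  = c(-0.12940952255092145, 0.22414386804185735, 0.83651630373746899,
            0.48296291314469025)
)

base_atom <- function(family) {
  h <- .wavelet_filters[[family]]
  if (is.null(h)) stopf("unknown wavelet family '%s'", family)
  g <- h * (-1)^(seq_along(h) - 1)   # rec_hi by the QMF relation
  g / sqrt(sum(g^2))
}

.cascade_cache <- new.env(parent = emptyenv())

# High-resolution cascade approximation of the wavelet function psi on the
# dyadic grid 2^-J over its support [0, L-1] (standard cascade algorithm:
# start from the wavelet filter, repeatedly upsample and refine with the
# scaling filter).
cascade_psi <- function(family, J = 10L) {
  key <- sprintf("%s_%d", family, J)
  if (!is.null(.cascade_cache[[key]])) return(.cascade_cache[[key]])
  g <- base_atom(family)
  h <- .wavelet_filters[[family]]
  v <- g
  for (k in seq_len(J - 1L)) {
    up <- numeric(2 * length(v) - 1)
    up[seq(1, length(up), by = 2)] <- v
    v <- stats::convolve(up, h, type = "open")  # refine with the reconstruction low-pass
  }
  out <- c(0, v, numeric((length(g) - 1) * 2^J + 1 - length(v) - 1))
  .cascade_cache[[key]] <- out
  out
}

# Scale-s atom: dyadic dilation of the cascade-refined wavelet, i.e. psi
# sampled every 2^(J-s) points of the high-resolution grid, giving length
# (L-1)*2^s + 1. Scale 0 is the wavelet filter itself (the level-0 cascade),
# which keeps its exact orthogonality to even translates.
cascade_atom <- function(family, s) {
  g <- base_atom(family)
  if (s == 0) return(g)
  J <- 10L
  psi <- cascade_psi(family, J)
  psi[seq(1L, by = 2L^(J - s), length.out = (length(g) - 1) * 2^s + 1)]
}

#' Build the shift-invariant wavelet atom dictionary
#'
#' One unit-norm atom waveform per (family, scale) pair; the dictionary spans
#' all temporal shifts with full support inside the signal. The scale-`s`
#' atom is the cascade-refined wavelet waveform dilated dyadically, of length
#' `(L - 1) * 2^s + 1` where `L` is the base filter length (so
#' `len(s+1) = 2 len(s) - 1`). Scale 0 is the finest (shortest) atom, scale 5
#' the coarsest.
#'
#' @param signal_length Length of the signals to decompose, in samples.
#' @param fs Sampling rate (Hz), carried along for reporting.
#' @param families Character vector of wavelet families; `"coif1"` and
#'   `"sym2"` are available.
#' @param scales Integer vector of dyadic scales (default `0:5`).
#' @return An `mp_dictionary`: environment-backed list with per-atom
#'   waveforms, nonzero tap positions, and valid shift counts.
#' @export
build_dictionary <- function(signal_length, fs = NA_real_,
                             families = c("coif1", "sym2"), scales = 0:5) {
  atoms <- list()
  for (fam in families) {
    for (s in scales) {
      w <- cascade_atom(fam, s)
      w <- w / sqrt(sum(w^2))
      key <- sprintf("%s_s%d", fam, s)
      nz <- which(w != 0)
      atoms[[key]] <- list(
        family = fam, scale = s, w = w, len = length(w),
        nz_idx = nz, nz_val = w[nz],
        n_shifts = signal_length - length(w) + 1L
      )
    }
  }
  max_len <- max(vapply(atoms, `[[`, integer(1), "len"))
  if (signal_length < max_len) {
    stopf("signal too short: %d samples < largest atom length %d",
          signal_length, max_len)
  }
  structure(
    list(families = families, scales = scales, fs = fs,
         signal_length = as.integer(signal_length), atoms = atoms,
         cache = new.env(parent = emptyenv())),
    class = "mp_dictionary"
  )
}

#' @export
print.mp_dictionary <- function(x, ...) {
  cat(sprintf("<mp_dictionary>  %d atoms (%s x scales %s), signal length %d\n",
              length(x$atoms), paste(x$families, collapse = "+"),
              paste(range(x$scales), collapse = "-"), x$signal_length))
  invisible(x)
}

#' Inner products of a residue with every atom at every valid shift
#'
#' Exact time-domain sliding dot products (the dilated atoms have only a few
#' nonzero taps, so this is both exact and fast). Shift `T` (1-based) places
#' the atom support at samples `T .. T + len - 1`.
#'
#' @param residue Numeric series of length `dict$signal_length`.
#' @param dict An `mp_dictionary`.
#' @return Named list, one numeric vector of length `n_shifts` per atom key.
#' @export
all_inner_products <- function(residue, dict) {
  if (length(residue) != dict$signal_length) {
    stopf("residue length %d != dictionary signal length %d",
          length(residue), dict$signal_length)
  }
  lapply(dict$atoms, function(a) {
    acc <- numeric(a$n_shifts)
    for (j in seq_along(a$nz_idx)) {
      p <- a$nz_idx[j]
      acc <- acc + a$nz_val[j] * residue[p:(p + a$n_shifts - 1L)]
    }
    acc
  })
}

# Cross-correlation tables between every atom pair: gram[[p]][[q]] is indexed
# by lag = T_q - T_p + len_q, covering lags -(len_q-1) .. (len_p-1). Cached in
# the dictionary environment; used for the incremental inner-product update.
atom_gram <- function(dict) {
  if (!is.null(dict$cache$gram)) return(dict$cache$gram)
  keys <- names(dict$atoms)
  gram <- list()
  for (p in keys) {
    ap <- dict$atoms[[p]]
    gp <- list()
    for (q in keys) {
      aq <- dict$atoms[[q]]
      # entry at index l + len_q holds sum_i ap[i] * aq[i - l]
      gp[[q]] <- stats::convolve(ap$w, aq$w, type = "open")
    }
    gram[[p]] <- gp
  }
  dict$cache$gram <- gram
  gram
}
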