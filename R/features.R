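#' Occupancy matrices of an MP decomposition
#'
#' One binary matrix per wavelet type: rows are scales 0..5, columns are
#' temporal locations (shift of the atom support start), and a cell is 1 iff
#' some pursuit iteration selected an atom of that type, scale and location.
#' Repeated selections of the same atom set the cell once.
#'
#' @param result An `mp_result`.
#' @return An `occupancy_matrix`: named list of binary matrices (one per
#'   family), each `length(scales) x signal_length`, with scales as rownames.
#' @export
occupancy <- function(result) {
  info <- result$dict_info
  out <- lapply(info$families, function(fam) {
    m <- matrix(0L, nrow = length(info$scales), ncol = info$signal_length,
                dimnames = list(paste0("s", info$scales), NULL))
    sel <- result$selections[result$selections$wavelet == fam, ]
    if (nrow(sel)) {
      m[cbind(match(sel$scale, info$scales), sel$shift)] <- 1L
    }
    m
  })
  names(out) <- info$families
  structure(out, class = "occupancy_matrix")
}

#' Occupancy features: per-(wavelet, scale) counts summed over time
#'
#' @param occ An [occupancy()] matrix set.
#' @return Named numeric vector of 12 counts, e.g. `mpf_coif1_s0`.
#' @export
occupancy_features <- function(occ) {
  out <- unlist(lapply(names(occ), function(fam) {
    v <- rowSums(occ[[fam]])
    names(v) <- sprintf("mpf_%s_%s", fam, names(v))
    v
  }))
  out
}

#' Decomposition decay-rate feature
#'
#' `ln(|b_M| / |b_1|)` where `b_1` and `b_M` are the first and last expansion
#' coefficients. Organized atrial activity is captured by few atoms, so its
#' coefficients decay fast and the feature is strongly negative; disorganized
#' activity decays slowly.
#'
#' @param result An `mp_result` with at least 2 iterations.
#' @return Scalar, always `<= 0` for a greedy pursuit.
#' @export
residue_feature <- function(result) {
  if (result$M_done < 2) stopf("need at least 2 pursuit iterations")
  if (result$b1 == 0) stopf("first coefficient is zero")
  log(abs(result$selections$coeff[result$M_done]) / result$b1)
}

#' Extract the 13 MP features for one record
#'
#' Twelve occupancy counts (2 wavelet types x 6 scales) plus the decay
#' feature `mpf_residue`.
#'
#' @param result An `mp_result`.
#' @param record_id,label Carried into the output row.
#' @return One-row tibble: `record_id`, `label`, `mpf_coif1_s0` ..
#'   `mpf_sym2_s5`, `mpf_residue`.
#' @export
extract_features <- function(result, record_id = "record", label = NA) {
  feats <- occupancy_features(occupancy(result))
  tibble::tibble(record_id = record_id, label = label,
                 !!!as.list(feats), mpf_residue = residue_feature(result))
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from rank sums with midranks for ties. The P value is exact
#' by enumeration of all group labelings when `nA + nB <= 12` and there are
#' no ties; otherwise a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b Numeric samples for the two groups.
#' @return Tibble with `U` (statistic of the first group), `p.value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' mwu_test(c(1, 2), c(3, 4))  # exact two-sided P = 1/3
mwu_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stopf("both groups must be nonempty")
  na <- length(a)
  nb <- length(b)
  n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (n <= 12 && !ties) {
    combos <- utils::combn(n, na)
    us <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    p <- 2 * min(mean(us <= u), mean(us >= u))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tt <- table(r)
    tie_term <- sum(tt^3 - tt) / (n * (n - 1))
    s2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (s2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(s2)
      if (abs(u - mu) < 0.5) z <- 0
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal"
  }
  tibble::tibble(U = u, p.value = min(p, 1), method = method)
}

# Feature columns of a feature table, in canonical order.
feature_cols <- function(features) {
  grep("^mpf_", names(features), value = TRUE)
}

#' Screen MP features with the Mann-Whitney U test
#'
#' Tests each feature between the two label groups and marks those with
#' `P < alpha` as selected. No multiple-testing correction is applied; the
#' screen is exploratory and the classifier sees only the surviving features.
#'
#' @param features Feature tibble from [extract_features()] rows (must have a
#'   `label` column with both classes present).
#' @param alpha Two-sided significance threshold (default 0.05).
#' @return Tibble with one row per feature: `feature`, `U`, `p.value`,
#'   `selected`.
#' @export
select_features <- function(features, alpha = 0.05) {
  if (length(unique(features$label[!is.na(features$label)])) < 2) {
    stopf("both classes must be present")
  }
  cols <- feature_cols(features)
  purrr::map_dfr(cols, function(cl) {
    g0 <- features[[cl]][features$label == 0]
    g1 <- features[[cl]][features$label == 1]
    tst <- mwu_test(g0, g1)
    tibble::tibble(feature = cl, U = tst$U, p.value = tst$p.value,
                   selected = tst$p.value < alpha)
  })
}

#' P value of the normalized expansion coefficient at every iteration
#'
#' For each pursuit iteration `m`, tests `ln(|b_m| / |b_1|)` between the two
#' classes with the Mann-Whitney U test. Used to examine how many iterations
#' are needed before the decay rate separates the classes.
#'
#' @param results List of `mp_result` objects (one per record).
#' @param labels Class labels (0/1), same length as `results`.
#' @return Tibble with `iter` and `p.value`, one row per iteration up to the
#'   shortest decomposition.
#' @export
decay_pvalue_curve <- function(results, labels) {
  if (length(results) != length(labels)) stopf("results and labels differ in length")
  if (length(unique(labels)) < 2 || min(table(labels)) < 2) {
    stopf("need at least 2 records per class")
  }
  m_min <- min(vapply(results, `[[`, integer(1), "M_done"))
  lb <- vapply(results, function(r) {
    log(pmax(abs(r$selections$coeff[seq_len(m_min)]), 1e-300) / r$b1)
  }, numeric(m_min))
  if (m_min == 1L) lb <- matrix(lb, nrow = 1)
  purrr::map_dfr(seq_len(m_min), function(m) {
    tibble::tibble(iter = m,
                   p.value = mwu_test(lb[m, labels == 0], lb[m, labels == 1])$p.value)
  })
}
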