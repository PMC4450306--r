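#' Fit a quadratic (or linear) discriminant model
#'
#' Gaussian class-conditional classifier: per-class sample means and
#' covariances (QDA) or a pooled covariance (LDA), priors from class
#' frequencies. A small ridge `lambda * mean(diag(S))` is added to each
#' covariance diagonal so the fit stays well-posed when the training class is
#' barely larger than the feature count.
#'
#' @param x Numeric matrix or data frame of features (rows = subjects).
#' @param y Class labels (two classes; coded by sorted unique value, the
#'   larger one is "class 1").
#' @param ridge Covariance regularization: `"lw"` (default) applies
#'   Ledoit-Wolf optimal shrinkage toward a scaled identity, which is
#'   parameter-free and appropriate when the per-class sample size barely
#'   exceeds the feature count; a number applies a fixed relative ridge
#'   `ridge * mean(diag(S))` instead.
#' @param pool Pool covariances (LDA) instead of per-class (QDA)?
#' @return A `qda_model`: list with per-class `prior`, `mean`, `cov`, plus
#'   bookkeeping.
#' @export
fit_qda <- function(x, y, ridge = "lw", pool = FALSE) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  if (length(classes) != 2) stopf("need exactly 2 classes, got %d", length(classes))
  if (min(table(y)) < 2) stopf("need at least 2 samples per class")
  parts <- lapply(classes, function(cl) {
    xi <- x[y == cl, , drop = FALSE]
    cov_i <- if (identical(ridge, "lw")) lw_cov(xi) else stats::cov(xi)
    list(prior = nrow(xi) / nrow(x), mean = colMeans(xi), cov = cov_i)
  })
  if (pool) {
    ns <- table(y)[as.character(classes)]
    pooled <- Reduce(`+`, Map(function(p, n) p$cov * (n - 1), parts, ns)) /
      (nrow(x) - 2)
    for (k in seq_along(parts)) parts[[k]]$cov <- pooled
  }
  for (k in seq_along(parts)) {
    s <- parts[[k]]$cov
    lam <- if (identical(ridge, "lw")) 1e-8 else ridge
    lam <- lam * max(mean(diag(s)), .Machine$double.eps)
    parts[[k]]$cov <- s + diag(lam, nrow(s))
  }
  names(parts) <- as.character(classes)
  structure(list(classes = classes, parts = parts, d = ncol(x),
                 features = colnames(x), pool = pool),
            class = "qda_model")
}

# Ledoit-Wolf (2004) shrinkage of the sample covariance toward a scaled
# identity; the shrinkage intensity is estimated from the data, so the
# estimator has no free parameter.
lw_cov <- function(xi) {
  n <- nrow(xi)
  d <- ncol(xi)
  xc <- sweep(xi, 2, colMeans(xi))
  s <- crossprod(xc) / n
  m <- sum(diag(s)) / d
  d2 <- sum((s - diag(m, d))^2)
  bbar <- 0
  for (k in seq_len(n)) bbar <- bbar + sum((tcrossprod(xc[k, ]) - s)^2)
  bbar <- bbar / n^2
  b2 <- min(bbar, d2)
  rho <- if (d2 > 0) b2 / d2 else 1
  shrunk <- rho * diag(m, d) + (1 - rho) * s
  # rescale MLE to the unbiased convention used elsewhere
  shrunk * n / max(n - 1, 1)
}

log_mvnorm <- function(x, mu, sigma) {
  ch <- chol(sigma)
  z <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(ch))) - length(mu) / 2 * log(2 * pi)
}

#' Posterior probability of class 1
#'
#' `P(1 | x)` under the fitted Gaussian class-conditional model, computed via
#' log densities for numerical stability.
#'
#' @param model A [fit_qda()] model.
#' @param x Numeric vector (one subject) or matrix (one row per subject).
#' @return Numeric vector of posteriors in `[0, 1]`.
#' @export
posterior <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != model$d) {
    stopf("feature dimension %d does not match model dimension %d", ncol(x), model$d)
  }
  apply(x, 1, function(xi) {
    lp <- vapply(model$parts, function(p) {
      log(p$prior) + log_mvnorm(xi, p$mean, p$cov)
    }, numeric(1))
    lp <- lp - max(lp)
    exp(lp[2]) / sum(exp(lp))
  })
}

#' @export
predict.qda_model <- function(object, newdata, ...) {
  tibble::tibble(posterior = posterior(object, newdata))
}

#' Leave-one-out cross-validated posteriors
#'
#' For each subject, fits the discriminant model on the remaining `n - 1`
#' subjects and records the posterior probability of class 1 for the held-out
#' subject. Feature screening can run inside each training fold (`selection =
#' "inside"`, the default, which keeps the held-out subject out of the
#' screen), once on the full cohort (`"outside"`), or not at all (`"none"`).
#' If no feature passes `alpha` in a fold, the single feature with the
#' smallest P value is used.
#'
#' @param features Feature tibble with `record_id`, `label`, and `mpf_*`
#'   columns (or columns named in `feature_cols`).
#' @param feature_cols Character vector of feature columns to consider;
#'   defaults to every `mpf_*` column.
#' @param selection `"inside"`, `"outside"`, or `"none"`.
#' @param alpha Screening threshold.
#' @param classifier `"qda"` or `"lda"`.
#' @param ridge Passed to [fit_qda()].
#' @return A `cv_result` tibble: `record_id`, `label`, `posterior`; the
#'   selection mode and per-fold feature counts are attached as attributes.
#' @export
loocv <- function(features, feature_cols = NULL,
                  selection = c("inside", "outside", "none"), alpha = 0.05,
                  classifier = c("qda", "lda"), ridge = "lw") {
  selection <- match.arg(selection)
  classifier <- match.arg(classifier)
  cols <- feature_cols %||% grep("^mpf_", names(features), value = TRUE)
  n <- nrow(features)
  if (n < 4) stopf("need at least 4 subjects")
  if (min(table(features$label)) < 2) stopf("need at least 2 subjects per class")
  pick <- function(dat) {
    if (selection == "none") return(cols)
    sel <- select_features(dat[, c("label", cols)], alpha = alpha)
    if (any(sel$selected)) sel$feature[sel$selected] else sel$feature[which.min(sel$p.value)]
  }
  fixed <- if (selection == "outside") pick(features) else NULL
  out <- purrr::map_dfr(seq_len(n), function(i) {
    train <- features[-i, ]
    if (length(unique(train$label)) < 2) {
      stopf("training fold %d contains a single class", i)
    }
    use <- fixed %||% pick(train)
    mod <- fit_qda(as.matrix(train[, use]), train$label, ridge = ridge,
                   pool = classifier == "lda")
    tibble::tibble(record_id = features$record_id[i],
                   label = features$label[i],
                   posterior = posterior(mod, as.matrix(features[i, use])),
                   n_features = length(use))
  })
  class(out) <- c("cv_result", class(out))
  attr(out, "selection") <- selection
  attr(out, "classifier") <- classifier
  attr(out, "features_considered") <- cols
  attr(out, "features_fixed") <- fixed
  out
}

#' ROC curve, AUC and Youden-optimal operating point
#'
#' Sweeps every distinct posterior as a decision threshold (predict class 1
#' when `posterior >= threshold`), computes sensitivity and specificity, the
#' trapezoid AUC (equal to the pairwise rank statistic `U / (n0 * n1)` up to
#' tie handling), and the operating point maximizing Youden's
#' `J = sens + spec - 1` (ties resolved toward higher sensitivity).
#'
#' @param cv A [loocv()] result, or any tibble with `label` and `posterior`.
#' @return A `roc_result`: list with `curve` (tibble: `threshold`,
#'   `sensitivity`, `specificity`), `auc`, `best` (threshold, sensitivity,
#'   specificity), and the input posteriors.
#' @export
roc_auc <- function(cv) {
  lab <- cv$label
  p <- cv$posterior
  if (length(unique(lab)) < 2) stopf("both classes must be present")
  ths <- c(sort(unique(p)), Inf)
  curve <- purrr::map_dfr(ths, function(t) {
    tibble::tibble(threshold = t,
                   sensitivity = mean(p[lab == 1] >= t),
                   specificity = mean(p[lab == 0] < t))
  })
  fpr <- 1 - curve$specificity
  tpr <- curve$sensitivity
  o <- order(fpr, tpr)
  fpr <- c(0, fpr[o], 1)
  tpr <- c(0, tpr[o], 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- curve$sensitivity + curve$specificity - 1
  cand <- which(j == max(j))
  best <- cand[which.max(curve$sensitivity[cand])]
  structure(
    list(curve = curve, auc = auc,
         best = list(threshold = curve$threshold[best],
                     sensitivity = curve$sensitivity[best],
                     specificity = curve$specificity[best]),
         posteriors = tibble::as_tibble(cv[, intersect(c("record_id", "label", "posterior"),
                                                       names(cv))])),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result>  AUC = %.3f; best operating point: sens %.0f%%, spec %.0f%% @ %.3g\n",
              x$auc, 100 * x$best$sensitivity, 100 * x$best$specificity,
              x$best$threshold))
  invisible(x)
}

#' Dominant atrial fibrillatory rate (AFR)
#'
#' Frequency of maximum Welch power (2 s Hann segments, 50% overlap) within
#' the fibrillatory band, by default 3--12 Hz.
#'
#' @param aa An `aa_segment` or numeric series.
#' @param fs Sampling rate (Hz); taken from the segment if omitted.
#' @param band Search band in Hz.
#' @param seg_sec Welch segment length in seconds.
#' @return Dominant frequency in Hz.
#' @export
afr <- function(aa, fs = NULL, band = c(3, 12), seg_sec = 2) {
  x <- if (inherits(aa, "aa_segment")) aa$samples else aa
  fs <- fs %||% (if (inherits(aa, "aa_segment")) aa$fs else NULL)
  if (is.null(fs)) stopf("sampling rate required")
  psd <- welch_psd(x, fs, seg_sec = seg_sec)
  inband <- psd[psd$freq >= band[1] & psd$freq <= band[2], ]
  if (nrow(inband) == 0 || max(inband$power) <= 0) {
    stopf("flat spectrum in the %g-%g Hz band", band[1], band[2])
  }
  inband$freq[which.max(inband$power)]
}
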