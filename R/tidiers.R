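#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy an MP decomposition into its selection table
#'
#' @param x An `mp_result`.
#' @param ... Unused.
#' @return Tibble with `iter`, `wavelet`, `scale`, `shift`, `coeff`,
#'   `residual_energy`.
#' @export
tidy.mp_result <- function(x, ...) x$selections

#' One-row summary of an MP decomposition
#'
#' @inheritParams tidy.mp_result
#' @return Tibble with `M_done`, `b1`, `final_energy`, `energy_fraction`
#'   (residual energy over initial), and `mpf_residue`.
#' @export
glance.mp_result <- function(x, ...) {
  e0 <- x$energy_trace[1] + x$selections$coeff[1]^2
  tibble::tibble(
    M_done = x$M_done, b1 = x$b1,
    final_energy = x$energy_trace[x$M_done],
    energy_fraction = x$energy_trace[x$M_done] / e0,
    mpf_residue = if (x$M_done >= 2) residue_feature(x) else NA_real_
  )
}

#' Tidy a ROC result into its curve
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' One-row ROC summary
#'
#' @inheritParams tidy.roc_result
#' @return Tibble with `auc`, `sensitivity`, `specificity`, `threshold` (at
#'   the Youden-optimal point).
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, sensitivity = x$best$sensitivity,
                 specificity = x$best$specificity, threshold = x$best$threshold)
}

#' Tidy a fitted discriminant model
#'
#' @param x A `qda_model`.
#' @param ... Unused.
#' @return Tibble with one row per (class, feature): `class`, `feature`,
#'   `mean`, `variance`, and the class `prior`.
#' @export
tidy.qda_model <- function(x, ...) {
  purrr::map_dfr(names(x$parts), function(cl) {
    p <- x$parts[[cl]]
    tibble::tibble(class = cl,
                   feature = x$features %||% paste0("x", seq_len(x$d)),
                   mean = unname(p$mean), variance = unname(diag(p$cov)),
                   prior = p$prior)
  })
}

#' One-row summary of a pipeline run
#'
#' @param x An `afmp_run`.
#' @param ... Unused.
#' @return Tibble with cohort size, selected-feature count, AUC of the MP
#'   pipeline and of the AFR comparator, best sens/spec, and the decay-feature
#'   P value.
#' @export
glance.afmp_run <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$features),
    n_selected = sum(x$selection$selected),
    auc = x$roc$auc, auc_afr = x$afr_roc$auc,
    sensitivity = x$roc$best$sensitivity,
    specificity = x$roc$best$specificity,
    decay_p = x$decay_p
  )
}

#' Plot an ECG record
#'
#' @param object An `ecg_record`.
#' @param window Time window in seconds to display (default first 10 s).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ecg_record <- function(object, window = c(0, 10), ...) {
  d <- as_tibble(object)
  d <- d[d$time_s >= window[1] & d$time_s <= window[2], ]
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s, .data$mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude (mV)",
                  title = object$record_id) +
    ggplot2::theme_minimal()
}

#' Plot the residual-energy decay of an MP decomposition
#'
#' @param object An `mp_result`.
#' @param ... Unused.
#' @return A ggplot of `|b_m| / |b_1|` against iteration, log scale.
#' @export
autoplot.mp_result <- function(object, ...) {
  d <- tibble::tibble(iter = object$selections$iter,
                      ratio = abs(object$selections$coeff) / object$b1)
  ggplot2::ggplot(d, ggplot2::aes(.data$iter, .data$ratio)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration m", y = "|b_m| / |b_1|") +
    ggplot2::theme_minimal()
}

#' Plot occupancy matrices
#'
#' Black marks show where the pursuit selected atoms of each wavelet type,
#' by scale (rows) and temporal location (columns).
#'
#' @param object An `occupancy_matrix`.
#' @param fs Optional sampling rate to express locations in seconds.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.occupancy_matrix <- function(object, fs = NULL, ...) {
  d <- purrr::map_dfr(names(object), function(fam) {
    idx <- which(object[[fam]] == 1L, arr.ind = TRUE)
    tibble::tibble(family = fam,
                   scale = rownames(object[[fam]])[idx[, 1]],
                   location = idx[, 2])
  })
  if (!is.null(fs)) d$location <- d$location / fs
  ggplot2::ggplot(d, ggplot2::aes(.data$location, .data$scale)) +
    ggplot2::geom_point(shape = 16, size = 0.6) +
    ggplot2::facet_wrap(~family, ncol = 1) +
    ggplot2::labs(x = if (is.null(fs)) "location (samples)" else "location (s)",
                  y = "scale") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot with the Youden-optimal point marked.
#' @export
autoplot.roc_result <- function(object, ...) {
  d <- object$curve
  ggplot2::ggplot(d, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::annotate("point", x = 1 - object$best$specificity,
                      y = object$best$sensitivity, colour = "red", size = 2) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a feature distribution by class
#'
#' @param features A feature tibble (rows = records).
#' @param which Character vector of feature columns; defaults to all.
#' @return A ggplot of per-class boxplots, one facet per feature.
#' @export
plot_features <- function(features, which = NULL) {
  cols <- which %||% grep("^mpf_", names(features), value = TRUE)
  d <- tidyr::pivot_longer(features[, c("label", cols)], -"label",
                           names_to = "feature", values_to = "value")
  d$label <- factor(d$label, levels = c(0, 1), labels = c("AF-Free", "AF-Relapse"))
  ggplot2::ggplot(d, ggplot2::aes(.data$label, .data$value, fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
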