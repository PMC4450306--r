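test_that("posteriors match the closed-form Gaussian Bayes rule on a toy geometry", {
  mu0 <- c(0, 0); mu1 <- c(2, 1)
  s0 <- matrix(c(1, 0.3, 0.3, 1), 2)
  s1 <- matrix(c(1.5, -0.2, -0.2, 0.8), 2)
  # construct samples whose moments are exactly (mu, s): use sqrtm trick
  mk <- function(mu, s, n = 40, seed = 1) {
    set.seed(seed)
    z <- matrix(rnorm(n * 2), n)
    z <- sweep(z, 2, colMeans(z))
    z <- z %*% solve(chol(stats::cov(z)))
    sweep(z %*% chol(s), 2, mu, `+`)
  }
  x <- rbind(mk(mu0, s0, seed = 1), mk(mu1, s1, seed = 2))
  y <- rep(0:1, each = 40)
  m <- fit_qda(x, y, ridge = 0)
  dens <- function(xx, mu, s) {
    exp(-0.5 * mahalanobis(matrix(xx, 1), mu, s)) / (2 * pi * sqrt(det(s)))
  }
  for (pt in list(c(0, 0), c(1, 0.5), c(3, -1), c(-2, 2))) {
    bayes <- 0.5 * dens(pt, mu1, s1) /
      (0.5 * dens(pt, mu0, s0) + 0.5 * dens(pt, mu1, s1))
    expect_equal(unname(posterior(m, pt)), bayes, tolerance = 1e-8)
  }
})

test_that("equal-covariance classes give a linear decision function", {
  set.seed(3)
  x0 <- matrix(rnorm(60), 30)
  x0 <- sweep(x0, 2, colMeans(x0))
  x1 <- sweep(x0, 2, c(2, 2), `+`)   # same sample covariance by construction
  m <- fit_qda(rbind(x0, x1), rep(0:1, each = 30), ridge = 0)
  # log-odds along a line must be linear: second differences vanish
  pts <- seq(-2, 4, length.out = 9)
  lo <- vapply(pts, function(t) {
    p <- posterior(m, c(t, t))
    log(p / (1 - p))
  }, numeric(1))
  expect_lt(max(abs(diff(diff(lo)))), 1e-8)
  # midpoint of two symmetric classes sits at posterior one half
  expect_equal(unname(posterior(m, c(1, 1))), 0.5, tolerance = 1e-8)
})

test_that("posteriors agree with MASS::qda and flip under label swap", {
  skip_if_not_installed("MASS")
  set.seed(7)
  x <- rbind(matrix(rnorm(80), 40), matrix(rnorm(80, 1.5), 40))
  y <- rep(0:1, each = 40)
  m <- fit_qda(x, y, ridge = 0)
  ref <- MASS::qda(x, grouping = y)
  newx <- matrix(rnorm(20, 0.7), 10)
  expect_equal(unname(posterior(m, newx)),
               unname(predict(ref, newx)$posterior[, "1"]), tolerance = 1e-6)

  m_sw <- fit_qda(x, 1 - y, ridge = 0)
  expect_equal(posterior(m_sw, newx), 1 - posterior(m, newx), tolerance = 1e-10)

  expect_error(posterior(m, c(1, 2, 3)), "dimension")
  expect_error(fit_qda(x, rep(0, 80)), "2 classes")
})

test_that("well-separated classes drive posteriors to the correct extremes", {
  set.seed(11)
  x <- rbind(matrix(rnorm(40, 0, 0.1), 20), matrix(rnorm(40, 5, 0.1), 20))
  y <- rep(0:1, each = 20)
  m <- fit_qda(x, y)
  expect_gt(unname(posterior(m, colMeans(x[y == 1, ]))), 0.99)
  expect_lt(unname(posterior(m, colMeans(x[y == 0, ]))), 0.01)
})

test_that("leave-one-out cross-validation holds each subject out once", {
  set.seed(13)
  n <- 16
  feats <- tibble::tibble(
    record_id = sprintf("r%02d", 1:n),
    label = rep(0:1, each = n / 2),
    mpf_a = rep(c(0, 4), each = n / 2) + rnorm(n, 0, 0.2),
    mpf_b = rnorm(n)
  )
  cv <- loocv(feats, selection = "none")
  expect_equal(nrow(cv), n)
  expect_identical(cv$record_id, feats$record_id)
  correct <- ifelse(cv$label == 1, cv$posterior > 0.5, cv$posterior < 0.5)
  expect_true(all(correct))

  expect_error(loocv(feats[1:3, ]), "at least 4")
})

test_that("permuted labels yield chance-level cross-validated AUC", {
  set.seed(17)
  n <- 16
  base <- tibble::tibble(
    record_id = sprintf("r%02d", 1:n),
    mpf_a = rnorm(n), mpf_b = rnorm(n)
  )
  aucs <- vapply(1:50, function(k) {
    set.seed(1000 + k)
    feats <- base
    feats$label <- sample(rep(0:1, each = n / 2))
    roc_auc(loocv(feats, selection = "none"))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("ROC handles perfect, chance, and tied scores; AUC equals the rank statistic", {
  perfect <- tibble::tibble(label = rep(0:1, each = 5),
                            posterior = c(runif(5, 0, 0.4), runif(5, 0.6, 1)))
  r <- roc_auc(perfect)
  expect_equal(r$auc, 1)
  expect_equal(r$best$sensitivity, 1)
  expect_equal(r$best$specificity, 1)

  inter <- tibble::tibble(label = rep(0:1, 10), posterior = rep(seq(0.05, 0.95, 0.1), each = 2))
  expect_equal(roc_auc(inter)$auc, 0.5, tolerance = 1e-12)

  set.seed(19)
  for (rep in 1:10) {
    lab <- sample(0:1, 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    sc <- round(runif(30), 2)  # ties on purpose
    expect_equal(roc_auc(tibble::tibble(label = lab, posterior = sc))$auc,
                 oracle_auc_pairs(lab, sc), tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC and is invariant under monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(23)
  lab <- rep(0:1, each = 15)
  sc <- rnorm(30) + lab
  mine <- roc_auc(tibble::tibble(label = lab, posterior = plogis(sc)))$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lab, plogis(sc), quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-10)
  trans <- roc_auc(tibble::tibble(label = lab, posterior = plogis(sc)^3))$auc
  expect_equal(mine, trans, tolerance = 1e-12)
})

test_that("AFR finds the dominant fibrillatory rate inside the 3-12 Hz band", {
  fs <- 250
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  expect_equal(afr(sin(2 * pi * 6.5 * t), fs), 6.5, tolerance = 0.5)
  # strong out-of-band tone must not distract the estimator
  x <- 5 * sin(2 * pi * 20 * t) + 0.3 * sin(2 * pi * 6 * t)
  expect_equal(afr(x, fs), 6, tolerance = 0.5)
  expect_error(afr(numeric(2500), fs), "flat spectrum")

  # a seeded organized record estimates its own dominant rate
  cfg <- synth_config(duration = 60, f0 = 6.0, f0_sd = 0,
                      phase_jitter_sd = 0.01, broadband_frac = 0.1)
  rec <- synthesize_record(cfg, label = 0, seed = 77, record_id = "t",
                           apply_preset = FALSE)
  seg <- extract_aa(rec)
  expect_equal(afr(seg), 6.0, tolerance = 0.3)
})

test_that("tidiers expose fitted models and ROC results as tibbles", {
  set.seed(29)
  x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 2), 20))
  y <- rep(0:1, each = 20)
  m <- fit_qda(x, y)
  td <- tidy(m)
  expect_equal(nrow(td), 4)   # 2 classes x 2 features
  expect_true(all(c("class", "feature", "mean", "variance", "prior") %in% names(td)))

  cv <- tibble::tibble(label = y, posterior = plogis(x[, 1]))
  r <- roc_auc(cv)
  expect_equal(glance(r)$auc, r$auc)
  expect_s3_class(tidy(r), "tbl_df")
})
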