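test_that("ROC sweep equals the Mann-Whitney rank formulation", {
  set.seed(30)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n)
    if (runif(1) < 0.3) scores <- round(scores, 1)  # force ties
    r <- roc_analysis(scores, labels)
    expect_equal(r$auc, r$auc_rank, tolerance = 1e-12)
    expect_equal(r$auc, auc_oracle(scores, labels), tolerance = 1e-12)
  }
})

test_that("ROC handles perfect, null and printed cases", {
  labels <- c(0, 0, 1, 1)
  expect_identical(roc_analysis(labels, labels)$auc, 1)
  r <- roc_analysis(c(0.1, 0.4, 0.35, 0.8), labels)
  expect_equal(r$auc, 0.75, tolerance = 1e-12)
  set.seed(31)
  null_auc <- roc_analysis(rnorm(2000), rbinom(2000, 1, 0.5))$auc
  expect_equal(null_auc, 0.5, tolerance = 0.05)
  expect_error(roc_analysis(rnorm(5), rep(1, 5)), "both classes")
  # operating point
  op <- roc_analysis(c(0.2, 0.3, 0.6, 0.9), labels, threshold = 0.5)
  expect_identical(op$sensitivity, 1)
  expect_identical(op$specificity, 1)
  # curve is a step function from (0,0) to (1,1)
  expect_identical(c(r$roc$fpr[1], r$roc$tpr[1]), c(0, 0))
  expect_identical(c(rev(r$roc$fpr)[1], rev(r$roc$tpr)[1]), c(1, 1))
  expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  # hand case
  p <- c(0.001, 0.01, 0.02, 0.04, 0.05)
  expect_equal(stats::p.adjust(p, method = "BH"),
               c(0.005, 0.025, 1 / 30, 0.05, 0.05), tolerance = 1e-12)
  set.seed(32)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_equal(stats::p.adjust(p, method = "BH"), bh_oracle(p),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap CI filter excludes gross outliers and keeps bounds ordered", {
  set.seed(33)
  excluded <- replicate(50, {
    vals <- c(rnorm(17), 10)
    f <- bootstrap_ci_filter(vals, n_boot = 400)
    !(10 %in% f$retained) && f$lower <= f$upper &&
      all(f$retained %in% vals)
  })
  expect_gte(mean(excluded), 0.9)
  same <- bootstrap_ci_filter(rep(3, 10))
  expect_identical(same$retained, rep(3, 10))
  expect_identical(c(same$lower, same$upper), c(3, 3))
  expect_error(bootstrap_ci_filter(c(1, 2)), "at least 3")
})

make_cohort_table <- function(n_ad = 17, n_hc = 18, shift = 0, sd = 1,
                              phase = "task", seed = 1) {
  set.seed(seed)
  n <- n_ad + n_hc
  group <- rep(c(1, 0), c(n_ad, n_hc))
  tab <- data.frame(subject_id = sprintf("S%02d", 1:n), group = group,
                    age = rnorm(n, 68, 9), phase = phase,
                    stringsAsFactors = FALSE)
  for (f in feature_names()) {
    tab[[f]] <- rnorm(n, sd = sd) + shift * group
    tab[[paste0("valid_", f)]] <- TRUE
  }
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

test_that("t-tests report pooled statistics with BH-adjusted q-values", {
  tab <- make_cohort_table(shift = 0.8, seed = 40)
  res <- ttests_fdr(tab, "task", ci_filter = FALSE)
  expect_identical(nrow(res), 17L)
  expect_true(all(res$q >= res$p - 1e-12))
  expect_true(all(res$q <= 1 & res$p >= 0))
  expect_true(all(sign(res$cohen_d) == sign(res$t)))
  expect_true(all(res$df == res$n_ad + res$n_hc - 2))
  # identical groups: t = 0, p = 1, d = 0
  tab0 <- make_cohort_table(shift = 0, seed = 41)
  for (f in feature_names()) tab0[[f]] <- rep(c(1, 2), 35 / 2 + 1)[1:35]
  tab0$group <- rep(c(1, 0), c(17, 18))
  for (f in feature_names()) tab0[[f]] <- tab0[[f]][c(1:35)]
  # construct exactly mirrored groups
  vals <- c(rnorm(17), rnorm(18))
  for (f in feature_names()) {
    tab0[[f]][tab0$group == 1] <- vals[1:17][1:17]
    tab0[[f]][tab0$group == 0] <- c(vals[1:17], mean(vals[1:17]))
  }
  res0 <- ttests_fdr(tab0, "task", ci_filter = FALSE)
  expect_true(all(abs(res0$t) < 1e-8))
  expect_true(all(res0$p > 0.999))
  expect_true(all(abs(res0$cohen_d) < 1e-8))
  # well-separated groups: huge effects after BH
  tabx <- make_cohort_table(shift = 0, seed = 42)
  for (f in feature_names()) {
    tabx[[f]] <- ifelse(tabx$group == 1, 1, 0) + rnorm(35, sd = 1e-3)
  }
  resx <- ttests_fdr(tabx, "task", ci_filter = FALSE)
  expect_true(all(abs(resx$cohen_d) > 10))
  expect_true(all(resx$q < 0.05))
})

test_that("LOOCV GLM classification scores out of sample", {
  # one perfectly separating feature
  tab <- make_cohort_table(shift = 0, seed = 50)
  tab$sampen_o2hb <- ifelse(tab$group == 1, 1, 0) + rnorm(35, sd = 0.01)
  res <- glm_loocv_classify(tab, "fNIRS", "task")
  expect_identical(res$auc, 1)
  expect_length(res$beta, 3L)  # intercept + 2 features
  expect_identical(length(res$scores), 35L)
  # pure-noise features give near-chance AUC on average
  set.seed(51)
  aucs <- replicate(50, {
    tabn <- make_cohort_table(shift = 0, seed = sample.int(1e6, 1))
    glm_loocv_classify(tabn, "EEG", "task")$auc
  })
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
  # collinear design handled by pseudo-inverse with identical scores
  tabc <- make_cohort_table(shift = 0.5, seed = 52)
  tabc$sampen_hhb <- tabc$sampen_o2hb  # duplicate column
  w <- capture_warnings(resc <- glm_loocv_classify(tabc, "fNIRS", "task"))
  expect_true(any(grepl("pseudo-inverse", w)))
  ref <- suppressWarnings(glm_loocv_classify(
    within(tabc, sampen_hhb <- sampen_o2hb / 2), "fNIRS", "task"))
  expect_equal(resc$scores, ref$scores, tolerance = 1e-8)
})

test_that("LOOCV scores are invariant to affine feature rescaling", {
  tab <- make_cohort_table(shift = 0.6, seed = 53)
  base <- glm_loocv_classify(tab, "NC", "task")
  tab$conden_o2hb_alpha <- 100 * tab$conden_o2hb_alpha - 7
  rescaled <- glm_loocv_classify(tab, "NC", "task")
  expect_equal(base$scores, rescaled$scores, tolerance = 1e-8)
})

test_that("paired AUC comparison behaves like a DeLong test", {
  tab <- make_cohort_table(shift = 0, seed = 60)
  tab$sampen_o2hb <- ifelse(tab$group == 1, 1, 0) + rnorm(35, sd = 0.05)
  good <- glm_loocv_classify(tab, "fNIRS", "task")
  noise <- glm_loocv_classify(tab, "EEG", "task")
  self <- compare_auc(good, good)
  expect_identical(self$z, 0)
  expect_identical(self$p, 1)
  ab <- compare_auc(good, noise)
  ba <- compare_auc(noise, good)
  expect_equal(ab$z, -ba$z, tolerance = 1e-10)
  expect_lt(ab$p, 0.01)
  expect_gt(ab$z, 0)  # the separating family has the larger AUC
  # a near-perfect vs pure-noise AUC difference is detected across seeds
  set.seed(61)
  detected <- replicate(50, {
    lab <- rep(c(0, 1), c(18, 17))
    sep <- roc_analysis(lab + rnorm(35, sd = 0.1), lab)
    rnd <- roc_analysis(rnorm(35), lab)
    compare_auc(sep, rnd)$p < 0.01
  })
  expect_gte(mean(detected), 0.9)
  # unpaired inputs refused
  other <- roc_analysis(rnorm(10), rep(c(0, 1), 5))
  expect_error(compare_auc(good, other), "paired")
})

test_that("Youden helper picks the threshold maximizing J", {
  r <- roc_analysis(c(0.1, 0.2, 0.6, 0.9, 0.8, 0.3),
                    c(0, 0, 1, 1, 1, 0))
  th <- youden_threshold(r)
  at <- roc_analysis(r$scores, r$labels, threshold = th)
  expect_identical(at$sensitivity + at$specificity, 2)
})
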