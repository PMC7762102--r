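#' Bootstrap confidence-interval filter
#'
#' Percentile bootstrap of a group's value distribution: each of
#' `n_boot` resamples contributes its empirical `(1-conf)/2` and
#' `1-(1-conf)/2` quantiles, the bounds are the resample means, and only
#' subject values inside the bounds are retained for descriptive
#' statistics.
#'
#' @param values numeric vector (group size >= 3).
#' @param n_boot number of bootstrap resamples.
#' @param conf confidence level.
#' @return list with `retained`, `keep` (logical mask), `lower`,
#'   `upper`.
#' @export
bootstrap_ci_filter <- function(values, n_boot = 1000, conf = 0.95) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("group size must be at least 3")
  a <- (1 - conf) / 2
  if (stats::sd(values) == 0) {
    return(list(retained = values, keep = rep(TRUE, length(values)),
                lower = values[1], upper = values[1]))
  }
  qs <- t(vapply(seq_len(n_boot), function(i) {
    stats::quantile(sample(values, replace = TRUE), probs = c(a, 1 - a),
                    names = FALSE)
  }, numeric(2)))
  lower <- mean(qs[, 1]); upper <- mean(qs[, 2])
  keep <- values >= lower & values <= upper
  list(retained = values[keep], keep = keep, lower = lower, upper = upper)
}

# Extract the feature columns of one family from a cohort table.
family_columns <- function(family) {
  bands <- eeg_band_table()$name
  switch(family,
         EEG = paste0("sampen_eeg_", bands),
         fNIRS = c("sampen_o2hb", "sampen_hhb"),
         NC = c(paste0("conden_o2hb_", bands), paste0("conden_hhb_", bands)),
         stop(sprintf("unknown feature family '%s'", family)))
}

#' Group comparisons with FDR correction
#'
#' Two-sample Student t-tests (pooled variance, AD minus HC) per
#' complexity metric within one phase, with optional per-group bootstrap
#' CI filtering of the values first, Benjamini-Hochberg adjustment
#' across the phase's metrics, and Cohen's d on the pooled SD. Degrees
#' of freedom vary per metric with the exclusions.
#'
#' @param cohort a `cohort_table` from [cohort_features()].
#' @param phase phase to analyze.
#' @param ci_filter apply [bootstrap_ci_filter()] per group first.
#' @param n_boot bootstrap resamples for the filter.
#' @return data.frame with one row per testable metric: `metric`,
#'   `n_ad`, `n_hc`, `t`, `df`, `p`, `q`, `cohen_d`, plus per-group CI
#'   bounds when filtering.
#' @export
ttests_fdr <- function(cohort, phase, ci_filter = TRUE, n_boot = 1000) {
  sub <- cohort[cohort$phase == phase, , drop = FALSE]
  if (nrow(sub) == 0L) stop(sprintf("no rows for phase '%s'", phase))
  rows <- list()
  for (metric in feature_names()) {
    ok <- sub[[paste0("valid_", metric)]] & is.finite(sub[[metric]])
    ad <- sub[[metric]][ok & sub$group == 1]
    hc <- sub[[metric]][ok & sub$group == 0]
    ci <- c(ad_lo = NA_real_, ad_hi = NA_real_,
            hc_lo = NA_real_, hc_hi = NA_real_)
    if (ci_filter && length(ad) >= 3 && length(hc) >= 3) {
      fa <- bootstrap_ci_filter(ad, n_boot = n_boot)
      fh <- bootstrap_ci_filter(hc, n_boot = n_boot)
      ad <- fa$retained; hc <- fh$retained
      ci <- c(ad_lo = fa$lower, ad_hi = fa$upper,
              hc_lo = fh$lower, hc_hi = fh$upper)
    }
    if (length(ad) < 2 || length(hc) < 2) {
      message(sprintf("metric %s skipped in phase %s: a group has < 2 values",
                      metric, phase))
      next
    }
    tt <- stats::t.test(ad, hc, var.equal = TRUE)
    sp <- sqrt(((length(ad) - 1) * stats::var(ad) +
                  (length(hc) - 1) * stats::var(hc)) /
                 (length(ad) + length(hc) - 2))
    d <- if (sp > 0) (mean(ad) - mean(hc)) / sp else 0
    rows[[length(rows) + 1L]] <- data.frame(
      metric = metric, n_ad = length(ad), n_hc = length(hc),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, cohen_d = d,
      ad_mean = mean(ad), hc_mean = mean(hc),
      t(ci), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable metrics in this phase")
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[, c("metric", "n_ad", "n_hc", "t", "df", "p", "q", "cohen_d",
          "ad_mean", "hc_mean", "ad_lo", "ad_hi", "hc_lo", "hc_hi")]
}

# Moore-Penrose pseudo-inverse (SVD).
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' GLM classifier with leave-one-out cross-validation
#'
#' Ordinary least-squares regression of the disease label (AD = 1,
#' HC = 0) on one feature family, scored out-of-sample by leave-one-out:
#' each subject's score comes from a model fit on all other subjects.
#' A full-sample fit supplies the attributable beta-weights. Subjects
#' with missing (gated-out) values in the family's features are dropped
#' for that family.
#'
#' @param cohort a `cohort_table`.
#' @param family `"EEG"` (5 features), `"fNIRS"` (2) or `"NC"` (10).
#' @param phase phase to analyze.
#' @return `roc_result` (see [roc_analysis()]) augmented with `family`,
#'   `phase`, `beta` (named full-fit coefficients incl. intercept),
#'   `subject_id` of the rows used.
#' @export
glm_loocv_classify <- function(cohort, family, phase) {
  cols <- family_columns(family)
  sub <- cohort[cohort$phase == phase, , drop = FALSE]
  X <- as.matrix(sub[, cols, drop = FALSE])
  vmask <- as.matrix(sub[, paste0("valid_", cols), drop = FALSE])
  X[!vmask] <- NA_real_
  complete <- stats::complete.cases(X)
  if (any(!complete))
    message(sprintf("%s/%s: %d subject(s) dropped for missing features",
                    family, phase, sum(!complete)))
  X <- X[complete, , drop = FALSE]
  y <- sub$group[complete]
  n <- length(y); p <- ncol(X)
  if (n <= p + 1)
    stop("too few subjects for the family size (need n > n_features + 1)")
  if (length(unique(y)) < 2) stop("both classes must be present")
  D <- cbind(1, X)
  fit_beta <- function(Dm, ym) {
    b <- tryCatch(qr.coef(qr(Dm), ym), error = function(e) NULL)
    if (is.null(b) || anyNA(b)) {
      warning("rank-deficient design: using pseudo-inverse")
      b <- drop(pinv(Dm) %*% ym)
    }
    b
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    b <- fit_beta(D[-i, , drop = FALSE], y[-i])
    scores[i] <- drop(D[i, , drop = FALSE] %*% b)
  }
  beta <- stats::setNames(fit_beta(D, y), c("(intercept)", cols))
  res <- roc_analysis(scores, y)
  res$family <- family
  res$phase <- phase
  res$beta <- beta
  res$subject_id <- sub$subject_id[complete]
  res
}

#' ROC curve, AUC and operating point
#'
#' The ROC curve is built by a threshold sweep over the unique scores
#' (predicted-AD when `score >= threshold`); the AUC is computed by the
#' rank (Mann-Whitney) formulation with midranks for ties, and the two
#' constructions agree exactly (the sweep's trapezoidal area equals the
#' rank statistic).
#'
#' @param scores numeric classifier outputs.
#' @param labels 0/1 group labels (1 = AD).
#' @param threshold optional operating threshold at which sensitivity
#'   and specificity are reported.
#' @return `roc_result`: list with `scores`, `labels`, `roc`
#'   (data.frame `threshold`, `fpr`, `tpr`), `auc`, `auc_rank`,
#'   `threshold`, `sensitivity`, `specificity`.
#' @export
roc_analysis <- function(scores, labels, threshold = NULL) {
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  # threshold sweep (ties grouped)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(th) mean(scores[labels == 1] >= th), 0)
  fpr <- vapply(thr, function(th) mean(scores[labels == 0] >= th), 0)
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  auc_sweep <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                      utils::tail(roc$tpr, -1)) / 2)
  # Mann-Whitney with midranks
  r <- rank(scores)
  auc_rank <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  res <- list(scores = scores, labels = labels, roc = roc,
              auc = auc_sweep, auc_rank = auc_rank,
              threshold = threshold,
              sensitivity = NA_real_, specificity = NA_real_)
  if (!is.null(threshold)) {
    res$sensitivity <- mean(scores[labels == 1] >= threshold)
    res$specificity <- mean(scores[labels == 0] < threshold)
  }
  class(res) <- "roc_result"
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result>%s AUC = %.3f (n1 = %d, n0 = %d)\n",
              if (!is.null(x$family)) paste0(" ", x$family, "/", x$phase)
              else "",
              x$auc, sum(x$labels == 1), sum(x$labels == 0)))
  if (!is.null(x$threshold) && is.finite(x$sensitivity))
    cat(sprintf("  threshold %.3g: sensitivity %.2f, specificity %.2f\n",
                x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Youden-optimal operating threshold
#'
#' Convenience helper maximizing sensitivity + specificity - 1 over the
#' swept thresholds. Operating thresholds are application choices; this
#' helper is explicitly an optimizer, not a default.
#'
#' @param result a `roc_result`.
#' @return the optimal threshold (numeric scalar).
#' @export
youden_threshold <- function(result) {
  stopifnot(inherits(result, "roc_result"))
  j <- result$roc$tpr - result$roc$fpr
  best <- which.max(j)
  result$roc$threshold[best]
}

#' Paired comparison of two AUCs (DeLong test)
#'
#' Compares the areas under two ROC curves built from the same subjects
#' (paired scores) with DeLong's test for correlated curves.
#'
#' @param result_a,result_b `roc_result`s over identical subjects (same
#'   labels in the same order).
#' @return list with `z` (positive when `result_a`'s AUC is larger) and
#'   two-sided `p`.
#' @export
compare_auc <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "roc_result"),
            inherits(result_b, "roc_result"))
  if (length(result_a$labels) != length(result_b$labels) ||
      any(result_a$labels != result_b$labels))
    stop("paired comparison requires identical subjects and labels")
  if (!is.null(result_a$subject_id) && !is.null(result_b$subject_id) &&
      any(result_a$subject_id != result_b$subject_id))
    stop("paired comparison requires identical subjects")
  if (isTRUE(all.equal(result_a$scores, result_b$scores)))
    return(list(z = 0, p = 1))
  ra <- pROC::roc(result_a$labels, result_a$scores, quiet = TRUE,
                  levels = c(0, 1), direction = "<")
  rb <- pROC::roc(result_b$labels, result_b$scores, quiet = TRUE,
                  levels = c(0, 1), direction = "<")
  tt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(z = unname(tt$statistic), p = tt$p.value)
}
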