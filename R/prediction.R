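# positive-call indicator per direction; thresholds are score midpoints so
# <= vs < never matters in practice, <= / >= is the fixed convention
roc_calls <- function(scores, threshold, direction) {
  if (direction == "lower") scores <= threshold else scores >= threshold
}

#' ROC curve for a continuous score against a binary outcome
#'
#' Builds the full ROC curve over thresholds placed at midpoints between
#' consecutive distinct scores plus `-Inf`/`+Inf` sentinels. `direction`
#' states which tail of the score predicts the positive class and is never
#' inferred from the data: `"lower"` means low scores call positives (a
#' shallow-excursion patient predicted to fail weaning), `"higher"` the
#' opposite. The AUC is the trapezoidal area, identical to the tie-corrected
#' Mann-Whitney probability; with a mismatched direction the AUC falls
#' below 0.5 and is reported as such (no auto-flip).
#'
#' @param scores numeric predictor.
#' @param labels logical (or 0/1) outcome, `TRUE` = positive.
#' @param direction `"lower"` or `"higher"`.
#' @return list of class `roc_result`: `thresholds`, `sens`, `spec`,
#'   `auc`, `direction`, `n_pos`, `n_neg` (plus `auc_ci_low`/`auc_ci_high`
#'   when filled in by [bootstrap_roc()]).
#' @export
roc_curve <- function(scores, labels, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  ok <- stats::complete.cases(scores, labels)
  scores <- scores[ok]
  labels <- as.logical(labels[ok])
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stopf("degenerate labels: both classes must be present")
  u <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
  sens <- spec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    call_pos <- roc_calls(scores, thresholds[i], direction)
    sens[i] <- sum(call_pos & labels) / n_pos
    spec[i] <- sum(!call_pos & !labels) / n_neg
  }
  ord <- order(1 - spec, sens)
  auc <- trapz((1 - spec)[ord], sens[ord])
  structure(list(thresholds = thresholds, sens = sens, spec = spec,
                 auc = auc, auc_ci_low = NA_real_, auc_ci_high = NA_real_,
                 direction = direction, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' Youden-optimal cutoff of a ROC curve
#'
#' Returns the threshold maximizing the Youden index `J = sens + spec - 1`.
#' Ties are broken deterministically: first toward higher sensitivity
#' (missing a weaning failure is the costlier error), then toward the
#' threshold making more positive calls.
#'
#' @param roc a [roc_curve()] result.
#' @return The cutoff (same units as the scores).
#' @export
youden_cutoff <- function(roc) {
  j <- roc$sens + roc$spec - 1
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1L) {
    best <- best[roc$sens[best] >= max(roc$sens[best]) - 1e-12]
    if (length(best) > 1L) {
      # more positive calls: higher threshold under "lower", lower under "higher"
      thr <- roc$thresholds[best]
      best <- best[if (roc$direction == "lower") which.max(thr) else which.min(thr)]
    }
  }
  roc$thresholds[best[1L]]
}

# Clopper-Pearson exact binomial interval
clopper_pearson <- function(x, n, conf_level = 0.95) {
  if (n == 0L) return(c(0, 1))
  a <- 1 - conf_level
  lo <- if (x == 0L) 0 else qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
  c(lo, hi)
}

#' Diagnostic performance at a fixed cutoff
#'
#' Confusion counts and the usual proportions — sensitivity, specificity,
#' positive and negative predictive value — each with an exact
#' (Clopper-Pearson) binomial confidence interval. Proportions with a zero
#' denominator (e.g. no negative calls) are `NA` with CI `[0, 1]`.
#'
#' @param scores,labels,direction as in [roc_curve()].
#' @param cutoff finite threshold.
#' @param conf_level CI level.
#' @return list of class `diagnostic_performance`: `cutoff`, `tp`, `fp`,
#'   `tn`, `fn`, and for each of `sens`, `spec`, `ppv`, `npv` the estimate
#'   plus `_ci_low`/`_ci_high`; `youden_j`.
#' @export
diagnostic_metrics <- function(scores, labels, cutoff,
                               direction = c("lower", "higher"),
                               conf_level = 0.95) {
  direction <- match.arg(direction)
  if (!is.finite(cutoff)) stopf("cutoff must be finite")
  ok <- stats::complete.cases(scores, labels)
  scores <- scores[ok]
  labels <- as.logical(labels[ok])
  call_pos <- roc_calls(scores, cutoff, direction)
  tp <- sum(call_pos & labels); fp <- sum(call_pos & !labels)
  tn <- sum(!call_pos & !labels); fn <- sum(!call_pos & labels)
  prop <- function(x, n) {
    ci <- clopper_pearson(x, n, conf_level)
    list(est = if (n) x / n else NA_real_, lo = ci[1L], hi = ci[2L])
  }
  se <- prop(tp, tp + fn); sp <- prop(tn, tn + fp)
  pv <- prop(tp, tp + fp); nv <- prop(tn, tn + fn)
  structure(list(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
                 sens = se$est, sens_ci_low = se$lo, sens_ci_high = se$hi,
                 spec = sp$est, spec_ci_low = sp$lo, spec_ci_high = sp$hi,
                 ppv = pv$est, ppv_ci_low = pv$lo, ppv_ci_high = pv$hi,
                 npv = nv$est, npv_ci_low = nv$lo, npv_ci_high = nv$hi,
                 youden_j = se$est + sp$est - 1),
            class = "diagnostic_performance")
}

#' Bootstrap confidence intervals for AUC and Youden cutoff
#'
#' Patient-level resampling with replacement, stratified by outcome class
#' so every replicate keeps both classes at their original counts; per
#' replicate the AUC and the Youden-optimal cutoff are recomputed, and
#' percentile intervals are returned. Fully reproducible from `seed`.
#'
#' @param scores,labels,direction as in [roc_curve()].
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @param conf_level CI level.
#' @return list: `auc_ci`, `cutoff_ci` (length-2 vectors), `aucs`,
#'   `cutoffs` (length-B vectors), `n_redrawn`.
#' @export
bootstrap_roc <- function(scores, labels, B = 1000L, seed = 1L,
                          direction = c("lower", "higher"),
                          conf_level = 0.95) {
  direction <- match.arg(direction)
  if (B < 1L) stopf("B must be >= 1")
  ok <- stats::complete.cases(scores, labels)
  scores <- scores[ok]
  labels <- as.logical(labels[ok])
  ipos <- which(labels); ineg <- which(!labels)
  if (!length(ipos) || !length(ineg))
    stopf("degenerate labels: both classes must be present")
  set.seed(seed)
  aucs <- cutoffs <- numeric(B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- c(sample(ipos, replace = TRUE), sample(ineg, replace = TRUE))
      if (length(unique(labels[idx])) == 2L) break    # stratified: always true
      n_redrawn <- n_redrawn + 1L
    }
    r <- roc_curve(scores[idx], labels[idx], direction)
    aucs[b] <- r$auc
    cutoffs[b] <- youden_cutoff(r)
  }
  a <- 1 - conf_level
  probs <- c(a / 2, 1 - a / 2)
  list(auc_ci = unname(quantile(aucs, probs)),
       cutoff_ci = unname(quantile(cutoffs[is.finite(cutoffs)], probs)),
       aucs = aucs, cutoffs = cutoffs, n_redrawn = n_redrawn)
}

# placement values: for each positive, the fraction of negatives it beats
# (ties count 1/2); and symmetrically for negatives
placements <- function(scores, labels) {
  sp <- scores[labels]; sn <- scores[!labels]
  v10 <- vapply(sp, function(s) mean((s > sn) + 0.5 * (s == sn)), numeric(1))
  v01 <- vapply(sn, function(s) mean((sp > s) + 0.5 * (sp == s)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated (paired) AUCs
#'
#' Nonparametric comparison of the AUCs of two markers measured on the same
#' subjects, using placement-value (structural-component) estimates of each
#' AUC, their variances and covariance:
#' `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov)`, two-sided normal
#' p-value. Scores are oriented so that higher values score the positive
#' class (pass `direction = "lower"` to negate both markers first; the test
#' is invariant to any common monotone transform).
#'
#' @param scores_a,scores_b paired marker values on identical subjects.
#' @param labels logical outcome, `TRUE` = positive.
#' @param direction orientation applied to both markers.
#' @return list: `auc_a`, `auc_b`, `z`, `p`. With identical placements the
#'   difference is 0/0; this degenerate case returns `z = 0, p = 1` when
#'   the AUCs agree and `NA` otherwise.
#' @export
delong_test <- function(scores_a, scores_b, labels,
                        direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  ok <- stats::complete.cases(scores_a, scores_b, labels)
  scores_a <- scores_a[ok]; scores_b <- scores_b[ok]
  labels <- as.logical(labels[ok])
  if (direction == "lower") {
    scores_a <- -scores_a
    scores_b <- -scores_b
  }
  if (!sum(labels) || !sum(!labels))
    stopf("degenerate labels: both classes must be present")
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  m <- sum(labels); n <- sum(!labels)
  var_a <- var(pa$v10) / m + var(pa$v01) / n
  var_b <- var(pb$v10) / m + var(pb$v01) / n
  cov_ab <- cov(pa$v10, pb$v10) / m + cov(pa$v01, pb$v01) / n
  denom2 <- var_a + var_b - 2 * cov_ab
  d <- pa$auc - pb$auc
  if (!is.finite(denom2) || denom2 <= .Machine$double.eps * 100) {
    if (abs(d) < 1e-12)
      return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p = 1))
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = NA_real_, p = NA_real_))
  }
  z <- d / sqrt(denom2)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = 2 * pnorm(-abs(z)))
}

#' @export
print.roc_result <- function(x, ...) {
  ci <- if (is.na(x$auc_ci_low)) "" else
    sprintf(" [95%% CI %.3f to %.3f]", x$auc_ci_low, x$auc_ci_high)
  cat(sprintf("ROC (%d positive / %d negative, %s predicts positive): AUC %.3f%s\n",
              x$n_pos, x$n_neg, x$direction, x$auc, ci))
  invisible(x)
}

#' @export
print.diagnostic_performance <- function(x, ...) {
  cat(sprintf("cutoff %.3g: sens %.2f [%.2f-%.2f], spec %.2f [%.2f-%.2f], ppv %.2f, npv %.2f, J = %.2f\n",
              x$cutoff, x$sens, x$sens_ci_low, x$sens_ci_high,
              x$spec, x$spec_ci_low, x$spec_ci_high, x$ppv, x$npv,
              x$youden_j))
  invisible(x)
}
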