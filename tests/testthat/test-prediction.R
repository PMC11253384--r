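test_that("ROC endpoints: perfect separation and uninformative scores", {
  lab <- rep(c(TRUE, FALSE), each = 5)
  perfect <- roc_curve(c(1:5, 11:15), lab, "lower")
  expect_equal(perfect$auc, 1)
  flat <- roc_curve(rep(2, 10), lab, "lower")
  expect_equal(flat$auc, 0.5)
  expect_error(roc_curve(1:5, rep(TRUE, 5), "lower"), "degenerate labels")
})

test_that("trapezoid AUC equals exhaustive pair counting with ties", {
  scores <- c(1, 2, 2, 3, 4, 4, 5, 6)
  labels <- c(0, 0, 1, 0, 1, 0, 1, 1)
  expect_equal(roc_curve(scores, labels, "higher")$auc,
               bf_auc_pairs(scores, labels, "higher"))
  set.seed(21)
  for (i in 1:100) {
    n <- sample(6:25, 1)
    sc <- sample(seq(0, 5, 0.5), n, replace = TRUE)   # plenty of ties
    lb <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!sum(lb) || !sum(!lb)) next
    expect_equal(roc_curve(sc, lb, "higher")$auc, bf_auc_pairs(sc, lb))
    expect_equal(roc_curve(sc, lb, "higher")$auc, proc_auc(sc, lb))
  }
})

test_that("AUC equals the tie-corrected Mann-Whitney statistic", {
  set.seed(22)
  for (i in 1:50) {
    n <- sample(8:40, 1)
    sc <- round(rnorm(n), 1)
    lb <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!sum(lb) || !sum(!lb)) next
    u <- sum(rank(sc)[lb]) - sum(lb) * (sum(lb) + 1) / 2
    expect_equal(roc_curve(sc, lb, "higher")$auc,
                 u / (sum(lb) * sum(!lb)))
  }
})

test_that("flipping the direction maps AUC to its complement", {
  set.seed(23)
  sc <- rnorm(30); lb <- rep(c(TRUE, FALSE), 15)
  a <- roc_curve(sc, lb, "lower")
  b <- roc_curve(sc, lb, "higher")
  expect_equal(a$auc, 1 - b$auc)
})

test_that("Youden cutoff maximizes J with deterministic tie-breaking", {
  lab <- rep(c(TRUE, FALSE), each = 4)
  r <- roc_curve(c(1, 2, 3, 4, 10, 11, 12, 13), lab, "lower")
  cut <- youden_cutoff(r)
  expect_equal(cut, 7)                   # midpoint of the separated classes
  expect_equal(max(r$sens + r$spec - 1), 1)
  # exhaustive scan agreement on random overlapping sets
  set.seed(24)
  for (i in 1:50) {
    sc <- round(c(rnorm(12, 0), rnorm(12, 1)), 1)
    lb <- rep(c(TRUE, FALSE), each = 12)
    r <- roc_curve(sc, lb, "lower")
    j_best <- bf_best_youden(sc, lb, "lower")
    cut <- youden_cutoff(r)
    call_pos <- sc <= cut
    j_at_cut <- sum(call_pos & lb) / 12 + sum(!call_pos & !lb) / 12 - 1
    expect_equal(j_at_cut, j_best)
  }
  # single distinct score: J = 0, sentinel cutoff making everyone positive
  r1 <- roc_curve(rep(3, 8), lab, "lower")
  expect_equal(youden_cutoff(r1), Inf)
})

test_that("diagnostic metrics mirror count arithmetic with exact CIs", {
  # tp 20, fn 4, tn 15, fp 7 at cutoff 0 (negatives score above it)
  scores <- c(rep(-1, 20), rep(1, 4), rep(1, 15), rep(-1, 7))
  labels <- rep(c(TRUE, FALSE), c(24, 22))
  dm <- diagnostic_metrics(scores, labels, 0, "lower")
  expect_equal(c(dm$tp, dm$fn, dm$tn, dm$fp), c(20, 4, 15, 7))
  expect_equal(dm$sens, 20 / 24, tolerance = 1e-12)
  expect_equal(dm$spec, 15 / 22, tolerance = 1e-12)
  expect_equal(dm$youden_j, dm$sens + dm$spec - 1)
  # CIs equal the exact binomial inversion
  bt <- binom.test(20, 24)$conf.int
  expect_equal(c(dm$sens_ci_low, dm$sens_ci_high), as.numeric(bt))
  # 0 of 10: documented exact upper bound
  scores0 <- c(rep(1, 10), rep(-1, 10))
  dm0 <- diagnostic_metrics(scores0, rep(c(TRUE, FALSE), each = 10), 0, "lower")
  expect_equal(dm0$sens, 0)
  expect_equal(dm0$sens_ci_low, 0)
  expect_equal(dm0$sens_ci_high, 1 - 0.025^(1 / 10), tolerance = 1e-9)
  # all correct: every proportion 1
  dmp <- diagnostic_metrics(c(1, 1, 9, 9), c(TRUE, TRUE, FALSE, FALSE),
                            5, "lower")
  expect_equal(c(dmp$sens, dmp$spec, dmp$ppv, dmp$npv), rep(1, 4))
})

test_that("flipping direction swaps sensitivity and specificity", {
  set.seed(25)
  sc <- rnorm(40); lb <- rep(c(TRUE, FALSE), 20)
  lo <- diagnostic_metrics(sc, lb, 0.3, "lower")
  hi <- diagnostic_metrics(sc, !lb, 0.3, "higher")
  expect_equal(lo$sens, hi$spec)
  expect_equal(lo$spec, hi$sens)
})

test_that("stratified bootstrap is reproducible and sane", {
  set.seed(26)
  sc <- c(rnorm(30, 0), rnorm(30, 3))
  lb <- rep(c(TRUE, FALSE), each = 30)
  b1 <- bootstrap_roc(sc, lb, B = 100, seed = 5, direction = "lower")
  b2 <- bootstrap_roc(sc, lb, B = 100, seed = 5, direction = "lower")
  expect_identical(b1, b2)
  expect_equal(b1$n_redrawn, 0L)
  single <- bootstrap_roc(sc, lb, B = 1, seed = 9, direction = "lower")
  expect_gt(single$aucs, 0.95)           # well-separated classes
})

test_that("DeLong test: degenerate and rank-invariance cases", {
  set.seed(27)
  sc <- rnorm(30); lb <- rep(c(TRUE, FALSE), 15)
  same <- delong_test(sc, sc, lb)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  mono <- delong_test(sc, exp(sc) + 5, lb)   # monotone transform
  expect_equal(mono$auc_a, mono$auc_b)
  expect_equal(mono$z, 0)
})

test_that("DeLong matches pROC on random paired markers", {
  set.seed(28)
  for (i in 1:20) {
    n <- 40
    lb <- rep(c(1, 0), each = n / 2)
    base <- rnorm(n) + lb
    a <- base + rnorm(n, 0, 0.7)
    b <- base + rnorm(n, 0, 0.7)
    mine <- delong_test(a, b, lb)
    theirs <- pROC::roc.test(
      pROC::roc(lb, a, direction = "<", quiet = TRUE),
      pROC::roc(lb, b, direction = "<", quiet = TRUE), method = "delong")
    expect_equal(mine$p, theirs$p.value, tolerance = 1e-9)
    expect_equal(mine$auc_a, as.numeric(theirs$estimate[1]), tolerance = 1e-9)
  }
})

test_that("Clopper-Pearson coverage is exact-conservative for small n", {
  for (n in c(5, 10, 20)) {
    for (p in c(0.1, 0.35, 0.5, 0.8)) {
      cover <- sum(vapply(0:n, function(x) {
        ci <- diaphmon:::clopper_pearson(x, n)
        (ci[1] <= p && p <= ci[2]) * dbinom(x, n, p)
      }, numeric(1)))
      expect_gte(cover, 0.95)
    }
  }
})
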