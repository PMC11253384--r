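#' Bland-Altman agreement analysis
#'
#' Summarizes paired measurements by the mean difference (bias), the limits
#' of agreement and a confidence interval for the bias. Differences are
#' `d = y - x`. The limits default to bias +/- 2 SD of the differences (the
#' "+/- 2 standard deviation" convention rather than 1.96); the bias CI is
#' the t interval `bias +/- t(1 - alpha/2, n-1) * sd / sqrt(n)`. The bias is
#' called significant when 0 lies outside its CI. Both interval kinds are
#' always reported because they are easily (and in print, sometimes
#' actually) confused: the limits of agreement describe single differences,
#' the CI describes the mean difference.
#'
#' @param x,y paired numeric vectors (reference and comparison method).
#' @param loa_multiplier SD multiplier for the limits of agreement.
#' @param conf_level confidence level for the bias CI.
#' @return list of class `agreement_result`: `n_pairs`, `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `bias_ci_low`, `bias_ci_high`,
#'   `bias_significant`.
#' @export
bland_altman <- function(x, y, loa_multiplier = 2, conf_level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(y) != n)
    stopf("bland_altman needs at least 3 complete pairs")
  d <- y - x
  bias <- mean(d)
  sd_diff <- sd(d)
  half <- qt(1 - (1 - conf_level) / 2, n - 1L) * sd_diff / sqrt(n)
  ci <- bias + c(-1, 1) * half
  structure(list(n_pairs = n, bias = bias, sd_diff = sd_diff,
                 loa_low = bias - loa_multiplier * sd_diff,
                 loa_high = bias + loa_multiplier * sd_diff,
                 bias_ci_low = ci[1L], bias_ci_high = ci[2L],
                 bias_significant = !(ci[1L] <= 0 && ci[2L] >= 0)),
            class = "agreement_result")
}

#' Classify patients as good or poor agreement
#'
#' A patient is "poor agreement" when at least one of their paired
#' differences lies strictly outside the pooled limits of agreement;
#' differences exactly on a limit count as inside.
#'
#' @param patient_diffs named list mapping patient id to their vector of
#'   differences.
#' @param loa numeric length-2 vector `c(low, high)` or an
#'   `agreement_result`.
#' @return named character vector, `"good"` or `"poor"` per patient.
#' @export
classify_agreement <- function(patient_diffs, loa) {
  if (inherits(loa, "agreement_result")) loa <- c(loa$loa_low, loa$loa_high)
  vapply(patient_diffs, function(d)
    if (any(d < loa[1L] | d > loa[2L])) "poor" else "good", character(1))
}

# all pairwise Passing-Bablok slopes: finite, +/-Inf for vertical pairs
# with distinct y, NA (omitted) for fully tied pairs and slopes == -1
pb_slopes <- function(x, y) {
  n <- length(x)
  dx <- outer(x, x, "-")[lower.tri(matrix(0, n, n))]
  dy <- outer(y, y, "-")[lower.tri(matrix(0, n, n))]
  s <- ifelse(dx == 0 & dy == 0, NA_real_,
              ifelse(dx == 0, sign(dy) * Inf, dy / dx))
  s <- s[!is.na(s) & s != -1]
  sort(s)
}

#' Passing-Bablok regression
#'
#' Rank-based, scale-equivariant linear regression for method comparison,
#' robust to measurement error in both variables. The slope is the shifted
#' median of all pairwise slopes `S_ij = (y_j - y_i)/(x_j - x_i)`, `i < j`,
#' where slopes equal to -1 and fully tied pairs are omitted, vertical pairs
#' count as +/-Inf by the sign of `dy`, and the median rank is offset by
#' `K`, the number of slopes below -1. Confidence bounds use the rank
#' offsets `w = z(1-alpha/2) * sqrt(n(n-1)(2n+5)/18)` around the median
#' rank; the intercept is `median(y - b x)` with its CI from the slope
#' bounds. Linearity is assessed with [cusum_linearity()].
#'
#' @param x,y paired numeric vectors, `n >= 3`, `x` not all identical.
#' @param alpha CI significance level.
#' @param mc_linearity number of Monte-Carlo sign permutations for the
#'   linearity p-value; 0 gives the 1.36 critical-value decision only.
#' @return list of class `pb_result`: `slope`, `slope_ci_low`,
#'   `slope_ci_high`, `intercept`, `intercept_ci_low`, `intercept_ci_high`,
#'   `cusum_stat`, `linearity_rejected`, `linearity_p`, `n_pairs`.
#' @export
passing_bablok <- function(x, y, alpha = 0.05, mc_linearity = 0L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("passing_bablok needs at least 3 pairs")
  if (length(unique(x)) == 1L)
    stopf("degenerate input: all x values identical")
  s <- pb_slopes(x, y)
  N <- length(s)
  if (!N) stopf("degenerate input: no usable pairwise slopes")
  K <- sum(s < -1)
  shifted_median <- function(off) {
    if (N %% 2L == 1L) {
      i <- (N + 1L) %/% 2L + off
      s[min(max(i, 1L), N)]
    } else {
      i <- N %/% 2L + off
      j <- i + 1L
      mean(s[c(min(max(i, 1L), N), min(max(j, 1L), N))])
    }
  }
  b <- shifted_median(K)
  w <- qnorm(1 - alpha / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- round((N - w) / 2)
  m2 <- N - m1 + 1L
  b_lo <- s[min(max(m1 + K, 1L), N)]
  b_hi <- s[min(max(m2 + K, 1L), N)]
  a <- median(y - b * x)
  a_lo <- median(y - b_hi * x)
  a_hi <- median(y - b_lo * x)
  res <- structure(list(slope = b, slope_ci_low = b_lo, slope_ci_high = b_hi,
                        intercept = a, intercept_ci_low = a_lo,
                        intercept_ci_high = a_hi, n_pairs = n,
                        cusum_stat = NA_real_, linearity_rejected = NA,
                        linearity_p = NA_real_),
                   class = "pb_result")
  cl <- cusum_linearity(x, y, res, n_perm = mc_linearity)
  res$cusum_stat <- cl$cusum_stat
  res$linearity_rejected <- cl$rejected
  res$linearity_p <- cl$p
  res
}

#' CUSUM test for linearity of a Passing-Bablok fit
#'
#' Residual signs `r_i = sign(y_i - a - b x_i)` are accumulated in order of
#' the score `D_i = y_i + x_i / b`: each positive residual adds
#' `sqrt(M/L)`, each negative subtracts `sqrt(L/M)` (`L`, `M` the positive
#' and negative counts). The statistic is `max_j |cusum_j| / sqrt(L + M)`,
#' compared to the Kolmogorov-Smirnov 5% critical value 1.36. An optional
#' Monte-Carlo p-value permutes the residual signs.
#'
#' @param x,y the data the fit was computed on.
#' @param fit a `pb_result` (only `slope` and `intercept` are used).
#' @param n_perm Monte-Carlo permutations (0 = critical-value decision
#'   only, p reported as a bound).
#' @param critical rejection threshold for the statistic.
#' @return list: `cusum_stat`, `rejected`, `p` (exact Monte-Carlo value, or
#'   `NA` when `n_perm = 0`; `p_bound` gives `">0.05"`/`"<=0.05"`).
#' @export
cusum_linearity <- function(x, y, fit, n_perm = 0L, critical = 1.36) {
  r <- sign(y - fit$intercept - fit$slope * x)
  L <- sum(r > 0); M <- sum(r < 0)
  if (L == 0L || M == 0L)
    return(list(cusum_stat = 0, rejected = FALSE, p = NA_real_,
                p_bound = ">0.05"))
  b <- if (fit$slope != 0 && is.finite(fit$slope)) fit$slope else NA_real_
  D <- if (is.na(b)) x else y + x / b
  ord <- order(D)
  rs <- r[ord]
  step <- ifelse(rs > 0, sqrt(M / L), ifelse(rs < 0, -sqrt(L / M), 0))
  stat <- max(abs(cumsum(step))) / sqrt(L + M)
  p <- NA_real_
  if (n_perm > 0L) {
    perm <- replicate(n_perm, {
      ps <- sample(rs)
      st <- ifelse(ps > 0, sqrt(M / L), ifelse(ps < 0, -sqrt(L / M), 0))
      max(abs(cumsum(st))) / sqrt(L + M)
    })
    p <- (sum(perm >= stat) + 1) / (n_perm + 1)
  }
  list(cusum_stat = stat, rejected = stat > critical, p = p,
       p_bound = if (stat > critical) "<=0.05" else ">0.05")
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation using average ranks for ties; the p-value uses the
#' t approximation `t = rho sqrt((n-2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return list: `rho`, `p`, `n`. `rho` is `NA` for constant input.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stopf("spearman_cor needs at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f [95%% CI %.3f to %.3f]%s\n",
              x$n_pairs, x$bias, x$bias_ci_low, x$bias_ci_high,
              if (x$bias_significant) " *" else ""))
  cat(sprintf("  limits of agreement: %.3f to %.3f (+/- 2 SD)\n",
              x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
print.pb_result <- function(x, ...) {
  cat(sprintf("Passing-Bablok (n = %d): slope %.3f [%.3f, %.3f], intercept %.3f [%.3f, %.3f]\n",
              x$n_pairs, x$slope, x$slope_ci_low, x$slope_ci_high,
              x$intercept, x$intercept_ci_low, x$intercept_ci_high))
  cat(sprintf("  CUSUM linearity: stat %.3f, linearity %srejected at 5%%\n",
              x$cusum_stat, if (isTRUE(x$linearity_rejected)) "" else "not "))
  invisible(x)
}
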