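#' Repeated-measures correlation (shared-slope ANCOVA)
#'
#' Estimates the common within-subject association between two repeatedly
#' measured variables by the shared-slope model
#' `y = subject intercepts + b x + error`, fit by least squares with
#' subject as a categorical factor. The coefficient is
#' `r_rm = sign(b) sqrt(SS_x / (SS_x + SS_error))`, where `SS_x` is the
#' sequential sum of squares for `x` after the subject factor, on
#' `df = n_obs - n_subjects - 1` error degrees of freedom; the p-value is
#' from the F statistic on `(1, df)` and the confidence interval from the
#' Fisher z transform with standard error `1 / sqrt(df - 1)`. Between-
#' subject level differences are absorbed by the intercepts, so adding a
#' distinct constant per subject to `x` and `y` leaves `r_rm` unchanged.
#'
#' Incomplete pairs are dropped per subject; subjects left with fewer than
#' 2 complete pairs are excluded (listed in the `excluded` element).
#'
#' @param subjects subject identifiers (one per observation).
#' @param x,y paired numeric observations.
#' @param conf_level CI level.
#' @return list of class `rmcorr_result`: `r_rm`, `df`, `ci_low`,
#'   `ci_high`, `p`, `slope`, `n_subjects`, `n_obs`, `excluded`.
#' @export
rmcorr <- function(subjects, x, y, conf_level = 0.95) {
  ok <- stats::complete.cases(subjects, x, y)
  subjects <- as.character(subjects[ok]); x <- x[ok]; y <- y[ok]
  counts <- table(subjects)
  excluded <- names(counts)[counts < 2L]
  keep <- !(subjects %in% excluded)
  subjects <- subjects[keep]; x <- x[keep]; y <- y[keep]
  n_subjects <- length(unique(subjects))
  n_obs <- length(x)
  if (n_subjects < 2L)
    stopf("insufficient data: need >= 2 subjects with >= 2 complete pairs")
  df <- n_obs - n_subjects - 1L
  if (df < 1L) stopf("insufficient data: no error degrees of freedom")

  # within-subject centering is the ANCOVA fit with subject intercepts
  xc <- x - stats::ave(x, subjects)
  yc <- y - stats::ave(y, subjects)
  sxx <- sum(xc^2)
  if (sxx <= 0) stopf("insufficient data: x constant within every subject")
  b <- sum(xc * yc) / sxx
  ss_x <- sum(xc * yc)^2 / sxx
  ss_err <- sum(yc^2) - ss_x
  if (ss_err < 0) ss_err <- 0
  r <- if (ss_x + ss_err <= 0) 0 else sign(b) * sqrt(ss_x / (ss_x + ss_err))
  f <- if (ss_err <= 0) Inf else ss_x / (ss_err / df)
  p <- pf(f, 1, df, lower.tail = FALSE)
  zr <- atanh(max(-1 + 1e-15, min(1 - 1e-15, r)))
  half <- qnorm(1 - (1 - conf_level) / 2) / sqrt(df - 1L)
  structure(list(r_rm = r, df = df, ci_low = tanh(zr - half),
                 ci_high = tanh(zr + half), p = p, slope = b,
                 n_subjects = n_subjects, n_obs = n_obs,
                 excluded = excluded),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("rmcorr: r = %.3f (95%% CI %.3f to %.3f), df = %d, p = %.3g\n",
              x$r_rm, x$ci_low, x$ci_high, x$df, x$p))
  cat(sprintf("  %d subjects, %d observations\n", x$n_subjects, x$n_obs))
  invisible(x)
}

#' Intra-individual Spearman correlation profiles
#'
#' One Spearman rank correlation per subject, to display the trend within
#' each patient alongside the pooled repeated-measures correlation.
#' Subjects with constant `x` or `y` get `NA`; subjects with only 2 pairs
#' yield +/-1 by construction and are flagged `low_n`.
#'
#' @inheritParams rmcorr
#' @return data.frame: `subject`, `rho`, `n_pairs`, `low_n`.
#' @export
per_subject_spearman <- function(subjects, x, y) {
  ok <- stats::complete.cases(subjects, x, y)
  subjects <- as.character(subjects[ok]); x <- x[ok]; y <- y[ok]
  ids <- unique(subjects)
  rows <- lapply(ids, function(s) {
    xi <- x[subjects == s]; yi <- y[subjects == s]
    n <- length(xi)
    if (n < 2L) return(NULL)
    rho <- if (sd(rank(xi)) == 0 || sd(rank(yi)) == 0) NA_real_
           else cor(rank(xi), rank(yi))
    data.frame(subject = s, rho = rho, n_pairs = n, low_n = n < 3L)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject = character(0), rho = numeric(0),
                      n_pairs = integer(0), low_n = logical(0))
  rownames(out) <- NULL
  out
}
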