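# Independent brute-force oracles, kept deliberately naive.

# Passing-Bablok slope by exhaustive double-loop enumeration
bf_pb_slope <- function(x, y) {
  s <- c()
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) next
    v <- if (dx == 0) sign(dy) * Inf else dy / dx
    if (v != -1) s <- c(s, v)
  }
  s <- sort(s)
  N <- length(s)
  K <- sum(s < -1)
  clamp <- function(i) min(max(i, 1), N)   # shared boundary convention
  b <- if (N %% 2 == 1) s[clamp((N + 1) / 2 + K)]
       else mean(c(s[clamp(N / 2 + K)], s[clamp(N / 2 + 1 + K)]))
  a <- median(y - b * x)
  list(slope = b, intercept = a)
}

# AUC by exhaustive positive/negative pair counting, ties scored 1/2
bf_auc_pairs <- function(scores, labels, direction = "higher") {
  if (direction == "lower") scores <- -scores
  sp <- scores[as.logical(labels)]
  sn <- scores[!as.logical(labels)]
  tot <- 0
  for (p in sp) for (q in sn)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(sp) * length(sn))
}

# Youden scan over every midpoint threshold plus sentinels
bf_best_youden <- function(scores, labels, direction = "lower") {
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- -Inf
  for (t in thr) {
    call_pos <- if (direction == "lower") scores <= t else scores >= t
    sens <- sum(call_pos & labels) / sum(labels)
    spec <- sum(!call_pos & !labels) / sum(!labels)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Spearman rho from the definition: Pearson correlation of average ranks
bf_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# quiet pROC helpers (independent ROC/DeLong oracle)
proc_auc <- function(scores, labels) {
  as.numeric(pROC::auc(pROC::roc(labels, scores, direction = "<",
                                 quiet = TRUE)))
}

# small noise-free simulated train used across tests
clean_train <- function(mean_rr = 15, mean_exdi = 1.2, duration = 60,
                        fs = 200, seed = 7, ...) {
  ph <- breath_phenotype(mean_exdi = mean_exdi, exdi_cv = 0,
                         mean_rr = mean_rr, rr_cv = 0, pdi_gain = 10,
                         pdi_noise_sd = 0, artifact_rate = 0, ...)
  simulate_breath_train(ph, duration, fs, seed = seed)
}

# fast, small cohort parameterization for pipeline-level tests
tiny_cohort <- function(n = 4, seed = 42, ...) {
  cohort_params(n_patients = n, seed = seed, ...)
}
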