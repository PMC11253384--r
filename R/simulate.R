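# lognormal draws parameterized by mean m and coefficient of variation cv
rlnorm_mean_cv <- function(n, m, cv) {
  if (cv <= 0) return(rep(m, n))
  s2 <- log(1 + cv^2)
  exp(rnorm(n, log(m) - s2 / 2, sqrt(s2)))
}

# derive child seeds from a master seed without disturbing the caller's RNG
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a train of breaths as a multichannel waveform
#'
#' Generates one continuous segment of synthetic respiratory signals from a
#' [breath_phenotype()], together with the ground truth needed to validate
#' every downstream analysis stage. Breaths are concatenated; within each
#' breath of duration `d` and inspiratory time `Ti = insp_fraction * d`:
#'
#' * displacement rises as a raised cosine from 0 to the breath's excursion
#'   `E` over `Ti`, then relaxes exponentially with time constant
#'   `0.4 * (d - Ti)` (shifted/rescaled to reach zero at the breath end, so
#'   consecutive breaths join continuously);
#' * Pdi is a half-sine of amplitude `pdi_gain * E + noise` over `Ti` and
#'   zero during expiration; `pes = 5 - 0.4 * pdi` and `pga = pes + pdi`,
#'   so `pga - pes = pdi` holds to machine precision at every sample;
#' * flow is the analytic time-derivative of a volume trace that rises to
#'   `VT = vt_per_exdi * E` over inspiration and returns to zero by the end
#'   of the breath, so the full-cycle integral of `|flow|` is exactly `2 VT`;
#' * the sync channel is a 1 Hz rectangular pulse train (0.1 s pulses).
#'
#' Cough/swallow artifacts are added at Poisson rate `artifact_rate` as brief
#' (0.3-0.8 s) half-sine transients of 5x the typical displacement and Pdi
#' amplitudes, and logged in the ground truth. Identical seeds give identical
#' output.
#'
#' @param phenotype a [breath_phenotype()].
#' @param duration segment length (s), > 0.
#' @param fs sampling frequency (Hz), >= 50.
#' @param seed integer seed.
#' @return A list with elements `record` (a [waveform_record()] with
#'   channels `disp`, `pes`, `pga`, `pdi`, `flow`, `sync`) and `truth`
#'   (data.frame of complete breaths: `onset_s`, `peak_s`, `end_s`, `exdi`,
#'   `pcvdi`, `pdi_amp`, `vt_ml`; attribute `artifacts` holds a data.frame
#'   of artifact `start_s`/`end_s` intervals).
#' @export
simulate_breath_train <- function(phenotype, duration, fs = 200, seed = 1L) {
  stopifnot(inherits(phenotype, "breath_phenotype"))
  if (!is.numeric(duration) || duration <= 0)
    stopf("duration must be positive")
  if (!is.numeric(fs) || fs < 50)
    stopf("fs must be >= 50 Hz")
  p <- phenotype
  set.seed(seed)

  # breath durations until the segment is covered
  mean_d <- 60 / p$mean_rr
  durs <- numeric(0)
  while (sum(durs) < duration + mean_d) {
    k <- max(16L, ceiling((duration - sum(durs)) / mean_d * 1.5))
    durs <- c(durs, rlnorm_mean_cv(k, mean_d, p$rr_cv))
  }
  onsets <- cumsum(c(0, durs))
  nb_all <- max(which(onsets < duration - 1e-9))      # breaths that start in-segment
  durs <- durs[seq_len(nb_all)]
  onsets <- onsets[seq_len(nb_all)]
  ends <- onsets + durs
  complete <- ends <= duration + 1e-9

  exdi <- rlnorm_mean_cv(nb_all, p$mean_exdi, p$exdi_cv)
  pdi_amp <- p$pdi_gain * exdi +
    if (p$pdi_noise_sd > 0) rnorm(nb_all, 0, p$pdi_noise_sd) else 0
  vt_l <- p$vt_per_exdi * exdi / 1000
  ti <- p$insp_fraction * durs
  te <- durs - ti
  tau <- 0.4 * te

  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1L) / fs
  bi <- findInterval(t, onsets)                        # breath index per sample
  tb <- t - onsets[bi]                                 # time within breath
  ti_s <- ti[bi]; te_s <- te[bi]; tau_s <- tau[bi]
  e_s <- exdi[bi]; a_s <- pdi_amp[bi]; vt_s <- vt_l[bi]
  insp <- tb < ti_s

  # expiratory relaxation: exponential with time constant 0.4 Te, shifted
  # and rescaled to end exactly at zero so breaths concatenate continuously
  r_end <- exp(-te_s / tau_s)
  disp <- ifelse(insp, e_s / 2 * (1 - cos(pi * tb / ti_s)),
                 e_s * (exp(-(tb - ti_s) / tau_s) - r_end) / (1 - r_end))
  pdi <- ifelse(insp, a_s * sin(pi * tb / ti_s), 0)
  flow <- ifelse(insp, vt_s / 2 * pi / ti_s * sin(pi * tb / ti_s),
                 -vt_s / 2 * pi / te_s * sin(pi * (tb - ti_s) / te_s))
  sync <- as.numeric((t %% 1) < 0.1)

  # artifacts: Poisson count over the segment, half-sine transients
  n_art <- if (p$artifact_rate > 0) rpois(1L, p$artifact_rate * duration / 60) else 0L
  artifacts <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (n_art > 0L) {
    a_start <- sort(runif(n_art, 0, duration - 0.8))
    a_dur <- runif(n_art, 0.3, 0.8)
    for (k in seq_len(n_art)) {
      idx <- which(t >= a_start[k] & t < a_start[k] + a_dur[k])
      if (!length(idx)) next
      shape <- sin(pi * (t[idx] - a_start[k]) / a_dur[k])
      disp[idx] <- disp[idx] + 5 * p$mean_exdi * shape
      pdi[idx] <- pdi[idx] + 5 * p$pdi_gain * p$mean_exdi * shape
    }
    artifacts <- data.frame(start_s = a_start, end_s = a_start + a_dur)
  }
  pes <- 5 - 0.4 * pdi
  pga <- pes + pdi

  rec <- waveform_record(list(disp = disp, pes = pes, pga = pga, pdi = pdi,
                              flow = flow, sync = sync), fs = fs)
  truth <- data.frame(onset_s = onsets, peak_s = onsets + ti, end_s = ends,
                      exdi = exdi, pcvdi = exdi * pi / (2 * ti),
                      pdi_amp = pdi_amp, vt_ml = vt_l * 1000)[complete, ,
                                                             drop = FALSE]
  rownames(truth) <- NULL
  attr(truth, "artifacts") <- artifacts
  list(record = rec, truth = truth)
}

#' Simulate one patient session (baseline, SBT, recovery)
#'
#' Builds a full monitored session: a baseline recording, the spontaneous
#' breathing trial (SBT) and a recovery recording, concatenated into one
#' waveform record with phase annotations. Failure patients keep the failure
#' phenotype throughout; when `sbt_failed = TRUE` the trial is truncated at a
#' uniformly drawn time between minute 3 and the scheduled SBT end (the
#' least-informative choice given only a count of intra-trial failures).
#'
#' Two paired snapshot measurements per metric (EXdi, PCVdi) emulate the
#' pre-SBT and post-SBT handheld ultrasound exams: the continuous-monitor
#' value is the 5% trimmed mean of 10 consecutive true breath values (the
#' last 10 baseline breaths / first 10 recovery breaths) and the snapshot
#' value adds `Gaussian(snapshot_bias, snapshot_noise_sd)` error plus, for
#' designated poor-agreement patients, a fixed patient-level offset. PCVdi
#' snapshot error is scaled 2.5x (velocity agreement is looser than
#' excursion agreement on the cm vs cm/s scales).
#'
#' @param params a [cohort_params()].
#' @param outcome `"success"` or `"failure"`.
#' @param seed integer seed for this patient.
#' @param fs sampling frequency (Hz).
#' @param baseline_min,sbt_min,recovery_min phase durations (minutes).
#' @param patient_id identifier stored in the record.
#' @param poor_agreement logical: is this the poor-agreement subgroup?
#' @param sbt_failed logical or `NA`; `NA` draws it from
#'   `params$sbt_failure_fraction` for failure patients.
#' @return A list of class `patient_dataset`: `record`, `truth` (per-phase
#'   list), `snapshots` (data.frame with one row per phase x metric),
#'   `outcome`, `sbt_failed`, `sbt_duration_s`, `patient_id`.
#' @export
simulate_patient <- function(params, outcome, seed = 1L, fs = 200,
                             baseline_min = 15, sbt_min = 30,
                             recovery_min = 15, patient_id = "P1",
                             poor_agreement = FALSE, sbt_failed = NA) {
  stopifnot(inherits(params, "cohort_params"))
  if (!outcome %in% c("success", "failure"))
    stopf("unknown outcome label '%s'", outcome)
  pheno <- if (outcome == "failure") params$failure_phenotype
           else params$success_phenotype
  set.seed(seed)
  # patient-level median excursion jitter (between-patient heterogeneity)
  if (pheno$between_cv > 0) {
    sig_b <- sqrt(log(1 + pheno$between_cv^2))
    pheno$mean_exdi <- pheno$mean_exdi * exp(rnorm(1L, 0, sig_b))
  }
  if (is.na(sbt_failed))
    sbt_failed <- outcome == "failure" && runif(1L) < params$sbt_failure_fraction
  sbt_dur_min <- sbt_min
  if (isTRUE(sbt_failed) && sbt_min > 3)
    sbt_dur_min <- runif(1L, 3, sbt_min)
  poor_offset <- if (poor_agreement)
    sample(c(-1, 1), 1L) * 3 * params$snapshot_noise_sd else 0
  phase_seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  snap_noise <- rnorm(4L)                      # pre/post x exdi/pcvdi

  sims <- list(
    baseline = simulate_breath_train(pheno, baseline_min * 60, fs, phase_seeds[1L]),
    sbt      = simulate_breath_train(pheno, sbt_dur_min * 60, fs, phase_seeds[2L]),
    recovery = simulate_breath_train(pheno, recovery_min * 60, fs, phase_seeds[3L]))

  offs <- cumsum(c(0, vapply(sims, function(s) s$record$n / fs, numeric(1))))
  channels <- lapply(names(sims[[1L]]$record$channels), function(ch)
    unlist(lapply(sims, function(s) s$record$channels[[ch]]), use.names = FALSE))
  names(channels) <- names(sims[[1L]]$record$channels)
  phases <- data.frame(phase = c("baseline", "sbt", "recovery"),
                       start_s = offs[1:3], end_s = offs[2:4])
  rec <- waveform_record(channels, fs = fs, patient_id = patient_id,
                         phases = phases)

  truth <- lapply(seq_along(sims), function(i) {
    tr <- sims[[i]]$truth
    tr$onset_s <- tr$onset_s + offs[i]
    tr$peak_s <- tr$peak_s + offs[i]
    tr$end_s <- tr$end_s + offs[i]
    ar <- attr(sims[[i]]$truth, "artifacts")
    ar$start_s <- ar$start_s + offs[i]; ar$end_s <- ar$end_s + offs[i]
    attr(tr, "artifacts") <- ar
    tr
  })
  names(truth) <- names(sims)

  snap_one <- function(values10, noise_z, scale) {
    cont <- trimmed_mean(values10, 0.05)
    data.frame(value_continuous = cont,
               value_snapshot = cont + scale *
                 (params$snapshot_bias + params$snapshot_noise_sd * noise_z +
                    poor_offset))
  }
  pre_ex <- tail(truth$baseline$exdi, 10L)
  pre_pc <- tail(truth$baseline$pcvdi, 10L)
  post_ex <- head(truth$recovery$exdi, 10L)
  post_pc <- head(truth$recovery$pcvdi, 10L)
  snapshots <- rbind(
    cbind(phase = "pre", metric = "exdi", snap_one(pre_ex, snap_noise[1L], 1)),
    cbind(phase = "pre", metric = "pcvdi", snap_one(pre_pc, snap_noise[2L], 2.5)),
    cbind(phase = "post", metric = "exdi", snap_one(post_ex, snap_noise[3L], 1)),
    cbind(phase = "post", metric = "pcvdi", snap_one(post_pc, snap_noise[4L], 2.5)))
  snapshots <- cbind(patient_id = patient_id, snapshots)

  structure(list(record = rec, truth = truth, snapshots = snapshots,
                 outcome = outcome, sbt_failed = sbt_failed,
                 sbt_duration_s = sbt_dur_min * 60, patient_id = patient_id),
            class = "patient_dataset")
}

#' Plan a cohort: outcome labels, subgroup flags and per-patient seeds
#'
#' Deterministic cohort bookkeeping: exactly
#' `round(n_patients * failure_prevalence)` patients are labelled failures
#' (stratified assignment, shuffled by the master seed), the poor-agreement
#' subgroup is drawn as an exact-count subset, and every patient receives a
#' derived seed. All columns are pure functions of `params` (including
#' `params$seed`).
#'
#' @param params a [cohort_params()].
#' @return data.frame with columns `patient_id`, `outcome`,
#'   `poor_agreement`, `seed`.
#' @export
cohort_plan <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_patients
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  n_fail <- round(n * params$failure_prevalence)
  outcome <- sample(rep(c("failure", "success"), c(n_fail, n - n_fail)))
  n_poor <- round(n * params$poor_agreement_fraction)
  poor <- logical(n)
  poor[sample.int(n, n_poor)] <- TRUE
  data.frame(patient_id = sprintf("P%02d", seq_len(n)), outcome = outcome,
             poor_agreement = poor,
             seed = sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate a full synthetic cohort
#'
#' Materializes every patient session of the plan given by [cohort_plan()].
#' For long sessions at 200 Hz this holds all waveforms in memory; the
#' streaming alternative used by [run_study()] analyzes each patient and
#' discards the waveforms.
#'
#' @inheritParams simulate_patient
#' @param params a [cohort_params()].
#' @return A list of class `cohort`: `plan` and `patients` (list of
#'   `patient_dataset`).
#' @export
simulate_cohort <- function(params, fs = 200, baseline_min = 15,
                            sbt_min = 30, recovery_min = 15) {
  plan <- cohort_plan(params)
  patients <- lapply(seq_len(nrow(plan)), function(i)
    simulate_patient(params, plan$outcome[i], seed = plan$seed[i], fs = fs,
                     baseline_min = baseline_min, sbt_min = sbt_min,
                     recovery_min = recovery_min,
                     patient_id = plan$patient_id[i],
                     poor_agreement = plan$poor_agreement[i]))
  structure(list(plan = plan, patients = patients), class = "cohort")
}

#' Simulate within-subject effort-excursion pairs at a target correlation
#'
#' Lightweight generator for minute-level (excursion, pressure-index) pairs
#' with an exactly calibrated within-subject Pearson correlation, used to
#' study the repeated-measures correlation estimator at the weak coupling
#' levels seen between EXdi and Pdi-derived indices. Within subject `s`,
#' `x` is lognormal with subject median `m_s` and CV `cv_x`, and
#' `y = alpha_s + gain * x + e` with `e ~ N(0, sigma)`. Mirroring the
#' phenotype coupling model (one noise SD per phenotype, not per subject),
#' `sigma` is a single constant calibrated so that the pooled within-subject
#' correlation equals `r_within`:
#' `sigma = gain * sqrt(E[var_s]) * sqrt(1 / r_within^2 - 1)`, where
#' `E[var_s] = (mean_x * cv_x)^2 * exp(2 * log(1 + between_cv^2))` is the
#' population mean within-subject variance of `x`.
#'
#' @param n_subjects number of subjects.
#' @param pairs_per_subject observations per subject.
#' @param r_within target within-subject correlation, in `(0, 1)`.
#' @param mean_x population median of the subject-level `x` medians.
#' @param cv_x within-subject CV of `x`.
#' @param between_cv between-subject CV of the `x` medians.
#' @param gain slope relating `y` to `x`.
#' @param intercept_sd SD of the subject-level intercepts of `y`.
#' @param seed integer seed.
#' @return data.frame with columns `subject`, `x`, `y`.
#' @export
simulate_effort_pairs <- function(n_subjects = 30, pairs_per_subject = 25,
                                  r_within = 0.22, mean_x = 1.0, cv_x = 0.25,
                                  between_cv = 0.5, gain = 12,
                                  intercept_sd = 4, seed = 1L) {
  if (r_within <= 0 || r_within >= 1) stopf("r_within must lie in (0, 1)")
  set.seed(seed)
  sig_b <- sqrt(log(1 + between_cv^2))
  m_s <- mean_x * exp(rnorm(n_subjects, 0, sig_b))
  alpha_s <- rnorm(n_subjects, 0, intercept_sd)
  # population mean within-subject SD of x: lognormal(m, cv) has sd m * cv
  sd_pool <- mean_x * cv_x * exp(sig_b^2)
  sigma <- gain * sd_pool * sqrt(1 / r_within^2 - 1)
  out <- lapply(seq_len(n_subjects), function(s) {
    x <- rlnorm_mean_cv(pairs_per_subject, m_s[s], cv_x)
    y <- alpha_s[s] + gain * x + rnorm(pairs_per_subject, 0, sigma)
    data.frame(subject = sprintf("S%02d", s), x = x, y = y)
  })
  do.call(rbind, out)
}
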