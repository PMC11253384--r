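#' Study configuration for an end-to-end synthetic run
#'
#' Bundles cohort parameters, session geometry and analysis settings for
#' [run_study()]. Defaults reproduce the monitored-weaning protocol: a
#' 15-min baseline recording, a 30-min spontaneous breathing trial, a
#' 15-min recovery, signals at 200 Hz, minute summaries at 1-5, 10, 20 and
#' 30 min after SBT onset, and prediction from the minute-2 excursion with
#' "lower predicts failure" orientation. Reduced `fs` and phase durations
#' give proportionally faster runs for simulation studies.
#'
#' @param cohort a [cohort_params()].
#' @param fs sampling frequency (Hz), >= 50.
#' @param baseline_min,sbt_min,recovery_min phase durations (minutes).
#' @param timepoints minutes after SBT onset for [minute_summary()].
#' @param prediction_minute which timepoint feeds the ROC analysis.
#' @param prediction_metric `"exdi"` or `"pcvdi"`.
#' @param direction ROC orientation, see [roc_curve()].
#' @param boot_B bootstrap replicates for [bootstrap_roc()].
#' @param out_dir optional directory for JSON report files.
#' @return list of class `study_config`.
#' @export
study_config <- function(cohort = cohort_params(), fs = 200,
                         baseline_min = 15, sbt_min = 30, recovery_min = 15,
                         timepoints = c(1, 2, 3, 4, 5, 10, 20, 30),
                         prediction_minute = 2,
                         prediction_metric = c("exdi", "pcvdi"),
                         direction = c("lower", "higher"),
                         boot_B = 1000L, out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_params"))
  if (fs < 50) stopf("fs must be >= 50 Hz")
  if (any(timepoints <= 0)) stopf("timepoints must be positive")
  if (!prediction_minute %in% timepoints)
    stopf("prediction_minute must be one of the timepoints")
  structure(list(cohort = cohort, fs = fs, baseline_min = baseline_min,
                 sbt_min = sbt_min, recovery_min = recovery_min,
                 timepoints = timepoints,
                 prediction_minute = prediction_minute,
                 prediction_metric = match.arg(prediction_metric),
                 direction = match.arg(direction),
                 boot_B = as.integer(boot_B), out_dir = out_dir),
            class = "study_config")
}

#' Analyze one patient session: breaths, validity, metrics, summaries
#'
#' The per-patient analysis chain: breath detection by Pdi zero crossings,
#' automated artifact flagging, per-breath metrics, and trimmed minute
#' summaries over the SBT. Summary windows are confined to the SBT phase,
#' so a truncated trial yields summaries only for the minutes it reached.
#'
#' @param patient a `patient_dataset` from [simulate_patient()].
#' @param timepoints minutes after SBT onset.
#' @return list: `breath_table`, `summaries`.
#' @export
analyze_patient <- function(patient, timepoints = c(1, 2, 3, 4, 5, 10, 20, 30)) {
  rec <- patient$record
  fs <- rec$fs
  br <- detect_breaths(rec$channels$pdi, fs, amplitude_floor = 0.5)
  br <- reject_artifacts(br, rec$channels$pdi, fs)
  bt <- compute_breath_metrics(rec, br)
  sbt <- rec$phases[rec$phases$phase == "sbt", ]
  sm <- minute_summary(bt, fs,
                       record_duration_s = sbt$start_s + patient$sbt_duration_s,
                       sbt_start = sbt$start_s, timepoints = timepoints)
  if (nrow(sm)) {
    sm <- cbind(patient_id = patient$patient_id, outcome = patient$outcome, sm)
  }
  list(breath_table = bt, summaries = sm)
}

#' Run the full synthetic study pipeline
#'
#' Simulates the cohort patient by patient (waveforms are analyzed and
#' discarded, so memory stays flat), then runs every analysis stage:
#'
#' 1. per-patient breath tables and trimmed minute summaries;
#' 2. method agreement on the pooled pre+post snapshot pairs
#'    (Bland-Altman with per-patient good/poor classification,
#'    Passing-Bablok with CUSUM linearity, Spearman), per metric;
#' 3. weaning-failure prediction from the configured minute and metric
#'    (ROC, Youden cutoff, diagnostic metrics with exact CIs, stratified
#'    bootstrap, DeLong comparison of the EXdi and PCVdi AUCs);
#' 4. repeated-measures correlation of the SBT minute series of EXdi
#'    against peak Pdi and against the pressure-time product, with
#'    intra-individual Spearman profiles.
#'
#' Everything is a pure function of the configuration (including its master
#' seed): two runs with the same config produce identical reports. When
#' `config$out_dir` is set, a JSON report and the summary tables are
#' written there.
#'
#' @param config a [study_config()].
#' @return list of class `study_report`: `plan`, `summaries`, `snapshots`,
#'   `agreement` (per metric), `prediction`, `rmcorr`, `manifest`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  params <- config$cohort
  plan <- cohort_plan(params)

  summaries <- list()
  snapshots <- list()
  outcomes <- data.frame(patient_id = plan$patient_id, outcome = plan$outcome,
                         sbt_failed = NA)
  for (i in seq_len(nrow(plan))) {
    pat <- simulate_patient(params, plan$outcome[i], seed = plan$seed[i],
                            fs = config$fs, baseline_min = config$baseline_min,
                            sbt_min = config$sbt_min,
                            recovery_min = config$recovery_min,
                            patient_id = plan$patient_id[i],
                            poor_agreement = plan$poor_agreement[i])
    res <- analyze_patient(pat, config$timepoints)
    summaries[[i]] <- res$summaries
    snapshots[[i]] <- pat$snapshots
    outcomes$sbt_failed[i] <- pat$sbt_failed
  }
  summaries <- do.call(rbind, summaries)
  snapshots <- do.call(rbind, snapshots)

  agreement <- lapply(c(exdi = "exdi", pcvdi = "pcvdi"), function(metric) {
    pp <- snapshot_pairs(snapshots, metric)
    ba <- bland_altman(pp$value_continuous, pp$value_snapshot)
    diffs <- split(pp$value_snapshot - pp$value_continuous, pp$patient_id)
    list(bland_altman = ba,
         patient_class = classify_agreement(diffs, ba),
         passing_bablok = passing_bablok(pp$value_continuous,
                                         pp$value_snapshot),
         spearman = spearman_cor(pp$value_continuous, pp$value_snapshot),
         n_pairs = nrow(pp))
  })

  m2 <- summaries[summaries$minute == config$prediction_minute, ]
  labels <- m2$outcome == "failure"
  metric_col <- paste0(config$prediction_metric, "_tm")
  scores <- m2[[metric_col]]
  prediction <- NULL
  if (sum(labels, na.rm = TRUE) && sum(!labels, na.rm = TRUE)) {
    roc <- roc_curve(scores, labels, config$direction)
    cutoff <- youden_cutoff(roc)
    boot_seed <- (params$seed + 1000003L) %% (.Machine$integer.max - 1L)
    boot <- bootstrap_roc(scores, labels, B = config$boot_B,
                          seed = boot_seed, direction = config$direction)
    roc$auc_ci_low <- boot$auc_ci[1L]
    roc$auc_ci_high <- boot$auc_ci[2L]
    dl <- delong_test(m2$exdi_tm, m2$pcvdi_tm, labels, direction = "lower")
    prediction <- list(
      minute = config$prediction_minute, metric = config$prediction_metric,
      roc = roc, cutoff = cutoff,
      performance = if (is.finite(cutoff))
        diagnostic_metrics(scores, labels, cutoff, config$direction)
      else NULL,
      bootstrap = boot[c("auc_ci", "cutoff_ci", "n_redrawn")],
      delong_exdi_vs_pcvdi = dl)
  }

  sbt_sum <- summaries[!is.na(summaries$exdi_tm), ]
  rm_pdi <- rmcorr(sbt_sum$patient_id, sbt_sum$exdi_tm, sbt_sum$pdi_peak_tm)
  rm_ptp <- rmcorr(sbt_sum$patient_id, sbt_sum$exdi_tm, sbt_sum$ptpdi_per_min)
  rmc <- list(exdi_vs_pdi_peak = rm_pdi, exdi_vs_ptpdi = rm_ptp,
              per_subject = per_subject_spearman(sbt_sum$patient_id,
                                                 sbt_sum$exdi_tm,
                                                 sbt_sum$pdi_peak_tm))

  manifest <- list(package_version = as.character(utils::packageVersion("diaphmon")),
                   seed = params$seed, n_patients = params$n_patients,
                   fs = config$fs, config_hash = config_hash(config))
  report <- structure(list(plan = plan, outcomes = outcomes,
                           summaries = summaries, snapshots = snapshots,
                           agreement = agreement, prediction = prediction,
                           rmcorr = rmc, manifest = manifest),
                      class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

# md5 of the canonical JSON serialization of the config
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}

#' Write a study report to disk
#'
#' Emits `report.json` (agreement, prediction, rmcorr and manifest in
#' machine-readable form) plus `minute_summaries.csv` and `snapshots.csv`.
#' Output is byte-stable for a fixed configuration.
#'
#' @param report a `study_report` from [run_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slim <- list(agreement = lapply(report$agreement, function(a)
    list(bland_altman = unclass(a$bland_altman),
         patient_class = as.list(a$patient_class),
         passing_bablok = unclass(a$passing_bablok),
         spearman = a$spearman, n_pairs = a$n_pairs)),
    prediction = if (!is.null(report$prediction)) list(
      minute = report$prediction$minute,
      metric = report$prediction$metric,
      auc = report$prediction$roc$auc,
      auc_ci = c(report$prediction$roc$auc_ci_low,
                 report$prediction$roc$auc_ci_high),
      cutoff = report$prediction$cutoff,
      performance = unclass(report$prediction$performance),
      delong = report$prediction$delong_exdi_vs_pcvdi),
    rmcorr = list(exdi_vs_pdi_peak = unclass(report$rmcorr$exdi_vs_pdi_peak),
                  exdi_vs_ptpdi = unclass(report$rmcorr$exdi_vs_ptpdi)),
    manifest = report$manifest)
  jsonlite::write_json(slim, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null", pretty = TRUE)
  data.table::fwrite(report$summaries, file.path(dir, "minute_summaries.csv"))
  data.table::fwrite(report$snapshots, file.path(dir, "snapshots.csv"))
  invisible(dir)
}

#' Extract paired continuous/snapshot measurements for one metric
#'
#' @param snapshots the `snapshots` table of a cohort or study report.
#' @param metric `"exdi"` or `"pcvdi"`.
#' @return data.frame: `patient_id`, `phase`, `value_continuous`,
#'   `value_snapshot` — one pre and one post row per patient.
#' @export
snapshot_pairs <- function(snapshots, metric = c("exdi", "pcvdi")) {
  metric <- match.arg(metric)
  out <- snapshots[snapshots$metric == metric,
                   c("patient_id", "phase", "value_continuous",
                     "value_snapshot")]
  rownames(out) <- NULL
  out
}

#' Composite weaning outcome from trial result and reintubation status
#'
#' Weaning failure is failing the spontaneous breathing trial, or passing
#' it but requiring reintubation within 48 h of extubation.
#'
#' @param sbt_passed logical vector: did the patient pass the SBT?
#' @param reintubated_48h logical vector: reintubation within 48 h (only
#'   meaningful for SBT passers; `NA` allowed for SBT failures).
#' @return character vector, `"failure"` or `"success"`.
#' @export
weaning_outcome <- function(sbt_passed, reintubated_48h) {
  stopifnot(length(sbt_passed) == length(reintubated_48h))
  ifelse(!sbt_passed | (!is.na(reintubated_48h) & reintubated_48h),
         "failure", "success")
}

#' Sample size for comparing two proportions (normal approximation)
#'
#' Per-group sample size
#' `n = ceiling((z_a sqrt(2 p q ) + z_b sqrt(p1 q1 + p2 q2))^2 / (p1-p2)^2)`
#' with pooled `p = (p1 + p2) / 2`, `z_a = qnorm(1 - alpha/sided)` and
#' `z_b = qnorm(power)`.
#'
#' @param p1,p2 the two event proportions, `0 < p2 < p1 < 1`.
#' @param alpha type I error rate.
#' @param power target power.
#' @param sided 1 or 2.
#' @return integer sample size per group (`Inf` when `p1 == p2`).
#' @export
sample_size_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.8,
                                        sided = 2) {
  if (!sided %in% c(1, 2)) stopf("sided must be 1 or 2")
  if (p1 == p2) return(Inf)
  if (!(p2 > 0 && p1 < 1 && p2 < p1))
    stopf("need 0 < p2 < p1 < 1")
  za <- qnorm(1 - alpha / sided)
  zb <- qnorm(power)
  pbar <- (p1 + p2) / 2
  ceiling((za * sqrt(2 * pbar * (1 - pbar)) +
             zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2)
}
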