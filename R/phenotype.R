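#' Breath phenotype: subject-level breathing pattern parameters
#'
#' A breath phenotype collects the subject-level parameters that drive the
#' synthetic waveform generator: how deep and how fast the patient breathes,
#' how tightly transdiaphragmatic pressure (Pdi) is coupled to diaphragm
#' excursion (EXdi), and how often motion artifacts (cough, swallow) occur.
#'
#' Per-breath excursion is drawn from a lognormal distribution with mean
#' `mean_exdi` and coefficient of variation `exdi_cv`; breath durations are
#' lognormal around `60/mean_rr` with CV `rr_cv`. The Pdi amplitude of each
#' breath is `pdi_gain * excursion` plus zero-mean Gaussian noise with SD
#' `pdi_noise_sd`, so the within-subject Pdi-EXdi correlation is a decreasing
#' function of `pdi_noise_sd`. `between_cv` is the lognormal CV of the
#' patient-level median excursion within a cohort group; it creates the
#' between-patient spread that interquartile ranges of real weaning cohorts
#' show, without which every simulated patient of a group would be identical.
#'
#' @param mean_exdi mean per-breath diaphragm excursion (cm).
#' @param exdi_cv breath-to-breath coefficient of variation of excursion,
#'   in `[0, 1)`.
#' @param mean_rr mean respiratory rate (breaths/min).
#' @param rr_cv breath-to-breath CV of breath duration, in `[0, 1)`.
#' @param pdi_gain subject-level coupling of Pdi amplitude to excursion
#'   (cmH2O per cm).
#' @param pdi_noise_sd SD of the per-breath Pdi amplitude noise (cmH2O).
#' @param vt_per_exdi tidal volume generated per cm of excursion (mL/cm).
#' @param artifact_rate cough/swallow artifact rate (events/min).
#' @param insp_fraction inspiratory fraction of the breath cycle, in
#'   `(0.2, 0.6)`.
#' @param between_cv between-patient lognormal CV of the patient median
#'   excursion (dimensionless).
#'
#' @return An object of class `breath_phenotype` (a named list).
#' @seealso [phenotype_weaning_success()], [phenotype_weaning_failure()],
#'   [simulate_breath_train()]
#' @export
breath_phenotype <- function(mean_exdi = 1.0, exdi_cv = 0.25,
                             mean_rr = 26, rr_cv = 0.08,
                             pdi_gain = 12, pdi_noise_sd = 2.5,
                             vt_per_exdi = 400, artifact_rate = 0.5,
                             insp_fraction = 0.4, between_cv = 0.5) {
  p <- list(mean_exdi = mean_exdi, exdi_cv = exdi_cv, mean_rr = mean_rr,
            rr_cv = rr_cv, pdi_gain = pdi_gain, pdi_noise_sd = pdi_noise_sd,
            vt_per_exdi = vt_per_exdi, artifact_rate = artifact_rate,
            insp_fraction = insp_fraction, between_cv = between_cv)
  scales <- c("mean_exdi", "mean_rr", "pdi_gain", "vt_per_exdi")
  for (f in scales)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] <= 0)
      stopf("phenotype field '%s' must be a positive scalar", f)
  for (f in c("pdi_noise_sd", "artifact_rate", "between_cv"))
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] < 0)
      stopf("phenotype field '%s' must be a non-negative scalar", f)
  if (p$insp_fraction <= 0.2 || p$insp_fraction >= 0.6)
    stopf("insp_fraction must lie in (0.2, 0.6)")
  for (f in c("exdi_cv", "rr_cv"))
    if (p[[f]] < 0 || p[[f]] >= 1)
      stopf("phenotype field '%s' must lie in [0, 1)", f)
  structure(p, class = "breath_phenotype")
}

#' Phenotype presets for weaning-success and weaning-failure patients
#'
#' Defaults emulate the minute-2 group profiles of a weaning cohort:
#' success patients with median EXdi 1.4 cm, RR 26/min, peak Pdi near
#' 13.5 cmH2O and tidal volume near 410 mL; failure patients with median
#' EXdi 0.8 cm, RR 27/min, peak Pdi near 15.9 cmH2O and tidal volume near
#' 437 mL (shallower but not weaker-pressure breathing). `pdi_gain` and
#' `vt_per_exdi` are the implied ratios; `between_cv` reproduces the wide
#' interquartile ranges of each group.
#'
#' @param ... overrides passed on to [breath_phenotype()].
#' @return A `breath_phenotype`.
#' @export
phenotype_weaning_success <- function(...) {
  args <- list(mean_exdi = 1.4, exdi_cv = 0.25, mean_rr = 26, rr_cv = 0.08,
               pdi_gain = 9.6, pdi_noise_sd = 2.5, vt_per_exdi = 294,
               artifact_rate = 0.5, insp_fraction = 0.4, between_cv = 0.7)
  args[names(list(...))] <- list(...)
  do.call(breath_phenotype, args)
}

#' @rdname phenotype_weaning_success
#' @export
phenotype_weaning_failure <- function(...) {
  args <- list(mean_exdi = 0.8, exdi_cv = 0.25, mean_rr = 27, rr_cv = 0.08,
               pdi_gain = 19.9, pdi_noise_sd = 2.5, vt_per_exdi = 546,
               artifact_rate = 0.5, insp_fraction = 0.4, between_cv = 0.4)
  args[names(list(...))] <- list(...)
  do.call(breath_phenotype, args)
}

#' Cohort parameters for the synthetic weaning study
#'
#' Bundles everything a reproducible synthetic cohort needs: size, outcome
#' prevalence, the two group phenotypes, the snapshot-ultrasound error model
#' and the master seed. Outcome labels are assigned by exact count
#' (`round(n_patients * failure_prevalence)` failures), not by Bernoulli
#' draws, so cohort-level tests are not flaky. Failure patients have their
#' spontaneous breathing trial truncated early (uniformly between minute 3
#' and the trial end) with probability `sbt_failure_fraction`; the remaining
#' failure patients complete the trial and are counted as post-extubation
#' reintubations.
#'
#' @param n_patients number of patients (>= 2).
#' @param failure_prevalence proportion of weaning failures in `[0, 1]`.
#' @param success_phenotype,failure_phenotype [breath_phenotype()] objects.
#' @param snapshot_noise_sd SD of the snapshot-ultrasound measurement error
#'   for excursion (cm).
#' @param snapshot_bias systematic snapshot-minus-continuous bias (cm).
#' @param poor_agreement_fraction fraction of patients given an extra
#'   patient-level snapshot offset (the poor-agreement subgroup).
#' @param sbt_failure_fraction among failure patients, fraction that fail
#'   during (and truncate) the trial rather than after extubation.
#' @param seed master integer seed; it fully determines all cohort output.
#'
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 46, failure_prevalence = 25 / 46,
                          success_phenotype = phenotype_weaning_success(),
                          failure_phenotype = phenotype_weaning_failure(),
                          snapshot_noise_sd = 0.35, snapshot_bias = 0.1,
                          poor_agreement_fraction = 0.15,
                          sbt_failure_fraction = 12 / 25,
                          seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 2)
    stopf("n_patients must be >= 2")
  if (failure_prevalence < 0 || failure_prevalence > 1)
    stopf("failure_prevalence must lie in [0, 1]")
  if (poor_agreement_fraction < 0 || poor_agreement_fraction > 1)
    stopf("poor_agreement_fraction must lie in [0, 1]")
  if (sbt_failure_fraction < 0 || sbt_failure_fraction > 1)
    stopf("sbt_failure_fraction must lie in [0, 1]")
  if (snapshot_noise_sd < 0) stopf("snapshot_noise_sd must be >= 0")
  stopifnot(inherits(success_phenotype, "breath_phenotype"),
            inherits(failure_phenotype, "breath_phenotype"))
  structure(list(n_patients = as.integer(n_patients),
                 failure_prevalence = failure_prevalence,
                 success_phenotype = success_phenotype,
                 failure_phenotype = failure_phenotype,
                 snapshot_noise_sd = snapshot_noise_sd,
                 snapshot_bias = snapshot_bias,
                 poor_agreement_fraction = poor_agreement_fraction,
                 sbt_failure_fraction = sbt_failure_fraction,
                 seed = as.integer(seed)),
            class = "cohort_params")
}
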