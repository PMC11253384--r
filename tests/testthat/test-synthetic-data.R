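test_that("breath timing and excursion are exact when variability is zero", {
  sim <- clean_train(mean_rr = 15, mean_exdi = 1.2, duration = 60)
  expect_equal(nrow(sim$truth), 15L)
  expect_equal(sim$truth$onset_s, seq(0, 56, by = 4))
  expect_equal(sim$truth$exdi, rep(1.2, 15))
  # Pdi amplitude is exactly gain * excursion without noise
  expect_equal(sim$truth$pdi_amp, rep(10 * 1.2, 15))
})

test_that("noise-free coupling gives a perfect within-subject correlation", {
  ph <- breath_phenotype(mean_exdi = 1.0, exdi_cv = 0.3, mean_rr = 20,
                         rr_cv = 0.1, pdi_gain = 8, pdi_noise_sd = 0,
                         artifact_rate = 0)
  sim <- simulate_breath_train(ph, 120, 200, seed = 3)
  expect_gt(nrow(sim$truth), 20)
  expect_equal(cor(sim$truth$pdi_amp, sim$truth$exdi,
                   method = "spearman"), 1)
})

test_that("pressure channels conserve pga - pes - pdi = 0 at every sample", {
  ph <- breath_phenotype(artifact_rate = 3)      # artifacts must not break it
  sim <- simulate_breath_train(ph, 90, 200, seed = 5)
  resid <- with(sim$record$channels, pga - pes - pdi)
  expect_lt(max(abs(resid)), 1e-12)
})

test_that("the waveform generator is a pure function of its seed", {
  ph <- breath_phenotype()
  a <- simulate_breath_train(ph, 45, 200, seed = 21)
  b <- simulate_breath_train(ph, 45, 200, seed = 21)
  c <- simulate_breath_train(ph, 45, 200, seed = 22)
  expect_identical(a, b)
  expect_false(identical(a$record$channels$disp, c$record$channels$disp))
})

test_that("realized Pdi-EXdi coupling decreases with amplitude noise", {
  rhos <- vapply(c(0.5, 3, 12), function(nsd) {
    ph <- breath_phenotype(exdi_cv = 0.3, pdi_noise_sd = nsd,
                           artifact_rate = 0)
    sim <- simulate_breath_train(ph, 600, 50, seed = 31)
    cor(sim$truth$pdi_amp, sim$truth$exdi, method = "spearman")
  }, numeric(1))
  expect_true(all(diff(rhos) < 0))
})

test_that("phenotype and cohort parameter invariants are enforced", {
  expect_error(breath_phenotype(mean_exdi = -1), "positive")
  expect_error(breath_phenotype(insp_fraction = 0.7), "insp_fraction")
  expect_error(breath_phenotype(exdi_cv = 1.2), "exdi_cv")
  expect_error(simulate_breath_train(breath_phenotype(), -5), "duration")
  expect_error(simulate_breath_train(breath_phenotype(), 60, fs = 10), "fs")
  expect_error(cohort_params(n_patients = 1), "n_patients")
  expect_error(cohort_params(failure_prevalence = 1.4), "prevalence")
})

test_that("noise-free snapshots equal the 10-breath trimmed mean of truth", {
  params <- tiny_cohort(snapshot_noise_sd = 0, snapshot_bias = 0,
                        poor_agreement_fraction = 0)
  pat <- simulate_patient(params, "success", seed = 9, fs = 50,
                          baseline_min = 1, sbt_min = 3, recovery_min = 1)
  pre <- pat$snapshots[pat$snapshots$phase == "pre" &
                         pat$snapshots$metric == "exdi", ]
  expect_equal(pre$value_snapshot, pre$value_continuous)
  expect_equal(pre$value_continuous,
               trimmed_mean(tail(pat$truth$baseline$exdi, 10), 0.05))
  post <- pat$snapshots[pat$snapshots$phase == "post" &
                          pat$snapshots$metric == "exdi", ]
  expect_equal(post$value_continuous,
               trimmed_mean(head(pat$truth$recovery$exdi, 10), 0.05))
})

test_that("patient simulation is deterministic and rejects unknown labels", {
  params <- tiny_cohort()
  a <- simulate_patient(params, "failure", seed = 4, fs = 50,
                        baseline_min = 1, sbt_min = 4, recovery_min = 1)
  b <- simulate_patient(params, "failure", seed = 4, fs = 50,
                        baseline_min = 1, sbt_min = 4, recovery_min = 1)
  expect_identical(a, b)
  expect_error(simulate_patient(params, "unknown", seed = 1), "outcome")
})

test_that("a truncated SBT ends between minute 3 and the scheduled end", {
  params <- tiny_cohort()
  pat <- simulate_patient(params, "failure", seed = 8, fs = 50,
                          baseline_min = 1, sbt_min = 30, recovery_min = 1,
                          sbt_failed = TRUE)
  expect_gte(pat$sbt_duration_s, 3 * 60)
  expect_lte(pat$sbt_duration_s, 30 * 60)
  full <- simulate_patient(params, "failure", seed = 8, fs = 50,
                           baseline_min = 1, sbt_min = 30, recovery_min = 1,
                           sbt_failed = FALSE)
  expect_equal(full$sbt_duration_s, 30 * 60)
})

test_that("cohort labels are assigned by exact count, not Bernoulli", {
  plan <- cohort_plan(cohort_params(n_patients = 46,
                                    failure_prevalence = 0.5435, seed = 1))
  expect_equal(sum(plan$outcome == "failure"), 25L)
  plan0 <- cohort_plan(cohort_params(n_patients = 20,
                                     failure_prevalence = 0, seed = 1))
  expect_true(all(plan0$outcome == "success"))
  # different master seeds: same label counts, different patient seeds
  p1 <- cohort_plan(cohort_params(n_patients = 48, seed = 10))
  p2 <- cohort_plan(cohort_params(n_patients = 48, seed = 11))
  expect_equal(sum(p1$outcome == "failure"), sum(p2$outcome == "failure"))
  expect_false(identical(p1$seed, p2$seed))
})

test_that("effort-pair generator hits its calibrated pooled correlation", {
  d <- simulate_effort_pairs(40, 50, r_within = 0.5, seed = 2)
  r <- rmcorr(d$subject, d$x, d$y)
  expect_lt(abs(r$r_rm - 0.5), 0.08)
  expect_identical(d, simulate_effort_pairs(40, 50, r_within = 0.5, seed = 2))
  expect_error(simulate_effort_pairs(10, 10, r_within = 1.2), "r_within")
})
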