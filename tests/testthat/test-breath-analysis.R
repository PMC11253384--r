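test_that("a 0.25 Hz sine segments into 15 breaths at upward crossings", {
  t <- (0:11999) / 200
  br <- detect_breaths(sin(2 * pi * 0.25 * t), 200, amplitude_floor = 0.05)
  expect_equal(nrow(br), 15L)
  # interior onsets sit at the upward zero crossings t = 8, 12, ..., 48;
  # within half a baseline window of either record edge the rolling median
  # of a sine is not exactly zero, so the outermost crossings shift slightly
  expect_true(all(abs((br$onset[3:13] - 1) / 200 - seq(8, 48, 4)) <= 2 / 200))
  expect_lt(max(abs((br$onset - 1) / 200 - seq(0, 56, 4))), 0.25)
})

test_that("degenerate signals yield an empty breath list, not an error", {
  expect_equal(nrow(detect_breaths(rep(0, 5000), 200)), 0L)
  expect_equal(nrow(detect_breaths(rep(3.7, 5000), 200)), 0L)
  expect_equal(nrow(detect_breaths(sin(1:100), 200)), 0L)   # < 2 s of signal
})

test_that("noise-free simulated trains are recovered exactly from Pdi", {
  sim <- clean_train(mean_rr = 20, duration = 60)
  br <- detect_breaths(sim$record$channels$pdi, 200)
  expect_equal(nrow(br), nrow(sim$truth))
  onset_err <- abs((br$onset - 1) / 200 - sim$truth$onset_s) * 200
  expect_true(all(onset_err <= 2))
})

test_that("a single inserted cough flags exactly the overlapping breath", {
  sim <- clean_train(mean_rr = 15, duration = 120, fs = 100)
  pdi <- sim$record$channels$pdi
  # transient on top of the 6th breath's inspiration (onset 20 s)
  idx <- which((0:(length(pdi) - 1)) / 100 >= 20.2 &
                 (0:(length(pdi) - 1)) / 100 < 20.7)
  pdi[idx] <- pdi[idx] + 5 * 12 * sin(pi * seq_along(idx) / length(idx))
  br <- detect_breaths(pdi, 100)
  br <- reject_artifacts(br, pdi, 100)
  bad <- which(!br$valid)
  onsets_s <- (br$onset - 1) / 100
  expect_length(bad, 1L)
  expect_true(onsets_s[bad] <= 20.7 && (br$end[bad] - 1) / 100 >= 20.2)
  # uniform train with no outliers: everything valid
  br0 <- reject_artifacts(detect_breaths(sim$record$channels$pdi, 100),
                          sim$record$channels$pdi, 100)
  expect_true(all(br0$valid))
  # k_mad = Inf disables amplitude flagging entirely
  brInf <- reject_artifacts(br, pdi, 100, k_mad = Inf)
  expect_true(all(brInf$valid))
})

test_that("simulator artifact log and automated flags agree", {
  ph <- breath_phenotype(exdi_cv = 0, rr_cv = 0, pdi_noise_sd = 0,
                         artifact_rate = 2)
  sim <- simulate_breath_train(ph, 300, 50, seed = 13)
  arts <- attr(sim$truth, "artifacts")
  expect_gt(nrow(arts), 0)
  br <- reject_artifacts(detect_breaths(sim$record$channels$pdi, 50),
                         sim$record$channels$pdi, 50)
  # every logged artifact overlaps at least one flagged breath
  onset_s <- (br$onset - 1) / 50
  end_s <- (br$end - 1) / 50
  for (k in seq_len(nrow(arts))) {
    overlap <- which(onset_s < arts$end_s[k] & end_s > arts$start_s[k])
    expect_true(any(!br$valid[overlap]))
  }
})

test_that("trimmed mean follows the floor rule per tail", {
  expect_equal(trimmed_mean(1:20, 0.05), mean(2:19))      # k = 1
  expect_equal(trimmed_mean(1:20, 0.05), 10.5)
  expect_equal(trimmed_mean(1:10, 0.05), mean(1:10))      # k = 0
  expect_equal(trimmed_mean(rep(4.2, 7), 0.2), 4.2)
  expect_true(is.na(trimmed_mean(numeric(0))))
  expect_error(trimmed_mean(1:5, 0.6), "fraction")
  # properties: bounded by the data, and fraction 0 is the plain mean
  for (i in 1:25) {
    v <- rnorm(sample(1:40, 1))
    f <- runif(1, 0, 0.49)
    tmv <- trimmed_mean(v, f)
    expect_gte(tmv, min(v))
    expect_lte(tmv, max(v))
    expect_equal(trimmed_mean(v, 0), mean(v))
  }
})

test_that("per-breath metrics match closed forms on constructed signals", {
  fs <- 200
  # triangle: 0 -> 1.2 cm over 1 s, back over 1 s
  tri <- c(seq(0, 1.2, length.out = fs + 1), seq(1.2, 0, length.out = fs + 1)[-1])
  rec <- waveform_record(list(disp = tri), fs = fs)
  breaths <- data.frame(onset = 1L, peak = fs + 1L, end = length(tri))
  bt <- compute_breath_metrics(rec, breaths)
  expect_equal(bt$exdi, 1.2)
  expect_equal(bt$pcvdi, 1.2, tolerance = 1e-10)

  # half-sine Pdi, A = 10, T = 1 s: PTP = 2AT/pi
  t <- (0:(2 * fs)) / fs
  pdi <- ifelse(t < 1, 10 * sin(pi * t), 0)
  rec2 <- waveform_record(list(disp = pdi / 10, pdi = pdi), fs = fs)
  bt2 <- compute_breath_metrics(rec2, data.frame(onset = 1L, peak = fs %/% 2L,
                                                 end = length(t)))
  expect_equal(bt2$ptpdi, 2 * 10 * 1 / pi, tolerance = 1e-3)
  expect_equal(bt2$pdi_peak, 10, tolerance = 1e-6)

  # square flow +0.5 L/s for 1 s then -0.5 L/s for 1 s: VT = 500 mL
  flow <- c(rep(0.5, fs), rep(-0.5, fs + 1))
  rec3 <- waveform_record(list(disp = seq(0, 1, length.out = 2 * fs + 1),
                               flow = flow), fs = fs)
  bt3 <- compute_breath_metrics(rec3, data.frame(onset = 1L, peak = fs + 1L,
                                                 end = 2L * fs + 1L))
  expect_equal(bt3$vt, 500)
  # metrics needing absent channels stay NA, others are computed
  expect_true(is.na(bt$vt) && is.na(bt$pdi_peak) && !is.na(bt$exdi))
})

test_that("scaling displacement scales exdi and pcvdi, boundaries fixed", {
  sim <- clean_train(mean_rr = 18, duration = 40, fs = 100, seed = 2)
  rec <- sim$record
  br <- detect_breaths(rec$channels$pdi, 100)
  bt1 <- compute_breath_metrics(rec, br)
  rec2 <- rec
  rec2$channels$disp <- 3.5 * rec$channels$disp
  br2 <- detect_breaths(rec2$channels$pdi, 100)
  expect_identical(br, br2)
  bt2 <- compute_breath_metrics(rec2, br2)
  expect_equal(bt2$exdi, 3.5 * bt1$exdi)
  expect_equal(bt2$pcvdi, 3.5 * bt1$pcvdi)
})

test_that("minute summaries follow the definitional arithmetic", {
  # 15 uniform breaths/min for 4 min: exdi 1 cm, vt 400 mL, ptpdi 10
  n <- 60
  bt <- data.frame(onset = 1L + (0:(n - 1)) * 200L, peak = 1L, end = 2L,
                   valid = TRUE, onset_s = (0:(n - 1)) * 4,
                   exdi = 1, pcvdi = 1.5, pdi_peak = 12, ptpdi = 10, vt = 400)
  sm <- minute_summary(bt, fs = 50, record_duration_s = 240, sbt_start = 0,
                       timepoints = 1:8)
  expect_equal(sm$minute, 1:4)          # truncated record: minutes 1-4 only
  expect_equal(sm$rr, rep(15, 4))
  expect_equal(sm$exdi_tm, rep(1, 4))
  expect_equal(sm$rsbi, rep(37.5, 4))          # 15 / 0.4 L
  expect_equal(sm$dia_rsbi, rep(1.5, 4))       # 15 / 10 mm
  expect_equal(sm$vt_over_exdi, rep(400, 4))
  expect_equal(sm$ptpdi_per_min, rep(150, 4))
  expect_equal(sm$n_rejected, rep(0, 4))
})

test_that("invalid breaths are excluded from summaries but counted", {
  bt <- data.frame(onset_s = seq(0, 56, 4), valid = rep(c(TRUE, FALSE), c(13, 2)),
                   exdi = c(rep(1, 13), 9, 9), pcvdi = 1, pdi_peak = 1,
                   ptpdi = 1, vt = 100)
  sm <- minute_summary(bt, fs = 50, record_duration_s = 60, sbt_start = 0,
                       timepoints = 1)
  expect_equal(sm$n_breaths_used, 13)
  expect_equal(sm$n_rejected, 2)
  expect_equal(sm$exdi_tm, 1)           # the flagged 9s never contribute
})

test_that("simulated minute means recover the phenotype excursion", {
  ph <- breath_phenotype(mean_exdi = 0.8, exdi_cv = 0, rr_cv = 0,
                         pdi_noise_sd = 0, artifact_rate = 0)
  sim <- simulate_breath_train(ph, 180, 100, seed = 6)
  br <- reject_artifacts(detect_breaths(sim$record$channels$pdi, 100),
                         sim$record$channels$pdi, 100)
  bt <- compute_breath_metrics(sim$record, br)
  sm <- minute_summary(bt, fs = 100, record_duration_s = 180, sbt_start = 0,
                       timepoints = 1:2)
  expect_true(all(abs(sm$exdi_tm - 0.8) / 0.8 < 0.01))
})

test_that("shifting a record in time changes boundaries, not metrics", {
  sim <- clean_train(mean_rr = 18, duration = 40, fs = 100, seed = 2)
  rec <- sim$record
  shift <- 250                          # 2.5 s of leading zeros
  rec2 <- waveform_record(lapply(rec$channels, function(v)
    c(numeric(shift), v[1:(length(v) - shift)])), fs = 100)
  br1 <- detect_breaths(rec$channels$pdi, 100)
  br2 <- detect_breaths(rec2$channels$pdi, 100)
  common <- seq_len(min(nrow(br1), nrow(br2)) - 1L)
  matched <- match(br1$onset[common] + shift, br2$onset)
  expect_true(all(!is.na(matched)))
  bt1 <- compute_breath_metrics(rec, br1)
  bt2 <- compute_breath_metrics(rec2, br2)
  expect_equal(bt2$exdi[matched], bt1$exdi[common], tolerance = 1e-10)
  expect_equal(bt2$ptpdi[matched], bt1$ptpdi[common], tolerance = 1e-10)
})
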