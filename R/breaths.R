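#' Detect breaths by zero crossings of a baseline-corrected signal
#'
#' Automatic breath segmentation in the style of post-processing pipelines
#' for transdiaphragmatic pressure: the signal is baseline-corrected by
#' subtracting a centered rolling median (window `baseline_window` seconds,
#' much longer than a breath, much shorter than a session phase), breath
#' onsets are the positive-going zero crossings of the corrected signal,
#' each breath spans one onset to the next, and the peak is the argmax of
#' the corrected signal within the breath. Candidate breaths shorter than
#' `min_duration` or smaller than the amplitude threshold are merged into
#' their neighbors. The detector works on either the Pdi channel (its
#' expiratory baseline is zero, so crossings fall at the true onsets) or,
#' for sessions without pressure channels, on the displacement channel
#' (crossings then fall mid-inspiration, which shifts onsets but preserves
#' breath counting).
#'
#' @param x numeric signal.
#' @param fs sampling frequency (Hz).
#' @param min_duration minimum breath duration (s).
#' @param min_amplitude amplitude threshold; default is 10% of the record's
#'   median breath amplitude with floor `amplitude_floor`.
#' @param amplitude_floor floor for the default threshold: 0.5 cmH2O suits
#'   Pdi, 0.05 cm suits displacement.
#' @param baseline_window rolling-median window (s).
#' @return data.frame with integer columns `onset`, `peak`, `end` (sample
#'   indices, `onset <= peak < end`), zero rows when the signal is too
#'   short, flat, or crossing-free.
#' @export
detect_breaths <- function(x, fs, min_duration = 0.5, min_amplitude = NULL,
                           amplitude_floor = 0.5, baseline_window = 10) {
  empty <- data.frame(onset = integer(0), peak = integer(0), end = integer(0))
  n <- length(x)
  if (n < 2 * fs) return(empty)
  k <- as.integer(baseline_window * fs)
  if (k %% 2L == 0L) k <- k + 1L
  if (k > n) k <- if (n %% 2L == 1L) n else n - 1L
  # endrule "constant" extends the first/last full-window median outward:
  # shrinking end windows would bend the baseline toward the signal itself
  corrected <- x - runmed(x, k, endrule = "constant")
  if (all(abs(corrected) < .Machine$double.eps * 100)) return(empty)
  up <- which(corrected[-n] <= 0 & corrected[-1L] > 0)
  if (length(up) < 1L) return(empty)
  onsets <- up
  ends <- c(onsets[-1L], n)
  # drop a trailing partial breath that is shorter than min_duration
  keep <- (ends - onsets) >= 1L
  keep[length(keep)] <- (n - onsets[length(onsets)]) >= min_duration * fs
  onsets <- onsets[keep]; ends <- ends[keep]
  if (!length(onsets)) return(empty)

  seg_peak <- function(o, e)
    o + which.max(corrected[o:e]) - 1L
  peaks <- mapply(seg_peak, onsets, ends)
  amp <- corrected[peaks] - corrected[onsets]

  thr <- if (is.null(min_amplitude))
    max(0.1 * median(amp), amplitude_floor) else min_amplitude

  # merge undersized candidates into neighbors, re-checking until stable
  repeat {
    if (length(onsets) <= 1L) break
    dur <- (ends - onsets) / fs
    bad <- which(dur < min_duration | amp < thr)
    if (!length(bad)) break
    i <- bad[1L]
    if (i == 1L) {                       # absorb into the following breath
      onsets[2L] <- onsets[1L]
      onsets <- onsets[-1L]
      ends <- ends[-1L]
    } else {                             # absorb into the previous breath
      ends[i - 1L] <- ends[i]
      onsets <- onsets[-i]; ends <- ends[-i]
    }
    peaks <- mapply(seg_peak, onsets, ends)
    amp <- corrected[peaks] - corrected[onsets]
  }
  dur <- (ends - onsets) / fs
  ok <- dur >= min_duration & amp >= thr
  onsets <- onsets[ok]; ends <- ends[ok]; peaks <- peaks[ok]
  data.frame(onset = as.integer(onsets), peak = as.integer(peaks),
             end = as.integer(ends))
}

#' Flag artifact-contaminated breaths
#'
#' Automated stand-in for the visual artifact screening applied to Pdi
#' tracings (coughs, swallows, movements): a breath is flagged invalid when
#' its amplitude exceeds `k_mad` median absolute deviations above the median
#' amplitude of its 3-minute neighborhood, or when it is shorter than
#' `min_duration`. Flags only — no breath is deleted.
#'
#' @param breaths data.frame from [detect_breaths()].
#' @param x the signal the breaths were detected on.
#' @param fs sampling frequency (Hz).
#' @param k_mad MAD multiplier; `Inf` disables amplitude flagging.
#' @param min_duration minimum valid breath duration (s).
#' @param window_min neighborhood half-width is `window_min / 2` minutes
#'   each side.
#' @return `breaths` with a logical `valid` column added.
#' @export
reject_artifacts <- function(breaths, x, fs, k_mad = 5, min_duration = 0.5,
                             window_min = 3) {
  if (!nrow(breaths)) {
    breaths$valid <- logical(0)
    return(breaths)
  }
  amp <- vapply(seq_len(nrow(breaths)), function(i)
    max(x[breaths$onset[i]:breaths$end[i]]) - x[breaths$onset[i]],
    numeric(1))
  dur <- (breaths$end - breaths$onset) / fs
  valid <- dur >= min_duration
  if (is.finite(k_mad)) {
    tmid <- breaths$onset / fs
    half <- window_min * 60 / 2
    for (i in seq_along(amp)) {
      nb <- abs(tmid - tmid[i]) <= half
      med <- median(amp[nb])
      madv <- mad(amp[nb])
      tol <- 1e-6 * max(1, med)          # numerical guard for uniform trains
      if (amp[i] > med + k_mad * madv + tol) valid[i] <- FALSE
    }
  }
  breaths$valid <- valid
  breaths
}

#' Per-breath metrics from a multichannel record
#'
#' Computes, for each detected breath, the physiological indices of
#' diaphragm motion and effort:
#'
#' * `exdi` (cm): maximal excursion, `max(disp)` within the breath minus
#'   the onset displacement;
#' * `pcvdi` (cm/s): peak contraction velocity, the maximum central-
#'   difference derivative of the 50 ms moving-average-smoothed displacement
#'   over the inspiratory interval (onset to displacement peak);
#' * `pdi_peak` (cmH2O): rise of Pdi from the onset value to its breath
#'   maximum;
#' * `ptpdi` (cmH2O.s): pressure-time product — trapezoidal integral of
#'   `pdi - pdi(onset)` over the breath with negative parts clipped to zero,
#'   which on a half-sine of amplitude `A` and inspiratory time `T` equals
#'   `2 A T / pi`;
#' * `vt` (mL): tidal volume — half the trapezoidal integral of `|flow|`
#'   over the breath (inspired plus expired volume, halved), or the
#'   inspiratory-only positive-flow integral when `vt_mode = "inspiration"`.
#'
#' Metrics whose channels are absent are returned as `NA`, the rest are
#' computed.
#'
#' @param record a [waveform_record()] with at least a `disp` channel.
#' @param breaths data.frame from [detect_breaths()] (and optionally
#'   [reject_artifacts()]).
#' @param smooth_ms moving-average width for the velocity derivative (ms).
#' @param vt_mode `"half_cycle"` (default) or `"inspiration"`.
#' @return A breath table: `breaths` plus columns `onset_s`, `duration_s`,
#'   `exdi`, `pcvdi`, `pdi_peak`, `ptpdi`, `vt` (and `valid = TRUE` if no
#'   validity flags were supplied).
#' @export
compute_breath_metrics <- function(record, breaths, smooth_ms = 50,
                                   vt_mode = c("half_cycle", "inspiration")) {
  stopifnot(inherits(record, "waveform_record"))
  vt_mode <- match.arg(vt_mode)
  fs <- record$fs
  disp <- record$channels$disp
  if (is.null(disp)) stopf("record has no displacement channel")
  pdi <- record$channels$pdi
  flow <- record$channels$flow
  nb <- nrow(breaths)
  if (is.null(breaths$valid)) breaths$valid <- rep(TRUE, nb)

  w <- max(1L, as.integer(round(fs * smooth_ms / 1000)))
  sm <- moving_average(disp, w)
  n <- length(disp)
  vel <- numeric(n)
  if (n >= 3L)
    vel[2:(n - 1L)] <- (sm[3:n] - sm[1:(n - 2L)]) * fs / 2

  out <- breaths
  out$onset_s <- record$t0 + (breaths$onset - 1L) / fs
  out$duration_s <- (breaths$end - breaths$onset) / fs
  out$exdi <- out$pcvdi <- out$pdi_peak <- out$ptpdi <- out$vt <- NA_real_
  for (i in seq_len(nb)) {
    o <- breaths$onset[i]; e <- breaths$end[i]
    seg <- o:e
    dpk <- o + which.max(disp[seg]) - 1L
    out$exdi[i] <- disp[dpk] - disp[o]
    out$pcvdi[i] <- if (dpk > o) max(vel[o:dpk]) else 0
    tt <- (seg - 1L) / fs
    if (!is.null(pdi)) {
      out$pdi_peak[i] <- max(pdi[seg]) - pdi[o]
      out$ptpdi[i] <- trapz(tt, pmax(pdi[seg] - pdi[o], 0))
    }
    if (!is.null(flow)) {
      out$vt[i] <- if (vt_mode == "half_cycle")
        0.5 * trapz(tt, abs(flow[seg])) * 1000
      else trapz(tt, pmax(flow[seg], 0)) * 1000
    }
  }
  out
}

#' Trimmed mean with floor-rule tail counts
#'
#' Drops `k = floor(fraction * n)` values from each tail of the sorted
#' sequence and averages the rest — the convention used for per-minute
#' breath summaries ("excluding the 5% largest and 5% smallest values").
#' Note the floor rule: for `n = 10` and `fraction = 0.05`, `k = 0` and the
#' plain mean is returned.
#'
#' @param values numeric vector.
#' @param fraction trim fraction per tail, in `[0, 0.5)`.
#' @return The trimmed mean, or `NA_real_` for empty input.
#' @export
trimmed_mean <- function(values, fraction = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (!n) return(NA_real_)
  if (fraction < 0 || fraction >= 0.5) stopf("fraction must lie in [0, 0.5)")
  k <- floor(fraction * n)
  if (2L * k >= n) return(median(values))
  s <- sort(values)
  mean(s[(k + 1L):(n - k)])
}

#' Per-minute summaries of breath metrics at protocol timepoints
#'
#' Summarizes a breath table over 1-minute leading-edge windows after SBT
#' onset: minute `m` covers `[sbt_start + (m-1)*60, sbt_start + m*60)`.
#' Only valid breaths whose onset falls in the window contribute. Metric
#' means are 5%/5% trimmed ([trimmed_mean()]); the pressure-time product is
#' the per-minute sum. Derived indices: `rsbi = rr / VT[L]` (breaths/min/L),
#' `dia_rsbi = rr / EXdi[mm]` (breaths/min/mm; the excursion is carried in
#' cm elsewhere and converted here), `vt_over_exdi` (mL/cm). Windows that
#' extend past the end of the record (a truncated SBT) yield no row.
#'
#' @param breath_table from [compute_breath_metrics()].
#' @param fs sampling frequency (Hz).
#' @param record_duration_s total record length (s).
#' @param sbt_start SBT onset time (s).
#' @param timepoints minutes after SBT onset to summarize.
#' @param trim trim fraction per tail.
#' @return data.frame with one row per available timepoint: `minute`, `rr`,
#'   `exdi_tm`, `pcvdi_tm`, `pdi_peak_tm`, `ptpdi_per_min`, `vt_tm`,
#'   `rsbi`, `dia_rsbi`, `vt_over_exdi`, `n_breaths_used`, `n_rejected`.
#' @export
minute_summary <- function(breath_table, fs, record_duration_s, sbt_start = 0,
                           timepoints = c(1, 2, 3, 4, 5, 10, 20, 30),
                           trim = 0.05) {
  if (any(timepoints <= 0)) stopf("timepoints must be positive minutes")
  onset_s <- breath_table$onset_s %||% ((breath_table$onset - 1L) / fs)
  valid <- breath_table$valid %||% rep(TRUE, nrow(breath_table))
  rows <- lapply(sort(timepoints), function(m) {
    w0 <- sbt_start + (m - 1) * 60
    w1 <- sbt_start + m * 60
    if (w1 > record_duration_s + 1e-9) return(NULL)
    inw <- onset_s >= w0 & onset_s < w1
    use <- inw & valid
    tm <- function(v) trimmed_mean(v[use], trim)
    rr <- sum(use)
    exdi_tm <- tm(breath_table$exdi)
    vt_tm <- tm(breath_table$vt)
    data.frame(minute = m, rr = rr, exdi_tm = exdi_tm,
               pcvdi_tm = tm(breath_table$pcvdi),
               pdi_peak_tm = tm(breath_table$pdi_peak),
               ptpdi_per_min = if (rr) sum(breath_table$ptpdi[use]) else NA_real_,
               vt_tm = vt_tm,
               rsbi = if (!is.na(vt_tm) && vt_tm > 0) rr / (vt_tm / 1000) else NA_real_,
               dia_rsbi = if (!is.na(exdi_tm) && exdi_tm > 0) rr / (exdi_tm * 10) else NA_real_,
               vt_over_exdi = if (!is.na(exdi_tm) && exdi_tm > 0 && !is.na(vt_tm))
                 vt_tm / exdi_tm else NA_real_,
               n_breaths_used = rr, n_rejected = sum(inw & !valid))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(minute = numeric(0), rr = numeric(0),
                      exdi_tm = numeric(0), pcvdi_tm = numeric(0),
                      pdi_peak_tm = numeric(0), ptpdi_per_min = numeric(0),
                      vt_tm = numeric(0), rsbi = numeric(0),
                      dia_rsbi = numeric(0), vt_over_exdi = numeric(0),
                      n_breaths_used = numeric(0), n_rejected = numeric(0))
  out
}
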