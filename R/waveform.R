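#' Multichannel respiratory waveform record
#'
#' Container for synchronized, uniformly sampled respiratory signals of one
#' patient session: diaphragm displacement (cm), esophageal and gastric
#' pressure (cmH2O), the derived transdiaphragmatic pressure
#' `pdi = pga - pes`, airflow (L/s) and an analog synchronization channel.
#' The time base is uniform: sample `i` is at `t0 + (i - 1) / fs` seconds.
#'
#' @param channels named list of equal-length numeric vectors; recognised
#'   names are `disp`, `pes`, `pga`, `pdi`, `flow`, `sync`.
#' @param fs sampling frequency (Hz), > 0.
#' @param t0 time of the first sample (s).
#' @param patient_id optional patient identifier.
#' @param phases optional data.frame with columns `phase`, `start_s`,
#'   `end_s`; intervals must be non-overlapping and within the record span.
#'
#' @return An object of class `waveform_record`.
#' @export
waveform_record <- function(channels, fs, t0 = 0, patient_id = NA_character_,
                            phases = NULL) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(names(channels) == ""))
    stopf("channels must be a named list")
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    stopf("all channels must have equal length")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stopf("fs must be a positive scalar")
  n <- lens[[1L]]
  span_end <- t0 + n / fs
  if (!is.null(phases)) {
    stopifnot(all(c("phase", "start_s", "end_s") %in% names(phases)))
    ph <- phases[order(phases$start_s), , drop = FALSE]
    if (any(ph$end_s < ph$start_s))
      stopf("phase intervals must have end >= start")
    if (nrow(ph) > 1L && any(ph$start_s[-1L] < ph$end_s[-nrow(ph)] - 1e-9))
      stopf("phase intervals must be non-overlapping")
    if (any(ph$start_s < t0 - 1e-9) || any(ph$end_s > span_end + 1e-9))
      stopf("phase intervals must lie within the record span")
    phases <- ph
  }
  structure(list(channels = lapply(channels, as.numeric), fs = fs, t0 = t0,
                 patient_id = patient_id, phases = phases, n = as.integer(n)),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> %d samples @ %g Hz (%.1f s), channels: %s\n",
              x$n, x$fs, x$n / x$fs, paste(names(x$channels), collapse = ", ")))
  if (!is.na(x$patient_id)) cat("  patient:", x$patient_id, "\n")
  if (!is.null(x$phases))
    cat("  phases:", paste(sprintf("%s[%g,%g]", x$phases$phase,
                                   x$phases$start_s, x$phases$end_s),
                           collapse = " "), "\n")
  invisible(x)
}

#' Sample times of a waveform record
#' @param record a [waveform_record()].
#' @return numeric vector of sample times (s).
#' @export
record_times <- function(record) {
  record$t0 + (seq_len(record$n) - 1L) / record$fs
}

# column-name mapping between file header and channel names
.wf_cols <- c(disp = "disp_cm", pes = "pes_cmh2o", pga = "pga_cmh2o",
              pdi = "pdi_cmh2o", flow = "flow_lps", sync = "sync")
.wf_units <- c(disp = "cm", pes = "cmH2O", pga = "cmH2O", pdi = "cmH2O",
               flow = "L/s", sync = "au")

#' Write a waveform record to a delimited text file
#'
#' UTF-8 comma-delimited format with `#` comment header lines carrying
#' `fs_hz`, `t0_s`, `patient_id`, one `phase:<name>=<start_s>,<end_s>` line
#' per session phase and one `units:<column>=<unit>` line per channel,
#' followed by a `time_s,...` header row and one row per sample. Sample
#' values are written with 6 significant digits; the time column with 0.1 ms
#' resolution (it is redundant — the declared `fs_hz` defines the time base —
#' and is validated, not trusted, on read).
#'
#' @param record a [waveform_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_waveforms()]
#' @export
write_waveforms <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  hdr <- c(sprintf("# fs_hz=%.10g", record$fs),
           sprintf("# t0_s=%.10g", record$t0))
  if (!is.na(record$patient_id))
    hdr <- c(hdr, sprintf("# patient_id=%s", record$patient_id))
  if (!is.null(record$phases))
    hdr <- c(hdr, sprintf("# phase:%s=%.10g,%.10g", record$phases$phase,
                          record$phases$start_s, record$phases$end_s))
  chn <- names(record$channels)
  unknown <- setdiff(chn, names(.wf_cols))
  if (length(unknown)) stopf("unknown channel '%s'", unknown[1L])
  hdr <- c(hdr, sprintf("# units:%s=%s", .wf_cols[chn], .wf_units[chn]))
  dt <- data.table::as.data.table(
    c(list(time_s = sprintf("%.4f", record_times(record))),
      lapply(record$channels, function(v) sprintf("%.6g", v))))
  data.table::setnames(dt, c("time_s", unname(.wf_cols[chn])))
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(hdr, con)
  close(con)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a waveform record from a delimited text file
#'
#' Parses the format written by [write_waveforms()]. The time column is
#' validated against the declared sampling rate: it must be strictly
#' increasing and uniform to within 1% jitter. When no `fs_hz` header is
#' present, `fs` is inferred from the median time step. Missing optional
#' channels are simply absent from the returned record (never fabricated).
#'
#' @param path input file path.
#' @return A [waveform_record()].
#' @export
read_waveforms <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, n = 200L, encoding = "UTF-8")
  n_comment <- match(FALSE, startsWith(lines, "#"), nomatch = length(lines) + 1L) - 1L
  hdr <- lines[seq_len(n_comment)]
  meta <- list(fs = NA_real_, t0 = 0, patient_id = NA_character_)
  phases <- list()
  for (h in sub("^#\\s*", "", hdr)) {
    kv <- strsplit(h, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) next
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (key == "fs_hz") meta$fs <- as.numeric(val)
    else if (key == "t0_s") meta$t0 <- as.numeric(val)
    else if (key == "patient_id") meta$patient_id <- val
    else if (startsWith(key, "phase:")) {
      se <- as.numeric(strsplit(val, ",", fixed = TRUE)[[1L]])
      if (length(se) != 2L || anyNA(se))
        stopf("malformed phase header line: '# %s'", h)
      phases[[length(phases) + 1L]] <-
        data.frame(phase = sub("^phase:", "", key),
                   start_s = se[1L], end_s = se[2L])
    }
  }
  dt <- tryCatch(
    data.table::fread(path, sep = ",", header = TRUE, fill = FALSE,
                      skip = n_comment, data.table = TRUE),
    error = function(e) stopf("malformed waveform file %s: %s", path,
                              conditionMessage(e)))
  if (!"time_s" %in% names(dt))
    stopf("malformed header: first column must be 'time_s'")
  tm <- dt$time_s
  if (!is.numeric(tm)) stopf("non-numeric time column")
  if (length(tm) < 2L) stopf("waveform file has fewer than 2 samples")
  dts <- diff(tm)
  bad <- which(dts <= 0)
  if (length(bad))
    stopf("non-monotone time at data row %d", bad[1L] + 1L)
  dt_med <- median(dts)
  jitter <- max(abs(dts - dt_med)) / dt_med
  if (jitter > 0.01)
    stopf("non-uniform sampling: time-step jitter %.1f%% at data row %d (> 1%%)",
          100 * jitter, which.max(abs(dts - dt_med)) + 1L)
  fs <- if (is.na(meta$fs)) 1 / dt_med else meta$fs
  if (!is.na(meta$fs) && abs(dt_med - 1 / meta$fs) / (1 / meta$fs) > 0.01)
    stopf("time column disagrees with declared fs_hz=%g", meta$fs)
  inv <- setNames(names(.wf_cols), .wf_cols)
  present <- intersect(names(dt), names(inv))
  if (!length(present)) stopf("no recognised signal columns in %s", path)
  channels <- lapply(present, function(cn) as.numeric(dt[[cn]]))
  names(channels) <- inv[present]
  waveform_record(channels, fs = fs, t0 = if (is.na(meta$fs)) tm[1L] else meta$t0,
                  patient_id = meta$patient_id,
                  phases = if (length(phases)) do.call(rbind, phases) else NULL)
}

#' Derive the transdiaphragmatic pressure channel
#'
#' Adds (or recomputes) `pdi` as the samplewise difference of gastric and
#' esophageal pressure, `pdi = pga - pes`. All other channels are untouched;
#' the operation is idempotent.
#'
#' @param record a [waveform_record()] with `pes` and `pga` channels.
#' @return The record with a `pdi` channel.
#' @export
derive_pdi <- function(record) {
  stopifnot(inherits(record, "waveform_record"))
  for (ch in c("pes", "pga"))
    if (is.null(record$channels[[ch]]))
      stopf("missing channel '%s'; cannot derive pdi", ch)
  record$channels$pdi <- record$channels$pga - record$channels$pes
  record
}

#' Align one record to another using the synchronization channel
#'
#' Estimates the lag between the two records' analog timing (sync) channels
#' by maximizing their cross-covariance over a bounded window, then shifts
#' `other`'s time origin so that its sync pulse train aligns with the
#' reference's. Lags are searched on the sample grid, so the residual lag
#' after alignment is below one sample.
#'
#' @param reference,other [waveform_record()]s containing `sync` channels
#'   sampled at the same rate.
#' @param max_lag_s half-width of the lag search window (s). Bounded because
#'   acquisition is near-simultaneous; an unbounded search over periodic
#'   pulse trains invites false maxima.
#' @return `other`, with `t0` shifted by the estimated lag and the estimate
#'   attached as attribute `lag_s`.
#' @export
synchronize <- function(reference, other, max_lag_s = 10) {
  stopifnot(inherits(reference, "waveform_record"),
            inherits(other, "waveform_record"))
  if (abs(reference$fs - other$fs) > 1e-9)
    stopf("records must share a sampling rate")
  a <- reference$channels$sync
  b <- other$channels$sync
  if (is.null(a) || is.null(b))
    stopf("synchronization error: both records need a 'sync' channel")
  if (sd(a) == 0 || sd(b) == 0)
    stopf("synchronization error: flat sync channel")
  fs <- reference$fs
  a <- a - mean(a)
  b <- b - mean(b)
  max_lag <- as.integer(round(max_lag_s * fs))
  # full linear cross-correlation via FFT; lag = (time of a) - (time of b)
  cc <- stats::convolve(a, b, conj = TRUE, type = "open")
  # cc index k pairs a[i] with b[i + (k - length(b))]; the delay of `other`
  # relative to the reference is the negated argmax (positive = trails)
  lags <- seq_along(cc) - length(b)
  keep <- abs(lags) <= max_lag
  if (!any(keep)) stopf("synchronization error: no overlap within window")
  cc <- cc[keep]; lags <- lags[keep]
  lag_s <- -lags[which.max(cc)] / fs
  # relabel other's samples onto the reference clock
  other$t0 <- other$t0 - lag_s
  if (!is.null(other$phases)) {
    other$phases$start_s <- other$phases$start_s - lag_s
    other$phases$end_s <- other$phases$end_s - lag_s
  }
  attr(other, "lag_s") <- lag_s
  other
}
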