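# From continuous EEG to per-condition, per-block MMN measurements:
# ocular correction -> epoch segmentation -> artifact rejection ->
# baseline correction -> condition x block averaging -> difference wave ->
# peak measurement at Fz.

#' Regression-based ocular correction
#'
#' Removes blink/eye-movement contamination by subtracting `b * EOG` from
#' each EEG channel, where `b` is the least-squares regression coefficient of
#' the channel on the EOG channel over the whole recording.
#'
#' @param recording A `continuous_recording` containing `eog_channel`.
#' @param eog_channel Name of the EOG channel (default `"VEOG"`).
#' @return The corrected recording, with the per-channel coefficients in
#'   attribute-free field `propagation` (named numeric).
#' @export
ocular_correct <- function(recording, eog_channel = "VEOG") {
  stopifnot(inherits(recording, "continuous_recording"))
  if (!eog_channel %in% recording$channel_labels) {
    stop("EOG channel '", eog_channel, "' not present")
  }
  eog <- recording$data[eog_channel, ]
  eog_c <- eog - mean(eog)
  ss <- sum(eog_c^2)
  if (!is.finite(ss) || ss == 0) {
    stop("EOG channel has zero variance; ocular correction unusable")
  }
  eeg_ch <- setdiff(recording$channel_labels, eog_channel)
  # sum(eog_c) == 0, so centering the channel is unnecessary
  b <- vapply(eeg_ch, function(ch) {
    sum(recording$data[ch, ] * eog_c) / ss
  }, numeric(1))
  for (ch in eeg_ch) {
    recording$data[ch, ] <- recording$data[ch, ] - b[ch] * eog
  }
  recording$propagation <- b
  recording
}

#' Segment a recording into fixed-length epochs
#'
#' One epoch per event, spanning `total_ms` beginning `pre_ms` before
#' stimulus onset. At 250 Hz the 50 ms pre-stimulus span is 12.5 samples;
#' the pre-stimulus sample count is floored (12 samples, 48 ms) so stimulus
#' onset falls on an exact sample, and the epoch is `floor(total_ms * fs)`
#' = 125 samples. Events too close to a recording edge for a full epoch are
#' dropped with a warning. Only EEG (non-EOG) channels are segmented.
#'
#' @param recording A `continuous_recording` (normally ocular-corrected).
#' @param events Event data.frame (`sample`, `code`, `block`); defaults to
#'   the recording's own event list.
#' @param pre_ms Pre-stimulus span in ms (default 50).
#' @param total_ms Total epoch length in ms (default 500).
#' @param eog_channel Channel excluded from segmentation.
#' @return An `epoch_set`: `epochs` (trials x channels x samples array),
#'   `condition_labels`, `block_labels`, `kept_flags`, `pre_samples`,
#'   `sampling_rate`.
#' @export
segment_epochs <- function(recording, events = recording$events, pre_ms = 50,
                           total_ms = 500, eog_channel = "VEOG") {
  stopifnot(inherits(recording, "continuous_recording"))
  fs <- recording$sampling_rate
  pre_samples <- floor(pre_ms * fs / 1000)
  total_samples <- floor(total_ms * fs / 1000)
  n <- ncol(recording$data)
  starts <- events$sample - pre_samples
  ok <- starts >= 1L & starts + total_samples - 1L <= n
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to the recording edge; dropped")
  }
  events <- events[ok, , drop = FALSE]
  starts <- starts[ok]
  eeg_ch <- setdiff(recording$channel_labels, eog_channel)
  nt <- length(starts)
  epochs <- array(NA_real_, dim = c(nt, length(eeg_ch), total_samples),
                  dimnames = list(NULL, eeg_ch, NULL))
  idx <- outer(starts, seq_len(total_samples) - 1L, "+")
  for (ch in seq_along(eeg_ch)) {
    epochs[, ch, ] <- recording$data[eeg_ch[ch], ][idx]
  }
  structure(list(epochs = epochs,
                 condition_labels = events$code,
                 block_labels = events$block,
                 kept_flags = rep(TRUE, nt),
                 pre_samples = pre_samples,
                 sampling_rate = fs), class = "epoch_set")
}

#' Reject epochs exceeding an absolute voltage threshold
#'
#' A trial is rejected iff any sample on any EEG channel exceeds the
#' threshold in absolute value (strictly greater). Applied after ocular
#' correction; the EOG channel is not part of the epoch set and so is never
#' consulted.
#'
#' @param epochs An `epoch_set`.
#' @param threshold_uv Rejection threshold in microvolts (default 100).
#' @return The epoch set with updated `kept_flags` and a `rejection_counts`
#'   table of kept trials per condition x block.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  bad <- rowSums(abs(epochs$epochs) > threshold_uv, dims = 1) > 0
  epochs$kept_flags <- epochs$kept_flags & !bad
  epochs$rejection_counts <- table(
    condition = epochs$condition_labels[epochs$kept_flags],
    block = epochs$block_labels[epochs$kept_flags])
  epochs
}

#' Baseline-correct epochs on the pre-stimulus window
#'
#' Subtracts, per trial and channel, the mean of the pre-stimulus samples;
#' afterwards every baseline-window mean is exactly zero. Idempotent.
#'
#' @param epochs An `epoch_set` with `pre_samples >= 1`.
#' @return The corrected epoch set.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$pre_samples < 1) stop("no pre-stimulus samples to baseline on")
  base <- rowMeans(epochs$epochs[, , seq_len(epochs$pre_samples),
                                 drop = FALSE], dims = 2)
  epochs$epochs <- epochs$epochs - as.vector(base) # recycles over samples
  epochs
}

#' Average kept epochs per condition and block
#'
#' @param epochs An `epoch_set` with `kept_flags` computed.
#' @param min_deviants Sufficiency threshold for deviant averages
#'   (default 30).
#' @return A list of `erp_average` objects, one per condition x block, named
#'   `"standard.1"`, `"deviant.1"`, ... Each holds `waveform` (channels x
#'   samples), `n_trials`, `condition`, `block`, `pre_samples`,
#'   `sampling_rate`, and for deviants a logical `sufficient`
#'   (`n_trials >= min_deviants`).
#' @export
average_condition_blocks <- function(epochs, min_deviants = 30) {
  stopifnot(inherits(epochs, "epoch_set"))
  conds <- c("standard", "deviant")
  blocks <- sort(unique(epochs$block_labels))
  out <- list()
  for (cn in conds) {
    for (b in blocks) {
      sel <- epochs$kept_flags & epochs$condition_labels == cn &
        epochs$block_labels == b
      if (!any(sel)) {
        stop("no kept epochs for ", cn, " in block ", b)
      }
      wf <- colMeans(epochs$epochs[sel, , , drop = FALSE], dims = 1)
      out[[paste(cn, b, sep = ".")]] <- structure(list(
        waveform = wf, n_trials = sum(sel), condition = cn, block = b,
        pre_samples = epochs$pre_samples,
        sampling_rate = epochs$sampling_rate,
        sufficient = if (cn == "deviant") sum(sel) >= min_deviants else NA),
        class = "erp_average")
    }
  }
  out
}

#' Deviant-minus-standard difference wave
#'
#' Point-by-point subtraction of the standard average from the deviant
#' average of the same block.
#'
#' @param deviant_avg,standard_avg `erp_average` objects of equal shape and
#'   block.
#' @return An `mmn_wave`: `waveform` (channels x samples), `block`,
#'   `n_deviants`, `n_standards`, `pre_samples`, `sampling_rate`,
#'   `sufficient`.
#' @export
compute_mmn <- function(deviant_avg, standard_avg) {
  stopifnot(inherits(deviant_avg, "erp_average"),
            inherits(standard_avg, "erp_average"))
  if (!identical(dim(deviant_avg$waveform), dim(standard_avg$waveform))) {
    stop("deviant and standard averages have different shapes")
  }
  if (!identical(deviant_avg$block, standard_avg$block)) {
    stop("deviant and standard averages come from different blocks")
  }
  structure(list(
    waveform = deviant_avg$waveform - standard_avg$waveform,
    block = deviant_avg$block,
    n_deviants = deviant_avg$n_trials,
    n_standards = standard_avg$n_trials,
    pre_samples = deviant_avg$pre_samples,
    sampling_rate = deviant_avg$sampling_rate,
    sufficient = isTRUE(deviant_avg$sufficient)), class = "mmn_wave")
}

#' Measure MMN peak amplitude and latency
#'
#' Amplitude is the minimum voltage of the difference wave at the measurement
#' channel within the search window (peak negative voltage relative to the
#' pre-stimulus baseline); latency is the time from stimulus onset to that
#' minimum, on the 4 ms sample grid. Ties are broken by the earliest sample.
#' A windowed minimum that is positive is reported as-is with
#' `quality = "positive"` rather than clamped.
#'
#' @param mmn An `mmn_wave` (or `erp_average`-like object with a waveform).
#' @param window_ms Search window in ms post-stimulus (default c(80, 220)).
#' @param channel Measurement channel (default `"Fz"`, the site of maximal
#'   amplitude).
#' @return A one-row data.frame: `block`, `amplitude_uv`, `latency_ms`,
#'   `n_deviants`, `sufficient`, `quality`.
#' @export
measure_mmn <- function(mmn, window_ms = c(80, 220), channel = "Fz") {
  stopifnot(inherits(mmn, "mmn_wave"))
  fs <- mmn$sampling_rate
  dt <- 1000 / fs
  onset_idx <- mmn$pre_samples + 1L
  k <- seq_len(ncol(mmn$waveform))
  t_post <- (k - onset_idx) * dt
  win <- which(t_post >= window_ms[1] & t_post <= window_ms[2])
  if (length(win) == 0) stop("search window outside the epoch span")
  w <- mmn$waveform[channel, win]
  j <- which.min(w) # first index on ties
  data.frame(block = mmn$block,
             amplitude_uv = w[j],
             latency_ms = t_post[win[j]],
             n_deviants = mmn$n_deviants,
             sufficient = mmn$sufficient,
             quality = if (w[j] > 0) "positive" else "ok",
             stringsAsFactors = FALSE)
}

#' Run the full MMN pipeline on one recording
#'
#' Ocular correction, segmentation, artifact rejection, baseline correction,
#' condition x block averaging, difference waves, and Fz peak measurement.
#'
#' @param recording A `continuous_recording`.
#' @param threshold_uv Artifact rejection threshold (uV).
#' @param window_ms MMN search window (ms post-stimulus).
#' @param pre_ms,total_ms Epoch geometry (ms).
#' @param eog_channel EOG channel name.
#' @param min_deviants Deviant-average sufficiency threshold.
#' @param ocular Apply regression ocular correction (default TRUE; disable
#'   for recordings constructed without an informative EOG channel).
#' @return A data.frame with one row per block: `block`, `amplitude_uv`,
#'   `latency_ms`, `n_deviants`, `sufficient`, `quality`.
#' @export
measure_recording <- function(recording, threshold_uv = 100,
                              window_ms = c(80, 220), pre_ms = 50,
                              total_ms = 500, eog_channel = "VEOG",
                              min_deviants = 30, ocular = TRUE) {
  corrected <- if (ocular) ocular_correct(recording, eog_channel) else
    recording
  ep <- segment_epochs(corrected, pre_ms = pre_ms, total_ms = total_ms,
                       eog_channel = eog_channel)
  ep <- reject_artifacts(ep, threshold_uv)
  ep <- baseline_correct(ep)
  avgs <- average_condition_blocks(ep, min_deviants = min_deviants)
  blocks <- sort(unique(ep$block_labels))
  out <- lapply(blocks, function(b) {
    diffw <- compute_mmn(avgs[[paste0("deviant.", b)]],
                         avgs[[paste0("standard.", b)]])
    measure_mmn(diffw, window_ms = window_ms)
  })
  do.call(rbind, out)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", dim(x$epochs)[1], " trials x ", dim(x$epochs)[2],
      " channels x ", dim(x$epochs)[3], " samples (",
      sum(x$kept_flags), " kept)\n", sep = "")
  invisible(x)
}

#' @export
print.erp_average <- function(x, ...) {
  cat("<erp_average> ", x$condition, " block ", x$block, ", n = ",
      x$n_trials, "\n", sep = "")
  invisible(x)
}
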