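# Readers and writers for the package's on-disk formats: BIDS-style events
# TSV, press-log TSV, EEG as CSV matrix + JSON sidecar, and tidy results
# tables. All writers round-trip losslessly through their readers (full
# double precision in the text representation).

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a session schedule as a BIDS-style events TSV
#'
#' Digits and tones are merged and sorted by onset. Columns: `onset` (s),
#' `duration` (s), `trial_type` (`digit`, `standard`, `deviant`), `value`
#' (digit or frequency label), `target` (0/1, digits only), `block` (1-3),
#' and `sample` (0-based index at `fs`, recorded explicitly to avoid
#' off-by-one ambiguity).
#'
#' @param schedule A `session_schedule`.
#' @param path Output path.
#' @param fs Sampling rate used for the `sample` column (default 250).
#' @export
write_events_tsv <- function(schedule, path, fs = 250) {
  dg <- schedule$digit_stream
  tn <- schedule$tone_stream
  ev <- rbind(
    data.frame(onset = dg$onsets / 1000, duration = dg$duration_ms / 1000,
               trial_type = "digit", value = as.character(dg$digits),
               target = as.integer(dg$target_flags), block = dg$block_index,
               stringsAsFactors = FALSE),
    data.frame(onset = tn$onsets / 1000, duration = tn$duration_ms / 1000,
               trial_type = as.character(tn$category),
               value = tn$frequency_label,
               target = 0L, block = tn$block_index, stringsAsFactors = FALSE))
  ev <- ev[order(ev$onset), ]
  ev$sample <- as.integer(round(ev$onset * fs))
  write_tsv(format_numeric(ev), path)
}

#' Read a session schedule from an events TSV
#'
#' Inverse of [write_events_tsv()]: reconstructs the `digit_stream` and
#' `tone_stream` (onsets in ms) and returns a `session_schedule`.
#'
#' @param path Path to the events TSV.
#' @param duration_min Session duration recorded in the schedule object.
#' @return A `session_schedule`.
#' @export
read_events_tsv <- function(path, duration_min = 12) {
  ev <- read_tsv(path)
  dg <- ev[ev$trial_type == "digit", ]
  tn <- ev[ev$trial_type %in% c("standard", "deviant"), ]
  digits <- new_digit_stream(dg$onset * 1000, as.integer(dg$value),
                             dg$target == 1, dg$block, duration_min,
                             c(NA, NA))
  tones <- new_tone_stream(tn$onset * 1000, tn$trial_type, tn$value,
                           tn$block, c(NA, NA))
  structure(list(digit_stream = digits, tone_stream = tones,
                 duration_min = duration_min), class = "session_schedule")
}

#' Write a press log as TSV
#'
#' One column, `onset_ms`.
#'
#' @param presses A `press_log`.
#' @param path Output path.
#' @export
write_presses_tsv <- function(presses, path) {
  write_tsv(format_numeric(data.frame(onset_ms = presses$press_times)), path)
}

#' Read a press log from TSV
#' @param path Path written by [write_presses_tsv()].
#' @return A `press_log`.
#' @export
read_presses_tsv <- function(path) {
  df <- read_tsv(path)
  structure(list(press_times = as.numeric(df$onset_ms)), class = "press_log")
}

#' Write a continuous recording as CSV + JSON sidecar
#'
#' `<prefix>_eeg.csv` holds the samples x channels matrix (named columns),
#' `<prefix>_eeg.json` the metadata (`channels`, `sampling_rate`, `units`),
#' and `<prefix>_recevents.tsv` the event list (`sample` 1-based, `code`,
#' `block`).
#'
#' @param recording A `continuous_recording`.
#' @param prefix Path prefix for the three files.
#' @return The prefix, invisibly.
#' @export
write_recording <- function(recording, prefix) {
  mat <- t(recording$data)
  colnames(mat) <- recording$channel_labels
  data.table::fwrite(as.data.frame(mat), paste0(prefix, "_eeg.csv"))
  jsonlite::write_json(list(channels = recording$channel_labels,
                            sampling_rate = recording$sampling_rate,
                            units = "uV",
                            n_samples = ncol(recording$data)),
                       paste0(prefix, "_eeg.json"), auto_unbox = TRUE)
  write_tsv(recording$events, paste0(prefix, "_recevents.tsv"))
  invisible(prefix)
}

#' Read a continuous recording written by [write_recording()]
#' @param prefix Path prefix used when writing.
#' @return A `continuous_recording`.
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_eeg.json"),
                              simplifyVector = TRUE)
  mat <- as.matrix(data.table::fread(paste0(prefix, "_eeg.csv")))
  events <- read_tsv(paste0(prefix, "_recevents.tsv"))
  new_continuous_recording(t(mat), meta$channels, events,
                           sampling_rate = meta$sampling_rate)
}

# full-precision text representation for numeric columns
format_numeric <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.12g", df[[j]])
  }
  df
}
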