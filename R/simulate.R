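# Synthetic continuous EEG and button-press behaviour embodying the
# condition-dependent effect structure of the crossover study.

FS_HZ <- 250
DT_MS <- 1000 / FS_HZ

new_continuous_recording <- function(data, channel_labels, events,
                                     sampling_rate = FS_HZ) {
  stopifnot(nrow(data) == length(channel_labels))
  if (nrow(events) > 0 &&
      (any(events$sample < 1L) || any(events$sample > ncol(data)))) {
    stop("event samples must lie within the recording")
  }
  structure(list(data = data, channel_labels = channel_labels,
                 sampling_rate = sampling_rate, events = events),
            class = "continuous_recording")
}

# 1/f ("pink") amplitude-spectrum noise, scaled to the requested SD.
# Synthesized in the frequency domain (Gaussian spectrum shaped by 1/sqrt(f))
# with inverse FFTs at a 2-3-5-smooth padded length; two real channels are
# packed into the real and imaginary parts of each complex FFT.
.sim_cache <- new.env(parent = emptyenv())

pink_noise_matrix <- function(nch, n, sd) {
  out <- matrix(0, nch, n)
  if (sd == 0 || n < 2) return(out)
  np <- stats::nextn(n, c(2, 3, 5))
  hkey <- paste0("h", np)
  h <- .sim_cache[[hkey]]
  if (is.null(h)) {
    k <- seq_len(np) - 1L
    k <- pmin(k, np - k) # two-sided frequency index
    h <- c(0, 1 / sqrt(k[-1]))
    .sim_cache[[hkey]] <- h
  }
  for (p in seq_len(ceiling(nch / 2))) {
    # a full (non-Hermitian) Gaussian spectrum yields two independent real
    # pink series in the real and imaginary parts of one inverse FFT
    spec <- (stats::rnorm(np) + 1i * stats::rnorm(np)) * h
    x <- stats::fft(spec, inverse = TRUE)[seq_len(n)]
    re <- Re(x)
    out[2L * p - 1L, ] <- re * (sd / stats::sd(re))
    c2 <- 2L * p
    if (c2 <= nch) {
      im <- Im(x)
      out[c2, ] <- im * (sd / stats::sd(im))
    }
  }
  out
}

pink_noise <- function(n, sd) pink_noise_matrix(1L, n, sd)[1L, ]

# Inverse-CDF draw from Normal(mean, sd) truncated to [lo, hi].
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), length.out = n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Stereotyped biphasic blink transient, 400 ms, unit peak amplitude.
blink_template <- function() {
  t <- seq(0, 400 - DT_MS, by = DT_MS)
  b <- exp(-((t - 120) / 60)^2 / 2) - 0.35 * exp(-((t - 280) / 70)^2 / 2)
  b / max(b)
}

# Damped sinusoid beginning after a cortical onset delay. The delay also
# guarantees that a following tone at the minimum 445 ms asynchrony
# contributes nothing inside the preceding 448 ms epoch tail.
standard_erp_template <- function(p) {
  delay <- if (is.null(p$delay_ms)) 20 else p$delay_ms
  t <- seq(0, p$dur_ms - DT_MS, by = DT_MS)
  td <- pmax(t - delay, 0)
  on <- as.numeric(t >= delay)
  p$amp * on * exp(-td / p$tau_ms) * sin(2 * pi * p$freq_hz * td / 1000)
}

mmn_component <- function(amp, peak_ms, width_ms) {
  lt <- ceiling((peak_ms + 6 * width_ms) / DT_MS)
  t <- (seq_len(lt) - 1) * DT_MS
  amp * exp(-((t - peak_ms) / width_ms)^2 / 2)
}

#' Simulate a continuous EEG recording for one session
#'
#' Builds a 4-channel (Fz, Cz, Pz, VEOG) 250 Hz recording in microvolts.
#' Every tone adds the damped-sinusoid standard template to the EEG channels
#' (scaled by the evoked topography); deviant tones additionally add the
#' Gaussian MMN negativity with amplitude `mmn_base_amp * amp_factor[cell]`
#' (plus any subject intercept) and peak latency shifted by
#' `latency_shift_ms` under ketamine. Background noise is pink plus a
#' random-phase alpha sinusoid; blinks occur as Poisson events on VEOG and
#' propagate to the EEG channels with the model's coefficients. The event
#' list records every tone with its category and block.
#'
#' @param schedule A `session_schedule`.
#' @param effects An `effect_model`.
#' @param cond A `condition`.
#' @param seed Optional integer seed.
#' @param subject_amp_shift Additive subject intercept on `mmn_base_amp` (uV).
#' @return A `continuous_recording`.
#' @export
simulate_eeg <- function(schedule, effects, cond, seed = NULL,
                         subject_amp_shift = 0) {
  stopifnot(inherits(schedule, "session_schedule"),
            inherits(effects, "effect_model"), inherits(cond, "condition"))
  if (!is.null(seed)) set.seed(seed)
  tones <- schedule$tone_stream
  last_ms <- max(c(tones$onsets, schedule$digit_stream$onsets, 0))
  n <- ceiling((last_ms + 1000) / DT_MS)
  channels <- c(EEG_CHANNELS, "VEOG")
  nch <- length(channels)

  data <- pink_noise_matrix(nch, n, effects$noise_sd)
  dimnames(data) <- list(channels, NULL)
  if (effects$alpha_amp > 0) {
    akey <- paste0("a", effects$alpha_freq_hz)
    ab <- .sim_cache[[akey]]
    if (is.null(ab) || length(ab$sb) < n) {
      base <- 2 * pi * effects$alpha_freq_hz * (seq_len(n) - 1) * DT_MS / 1000
      ab <- list(sb = sin(base), cb = cos(base))
      .sim_cache[[akey]] <- ab
    }
    sb <- ab$sb[seq_len(n)]
    cb <- ab$cb[seq_len(n)]
    phase <- stats::runif(nch, 0, 2 * pi)
    for (ch in seq_len(nch)) {
      data[ch, ] <- data[ch, ] +
        effects$alpha_amp * (cos(phase[ch]) * sb + sin(phase[ch]) * cb)
    }
  }

  # blinks: VEOG transient propagating to the EEG channels
  if (effects$blink_rate > 0) {
    btmpl <- blink_template()
    nb <- stats::rpois(1, effects$blink_rate * (last_ms + 1000) / 60000)
    if (nb > 0) {
      starts <- sort(round(stats::runif(nb, 1, n - length(btmpl))))
      prop <- c(effects$blink_propagation[EEG_CHANNELS], VEOG = 1)
      for (s0 in starts) {
        idx <- s0:(s0 + length(btmpl) - 1L)
        add <- effects$blink_amplitude * btmpl
        data[, idx] <- data[, idx] + outer(unname(prop), add)
      }
    }
  }

  # evoked responses, time-locked to the sample nearest each tone onset
  ev_samples <- pmax(1L, as.integer(round(tones$onsets / DT_MS)) + 1L)
  stmpl <- standard_erp_template(effects$standard_erp)
  dev <- tones$category == "deviant"
  amp <- (effects$mmn_base_amp + subject_amp_shift) *
    cell_values(effects$amp_factor, cond)
  peak <- effects$mmn_peak_latency_ms +
    if (cond$drug == "KI") effects$latency_shift_ms else 0
  mt_by_block <- lapply(1:3, function(b) {
    mmn_component(amp[b], peak, effects$mmn_width_ms)
  })
  # successive tones are >= 445 ms apart and both templates are shorter, so
  # index vectors within one addition never repeat
  keep <- ev_samples + length(stmpl) - 1L <= n
  sidx <- outer(ev_samples[keep], seq_along(stmpl) - 1L, "+")
  svals <- rep(stmpl, each = sum(keep))
  for (ch in EEG_CHANNELS) {
    data[ch, sidx] <- data[ch, sidx] + effects$erp_topography[ch] * svals
  }
  for (b in 1:3) {
    mt <- mt_by_block[[b]]
    es <- ev_samples[dev & tones$block_index == b &
                       ev_samples + length(mt) - 1L <= n]
    if (length(es) == 0) next
    midx <- outer(es, seq_along(mt) - 1L, "+")
    mvals <- rep(mt, each = length(es))
    for (ch in EEG_CHANNELS) {
      data[ch, midx] <- data[ch, midx] + effects$mmn_topography[ch] * mvals
    }
  }

  events <- data.frame(sample = ev_samples,
                       code = as.character(tones$category),
                       block = tones$block_index,
                       stringsAsFactors = FALSE)
  new_continuous_recording(data, channels, events)
}

#' Simulate RVIP button presses for one session
#'
#' Each target elicits a press with the cell's `hit_prob` at a latency drawn
#' from a truncated normal on the 100-1000 ms response window; each
#' non-target digit elicits a spurious press with the cell's `fa_prob` (same
#' latency distribution). Press times are returned sorted and strictly
#' increasing.
#'
#' @param digits A `digit_stream`.
#' @param effects An `effect_model`.
#' @param cond A `condition`.
#' @param seed Optional integer seed.
#' @param subject_hit_shift Additive subject intercept on logit(hit_prob).
#' @return A `press_log` with `press_times` in ms from session start.
#' @export
simulate_behavior <- function(digits, effects, cond, seed = NULL,
                              subject_hit_shift = 0) {
  stopifnot(inherits(digits, "digit_stream"),
            inherits(effects, "effect_model"), inherits(cond, "condition"))
  if (!is.null(seed)) set.seed(seed)
  hp <- stats::plogis(stats::qlogis(pmin(pmax(
    cell_values(effects$hit_prob, cond), 1e-9), 1 - 1e-9)) + subject_hit_shift)
  hp[cell_values(effects$hit_prob, cond) == 0] <- 0
  hp[cell_values(effects$hit_prob, cond) == 1] <- 1
  fp <- cell_values(effects$fa_prob, cond)
  rtm <- cell_values(effects$rt_mean_ms, cond)

  blk <- digits$block_index
  tgt <- digits$target_flags
  presses <- numeric(0)
  for (b in 1:3) {
    t_on <- digits$onsets[tgt & blk == b]
    hit <- stats::runif(length(t_on)) < hp[b]
    if (any(hit)) {
      presses <- c(presses, t_on[hit] +
                     rtruncnorm(sum(hit), rtm[b], effects$rt_sd_ms, 100, 1000))
    }
    n_on <- digits$onsets[!tgt & blk == b]
    fa <- stats::runif(length(n_on)) < fp[b]
    if (any(fa)) {
      presses <- c(presses, n_on[fa] +
                     rtruncnorm(sum(fa), rtm[b], effects$rt_sd_ms, 100, 1000))
    }
  }
  presses <- sort(presses)
  presses <- presses[!duplicated(presses)]
  structure(list(press_times = presses), class = "press_log")
}

#' Simulate the full crossover study
#'
#' Generates `2 * n_per_group` subjects (L-HD and H-HD), each completing the
#' four gum x drug sessions in counterbalanced (balanced Latin square) order.
#' Each subject receives Gaussian random intercepts on MMN amplitude and on
#' logit(hit probability); each subject x session gets its own stimulus
#' schedule, EEG, and press log from a seed substream spawned by the master
#' seed.
#'
#' @param n_per_group Subjects per HD group (>= 2).
#' @param effects An `effect_model`.
#' @param seed Optional master integer seed.
#' @param handler Optional function applied to each session record as it is
#'   produced; when supplied, only the handler's return values are kept
#'   (memory-light streaming). A record is a list with `subject`, `group`,
#'   `session`, `order_position`, `cond`, `schedule`, `recording`, `presses`,
#'   `sub_seed`.
#' @param duration_min Session duration in minutes (default 12); ignored if
#'   `paradigm` is given.
#' @param paradigm Optional paradigm parameter list as in
#'   [default_study_config()]`$paradigm`; defaults scale the standard
#'   12-min design to `duration_min`.
#' @return A list of class `study_simulation` with `manifest` (one row per
#'   subject x session) and `records` (raw records, or handler results).
#' @export
simulate_study <- function(n_per_group = 12, effects = effect_model(),
                           seed = NULL, handler = NULL, duration_min = 12,
                           paradigm = NULL) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (is.null(paradigm)) {
    paradigm <- default_study_config()$paradigm
    paradigm$duration_min <- duration_min
    paradigm$n_tones <- 100 * duration_min
  }
  if (!is.null(seed)) set.seed(seed)
  n_sub <- 2L * n_per_group
  sessions <- crossover_sessions()
  # balanced Latin square over the four sessions, recycled over subjects
  latin <- rbind(c(1, 2, 4, 3), c(2, 3, 1, 4), c(3, 4, 2, 1), c(4, 1, 3, 2))
  groups <- rep(GROUP_LEVELS, each = n_per_group)
  amp_shift <- stats::rnorm(n_sub, 0, effects$subject_amp_sd)
  hit_shift <- stats::rnorm(n_sub, 0, effects$subject_hit_logit_sd)
  sub_seeds <- matrix(sample.int(.Machine$integer.max, n_sub * 4L),
                      nrow = n_sub)

  manifest <- NULL
  records <- vector("list", n_sub * 4L)
  i <- 0L
  for (s in seq_len(n_sub)) {
    order_s <- latin[(s - 1L) %% 4L + 1L, ]
    for (pos in 1:4) {
      i <- i + 1L
      sess <- order_s[pos]
      cond <- condition(groups[s], sessions$gum[sess], sessions$drug[sess])
      set.seed(sub_seeds[s, pos])
      schedule <- schedule_from_config(paradigm)
      recording <- simulate_eeg(schedule, effects, cond,
                                subject_amp_shift = amp_shift[s])
      presses <- simulate_behavior(schedule$digit_stream, effects, cond,
                                   subject_hit_shift = hit_shift[s])
      rec <- list(subject = s, group = groups[s], session = sess,
                  order_position = pos, cond = cond, schedule = schedule,
                  recording = recording, presses = presses,
                  sub_seed = sub_seeds[s, pos])
      records[[i]] <- if (is.null(handler)) rec else handler(rec)
      manifest <- rbind(manifest, data.frame(
        subject = s, group = groups[s], session = sess,
        order_position = pos, gum = cond$gum, drug = cond$drug,
        seed = sub_seeds[s, pos], stringsAsFactors = FALSE))
    }
  }
  structure(list(manifest = manifest, records = records,
                 n_per_group = n_per_group), class = "study_simulation")
}

#' Simulate a study and reduce it to measurement tables
#'
#' Streams through [simulate_study()], immediately running the ERP pipeline
#' and RVIP scoring on each session and discarding the raw recording, so a
#' full 24-subject study fits comfortably in memory.
#'
#' @inheritParams simulate_study
#' @param ... Passed to [measure_recording()].
#' @return A list with `mmn` (subject, group, gum, drug, block, amplitude_uv,
#'   latency_ms, n_deviants, sufficient) and `rvip` (the per-block metrics)
#'   data.frames, each with `2 * n_per_group * 4 * 3` rows.
#' @export
simulate_measured_study <- function(n_per_group = 12,
                                    effects = effect_model(), seed = NULL,
                                    duration_min = 12, paradigm = NULL,
                                    ...) {
  handler <- function(rec) {
    mm <- measure_recording(rec$recording, ...)
    rv <- block_metrics(rec$schedule$digit_stream, rec$presses)
    meta <- data.frame(subject = rec$subject, group = rec$group,
                       gum = rec$cond$gum, drug = rec$cond$drug,
                       stringsAsFactors = FALSE)
    list(mmn = cbind(meta[rep(1, nrow(mm)), ], mm, row.names = NULL),
         rvip = cbind(meta[rep(1, nrow(rv)), ], rv, row.names = NULL))
  }
  sim <- simulate_study(n_per_group, effects, seed, handler = handler,
                        duration_min = duration_min, paradigm = paradigm)
  list(mmn = do.call(rbind, lapply(sim$records, `[[`, "mmn")),
       rvip = do.call(rbind, lapply(sim$records, `[[`, "rvip")),
       manifest = sim$manifest)
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat("<continuous_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$sampling_rate, " Hz, ", nrow(x$events), " events\n",
      sep = "")
  invisible(x)
}

#' @export
print.press_log <- function(x, ...) {
  cat("<press_log> ", length(x$press_times), " presses\n", sep = "")
  invisible(x)
}
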