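# Scoring button presses against the digit stream: hits, false alarms,
# reaction time, and signal-detection d-prime, per 4-min block.

#' Classify presses as hits or false alarms
#'
#' Presses are scanned in time order. A press is a hit iff it falls within
#' the response window (closed at both ends) after some target's onset and
#' that target has not already been credited; when windows overlap, the
#' earlier unclaimed target is credited. Every other press is a false alarm.
#' A false alarm is attributed to the most recent digit at or before the
#' press (its presumed eliciting stimulus) for block assignment.
#'
#' @param digits A `digit_stream` with targets flagged.
#' @param presses A `press_log` (sorted press times, ms).
#' @param window_ms Response window after target onset, default c(100, 1000).
#' @return A list with `presses` (one row per press: `time_ms`, `type`
#'   "hit"/"fa", `target_index`, `rt_ms`, `block`) and `targets` (one row per
#'   target: `index`, `onset_ms`, `block`, `hit`, `rt_ms`).
#' @export
classify_responses <- function(digits, presses, window_ms = c(100, 1000)) {
  stopifnot(inherits(digits, "digit_stream"), inherits(presses, "press_log"))
  p <- presses$press_times
  if (is.unsorted(p, strictly = TRUE)) stop("press times must be strictly increasing")
  tgt_idx <- which(digits$target_flags)
  tgt_on <- digits$onsets[tgt_idx]
  tgt_blk <- digits$block_index[tgt_idx]
  claimed <- rep(FALSE, length(tgt_idx))
  tgt_rt <- rep(NA_real_, length(tgt_idx))

  np <- length(p)
  type <- character(np)
  p_tgt <- rep(NA_integer_, np)
  p_rt <- rep(NA_real_, np)
  p_blk <- rep(NA_integer_, np)
  for (i in seq_len(np)) {
    in_win <- which(!claimed & p[i] >= tgt_on + window_ms[1] &
                      p[i] <= tgt_on + window_ms[2])
    if (length(in_win) > 0) {
      j <- in_win[1] # earliest unclaimed target
      claimed[j] <- TRUE
      tgt_rt[j] <- p[i] - tgt_on[j]
      type[i] <- "hit"
      p_tgt[i] <- tgt_idx[j]
      p_rt[i] <- tgt_rt[j]
      p_blk[i] <- tgt_blk[j]
    } else {
      type[i] <- "fa"
      k <- findInterval(p[i], digits$onsets)
      p_blk[i] <- if (k >= 1) digits$block_index[k] else 1L
    }
  }
  list(
    presses = data.frame(time_ms = p, type = type, target_index = p_tgt,
                         rt_ms = p_rt, block = p_blk,
                         stringsAsFactors = FALSE),
    targets = data.frame(index = tgt_idx, onset_ms = tgt_on, block = tgt_blk,
                         hit = claimed, rt_ms = tgt_rt,
                         stringsAsFactors = FALSE))
}

#' Signal-detection sensitivity d-prime
#'
#' `d' = z(H) - z(F)` with the standard extreme-rate adjustment: a rate of 0
#' becomes `1/(2N)` and a rate of 1 becomes `1 - 1/(2N)`, where `N` is the
#' number of trials of that type (targets for H, non-targets for F), so the
#' statistic is always finite.
#'
#' @param n_hits,n_targets Hit count and target count.
#' @param n_fa,n_nontargets False-alarm count and non-target digit count.
#' @return A list with `dprime`, `hit_rate`, `fa_rate` (post-correction
#'   rates).
#' @export
compute_dprime <- function(n_hits, n_targets, n_fa, n_nontargets) {
  if (n_targets < 1 || n_nontargets < 1) {
    stop("n_targets and n_nontargets must be >= 1")
  }
  correct_rate <- function(k, n) {
    r <- k / n
    if (r == 0) r <- 1 / (2 * n)
    if (r == 1) r <- 1 - 1 / (2 * n)
    r
  }
  h <- correct_rate(n_hits, n_targets)
  f <- correct_rate(n_fa, n_nontargets)
  list(dprime = stats::qnorm(h) - stats::qnorm(f), hit_rate = h, fa_rate = f)
}

#' Per-block RVIP performance metrics
#'
#' Classifies the presses and aggregates per 4-min block: target and hit
#' counts, percent hits, false-alarm count and percent (of non-target
#' digits), mean RT over hits, and d-prime. A press contributes to the block
#' of its eliciting stimulus.
#'
#' @inheritParams classify_responses
#' @return A data.frame with one row per block: `block`, `n_targets`,
#'   `n_hits`, `pct_hits`, `n_fa`, `pct_fa`, `mean_rt_ms`, `dprime`.
#' @export
block_metrics <- function(digits, presses, window_ms = c(100, 1000)) {
  cls <- classify_responses(digits, presses, window_ms)
  blocks <- sort(unique(digits$block_index))
  out <- lapply(blocks, function(b) {
    tg <- cls$targets[cls$targets$block == b, ]
    n_targets <- nrow(tg)
    n_hits <- sum(tg$hit)
    n_nontargets <- sum(digits$block_index == b) - n_targets
    n_fa <- sum(cls$presses$type == "fa" & cls$presses$block == b)
    dp <- compute_dprime(n_hits, n_targets, n_fa, n_nontargets)
    data.frame(block = b, n_targets = n_targets, n_hits = n_hits,
               pct_hits = 100 * n_hits / n_targets, n_fa = n_fa,
               pct_fa = 100 * n_fa / n_nontargets,
               mean_rt_ms = if (n_hits > 0) mean(tg$rt_ms[tg$hit]) else NA_real_,
               dprime = dp$dprime)
  })
  do.call(rbind, out)
}
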