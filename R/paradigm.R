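# Stimulus schedules for the dual-task session: a visual digit stream (RVIP
# continuous performance task) and an auditory oddball tone stream, jittered
# independently and then interleaved so the two modalities never overlap.

ODD_DIGITS <- c(1L, 3L, 5L, 7L, 9L)
EVEN_DIGITS <- c(2L, 4L, 6L, 8L)

new_digit_stream <- function(onsets, digits, target_flags, block_index,
                             duration_min, soa_range_ms) {
  structure(list(
    onsets = as.numeric(onsets),
    digits = as.integer(digits),
    duration_ms = 50,
    target_flags = as.logical(target_flags),
    block_index = as.integer(block_index),
    duration_min = duration_min,
    soa_range_ms = soa_range_ms
  ), class = "digit_stream")
}

new_tone_stream <- function(onsets, category, frequency_label, block_index,
                            soa_range_ms) {
  structure(list(
    onsets = as.numeric(onsets),
    category = factor(category, levels = c("standard", "deviant")),
    frequency_label = as.character(frequency_label),
    duration_ms = 50,
    block_index = as.integer(block_index),
    soa_range_ms = soa_range_ms
  ), class = "tone_stream")
}

# Uniformly sample k sorted positions in lo..hi whose consecutive differences
# are all >= gap, via the classical bijection with an unconstrained sample.
sample_spaced_positions <- function(k, lo, hi, gap) {
  if (k == 0L) return(integer(0))
  m <- hi - lo + 1L - (k - 1L) * (gap - 1L)
  if (m < k) {
    stop("infeasible packing: cannot place ", k, " events in ", hi - lo + 1L,
         " slots with minimum spacing ", gap, call. = FALSE)
  }
  u <- sort(sample.int(m, k))
  lo - 1L + u + (gap - 1L) * (seq_len(k) - 1L)
}

#' Find RVIP targets in a digit sequence
#'
#' A target is the third digit of three consecutive odd digits. All completing
#' indices are returned, so a run of four odd digits yields two targets; the
#' default generator excludes such runs by construction, but arbitrary input
#' is handled.
#'
#' @param digits Integer vector with values in 1..9.
#' @return Sorted integer vector of 1-based target indices (each `i` satisfies
#'   `digits[i-2]`, `digits[i-1]`, `digits[i]` all odd).
#' @examples
#' identify_targets(c(2, 3, 5, 7, 4)) # 4
#' @export
identify_targets <- function(digits) {
  if (length(digits) == 0) return(integer(0))
  digits <- as.integer(digits)
  if (anyNA(digits) || any(digits < 1L | digits > 9L)) {
    stop("digits must be integers in 1..9")
  }
  n <- length(digits)
  if (n < 3L) return(integer(0))
  odd <- digits %% 2L == 1L
  idx <- 3:n
  idx[odd[idx] & odd[idx - 1L] & odd[idx - 2L]]
}

#' Generate the RVIP digit stream
#'
#' Digits 1-9 are presented at a fixed nominal rate with inter-onset
#' intervals jittered uniformly over `soa_range_ms`. Targets (the third of
#' three consecutive odd digits) are planted at the requested rate, with
#' consecutive targets separated by at least `min_separation` intervening
#' digits. Non-target digits are drawn so that they never complete an odd
#' triad: the digit immediately preceding each planted triad is forced even,
#' and any free draw that would follow two odd digits is drawn from the even
#' digits only. The flagged set is therefore exactly the set found by an
#' exhaustive scan.
#'
#' @param duration_min Session duration in whole minutes (default 12).
#' @param rate_per_min Digits per minute (default 110).
#' @param targets_per_min Targets per minute (default 10).
#' @param min_separation Minimum number of intervening digits between
#'   consecutive targets (default 5).
#' @param soa_range_ms Inter-onset jitter range in ms (default c(445, 645)).
#' @param seed Optional integer seed.
#' @return A `digit_stream`: onsets (ms), digits, 50 ms event duration,
#'   logical target flags, and block index partitioning the stream into three
#'   equal-count blocks.
#' @export
generate_digit_stream <- function(duration_min = 12, rate_per_min = 110,
                                  targets_per_min = 10, min_separation = 5,
                                  soa_range_ms = c(445, 645), seed = NULL) {
  if (duration_min < 0) stop("duration_min must be >= 0")
  if (duration_min != round(duration_min)) {
    stop("duration_min must be a whole number of minutes")
  }
  duration_min <- as.integer(duration_min)
  if (rate_per_min != round(rate_per_min) ||
      targets_per_min != round(targets_per_min)) {
    stop("rate_per_min and targets_per_min must be integer event counts")
  }
  n <- duration_min * rate_per_min
  if (n == 0L) {
    return(new_digit_stream(numeric(0), integer(0), logical(0), integer(0),
                            duration_min, soa_range_ms))
  }
  if (!is.null(seed)) set.seed(seed)
  rate_per_min <- as.integer(rate_per_min)
  k <- as.integer(targets_per_min)
  gap <- as.integer(min_separation) + 1L

  # Plant target indices minute by minute so the target rate is uniform over
  # the session; the spacing constraint is enforced across minute boundaries.
  flags <- integer(0)
  prev <- -.Machine$integer.max
  for (m in seq_len(duration_min)) {
    lo <- max((m - 1L) * rate_per_min + 1L, prev + gap, 3L)
    hi <- m * rate_per_min
    f <- sample_spaced_positions(k, lo, hi, gap)
    if (k > 0L) {
      flags <- c(flags, f)
      prev <- f[k]
    }
  }

  digits <- integer(n)
  filled <- logical(n)
  for (f in flags) {
    digits[(f - 2L):f] <- sample(ODD_DIGITS, 3L, replace = TRUE)
    filled[(f - 2L):f] <- TRUE
  }
  pre <- flags - 3L
  pre <- pre[pre >= 1L]
  if (length(pre)) {
    digits[pre] <- sample(EVEN_DIGITS, length(pre), replace = TRUE)
    filled[pre] <- TRUE
  }
  odd <- filled & (digits %% 2L == 1L)
  for (p in which(!filled)) {
    if (p >= 3L && odd[p - 1L] && odd[p - 2L]) {
      d <- EVEN_DIGITS[sample.int(4L, 1L)]
    } else {
      d <- sample.int(9L, 1L)
    }
    digits[p] <- d
    odd[p] <- d %% 2L == 1L
  }

  onsets <- cumsum(stats::runif(n, soa_range_ms[1], soa_range_ms[2]))
  target_flags <- logical(n)
  target_flags[flags] <- TRUE
  block_index <- as.integer(ceiling(seq_len(n) * 3 / n))
  new_digit_stream(onsets, digits, target_flags, block_index, duration_min,
                   soa_range_ms)
}

#' Generate the auditory oddball tone stream
#'
#' Tones are jittered uniformly over `soa_range_ms`. Deviants are placed by
#' stratified randomization: exactly `deviant_fraction` of each block, drawn
#' uniformly among placements with at least one standard between consecutive
#' deviants (also across block boundaries) so every deviant occurs in a
#' standard context.
#'
#' @param n_tones Total number of tones (default 1200).
#' @param deviant_fraction Proportion of deviants (default 0.10); must give an
#'   integer count per block.
#' @param soa_range_ms Inter-onset jitter range in ms.
#' @param n_blocks Number of equal blocks (default 3).
#' @param standard_hz,deviant_hz Frequency labels carried as metadata only; no
#'   audio is synthesized.
#' @param seed Optional integer seed.
#' @return A `tone_stream` with onsets (ms), standard/deviant category,
#'   frequency labels, and block index.
#' @export
generate_tone_stream <- function(n_tones = 1200, deviant_fraction = 0.10,
                                 soa_range_ms = c(445, 645), n_blocks = 3,
                                 standard_hz = 1000, deviant_hz = 1100,
                                 seed = NULL) {
  if (n_tones == 0) {
    return(new_tone_stream(numeric(0), character(0), character(0), integer(0),
                           soa_range_ms))
  }
  if (n_tones %% n_blocks != 0) {
    stop("n_tones must divide into ", n_blocks, " equal blocks")
  }
  block_size <- as.integer(n_tones / n_blocks)
  kd <- deviant_fraction * block_size
  if (abs(kd - round(kd)) > 1e-9) {
    stop("deviant_fraction * block size must be an integer ",
         "(got ", kd, " deviants per ", block_size, "-stimulus block)")
  }
  kd <- as.integer(round(kd))
  if (!is.null(seed)) set.seed(seed)

  deviant <- logical(n_tones)
  prev_last <- FALSE
  for (b in seq_len(n_blocks)) {
    off <- (b - 1L) * block_size
    lo <- if (prev_last) 2L else 1L # no two deviants back to back
    pos <- sample_spaced_positions(kd, lo, block_size, 2L)
    deviant[off + pos] <- TRUE
    prev_last <- kd > 0L && pos[kd] == block_size
  }

  onsets <- cumsum(stats::runif(n_tones, soa_range_ms[1], soa_range_ms[2]))
  category <- ifelse(deviant, "deviant", "standard")
  freq <- ifelse(deviant, paste(deviant_hz, "Hz"), paste(standard_hz, "Hz"))
  block_index <- rep(seq_len(n_blocks), each = block_size)
  new_tone_stream(onsets, category, freq, block_index, soa_range_ms)
}

# Sub-intervals of [lo, hi] whose points t keep [t, t+50) clear of every
# digit interval [d, d+50). Returns a 2-column matrix of segment bounds.
allowed_onset_segments <- function(lo, hi, digit_onsets, dur = 50) {
  near <- digit_onsets[digit_onsets > lo - dur & digit_onsets < hi + dur]
  segs <- matrix(c(lo, hi), ncol = 2)
  for (d in near) {
    zlo <- d - dur
    zhi <- d + dur
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nrow(segs))) {
      a <- segs[i, 1]; b <- segs[i, 2]
      if (zhi <= a || zlo >= b) {
        out <- rbind(out, c(a, b))
      } else {
        if (zlo > a) out <- rbind(out, c(a, zlo))
        if (zhi < b) out <- rbind(out, c(zhi, b))
      }
    }
    segs <- out
  }
  segs[segs[, 2] > segs[, 1], , drop = FALSE]
}

#' Interleave tone and digit streams without temporal overlap
#'
#' Tone onsets are re-jittered sequentially: each inter-onset interval is
#' drawn uniformly from the feasible subset of `soa_range_ms` that keeps the
#' 50 ms tone presentation clear of every 50 ms digit presentation. Digit
#' onsets and the within-stream event orders are unchanged. Because digit
#' intervals are at least 445 ms apart, a 200 ms jitter window always retains
#' feasible room; an empty feasible set raises a configuration error.
#'
#' @param tones A `tone_stream`.
#' @param digits A `digit_stream`.
#' @param soa_range_ms Tone inter-onset jitter range in ms.
#' @param seed Optional integer seed.
#' @return A `session_schedule` with fields `digit_stream`, `tone_stream`,
#'   `duration_min`.
#' @export
interleave <- function(tones, digits, soa_range_ms = tones$soa_range_ms,
                       seed = NULL) {
  stopifnot(inherits(tones, "tone_stream"), inherits(digits, "digit_stream"))
  if (!is.null(seed)) set.seed(seed)
  d <- sort(digits$onsets)
  nd <- length(d)
  n <- length(tones$onsets)
  new_onsets <- numeric(n)
  prev <- 0
  collides <- function(t) {
    k <- findInterval(t, d)
    (k >= 1L && t - d[k] < 50) || (k < nd && d[k + 1L] - t < 50)
  }
  for (i in seq_len(n)) {
    # re-jitter within the SOA range until the tone clears every digit;
    # fall back to exact sampling from the feasible segments if unlucky
    placed <- FALSE
    for (try in 1:20) {
      t <- prev + stats::runif(1, soa_range_ms[1], soa_range_ms[2])
      if (!collides(t)) { placed <- TRUE; break }
    }
    if (!placed) {
      segs <- allowed_onset_segments(prev + soa_range_ms[1],
                                     prev + soa_range_ms[2], d)
      if (nrow(segs) == 0) {
        stop("cannot place tone ", i, " without overlapping a digit")
      }
      len <- segs[, 2] - segs[, 1]
      cs <- cumsum(len)
      x <- stats::runif(1, 0, cs[length(cs)])
      j <- which(x <= cs)[1]
      t <- segs[j, 1] + x - if (j > 1) cs[j - 1] else 0
    }
    new_onsets[i] <- t
    prev <- t
  }
  session_duration_ms <- digits$duration_min * 60000
  if (n > 0 && length(d) > 0 && new_onsets[n] + 50 > session_duration_ms) {
    stop("tone stream does not fit inside the ", digits$duration_min,
         "-min session")
  }
  tones$onsets <- new_onsets
  structure(list(digit_stream = digits, tone_stream = tones,
                 duration_min = digits$duration_min),
            class = "session_schedule")
}

#' Count overlapping tone/digit presentation pairs in a schedule
#'
#' Audit helper: the number of (tone, digit) pairs whose 50 ms presentation
#' intervals overlap with positive duration. A valid schedule returns 0.
#'
#' @param schedule A `session_schedule`.
#' @return Integer overlap count.
#' @export
schedule_overlap_count <- function(schedule) {
  tt <- schedule$tone_stream$onsets
  dd <- schedule$digit_stream$onsets
  if (length(tt) == 0 || length(dd) == 0) return(0L)
  dd <- sort(dd)
  # overlap iff |t - d| < 50; check the two nearest digits for each tone
  pos <- findInterval(tt, dd)
  count <- 0L
  for (k in seq_along(tt)) {
    for (j in c(pos[k], pos[k] + 1L)) {
      if (j >= 1L && j <= length(dd) && abs(tt[k] - dd[j]) < 50) {
        count <- count + 1L
      }
    }
  }
  count
}

#' Generate a complete default session schedule
#'
#' Convenience wrapper building the default 12-min dual-task session: 1320
#' digits (120 targets) and 1200 tones (10\% deviants, 40 per block),
#' interleaved without overlap.
#'
#' @param seed Optional integer seed.
#' @param duration_min Session duration in minutes.
#' @return A `session_schedule`.
#' @export
generate_session_schedule <- function(seed = NULL, duration_min = 12) {
  if (!is.null(seed)) set.seed(seed)
  digits <- generate_digit_stream(duration_min = duration_min)
  tones <- generate_tone_stream(n_tones = 100 * duration_min)
  interleave(tones, digits)
}

#' @export
print.digit_stream <- function(x, ...) {
  cat("<digit_stream> ", length(x$digits), " digits, ",
      sum(x$target_flags), " targets, ", x$duration_min, " min\n", sep = "")
  invisible(x)
}

#' @export
print.tone_stream <- function(x, ...) {
  cat("<tone_stream> ", length(x$onsets), " tones, ",
      sum(x$category == "deviant"), " deviants\n", sep = "")
  invisible(x)
}

#' @export
print.session_schedule <- function(x, ...) {
  cat("<session_schedule> ", x$duration_min, " min: ",
      length(x$digit_stream$digits), " digits / ",
      length(x$tone_stream$onsets), " tones\n", sep = "")
  invisible(x)
}
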