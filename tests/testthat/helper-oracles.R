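# Independent brute-force oracles and small shared fixtures.

# exhaustive scan over every length-3 window
brute_targets <- function(digits) {
  hits <- integer(0)
  if (length(digits) < 3) return(hits)
  for (i in 3:length(digits)) {
    if (all(digits[(i - 2):i] %% 2 == 1)) hits <- c(hits, i)
  }
  hits
}

# exhaustive pairwise interval-intersection count (positive-measure overlap)
brute_overlap_count <- function(schedule, dur = 50) {
  tt <- schedule$tone_stream$onsets
  dd <- schedule$digit_stream$onsets
  n <- 0L
  for (t in tt) {
    n <- n + sum(t < dd + dur & dd < t + dur)
  }
  n
}

# target-centric assignment under the first-press / earlier-target rules
oracle_classify <- function(target_onsets, presses, win = c(100, 1000)) {
  used <- rep(FALSE, length(presses))
  hit <- rep(FALSE, length(target_onsets))
  rt <- rep(NA_real_, length(target_onsets))
  for (j in order(target_onsets)) {
    w <- which(!used & presses >= target_onsets[j] + win[1] &
                 presses <= target_onsets[j] + win[2])
    if (length(w)) {
      used[w[1]] <- TRUE
      hit[j] <- TRUE
      rt[j] <- presses[w[1]] - target_onsets[j]
    }
  }
  list(hit = hit, rt = rt, press_is_hit = used)
}

# classical algebraic form of Box's epsilon (Winer), independent of the
# eigenvalue route used by the package
box_epsilon_oracle <- function(S) {
  k <- nrow(S)
  sbar <- mean(S)
  sdiag <- mean(diag(S))
  srow <- rowMeans(S)
  num <- (k * (sdiag - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(srow^2) + k^2 * sbar^2)
  num / den
}

# full aov() projection oracle for the split-plot design
aov_oracle <- function(d, dv = "value") {
  d$value_ <- d[[dv]]
  d$block <- factor(d$block)
  d$subject <- factor(d$subject)
  fit <- stats::aov(
    value_ ~ group * gum * drug * block + Error(subject / (gum * drug * block)),
    data = d)
  s <- summary(fit)
  out <- list()
  for (st in names(s)) {
    tab <- as.data.frame(s[[st]][[1]])
    rn <- trimws(rownames(tab))
    res <- which(rn == "Residuals")
    for (i in seq_along(rn)) {
      if (i == res) next
      out[[rn[i]]] <- c(ss = tab[i, "Sum Sq"], df1 = tab[i, "Df"],
                        F = tab[i, "F value"], df2 = tab[res, "Df"],
                        ss_error = tab[res, "Sum Sq"])
    }
  }
  out
}

# random balanced split-plot dataset with arbitrary effects
random_splitplot_data <- function(n_per_group = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- simulate_null_splitplot(n_per_group)
  d$value <- d$value +
    stats::rnorm(1, 0, 2) * (d$group == "H-HD") +
    stats::rnorm(1, 0, 2) * (d$gum == "NG") +
    stats::rnorm(1, 0, 1) * (d$gum == "NG") * (d$block == 3) +
    stats::rnorm(1, 0, 1) * (d$drug == "KI") * (d$group == "H-HD")
  d
}

# noiseless effect model for exact-construction tests
quiet_effects <- function(...) {
  effect_model(noise_sd = 0, alpha_amp = 0, blink_rate = 0, ...)
}

# small 3-min session schedule, cached per seed (tests reuse these)
.schedule_cache <- new.env(parent = emptyenv())
small_schedule <- function(seed = 1) {
  key <- as.character(seed)
  if (is.null(.schedule_cache[[key]])) {
    set.seed(seed)
    .schedule_cache[[key]] <- generate_session_schedule(duration_min = 3)
  }
  .schedule_cache[[key]]
}

all_zero_amp <- function() {
  a <- default_amp_factor_zero()
  a
}

default_amp_factor_zero <- function() {
  em <- effect_model()
  a <- em$amp_factor
  a[] <- 0
  a
}
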