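# The effect model: every condition-dependent parameter of the synthetic
# study, indexed by the 2 (HD group) x 2 (gum) x 2 (drug) x 3 (block) design
# cell. Defaults encode the qualitative drug/group/block pattern the package
# is calibrated to detect: ketamine attenuates the MMN in the H-HD group
# under placebo gum (most strongly in block 3) and slows its peak; nicotine
# gum blocks that attenuation; nicotine raises hit rate and lowers false
# alarms under placebo infusion but not under ketamine; hit rate declines
# after block 1; the H-HD group starts from a worse hit rate and slower RT.

GROUP_LEVELS <- c("L-HD", "H-HD")
GUM_LEVELS <- c("PG", "NG")
DRUG_LEVELS <- c("PI", "KI")
EEG_CHANNELS <- c("Fz", "Cz", "Pz")

cell_array <- function(fill = 0) {
  array(fill, dim = c(2, 2, 2, 3),
        dimnames = list(group = GROUP_LEVELS, gum = GUM_LEVELS,
                        drug = DRUG_LEVELS, block = c("1", "2", "3")))
}

#' Default cell-indexed parameter arrays
#'
#' The 2x2x2x3 group x gum x drug x block arrays behind the [effect_model()]
#' defaults, exposed so single cells can be modified before construction.
#'
#' @return A named numeric array with dimensions group (L-HD, H-HD), gum
#'   (PG, NG), drug (PI, KI), block (1-3).
#' @name default_cells
NULL

#' @rdname default_cells
#' @export
default_amp_factor <- function() {
  a <- cell_array(1)
  a["H-HD", "PG", "KI", ] <- c(0.85, 0.75, 0.55) # ketamine attenuation, worst in block 3
  a["L-HD", "PG", "KI", ] <- 0.92
  a["H-HD", "NG", "KI", ] <- 1.00                # nicotine blocks the attenuation
  a["L-HD", "NG", "KI", ] <- 0.95
  a
}

#' @rdname default_cells
#' @export
default_hit_prob <- function() {
  h <- cell_array()
  h["L-HD", , , ] <- rep(c(0.88, 0.84, 0.83), each = 4)
  h["H-HD", , , ] <- rep(c(0.80, 0.75, 0.75), each = 4)
  # nicotine improves detection under placebo infusion only
  h["L-HD", "NG", "PI", ] <- h["L-HD", "PG", "PI", ] + 0.05
  h["H-HD", "NG", "PI", ] <- h["H-HD", "PG", "PI", ] + 0.10
  h
}

#' @rdname default_cells
#' @export
default_fa_prob <- function() {
  f <- cell_array(0.010)
  f[, "PG", , 3] <- 0.013 # late-session errors under placebo gum
  f[, "NG", , ] <- 0.006  # nicotine reduces false alarms
  f
}

#' @rdname default_cells
#' @export
default_rt_mean <- function() {
  r <- cell_array()
  r["L-HD", , , ] <- 420
  r["H-HD", , , ] <- 455
  r[, "NG", , ] <- r[, "NG", , ] - 25      # nicotine speeds responses
  r["L-HD", , "KI", ] <- r["L-HD", , "KI", ] + 25 # ketamine slows the faster group
  r
}

#' Condition-dependent parameters of the synthetic study
#'
#' Bundles every parameter of the synthetic EEG and behaviour generators.
#' Cell-indexed parameters (`amp_factor`, `hit_prob`, `fa_prob`,
#' `rt_mean_ms`) are 2x2x2x3 arrays over group (L-HD, H-HD), gum (PG, NG),
#' drug (PI, KI), and block (1-3); scalars apply everywhere.
#'
#' @param mmn_base_amp MMN peak amplitude at Fz in microvolts (negative).
#' @param mmn_peak_latency_ms MMN peak latency from tone onset (ms); the
#'   default 148 ms lies on the 4 ms sampling grid.
#' @param mmn_width_ms Gaussian SD of the MMN component (ms).
#' @param latency_shift_ms Added to the MMN peak latency under ketamine (KI).
#' @param amp_factor Multiplicative MMN amplitude factor per design cell,
#'   each in `[0, 2]`.
#' @param standard_erp Damped-sinusoid template parameters shared by
#'   standards and deviants: `amp` (uV), `freq_hz`, `tau_ms`, `dur_ms`, and
#'   an optional `delay_ms` cortical onset delay (default 20 ms).
#' @param erp_topography,mmn_topography Per-channel scaling of the evoked
#'   template and of the MMN component (Fz maximal).
#' @param noise_sd Background EEG noise SD in microvolts (pink spectrum).
#' @param alpha_amp,alpha_freq_hz Amplitude (uV) and frequency of the
#'   ongoing alpha sinusoid (random phase per channel).
#' @param blink_rate Blink events per minute (Poisson).
#' @param blink_amplitude Peak blink amplitude on the VEOG channel (uV).
#' @param blink_propagation Fraction of the VEOG blink reaching each EEG
#'   channel; ground truth for ocular-correction recovery.
#' @param hit_prob,fa_prob Per-cell probability that a target is detected /
#'   that a non-target digit elicits a spurious press.
#' @param rt_mean_ms,rt_sd_ms Truncated-normal response-time parameters (ms),
#'   clipped to the 100-1000 ms response window.
#' @param subject_amp_sd SD of the Gaussian subject intercept added to
#'   `mmn_base_amp` (uV).
#' @param subject_hit_logit_sd SD of the Gaussian subject intercept on
#'   logit(hit_prob).
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(mmn_base_amp = -3,
                         mmn_peak_latency_ms = 148,
                         mmn_width_ms = 20,
                         latency_shift_ms = 16,
                         amp_factor = default_amp_factor(),
                         standard_erp = list(amp = 3, freq_hz = 6,
                                             tau_ms = 120, dur_ms = 350),
                         erp_topography = c(Fz = 1, Cz = 0.9, Pz = 0.7),
                         mmn_topography = c(Fz = 1, Cz = 0.85, Pz = 0.6),
                         noise_sd = 4,
                         alpha_amp = 2,
                         alpha_freq_hz = 10,
                         blink_rate = 12,
                         blink_amplitude = 150,
                         blink_propagation = c(Fz = 0.15, Cz = 0.10,
                                               Pz = 0.05),
                         hit_prob = default_hit_prob(),
                         fa_prob = default_fa_prob(),
                         rt_mean_ms = default_rt_mean(),
                         rt_sd_ms = 80,
                         subject_amp_sd = 0.5,
                         subject_hit_logit_sd = 0.4) {
  em <- structure(as.list(environment()), class = "effect_model")
  validate_effect_model(em)
  em
}

validate_effect_model <- function(em) {
  chk_cells <- function(x, name) {
    if (!is.array(x) || !identical(dim(x), c(2L, 2L, 2L, 3L))) {
      stop(name, " must be a 2x2x2x3 group x gum x drug x block array")
    }
  }
  chk_cells(em$amp_factor, "amp_factor")
  chk_cells(em$hit_prob, "hit_prob")
  chk_cells(em$fa_prob, "fa_prob")
  chk_cells(em$rt_mean_ms, "rt_mean_ms")
  if (any(em$amp_factor < 0 | em$amp_factor > 2)) {
    stop("amp_factor entries must lie in [0, 2]")
  }
  if (any(em$hit_prob < 0 | em$hit_prob > 1) ||
      any(em$fa_prob < 0 | em$fa_prob > 1)) {
    stop("hit_prob and fa_prob entries must lie in [0, 1]")
  }
  if (any(em$rt_mean_ms <= 100 | em$rt_mean_ms >= 1000)) {
    stop("rt_mean_ms entries must lie in (100, 1000)")
  }
  if (em$noise_sd < 0 || em$blink_rate < 0) {
    stop("noise_sd and blink_rate must be non-negative")
  }
  invisible(em)
}

#' Construct a session condition
#'
#' @param group `"L-HD"` or `"H-HD"` (between-subject hallucination/delusion
#'   proneness group).
#' @param gum `"PG"` (placebo) or `"NG"` (nicotine gum).
#' @param drug `"PI"` (placebo) or `"KI"` (ketamine infusion).
#' @return An object of class `condition`.
#' @export
condition <- function(group, gum, drug) {
  group <- match.arg(group, GROUP_LEVELS)
  gum <- match.arg(gum, GUM_LEVELS)
  drug <- match.arg(drug, DRUG_LEVELS)
  structure(list(group = group, gum = gum, drug = drug), class = "condition")
}

#' The four gum x drug crossover sessions
#'
#' @return A data.frame with columns `gum` and `drug` in the canonical order
#'   PG-PI, PG-KI, NG-PI, NG-KI.
#' @export
crossover_sessions <- function() {
  data.frame(gum = c("PG", "PG", "NG", "NG"),
             drug = c("PI", "KI", "PI", "KI"),
             stringsAsFactors = FALSE)
}

# Per-block vector of a cell-indexed parameter for one condition.
cell_values <- function(arr, cond) {
  unname(arr[cond$group, cond$gum, cond$drug, ])
}

#' @export
print.effect_model <- function(x, ...) {
  cat("<effect_model> MMN ", x$mmn_base_amp, " uV @ ", x$mmn_peak_latency_ms,
      " ms (KI shift +", x$latency_shift_ms, " ms), noise sd ", x$noise_sd,
      " uV, blink ", x$blink_rate, "/min\n", sep = "")
  invisible(x)
}
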