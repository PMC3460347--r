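---
title: "Simulating and analysing a dual-task MMN / RVIP crossover study"
author: "mmnrvip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing a dual-task MMN / RVIP crossover study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmnrvip)
```

## The design being modelled

`mmnrvip` implements, end to end, the computational analysis of a dual-task
psychopharmacology session: participants perform the rapid visual
information processing (RVIP) task — a continuous performance test of
sustained attention — while task-irrelevant auditory tones elicit the
mismatch negativity (MMN), an event-related potential indexing auditory
sensory memory. The study design is a 2 x 2 x 2 x 3 split-plot crossover:
a between-subject factor (lower vs higher psychometric proneness to
hallucinations and delusions, L-HD / H-HD, 12 subjects each), two
within-subject drug factors (placebo vs nicotine gum, PG / NG; placebo vs
ketamine infusion, PI / KI; all four combinations per subject in
counterbalanced order), and three successive 4-min time blocks per 12-min
session.

No recorded data ship with the package. Instead a synthetic-data module
generates continuous EEG and button-press behaviour with a known,
condition-dependent effect structure, so that every stage of the pipeline
can be verified by parameter recovery and every statistical routine by
independent oracles.

## Stimulus paradigm

The RVIP stream presents digits 1–9 at 110/min for 12 min (1320 digits),
with inter-onset intervals drawn uniformly on 445–645 ms (mean 545 ms).
Targets — the third of three consecutive odd digits — occur 10 times per
minute (120 per session), with at least five intervening digits between
consecutive targets. Because the definition is contextual, unplanned
targets must be suppressed: the generator forces the digit immediately
preceding each planted odd triad to be even, and any free draw following
two odd digits is taken from the even digits. The planted flag set is
therefore provably identical to an exhaustive scan, which the tests verify
with a brute-force oracle.

The oddball stream presents 1200 tones at the same 445–645 ms asynchrony;
10% are pitch deviants, stratified as exactly 40 per 400-stimulus block
with at least one standard between consecutive deviants so every deviant
occurs in a standard context. Tone frequencies (1000 Hz standard, 1100 Hz
deviant) are carried as labels only; no audio is synthesized.

The two modalities are interleaved without temporal overlap: tone onsets
are re-jittered sequentially within the allowed asynchrony range until the
50 ms tone presentation clears every 50 ms digit presentation. Because
digit presentations are at least 445 ms apart, a 200 ms jitter window
always retains at least 100 ms of feasible room, so the construction cannot
deadlock; an exhaustive pairwise audit in the test suite confirms zero
overlaps.

Session blocks are defined by event count (each block holds exactly one
third of the events); with the 545 ms mean asynchrony a block spans very
close to its nominal 4 min.

## The synthetic EEG model

Each session yields a 4-channel (Fz, Cz, Pz, VEOG), 250 Hz continuous
recording in microvolts, built from four additive parts:

* **Evoked template.** Every tone adds a damped sinusoid (3 µV, 6 Hz,
  120 ms decay, 350 ms duration) after a 20 ms cortical onset delay,
  scaled by a fixed topography (Fz 1.0, Cz 0.9, Pz 0.7). The onset delay
  also guarantees that a tone at the minimum 445 ms asynchrony contributes
  nothing inside the previous epoch's 448 ms tail, which makes the
  noiseless superposition tests exact.
* **MMN component.** Deviant tones additionally add a Gaussian negativity
  with amplitude `mmn_base_amp * amp_factor[cell]` (default −3 µV at Fz,
  topography Fz 1.0 / Cz 0.85 / Pz 0.6), peak latency 148 ms (on the 4 ms
  sample grid) shifted +16 ms under ketamine, and width (Gaussian SD)
  20 ms.
* **Background noise.** Pink (1/f amplitude spectrum) noise at 4 µV SD per
  channel plus a 10 Hz alpha sinusoid (2 µV, random phase per channel),
  synthesized in the frequency domain.
* **Blinks.** A stereotyped 400 ms biphasic transient (150 µV peak) occurs
  as a Poisson process at 12/min on VEOG and propagates to Fz/Cz/Pz with
  fixed coefficients 0.15/0.10/0.05, giving ocular correction a known
  ground truth.

Button presses are generated per digit: each target elicits a press with
the cell's hit probability at a latency drawn from a truncated normal
(cell mean, SD 80 ms) clipped to the 100–1000 ms response window; each
non-target elicits a spurious press with the cell's false-alarm
probability. A truncated normal was chosen over an ex-Gaussian as the
simplest distribution compatible with the scoring window; swapping the
distribution only requires replacing the internal `rtruncnorm()` draw.

Subjects receive Gaussian random intercepts on MMN amplitude (SD 0.5 µV)
and on logit hit probability (SD 0.4), chosen so that simulated
between-subject spread is of the same order as the standard errors typical
of a 12-subject group; this is a plausibility choice, not a reproduction
claim. Sessions are assumed independent given the subject intercept — no
carry-over structure is modelled. Session order is counterbalanced with a
balanced Latin square, and each subject x session draws its own seed from
the master seed, so any single recording is reproducible in isolation.

### Default effect calibration

The default `effect_model()` encodes the qualitative pattern the analysis
is designed to detect, with every condition-dependent parameter indexed by
the group x gum x drug x block cell:

* ketamine attenuates the MMN in the H-HD group under placebo gum
  (amplitude factors 0.85/0.75/0.55 over blocks 1–3) and mildly in L-HD
  (0.92); under nicotine gum the attenuation is absent (factors 1.0/0.95);
* ketamine shifts the MMN peak +16 ms in every cell;
* hit probability starts lower in H-HD (0.80 vs 0.88 in block 1) and
  declines after block 1 in every cell; nicotine raises it under placebo
  infusion (+0.05 L-HD, +0.10 H-HD) but not under ketamine;
* false alarms run at about 1% of non-target digits, rising late in the
  session under placebo gum and falling to 0.6% under nicotine; implied
  sensitivity is d' near 3–3.9, the usual range for this task;
* responses average 420 ms (L-HD) vs 455 ms (H-HD), sped 25 ms by
  nicotine, slowed 25 ms by ketamine in the faster group only.

## The ERP pipeline

Processing follows the classical averaging chain: ocular correction,
epoch segmentation, artifact rejection, baseline correction, separate
standard/deviant averaging per block, difference waves, and peak
measurement.

* **Ocular correction** subtracts `b x VEOG` from each EEG channel, with
  `b` the least-squares regression of the channel on VEOG over the whole
  recording. Whole-recording regression was chosen over trial-based
  variants because it has a recoverable ground truth in simulation (the
  blink propagation coefficients); the tests require the estimate to be
  within ±0.02 of truth on average.
* **Segmentation** cuts 500 ms epochs beginning 50 ms before each tone.
  At 250 Hz the pre-stimulus span is 12.5 samples; the count is floored to
  12 samples (48 ms) so that stimulus onset falls exactly on a sample, and
  the epoch is 125 samples. Events too close to a recording edge are
  dropped with a warning.
* **Artifact rejection** removes any epoch in which any sample on any EEG
  (non-EOG) channel exceeds 100 µV in absolute value, applied after
  ocular correction. The order chosen here — correct, segment, reject,
  baseline — is a documented package decision.
* **Baseline correction** subtracts the pre-stimulus mean per trial and
  channel; it is idempotent and leaves the baseline window exactly zero.
* **Averaging** produces one average per condition x block; deviant
  averages carry a sufficiency flag requiring at least 30 epochs.
* **Measurement** takes the deviant-minus-standard difference wave and
  reports the minimum voltage at Fz within 80–220 ms post-onset
  (amplitude) and its time (latency), on the 4 ms grid with no sub-sample
  interpolation; ties break to the earliest sample. A positive windowed
  minimum is reported as-is with a quality flag rather than clamped, and
  Cz/Pz averages are computed and stored but not measured, Fz being the
  site of maximal amplitude. No additional digital filter is applied by
  default: the simulated signals are already band-limited, mirroring a
  hardware-filtered acquisition chain.

## RVIP scoring

Presses are scanned in time order; a press is a hit iff it is the first
press inside the 100–1000 ms window (closed at both ends) of a
not-yet-credited target, crediting the earlier target when windows
overlap; every other press is a false alarm. Percent false alarms uses
non-target digits as the denominator — the standard continuous-performance
convention, and the bounded rate that d' requires. Sensitivity is
`d' = z(H) − z(F)` with the standard extreme-rate adjustment (0 becomes
`1/(2N)`, 1 becomes `1 − 1/(2N)`), so a perfect block yields a finite
score. Metrics aggregate per block, each press counting toward the block
of its eliciting stimulus.

## Statistics

`split_plot_anova()` fits the 2 (group, between) x 2 x 2 x 3 (within)
design from cell and marginal means by inclusion–exclusion, with the
classical error strata: subjects-within-groups for the group effect, and
each within-effect's interaction with subjects-within-groups for that
effect and its group interaction. The implementation requires balanced
complete data (equal group sizes, one observation per subject per cell)
and refuses anything else — the design is a complete crossover and
imputation is out of scope. The test suite proves equality of every SS,
df, and F with an independent `aov()` projection fit on 100 random
balanced instances at 1e-8 relative tolerance.

Greenhouse–Geisser epsilon is estimated per within-factor combination from
the pooled within-group covariance of orthonormal contrast scores
(`epsilon = tr(S)^2 / (d tr(S^2))`); two-level factors have epsilon
identically 1, so the correction only affects effects involving the
three-level block factor. No sphericity pre-test gates the correction:
raw and corrected p values are always reported side by side, leaving the
choice explicit rather than automatic. Follow-ups are Bonferroni-adjusted
pairwise comparisons (`p_adj = min(1, m p_raw)`) against a caller-supplied
error term, with the family size `m` an explicit argument because the
comparison families behind any particular figure are a reporting choice,
not a property of the data. Change scores subtract each subject's
double-placebo (PG–PI) value, and `mmn_dprime_correlation()` provides the
Pearson r / t-based p used to relate MMN amplitude to d'.

## Numerical and calibration choices

* **Recovery calibration.** The default noise level and MMN width were
  fixed by a Monte-Carlo recovery run before the acceptance suite was
  written: at 4 µV pink noise, 2 µV alpha, and a 20 ms component width,
  single-session block estimates recover the injected amplitude with
  ≈0.5 µV and the latency with ≈5 ms mean absolute error over 20 seeds —
  inside the ±0.75 µV / ±8 ms tolerances the acceptance suite asserts,
  with margin for seed-to-seed variation. A wider (28 ms) component makes
  the peak too flat for sample-grid latency picking at this noise level.
* **Type-I calibration.** With no effects and a deliberately non-spherical
  block covariance, the GG-corrected block test rejects at ≈5% (the suite
  runs 2000 null ANOVAs and requires 3–7%).
* **Problem sizes.** The acceptance suite uses 20 seeds for recovery, 2000
  null simulations for calibration, and 50 full-study replicates (24
  subjects x 4 sessions each) for qualitative pattern recovery; these
  sizes give stable Monte-Carlo estimates while keeping a full run in the
  tens of minutes on one core.
* **Degenerate inputs.** Constant dependent variables report undefined F
  with zero SS rather than failing; zero-variance EOG, empty
  condition-blocks, incomplete crossovers, and infeasible packing
  configurations raise explicit errors.
* **Ties and rounding.** Peak latency ties break to the earliest sample;
  stimulus onsets are rounded to the nearest sample when the evoked
  response is injected; events TSVs carry an explicit 0-based `sample`
  column to avoid off-by-one ambiguity between readers.

## What passing tests do and do not show

The generator emulates the features the pipeline is sensitive to —
jittered dual-modality schedules, realistic evoked and background spectra,
blinks with known propagation, condition-dependent amplitudes, latencies,
and response rates, subject heterogeneity. It does not emulate
non-stationary noise, electrode drift or pops, muscle or movement
artifacts, ex-Gaussian response tails, learning or fatigue beyond the
built-in block effects, session carry-over, or true individual ERP
morphology. Parameter recovery here therefore demonstrates that the
pipeline is correct and well calibrated for data of this class, not that
it would be unbiased on any particular laboratory recording. Real F values
and group means from human data are likewise outside what the synthetic
study can or should reproduce; the statistics module is validated by
oracle equivalence and error calibration instead.

## A worked example

```{r, eval = FALSE}
library(mmnrvip)

# one subject-session: schedule, EEG, behaviour
sch <- generate_session_schedule(seed = 1)
em  <- effect_model()
rec <- simulate_eeg(sch, em, condition("H-HD", "PG", "KI"), seed = 2)
measure_recording(rec)

# a full 24-subject study reduced to measurement tables
ms  <- simulate_measured_study(n_per_group = 12, seed = 101)
fit <- split_plot_anova(ms$mmn, dv = "amplitude_uv")
fit$table[fit$table$effect == "group:gum:drug", ]

# follow-up: H-HD cell means under the four sessions, Bonferroni-adjusted
hh <- ms$mmn[ms$mmn$group == "H-HD", ]
cells <- aggregate(amplitude_uv ~ gum + drug, hh, mean)
cells <- data.frame(label = paste(cells$gum, cells$drug, sep = "-"),
                    mean = cells$amplitude_uv, n = 36)
err <- fit$table[fit$table$effect == "group:gum:drug", ]
bonferroni_pairwise(cells, err$ms_error, err$df2, m = 4)
```
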