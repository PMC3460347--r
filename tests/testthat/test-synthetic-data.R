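test_that("effect model validates parameter ranges", {
  expect_s3_class(effect_model(), "effect_model")
  bad_amp <- default_amp_factor()
  bad_amp[1] <- 2.5
  expect_error(effect_model(amp_factor = bad_amp), "\\[0, 2\\]")
  bad_hit <- default_hit_prob()
  bad_hit[1] <- 1.2
  expect_error(effect_model(hit_prob = bad_hit), "\\[0, 1\\]")
  bad_rt <- default_rt_mean()
  bad_rt[1] <- 90
  expect_error(effect_model(rt_mean_ms = bad_rt), "\\(100, 1000\\)")
  expect_error(effect_model(amp_factor = matrix(1, 2, 2)), "2x2x2x3")
})

test_that("default calibration encodes the qualitative drug/group pattern", {
  em <- effect_model()
  a <- em$amp_factor
  # ketamine attenuates H-HD amplitude under placebo gum, worst in block 3
  expect_true(all(a["H-HD", "PG", "KI", ] < 1))
  expect_true(a["H-HD", "PG", "KI", "3"] == min(a["H-HD", "PG", "KI", ]))
  # nicotine restores the amplitude under ketamine
  expect_true(all(a["H-HD", "NG", "KI", ] > a["H-HD", "PG", "KI", ]))
  # ketamine delays the peak
  expect_gt(em$latency_shift_ms, 0)
  h <- em$hit_prob
  # nicotine raises hit rate under placebo infusion, not under ketamine
  expect_true(all(h[, "NG", "PI", ] > h[, "PG", "PI", ]))
  expect_true(all(h[, "NG", "KI", ] <= h[, "PG", "KI", ] + 1e-12))
  # vigilance decrement after block 1; H-HD below L-HD; RT slower in H-HD
  expect_true(all(h[, , , "2"] < h[, , , "1"]))
  expect_true(all(h["H-HD", , , ] < h["L-HD", , , ]))
  expect_true(all(em$fa_prob[, "NG", , ] < em$fa_prob[, "PG", , ]))
  expect_true(all(em$rt_mean_ms["H-HD", "PG", "PI", ] >
                    em$rt_mean_ms["L-HD", "PG", "PI", ]))
})

test_that("noiseless simulation superposes template and MMN exactly", {
  sch <- small_schedule(1)
  em <- quiet_effects()
  rec <- simulate_eeg(sch, em, condition("L-HD", "PG", "PI"), seed = 1)
  mm <- measure_recording(rec, ocular = FALSE)
  expect_equal(mm$amplitude_uv, rep(-3, 3), tolerance = 1e-6)
  expect_equal(mm$latency_ms, rep(148, 3))
  # the full difference wave equals the injected Gaussian pointwise
  ep <- baseline_correct(segment_epochs(rec))
  avgs <- average_condition_blocks(ep)
  diffw <- compute_mmn(avgs[["deviant.1"]], avgs[["standard.1"]])
  t_post <- (seq_len(125) - 13) * 4
  expected <- -3 * exp(-((t_post - 148) / 20)^2 / 2)
  expected[t_post < 0] <- 0
  expect_lt(max(abs(diffw$waveform["Fz", ] - expected)), 1e-6)
  # topography scaling at Cz
  expect_lt(max(abs(diffw$waveform["Cz", ] - 0.85 * expected)), 1e-6)
})

test_that("a zero amplitude factor yields a null difference wave", {
  sch <- small_schedule(1)
  em <- quiet_effects(amp_factor = default_amp_factor_zero())
  rec <- simulate_eeg(sch, em, condition("L-HD", "PG", "PI"), seed = 1)
  ep <- baseline_correct(segment_epochs(rec))
  avgs <- average_condition_blocks(ep)
  for (b in 1:3) {
    diffw <- compute_mmn(avgs[[paste0("deviant.", b)]],
                         avgs[[paste0("standard.", b)]])
    expect_lt(max(abs(diffw$waveform)), 1e-9)
  }
})

test_that("pipeline output scales linearly with the injected amplitude", {
  sch <- small_schedule(2)
  for (scale in c(0.5, 2)) {
    em <- quiet_effects(mmn_base_amp = -3 * scale)
    rec <- simulate_eeg(sch, em, condition("L-HD", "PG", "PI"), seed = 1)
    mm <- measure_recording(rec, ocular = FALSE)
    expect_equal(mm$amplitude_uv, rep(-3 * scale, 3), tolerance = 1e-6)
  }
})

test_that("latency measurements track the injected peak shift", {
  sch <- small_schedule(2)
  em <- quiet_effects()
  rec_ki <- simulate_eeg(sch, em, condition("L-HD", "NG", "KI"), seed = 1)
  mm <- measure_recording(rec_ki, ocular = FALSE)
  expect_equal(mm$latency_ms, rep(148 + 16, 3))
  em2 <- quiet_effects(mmn_peak_latency_ms = 148 + 24)
  rec2 <- simulate_eeg(sch, em2, condition("L-HD", "PG", "PI"), seed = 1)
  expect_equal(measure_recording(rec2, ocular = FALSE)$latency_ms,
               rep(148 + 24, 3))
})

test_that("identical configuration and seed give bit-identical output", {
  sch <- small_schedule(3)
  em <- effect_model()
  cond <- condition("H-HD", "NG", "KI")
  r1 <- simulate_eeg(sch, em, cond, seed = 99)
  r2 <- simulate_eeg(sch, em, cond, seed = 99)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)
  p1 <- simulate_behavior(sch$digit_stream, em, cond, seed = 99)
  p2 <- simulate_behavior(sch$digit_stream, em, cond, seed = 99)
  expect_identical(p1$press_times, p2$press_times)
})

test_that("degenerate response distributions behave exactly", {
  sch <- small_schedule(1)
  hp1 <- default_hit_prob(); hp1[] <- 1
  fa0 <- default_fa_prob(); fa0[] <- 0
  rt400 <- default_rt_mean(); rt400[] <- 400
  em <- effect_model(hit_prob = hp1, fa_prob = fa0, rt_mean_ms = rt400,
                     rt_sd_ms = 0)
  pl <- simulate_behavior(sch$digit_stream, em, condition("L-HD", "PG", "PI"),
                          seed = 1)
  tgt <- sch$digit_stream$onsets[sch$digit_stream$target_flags]
  expect_equal(sort(pl$press_times), sort(tgt + 400))

  hp0 <- default_hit_prob(); hp0[] <- 0
  em0 <- effect_model(hit_prob = hp0, fa_prob = fa0)
  pl0 <- simulate_behavior(sch$digit_stream, em0,
                           condition("L-HD", "PG", "PI"), seed = 1)
  expect_length(pl0$press_times, 0)
})

test_that("simulated hit fraction sits inside the exact binomial band", {
  sch <- small_schedule(4)
  hp <- default_hit_prob(); hp[] <- 0.8
  fa0 <- default_fa_prob(); fa0[] <- 0
  em <- effect_model(hit_prob = hp, fa_prob = fa0, subject_hit_logit_sd = 0)
  n_targets <- sum(sch$digit_stream$target_flags)
  total_hits <- 0
  n_seeds <- 200
  for (s in 1:n_seeds) {
    pl <- simulate_behavior(sch$digit_stream, em,
                            condition("L-HD", "PG", "PI"), seed = s)
    total_hits <- total_hits + length(pl$press_times)
  }
  n_trials <- n_targets * n_seeds
  band <- qbinom(c(0.005, 0.995), n_trials, 0.8)
  expect_gte(total_hits, band[1])
  expect_lte(total_hits, band[2])
})

test_that("study simulation builds the counterbalanced crossover", {
  sim <- simulate_study(n_per_group = 2, seed = 5, duration_min = 3,
                        handler = function(rec) {
                          list(subject = rec$subject, cond = rec$cond,
                               n_events = nrow(rec$recording$events))
                        })
  expect_equal(nrow(sim$manifest), 16) # 4 subjects x 4 sessions
  expect_length(sim$records, 16)
  expect_true(all(vapply(sim$records, `[[`, 0, "n_events") == 300))
  # each subject sees all four sessions once
  by_subj <- table(sim$manifest$subject, paste(sim$manifest$gum,
                                               sim$manifest$drug))
  expect_true(all(by_subj == 1))
  # Latin-square counterbalance: over 4 subjects every session occupies
  # every ordinal position exactly once
  pos <- table(sim$manifest$session, sim$manifest$order_position)
  expect_true(all(pos == 1))
  expect_error(simulate_study(n_per_group = 1), ">= 2")
})

test_that("press logs are strictly increasing and within the session", {
  sch <- small_schedule(5)
  em <- effect_model()
  for (s in 1:5) {
    pl <- simulate_behavior(sch$digit_stream, em,
                            condition("H-HD", "NG", "KI"), seed = s)
    expect_false(is.unsorted(pl$press_times, strictly = TRUE))
    expect_true(all(pl$press_times > 0))
    expect_true(all(pl$press_times <=
                      max(sch$digit_stream$onsets) + 1000))
  }
})
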