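make_recording <- function(data, channels = c("Fz", "Cz", "Pz", "VEOG"),
                           events = data.frame(sample = integer(0),
                                               code = character(0),
                                               block = integer(0))) {
  structure(list(data = data, channel_labels = channels,
                 sampling_rate = 250, events = events),
            class = "continuous_recording")
}

test_that("ocular regression recovers exact and null propagation", {
  set.seed(1)
  eog <- rnorm(2000, 0, 50)
  dat <- rbind(Fz = 0.1 * eog, Cz = 0.2 * eog, Pz = 0 * eog, VEOG = eog)
  rec <- ocular_correct(make_recording(dat))
  expect_equal(unname(rec$propagation), c(0.1, 0.2, 0), tolerance = 1e-12)
  expect_lt(max(abs(rec$data[c("Fz", "Cz", "Pz"), ])), 1e-9)

  # orthogonal EOG leaves the data unchanged
  t <- seq_len(2000)
  eog2 <- sin(2 * pi * t / 100)
  sig <- cos(2 * pi * t / 100)
  dat2 <- rbind(Fz = sig, Cz = sig, Pz = sig, VEOG = eog2)
  rec2 <- ocular_correct(make_recording(dat2))
  expect_lt(max(abs(rec2$propagation)), 1e-9)
  expect_equal(rec2$data["Fz", ], dat2["Fz", ], tolerance = 1e-9)

  expect_error(ocular_correct(make_recording(rbind(Fz = rnorm(100),
                                                   VEOG = rep(1, 100)),
                                             c("Fz", "VEOG"))),
               "zero variance")
})

test_that("blink propagation is recovered from simulated recordings", {
  em <- effect_model()
  cond <- condition("L-HD", "PG", "PI")
  errs <- c()
  for (s in 1:20) {
    set.seed(s)
    sch <- small_schedule(s %% 5 + 1)
    rec <- simulate_eeg(sch, em, cond)
    corrected <- ocular_correct(rec)
    errs <- c(errs, abs(corrected$propagation["Fz"] - 0.15))
  }
  expect_lt(mean(errs), 0.02)
  expect_lt(max(errs), 0.04)
})

test_that("segmentation slices the continuous data at exact offsets", {
  set.seed(2)
  n <- 5000
  dat <- matrix(rnorm(4 * n), 4, n,
                dimnames = list(c("Fz", "Cz", "Pz", "VEOG"), NULL))
  events <- data.frame(sample = c(100, 500, 900), code = "standard",
                       block = 1L)
  rec <- make_recording(dat, events = events)
  ep <- segment_epochs(rec, events)
  expect_equal(dim(ep$epochs), c(3, 3, 125))
  expect_equal(ep$pre_samples, 12)
  # direct indexing oracle
  for (i in 1:3) {
    sl <- dat["Cz", (events$sample[i] - 12):(events$sample[i] + 112)]
    expect_equal(unname(ep$epochs[i, "Cz", ]), unname(sl))
  }
  # edge events are dropped with a warning
  events2 <- rbind(events, data.frame(sample = 3, code = "standard",
                                      block = 1L))
  expect_warning(ep2 <- segment_epochs(rec, events2), "dropped")
  expect_equal(dim(ep2$epochs)[1], 3)
})

test_that("artifact rejection matches the exhaustive scan and is monotone", {
  set.seed(3)
  ep <- segment_epochs(
    make_recording(matrix(rnorm(4 * 20000, 0, 40), 4, 20000,
                          dimnames = list(c("Fz", "Cz", "Pz", "VEOG"), NULL)),
                   events = data.frame(sample = seq(200, 19000, by = 150),
                                       code = "standard", block = 1L)))
  rej <- reject_artifacts(ep, 100)
  brute <- vapply(seq_len(dim(ep$epochs)[1]), function(i) {
    !any(abs(ep$epochs[i, , ]) > 100)
  }, logical(1))
  expect_identical(rej$kept_flags, brute)
  # threshold boundary: exactly 100 is kept, 100 + eps is not
  dat <- array(0, c(2, 3, 125))
  dat[1, 2, 50] <- 101
  dat[2, 1, 10] <- 100
  ep2 <- structure(list(epochs = dat, condition_labels = c("deviant", "standard"),
                        block_labels = c(1L, 1L), kept_flags = c(TRUE, TRUE),
                        pre_samples = 12, sampling_rate = 250),
                   class = "epoch_set")
  rej2 <- reject_artifacts(ep2, 100)
  expect_identical(rej2$kept_flags, c(FALSE, TRUE))
  # monotonicity: lowering the threshold never keeps more trials
  kept <- vapply(c(150, 100, 60, 30),
                 function(th) sum(reject_artifacts(ep, th)$kept_flags),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("baseline correction zeroes the pre-stimulus mean and is idempotent", {
  dat <- array(7, c(2, 3, 125))
  ep <- structure(list(epochs = dat, condition_labels = c("standard", "deviant"),
                       block_labels = c(1L, 1L), kept_flags = c(TRUE, TRUE),
                       pre_samples = 12, sampling_rate = 250),
                  class = "epoch_set")
  bc <- baseline_correct(ep)
  expect_true(all(bc$epochs == 0)) # constant epoch becomes null
  set.seed(4)
  ep$epochs <- array(rnorm(2 * 3 * 125), c(2, 3, 125))
  bc <- baseline_correct(ep)
  expect_lt(max(abs(rowMeans(bc$epochs[, , 1:12], dims = 2))), 1e-9)
  bc2 <- baseline_correct(bc)
  expect_equal(bc2$epochs, bc$epochs, tolerance = 1e-12)
})

test_that("condition-block averages equal the arithmetic mean of kept trials", {
  set.seed(5)
  nt <- 24
  dat <- array(rnorm(nt * 3 * 125), c(nt, 3, 125),
               dimnames = list(NULL, c("Fz", "Cz", "Pz"), NULL))
  labels <- rep(c("standard", "deviant"), each = nt / 2)
  blocks <- rep(1:3, length.out = nt)
  kept <- rep(c(TRUE, TRUE, TRUE, FALSE), length.out = nt)
  ep <- structure(list(epochs = dat, condition_labels = labels,
                       block_labels = blocks, kept_flags = kept,
                       pre_samples = 12, sampling_rate = 250),
                  class = "epoch_set")
  avgs <- average_condition_blocks(ep, min_deviants = 3)
  sel <- kept & labels == "deviant" & blocks == 2
  manual <- apply(dat[sel, , , drop = FALSE], c(2, 3), mean)
  expect_equal(avgs[["deviant.2"]]$waveform, manual, tolerance = 1e-12)
  expect_equal(avgs[["deviant.2"]]$n_trials, sum(sel))
  # identical epochs average to any single epoch
  dat2 <- dat
  for (i in seq_len(nt)) dat2[i, , ] <- dat[1, , ]
  ep$epochs <- dat2
  avg1 <- average_condition_blocks(ep, min_deviants = 1)[["standard.1"]]
  expect_equal(avg1$waveform, dat[1, , ], tolerance = 1e-12)
  # an emptied cell is a hard error naming the cell
  ep$kept_flags <- kept & !(labels == "deviant" & blocks == 3)
  expect_error(average_condition_blocks(ep), "deviant in block 3")
})

test_that("difference waves are exact pointwise subtractions", {
  set.seed(6)
  wf1 <- matrix(rnorm(3 * 125), 3, 125,
                dimnames = list(c("Fz", "Cz", "Pz"), NULL))
  g <- matrix(rep(-2 * exp(-((1:125 - 50) / 10)^2 / 2), each = 3), 3, 125)
  mk <- function(wf, cond) {
    structure(list(waveform = wf, n_trials = 40, condition = cond, block = 1,
                   pre_samples = 12, sampling_rate = 250, sufficient = TRUE),
              class = "erp_average")
  }
  d0 <- compute_mmn(mk(wf1, "deviant"), mk(wf1, "standard"))
  expect_true(all(d0$waveform == 0))
  dg <- compute_mmn(mk(wf1 + g, "deviant"), mk(wf1, "standard"))
  expect_equal(dg$waveform, unname(g), ignore_attr = TRUE, tolerance = 1e-12)
  bad <- mk(wf1[, 1:100], "standard")
  expect_error(compute_mmn(mk(wf1, "deviant"), bad), "shape")
})

test_that("peak measurement equals the exhaustive argmin with earliest ties", {
  mk_wave <- function(wf) {
    structure(list(waveform = wf, block = 1, n_deviants = 40,
                   n_standards = 360, pre_samples = 12, sampling_rate = 250,
                   sufficient = TRUE), class = "mmn_wave")
  }
  # constructed Gaussian minimum
  t_post <- (seq_len(125) - 13) * 4
  g <- -3 * exp(-((t_post - 148) / 20)^2 / 2)
  wf <- matrix(rep(g, each = 3), 3, 125,
               dimnames = list(c("Fz", "Cz", "Pz"), NULL))
  m <- measure_mmn(mk_wave(wf))
  expect_equal(m$amplitude_uv, -3)
  expect_equal(m$latency_ms, 148)
  # identically-zero wave reports 0 uV at the window start
  m0 <- measure_mmn(mk_wave(matrix(0, 3, 125,
                                   dimnames = list(c("Fz", "Cz", "Pz"), NULL))))
  expect_equal(m0$amplitude_uv, 0)
  expect_equal(m0$latency_ms, 80)
  expect_equal(m0$quality, "ok")
  # random waves match a brute-force scan of the window
  set.seed(7)
  for (i in 1:10) {
    wf <- matrix(rnorm(3 * 125), 3, 125,
                 dimnames = list(c("Fz", "Cz", "Pz"), NULL))
    m <- measure_mmn(mk_wave(wf))
    win <- which(t_post >= 80 & t_post <= 220)
    vals <- wf["Fz", win]
    expect_equal(m$amplitude_uv, min(vals))
    expect_equal(m$latency_ms, t_post[win[which.min(vals)]])
  }
  # positive-only difference waves are flagged, not clamped
  mp <- measure_mmn(mk_wave(matrix(2, 3, 125,
                                   dimnames = list(c("Fz", "Cz", "Pz"), NULL))))
  expect_equal(mp$amplitude_uv, 2)
  expect_equal(mp$quality, "positive")
})
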