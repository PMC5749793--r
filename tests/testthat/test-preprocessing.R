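make_rec <- function(m, rate = 250, channels = NULL) {
  channels <- channels %||% paste0("ch", seq_len(nrow(m)))
  psg_recording(m, rate, channels)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("resampling preserves spectral content and rejects upsampling", {
  tt <- (0:(500 * 8 - 1)) / 500
  rec <- make_rec(rbind(sin(2 * pi * 10 * tt), cos(2 * pi * 3 * tt)), rate = 500)
  out <- psg_resample(rec, 250)
  expect_equal(out$rate, 250)
  expect_equal(ncol(out$samples), 250 * 8)
  # spectral peak of channel 1 stays at 10 Hz (discrete Fourier oracle)
  sp <- Mod(fft(out$samples[1, ]))[1:(250 * 4)]
  freqs <- (seq_along(sp) - 1) / 8
  expect_equal(freqs[which.max(sp)], 10)
  # identity when target equals source
  expect_identical(psg_resample(rec, 500)$samples, rec$samples)
  expect_error(psg_resample(rec, 1000), "upsampling")
  expect_error(psg_resample(rec, 333), "integer")
})

test_that("band-pass is zero-phase, rejects DC and attenuates 60 Hz by 40 dB", {
  tt <- (0:4999) / 250
  dc <- make_rec(matrix(5, 1, 5000))
  out <- psg_bandpass(dc)
  expect_lt(max(abs(out$samples)), 0.05)        # > 99% attenuation
  tone <- sin(2 * pi * 10 * tt)
  y <- psg_bandpass(make_rec(rbind(tone)))$samples[1, ]
  cc <- ccf(tone, y, lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)    # zero-phase: peak at lag 0
  s60 <- sin(2 * pi * 60 * tt)
  y60 <- psg_bandpass(make_rec(rbind(s60)))$samples[1, ]
  atten_db <- 20 * log10(sd(y60[500:4500]) / sd(s60[500:4500]))
  expect_lte(atten_db, -40)
  expect_error(psg_bandpass(make_rec(rbind(tone)), high = 125), "Nyquist")
  # channel count, order and rate preserved
  rec3 <- make_rec(matrix(rnorm(3 * 2500), 3), channels = c("a", "b", "c"))
  f3 <- psg_bandpass(rec3)
  expect_identical(f3$channels, c("a", "b", "c"))
  expect_identical(f3$rate, rec3$rate)
})

test_that("average re-referencing zeroes the EEG mean and is idempotent", {
  set.seed(1)
  m <- matrix(rnorm(4 * 1000), 4)
  rec <- make_rec(m, channels = c("C3", "C4", "EMG", "EOG"))
  out <- psg_rereference(rec)
  expect_lt(max(abs(colMeans(out$samples[1:2, ]))), 1e-9)
  expect_identical(out$samples[3:4, ], rec$samples[3:4, ])  # EMG/EOG untouched
  # adding a constant offset to all EEG channels changes nothing
  rec_off <- rec; rec_off$samples[1:2, ] <- rec_off$samples[1:2, ] + 42
  expect_equal(psg_rereference(rec_off)$samples, out$samples, tolerance = 1e-9)
  # x and -x are already average-referenced
  sym <- make_rec(rbind(m[1, ], -m[1, ]), channels = c("C3", "C4"))
  expect_equal(psg_rereference(sym)$samples, sym$samples, tolerance = 1e-12)
  # idempotent
  expect_equal(psg_rereference(out)$samples, out$samples, tolerance = 1e-12)
  expect_error(psg_rereference(make_rec(m[1, , drop = FALSE], channels = "C3")),
               "two EEG channels")
})

test_that("ocular regression recovers a planted coefficient and leaves clean data alone", {
  set.seed(2)
  n <- 20000
  eog <- as.numeric(stats::filter(rnorm(n), 0.95, method = "recursive"))
  clean <- matrix(rnorm(2 * n), 2)
  m <- rbind(clean[1, ] + 0.3 * eog, clean[2, ], eog)
  rec <- make_rec(m, channels = c("F3", "Pz", "EOG"))
  out <- psg_ocular_correct(rec)
  cf <- attr(out, "eog_coefficients")
  expect_equal(unname(cf["F3", "EOG"]), 0.3, tolerance = 0.01)
  expect_lt(abs(cor(out$samples["F3", ], eog)), 0.02)
  expect_identical(out$samples["EOG", ], rec$samples["EOG", ])  # EOG retained raw
  # zero EOG: EEG unchanged
  rec0 <- make_rec(rbind(clean, 0), channels = c("F3", "Pz", "EOG"))
  out0 <- psg_ocular_correct(rec0)
  expect_equal(out0$samples[1:2, ], clean, tolerance = 1e-9, ignore_attr = TRUE)
  # orthogonal EOG: coefficient ~ 0
  expect_lt(abs(cf["Pz", "EOG"]), 0.01)
  expect_error(psg_ocular_correct(rec, eog_channels = "VEOG"), "missing EOG")
})

test_that("canonical channel selection enforces the 14-channel order", {
  set.seed(3)
  labels <- c("Fp1", sample(CANONICAL_CHANNELS), "Fp2")  # shuffled superset
  rec <- make_rec(matrix(rnorm(16 * 100), 16), channels = labels)
  out <- select_canonical_channels(rec)
  expect_identical(out$channels, CANONICAL_CHANNELS)
  for (ch in CANONICAL_CHANNELS)
    expect_identical(out$samples[ch, ], rec$samples[ch, ])
  # identity + idempotence when already canonical
  expect_identical(select_canonical_channels(out)$samples, out$samples)
  # case-insensitive matching
  rec_lc <- make_rec(rec$samples, channels = tolower(labels))
  expect_identical(dim(select_canonical_channels(rec_lc)$samples), c(14L, 100L))
  # missing channel named in the error
  rec_miss <- make_rec(rec$samples[labels != "T3", ], channels = labels[labels != "T3"])
  expect_error(select_canonical_channels(rec_miss), "missing channel T3")
})

test_that("epoch segmentation drops trailing partials and keeps half-open ranges", {
  rec <- make_rec(matrix(0, 1, 250 * 60))
  g <- segment_epochs(rec)
  expect_equal(nrow(g), 2)
  expect_equal(g$end_sample - g$start_sample + 1L, c(7500L, 7500L))
  expect_equal(g$epoch, c(0L, 1L))
  expect_equal(g$start_sample[2], g$end_sample[1] + 1L)  # contiguous, non-overlapping
  g65 <- segment_epochs(make_rec(matrix(0, 1, 250 * 65)))
  expect_equal(nrow(g65), 2)                              # 5 s discarded
  expect_error(segment_epochs(make_rec(matrix(0, 1, 250 * 10))), "shorter")
})

test_that("day/night tagging uses the epoch midpoint and flags uncovered epochs", {
  rec <- make_rec(matrix(0, 1, 250 * 150))  # 5 epochs
  g <- segment_epochs(rec)
  all_day <- data.frame(start_s = 0, end_s = 150, tag = "day")
  expect_equal(split_day_night(g, all_day), rep("day", 5))
  # boundary at 100 s splits epoch 3 (90-120 s, midpoint 105): tagged night
  iv <- data.frame(start_s = c(0, 100), end_s = c(100, 150),
                   tag = c("day", "night"))
  expect_equal(split_day_night(g, iv), c("day", "day", "day", "night", "night"))
  short <- data.frame(start_s = 0, end_s = 70, tag = "day")
  expect_warning(tags <- split_day_night(g, short), "not covered")
  expect_equal(sum(tags == "day") + sum(tags == "untagged"), 5)
})

test_that("eye-state alignment replicates 5 min labels onto ten 30 s epochs", {
  rec <- make_rec(matrix(0, 1, 250 * 3600))  # 1 h = 120 epochs
  g <- segment_epochs(rec)
  ann <- rep(c("O", "C"), 6)
  al <- align_eye_states(g, ann)
  expect_equal(nrow(al), 120)
  expect_equal(al$eye_state, rep(rep(c("O", "C"), 6), each = 10))
  expect_false(any(al$excluded))
  # a single C annotation: ten C epochs, rest padded NA and excluded
  al1 <- align_eye_states(g, "C")
  expect_equal(sum(al1$eye_state == "C", na.rm = TRUE), 10)
  expect_equal(sum(al1$excluded), 110)
  alna <- align_eye_states(g, c("O", NA, "OC"))
  expect_equal(sum(alna$excluded), 10 + 90)
  expect_error(align_eye_states(g, c("O", "X")), "labels")
})

test_that("the preprocessing chain composes on a synthetic montage", {
  spec <- subject_spec("healthy", duration_s = 4 * 30, sampling_rate = 500, seed = 2)
  rec <- synthesize_recording(rep(c("W", "N2"), 2), spec = spec)
  out <- preprocess_recording(rec)
  expect_identical(out$channels, CANONICAL_CHANNELS)
  expect_equal(out$rate, 250)
  expect_equal(ncol(out$samples), 4 * 30 * 250)
  expect_true(all(is.finite(out$samples)))
})
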