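test_that("hypnogram simulation is deterministic and respects the chain", {
  spec <- subject_spec("healthy", duration_s = 600, seed = 11)
  expect_identical(simulate_hypnogram(spec), simulate_hypnogram(spec))
  expect_equal(simulate_hypnogram(spec)[1], "W")
  # absorbing wake chain
  tm <- diag(5); dimnames(tm) <- list(STAGE_LEVELS, STAGE_LEVELS)
  abs_spec <- subject_spec("healthy", duration_s = 600, transition_matrix = tm, seed = 1)
  expect_identical(simulate_hypnogram(abs_spec), rep("W", 20))
  bad <- default_transition_matrix(); bad[1, 1] <- 2
  expect_error(subject_spec("healthy", transition_matrix = bad), "invalid spec")
})

test_that("empirical stage fractions match the stationary distribution", {
  tm <- default_transition_matrix()
  # oracle: left eigenvector of the transition matrix
  ev <- eigen(t(tm))
  pi_stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_stat <- pi_stat / sum(pi_stat)
  names(pi_stat) <- STAGE_LEVELS
  # pool several 8 h chains: stage bouts are sticky, so a single night's
  # fractions fluctuate; pooling tests the same long-run property with power
  stages <- unlist(lapply(1:20, function(i)
    simulate_hypnogram(subject_spec("healthy", duration_s = 8 * 3600, seed = i))))
  emp <- table(factor(stages, STAGE_LEVELS)) / length(stages)
  expect_true(all(abs(as.numeric(emp) - pi_stat) < 0.05))
})

test_that("recording synthesis is deterministic and validates its inputs", {
  spec <- subject_spec("healthy", duration_s = 90, sampling_rate = 250, seed = 5)
  r1 <- synthesize_recording(c("W", "N2", "N3"), spec = spec)
  r2 <- synthesize_recording(c("W", "N2", "N3"), spec = spec)
  expect_identical(r1$samples, r2$samples)
  expect_equal(r1$rate, 250)
  expect_true(all(c(CANONICAL_CHANNELS, "Fp1", "Fp2") %in% r1$channels))
  expect_error(synthesize_recording(character(0), spec = spec), "empty")
  expect_error(synthesize_recording(c("W", "S4"), spec = spec), "unknown stage")
  expect_error(subject_spec("healthy", duration_s = 45), "multiple of 30")
})

test_that("generated epochs follow the stage complexity ordering", {
  spec <- subject_spec("healthy", duration_s = 250 * 30, sampling_rate = 250,
                       seed = 11, extra_channels = NULL)
  stages <- rep(STAGE_LEVELS, each = 50)
  rec <- select_canonical_channels(synthesize_recording(stages, spec = spec))
  grid <- segment_epochs(rec)
  f3 <- rowMeans(epoch_features(rec, grid, pe_params(3, 3)))
  m3 <- tapply(f3, stages, mean)
  expect_true(m3["W"] > m3["R"])
  expect_true(m3["R"] > m3["N1"])
  expect_true(m3["N1"] > m3["N2"])
  expect_true(m3["N2"] > m3["N3"])
  f1 <- rowMeans(epoch_features(rec, grid, pe_params(3, 1)))
  m1 <- tapply(f1, stages, mean)
  expect_gt(m1["W"], m1["N3"])
  # physiological side contracts: REM has busy EOG and silent EMG
  eogv <- tapply(apply(matrix(rec$samples["EOG", ], 7500), 2, var), stages, mean)
  expect_gt(eogv[["R"]], eogv[["N2"]])
  emgr <- tapply(apply(matrix(rec$samples["EMG", ], 7500), 2, sd), stages, mean)
  expect_lt(emgr[["R"]], emgr[["W"]])
  # N3 dominated by low frequencies: spectral edge check on one N3 epoch
  n3 <- rec$samples["Cz", (200 * 7500 + 1):(201 * 7500)]
  w <- rec$samples["Cz", 1:7500]
  spec_frac <- function(x) {
    sp <- Mod(fft(x))[2:1876]^2  # up to ~62 Hz
    f <- (2:1876 - 1) / 30
    sum(sp[f <= 4]) / sum(sp)
  }
  expect_gt(spec_frac(n3), spec_frac(w))
})

test_that("DOC simulation contrasts MCS and UWS and annotates eyes consistently", {
  mk <- function(g) simulate_doc_subject(subject_spec(
    g, duration_s = 100 * 30, sampling_rate = 250, seed = 21,
    day_hours = 8, night_hours = 8, extra_channels = NULL))
  mcs <- mk("MCS"); uws <- mk("UWS")
  expect_error(simulate_doc_subject(subject_spec("healthy")), "MCS or UWS")
  pe_diff <- function(d) {
    rec <- select_canonical_channels(d$recording)
    g <- segment_epochs(rec)
    f <- epoch_features(rec, g, pe_params(3, 3))
    tag <- split_day_night(g, d$intervals)
    abs(mean(f[tag == "day", ]) - mean(f[tag == "night", ]))
  }
  expect_gt(pe_diff(mcs), pe_diff(uws))
  # night shows >= 2 distinct sleep-like sub-states in MCS
  night_states <- unique(mcs$latent$state[mcs$latent$day_night == "night"])
  expect_gte(length(setdiff(night_states, c("wake", "arousal"))), 2)
  # annotation span covers the recording: one 5 min label per ten epochs
  expect_equal(length(mcs$eye_states), ceiling(nrow(mcs$latent) / 10))
  # UWS modulation depth defaults respect UWS <= MCS
  expect_lte(subject_spec("UWS")$modulation_depth, subject_spec("MCS")$modulation_depth)
})

test_that("unscorable video fractions behave as requested", {
  sp_all <- subject_spec("MCS", duration_s = 100 * 30, sampling_rate = 100,
                         seed = 8, unscorable_fraction = 1, extra_channels = NULL)
  expect_true(all(is.na(simulate_doc_subject(sp_all)$eye_states)))
  # realistic night regime: ~62% of blocks unscorable (binomial tolerance)
  sp <- subject_spec("MCS", duration_s = 1200 * 30, sampling_rate = 100,
                     seed = 9, unscorable_fraction = 0.62, extra_channels = NULL)
  eyes <- simulate_doc_subject(sp)$eye_states
  phat <- mean(is.na(eyes))
  expect_lt(abs(phat - 0.62), 3 * sqrt(0.62 * 0.38 / length(eyes)) + 0.01)
})

test_that("eye states latch to the latent state up to the error rate", {
  sp <- subject_spec("MCS", duration_s = 600 * 30, sampling_rate = 100, seed = 13,
                     unscorable_fraction = 0, extra_channels = NULL)
  d <- simulate_doc_subject(sp)
  blocks <- split(d$latent$wake_like, (seq_len(nrow(d$latent)) - 1) %/% 10)
  expected <- vapply(blocks, function(b) {
    f <- mean(!b)
    if (f >= 0.7) "C" else if (f <= 0.3) "O" else "OC"
  }, character(1))
  scorable <- expected %in% c("O", "C")
  agree <- mean(d$eye_states[scorable] == expected[scorable])
  expect_gt(agree, 0.85)  # 5% flip rate leaves high but imperfect agreement
  expect_lt(agree, 1)
})

test_that("feature-level cohorts are stage-separated and reproducible", {
  co <- simulate_feature_cohort(n_subjects = 4, epochs_per_stage = 15, seed = 2)
  expect_s3_class(co, "labeled_feature_set")
  expect_equal(length(co$features), 4)
  expect_equal(colnames(co$features[[1]]), CANONICAL_CHANNELS)
  co2 <- simulate_feature_cohort(n_subjects = 4, epochs_per_stage = 15, seed = 2)
  expect_identical(co$features, co2$features)
  x <- co$features[[1]]; y <- co$stages[[1]]
  m <- tapply(rowMeans(x), y, mean)
  expect_true(m["W"] > m["N2"] && m["N2"] > m["N3"])
})

test_that("recordings and annotations round-trip through plain-text formats", {
  spec <- subject_spec("healthy", duration_s = 60, sampling_rate = 100, seed = 4,
                       extra_channels = NULL)
  rec <- synthesize_recording(c("W", "N2"), spec = spec)
  pre <- file.path(tempdir(), "rec_rt")
  write_recording(rec, pre)
  rec2 <- read_recording(pre)
  expect_equal(rec2$samples, rec$samples, tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(rec2$channels, rec$channels)
  lab_file <- tempfile(fileext = ".csv")
  write_labels_csv(c("W", "N2"), lab_file)
  expect_identical(read_labels_csv(lab_file), c("W", "N2"))
  yml <- tempfile(fileext = ".yml")
  write_spec_yaml(spec, yml)
  expect_true(file.exists(yml))
})
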