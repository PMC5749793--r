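#' Per-stage signal model for the synthetic PSG generator
#'
#' Describes, for each sleep stage, the spectral composition of the synthetic
#' EEG (band-power fractions for delta 1-4, theta 4-8, alpha 8-12 and beta
#' 12-30 Hz), the fraction of band-limited 1/f background, the overall EEG
#' amplitude, EOG burst statistics and EMG tone. The defaults are calibrated
#' so that normalized permutation entropy of the generated signal is ordered
#' W > R > N1 > N2 > N3 (wake most irregular, slow-wave sleep most regular)
#' for n = 3 and tau in \{1, 3\} — the regularity structure the downstream
#' analysis assumes.
#'
#' The 1/f background is band-limited (AR(0.99) driven by white noise, then
#' low-passed at 35 Hz), emulating the acquisition anti-alias filter; a
#' broadband white floor would dominate adjacent-sample ordinal patterns and
#' destroy the stage ordering at tau = 1.
#'
#' @param band_fractions 5 x 4 matrix (rows W, N1, N2, N3, R; columns delta,
#'   theta, alpha, beta), each row summing to 1.
#' @param pink_fraction per-stage power fraction of the 1/f background.
#' @param white_fraction per-stage power fraction of broadband white noise
#'   (default 0; see above).
#' @param amplitude_uV per-stage EEG RMS amplitude in µV.
#' @param eog_burst_rate per-stage EOG event rate (blinks / eye movements),
#'   events per minute.
#' @param eog_burst_amp per-stage EOG event amplitude, µV.
#' @param emg_rms per-stage EMG tone, µV RMS.
#' @return An object of class `stage_signal_model`.
#' @export
stage_signal_model <- function(
    band_fractions = rbind(
      W  = c(delta = 0.05, theta = 0.10, alpha = 0.35, beta = 0.50),
      N1 = c(0.20, 0.45, 0.20, 0.15),
      N2 = c(0.45, 0.30, 0.15, 0.10),
      N3 = c(0.80, 0.12, 0.05, 0.03),
      R  = c(0.15, 0.30, 0.25, 0.30)),
    pink_fraction = c(W = 0.15, N1 = 0.25, N2 = 0.30, N3 = 0.35, R = 0.20),
    white_fraction = c(W = 0, N1 = 0, N2 = 0, N3 = 0, R = 0),
    amplitude_uV = c(W = 25, N1 = 30, N2 = 40, N3 = 70, R = 28),
    eog_burst_rate = c(W = 10, N1 = 4, N2 = 1, N3 = 0.5, R = 20),
    eog_burst_amp = c(W = 120, N1 = 60, N2 = 40, N3 = 30, R = 100),
    emg_rms = c(W = 30, N1 = 12, N2 = 8, N3 = 6, R = 2)) {
  colnames(band_fractions) <- c("delta", "theta", "alpha", "beta")
  m <- structure(list(band_fractions = band_fractions,
                      pink_fraction = pink_fraction,
                      white_fraction = white_fraction,
                      amplitude_uV = amplitude_uV,
                      eog_burst_rate = eog_burst_rate,
                      eog_burst_amp = eog_burst_amp,
                      emg_rms = emg_rms,
                      pe_order = c("W", "R", "N1", "N2", "N3")),
                 class = "stage_signal_model")
  validate_stage_signal_model(m)
  m
}

validate_stage_signal_model <- function(m) {
  assert_that(all(STAGE_LEVELS %in% rownames(m$band_fractions)),
              "every stage of {W,N1,N2,N3,R} must be present in the model")
  assert_that(all(abs(rowSums(m$band_fractions) - 1) < 1e-8),
              "band fractions must sum to 1 per stage")
  for (f in c("pink_fraction", "white_fraction", "amplitude_uV",
              "eog_burst_rate", "eog_burst_amp", "emg_rms"))
    assert_that(all(STAGE_LEVELS %in% names(m[[f]])),
                "field ", f, " must name every stage")
  assert_that(all(m$pink_fraction + m$white_fraction < 1),
              "pink + white fractions must leave room for the band mixture")
  invisible(m)
}

#' Default healthy hypnogram transition matrix (30 s steps)
#'
#' Row-stochastic 5 x 5 matrix over W, N1, N2, N3, R with sticky stages and
#' realistic routing (wake enters sleep via N1; N3 is reached through N2).
#'
#' @return A 5 x 5 row-stochastic matrix.
#' @export
default_transition_matrix <- function() {
  tm <- rbind(
    W  = c(0.92, 0.06, 0.01, 0.00, 0.01),
    N1 = c(0.10, 0.55, 0.30, 0.01, 0.04),
    N2 = c(0.02, 0.03, 0.85, 0.06, 0.04),
    N3 = c(0.01, 0.01, 0.10, 0.87, 0.01),
    R  = c(0.03, 0.05, 0.05, 0.01, 0.86))
  colnames(tm) <- STAGE_LEVELS
  tm
}

#' Specification of one synthetic subject
#'
#' @param group "healthy", "MCS" or "UWS".
#' @param duration_s recording duration, a positive multiple of 30 s.
#'   Defaults to 8 h for healthy and 24 h for DOC groups.
#' @param sampling_rate acquisition sampling rate in Hz (default 500, so the
#'   downsampling stage of the pipeline is exercised).
#' @param transition_matrix 5 x 5 row-stochastic hypnogram transition matrix
#'   (healthy subjects).
#' @param modulation_depth day/night complexity modulation depth in `[0, 1]`:
#'   1 swings between the full wake and sleep signal models, 0 freezes the
#'   signal at their midpoint blend regardless of the latent state. Defaults:
#'   MCS 0.9, UWS 0.05 (UWS <= MCS by construction).
#' @param unscorable_fraction probability that a 5 min video epoch is
#'   unscorable (NA); a scalar, or a named vector `c(day = , night = )`.
#'   Defaults to the realistic regime `c(day = 0.15, night = 0.62)`.
#' @param day_hours,night_hours circadian layout for DOC recordings
#'   (defaults 10.1 and 5.9 h); scaled proportionally for short recordings.
#' @param eye_error_rate probability that a scorable video epoch's O/C label
#'   contradicts the latent state (imperfect behavioral proxy; default 0.05).
#' @param extra_channels extra EEG labels generated beyond the canonical 14,
#'   so channel selection is exercised (default Fp1, Fp2; NULL for none).
#' @param subject_id optional identifier.
#' @param seed integer random seed; all randomness derives from it.
#' @return An object of class `subject_spec`.
#' @export
subject_spec <- function(group = c("healthy", "MCS", "UWS"),
                         duration_s = NULL,
                         sampling_rate = 500,
                         transition_matrix = default_transition_matrix(),
                         modulation_depth = NULL,
                         unscorable_fraction = c(day = 0.15, night = 0.62),
                         day_hours = 10.1, night_hours = 5.9,
                         eye_error_rate = 0.05,
                         extra_channels = c("Fp1", "Fp2"),
                         subject_id = NULL, seed = 1L) {
  group <- match.arg(group)
  duration_s <- duration_s %||% if (group == "healthy") 8 * 3600 else 24 * 3600
  assert_that(duration_s > 0 && abs(duration_s %% 30) < 1e-9,
              "duration_s must be a positive multiple of 30 s")
  modulation_depth <- modulation_depth %||%
    switch(group, healthy = NA_real_, MCS = 0.9, UWS = 0.05)
  if (group != "healthy")
    assert_that(modulation_depth >= 0 && modulation_depth <= 1,
                "modulation_depth must be in [0, 1]")
  if (length(unscorable_fraction) == 1)
    unscorable_fraction <- c(day = unname(unscorable_fraction),
                             night = unname(unscorable_fraction))
  assert_that(all(unscorable_fraction >= 0 & unscorable_fraction <= 1),
              "unscorable_fraction must lie in [0, 1]")
  validate_transition_matrix(transition_matrix)
  structure(list(group = group, duration_s = duration_s,
                 sampling_rate = sampling_rate,
                 transition_matrix = transition_matrix,
                 modulation_depth = modulation_depth,
                 unscorable_fraction = unscorable_fraction,
                 day_hours = day_hours, night_hours = night_hours,
                 eye_error_rate = eye_error_rate,
                 extra_channels = extra_channels,
                 subject_id = subject_id %||% paste0(group, "-", seed),
                 seed = as.integer(seed)),
            class = "subject_spec")
}

validate_transition_matrix <- function(tm) {
  assert_that(is.matrix(tm) && all(dim(tm) == c(5, 5)),
              "transition matrix must be 5 x 5")
  assert_that(all(tm >= 0) && all(abs(rowSums(tm) - 1) < 1e-8),
              "invalid spec: transition matrix rows must be non-negative and sum to 1")
}

#' Simulate a healthy hypnogram as a first-order Markov chain on 30 s epochs
#'
#' @param spec a `subject_spec`.
#' @return Character vector of stage labels (one per 30 s epoch), starting
#'   in W; deterministic given `spec$seed`.
#' @export
simulate_hypnogram <- function(spec) {
  validate_transition_matrix(spec$transition_matrix)
  n_epochs <- as.integer(spec$duration_s / 30)
  assert_that(n_epochs >= 1, "empty recording: duration must cover >= 1 epoch")
  tm <- spec$transition_matrix[STAGE_LEVELS, STAGE_LEVELS]
  with_preserved_seed(derive_seed(spec$seed, 1L), {
    stages <- character(n_epochs)
    stages[1] <- "W"
    if (n_epochs > 1) {
      for (i in 2:n_epochs) {
        stages[i] <- sample(STAGE_LEVELS, 1L, prob = tm[stages[i - 1], ])
      }
    }
    stages
  })
}

# --- internal synthesis core -------------------------------------------------

band_edges <- function() list(delta = c(1, 4), theta = c(4, 8),
                              alpha = c(8, 12), beta = c(12, 30))

# fixed per-channel band gains (delta, theta, alpha, beta): crude topography
channel_band_gain <- function(channel) {
  switch(substr(channel, 1, 2),
         "Fp" = c(1.30, 1.10, 0.80, 1.00),
         "F3" = , "Fz" = , "F4" = c(1.25, 1.10, 0.85, 1.00),
         "C3" = , "Cz" = , "C4" = c(1.00, 1.00, 1.00, 1.10),
         "P3" = , "Pz" = , "P4" = c(0.90, 1.00, 1.25, 0.95),
         "T3" = , "T4" = c(1.00, 1.10, 0.90, 1.15),
         "Oz" = c(0.85, 0.95, 1.50, 0.90),
         c(1, 1, 1, 1))
}

# EOG leakage coefficient into an EEG channel (front-to-back decay)
eog_leak_coef <- function(channel) {
  switch(substr(channel, 1, 2),
         "Fp" = 0.45,
         "F3" = , "Fz" = , "F4" = 0.30,
         "C3" = , "Cz" = , "C4" = 0.12,
         "P3" = , "Pz" = , "P4" = 0.05,
         "T3" = , "T4" = 0.08,
         "Oz" = 0.03,
         0)
}

unit_sd <- function(x) {
  s <- sd(x)
  if (s == 0) x else x / s
}

single_pass <- function(flt, x) cpp_iir_filter(flt$b, flt$a, x)

# white-noise power gain of a filter (or cascade), from its impulse response
noise_gain <- function(..., len = 8192) {
  h <- c(1, rep(0, len - 1))
  for (flt in list(...)) h <- single_pass(flt, h)
  sqrt(sum(h^2))
}

# Synthesize all channels for a sequence of per-epoch mixing parameters.
# params: list with per-epoch band (E x 4), pink (E), white (E), amp (E),
# eog_rate (E), eog_amp (E), emg_rms (E).
synth_core <- function(params, rate, seed, extra_channels = c("Fp1", "Fp2")) {
  E <- nrow(params$band)
  spp <- as.integer(30 * rate)          # samples per epoch
  N <- E * spp
  nyq <- rate / 2
  eeg_channels <- c(CANONICAL_EEG_CHANNELS, extra_channels)
  all_channels <- c(eeg_channels, "EMG", "EOG")
  bp <- lapply(band_edges(), function(e) signal::butter(2, e / nyq, type = "pass"))
  lp35 <- signal::butter(2, min(35, 0.9 * nyq) / nyq, type = "low")
  lp8 <- signal::butter(2, 8 / nyq, type = "low")

  with_preserved_seed(derive_seed(seed, 2L), {
    out <- matrix(0, nrow = length(all_channels), ncol = N,
                  dimnames = list(all_channels, NULL))

    # EOG: slow drift + stage-dependent bursts (blinks / REMs)
    slow <- unit_sd(single_pass(lp8, cpp_iir_filter(1, c(1, -0.995), rnorm(N))))
    broad <- unit_sd(single_pass(bp$theta, rnorm(N)))
    eog <- 15 * slow + 4 * broad
    for (e in seq_len(E)) {
      n_ev <- rpois(1, params$eog_rate[e] * 30 / 60)
      if (n_ev > 0) {
        centers <- floor(runif(n_ev, 0, spp - 1)) + (e - 1L) * spp
        for (cidx in centers) {
          half <- as.integer(0.45 * rate)        # ~0.9 s event
          idx <- max(1, cidx - half):min(N, cidx + half)
          shape <- exp(-((idx - cidx) / (0.15 * rate))^2 / 2)
          eog[idx] <- eog[idx] +
            sample(c(-1, 1), 1) * runif(1, 0.6, 1.2) * params$eog_amp[e] * shape
        }
      }
    }
    out["EOG", ] <- eog

    # EMG: stage-dependent broadband tone over a fixed colored baseline, so
    # the tone/baseline ratio (hence the spectrum, hence PE) tracks the stage
    emg_base <- unit_sd(cpp_iir_filter(1, c(1, -0.9), rnorm(N)))
    tone <- rep(params$emg_rms, each = spp)
    out["EMG", ] <- tone * rnorm(N) + 6 * emg_base

    # EEG channels: per-epoch band mixture + band-limited 1/f background.
    # Filter gains are exact (impulse response) so normalization is
    # deterministic; channels sharing a topography profile share the
    # expanded per-sample weight vectors.
    ar99 <- list(b = 1, a = c(1, -0.99))
    g_band <- vapply(bp, noise_gain, numeric(1), len = as.integer(16 * rate))
    g_pink <- noise_gain(ar99, lp35, len = as.integer(16 * rate))
    w_pink <- rep(sqrt(params$pink), each = spp)
    w_white <- rep(sqrt(params$white), each = spp)
    amp <- rep(params$amp, each = spp)
    band_rest <- 1 - params$pink - params$white
    profile <- vapply(eeg_channels,
                      function(ch) paste(channel_band_gain(ch), collapse = ","),
                      character(1))
    for (pf in unique(profile)) {
      gain <- channel_band_gain(eeg_channels[profile == pf][1])
      frac <- sweep(params$band, 2, gain, `*`)
      frac <- frac / rowSums(frac) * band_rest       # E x 4, channel-adjusted
      wts <- lapply(1:4, function(b) rep(sqrt(frac[, b]), each = spp))
      for (ch in eeg_channels[profile == pf]) {
        wn <- rnorm(N)
        sig <- w_pink * (single_pass(lp35, single_pass(ar99, wn)) / g_pink)
        for (b in 1:4) sig <- sig + wts[[b]] * (single_pass(bp[[b]], wn) / g_band[b])
        if (any(params$white > 0)) sig <- sig + w_white * rnorm(N)
        out[ch, ] <- amp * sig + eog_leak_coef(ch) * eog
      }
    }
    out
  })
}

stage_params <- function(stages, model) {
  i <- match(stages, rownames(model$band_fractions))
  list(band = model$band_fractions[i, , drop = FALSE],
       pink = unname(model$pink_fraction[stages]),
       white = unname(model$white_fraction[stages]),
       amp = unname(model$amplitude_uV[stages]),
       eog_rate = unname(model$eog_burst_rate[stages]),
       eog_amp = unname(model$eog_burst_amp[stages]),
       emg_rms = unname(model$emg_rms[stages]))
}

#' Synthesize a multichannel PSG recording from a stage label sequence
#'
#' Each 30 s epoch follows its stage's signal model: a mixture of band-limited
#' Gaussian noise components plus a band-limited 1/f background for the EEG
#' channels, burst-laden EOG and tone-modulated EMG. REM epochs have elevated
#' EOG variance and minimal EMG tone; N3 epochs are dominated by
#' low-frequency content.
#'
#' @param stages character vector of stage labels (one per 30 s epoch).
#' @param model a `stage_signal_model`.
#' @param spec a `subject_spec` (supplies sampling rate, extra channels and
#'   the random seed).
#' @return A `psg_recording`; bit-identical for identical inputs and seed.
#' @export
synthesize_recording <- function(stages, model = stage_signal_model(), spec) {
  assert_that(length(stages) >= 1, "empty recording: stage sequence is empty")
  bad <- setdiff(unique(stages), STAGE_LEVELS)
  assert_that(length(bad) == 0, "unknown stage label(s): ", paste(bad, collapse = ", "))
  validate_stage_signal_model(model)
  samples <- synth_core(stage_params(stages, model), spec$sampling_rate,
                        spec$seed, spec$extra_channels)
  psg_recording(samples, rate = spec$sampling_rate,
                subject = spec$subject_id, group = spec$group)
}

#' Simulate a full healthy subject (hypnogram + recording)
#'
#' @param spec a `subject_spec` with `group = "healthy"`.
#' @param model a `stage_signal_model`.
#' @return List with `recording` (a `psg_recording`) and `stages` (character
#'   vector, one label per 30 s epoch).
#' @export
simulate_healthy_subject <- function(spec, model = stage_signal_model()) {
  assert_that(spec$group == "healthy", "spec$group must be 'healthy'")
  stages <- simulate_hypnogram(spec)
  list(recording = synthesize_recording(stages, model, spec), stages = stages)
}

# circadian day/night layout: day - night - day, boundaries on the 30 s grid
doc_intervals <- function(duration_s, day_hours, night_hours) {
  tot <- (day_hours + night_hours) * 3600
  night_s <- if (duration_s >= tot) night_hours * 3600
             else duration_s * night_hours / (day_hours + night_hours)
  night_s <- 30 * round(night_s / 30)
  d1 <- 30 * round((duration_s - night_s) / 2 / 30)
  iv <- data.frame(start_s = c(0, d1, d1 + night_s),
                   end_s = c(d1, d1 + night_s, duration_s),
                   tag = c("day", "night", "day"))
  iv[iv$end_s > iv$start_s, , drop = FALSE]
}

# latent state machine for DOC subjects: day wake/nap chain, night chain over
# two sleep-like sub-states plus brief arousals
doc_latent <- function(epoch_tag, seed) {
  E <- length(epoch_tag)
  state <- character(E)
  with_preserved_seed(derive_seed(seed, 3L), {
    cur_day <- "wake"; cur_night <- "N2s"
    for (i in seq_len(E)) {
      if (epoch_tag[i] == "day") {
        u <- runif(1)
        cur_day <- if (cur_day == "wake") {
          if (u < 0.03) "nap" else "wake"
        } else if (u < 0.15) "wake" else "nap"
        state[i] <- cur_day
      } else {
        u <- runif(1)
        cur_night <- switch(cur_night,
          N2s = if (u < 0.05) "Rs" else if (u < 0.07) "arousal" else "N2s",
          Rs = if (u < 0.05) "N2s" else if (u < 0.07) "arousal" else "Rs",
          arousal = if (u < 0.12) "N2s" else if (u < 0.15) "Rs" else "arousal")
        state[i] <- cur_night
      }
    }
  })
  wake_like <- state %in% c("wake", "arousal")
  partner <- ifelse(state == "Rs", "R", "N2")
  data.frame(epoch = seq_len(E) - 1L, state = state, wake_like = wake_like,
             partner = partner, stringsAsFactors = FALSE)
}

blend_params <- function(latent, depth, model) {
  lam <- 0.5 + depth * (as.numeric(latent$wake_like) - 0.5)
  pw <- stage_params(rep("W", nrow(latent)), model)
  ps <- stage_params(latent$partner, model)
  list(band = lam * pw$band + (1 - lam) * ps$band,
       pink = lam * pw$pink + (1 - lam) * ps$pink,
       white = lam * pw$white + (1 - lam) * ps$white,
       amp = lam * pw$amp + (1 - lam) * ps$amp,
       eog_rate = lam * pw$eog_rate + (1 - lam) * ps$eog_rate,
       eog_amp = lam * pw$eog_amp + (1 - lam) * ps$eog_amp,
       emg_rms = lam * pw$emg_rms + (1 - lam) * ps$emg_rms)
}

# eye-state video annotation on the 5 min grid, latched to the latent state
# with a configurable error rate and unscorable (NA) overlay
doc_eye_states <- function(latent, epoch_tag, spec) {
  E <- nrow(latent)
  n_blocks <- ceiling(E / 10)
  with_preserved_seed(derive_seed(spec$seed, 4L), {
    labels <- character(n_blocks)
    for (b in seq_len(n_blocks)) {
      idx <- ((b - 1L) * 10L + 1L):min(b * 10L, E)
      f_sleep <- mean(!latent$wake_like[idx])
      lab <- if (f_sleep >= 0.7) "C" else if (f_sleep <= 0.3) "O" else "OC"
      if (lab %in% c("O", "C") && runif(1) < spec$eye_error_rate)
        lab <- if (lab == "O") "C" else "O"
      tag <- names(which.max(table(epoch_tag[idx])))
      if (runif(1) < spec$unscorable_fraction[[tag]]) lab <- NA_character_
      labels[b] <- lab
    }
    labels
  })
}

#' Simulate a DOC (MCS or UWS) subject: 24 h-style recording, day/night
#' intervals and eye-state video annotation
#'
#' The latent state alternates wake-like day periods and night periods with
#' two distinct sleep-like sub-states (N2-like and REM-like) plus brief
#' arousals. The signal is a blend of the wake and current sleep sub-state
#' models; `modulation_depth` scales the day/night contrast, so MCS subjects
#' (default depth 0.9) show strong complexity modulation and distinct night
#' sub-states while UWS subjects (default 0.05) barely modulate. Eye states
#' latch to the latent state (C during sleep-like, O during wake-like) with
#' the spec's error rate, and a day/night-specific fraction of 5 min video
#' epochs is unscorable (NA). Note the eyes track the latent behavioral state
#' even when, as in UWS, the cortical signal does not.
#'
#' @param spec a `subject_spec` with `group` of "MCS" or "UWS".
#' @param model a `stage_signal_model`.
#' @return List with `recording`, `intervals` (data frame start_s/end_s/tag),
#'   `eye_states` (character per 5 min epoch: "O", "C", "OC" or NA) and
#'   `latent` (per-epoch latent state data frame, for validation).
#' @export
simulate_doc_subject <- function(spec, model = stage_signal_model()) {
  assert_that(spec$group %in% c("MCS", "UWS"),
              "group must be MCS or UWS; use simulate_healthy_subject() for healthy")
  E <- as.integer(spec$duration_s / 30)
  iv <- doc_intervals(spec$duration_s, spec$day_hours, spec$night_hours)
  mid <- (seq_len(E) - 0.5) * 30
  tag <- rep("day", E)
  for (r in seq_len(nrow(iv)))
    tag[mid >= iv$start_s[r] & mid < iv$end_s[r]] <- iv$tag[r]
  latent <- doc_latent(tag, spec$seed)
  params <- blend_params(latent, spec$modulation_depth, model)
  samples <- synth_core(params, spec$sampling_rate, spec$seed, spec$extra_channels)
  rec <- psg_recording(samples, rate = spec$sampling_rate,
                       subject = spec$subject_id, group = spec$group,
                       intervals = iv)
  eyes <- doc_eye_states(latent, tag, spec)
  latent$day_night <- tag
  list(recording = rec, intervals = iv, eye_states = eyes, latent = latent)
}

#' Simulate a mixed cohort of healthy and DOC subjects
#'
#' Per-subject seeds are derived from the master seed via a counter, so the
#' whole cohort is reproducible from one integer.
#'
#' @param n_healthy,n_mcs,n_uws subject counts per group.
#' @param healthy_duration_s,doc_duration_s recording durations (multiples of
#'   30 s).
#' @param sampling_rate acquisition rate in Hz.
#' @param seed master seed.
#' @param ... further arguments passed to [subject_spec()].
#' @return List with elements `healthy` (each: spec, recording, stages) and
#'   `doc` (each: spec, recording, intervals, eye_states, latent).
#' @export
simulate_cohort <- function(n_healthy = 3, n_mcs = 1, n_uws = 1,
                            healthy_duration_s = 3600, doc_duration_s = 3600,
                            sampling_rate = 500, seed = 1L, ...) {
  k <- 0L
  healthy <- lapply(seq_len(n_healthy), function(i) {
    k <<- k + 1L
    # inclusion criterion: a training-cohort night must exhibit every stage
    # (re-draw the chain from a fresh substream otherwise)
    for (try in 0:100) {
      spec <- subject_spec("healthy", duration_s = healthy_duration_s,
                           sampling_rate = sampling_rate,
                           subject_id = sprintf("H%02d", i),
                           seed = derive_seed(seed, k + 1000L * try), ...)
      stages <- simulate_hypnogram(spec)
      if (all(STAGE_LEVELS %in% stages) || try == 100) break
    }
    list(spec = spec, recording = synthesize_recording(stages, spec = spec),
         stages = stages)
  })
  doc <- lapply(seq_len(n_mcs + n_uws), function(i) {
    k <<- k + 1L
    grp <- if (i <= n_mcs) "MCS" else "UWS"
    id <- if (i <= n_mcs) sprintf("M%02d", i) else sprintf("U%02d", i - n_mcs)
    spec <- subject_spec(grp, duration_s = doc_duration_s,
                         sampling_rate = sampling_rate, subject_id = id,
                         seed = derive_seed(seed, k), ...)
    c(list(spec = spec), simulate_doc_subject(spec))
  })
  list(healthy = healthy, doc = doc)
}

#' Simulate a feature-level healthy cohort (per-epoch PE vectors + labels)
#'
#' Draws per-epoch, per-channel normalized PE values directly from
#' stage-separated Gaussian distributions (stage profiles matching the
#' signal-level generator's calibration, subject-level random offsets, and
#' epoch noise), bypassing signal synthesis. Useful for classifier studies
#' where only the feature distribution matters.
#'
#' @param n_subjects number of subjects.
#' @param epochs_per_stage epochs per stage per subject.
#' @param subject_sd SD of the per-subject offset.
#' @param epoch_sd SD of the per-epoch noise.
#' @param seed master seed.
#' @return A `labeled_feature_set`.
#' @export
simulate_feature_cohort <- function(n_subjects = 10, epochs_per_stage = 20,
                                    subject_sd = 0.005, epoch_sd = 0.012,
                                    seed = 1L) {
  # stage x channel mean PE profiles: EEG channels share the stage ordering,
  # EMG and EOG carry the wake/REM contrast (atonia, eye movements)
  eeg_base <- c(W = 0.945, N1 = 0.902, N2 = 0.895, N3 = 0.874, R = 0.930)
  emg <- c(W = 0.970, N1 = 0.905, N2 = 0.885, N3 = 0.875, R = 0.790)
  eog <- c(W = 0.930, N1 = 0.900, N2 = 0.865, N3 = 0.850, R = 0.905)
  ch_off <- seq(-0.006, 0.006, length.out = 12)   # mild topographic spread
  profile <- sapply(STAGE_LEVELS, function(s)
    c(eeg_base[s] + ch_off, emg[s], eog[s]))      # 14 x 5
  rownames(profile) <- CANONICAL_CHANNELS
  stages <- rep(STAGE_LEVELS, each = epochs_per_stage)
  feats <- list(); labs <- list()
  for (i in seq_len(n_subjects)) {
    with_preserved_seed(derive_seed(seed, i), {
      subj_off <- rnorm(14, 0, subject_sd)
      x <- t(profile[, stages]) +
        matrix(rep(subj_off, each = length(stages)), ncol = 14) +
        matrix(rnorm(length(stages) * 14, 0, epoch_sd), ncol = 14)
      colnames(x) <- CANONICAL_CHANNELS
      feats[[i]] <- pmin(pmax(x, 0), 1)
      labs[[i]] <- stages
    })
  }
  labeled_feature_set(feats, labs, subjects = sprintf("S%02d", seq_len(n_subjects)))
}

#' Write synthetic cohort annotations as plain-text files
#'
#' Stage labels and eye states as CSV `(epoch_index, label)`, day/night
#' intervals as CSV `(start_s, end_s, tag)`, subject specs as YAML.
#'
#' @param labels character vector of per-epoch labels (30 s or 5 min grid).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_labels_csv <- function(labels, file) {
  utils::write.csv(data.frame(epoch_index = seq_along(labels) - 1L,
                              label = labels),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  as.character(df$label)
}

#' @param intervals data frame with start_s, end_s, tag.
#' @rdname write_labels_csv
#' @export
write_intervals_csv <- function(intervals, file) {
  utils::write.csv(intervals, file, row.names = FALSE)
  invisible(file)
}

#' @param spec a `subject_spec`.
#' @rdname write_labels_csv
#' @export
write_spec_yaml <- function(spec, file) {
  s <- unclass(spec)
  s$transition_matrix <- apply(spec$transition_matrix, 1, as.list, simplify = FALSE)
  yaml::write_yaml(s, file)
  invisible(file)
}
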