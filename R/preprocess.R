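#' Zero-phase IIR filtering (forward-backward)
#'
#' Applies an IIR filter forward and backward so the effective magnitude
#' response is squared and the phase response is zero. Start-up transients
#' are controlled with odd-reflection padding and steady-state initial
#' conditions (the standard filtfilt construction).
#'
#' @param b,a numerator / denominator filter coefficients.
#' @param x numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
zero_phase_filter <- function(b, a, x) {
  nf <- max(length(b), length(a))
  n <- nf - 1L
  if (n < 1) return(as.numeric(b[1] / a[1]) * x)
  pad <- min(length(x) - 1L, 3L * n)
  assert_that(pad >= 1, "signal too short to filter")
  # steady-state initial state for a unit step (companion-matrix solve)
  aa <- a / a[1]; bb <- b / a[1]
  bb <- c(bb, rep(0, nf - length(bb)))
  aa <- c(aa, rep(0, nf - length(aa)))
  comp <- matrix(0, n, n)
  comp[1, ] <- -aa[2:nf]
  if (n > 1) comp[cbind(2:n, 1:(n - 1))] <- 1
  zi <- solve(diag(n) - t(comp), bb[2:nf] - aa[2:nf] * bb[1])
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[length(x)] - x[(length(x) - 1):(length(x) - pad)])
  y <- cpp_iir_filter(b, a, ext, zi * ext[1])
  y <- rev(cpp_iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + length(x))]
}

#' Downsample a recording with anti-alias filtering
#'
#' Integer-factor decimation: a zero-phase Butterworth low-pass at 80% of the
#' new Nyquist frequency, then every q-th sample. The study's use case is
#' 500 to 250 Hz.
#'
#' @param rec a `psg_recording`.
#' @param target_rate target sampling rate in Hz (default 250); must divide
#'   the source rate. Upsampling is not supported.
#' @return The resampled `psg_recording`.
#' @export
psg_resample <- function(rec, target_rate = 250) {
  assert_that(target_rate <= rec$rate,
              "upsampling (target rate above source rate) is out of scope")
  if (target_rate == rec$rate) return(rec)
  q <- rec$rate / target_rate
  assert_that(abs(q - round(q)) < 1e-9,
              "target rate must divide the source rate (integer decimation)")
  q <- as.integer(round(q))
  lp <- signal::butter(8, 0.8 / q, type = "low")
  keep <- seq(1, ncol(rec$samples), by = q)
  out <- matrix(0, nrow(rec$samples), length(keep))
  for (i in seq_len(nrow(out)))
    out[i, ] <- zero_phase_filter(lp$b, lp$a, rec$samples[i, ])[keep]
  psg_recording(out, rate = target_rate, channels = rec$channels,
                subject = rec$subject, group = rec$group, intervals = rec$intervals)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Defaults reproduce the standard sleep-EEG conditioning: 1-30 Hz, design
#' order 4, applied forward-backward ("zero phase IIR Butterworth filter of
#' order 4" in the Brain Vision sense; the magnitude response is squared by
#' the two passes).
#'
#' @param rec a `psg_recording`.
#' @param low,high band edges in Hz.
#' @param order Butterworth design order (per band edge).
#' @return The filtered `psg_recording` (channel count, order, rate preserved).
#' @export
psg_bandpass <- function(rec, low = 1, high = 30, order = 4) {
  nyq <- rec$rate / 2
  assert_that(low > 0 && low < high, "need 0 < low < high")
  assert_that(high < nyq, "high band edge must be below the Nyquist frequency")
  flt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  for (i in seq_len(nrow(rec$samples)))
    rec$samples[i, ] <- zero_phase_filter(flt$b, flt$a, rec$samples[i, ])
  rec
}

#' Re-reference EEG channels to a common (average) reference
#'
#' Subtracts, at every sample, the mean across EEG channels from each EEG
#' channel. Non-EEG channels (EMG, EOG and anything not in `eeg_channels`)
#' are excluded from the reference computation and left untouched.
#'
#' @param rec a `psg_recording`.
#' @param scheme reference scheme; only "average" is implemented.
#' @param eeg_channels channels entering the reference (default: all channels
#'   except EMG/EOG-like labels).
#' @return The re-referenced `psg_recording`.
#' @export
psg_rereference <- function(rec, scheme = "average",
                            eeg_channels = setdiff(rec$channels, c("EMG", "EOG"))) {
  assert_that(identical(scheme, "average"), "only the average reference is implemented")
  eeg_channels <- intersect(rec$channels, eeg_channels)
  assert_that(length(eeg_channels) >= 2,
              "average re-referencing needs at least two EEG channels")
  idx <- match(eeg_channels, rec$channels)
  ref <- colMeans(rec$samples[idx, , drop = FALSE])
  rec$samples[idx, ] <- sweep(rec$samples[idx, , drop = FALSE], 2, ref)
  rec
}

#' Regression-based ocular artifact correction
#'
#' Fits, over the whole recording, an ordinary least-squares regression of
#' each EEG channel on the EOG channel(s) (jointly, with intercept) and
#' subtracts the estimated EOG contribution. The EOG channels themselves are
#' retained unmodified for later feature use.
#'
#' @param rec a `psg_recording`.
#' @param eog_channels names of the EOG regressor channel(s).
#' @return The corrected `psg_recording`, with the fitted coefficients in
#'   attribute `"eog_coefficients"` (EEG channels x EOG channels).
#' @export
psg_ocular_correct <- function(rec, eog_channels = "EOG") {
  missing <- setdiff(eog_channels, rec$channels)
  assert_that(length(missing) == 0,
              "missing EOG channel(s): ", paste(missing, collapse = ", "))
  eeg <- setdiff(rec$channels, eog_channels)
  # least squares via normal equations on channel-row matrices (with
  # intercept); pseudoinverse handles rank deficiency (e.g. EOG == 0)
  G <- rbind(1, rec$samples[eog_channels, , drop = FALSE])   # (1+k) x N
  Y <- rec$samples[eeg, , drop = FALSE]                      # n_eeg x N
  GGt <- G %*% t(G)
  sv <- svd(GGt)
  pos <- sv$d > max(sv$d) * 1e-12
  inv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  beta <- (Y %*% t(G)) %*% inv                               # n_eeg x (1+k)
  coefs <- beta[, -1, drop = FALSE]
  rec$samples[eeg, ] <- Y - coefs %*% G[-1, , drop = FALSE]
  colnames(coefs) <- eog_channels
  rownames(coefs) <- eeg
  attr(rec, "eog_coefficients") <- coefs
  rec
}

#' Select the canonical 14-channel montage
#'
#' Keeps exactly the fourteen channels common to all subjects (F3, Fz, F4,
#' C3, Cz, C4, P3, Pz, P4, T3, T4, Oz, EMG, EOG), in that order; matching is
#' case-insensitive.
#'
#' @param rec a `psg_recording`.
#' @return The 14-channel `psg_recording` in canonical order.
#' @export
select_canonical_channels <- function(rec) {
  idx <- match(tolower(CANONICAL_CHANNELS), tolower(rec$channels))
  if (anyNA(idx)) {
    miss <- CANONICAL_CHANNELS[is.na(idx)]
    stop_docsleep("missing channel ", paste(miss, collapse = ", "))
  }
  psg_recording(rec$samples[idx, , drop = FALSE], rate = rec$rate,
                channels = CANONICAL_CHANNELS, subject = rec$subject,
                group = rec$group, intervals = rec$intervals)
}

#' Run the full conditioning chain in the fixed pipeline order
#'
#' resample -> band-pass -> average re-reference -> ocular regression ->
#' canonical channel selection.
#'
#' @param rec a `psg_recording`.
#' @param target_rate,low,high,order filter parameters (study defaults).
#' @param eog_channels EOG regressor channel names.
#' @return The preprocessed 14-channel `psg_recording`.
#' @export
preprocess_recording <- function(rec, target_rate = 250, low = 1, high = 30,
                                 order = 4, eog_channels = "EOG") {
  rec <- psg_resample(rec, target_rate)
  rec <- psg_bandpass(rec, low, high, order)
  rec <- psg_rereference(rec)
  rec <- psg_ocular_correct(rec, eog_channels)
  select_canonical_channels(rec)
}
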