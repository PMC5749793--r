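#' Permutation entropy parameters
#'
#' @param n embedding dimension: how many amplitudes each ordinal symbol
#'   compares (default 3, giving 3! = 6 patterns). Must be 2..7.
#' @param tau lag between compared points, in samples at the analysis rate
#'   (the study uses 1 and 3 at 250 Hz).
#' @param normalize divide the Shannon entropy by log(n!) so values lie in
#'   `[0, 1]` (default TRUE).
#' @return An object of class `pe_params`.
#' @export
pe_params <- function(n = 3, tau = 1, normalize = TRUE) {
  assert_that(n >= 2 && n <= 7, "embedding dimension n must be in 2..7")
  assert_that(tau >= 1, "lag tau must be >= 1")
  structure(list(n = as.integer(n), tau = as.integer(tau),
                 normalize = isTRUE(normalize)),
            class = "pe_params")
}

# all n! sorting permutations, their display names and rank-encoding codes
pattern_table <- function(n) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  P <- perms(0:(n - 1))                      # argsort tuples, lexicographic
  codes <- vapply(P, function(s) {
    r <- integer(n)
    r[s + 1L] <- 0:(n - 1)                   # rank of each window position
    sum(r * n^(0:(n - 1)))
  }, numeric(1))
  list(names = vapply(P, paste, character(1), collapse = ""),
       codes = as.integer(codes))
}

#' Ordinal pattern counts of a signal
#'
#' Slides a window of `n` points spaced `tau` samples apart along the signal
#' and counts how often each of the n! orderings occurs. A window's pattern
#' is the permutation that sorts it ascending; equal amplitudes are ranked
#' earlier-index-first (stable), so the result is deterministic for signals
#' with ties.
#'
#' @param x numeric signal.
#' @param params a `pe_params`.
#' @return Named integer vector over all n! patterns (names like "012",
#'   "201": the 0-based indices of the window elements in ascending order),
#'   summing to `length(x) - (n-1)*tau`.
#' @export
ordinal_pattern_counts <- function(x, params = pe_params()) {
  n <- params$n; tau <- params$tau
  assert_that(length(x) >= (n - 1) * tau + 1,
              "signal too short: need at least (n-1)*tau + 1 samples")
  codes <- cpp_ordinal_codes(as.numeric(x), n, tau)
  tab <- tabulate(codes + 1L, nbins = n^n)
  pt <- pattern_table(n)
  counts <- tab[pt$codes + 1L]
  names(counts) <- pt$names
  counts
}

#' Normalized permutation entropy
#'
#' Shannon entropy of the ordinal pattern distribution,
#' H = -sum p log p over patterns with nonzero relative frequency, divided
#' by log(n!) when normalized. 0 for any single-pattern (e.g. strictly
#' monotone) signal; 1 iff all n! patterns are equally frequent.
#'
#' @param x numeric signal.
#' @param params a `pe_params`.
#' @return Scalar in `[0, 1]` (or in `[0, log(n!)]` unnormalized).
#' @export
permutation_entropy <- function(x, params = pe_params()) {
  counts <- ordinal_pattern_counts(x, params)
  p <- counts[counts > 0] / sum(counts)
  h <- 0 - sum(p * log(p))  # 0 - x: avoid IEEE negative zero
  if (params$normalize) h / log(factorial(params$n)) else h
}

#' Per-epoch, per-channel permutation entropy feature matrix
#'
#' Computes normalized PE for every (epoch, channel) cell of a segmented
#' recording, including the EMG and EOG channels (whose complexity carries
#' stage information: muscle atonia in REM, eye movements in wake/REM).
#'
#' @param rec a `psg_recording` (typically the canonical 14 channels).
#' @param grid an `epoch_grid` from [segment_epochs()] of the same recording.
#' @param params a `pe_params`.
#' @return An `epochs x channels` matrix of class `pe_features` with the
#'   parameters in attribute `"params"`.
#' @export
epoch_features <- function(rec, grid, params = pe_params()) {
  assert_that(abs(attr(grid, "rate") - rec$rate) < 1e-9,
              "grid/recording mismatch: sampling rates differ")
  assert_that(max(grid$end_sample) <= ncol(rec$samples),
              "grid/recording mismatch: grid extends past the recording")
  E <- nrow(grid)
  out <- matrix(NA_real_, E, length(rec$channels),
                dimnames = list(NULL, rec$channels))
  n <- params$n; tau <- params$tau
  lognf <- log(factorial(n))
  nbins <- n^n
  valid <- pattern_table(n)$codes + 1L
  for (ch in seq_along(rec$channels)) {
    x <- rec$samples[ch, ]
    for (e in seq_len(E)) {
      codes <- cpp_ordinal_codes(x[grid$start_sample[e]:grid$end_sample[e]], n, tau)
      tab <- tabulate(codes + 1L, nbins = nbins)[valid]
      p <- tab[tab > 0] / sum(tab)
      h <- 0 - sum(p * log(p))
      out[e, ch] <- if (params$normalize) h / lognf else h
    }
  }
  structure(out, params = params, class = c("pe_features", "matrix", "array"))
}

#' Write / read a feature matrix as CSV with a YAML parameter sidecar
#'
#' CSV columns: `epoch_index`, then one column per channel; the sidecar
#' `<file>.yml` records the PE parameters.
#'
#' @param features a `pe_features` matrix.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_features_csv <- function(features, file) {
  df <- data.frame(epoch_index = seq_len(nrow(features)) - 1L, features,
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  p <- attr(features, "params")
  yaml::write_yaml(list(n = p$n, tau = p$tau, normalize = p$normalize),
                   paste0(file, ".yml"))
  invisible(file)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  p <- yaml::read_yaml(paste0(file, ".yml"))
  structure(m, params = pe_params(p$n, p$tau, p$normalize),
            class = c("pe_features", "matrix", "array"))
}
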