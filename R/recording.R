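#' Multichannel PSG recording container
#'
#' A lightweight container for a multichannel polysomnography recording:
#' a channels-by-samples numeric matrix in microvolts, its sampling rate,
#' ordered unique channel labels, and optional subject/group metadata and
#' day/night intervals.
#'
#' @param samples numeric matrix, channels x samples (µV). Row names, if
#'   present, must agree with `channels`.
#' @param rate sampling rate in Hz (> 0).
#' @param channels character vector of unique channel labels, one per row.
#' @param subject optional subject identifier.
#' @param group optional group label (e.g. "healthy", "MCS", "UWS").
#' @param intervals optional data frame with columns `start_s`, `end_s`,
#'   `tag` ("day"/"night") covering sub-spans of the recording.
#' @return An object of class `psg_recording`.
#' @export
psg_recording <- function(samples, rate, channels = rownames(samples),
                          subject = NA_character_, group = NA_character_,
                          intervals = NULL) {
  assert_that(is.matrix(samples) && is.numeric(samples),
              "samples must be a numeric channels x samples matrix")
  assert_that(length(rate) == 1 && is.finite(rate) && rate > 0,
              "rate must be a positive number")
  assert_that(!is.null(channels) && length(channels) == nrow(samples),
              "one channel label per sample row is required")
  assert_that(!anyDuplicated(channels), "channel labels must be unique")
  if (!is.null(intervals)) {
    assert_that(all(c("start_s", "end_s", "tag") %in% names(intervals)),
                "intervals needs columns start_s, end_s, tag")
    dur <- ncol(samples) / rate
    assert_that(all(intervals$start_s >= 0) && all(intervals$end_s <= dur + 1e-9),
                "intervals must lie within [0, duration]")
  }
  rownames(samples) <- channels
  structure(list(samples = samples, rate = rate, channels = channels,
                 subject = subject, group = group, intervals = intervals),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("<psg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate, duration_s(x)))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  if (!is.na(x$subject)) cat("  subject:", x$subject, " group:", x$group, "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `psg_recording`.
#' @return duration in seconds.
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$rate

#' Write / read a recording as a plain numeric matrix plus JSON sidecar
#'
#' The matrix is written as headerless CSV (one row per channel) with a JSON
#' sidecar carrying the sampling rate, channel labels, metadata and intervals.
#'
#' @param rec a `psg_recording`.
#' @param prefix path prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  utils::write.table(rec$samples, paste0(prefix, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(rate = rec$rate, channels = rec$channels,
               subject = rec$subject, group = rec$group,
               intervals = rec$intervals)
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(paste0(prefix, ".csv"), sep = ","))
  dimnames(m) <- NULL
  iv <- meta$intervals
  if (!is.null(iv) && length(iv) == 0) iv <- NULL
  if (!is.null(iv)) iv <- as.data.frame(iv)
  psg_recording(m, rate = meta$rate, channels = meta$channels,
                subject = meta$subject %||% NA_character_,
                group = meta$group %||% NA_character_, intervals = iv)
}
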