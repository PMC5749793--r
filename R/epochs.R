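#' Segment a recording into consecutive 30 s epochs
#'
#' Epochs are contiguous, non-overlapping, half-open sample ranges on a
#' 0-based epoch index; a trailing partial epoch is dropped.
#'
#' @param rec a `psg_recording`.
#' @param epoch_s epoch length in seconds (default 30, the AASM grid).
#' @return An `epoch_grid`: data frame with columns `epoch` (0-based),
#'   `start_s`, `end_s`, `start_sample`, `end_sample` (half-open, 1-based
#'   start), plus attributes `rate`, `epoch_s`, `samples_per_epoch`.
#' @export
segment_epochs <- function(rec, epoch_s = 30) {
  dur <- duration_s(rec)
  assert_that(dur >= epoch_s, "recording shorter than one epoch")
  spp <- as.integer(round(epoch_s * rec$rate))
  n <- floor(ncol(rec$samples) / spp)
  g <- data.frame(epoch = seq_len(n) - 1L,
                  start_s = (seq_len(n) - 1L) * epoch_s,
                  end_s = seq_len(n) * epoch_s,
                  start_sample = (seq_len(n) - 1L) * spp + 1L,
                  end_sample = seq_len(n) * spp)
  attr(g, "rate") <- rec$rate
  attr(g, "epoch_s") <- epoch_s
  attr(g, "samples_per_epoch") <- spp
  class(g) <- c("epoch_grid", "data.frame")
  g
}

#' Tag epochs as day or night by their midpoint
#'
#' Each epoch receives the tag of the interval containing its temporal
#' midpoint; epochs whose midpoint is covered by no interval are tagged
#' `"untagged"` with a warning.
#'
#' @param grid an `epoch_grid`.
#' @param intervals data frame with columns `start_s`, `end_s`, `tag`.
#' @return Character vector of tags, one per epoch.
#' @export
split_day_night <- function(grid, intervals) {
  mid <- (grid$start_s + grid$end_s) / 2
  tag <- rep("untagged", nrow(grid))
  for (r in seq_len(nrow(intervals))) {
    inside <- mid >= intervals$start_s[r] & mid < intervals$end_s[r]
    tag[inside] <- intervals$tag[r]
  }
  if (any(tag == "untagged"))
    warning(sum(tag == "untagged"), " epoch midpoint(s) not covered by any interval")
  tag
}

#' Align 5 min eye-state video annotations to the 30 s epoch grid
#'
#' Each 5 min video label is replicated onto its ten 30 s epochs; epochs
#' beyond the annotated span are padded with NA. NA epochs (unscorable video)
#' are flagged for exclusion from quantitative evaluation.
#'
#' @param grid an `epoch_grid`.
#' @param eye_states character vector of per-5-min labels: "O", "C", "OC"
#'   or NA.
#' @return Data frame with columns `epoch`, `eye_state`, `excluded`.
#' @export
align_eye_states <- function(grid, eye_states) {
  assert_that(attr(grid, "epoch_s") == 30, "eye-state alignment assumes 30 s epochs")
  ok <- setdiff(unique(eye_states), c("O", "C", "OC"))
  assert_that(all(is.na(ok)), "eye-state labels must be O, C, OC or NA")
  per_epoch <- rep(eye_states, each = 10L)
  n <- nrow(grid)
  if (length(per_epoch) < n) per_epoch <- c(per_epoch, rep(NA_character_, n - length(per_epoch)))
  per_epoch <- per_epoch[seq_len(n)]
  data.frame(epoch = grid$epoch, eye_state = per_epoch,
             excluded = is.na(per_epoch), stringsAsFactors = FALSE)
}

#' Write an epoch tag table as CSV
#'
#' @param grid an `epoch_grid`.
#' @param day_night,eye_state,stage optional per-epoch tag vectors.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_epoch_table <- function(grid, file, day_night = NULL, eye_state = NULL,
                              stage = NULL) {
  df <- data.frame(epoch_index = grid$epoch, start_s = grid$start_s)
  if (!is.null(day_night)) df$day_night <- day_night
  if (!is.null(eye_state)) {
    df$eye_state <- eye_state
    df$excluded <- is.na(eye_state)
  }
  if (!is.null(stage)) df$stage <- stage
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
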