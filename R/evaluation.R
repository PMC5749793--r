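#' Collapse five-class stage labels to binary sleep/wake
#'
#' W maps to "wake"; N1, N2, N3 and R are jointly considered a single sleep
#' class (only a binary behavioral index — eyes open vs closed — is available
#' for validation in DOC).
#'
#' @param stages character vector of stage labels.
#' @return Character vector of "wake"/"sleep", same length.
#' @export
collapse_to_binary <- function(stages) {
  bad <- setdiff(unique(stages), STAGE_LEVELS)
  assert_that(length(bad) == 0, "unknown stage label(s): ",
              paste(bad, collapse = ", "))
  ifelse(stages == "W", "wake", "sleep")
}

#' Binary F1 of sleep predictions against eye-state annotations
#'
#' The positive class is agreement between predicted sleep and eyes closed
#' (C): TP = sleep & C, FP = sleep & not-C, FN = wake & C, TN = wake & not-C.
#' Unscorable (NA) epochs are always excluded; "OC" (switching) epochs are
#' excluded by default or counted as not-closed in strict mode. F1 =
#' 2 * precision * recall / (precision + recall); when no positive epochs
#' exist on either side the score is undefined and flagged.
#'
#' Caveat surfaced in every report: wake with closed eyes is counted as a
#' false negative under this behavioral proxy even though the prediction may
#' be right — the eyes provide only a coarse index of wakefulness.
#'
#' @param pred character vector of "sleep"/"wake" per 30 s epoch (use
#'   [collapse_to_binary()] first).
#' @param eyes character vector per 30 s epoch: "O", "C", "OC" or NA (use
#'   [align_eye_states()] to expand 5 min annotations).
#' @param oc_policy "exclude" (default) or "as_open" (strict: OC counts as
#'   not-closed).
#' @return A `binary_validation` list: confusion counts, precision, recall,
#'   `f1`, `undefined` flag and exclusion bookkeeping.
#' @export
binary_f1 <- function(pred, eyes, oc_policy = c("exclude", "as_open")) {
  oc_policy <- match.arg(oc_policy)
  assert_that(length(pred) == length(eyes),
              "prediction and eye-state sequences must be aligned")
  assert_that(all(pred %in% c("sleep", "wake")),
              "predictions must be 'sleep'/'wake'")
  n_na <- sum(is.na(eyes))
  n_oc <- sum(eyes == "OC", na.rm = TRUE)
  include <- !is.na(eyes) & (eyes != "OC" | oc_policy == "as_open")
  p <- pred[include]; e <- eyes[include]
  tp <- sum(p == "sleep" & e == "C")
  fp <- sum(p == "sleep" & e != "C")
  fn <- sum(p == "wake" & e == "C")
  tn <- sum(p == "wake" & e != "C")
  undefined <- (tp + fp + fn) == 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (undefined) NA_real_
        else if (precision + recall > 0) 2 * precision * recall / (precision + recall)
        else 0
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall, f1 = f1,
                 undefined = undefined, n_included = sum(include),
                 n_excluded_na = n_na, n_oc = n_oc, oc_policy = oc_policy,
                 note = paste("wake-with-closed-eyes counts as a false negative",
                              "under the eye-state proxy")),
            class = "binary_validation")
}

#' @export
print.binary_validation <- function(x, ...) {
  cat(sprintf("<binary_validation> F1 %.3f (precision %.3f, recall %.3f); %d epochs included, %d NA excluded, %d O/C\n",
              x$f1, x$precision, x$recall, x$n_included, x$n_excluded_na, x$n_oc))
  invisible(x)
}

#' Cohort-level summary of per-subject binary F1 scores
#'
#' Median and unscaled median absolute deviation across subjects, with mean
#' and SD alongside, split by patient group when provided, plus lists of
#' high (F1 >= 0.75) and low (F1 <= 0.3) performers.
#'
#' @param f1 numeric vector of per-subject F1 scores.
#' @param subjects optional subject ids.
#' @param groups optional group labels (e.g. MCS/UWS) for stratified summaries.
#' @return A `cohort_report` list.
#' @export
cohort_report <- function(f1, subjects = NULL, groups = NULL) {
  assert_that(length(f1) >= 1, "empty F1 list")
  subjects <- subjects %||% sprintf("S%02d", seq_along(f1))
  summ <- function(v) list(median = stats::median(v),
                           mad = stats::mad(v, constant = 1),
                           mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
                           n = length(v))
  per_group <- NULL
  if (!is.null(groups))
    per_group <- lapply(split(f1, groups), summ)
  structure(list(overall = summ(f1), per_group = per_group,
                 subjects = subjects, f1 = f1,
                 high_performers = subjects[f1 >= 0.75 & !is.na(f1)],
                 low_performers = subjects[f1 <= 0.3 & !is.na(f1)]),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf("<cohort_report> %d subjects: median F1 %.3f (MAD %.3f), mean %.3f (SD %.3f)\n",
              o$n, o$median, o$mad, o$mean, o$sd))
  invisible(x)
}

#' Export an annotated hypnogram as CSV
#'
#' One row per 30 s epoch: predicted stage, collapsed binary label, eye
#' state (NA stretches flagged not-scorable), day/night tag and inclusion
#' flag. 120 epochs correspond to one hour.
#'
#' @param stages predicted stage labels per epoch.
#' @param eyes per-epoch eye states ("O","C","OC",NA), aligned.
#' @param day_night per-epoch day/night tags, aligned.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
export_hypnogram <- function(stages, eyes, day_night, file) {
  assert_that(length(stages) == length(eyes) && length(stages) == length(day_night),
              "misaligned sequences")
  df <- data.frame(epoch_index = seq_along(stages) - 1L,
                   stage = stages,
                   binary = collapse_to_binary(stages),
                   eye_state = ifelse(is.na(eyes), "NA", eyes),
                   day_night = day_night,
                   included = !is.na(eyes),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname export_hypnogram
#' @export
read_hypnogram <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  df$eye_state[df$eye_state == "NA"] <- NA_character_
  df
}
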