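#' Cut per-trial epochs from a preprocessed trace
#'
#' Extracts, for every event, the samples with onset + span[1] <= t <
#' onset + span[2] and re-times them relative to stimulus onset. The default
#' span \[-500, 3000) ms contains the 500-ms pre-stimulus baseline, every
#' task's summary window and the latest effects seen in condition
#' contrasts; overlap with the following trial is harmless because analyses
#' only read defined windows. Epochs that run over a recording edge (fewer
#' samples than the full grid) are dropped with a message.
#'
#' @param trace Preprocessed mono trace ([interpolate_linear()] applied).
#' @param events Event tibble for the same subject and task.
#' @param span Numeric `c(start_ms, end_ms)` relative to onset.
#' @return A long tibble with one row per epoch sample: `subject_id`,
#'   `task`, `trial_index`, `block`, `condition`, `correct`, `rt_ms`,
#'   `rel_time_ms`, `diameter_mm`, `interpolated`. Attribute `rate_hz` is
#'   carried over; attribute `n_dropped_edge` counts dropped edge epochs.
#' @export
epoch_trace <- function(trace, events, span = c(-500, 3000)) {
  check_window(span, "span")
  if (nrow(events) == 0) abort("no events to epoch")
  rate <- attr(trace, "rate_hz") %||% 60
  idx <- purrr::map(events$onset_ms, function(on) {
    which(in_window(trace$time_ms - on, span))
  })
  lens <- lengths(idx)
  short <- lens < max(lens)
  if (any(short)) {
    inform(sprintf("dropping %d epoch(s) overlapping the recording edge", sum(short)))
    idx <- idx[!short]
    lens <- lens[!short]
  }
  keep <- which(!short)
  flat <- unlist(idx, use.names = FALSE)
  out <- tibble::tibble(
    subject_id = rep(events$subject_id[keep], lens),
    task = rep(events$task[keep], lens),
    trial_index = rep(events$trial_index[keep], lens),
    block = rep(events$block[keep], lens),
    condition = rep(events$condition[keep], lens),
    correct = rep(events$correct[keep], lens),
    rt_ms = rep(events$rt_ms[keep], lens),
    rel_time_ms = round(trace$time_ms[flat] - rep(events$onset_ms[keep], lens), 6),
    diameter_mm = trace$diameter_mm[flat],
    interpolated = trace$interpolated[flat]
  )
  attr(out, "rate_hz") <- rate
  attr(out, "n_dropped_edge") <- sum(short)
  out
}

#' Baseline-correct epochs
#'
#' Subtracts from every sample of an epoch the mean pupil diameter recorded
#' in the pre-stimulus baseline interval (default the 500 ms before onset),
#' turning absolute diameter into task-evoked dilation. Epochs whose
#' baseline interval contains no samples are dropped with a message.
#'
#' @param epochs Long epoch tibble from [epoch_trace()].
#' @param baseline Numeric `c(start_ms, end_ms)` relative to onset
#'   (default `c(-500, 0)`).
#' @return The tibble with added columns `baseline_mm` (the subtracted
#'   per-epoch mean) and `dilation_mm`. Within each epoch the mean of
#'   `dilation_mm` over the baseline interval is 0 (to rounding).
#' @export
baseline_correct <- function(epochs, baseline = c(-500, 0)) {
  check_window(baseline, "baseline")
  keys <- c("subject_id", "task", "trial_index")
  bl <- epochs |>
    dplyr::filter(in_window(.data$rel_time_ms, baseline)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(baseline_mm = mean(.data$diameter_mm), .groups = "drop")
  out <- epochs |>
    dplyr::left_join(bl, by = keys) |>
    dplyr::mutate(dilation_mm = .data$diameter_mm - .data$baseline_mm)
  nob <- is.na(out$baseline_mm)
  if (any(nob)) {
    dropped <- dplyr::distinct(out[nob, c("subject_id", "task", "trial_index")])
    inform(sprintf("dropping %d epoch(s) with an empty baseline interval", nrow(dropped)))
    out <- out[!nob, ]
  }
  for (a in c("rate_hz", "n_dropped_edge")) attr(out, a) <- attr(epochs, a)
  out
}

#' Flag epochs for exclusion by interpolated-data fraction
#'
#' A trial is excluded when more than `threshold` of the samples in its
#' baseline interval and/or in its summary window were interpolated
#' (i.e. `frac > threshold` in either interval; a fraction of exactly
#' `threshold` is kept). The default threshold 0.70 balances data loss
#' against artifact inclusion; 0.50 is a stricter variant that discards
#' considerably more trials.
#'
#' @param epochs Long epoch tibble (baseline-corrected or not).
#' @param window Summary window `c(start_ms, end_ms)` relative to onset,
#'   e.g. [task_window()].
#' @param threshold Maximum tolerated interpolated fraction (default 0.70).
#' @param baseline Baseline interval (default `c(-500, 0)`).
#' @return One row per epoch: identifiers, `condition`, `correct`, `rt_ms`,
#'   `frac_interp_baseline`, `frac_interp_window`, `included`.
#' @export
apply_exclusion <- function(epochs, window, threshold = 0.70, baseline = c(-500, 0)) {
  check_window(window)
  check_window(baseline, "baseline")
  stopifnot(threshold >= 0, threshold <= 1)
  epochs |>
    dplyr::group_by(.data$subject_id, .data$task, .data$trial_index,
                    .data$block, .data$condition, .data$correct, .data$rt_ms) |>
    dplyr::summarise(
      frac_interp_baseline = frac_in(.data$interpolated, .data$rel_time_ms, baseline),
      frac_interp_window = frac_in(.data$interpolated, .data$rel_time_ms, window),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      included = !(.data$frac_interp_baseline > threshold |
                     .data$frac_interp_window > threshold)
    )
}

# interpolated fraction over rel-time interval [w1, w2); NA when empty
frac_in <- function(flag, rel, window) {
  inw <- in_window(rel, window)
  if (!any(inw)) return(NA_real_)
  mean(flag[inw])
}

#' Per-epoch mean dilation in a summary window
#'
#' Averages baseline-corrected dilation over the 500-ms summary window of
#' each included epoch; the per-trial scalar all individual-differences
#' analyses consume.
#'
#' @param epochs Baseline-corrected long epoch tibble.
#' @param window Summary window `c(start_ms, end_ms)` relative to onset.
#' @param inclusion Optional tibble from [apply_exclusion()]; when given,
#'   excluded epochs are refused (an error names the first one) unless they
#'   are first filtered out by the caller.
#' @return One row per epoch with `window_mean_mm` plus identifiers.
#' @export
window_mean <- function(epochs, window, inclusion = NULL) {
  check_window(window)
  if (!is.null(inclusion)) {
    excl <- inclusion[!inclusion$included, ]
    present <- dplyr::semi_join(
      excl, dplyr::distinct(epochs[, c("subject_id", "task", "trial_index")]),
      by = c("subject_id", "task", "trial_index")
    )
    if (nrow(present) > 0) {
      abort(sprintf(
        "epoch subject %s task %s trial %d is excluded (interpolated fraction %.2f baseline / %.2f window); filter it out before window_mean()",
        present$subject_id[1], present$task[1], present$trial_index[1],
        present$frac_interp_baseline[1], present$frac_interp_window[1]
      ))
    }
  }
  epochs |>
    dplyr::filter(in_window(.data$rel_time_ms, window)) |>
    dplyr::group_by(.data$subject_id, .data$task, .data$trial_index,
                    .data$block, .data$condition, .data$correct, .data$rt_ms) |>
    dplyr::summarise(window_mean_mm = mean(.data$dilation_mm), .groups = "drop")
}

#' Keep only included epochs
#'
#' Convenience filter joining the long epoch tibble against an inclusion
#' table from [apply_exclusion()].
#'
#' @param epochs Long epoch tibble.
#' @param inclusion Tibble from [apply_exclusion()].
#' @return The epochs of included trials only.
#' @export
filter_included <- function(epochs, inclusion) {
  keep <- inclusion[inclusion$included, c("subject_id", "task", "trial_index")]
  out <- dplyr::semi_join(epochs, keep, by = c("subject_id", "task", "trial_index"))
  for (a in c("rate_hz", "n_dropped_edge")) attr(out, a) <- attr(epochs, a)
  out
}
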