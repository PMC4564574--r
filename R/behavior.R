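#' Score 2-Back trials
#'
#' Labels every trial of a 2-Back event table: trial t (0-based within
#' block) is a `match` when its letter equals the letter at t - 2 in the
#' same block, otherwise `nonmatch`; the first two trials of each block
#' have no t - 2 and are non-scorable. Each trial is also an encoding
#' trial: `encoding_ok` is the correctness of the response at t + 2 (its
#' target), defined only where t + 2 exists.
#'
#' @param events Event tibble for the 2-Back task with `stimulus` letters
#'   and `correct` flags, ordered by trial within block.
#' @return The tibble with added `condition` (`match`/`nonmatch`),
#'   `scorable` and `encoding_ok` columns.
#' @export
score_2back <- function(events) {
  stopifnot(all(events$task == "2back"))
  events |>
    dplyr::group_by(.data$subject_id, .data$block) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::mutate(
      scorable = dplyr::row_number() > 2,
      condition = dplyr::if_else(
        .data$scorable,
        dplyr::if_else(.data$stimulus == dplyr::lag(.data$stimulus, 2),
                       "match", "nonmatch"),
        NA_character_
      ),
      encoding_ok = dplyr::lead(.data$correct, 2)
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$subject_id, .data$block, .data$trial_index)
}

#' Flag reaction times below the floor
#'
#' Anticipatory responses: RTs strictly below `floor_ms` are flagged for
#' exclusion, on the 2-Back and Number Switch tasks only (the Stroop task
#' is exempt). An RT of exactly `floor_ms` is kept.
#'
#' @param records Trial tibble with `task` and `rt_ms`.
#' @param floor_ms RT floor in ms (default 300).
#' @param tasks Tasks in scope (default `c("2back", "switch")`).
#' @return The tibble with a logical `rt_floor_excluded` column (always
#'   `FALSE` where `rt_ms` is absent or the task is out of scope).
#' @export
filter_rt_floor <- function(records, floor_ms = 300, tasks = c("2back", "switch")) {
  records |>
    dplyr::mutate(
      rt_floor_excluded = .data$task %in% tasks &
        !is.na(.data$rt_ms) & .data$rt_ms < floor_ms
    )
}

#' Flag reaction-time outliers at k standard deviations
#'
#' Within each subject-by-condition cell, flags correct-trial RTs deviating
#' more than `k` SDs from that cell's mean (mean and SD computed from the
#' cell's surviving correct RTs before any flagging; a single pass, no
#' iteration). Applied to the Stroop and Number Switch tasks; cells with
#' zero SD flag nothing. Trials already flagged by [filter_rt_floor()] are
#' not part of the reference statistics.
#'
#' @param records Trial tibble with `task`, `condition`, `correct`, `rt_ms`
#'   and (optionally) `rt_floor_excluded`.
#' @param k SD multiplier (default 3).
#' @param tasks Tasks in scope (default `c("stroop", "switch")`).
#' @return The tibble with a logical `rt_sd_excluded` column.
#' @export
filter_rt_sd <- function(records, k = 3, tasks = c("stroop", "switch")) {
  if (!"rt_floor_excluded" %in% names(records)) records$rt_floor_excluded <- FALSE
  records |>
    dplyr::group_by(.data$subject_id, .data$task, .data$condition) |>
    dplyr::mutate(
      rt_sd_excluded = {
        eligible <- .data$task %in% tasks & .data$correct %in% TRUE &
          !is.na(.data$rt_ms) & !.data$rt_floor_excluded & !is.na(.data$condition)
        m <- mean(.data$rt_ms[eligible])
        s <- stats::sd(.data$rt_ms[eligible])
        if (sum(eligible) < 2 || is.na(s) || s == 0) {
          rep(FALSE, dplyr::n())
        } else {
          eligible & abs(.data$rt_ms - m) > k * s
        }
      }
    ) |>
    dplyr::ungroup()
}

#' Flag between-subject outliers per measure
#'
#' Flags subjects whose value on a measure deviates more than `k` SDs from
#' the across-subject mean. Exclusion is per measure: a subject flagged on
#' one measure stays in analyses of every other measure.
#'
#' @param measures Tibble with `subject_id` and one or more numeric measure
#'   columns.
#' @param vars Character vector of measure columns to screen (default: all
#'   numeric columns).
#' @param k SD multiplier (default 3).
#' @return A long tibble `subject_id`, `measure`, `value`, `outlier`.
#' @export
subject_outliers <- function(measures, vars = NULL, k = 3) {
  if (is.null(vars)) {
    vars <- names(measures)[purrr::map_lgl(measures, is.numeric)]
    vars <- setdiff(vars, "subject_id")
  }
  if (dplyr::n_distinct(measures$subject_id) < 3) {
    abort("subject_outliers needs at least 3 subjects")
  }
  measures |>
    dplyr::select("subject_id", dplyr::all_of(vars)) |>
    tidyr::pivot_longer(-"subject_id", names_to = "measure", values_to = "value") |>
    dplyr::group_by(.data$measure) |>
    dplyr::mutate(
      outlier = {
        m <- mean(.data$value, na.rm = TRUE)
        s <- stats::sd(.data$value, na.rm = TRUE)
        if (is.na(s) || s == 0) rep(FALSE, dplyr::n())
        else !is.na(.data$value) & abs(.data$value - m) > k * s
      }
    ) |>
    dplyr::ungroup()
}

#' Square-root transform of error counts
#'
#' Error counts are right-skewed (mass near zero); the square root pulls
#' the tail in and normalizes the distribution for correlation and
#' regression analyses.
#'
#' @param x Non-negative numeric vector of counts.
#' @return `sqrt(x)`.
#' @export
sqrt_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort("error counts must be non-negative")
  sqrt(x)
}

# shared helper: drop flagged trials, keep scorable ones
surviving <- function(records) {
  if (!"rt_floor_excluded" %in% names(records)) records$rt_floor_excluded <- FALSE
  if (!"rt_sd_excluded" %in% names(records)) records$rt_sd_excluded <- FALSE
  dplyr::filter(records, !.data$rt_floor_excluded, !.data$rt_sd_excluded,
                !is.na(.data$condition))
}

#' Per-subject Stroop interference effect
#'
#' RT effect: mean correct incongruent RT minus mean correct congruent RT
#' on surviving trials. Error effect: incongruent minus congruent error
#' percentage (all surviving trials as denominator per condition).
#'
#' @param records Scored Stroop trial tibble (after the RT filters).
#' @return One row per subject: `rt_effect_ms`, `error_effect_pct`, plus
#'   the per-condition means `rt_congruent`, `rt_incongruent`,
#'   `err_congruent_pct`, `err_incongruent_pct`.
#' @export
stroop_effect <- function(records) {
  recs <- surviving(dplyr::filter(records, .data$task == "stroop"))
  out <- recs |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::summarise(
      rt = mean(.data$rt_ms[.data$correct %in% TRUE]),
      err_pct = 100 * mean(!(.data$correct %in% TRUE)),
      n_correct = sum(.data$correct %in% TRUE),
      .groups = "drop"
    )
  empty <- out$subject_id[out$n_correct == 0]
  if (length(empty) > 0) {
    abort(sprintf("no surviving correct trials in a condition for subject(s): %s",
                  paste(unique(empty), collapse = ", ")))
  }
  out |>
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "condition",
                       values_from = c("rt", "err_pct")) |>
    dplyr::transmute(
      subject_id = .data$subject_id,
      rt_congruent = .data$rt_congruent,
      rt_incongruent = .data$rt_incongruent,
      err_congruent_pct = .data$err_pct_congruent,
      err_incongruent_pct = .data$err_pct_incongruent,
      rt_effect_ms = .data$rt_incongruent - .data$rt_congruent,
      error_effect_pct = .data$err_pct_incongruent - .data$err_pct_congruent
    )
}

#' Per-subject switch cost
#'
#' On the mixed blocks only: RT cost is mean correct switch RT minus mean
#' correct non-switch RT; `correct_cost` is the difference in
#' correct-response rates (switch minus non-switch). Trials are labelled
#' `switch` when their cue color differs from the previous trial's; the
#' first mixed-block trial has no predecessor and enters neither category.
#'
#' @param records Scored Number Switch trial tibble (after the RT filters),
#'   with `condition` in `switch`/`nonswitch` on mixed-block trials.
#' @return One row per subject: `rt_cost_ms`, `correct_cost`, plus
#'   per-condition means.
#' @export
switch_cost <- function(records) {
  recs <- surviving(dplyr::filter(records, .data$task == "switch",
                                  .data$condition %in% c("switch", "nonswitch")))
  out <- recs |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::summarise(
      rt = mean(.data$rt_ms[.data$correct %in% TRUE]),
      correct_rate = mean(.data$correct %in% TRUE),
      n_correct = sum(.data$correct %in% TRUE),
      .groups = "drop"
    )
  empty <- out$subject_id[out$n_correct == 0]
  if (length(empty) > 0) {
    abort(sprintf("no surviving correct trials in a condition for subject(s): %s",
                  paste(unique(empty), collapse = ", ")))
  }
  out |>
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "condition",
                       values_from = c("rt", "correct_rate")) |>
    dplyr::transmute(
      subject_id = .data$subject_id,
      rt_nonswitch = .data$rt_nonswitch,
      rt_switch = .data$rt_switch,
      correct_rate_nonswitch = .data$correct_rate_nonswitch,
      correct_rate_switch = .data$correct_rate_switch,
      rt_cost_ms = .data$rt_switch - .data$rt_nonswitch,
      correct_cost = .data$correct_rate_switch - .data$correct_rate_nonswitch
    )
}

#' Per-subject descriptives per task and condition
#'
#' Error percentage (scorable surviving trials as denominator) and mean
#' correct RT per subject, task and condition, mirroring a descriptives
#' table; conditionless rows (e.g. the whole 2-Back task) use the task
#' total.
#'
#' @param records Scored trial tibble for any subset of tasks.
#' @return Tibble `subject_id`, `task`, `condition` (`"all"` for task
#'   totals), `n_trials`, `error_pct`, `mean_rt_ms`.
#' @export
subject_measures <- function(records) {
  recs <- surviving(records)
  per_cond <- recs |>
    dplyr::group_by(.data$subject_id, .data$task, .data$condition) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      error_pct = 100 * mean(!(.data$correct %in% TRUE)),
      mean_rt_ms = mean(.data$rt_ms[.data$correct %in% TRUE]),
      .groups = "drop"
    )
  totals <- recs |>
    dplyr::group_by(.data$subject_id, .data$task) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      error_pct = 100 * mean(!(.data$correct %in% TRUE)),
      mean_rt_ms = mean(.data$rt_ms[.data$correct %in% TRUE]),
      .groups = "drop"
    ) |>
    dplyr::mutate(condition = "all")
  dplyr::bind_rows(per_cond, totals) |>
    dplyr::arrange(.data$subject_id, .data$task, .data$condition)
}
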