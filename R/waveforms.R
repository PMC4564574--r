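#' Per-subject condition-mean waveforms
#'
#' Averages baseline-corrected dilation over a subject's included trials of
#' each condition, sample by sample. By default only correct trials enter,
#' matching the condition contrasts of interest; set `correct_only = FALSE`
#' for error-related analyses.
#'
#' @param epochs Baseline-corrected long epoch tibble (already filtered to
#'   included trials, see [filter_included()]).
#' @param correct_only Keep correct trials only (default `TRUE`).
#' @param min_trials Minimum trials a subject must contribute per condition
#'   (default 1); cells below it are dropped.
#' @return Tibble `subject_id`, `condition`, `rel_time_ms`, `mean_mm`,
#'   `n_trials`.
#' @export
subject_waveforms <- function(epochs, correct_only = TRUE, min_trials = 1) {
  if (correct_only) epochs <- dplyr::filter(epochs, .data$correct %in% TRUE)
  if (nrow(epochs) == 0) abort("no epochs left to average")
  out <- epochs |>
    dplyr::group_by(.data$subject_id, .data$condition, .data$rel_time_ms) |>
    dplyr::summarise(
      mean_mm = mean(.data$dilation_mm),
      n_trials = dplyr::n_distinct(.data$trial_index),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_trials >= min_trials)
  attr(out, "rate_hz") <- attr(epochs, "rate_hz")
  out
}

#' Grand-average waveform across subjects
#'
#' Pointwise mean and standard error over subjects of the per-subject
#' condition means; the curves plotted in waveform figures.
#'
#' @param waveforms Tibble from [subject_waveforms()].
#' @return Tibble `condition`, `rel_time_ms`, `mean_mm`, `sem_mm`,
#'   `n_subjects`.
#' @export
grand_average <- function(waveforms) {
  grids <- waveforms |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::summarise(key = paste(.data$rel_time_ms, collapse = ","), .groups = "drop")
  if (dplyr::n_distinct(grids$key) > 1) {
    abort("rel_time grids differ across subjects/conditions; cannot align")
  }
  if (dplyr::n_distinct(waveforms$subject_id) < 2) {
    abort("grand_average needs at least 2 subjects")
  }
  waveforms |>
    dplyr::group_by(.data$condition, .data$rel_time_ms) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      sem_mm = stats::sd(.data$mean_mm) / sqrt(.data$n_subjects[1]),
      mean_mm = mean(.data$mean_mm),
      .groups = "drop"
    ) |>
    dplyr::select("condition", "rel_time_ms", "mean_mm", "sem_mm", "n_subjects")
}

#' Sample-wise paired t-tests between two conditions
#'
#' At every time sample, a two-tailed paired t-test across subjects on the
#' subject-level condition means (condition A minus condition B), df = n-1.
#' A zero-variance difference with non-zero mean is reported as t = +/-Inf,
#' p = 0 (the limiting case); an identically zero difference as t = 0,
#' p = 1.
#'
#' @param waveforms Tibble from [subject_waveforms()].
#' @param cond_a,cond_b Condition labels to contrast (A minus B).
#' @param on_unpaired What to do with subjects present in only one
#'   condition: `"error"` (default) names them and aborts; `"drop"` removes
#'   them from the contrast with a message.
#' @return Tibble `rel_time_ms`, `mean_diff_mm`, `t`, `df`, `p`.
#' @export
samplewise_paired_t <- function(waveforms, cond_a, cond_b,
                                on_unpaired = c("error", "drop")) {
  on_unpaired <- match.arg(on_unpaired)
  wide <- waveforms |>
    dplyr::filter(.data$condition %in% c(cond_a, cond_b)) |>
    dplyr::select("subject_id", "condition", "rel_time_ms", "mean_mm") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_mm")
  unpaired <- unique(wide$subject_id[is.na(wide[[cond_a]]) | is.na(wide[[cond_b]])])
  if (length(unpaired) > 0) {
    if (on_unpaired == "error") {
      abort(sprintf("subject(s) present in only one condition: %s",
                    paste(unpaired, collapse = ", ")))
    }
    inform(sprintf("dropping subject(s) present in only one condition: %s",
                   paste(unpaired, collapse = ", ")))
    wide <- wide[!(wide$subject_id %in% unpaired), ]
  }
  n <- dplyr::n_distinct(wide$subject_id)
  if (n < 3) abort("samplewise_paired_t needs at least 3 subjects")
  out <- wide |>
    dplyr::mutate(diff = .data[[cond_a]] - .data[[cond_b]]) |>
    dplyr::group_by(.data$rel_time_ms) |>
    dplyr::summarise(
      mean_diff_mm = mean(.data$diff),
      sd_diff = stats::sd(.data$diff),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      df = .data$n - 1,
      t = dplyr::case_when(
        .data$sd_diff > 0 ~ .data$mean_diff_mm / (.data$sd_diff / sqrt(.data$n)),
        .data$mean_diff_mm == 0 ~ 0,
        TRUE ~ sign(.data$mean_diff_mm) * Inf
      ),
      p = dplyr::if_else(is.infinite(.data$t), 0,
                         2 * stats::pt(abs(.data$t), df = .data$df, lower.tail = FALSE))
    ) |>
    dplyr::select("rel_time_ms", "mean_diff_mm", "t", "df", "p")
  out
}

#' Contiguity-thresholded cluster detection
#'
#' Finds maximal runs of consecutive samples whose p-values fall below
#' `alpha` and keeps runs of at least `min_run` samples; the contiguity
#' requirement controls the multiple comparisons implicit in testing every
#' sample. Cluster bounds are the times of the first and last member
#' sample.
#'
#' @param tests Tibble from [samplewise_paired_t()] (needs `rel_time_ms`,
#'   `p` and optionally `t`), ordered by time.
#' @param alpha Per-sample significance threshold (default 0.001).
#' @param min_run Minimum cluster length in samples (default 6).
#' @return A tibble of class `pupil_clusters`: `cluster`, `start_ms`,
#'   `end_ms`, `n_samples`, `mean_t`, `min_p`; zero rows when nothing
#'   survives. Attributes `alpha` and `min_run` record the rule.
#' @export
#' @examples
#' p <- c(rep(0.5, 4), rep(1e-4, 6), 0.5)
#' detect_clusters(tibble::tibble(
#'   rel_time_ms = seq_along(p) * 16.7, t = 5, p = p
#' ))
detect_clusters <- function(tests, alpha = 0.001, min_run = 6) {
  stopifnot(all(is.finite(tests$p) | tests$p == 0))
  tests <- dplyr::arrange(tests, .data$rel_time_ms)
  sig <- tests$p < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  out <- tibble::tibble(
    cluster = seq_len(sum(keep)),
    start_ms = tests$rel_time_ms[starts[keep]],
    end_ms = tests$rel_time_ms[ends[keep]],
    n_samples = r$lengths[keep],
    mean_t = purrr::map2_dbl(starts[keep], ends[keep], function(a, b) {
      if ("t" %in% names(tests)) mean(tests$t[a:b]) else NA_real_
    }),
    min_p = purrr::map2_dbl(starts[keep], ends[keep], function(a, b) min(tests$p[a:b]))
  )
  attr(out, "alpha") <- alpha
  attr(out, "min_run") <- min_run
  class(out) <- c("pupil_clusters", class(out))
  out
}

#' @export
print.pupil_clusters <- function(x, ...) {
  cat(sprintf("Significant clusters (p < %g, >= %d contiguous samples): %d\n",
              attr(x, "alpha"), attr(x, "min_run"), nrow(x)))
  if (nrow(x) > 0) print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Select a summary window on the sample grid
#'
#' Scans every window of `width_ms` on the grid, keeps those containing the
#' global peak of the grand-average curve, and among them returns the one
#' maximizing the mean |t| (two-condition tasks) or the mean of the curve
#' itself when no t series is given (single-condition task). Ties on the
#' sensitivity score break to the window with the larger mean of the curve,
#' then to the earliest start. Used to reproduce how fixed summary windows were
#' chosen; routine analyses use [task_window()] defaults.
#'
#' @param curve Tibble with `rel_time_ms` and `mean_mm` (a grand average or
#'   a condition difference).
#' @param tests Optional tibble with `rel_time_ms` and `t` on the same grid.
#' @param width_ms Window width (default 500).
#' @return Numeric `c(start_ms, end_ms)` where end is start + `width_ms`.
#' @export
select_window <- function(curve, tests = NULL, width_ms = 500) {
  curve <- dplyr::arrange(curve, .data$rel_time_ms)
  tt <- curve$rel_time_ms
  if (max(tt) - min(tt) < width_ms) abort("grid shorter than the window width")
  score <- if (is.null(tests)) {
    curve$mean_mm
  } else {
    tests <- dplyr::arrange(tests, .data$rel_time_ms)
    if (!isTRUE(all.equal(tests$rel_time_ms, tt))) abort("t series grid differs from curve grid")
    abs(tests$t)
  }
  peak_i <- which.max(curve$mean_mm)
  starts <- which(tt <= tt[length(tt)] - width_ms + 1e-9)
  wins <- purrr::map(starts, function(s) {
    which(tt >= tt[s] & tt < tt[s] + width_ms)
  })
  contains <- purrr::map_lgl(wins, function(w) peak_i %in% w)
  if (!any(contains)) {
    warn("peak lies at a grid edge; widening search to the nearest feasible windows")
    # fall back to the windows closest to the peak
    dist <- purrr::map_dbl(wins, function(w) min(abs(tt[w] - tt[peak_i])))
    contains <- dist == min(dist)
  }
  cand <- which(contains)
  primary <- purrr::map_dbl(wins[cand], function(w) mean(score[w]))
  # ties on sensitivity break to the window with the larger mean dilation,
  # then to the earliest start
  top <- which(primary > max(primary) - 1e-12)
  secondary <- purrr::map_dbl(wins[cand[top]], function(w) mean(curve$mean_mm[w]))
  best <- cand[top[which.max(secondary)]]  # which.max takes the first = earliest
  c(tt[best], tt[best] + width_ms)
}
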