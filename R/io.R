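#' Read an eye-tracker pupil sample table
#'
#' Reads a tab-separated sample export with one row per eye-tracker sample
#' and columns `time_ms`, `left_mm`, `right_mm`, `left_valid`, `right_valid`.
#' Timestamps must be strictly increasing and roughly regular at the nominal
#' sampling rate (inter-sample intervals within 20% of `1000 / rate_hz`);
#' diameters must be positive wherever the corresponding validity flag is
#' set. Violations are reported with the offending row number.
#'
#' @param path Path to a tab-separated sample file with a header row.
#' @param rate_hz Nominal sampling rate in Hz (60 for a Tobii T120 stream).
#' @return A tibble with columns `time_ms` (double), `left_mm`, `right_mm`
#'   (double, `NA` allowed where invalid), `left_valid`, `right_valid`
#'   (logical), carrying the nominal rate in attribute `rate_hz`.
#' @seealso [write_pupil_samples()], [combine_eyes()]
#' @export
read_pupil_samples <- function(path, rate_hz = 60) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_pupil_samples(as_sample_table(raw, file = path), rate_hz = rate_hz)
}

# coerce character columns from disk to the sample schema
as_sample_table <- function(raw, file = "<samples>") {
  need <- c("time_ms", "left_mm", "right_mm", "left_valid", "right_valid")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing sample column(s): %s", file, paste(miss, collapse = ", ")))
  }
  tibble::tibble(
    time_ms     = num_col(raw$time_ms),
    left_mm     = num_col(raw$left_mm),
    right_mm    = num_col(raw$right_mm),
    left_valid  = as_flag(raw$left_valid),
    right_valid = as_flag(raw$right_valid)
  )
}

num_col <- function(x) {
  if (is.character(x)) x <- dplyr::na_if(x, "")
  as.double(x)
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1")] <- TRUE
  out[x %in% c("FALSE", "F", "0")] <- FALSE
  out
}

#' Validate a sample table against its invariants
#'
#' @param samples A sample tibble as returned by [read_pupil_samples()].
#' @param rate_hz Nominal sampling rate in Hz.
#' @param jitter Allowed relative deviation of inter-sample intervals from
#'   the nominal period (default 0.2).
#' @return The validated tibble (invisibly identical), with `rate_hz` attached.
#' @export
validate_pupil_samples <- function(samples, rate_hz = 60, jitter = 0.2) {
  stopifnot(is.data.frame(samples))
  samples <- as_sample_table(samples)
  bad_time <- which(!is.finite(samples$time_ms))
  if (length(bad_time) > 0) {
    abort(sprintf("non-numeric time_ms at row %d", bad_time[1]))
  }
  if (nrow(samples) > 1) {
    dt <- diff(samples$time_ms)
    nonmono <- which(dt <= 0)
    if (length(nonmono) > 0) {
      abort(sprintf("time_ms not strictly increasing at row %d", nonmono[1] + 1L))
    }
    period <- 1000 / rate_hz
    off <- which(abs(dt - period) > jitter * period)
    if (length(off) > 0) {
      warn(sprintf(
        "%d inter-sample interval(s) deviate more than %.0f%% from the nominal %.2f ms (first at row %d)",
        length(off), 100 * jitter, period, off[1] + 1L
      ))
    }
  }
  for (eye in c("left", "right")) {
    d <- samples[[paste0(eye, "_mm")]]
    v <- samples[[paste0(eye, "_valid")]]
    bad <- which(v & (!is.finite(d) | d <= 0))
    if (length(bad) > 0) {
      abort(sprintf("%s eye marked valid but diameter missing or non-positive at row %d", eye, bad[1]))
    }
  }
  attr(samples, "rate_hz") <- rate_hz
  samples
}

#' Write a pupil sample table
#'
#' Inverse of [read_pupil_samples()]: tab-separated, header row, `"."`
#' decimal, empty string for absent diameters. Round-trips values exactly
#' (full double precision).
#'
#' @param samples Sample tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pupil_samples <- function(samples, path) {
  out <- tibble::tibble(
    time_ms     = num_chr(samples$time_ms),
    left_mm     = num_chr(samples$left_mm),
    right_mm    = num_chr(samples$right_mm),
    left_valid  = as.character(samples$left_valid),
    right_valid = as.character(samples$right_valid)
  )
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

# full-precision, locale-independent number formatting ("." decimal)
num_chr <- function(x) {
  out <- formatC(x, format = "g", digits = 17)
  out <- trimws(out)
  out[is.na(x)] <- NA_character_
  out
}

#' Read a behavioral event table
#'
#' Reads a tab-separated trial/event export with columns `subject_id`,
#' `task`, `trial_index`, `block`, `onset_ms`, `condition`, `stimulus`,
#' `response`, `correct`, `rt_ms`. Empty strings encode absent values
#' (e.g. no response given). Onsets must increase within subject and task;
#' `task` must be one of `2back`, `stroop`, `switch`.
#'
#' @param path Path to a tab-separated event file with a header row.
#' @return A tibble with typed columns (`correct` logical, `rt_ms` double).
#' @seealso [write_pupil_events()]
#' @export
read_pupil_events <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  validate_pupil_events(as_event_table(raw, file = path))
}

as_event_table <- function(raw, file = "<events>") {
  need <- c("subject_id", "task", "trial_index", "block", "onset_ms",
            "condition", "stimulus", "response", "correct", "rt_ms")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing event column(s): %s", file, paste(miss, collapse = ", ")))
  }
  tibble::tibble(
    subject_id  = as.character(raw$subject_id),
    task        = as.character(raw$task),
    trial_index = as.integer(raw$trial_index),
    block       = as.integer(raw$block),
    onset_ms    = as.double(raw$onset_ms),
    condition   = dplyr::na_if(as.character(raw$condition), ""),
    stimulus    = as.character(raw$stimulus),
    response    = dplyr::na_if(as.character(raw$response), ""),
    correct     = as_flag(dplyr::na_if(as.character(raw$correct), "")),
    rt_ms       = as.double(dplyr::na_if(as.character(raw$rt_ms), ""))
  )
}

#' Validate an event table against its invariants
#'
#' @param events Event tibble.
#' @return The validated tibble.
#' @export
validate_pupil_events <- function(events) {
  events <- as_event_table(events)
  bad_task <- setdiff(unique(events$task), .tasks)
  if (length(bad_task) > 0) {
    abort(sprintf("unknown task label(s): %s", paste(bad_task, collapse = ", ")))
  }
  chk <- events |>
    dplyr::group_by(.data$subject_id, .data$task) |>
    dplyr::summarise(mono = all(diff(.data$onset_ms) > 0), .groups = "drop")
  if (any(!chk$mono)) {
    bad <- chk[!chk$mono, ]
    abort(sprintf("onset_ms not increasing for subject %s, task %s",
                  bad$subject_id[1], bad$task[1]))
  }
  for (tk in unique(events$task)) {
    legal <- .task_conditions[[tk]]
    seen <- unique(events$condition[events$task == tk])
    bad <- setdiff(seen[!is.na(seen)], legal)
    if (length(bad) > 0) {
      abort(sprintf("illegal condition label(s) for task %s: %s", tk,
                    paste(bad, collapse = ", ")))
    }
  }
  events
}

#' Write a behavioral event table
#'
#' @param events Event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pupil_events <- function(events, path) {
  out <- events |>
    dplyr::mutate(
      onset_ms = num_chr(.data$onset_ms),
      rt_ms = num_chr(.data$rt_ms),
      correct = as.character(.data$correct)
    )
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Combine the two eyes into a single pupil trace
#'
#' A sample is missing when the tracker marked the left and/or right eye
#' invalid; otherwise its diameter is the mean of the two eyes. The result
#' is the single time series ("mono trace") all downstream preprocessing
#' operates on.
#'
#' @param samples Sample tibble from [read_pupil_samples()].
#' @param rate_hz Nominal sampling rate; defaults to the table's `rate_hz`
#'   attribute, else 60.
#' @return A tibble with columns `time_ms`, `diameter_mm` (`NA` where
#'   missing), `missing` and `interpolated` (logical; `interpolated` all
#'   `FALSE` until [interpolate_linear()]), with attribute `rate_hz`.
#' @export
#' @examples
#' s <- tibble::tibble(
#'   time_ms = c(0, 16.7, 33.3), left_mm = c(3, 3.1, NA),
#'   right_mm = c(5, 5.1, 5.2), left_valid = c(TRUE, TRUE, FALSE),
#'   right_valid = c(TRUE, TRUE, TRUE)
#' )
#' combine_eyes(s)
combine_eyes <- function(samples, rate_hz = attr(samples, "rate_hz") %||% 60) {
  if (nrow(samples) == 0) abort("empty sample table: nothing to combine")
  lv <- samples$left_valid %in% TRUE
  rv <- samples$right_valid %in% TRUE
  missing <- !(lv & rv)
  diameter <- ifelse(missing, NA_real_, (samples$left_mm + samples$right_mm) / 2)
  trace <- tibble::tibble(
    time_ms = samples$time_ms,
    diameter_mm = diameter,
    missing = missing,
    interpolated = FALSE
  )
  attr(trace, "rate_hz") <- rate_hz
  trace
}
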