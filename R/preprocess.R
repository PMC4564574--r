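#' Pad missing-data runs
#'
#' Extends every missing run by `pad_samples` samples on each side, clipped
#' at the trace boundaries. Blink and artifact onsets/offsets recorded by
#' the tracker are unreliable at the edges of a run, so the padded samples
#' are treated as missing too before interpolation.
#'
#' @param trace Mono trace from [combine_eyes()].
#' @param pad_samples Non-negative number of samples to pad on each side
#'   (default 3).
#' @return The trace with `missing` widened and the corresponding
#'   `diameter_mm` entries set to `NA`. Applying the function twice with pad
#'   `p` equals applying it once with pad `2p`.
#' @export
pad_missing <- function(trace, pad_samples = 3) {
  stopifnot(is.data.frame(trace))
  if (!is.numeric(pad_samples) || length(pad_samples) != 1L ||
      is.na(pad_samples) || pad_samples < 0) {
    abort("`pad_samples` must be a single non-negative number")
  }
  pad_samples <- as.integer(pad_samples)
  n <- nrow(trace)
  if (n == 0 || pad_samples == 0 || !any(trace$missing)) return(trace)
  idx <- which(trace$missing)
  padded <- rep(FALSE, n)
  for (k in -pad_samples:pad_samples) {
    j <- idx + k
    j <- j[j >= 1 & j <= n]
    padded[j] <- TRUE
  }
  trace$missing <- padded
  trace$diameter_mm[padded] <- NA_real_
  trace
}

#' Fill missing samples by linear interpolation
#'
#' Each missing run bounded by valid samples on both sides is filled with
#' the straight line through the bounding values against real timestamps
#' (robust to sampling jitter). Runs touching a trace boundary have no
#' anchor on one side and are filled by holding the nearest valid value.
#' Filled samples are flagged `interpolated`; originally valid samples are
#' left bit-identical.
#'
#' @param trace Mono trace, normally after [pad_missing()].
#' @return The trace with no `NA` diameters and `interpolated` set exactly
#'   on the filled samples.
#' @export
#' @examples
#' tr <- tibble::tibble(
#'   time_ms = c(0, 10, 20), diameter_mm = c(2, NA, 4),
#'   missing = c(FALSE, TRUE, FALSE), interpolated = FALSE
#' )
#' interpolate_linear(tr)$diameter_mm  # 2 3 4
interpolate_linear <- function(trace) {
  n <- nrow(trace)
  t <- trace$time_ms
  d <- trace$diameter_mm
  valid <- !trace$missing
  if (!any(valid)) abort("unrecoverable trace: every sample is missing")
  if (all(valid)) return(trace)
  vi <- which(valid)
  # interior gaps: line through the two bounding valid samples; a single
  # anchor degenerates to a constant hold
  filled <- if (length(vi) == 1) {
    rep(d[vi], n)
  } else {
    stats::approx(x = t[vi], y = d[vi], xout = t, method = "linear", rule = 2)$y
  }
  trace$diameter_mm <- ifelse(valid, d, filled)
  trace$interpolated <- trace$interpolated | !valid
  trace
}

#' Fraction of interpolated samples in a time window
#'
#' The trial-exclusion statistic: the share of samples inside
#' `[start_ms, end_ms)` that carry the `interpolated` flag. Membership is
#' start-inclusive, end-exclusive on the trace's sample timestamps.
#'
#' @param trace Mono trace after [interpolate_linear()].
#' @param window Numeric `c(start_ms, end_ms)` in trace time.
#' @return A fraction in `[0, 1]`.
#' @export
interpolated_fraction <- function(trace, window) {
  check_window(window)
  inside <- in_window(trace$time_ms, window)
  n <- sum(inside)
  if (n == 0) {
    abort(sprintf("empty interval: no samples in [%g, %g) ms", window[1], window[2]))
  }
  sum(trace$interpolated[inside]) / n
}
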