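# in-code fixtures and independent oracles shared across test files

# regular 60 Hz mono trace with a given missing mask
make_trace <- function(values, missing = rep(FALSE, length(values)), rate_hz = 60) {
  n <- length(values)
  tr <- tibble::tibble(
    time_ms = (seq_len(n) - 1) * 1000 / rate_hz,
    diameter_mm = ifelse(missing, NA_real_, values),
    missing = missing,
    interpolated = FALSE
  )
  attr(tr, "rate_hz") <- rate_hz
  tr
}

# binocular sample table with both eyes equal to `values`
make_samples <- function(values, valid = rep(TRUE, length(values)), rate_hz = 60) {
  n <- length(values)
  tibble::tibble(
    time_ms = (seq_len(n) - 1) * 1000 / rate_hz,
    left_mm = ifelse(valid, values, NA_real_),
    right_mm = ifelse(valid, values, NA_real_),
    left_valid = valid,
    right_valid = valid
  )
}

# brute-force oracle: indices within `pad` of any missing index
oracle_pad <- function(missing, pad) {
  idx <- which(missing)
  out <- rep(FALSE, length(missing))
  for (i in seq_along(missing)) {
    if (length(idx) > 0 && min(abs(idx - i)) <= pad) out[i] <- TRUE
  }
  out
}

# per-gap two-point line equation oracle for linear interpolation
oracle_line_fill <- function(time, values, missing) {
  out <- values
  vi <- which(!missing)
  for (i in which(missing)) {
    lo <- vi[vi < i]
    hi <- vi[vi > i]
    if (length(lo) == 0) {
      out[i] <- values[hi[1]]
    } else if (length(hi) == 0) {
      out[i] <- values[lo[length(lo)]]
    } else {
      a <- lo[length(lo)]; b <- hi[1]
      slope <- (values[b] - values[a]) / (time[b] - time[a])
      out[i] <- values[a] + slope * (time[i] - time[a])
    }
  }
  out
}

# textbook paired t from difference scores
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(abs(t), df = n - 1, lower.tail = FALSE))
}

# brute-force run scanner: maximal runs of p < alpha with length >= min_run
oracle_runs <- function(p, alpha, min_run) {
  sig <- p < alpha
  runs <- list()
  i <- 1
  while (i <= length(sig)) {
    if (sig[i]) {
      j <- i
      while (j < length(sig) && sig[j + 1]) j <- j + 1
      if (j - i + 1 >= min_run) runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs
}

# sample skewness (adjusted Fisher-Pearson not needed; plain moment ratio)
oracle_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

# subject-level waveform stack as a tibble on a shared grid
make_waveforms <- function(mat_a, mat_b, rate_hz = 60) {
  # mat_*: subjects x samples matrices of condition means
  n_s <- nrow(mat_a); n_t <- ncol(mat_a)
  grid <- (seq_len(n_t) - 1) * 1000 / rate_hz
  dplyr::bind_rows(
    tidyr::expand_grid(subject_id = sprintf("s%02d", seq_len(n_s)),
                       rel_time_ms = grid) |>
      dplyr::mutate(condition = "a", mean_mm = as.vector(t(mat_a)), n_trials = 10L),
    tidyr::expand_grid(subject_id = sprintf("s%02d", seq_len(n_s)),
                       rel_time_ms = grid) |>
      dplyr::mutate(condition = "b", mean_mm = as.vector(t(mat_b)), n_trials = 10L)
  )
}
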