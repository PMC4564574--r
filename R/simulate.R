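#' Task design configuration
#'
#' Trial-structure constants of the three cognitive-control tasks: the
#' 2-Back (two blocks of 45 experimental trials, 34 match trials in total),
#' the Stroop (three blocks of 18 congruent plus 18 incongruent trials,
#' three color words in three ink colors) and the Number Switch (two pure
#' blocks then two mixed blocks of 32 trials, parity rule in yellow,
#' magnitude rule in blue). All inter-trial intervals are 2000 ms; response
#' windows are 1500 ms (2-Back) and 3000 ms (Stroop, Number Switch).
#'
#' @param blocks_2back,trials_per_block_2back,n_match 2-Back structure.
#' @param match_split Matches per 2-Back block (default as even as
#'   possible, 17/17).
#' @param stroop_blocks,stroop_per_cond Stroop structure (trials per
#'   condition per block).
#' @param switch_pure_blocks,switch_mixed_blocks,switch_block_trials Number
#'   Switch structure.
#' @param iti_ms Inter-trial interval.
#' @param timeout_ms Named response windows per task.
#' @return A list of class `design_config`.
#' @export
design_config <- function(blocks_2back = 2, trials_per_block_2back = 45,
                          n_match = 34, match_split = NULL,
                          stroop_blocks = 3, stroop_per_cond = 18,
                          switch_pure_blocks = 2, switch_mixed_blocks = 2,
                          switch_block_trials = 32,
                          iti_ms = 2000,
                          timeout_ms = c(`2back` = 1500, stroop = 3000, switch = 3000)) {
  if (is.null(match_split)) {
    base <- n_match %/% blocks_2back
    match_split <- rep(base, blocks_2back)
    extra <- n_match - sum(match_split)
    if (extra > 0) match_split[seq_len(extra)] <- match_split[seq_len(extra)] + 1L
  }
  stopifnot(sum(match_split) == n_match, length(match_split) == blocks_2back)
  if (any(match_split > trials_per_block_2back - 2)) {
    abort("infeasible 2-Back design: more matches than scorable trials in a block")
  }
  structure(
    list(
      blocks_2back = blocks_2back,
      trials_per_block_2back = trials_per_block_2back,
      n_match = n_match,
      match_split = match_split,
      alphabet = setdiff(LETTERS, c("A", "E", "I", "O", "U")),
      stroop_blocks = stroop_blocks,
      stroop_per_cond = stroop_per_cond,
      stroop_words = c(oranje = "orange", blauw = "blue", groen = "green"),
      switch_pure_blocks = switch_pure_blocks,
      switch_mixed_blocks = switch_mixed_blocks,
      switch_block_trials = switch_block_trials,
      switch_colors = c("yellow", "blue"),
      iti_ms = iti_ms,
      timeout_ms = timeout_ms
    ),
    class = "design_config"
  )
}

#' Generate a 2-Back letter sequence
#'
#' Builds a letter sequence over the configured blocks with exactly
#' `n_match` trials whose letter equals the letter two positions earlier in
#' the same block, and no accidental extra matches: match positions are
#' sampled among scorable positions, matching trials copy their t-2 letter
#' and all other trials draw a letter different from theirs.
#'
#' @param design A [design_config()].
#' @param seed Integer seed; same seed, same sequence.
#' @return Tibble `block`, `trial_index` (1-based across blocks),
#'   `stimulus`, `condition` (`match`/`nonmatch`, `NA` on the two
#'   non-scorable leading trials per block), `correct_response`
#'   (`match`/`nonmatch`, `NA` where non-scorable).
#' @export
#' @examples
#' seq2b <- gen_2back_sequence(design_config(), seed = 1)
#' mean(seq2b$condition == "match", na.rm = TRUE) * 90 / 90
gen_2back_sequence <- function(design = design_config(), seed = 1) {
  set.seed(seed)
  ab <- design$alphabet
  blocks <- purrr::map(seq_len(design$blocks_2back), function(b) {
    n <- design$trials_per_block_2back
    n_m <- design$match_split[b]
    scorable <- 3:n
    match_pos <- sort(sample(scorable, n_m))
    letters_b <- character(n)
    letters_b[1] <- sample(ab, 1)
    letters_b[2] <- sample(ab, 1)
    for (t in scorable) {
      if (t %in% match_pos) {
        letters_b[t] <- letters_b[t - 2]
      } else {
        letters_b[t] <- sample(setdiff(ab, letters_b[t - 2]), 1)
      }
    }
    cond <- rep(NA_character_, n)
    cond[scorable] <- ifelse(scorable %in% match_pos, "match", "nonmatch")
    tibble::tibble(block = b, stimulus = letters_b, condition = cond)
  })
  out <- dplyr::bind_rows(blocks)
  out$trial_index <- seq_len(nrow(out))
  out$correct_response <- out$condition
  out[, c("block", "trial_index", "stimulus", "condition", "correct_response")]
}

#' Generate a Stroop trial sequence
#'
#' Per block, exactly `stroop_per_cond` congruent (word equals ink color)
#' and `stroop_per_cond` incongruent (word differs from ink color) trials
#' in shuffled order, drawn from the three color words crossed with the
#' three ink colors.
#'
#' @inheritParams gen_2back_sequence
#' @return Tibble `block`, `trial_index`, `word`, `ink`, `stimulus`
#'   (`word/ink`), `condition`, `correct_response` (the ink color).
#' @export
gen_stroop_sequence <- function(design = design_config(), seed = 1) {
  set.seed(seed)
  words <- names(design$stroop_words)
  inks <- unname(design$stroop_words)
  blocks <- purrr::map(seq_len(design$stroop_blocks), function(b) {
    m <- design$stroop_per_cond
    wc <- sample(words, m, replace = TRUE)
    cong <- tibble::tibble(word = wc, ink = unname(design$stroop_words[wc]),
                           condition = "congruent")
    wi <- sample(words, m, replace = TRUE)
    incg <- tibble::tibble(
      word = wi,
      ink = purrr::map_chr(wi, function(w) sample(setdiff(inks, design$stroop_words[[w]]), 1)),
      condition = "incongruent"
    )
    trials <- dplyr::bind_rows(cong, incg)
    trials <- trials[sample.int(nrow(trials)), ]
    trials$block <- b
    trials
  })
  out <- dplyr::bind_rows(blocks)
  out$trial_index <- seq_len(nrow(out))
  out$stimulus <- paste(out$word, out$ink, sep = "/")
  out$correct_response <- out$ink
  out[, c("block", "trial_index", "word", "ink", "stimulus", "condition",
          "correct_response")]
}

#' Generate a Number Switch trial sequence
#'
#' Blocks 1 and 2 are pure: a single cue color each (order counterbalanced
#' via `first_color`), no switching. Blocks 3 and 4 draw the cue color at
#' random per trial; a mixed-block trial is a `switch` trial when its color
#' differs from the previous trial's, `nonswitch` when it repeats, and the
#' first trial of each mixed block is unlabeled. The correct response
#' follows the active rule: parity (`odd`/`even`) in yellow, magnitude
#' relative to five (`gt5`/`le5`) in blue.
#'
#' @inheritParams gen_2back_sequence
#' @param first_color Cue color of the first pure block (counterbalancing
#'   flag), `"yellow"` or `"blue"`.
#' @return Tibble `block`, `trial_index`, `number`, `color`, `stimulus`
#'   (`number/color`), `condition` (`pure`, `switch`, `nonswitch` or `NA`),
#'   `correct_response`.
#' @export
gen_switch_sequence <- function(design = design_config(), seed = 1,
                                first_color = c("yellow", "blue")) {
  set.seed(seed)
  first_color <- match.arg(first_color)
  colors <- design$switch_colors
  pure_order <- c(first_color, setdiff(colors, first_color))
  n <- design$switch_block_trials
  blocks <- list()
  for (b in seq_len(design$switch_pure_blocks)) {
    blocks[[b]] <- tibble::tibble(
      block = b,
      number = sample(1:10, n, replace = TRUE),
      color = pure_order[b],
      condition = "pure"
    )
  }
  for (b in design$switch_pure_blocks + seq_len(design$switch_mixed_blocks)) {
    col <- sample(colors, n, replace = TRUE)
    cond <- c(NA_character_,
              ifelse(col[-1] != col[-n], "switch", "nonswitch"))
    blocks[[b]] <- tibble::tibble(block = as.integer(b),
                                  number = sample(1:10, n, replace = TRUE),
                                  color = col, condition = cond)
  }
  out <- dplyr::bind_rows(blocks)
  out$trial_index <- seq_len(nrow(out))
  out$stimulus <- paste(out$number, out$color, sep = "/")
  out$correct_response <- switch_rule(out$number, out$color)
  out[, c("block", "trial_index", "number", "color", "stimulus", "condition",
          "correct_response")]
}

#' Correct response under the Number Switch rules
#'
#' @param number Integer 1--10.
#' @param color Cue color, `"yellow"` (parity rule) or `"blue"` (magnitude
#'   rule).
#' @return `odd`/`even` for yellow, `gt5`/`le5` for blue.
#' @export
#' @examples
#' switch_rule(7, "yellow")  # "odd"
#' switch_rule(3, "blue")    # "le5"
switch_rule <- function(number, color) {
  ifelse(color == "yellow",
         ifelse(number %% 2 == 1, "odd", "even"),
         ifelse(number > 5, "gt5", "le5"))
}

#' Unit-peak pupil response kernel
#'
#' A gamma-shaped impulse response describing the pupil's sluggish reaction
#' to a discrete cognitive event: `(t/t_max)^n * exp(n * (1 - t/t_max))`
#' for t >= 0 and 0 before the event, which peaks at exactly 1 when
#' t = `t_max_ms`. Used only by the simulator; the analysis side never
#' assumes a waveform shape.
#'
#' @param t_ms Time since event onset in ms (vectorized).
#' @param n_shape Shape exponent (default 10.1).
#' @param t_max_ms Time-to-peak in ms.
#' @return Kernel values in `[0, 1]`.
#' @export
#' @examples
#' prf(1350, t_max_ms = 1350)  # exactly 1
prf <- function(t_ms, n_shape = 10.1, t_max_ms = 1350) {
  out <- numeric(length(t_ms))
  pos <- t_ms > 0
  r <- t_ms[pos] / t_max_ms
  out[pos] <- r^n_shape * exp(n_shape * (1 - r))
  out
}

#' Simulation configuration
#'
#' The measurement and behavior model of the synthetic study. Each subject
#' s carries a latent effort trait theta_s ~ N(0, 1). The pupil trace is
#' subject baseline + per-trial amplitude x unit-peak kernel + AR(1)
#' noise; the per-trial amplitude is the condition amplitude (defaults
#' calibrated to group descriptives: 2-Back 0.098, congruent 0.110,
#' incongruent 0.152, non-switch 0.131, switch 0.171 mm) plus an
#' effort-coupled subject shift, a condition-specific subject deviation, a
#' trial deviation, and an increment on error trials. Blinks arrive as a
#' Poisson process with geometric run lengths and invalidate both eyes.
#' Behavior: lognormal RTs with condition-specific means (calibrated to
#' the group RT descriptives) and error probability
#' logistic(intercept_c - slope x theta_s), so higher-effort subjects both
#' dilate more and err less.
#'
#' @param n_subjects Number of subjects (default 35).
#' @param rate_hz Sampling rate (default 60).
#' @param baseline_mean_mm,baseline_sd_mm Between-subject pupil baseline.
#' @param amplitudes Named list per task of named condition amplitudes (mm).
#' @param amp_effort_coupling Amplitude shift per effort SD (mm).
#' @param amp_subject_sd Condition-specific between-subject amplitude SD.
#' @param amp_trial_sd Trial-to-trial amplitude SD.
#' @param error_amp_increment Extra amplitude on error trials (mm).
#' @param prf_n_shape Kernel shape exponent.
#' @param prf_t_max_ms Named kernel time-to-peak per task (ms), placed
#'   inside each task's summary window.
#' @param ar_phi,ar_sigma AR(1) noise coefficient and innovation SD (mm).
#' @param eye_noise_sd Independent per-eye measurement noise SD (mm).
#' @param blink_rate_per_s Blink/artifact onset rate (Poisson).
#' @param blink_mean_ms Mean artifact run length (geometric, in samples at
#'   `rate_hz`).
#' @param rt_mean_ms Named list per task of named condition mean RTs (ms).
#' @param rt_subject_sdlog,rt_trial_sdlog Between-subject and trial
#'   lognormal RT spread (log scale).
#' @param error_rate Named list per task of named condition mean error
#'   rates.
#' @param error_effort_slope Logit decrease in error probability per effort
#'   SD.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 35,
                       rate_hz = 60,
                       baseline_mean_mm = 4.5, baseline_sd_mm = 0.4,
                       amplitudes = list(
                         `2back` = c(all = 0.098),
                         stroop = c(congruent = 0.110, incongruent = 0.152),
                         switch = c(nonswitch = 0.131, switch = 0.171, pure = 0.131)
                       ),
                       amp_effort_coupling = 0.06,
                       amp_subject_sd = 0.03,
                       amp_trial_sd = 0.05,
                       error_amp_increment = 0.08,
                       prf_n_shape = 10.1,
                       prf_t_max_ms = c(`2back` = 1350, stroop = 1250, switch = 1550),
                       ar_phi = 0.95, ar_sigma = 0.010,
                       eye_noise_sd = 0.01,
                       blink_rate_per_s = 0.4, blink_mean_ms = 500,
                       rt_mean_ms = list(
                         `2back` = c(all = 742),
                         stroop = c(congruent = 623, incongruent = 705),
                         switch = c(nonswitch = 1110, switch = 1279, pure = 1000)
                       ),
                       rt_subject_sdlog = 0.12,
                       rt_trial_sdlog = 0.25,
                       error_rate = list(
                         `2back` = c(all = 0.143),
                         stroop = c(congruent = 0.019, incongruent = 0.043),
                         switch = c(nonswitch = 0.093, switch = 0.105, pure = 0.07)
                       ),
                       error_effort_slope = 0.2) {
  structure(
    list(
      n_subjects = n_subjects, rate_hz = rate_hz,
      baseline_mean_mm = baseline_mean_mm, baseline_sd_mm = baseline_sd_mm,
      amplitudes = amplitudes,
      amp_effort_coupling = amp_effort_coupling,
      amp_subject_sd = amp_subject_sd,
      amp_trial_sd = amp_trial_sd,
      error_amp_increment = error_amp_increment,
      prf_n_shape = prf_n_shape, prf_t_max_ms = prf_t_max_ms,
      ar_phi = ar_phi, ar_sigma = ar_sigma,
      eye_noise_sd = eye_noise_sd,
      blink_rate_per_s = blink_rate_per_s, blink_mean_ms = blink_mean_ms,
      rt_mean_ms = rt_mean_ms,
      rt_subject_sdlog = rt_subject_sdlog, rt_trial_sdlog = rt_trial_sdlog,
      error_rate = error_rate,
      error_effort_slope = error_effort_slope
    ),
    class = "sim_config"
  )
}

# logit intercept giving a population-mean error rate under
# p = plogis(b0 - s * theta), theta ~ N(0,1) (logistic-normal approximation)
error_intercept <- function(rate, slope) {
  stats::qlogis(rate) * sqrt(1 + (slope / 1.7)^2)
}

# task sequence for one subject, as an event skeleton
gen_task_sequence <- function(task, design, seed, first_color = "yellow") {
  switch(task,
    `2back` = gen_2back_sequence(design, seed),
    stroop = gen_stroop_sequence(design, seed),
    switch = gen_switch_sequence(design, seed, first_color = first_color)
  )
}

#' Simulate one subject's session on one task
#'
#' Draws the subject's behavior (correctness and RT per trial) and the
#' binocular pupil sample stream implied by the measurement model of
#' [sim_config()], at trial onsets spaced `timeout + ITI` apart.
#'
#' @param task `"2back"`, `"stroop"` or `"switch"`.
#' @param design A [design_config()].
#' @param sim A [sim_config()].
#' @param subject_id Subject label.
#' @param theta Subject effort trait (typically drawn by
#'   [simulate_study()]).
#' @param seed Integer seed for this subject-task stream.
#' @param blink Logical; simulate the blink/artifact process (default
#'   `TRUE`).
#' @return A list with `samples` (binocular sample tibble), `events`
#'   (event tibble) and `truth` (one-row tibble of generating values:
#'   theta, per-condition true amplitude for this subject).
#' @export
simulate_subject <- function(task, design = design_config(), sim = sim_config(),
                             subject_id = "s01", theta = 0, seed = 1,
                             blink = TRUE) {
  task <- match.arg(task, .tasks)
  set.seed(seed)
  first_color <- sample(c("yellow", "blue"), 1)
  trials <- gen_task_sequence(task, design, seed = sample.int(2^30, 1),
                              first_color = first_color)
  n_trials <- nrow(trials)
  slot_ms <- design$timeout_ms[[task]] + design$iti_ms
  onsets <- 1000 + (seq_len(n_trials) - 1) * slot_ms

  conds <- trials$condition
  cond_key <- ifelse(is.na(conds), NA_character_, conds)
  amp_names <- names(sim$amplitudes[[task]])
  lookup <- function(tbl, key) {
    out <- tbl[key]
    miss <- is.na(names(out)) | !(key %in% names(tbl))
    out[miss] <- if ("all" %in% names(tbl)) tbl[["all"]] else mean(tbl)
    unname(out)
  }
  key <- if (identical(amp_names, "all")) rep("all", n_trials) else cond_key

  # behavior: error probability and RT per trial
  slope <- sim$error_effort_slope
  p_err <- stats::plogis(error_intercept(lookup(sim$error_rate[[task]], key), slope) -
                           slope * theta)
  correct <- stats::runif(n_trials) >= p_err
  subj_rt_off <- stats::rnorm(1, 0, sim$rt_subject_sdlog)
  mu <- log(lookup(sim$rt_mean_ms[[task]], key)) + subj_rt_off - sim$rt_trial_sdlog^2 / 2
  rt <- stats::rlnorm(n_trials, meanlog = mu, sdlog = sim$rt_trial_sdlog)
  rt <- pmax(rt, 180)
  timeout <- design$timeout_ms[[task]]
  omitted <- rt > timeout
  correct[omitted] <- FALSE
  rt[omitted] <- NA_real_

  response <- ifelse(is.na(rt), NA_character_,
                     ifelse(correct, trials$correct_response,
                            paste0("not_", trials$correct_response)))

  # per-trial kernel amplitude
  cond_amp <- lookup(sim$amplitudes[[task]], key)
  cond_levels <- unique(key[!is.na(key)])
  eta <- stats::rnorm(length(cond_levels), 0, sim$amp_subject_sd)
  names(eta) <- cond_levels
  amp <- cond_amp + sim$amp_effort_coupling * theta +
    ifelse(is.na(key), 0, eta[key]) +
    stats::rnorm(n_trials, 0, sim$amp_trial_sd) +
    ifelse(correct, 0, sim$error_amp_increment)
  amp <- pmax(amp, 0)

  # continuous trace
  dt <- 1000 / sim$rate_hz
  total_ms <- onsets[n_trials] + 5000
  time_ms <- seq(0, total_ms, by = dt)
  n <- length(time_ms)
  base <- sim$baseline_mean_mm + stats::rnorm(1, 0, sim$baseline_sd_mm)
  noise <- as.numeric(stats::filter(stats::rnorm(n, 0, sim$ar_sigma),
                                    sim$ar_phi, method = "recursive"))
  trace <- rep(base, n) + noise
  t_max <- sim$prf_t_max_ms[[task]]
  support <- ceiling(4000 / dt)
  kern <- prf((0:support) * dt, n_shape = sim$prf_n_shape, t_max_ms = t_max)
  for (i in seq_len(n_trials)) {
    i0 <- findInterval(onsets[i], time_ms)  # last sample at or before onset
    idx <- (i0 + 1):min(i0 + support + 1, n)
    trace[idx] <- trace[idx] + amp[i] * prf(time_ms[idx] - onsets[i],
                                            n_shape = sim$prf_n_shape,
                                            t_max_ms = t_max)
  }

  # blink / artifact process: Poisson onsets, geometric run lengths
  valid <- rep(TRUE, n)
  if (blink && sim$blink_rate_per_s > 0) {
    n_blinks <- stats::rpois(1, sim$blink_rate_per_s * total_ms / 1000)
    if (n_blinks > 0) {
      starts <- sample.int(n, n_blinks, replace = TRUE)
      mean_len <- max(sim$blink_mean_ms / dt, 1)
      lens <- 1 + stats::rgeom(n_blinks, 1 / mean_len)
      for (b in seq_len(n_blinks)) {
        valid[starts[b]:min(starts[b] + lens[b] - 1, n)] <- FALSE
      }
    }
  }

  samples <- tibble::tibble(
    time_ms = time_ms,
    left_mm = ifelse(valid, trace + stats::rnorm(n, 0, sim$eye_noise_sd), NA_real_),
    right_mm = ifelse(valid, trace + stats::rnorm(n, 0, sim$eye_noise_sd), NA_real_),
    left_valid = valid,
    right_valid = valid
  )
  attr(samples, "rate_hz") <- sim$rate_hz

  events <- tibble::tibble(
    subject_id = subject_id,
    task = task,
    trial_index = trials$trial_index,
    block = trials$block,
    onset_ms = onsets,
    condition = trials$condition,
    stimulus = trials$stimulus,
    response = response,
    correct = correct,
    rt_ms = rt
  )

  truth <- tibble::tibble(
    subject_id = subject_id, task = task, theta = theta,
    condition = cond_levels,
    true_amplitude = unname(cond_amp[match(cond_levels, key)] +
                              sim$amp_effort_coupling * theta + eta[cond_levels])
  )
  list(samples = samples, events = events, truth = truth)
}

#' Simulate a complete multi-subject study
#'
#' Draws each subject's effort trait and simulates every requested task,
#' optionally writing the per-subject sample and event tables plus a
#' ground-truth table to disk in the package's TSV schemas. All randomness
#' flows from the single root seed; per-subject streams are derived from
#' it deterministically.
#'
#' @param sim A [sim_config()].
#' @param design A [design_config()].
#' @param tasks Tasks to simulate (default all three).
#' @param seed Root seed.
#' @param dir Output directory; when `NULL` (default) the study is returned
#'   in memory only.
#' @param blink Simulate the blink process (default `TRUE`).
#' @return A list with `subjects` (per subject: per task `samples` and
#'   `events`), `truth` (one row per subject, task and condition) and
#'   `dir`. On disk: `samples_<subject>_<task>.tsv`,
#'   `events_<subject>_<task>.tsv` and `ground_truth.tsv`.
#' @export
simulate_study <- function(sim = sim_config(), design = design_config(),
                           tasks = .tasks, seed = 1, dir = NULL, blink = TRUE) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(sim$n_subjects))
  thetas <- stats::rnorm(sim$n_subjects)
  subseeds <- matrix(sample.int(2^30, sim$n_subjects * length(tasks)),
                     nrow = sim$n_subjects)
  subjects <- purrr::map(seq_len(sim$n_subjects), function(s) {
    per_task <- purrr::map(seq_along(tasks), function(k) {
      simulate_subject(tasks[k], design, sim, subject_id = ids[s],
                       theta = thetas[s], seed = subseeds[s, k], blink = blink)
    })
    names(per_task) <- tasks
    per_task
  })
  names(subjects) <- ids
  truth <- purrr::map_dfr(subjects, function(st) purrr::map_dfr(st, "truth"))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (s in ids) {
      for (tk in tasks) {
        write_pupil_samples(subjects[[s]][[tk]]$samples,
                            file.path(dir, sprintf("samples_%s_%s.tsv", s, tk)))
        write_pupil_events(subjects[[s]][[tk]]$events,
                           file.path(dir, sprintf("events_%s_%s.tsv", s, tk)))
      }
    }
    readr::write_tsv(truth, file.path(dir, "ground_truth.tsv"), progress = FALSE)
  }
  list(subjects = subjects, truth = truth, dir = dir)
}
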