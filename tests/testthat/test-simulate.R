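test_that("the default 2-Back design has exactly 34 matches in 90 trials", {
  seq2b <- gen_2back_sequence(design_config(), seed = 7)
  expect_identical(nrow(seq2b), 90L)
  # brute-force rescan within block structure
  rescan <- seq2b |>
    dplyr::group_by(block) |>
    dplyr::mutate(is_match = dplyr::row_number() > 2 &
                    stimulus == dplyr::lag(stimulus, 2)) |>
    dplyr::ungroup()
  expect_identical(sum(rescan$is_match), 34L)
  expect_identical(which(rescan$is_match), which(seq2b$condition == "match"))
  expect_equal(100 * 34 / 90, 37.8, tolerance = 0.01)
  # non-scorable lead-ins carry no label
  expect_true(all(is.na(seq2b$condition[seq2b$trial_index %in% c(1, 2, 46, 47)])))
  expect_identical(gen_2back_sequence(seed = 7), seq2b)  # determinism
  expect_error(design_config(n_match = 88), "infeasible")
})

test_that("the Stroop design has 18+18 trials per block with word-ink constraints", {
  st <- gen_stroop_sequence(design_config(), seed = 7)
  expect_identical(nrow(st), 108L)
  counts <- dplyr::count(st, block, condition)
  expect_true(all(counts$n == 18))
  expect_identical(nrow(counts), 6L)
  cong <- st[st$condition == "congruent", ]
  incg <- st[st$condition == "incongruent", ]
  map <- c(oranje = "orange", blauw = "blue", groen = "green")
  expect_true(all(map[cong$word] == cong$ink))
  expect_true(all(map[incg$word] != incg$ink))
  expect_identical(sum(st$condition == "congruent"), 54L)
  expect_identical(gen_stroop_sequence(seed = 7), st)
})

test_that("the switch design has pure then mixed blocks with rule-correct responses", {
  sw <- gen_switch_sequence(design_config(), seed = 7, first_color = "yellow")
  expect_identical(nrow(sw), 128L)
  expect_true(all(sw$condition[sw$block <= 2] == "pure"))
  expect_identical(unique(sw$color[sw$block == 1]), "yellow")
  expect_identical(unique(sw$color[sw$block == 2]), "blue")
  # switch labels equal the brute-force color-change scan within mixed blocks
  for (b in 3:4) {
    blk <- sw[sw$block == b, ]
    expect_true(is.na(blk$condition[1]))
    want <- ifelse(blk$color[-1] != blk$color[-nrow(blk)], "switch", "nonswitch")
    expect_identical(blk$condition[-1], want)
  }
  # response rules: parity in yellow, magnitude in blue
  expect_identical(switch_rule(7, "yellow"), "odd")
  expect_identical(switch_rule(4, "yellow"), "even")
  expect_identical(switch_rule(3, "blue"), "le5")
  expect_identical(switch_rule(5, "blue"), "le5")
  expect_identical(switch_rule(8, "blue"), "gt5")
  expect_identical(sw$correct_response, switch_rule(sw$number, sw$color))
})

test_that("the pupil kernel is unit-peak at t_max and zero before onset", {
  expect_equal(prf(1350, t_max_ms = 1350), 1.0)
  expect_equal(prf(0), 0.0)
  expect_equal(prf(-100), 0.0)
  grid <- seq(0, 4000, by = 0.5)
  for (tm in c(930, 1250, 1550)) {
    v <- prf(grid, t_max_ms = tm)
    expect_lt(abs(grid[which.max(v)] - tm), 0.5 + 1e-9)
    expect_true(all(v <= 1 + 1e-12))
  }
})

test_that("a noise-free single trial recovers its amplitude in the summary window", {
  sim <- sim_config(ar_sigma = 0, eye_noise_sd = 0, blink_rate_per_s = 0,
                    amp_trial_sd = 0, amp_subject_sd = 0, amp_effort_coupling = 0,
                    baseline_sd_mm = 0)
  design <- design_config(stroop_blocks = 1, stroop_per_cond = 1)
  sub <- simulate_subject("stroop", design, sim, theta = 0, seed = 9, blink = FALSE)
  tr <- interpolate_linear(pad_missing(combine_eyes(sub$samples)))
  ep <- baseline_correct(epoch_trace(tr, sub$events))
  wm <- window_mean(ep, task_window("stroop"))
  # closed-form kernel mean over the window, given the trial's true amplitude
  truth <- sub$truth
  for (i in seq_len(nrow(wm))) {
    amp_i <- truth$true_amplitude[truth$condition == wm$condition[i]]
    if (!(wm$correct[i] %in% TRUE)) amp_i <- amp_i + sim$error_amp_increment
    grid <- seq(1000, 1500 - 1000 / 60, by = 1000 / 60)
    expect_equal(wm$window_mean_mm[i], amp_i * mean(prf(grid, t_max_ms = 1250)),
                 tolerance = 0.02)
  }
})

test_that("a zero-amplitude study produces near-zero grand averages and no clusters", {
  sim <- sim_config(
    n_subjects = 8,
    amplitudes = list(stroop = c(congruent = 0, incongruent = 0)),
    amp_effort_coupling = 0, amp_subject_sd = 0, amp_trial_sd = 0,
    error_amp_increment = 0
  )
  design <- design_config(stroop_blocks = 1, stroop_per_cond = 9)
  study <- simulate_study(sim, design, tasks = "stroop", seed = 11, blink = FALSE)
  eps <- purrr::map_dfr(study$subjects, function(st) {
    tr <- interpolate_linear(combine_eyes(st$stroop$samples))
    baseline_correct(epoch_trace(tr, st$stroop$events))
  })
  wf <- subject_waveforms(eps, correct_only = TRUE)
  ga <- grand_average(wf)
  expect_lt(max(abs(ga$mean_mm)), 0.05)
  tests <- samplewise_paired_t(wf, "incongruent", "congruent")
  expect_identical(nrow(detect_clusters(tests)), 0L)
})

test_that("same seed reproduces a study bit for bit; truth covers all subjects", {
  sim <- sim_config(n_subjects = 2)
  design <- design_config(stroop_blocks = 1, stroop_per_cond = 4)
  s1 <- simulate_study(sim, design, tasks = "stroop", seed = 21)
  s2 <- simulate_study(sim, design, tasks = "stroop", seed = 21)
  expect_identical(s1$subjects, s2$subjects)
  expect_identical(dplyr::n_distinct(s1$truth$subject_id), 2L)
  s3 <- simulate_study(sim, design, tasks = "stroop", seed = 22)
  expect_false(identical(s1$subjects, s3$subjects))
})

test_that("a simulated dataset round-trips through disk and validates", {
  dir <- withr::local_tempdir()
  sim <- sim_config(n_subjects = 2)
  design <- design_config(stroop_blocks = 1, stroop_per_cond = 4,
                          blocks_2back = 1, trials_per_block_2back = 10,
                          n_match = 3, match_split = 3)
  study <- simulate_study(sim, design, tasks = c("stroop", "2back"),
                          seed = 31, dir = dir)
  rep <- suppressWarnings(validate_dataset(dir))
  expect_true(all(rep$ok))
  expect_identical(nrow(rep), 8L)
  ev <- read_pupil_events(file.path(dir, "events_s01_stroop.tsv"))
  expect_equal(as.data.frame(ev), as.data.frame(study$subjects$s01$stroop$events))
})

test_that("group mean window dilation tracks configured amplitudes", {
  # with trial and subject noise on, the group mean per condition should sit
  # within Monte-Carlo error of the kernel-implied configured value
  sim <- sim_config(n_subjects = 50, blink_rate_per_s = 0)
  design <- design_config(stroop_blocks = 2, stroop_per_cond = 12)
  study <- simulate_study(sim, design, tasks = "stroop", seed = 41, blink = FALSE)
  wm <- purrr::map_dfr(study$subjects, function(st) {
    tr <- interpolate_linear(combine_eyes(st$stroop$samples))
    ep <- baseline_correct(epoch_trace(tr, st$stroop$events))
    window_mean(ep, task_window("stroop"))
  })
  grid <- seq(1000, 1500 - 1000 / 60, by = 1000 / 60)
  kmean <- mean(prf(grid, t_max_ms = 1250))
  per_subj <- wm |>
    dplyr::filter(correct) |>
    dplyr::group_by(subject_id, condition) |>
    dplyr::summarise(d = mean(window_mean_mm), .groups = "drop")
  grp <- per_subj |>
    dplyr::group_by(condition) |>
    dplyr::summarise(m = mean(d), sem = sd(d) / sqrt(dplyr::n()))
  for (cond in c("congruent", "incongruent")) {
    want <- sim$amplitudes$stroop[[cond]] * kmean
    row <- grp[grp$condition == cond, ]
    expect_lt(abs(row$m - want), 2 * row$sem + 0.01)
  }
})
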