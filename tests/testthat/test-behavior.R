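mk_records <- function(task, condition, correct, rt_ms, subject_id = "s01",
                       block = 1L, stimulus = "x") {
  n <- length(condition)
  tibble::tibble(
    subject_id = rep_len(subject_id, n), task = task,
    trial_index = seq_len(n), block = rep_len(block, n),
    onset_ms = seq_len(n) * 5000,
    condition = condition, stimulus = rep_len(stimulus, n),
    response = "r", correct = correct, rt_ms = rt_ms
  )
}

test_that("score_2back labels matches, non-scorable lead-ins and encoding success", {
  ev <- mk_records("2back", rep(NA_character_, 5), c(TRUE, TRUE, TRUE, FALSE, TRUE),
                   rep(600, 5))
  ev$stimulus <- c("A", "B", "A", "C", "A")
  sc <- score_2back(ev)
  expect_identical(sc$scorable, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_identical(sc$condition, c(NA, NA, "match", "nonmatch", "match"))
  # encoding_ok(t) = correct(t + 2)
  expect_identical(sc$encoding_ok, c(TRUE, FALSE, TRUE, NA, NA))

  ev2 <- ev
  ev2$correct <- TRUE
  sc2 <- score_2back(ev2)
  expect_true(all(sc2$encoding_ok[1:3]))

  # block boundaries reset the t-2 reference
  ev3 <- dplyr::bind_rows(ev, dplyr::mutate(ev, block = 2L, trial_index = 6:10))
  sc3 <- score_2back(ev3)
  expect_identical(sc3$scorable[6:7], c(FALSE, FALSE))
})

test_that("score_2back match labels equal brute-force letter comparison on random sequences", {
  set.seed(501)
  for (i in 1:20) {
    n <- sample(10:45, 1)
    letters_i <- sample(LETTERS[1:4], n, replace = TRUE)
    ev <- mk_records("2back", rep(NA_character_, n), rep(TRUE, n), rep(600, n))
    ev$stimulus <- letters_i
    sc <- score_2back(ev)
    for (t in 3:n) {
      expect_identical(sc$condition[t],
                       ifelse(letters_i[t] == letters_i[t - 2], "match", "nonmatch"))
    }
  }
})

test_that("RT floor flags sub-300 ms responses on 2-Back and Switch but not Stroop", {
  recs <- dplyr::bind_rows(
    mk_records("switch", c("switch", "nonswitch"), c(TRUE, TRUE), c(299, 300)),
    mk_records("stroop", c("congruent", "congruent"), c(TRUE, TRUE), c(250, 700)),
    mk_records("2back", c("match", "match"), c(TRUE, TRUE), c(100, NA))
  )
  out <- filter_rt_floor(recs)
  expect_identical(out$rt_floor_excluded,
                   c(TRUE, FALSE,   # 299 out, 300 exactly kept
                     FALSE, FALSE,  # stroop exempt
                     TRUE, FALSE))  # NA rt never flagged
})

test_that("3-SD RT trimming works within subject-condition cells in a single pass", {
  # cell {600 x 10, 5000}: the 5000 is beyond 3 SD of the cell statistics
  rts <- c(rep(600, 10), 5000)
  recs <- mk_records("stroop", rep("congruent", 11), rep(TRUE, 11), rts)
  out <- filter_rt_sd(recs, k = 3)
  expect_identical(out$rt_sd_excluded, c(rep(FALSE, 10), TRUE))
  m <- mean(rts); s <- sd(rts)
  expect_identical(out$rt_sd_excluded, abs(rts - m) > 3 * s)

  # all-identical RTs: SD 0, nothing flagged
  same <- mk_records("stroop", rep("congruent", 8), rep(TRUE, 8), rep(640, 8))
  expect_false(any(filter_rt_sd(same)$rt_sd_excluded))

  # brute-force z-score oracle on random cells, including out-of-scope tasks
  set.seed(502)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    task <- sample(c("stroop", "switch", "2back"), 1)
    cond <- sample(c("congruent", "incongruent"), n, replace = TRUE)
    if (task != "stroop") cond <- sample(c("switch", "nonswitch"), n, replace = TRUE)
    rt <- rlnorm(n, log(650), 0.4)
    recs_i <- mk_records(task, cond, rep(TRUE, n), rt)
    out_i <- filter_rt_sd(recs_i, k = 2)
    for (cc in unique(cond)) {
      cell <- cond == cc
      m <- mean(rt[cell]); s <- sd(rt[cell])
      want <- if (task == "2back" || sum(cell) < 2 || s == 0) {
        rep(FALSE, sum(cell))
      } else {
        abs(rt[cell] - m) > 2 * s
      }
      expect_identical(out_i$rt_sd_excluded[cell], want)
    }
  }
})

test_that("between-subject outliers are flagged per measure only", {
  m <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:35),
    errors = c(rep(10, 34), 200),
    rt = rep(650, 35)
  )
  out <- subject_outliers(m)
  flagged <- out[out$outlier, ]
  expect_identical(nrow(flagged), 1L)
  expect_identical(flagged$subject_id, "s35")
  expect_identical(flagged$measure, "errors")  # rt untouched for s35

  allsame <- tibble::tibble(subject_id = sprintf("s%02d", 1:5), v = rep(3, 5))
  expect_false(any(subject_outliers(allsame)$outlier))

  set.seed(503)
  vals <- rnorm(35)
  tb <- tibble::tibble(subject_id = sprintf("s%02d", 1:35), v = vals)
  out2 <- subject_outliers(tb)
  expect_identical(out2$outlier, abs(vals - mean(vals)) > 3 * sd(vals))
})

test_that("square-root transform reduces right skew and rejects negatives", {
  expect_equal(sqrt_transform(c(0, 4)), c(0, 2))
  expect_equal(sqrt_transform(2), sqrt(2))
  expect_error(sqrt_transform(-1), "non-negative")
  set.seed(504)
  for (i in 1:10) {
    counts <- rpois(200, exp(rnorm(200, 1, 0.8)))  # right-skewed mixture
    expect_lt(oracle_skewness(sqrt_transform(counts)), oracle_skewness(counts))
  }
})

test_that("stroop_effect computes incongruent-minus-congruent RT and error differences", {
  recs <- mk_records("stroop",
                     c("congruent", "congruent", "incongruent", "incongruent"),
                     rep(TRUE, 4), c(600, 620, 700, 720))
  eff <- stroop_effect(recs)
  expect_equal(eff$rt_effect_ms, 100)
  expect_equal(eff$error_effect_pct, 0)

  # identical distributions: zero effect
  recs2 <- mk_records("stroop", rep(c("congruent", "incongruent"), each = 3),
                      rep(TRUE, 6), rep(650, 6))
  expect_equal(stroop_effect(recs2)$rt_effect_ms, 0)

  # errors enter the error effect but not the RT means
  recs3 <- mk_records("stroop", rep(c("congruent", "incongruent"), each = 4),
                      c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
                      c(600, 610, 620, 9000, 700, 710, 9000, 9000))
  eff3 <- stroop_effect(recs3)
  expect_equal(eff3$rt_effect_ms, 705 - 610)
  expect_equal(eff3$error_effect_pct, 50 - 25)

  recs4 <- mk_records("stroop", rep("congruent", 3), rep(TRUE, 3), rep(600, 3))
  expect_error(stroop_effect(recs4))
})

test_that("switch_cost uses mixed blocks with previous-trial cue labeling", {
  # colors Y,Y,B,B,Y -> labels (-, nonswitch, switch, nonswitch, switch)
  colors <- c("yellow", "yellow", "blue", "blue", "yellow")
  lab <- c(NA, ifelse(colors[-1] != colors[-5], "switch", "nonswitch"))
  expect_identical(lab, c(NA, "nonswitch", "switch", "nonswitch", "switch"))

  recs <- mk_records("switch", c(lab, lab), rep(TRUE, 10),
                     c(NA, 1100, 1300, 1120, 1260, NA, 1100, 1300, 1120, 1260),
                     block = rep(c(3L, 4L), each = 5))
  cost <- switch_cost(recs)
  expect_equal(cost$rt_cost_ms, mean(c(1300, 1260)) - mean(c(1100, 1120)))
  expect_equal(cost$correct_cost, 0)

  # identical RT distributions across labels: zero cost
  recs2 <- mk_records("switch", rep(c("switch", "nonswitch"), 4), rep(TRUE, 8),
                      rep(1200, 8), block = 3L)
  expect_equal(switch_cost(recs2)$rt_cost_ms, 0)

  # correct_cost is a rate difference
  recs3 <- mk_records("switch", rep(c("switch", "nonswitch"), each = 4),
                      c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
                      rep(1200, 8), block = 3L)
  expect_equal(switch_cost(recs3)$correct_cost, 0.5 - 0.75)
})

test_that("group-level effects reproduce printed-mean arithmetic", {
  # Stroop: group mean incongruent 705 minus congruent 623 = 82 ms
  set.seed(505)
  n <- 35
  subj <- sprintf("s%02d", 1:n)
  cong <- rnorm(n, 623, 1e-9)
  incg <- rnorm(n, 705, 1e-9)
  recs <- purrr::map_dfr(1:n, function(i) {
    mk_records("stroop", c("congruent", "incongruent"), c(TRUE, TRUE),
               c(cong[i], incg[i]), subject_id = subj[i])
  })
  expect_equal(mean(stroop_effect(recs)$rt_effect_ms), 705 - 623, tolerance = 1e-6)

  # Number Switch: 1279 - 1110 = 169 ms
  sw <- rnorm(n, 1279, 1e-9); nsw <- rnorm(n, 1110, 1e-9)
  recs2 <- purrr::map_dfr(1:n, function(i) {
    mk_records("switch", c("switch", "nonswitch"), c(TRUE, TRUE),
               c(sw[i], nsw[i]), subject_id = subj[i], block = 3L)
  })
  expect_equal(mean(switch_cost(recs2)$rt_cost_ms), 1279 - 1110, tolerance = 1e-6)
})

test_that("error % and correct % partition scorable cells and filters only remove trials", {
  set.seed(506)
  recs <- mk_records("stroop", sample(c("congruent", "incongruent"), 40, TRUE),
                     runif(40) > 0.2, rlnorm(40, log(650), 0.3))
  recs <- filter_rt_sd(filter_rt_floor(recs), k = 2)
  sm <- subject_measures(recs)
  ok <- sm[sm$condition != "all", ]
  pct_correct <- 100 * sapply(seq_len(nrow(ok)), function(i) {
    kept <- recs[!recs$rt_floor_excluded & !recs$rt_sd_excluded &
                   recs$condition == ok$condition[i], ]
    mean(kept$correct)
  })
  expect_equal(ok$error_pct + pct_correct, rep(100, nrow(ok)))
  expect_true(all(ok$n_trials <= table(recs$condition)[ok$condition]))
})
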