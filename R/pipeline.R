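#' Pipeline run configuration
#'
#' Collects every numeric parameter of the pipeline with its standard
#' default: 3-sample artifact padding, 500-ms baseline, 0.70 interpolated
#' exclusion threshold, the per-task 500-ms summary windows, the
#' cluster rule (p < 0.001, at least 6 contiguous samples), the 300-ms RT
#' floor, 3-SD trial and subject trims, and the 0.05 stepwise entry
#' threshold. Round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param tasks Tasks to analyze.
#' @param pad_samples,baseline,exclusion_threshold,windows,span
#'   Preprocessing and epoching parameters.
#' @param cluster_alpha,cluster_min_run Cluster rule.
#' @param rt_floor_ms,rt_sd_k,subject_outlier_k Behavioral filters.
#' @param entry_alpha Stepwise entry threshold (0.05; 0.10 is the
#'   accepted lenient variant).
#' @param seed Root seed for simulation-backed runs.
#' @param ... Overrides stored verbatim.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(tasks = .tasks,
                            pad_samples = 3,
                            baseline = c(-500, 0),
                            exclusion_threshold = 0.70,
                            windows = list(`2back` = c(1100, 1600),
                                           stroop = c(1000, 1500),
                                           switch = c(1300, 1800)),
                            span = c(-500, 3000),
                            cluster_alpha = 0.001,
                            cluster_min_run = 6,
                            rt_floor_ms = 300,
                            rt_sd_k = 3,
                            subject_outlier_k = 3,
                            entry_alpha = 0.05,
                            seed = 1,
                            ...) {
  structure(
    c(list(tasks = tasks, pad_samples = pad_samples, baseline = baseline,
           exclusion_threshold = exclusion_threshold, windows = windows,
           span = span, cluster_alpha = cluster_alpha,
           cluster_min_run = cluster_min_run, rt_floor_ms = rt_floor_ms,
           rt_sd_k = rt_sd_k, subject_outlier_k = subject_outlier_k,
           entry_alpha = entry_alpha, seed = seed),
      list(...)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Validate an on-disk dataset
#'
#' Checks every `samples_*.tsv` and `events_*.tsv` file in a directory
#' against the package's schemas and invariants, and warns about events
#' whose onset lies outside the span of the matching sample trace.
#'
#' @param dir Dataset directory.
#' @param rate_hz Nominal sampling rate.
#' @return Tibble `file`, `ok`, `reason` (`NA` when valid).
#' @export
validate_dataset <- function(dir, rate_hz = 60) {
  files <- list.files(dir, pattern = "^(samples|events)_.*\\.tsv$")
  if (length(files) == 0) abort(sprintf("no dataset files found in %s", dir))
  res <- purrr::map_dfr(files, function(f) {
    ok <- TRUE; reason <- NA_character_
    tryCatch({
      if (startsWith(f, "samples_")) {
        read_pupil_samples(file.path(dir, f), rate_hz = rate_hz)
      } else {
        ev <- read_pupil_events(file.path(dir, f))
        sf <- file.path(dir, sub("^events_", "samples_", f))
        if (file.exists(sf)) {
          # the samples file is validated on its own; a broken one should
          # not fail the event table, so the cross-check is best-effort
          tryCatch({
            sm <- suppressWarnings(read_pupil_samples(sf, rate_hz = rate_hz))
            out <- ev$trial_index[ev$onset_ms < min(sm$time_ms) |
                                    ev$onset_ms > max(sm$time_ms)]
            if (length(out) > 0) {
              warn(sprintf("%s: trial(s) %s outside the trace span", f,
                           paste(out, collapse = ", ")))
            }
          }, error = function(e) NULL)
        }
      }
    }, error = function(e) {
      ok <<- FALSE; reason <<- conditionMessage(e)
    })
    tibble::tibble(file = f, ok = ok, reason = reason)
  })
  res
}

# preprocess one subject-task pair up to window means + inclusion
process_subject_task <- function(samples, events, config, rate_hz = 60) {
  task <- events$task[1]
  window <- config$windows[[task]]
  trace <- combine_eyes(samples, rate_hz = rate_hz) |>
    pad_missing(pad_samples = config$pad_samples) |>
    interpolate_linear()
  epochs <- epoch_trace(trace, events, span = config$span) |>
    baseline_correct(baseline = config$baseline)
  inclusion <- apply_exclusion(epochs, window = window,
                               threshold = config$exclusion_threshold,
                               baseline = config$baseline)
  included <- filter_included(epochs, inclusion)
  means <- window_mean(included, window = window)
  list(epochs = included, inclusion = inclusion, window_means = means)
}

# condition waveform analysis for one task across subjects
analyze_task_waveforms <- function(epochs, task, config) {
  contrast <- switch(task,
    stroop = c("incongruent", "congruent"),
    switch = c("switch", "nonswitch"),
    NULL
  )
  if (!is.null(contrast)) {
    epochs <- dplyr::filter(epochs, .data$condition %in% contrast)
  }
  wf <- subject_waveforms(epochs, correct_only = TRUE)
  ga <- grand_average(wf)
  tests <- NULL; clusters <- NULL
  if (!is.null(contrast)) {
    tests <- tryCatch(
      samplewise_paired_t(wf, contrast[1], contrast[2], on_unpaired = "drop"),
      error = function(e) {
        warn(sprintf("%s contrast skipped: %s", task, conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(tests)) {
      clusters <- detect_clusters(tests, alpha = config$cluster_alpha,
                                  min_run = config$cluster_min_run)
    }
  }
  list(waveforms = wf, grand_average = ga, tests = tests, clusters = clusters,
       contrast = contrast)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> epoch -> analyze ->
#' report. Given a dataset directory the study is read from disk;
#' otherwise a synthetic study is simulated from `sim`/`design` under the
#' config's seed. The result bundle contains per-subject descriptives,
#' condition grand averages with cluster annotations, behavioral indices,
#' correlation matrices and the error-vs-correct dilation contrasts; with
#' `out_dir` everything is also written as TSV plus a plain-text report
#' whose header records the config and its hash.
#'
#' @param config A [pipeline_config()].
#' @param data_dir Optional dataset directory (as written by
#'   [simulate_study()]).
#' @param out_dir Optional output directory.
#' @param sim,design Simulation configs used when `data_dir` is `NULL`.
#' @return A list of class `pupilflow_run`: `window_means`, `measures`,
#'   `behavior` (per-task index tibbles), `waveforms` (per task:
#'   grand average, tests, clusters), `correlations`, `contrasts`,
#'   `exclusion_census`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), data_dir = NULL,
                         out_dir = NULL, sim = sim_config(),
                         design = design_config()) {
  rate_hz <- if (is.null(data_dir)) sim$rate_hz else 60
  if (is.null(data_dir)) {
    study <- simulate_study(sim, design, tasks = config$tasks, seed = config$seed)
    pairs <- purrr::flatten(purrr::map(names(study$subjects), function(s) {
      purrr::map(config$tasks, function(tk) study$subjects[[s]][[tk]])
    }))
  } else {
    ev_files <- list.files(data_dir, pattern = "^events_.*\\.tsv$", full.names = TRUE)
    pairs <- purrr::map(ev_files, function(f) {
      list(events = read_pupil_events(f),
           samples = suppressWarnings(
             read_pupil_samples(sub("events_", "samples_", f), rate_hz = rate_hz)))
    })
  }
  pairs <- purrr::keep(pairs, function(p) p$events$task[1] %in% config$tasks)

  processed <- purrr::map(pairs, function(p) {
    res <- tryCatch(
      process_subject_task(p$samples, p$events, config, rate_hz = rate_hz),
      error = function(e) {
        warn(sprintf("skipping subject %s task %s: %s",
                     p$events$subject_id[1], p$events$task[1], conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(res)) res$events <- p$events
    res
  })
  processed <- purrr::compact(processed)
  if (length(processed) == 0) abort("no subject-task pair survived preprocessing")

  all_epochs <- dplyr::bind_rows(purrr::map(processed, "epochs"))
  attr(all_epochs, "rate_hz") <- rate_hz
  all_inclusion <- dplyr::bind_rows(purrr::map(processed, "inclusion"))
  all_means <- dplyr::bind_rows(purrr::map(processed, "window_means"))
  all_events <- dplyr::bind_rows(purrr::map(processed, "events"))

  census <- all_inclusion |>
    dplyr::group_by(.data$task, .data$condition) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     n_included = sum(.data$included),
                     retention = mean(.data$included), .groups = "drop")

  # behavioral scoring and filters
  records <- all_events
  if ("2back" %in% config$tasks) {
    nb <- score_2back(dplyr::filter(records, .data$task == "2back"))
    records <- dplyr::bind_rows(nb, dplyr::filter(records, .data$task != "2back"))
  }
  records <- records |>
    filter_rt_floor(floor_ms = config$rt_floor_ms) |>
    filter_rt_sd(k = config$rt_sd_k)
  if (!"scorable" %in% names(records)) records$scorable <- NA
  behavior <- list()
  if ("stroop" %in% config$tasks) behavior$stroop <- stroop_effect(records)
  if ("switch" %in% config$tasks) behavior$switch <- switch_cost(records)
  measures <- subject_measures(dplyr::filter(
    records, !(.data$task == "2back" & !(.data$scorable %in% TRUE))))

  waveres <- purrr::map(config$tasks, function(tk) {
    ep <- dplyr::filter(all_epochs, .data$task == tk)
    if (nrow(ep) == 0) return(NULL)
    analyze_task_waveforms(ep, tk, config)
  })
  names(waveres) <- config$tasks

  # per-subject dilation measures and the between-subject layer
  dil <- all_means |>
    dplyr::group_by(.data$subject_id, .data$task, .data$condition, .data$correct) |>
    dplyr::summarise(dilation_mm = mean(.data$window_mean_mm), .groups = "drop")
  correlations <- list()
  contrasts <- list()
  for (tk in config$tasks) {
    dtk <- dplyr::filter(dil, .data$task == tk)
    err <- measures |>
      dplyr::filter(.data$task == tk, .data$condition == "all") |>
      dplyr::select("subject_id", "error_pct", "mean_rt_ms")
    pd_correct <- dtk |>
      dplyr::filter(.data$correct %in% TRUE) |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(pd_correct = mean(.data$dilation_mm), .groups = "drop")
    tbl <- dplyr::left_join(err, pd_correct, by = "subject_id")
    correlations[[tk]] <- correlation_matrix(tbl)
    # error-related contrast: dilation on incorrect vs correct trials
    wide <- dtk |>
      dplyr::group_by(.data$subject_id, .data$correct) |>
      dplyr::summarise(d = mean(.data$dilation_mm), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "correct", values_from = "d")
    if (all(c("TRUE", "FALSE") %in% names(wide))) {
      ok <- stats::complete.cases(wide[["TRUE"]], wide[["FALSE"]])
      if (sum(ok) >= 3) {
        contrasts[[tk]] <- paired_contrast(wide[["FALSE"]][ok], wide[["TRUE"]][ok])
      }
    }
  }

  run <- structure(
    list(window_means = all_means, measures = measures, behavior = behavior,
         waveforms = waveres, correlations = correlations,
         contrasts = contrasts, exclusion_census = census,
         inclusion = all_inclusion,
         config = config, config_hash = rlang::hash(unclass(config))),
    class = "pupilflow_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# write the result bundle as TSVs plus a plain-text report
write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_tsv(run$measures, file.path(out_dir, "subject_measures.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$window_means, file.path(out_dir, "window_means.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$exclusion_census, file.path(out_dir, "exclusion_census.tsv"),
                   progress = FALSE)
  for (tk in names(run$waveforms)) {
    wr <- run$waveforms[[tk]]
    if (is.null(wr)) next
    readr::write_tsv(wr$grand_average,
                     file.path(out_dir, sprintf("grand_average_%s.tsv", tk)),
                     progress = FALSE)
    if (!is.null(wr$clusters)) {
      cl <- tibble::as_tibble(wr$clusters)
      cl$contrast <- paste(wr$contrast, collapse = "_vs_")
      readr::write_tsv(cl, file.path(out_dir, sprintf("clusters_%s.tsv", tk)),
                       progress = FALSE)
    }
  }
  for (tk in names(run$correlations)) {
    readr::write_tsv(run$correlations[[tk]],
                     file.path(out_dir, sprintf("correlations_%s.tsv", tk)),
                     progress = FALSE)
  }
  writeLines(render_report(run), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

# plain-text report mirroring the descriptive/correlation table layout
render_report <- function(run) {
  lines <- c(
    "pupilflow analysis report",
    sprintf("config hash: %s", run$config_hash),
    sprintf("seed: %s", run$config$seed),
    "",
    "== Trial retention (interpolated-data exclusion) =="
  )
  for (i in seq_len(nrow(run$exclusion_census))) {
    r <- run$exclusion_census[i, ]
    lines <- c(lines, sprintf("  %-8s %-12s %4d / %4d kept (%.1f%%)",
                              r$task, r$condition %||% "-", r$n_included,
                              r$n_trials, 100 * r$retention))
  }
  lines <- c(lines, "", "== Group descriptives ==")
  grp <- run$measures |>
    dplyr::group_by(.data$task, .data$condition) |>
    dplyr::summarise(error_pct = mean(.data$error_pct),
                     rt = mean(.data$mean_rt_ms, na.rm = TRUE), .groups = "drop")
  for (i in seq_len(nrow(grp))) {
    r <- grp[i, ]
    lines <- c(lines, sprintf("  %-8s %-12s errors %5.1f%%  RT %6.0f ms",
                              r$task, r$condition, r$error_pct, r$rt))
  }
  lines <- c(lines, "", "== Condition contrasts (waveform clusters) ==")
  for (tk in names(run$waveforms)) {
    wr <- run$waveforms[[tk]]
    if (is.null(wr) || is.null(wr$clusters)) next
    if (nrow(wr$clusters) == 0) {
      lines <- c(lines, sprintf("  %s (%s): no significant clusters", tk,
                                paste(wr$contrast, collapse = " vs ")))
    } else {
      for (i in seq_len(nrow(wr$clusters))) {
        cl <- wr$clusters[i, ]
        lines <- c(lines, sprintf(
          "  %s (%s): %.0f-%.0f ms, %d samples, mean t = %.2f",
          tk, paste(wr$contrast, collapse = " vs "),
          cl$start_ms, cl$end_ms, cl$n_samples, cl$mean_t))
      }
    }
  }
  lines <- c(lines, "", "== Error-related dilation contrasts ==")
  for (tk in names(run$contrasts)) {
    x <- run$contrasts[[tk]]
    lines <- c(lines, sprintf(
      "  %s: incorrect %.3f vs correct %.3f mm, F(%d,%d) = %.2f, p = %.3g, pes = %.3f",
      tk, x$mean_a, x$mean_b, x$df1, x$df2, x$f, x$p, x$pes))
  }
  lines
}

#' @export
print.pupilflow_run <- function(x, ...) {
  cat(paste(render_report(x), collapse = "\n"), "\n")
  invisible(x)
}
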