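# Tabular I/O and the end-to-end pipeline.
#
# All tables are TSV with a header line. Column contracts:
#   samples: participant, trial, t_ms, x_px, y_px, valid
#   trials:  the generate_design()/simulate_behavior() columns
#   events:  the detect_events() columns

samples_cols <- c("participant", "trial", "t_ms", "x_px", "y_px", "valid")

#' Read and write gaze-sample tables
#'
#' TSV round-trip for the samples contract. Reading validates the header
#' and per-trial timestamp monotonicity and reports the offending line on
#' failure.
#'
#' @param path File path.
#' @return `read_samples()` returns a samples tibble.
#' @export
read_samples <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(samples_cols, names(d))
  if (length(missing_cols) > 0) {
    stop("samples file lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d$participant <- as.character(d$participant)
  d$trial <- as.integer(d$trial)
  key <- paste(d$participant, d$trial)
  new_trial <- key != dplyr::lag(key, default = "")
  bad <- which(!new_trial & diff(c(-Inf, d$t_ms)) <= 0)
  if (length(bad) > 0) {
    stop("non-monotone timestamps within a trial at line ", bad[1] + 1,
         call. = FALSE)
  }
  d[samples_cols]
}

#' @rdname read_samples
#' @param samples A samples tibble.
#' @export
write_samples <- function(samples, path) {
  out <- samples[samples_cols]
  # Canonical formatting: positions at millipixel precision, so that
  # write(read(f)) is byte-identical.
  out$x_px <- round(out$x_px, 3)
  out$y_px <- round(out$y_px, 3)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write trial and event tables
#'
#' @param path File path.
#' @return The corresponding tibble.
#' @export
read_trials <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("experiment", "participant", "trial", "prior", "condition")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols) > 0) {
    stop("trials file lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d$participant <- as.character(d$participant)
  d
}

#' @rdname read_trials
#' @param x A tibble to write.
#' @export
write_trials <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_trials
#' @export
read_events <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("participant", "trial", "kind", "onset_ms", "offset_ms")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols) > 0) {
    stop("events file lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d$participant <- as.character(d$participant)
  d
}

#' @rdname read_trials
#' @export
write_events <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Collects everything one reproducible run needs. `seed` is mandatory:
#' every stochastic stage draws from seeds derived from it.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param n_participants Cohort size to simulate (ignored when `samples`
#'   and `trials` paths are given).
#' @param seed Integer root seed.
#' @param out_dir Output directory for the result bundle.
#' @param samples,trials Optional paths to existing input tables; when
#'   `NULL` the cohort is simulated.
#' @param roi_config Optional path to an ROI YAML ([read_roiset()]).
#' @param behavior,gaze,detection,rules Parameter objects (or lists of
#'   arguments) for the corresponding stages.
#' @param inject Logical: inject blinks/data loss into simulated gaze.
#' @return An object of class `run_config`.
#' @export
run_config <- function(experiment, n_participants = 4, seed, out_dir,
                       samples = NULL, trials = NULL, roi_config = NULL,
                       behavior = behavior_params(),
                       gaze = gaze_sim_params(),
                       detection = detection_params(),
                       rules = exclusion_rules(),
                       inject = TRUE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  for (p in c(samples, trials, roi_config)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured path does not exist: ", p, call. = FALSE)
    }
  }
  experiment_spec(experiment)  # validates the id
  structure(list(experiment = experiment, n_participants = n_participants,
                 seed = as.integer(seed), out_dir = out_dir,
                 samples = samples, trials = trials, roi_config = roi_config,
                 behavior = behavior, gaze = gaze, detection = detection,
                 rules = rules, inject = inject),
            class = "run_config")
}

#' Run the full pipeline
#'
#' simulate (optional) -> detect -> validate -> metrics -> stats. Writes
#' every intermediate table (TSV) plus a provenance record (seed, package
#' version, configuration hash) to `out_dir` and returns the bundle
#' invisibly as a list.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage messages.
#' @return (Invisibly) a list with `trials`, `samples`, `events`,
#'   `trial_validity`, `participant_validity`, `metrics`, `stats` and
#'   `provenance`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[gazexpect] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  rois <- if (!is.null(config$roi_config)) read_roiset(config$roi_config)
          else build_default_roiset()
  screen <- roi_screen(rois)

  if (!is.null(config$trials) && !is.null(config$samples)) {
    say("loading input tables")
    trials <- read_trials(config$trials)
    samples <- read_samples(config$samples)
  } else {
    say("simulating cohort: ", config$experiment, ", ",
        config$n_participants, " participants")
    design <- generate_cohort_design(config$experiment,
                                     config$n_participants, config$seed)
    trials <- simulate_behavior(design, config$behavior,
                                seed = config$seed + 1L)
    sim <- simulate_gaze_cohort(trials, config$gaze, rois,
                                seed = config$seed + 2L)
    samples <- sim$samples
    if (isTRUE(config$inject)) {
      samples <- inject_artifacts(samples, config$gaze$loss_rate,
                                  config$gaze$blink_rate,
                                  seed = config$seed + 3L)
    }
  }

  say("detecting events")
  events <- detect_events(samples, config$detection, screen,
                          config$gaze$sampling_rate)

  say("applying exclusion rules")
  tv <- validate_trials(trials, samples, events, rois, config$rules)
  pv <- validate_participants(tv, trials, config$rules)
  say(sum(!tv$included), "/", nrow(tv), " trials excluded; ",
      sum(!pv$included), "/", nrow(pv), " participants excluded")

  ok_participants <- pv$participant[pv$included]
  valid <- trials |>
    dplyr::semi_join(dplyr::filter(tv, .data$included),
                     by = c("participant", "trial")) |>
    dplyr::filter(.data$participant %in% ok_participants) |>
    roi_class_map()

  say("computing metrics")
  metrics <- list(rt = rt_summary(valid),
                  assimilation = assimilation_index(valid))
  stats_out <- list()
  if (config$experiment == "exp1") {
    metrics$predictive <- predictive_saccade_table(valid, events, rois,
                                                   config$detection)
    wide <- metrics$predictive |>
      tidyr::pivot_wider(names_from = c("sacc_rank", "expectation"),
                         values_from = "pct")
    if (nrow(wide) >= 3 && !anyNA(wide)) {
      long <- metrics$predictive |>
        dplyr::mutate(sacc_rank = factor(.data$sacc_rank))
      stats_out$predictive_anova <-
        rm_anova(long, subject = "participant", value = "pct",
                 within = c("expectation", "sacc_rank"))
    }
  } else {
    metrics$fixation_order <- fixation_order_table(valid, events, rois,
                                                   seed = config$seed + 4L)
    metrics$sampling <- sampling_summary(valid, events, rois)
    metrics$last_fixation <- last_fixation_bias(valid, events, rois)
    ord <- metrics$fixation_order |>
      dplyr::filter(.data$roi_class == "expected")
    # The 3-df quadratic form needs clearly more clusters than categories.
    if (nrow(ord) > 0 && dplyr::n_distinct(ord$participant) >= 5) {
      stats_out$order_gof <- clustered_gof(
        ord$participant, ord$ordinal, pi0 = rep(0.25, 4), levels = 1:4)
    }
  }
  if (dplyr::n_distinct(metrics$rt$participant) >= 3) {
    stats_out$rt_anova <- rm_anova(metrics$rt, subject = "participant",
                                   value = "mean_rt_ms",
                                   within = "condition")
  }
  if (nrow(metrics$assimilation) >= 3) {
    stats_out$assimilation_t <-
      paired_tests(metrics$assimilation$assimilation_index, mu = 50)
  }

  say("writing bundle")
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  provenance <- list(package = "gazexpect",
                     version = as.character(utils::packageVersion("gazexpect")),
                     seed = config$seed, experiment = config$experiment,
                     config_hash = cfg_hash,
                     timestamp = format(Sys.time(), tz = "UTC"))
  write_trials(trials, file.path(config$out_dir, "trials.tsv"))
  write_samples(samples, file.path(config$out_dir, "samples.tsv"))
  write_events(events, file.path(config$out_dir, "events.tsv"))
  write_trials(tv, file.path(config$out_dir, "trial_validity.tsv"))
  write_trials(pv, file.path(config$out_dir, "participant_validity.tsv"))
  write_trials(metrics$rt, file.path(config$out_dir, "rt_summary.tsv"))
  write_trials(metrics$assimilation,
               file.path(config$out_dir, "assimilation.tsv"))
  stats_tbl <- if (length(stats_out) > 0) {
    dplyr::bind_rows(stats_out, .id = "analysis")
  } else {
    tibble::tibble(analysis = character(), name = character(),
                   statistic = numeric(), p_value = numeric())
  }
  write_trials(stats_tbl, file.path(config$out_dir, "stats.tsv"))
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE)

  invisible(list(trials = trials, samples = samples, events = events,
                 trial_validity = tv, participant_validity = pv,
                 metrics = metrics, stats = stats_out,
                 provenance = provenance))
}
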