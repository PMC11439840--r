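# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

default_rois <- function() {
  if (is.null(.fixtures$rois)) .fixtures$rois <- build_default_roiset()
  .fixtures$rois
}

# A small simulated cohort (design + responses + clean gaze + detected
# events), keyed by its arguments.
small_cohort <- function(experiment = "exp1", n_participants = 2, seed = 101,
                         gaze = gaze_sim_params(), behavior = behavior_params(),
                         n_trials = NULL) {
  key <- rlang::hash(list(experiment, n_participants, seed, gaze, behavior,
                          n_trials))
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  rois <- default_rois()
  design <- generate_cohort_design(experiment, n_participants, seed)
  trials <- simulate_behavior(design, behavior, seed = seed + 1)
  if (!is.null(n_trials)) trials <- trials[seq_len(n_trials), ]
  sim <- simulate_gaze_cohort(trials, gaze, rois, seed = seed + 2)
  events <- detect_events(sim$samples, detection_params(),
                          roi_screen(rois), gaze$sampling_rate)
  out <- list(trials = trials, samples = sim$samples,
              truth = sim$events, events = events, rois = rois)
  .fixtures[[key]] <- out
  out
}

# Hand-built events table row.
make_event <- function(participant = "p1", trial = 1L, kind = "fixation",
                       onset, offset, x = 0, y = 0, x_off = x, y_off = y) {
  tibble::tibble(participant = participant, trial = trial, kind = kind,
                 onset_ms = onset, offset_ms = offset,
                 duration_ms = offset - onset,
                 x_on = x, y_on = y, x_off = x_off, y_off = y_off,
                 amplitude_deg = NA_real_, peak_vel = NA_real_,
                 x_centroid = ifelse(kind == "fixation", x, NA_real_),
                 y_centroid = ifelse(kind == "fixation", y, NA_real_))
}

# Centre of a feature ROI (first rectangle of the label).
feature_center <- function(lab, rois = default_rois()) {
  r <- rois[rois$label == lab & rois$role == "feature", ][1, ]
  c(x = r$x + r$w / 2, y = r$y + r$h / 2)
}
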