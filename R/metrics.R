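# Derived eye-movement and behavioural measures.
#
# Per-trial ROI classes: the "expected" ROI is the feature of the cued
# identity; the "unexpected" ROI is the feature of the shown identity in
# mismatch trials or of the other morph member in partial trials (match
# trials have no unexpected ROI); the remaining two feature ROIs are the
# "other" ROIs.

#' Per-trial ROI class map
#'
#' Adds `expected_roi`, `unexpected_roi` and `other_rois` (comma-joined)
#' columns to a trial table.
#'
#' @param trials Design (+ response) tibble.
#' @return The trials tibble with ROI-class columns.
#' @export
roi_class_map <- function(trials) {
  feats <- unname(identity_features)
  trials |>
    dplyr::mutate(
      expected_roi = .data$prior_feature,
      unexpected_roi = dplyr::case_when(
        condition == "mismatch" ~ unname(identity_features[shown_identity]),
        condition == "partial" ~ unname(identity_features[partner]),
        TRUE ~ NA_character_
      ),
      other_rois = purrr::map2_chr(
        .data$expected_roi, .data$unexpected_roi,
        function(e, u) paste(setdiff(feats, c(e, u)), collapse = ","))
    )
}

roi_class_of <- function(label, expected, unexpected) {
  dplyr::case_when(
    is.na(label) ~ NA_character_,
    label == expected ~ "expected",
    !is.na(unexpected) & label == unexpected ~ "unexpected",
    TRUE ~ "other"
  )
}

# Fixations of one trial during a window, with their feature-ROI label.
trial_fixations <- function(ev, rois, w0, w1) {
  fx <- ev[ev$kind == "fixation" & ev$offset_ms > w0 & ev$onset_ms < w1, ,
           drop = FALSE]
  if (nrow(fx) > 0) {
    fx$roi <- classify_point(fx$x_centroid, fx$y_centroid, rois,
                             role = "feature")
  } else {
    fx$roi <- character(0)
  }
  fx
}

split_events <- function(events) {
  key <- paste(events$participant, events$trial)
  split(seq_len(nrow(events)), factor(key, unique(key)))
}

#' Anticipatory-saccade 2 x 2 relative-frequency table
#'
#' For every feature ROI, the percentage of qualifying first (second)
#' anticipatory saccades landing in it is computed separately over trials
#' in which its feature was expected and trials in which it was not; each
#' ROI's feature is expected in a quarter of the trials (1:3), which the
#' per-ROI relative frequencies account for. The four per-ROI percentages
#' are then averaged, yielding one value per `saccade rank x expectation`
#' cell per participant.
#'
#' @param trials Validated Experiment 1 design + response tibble.
#' @param events Events tibble.
#' @param rois A [roiset()].
#' @param params A [detection_params()] (latency criterion).
#' @return A tibble: `participant`, `sacc_rank` (1, 2), `expectation`
#'   (`expected`, `unexpected`), `pct` (may be `NaN` when a participant has
#'   no qualifying saccade in a cell).
#' @export
predictive_saccade_table <- function(trials, events,
                                     rois = build_default_roiset(),
                                     params = detection_params()) {
  eparts <- split_events(events)
  feats <- unname(identity_features)

  per_trial <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    key <- paste(tr$participant, tr$trial)
    if (!key %in% names(eparts)) return(NULL)
    ev <- events[eparts[[key]], ]
    sac <- predictive_saccades(ev, tr$t_outline_on, tr$t_face_on, params)
    if (nrow(sac) == 0) return(NULL)
    land <- classify_point(sac$x_off, sac$y_off, rois, role = "feature")
    tibble::tibble(participant = tr$participant,
                   expected_feature = tr$prior_feature,
                   sacc_rank = sac$sacc_rank, landing = land)
  })
  per_trial <- dplyr::bind_rows(per_trial)

  grid <- tidyr::expand_grid(
    participant = unique(trials$participant),
    sacc_rank = 1:2, roi = feats, expectation = c("expected", "unexpected"))
  cells <- grid |>
    dplyr::left_join(per_trial, by = c("participant", "sacc_rank"),
                     relationship = "many-to-many") |>
    dplyr::filter(is.na(.data$expected_feature) |
                    (.data$expectation == "expected") ==
                    (.data$roi == .data$expected_feature)) |>
    dplyr::group_by(.data$participant, .data$sacc_rank, .data$roi,
                    .data$expectation) |>
    dplyr::summarise(
      n = sum(!is.na(.data$expected_feature)),
      hits = sum(.data$landing == .data$roi, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(pct = 100 * .data$hits / .data$n)

  cells |>
    dplyr::group_by(.data$participant, .data$sacc_rank, .data$expectation) |>
    dplyr::summarise(pct = mean(.data$pct), .groups = "drop")
}

#' Fixation order of the feature ROIs in one trial
#'
#' Ranks the four feature ROIs by the onset of their first fixation during
#' the face presentation (ordinals 1-4). ROIs that were never fixated are
#' assigned the remaining ordinals uniformly at random, so the result is
#' always a bijection onto 1-4. Trials without any feature-ROI fixation are
#' not applicable and return `NULL`.
#'
#' @param ev Events tibble of one trial.
#' @param rois A [roiset()].
#' @param w0,w1 Analysis window in ms (face presentation).
#' @return A tibble `roi`, `ordinal`, `fixated`, or `NULL`.
#' @export
fixation_order <- function(ev, rois, w0 = -Inf, w1 = Inf) {
  feats <- unname(identity_features)
  fx <- trial_fixations(ev, rois, w0, w1)
  fx <- fx[!is.na(fx$roi), , drop = FALSE]
  if (nrow(fx) == 0) return(NULL)
  first <- fx |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(onset = min(.data$onset_ms))
  first <- first[order(first$onset), ]
  out <- tibble::tibble(roi = feats, ordinal = NA_integer_,
                        fixated = feats %in% first$roi)
  out$ordinal[match(first$roi, out$roi)] <- seq_len(nrow(first))
  missing <- which(!out$fixated)
  if (length(missing) > 0) {
    free <- setdiff(1:4, out$ordinal)
    out$ordinal[missing] <- if (length(free) == 1) free else sample(free)
  }
  out
}

#' Fixation ordinals for a table of trials
#'
#' Applies [fixation_order()] to every trial; the random fill of unfixated
#' ROIs draws from `seed`.
#'
#' @param trials Validated trial tibble.
#' @param events Events tibble.
#' @param rois A [roiset()].
#' @param seed Integer seed for the random ordinal fill.
#' @return A tibble: `participant`, `trial`, `roi`, `roi_class`, `ordinal`,
#'   `fixated`; inapplicable trials are absent.
#' @export
fixation_order_table <- function(trials, events,
                                 rois = build_default_roiset(), seed = 1) {
  trials <- if ("expected_roi" %in% names(trials)) trials
            else roi_class_map(trials)
  eparts <- split_events(events)
  withr::with_seed(as.integer(seed), {
    out <- lapply(seq_len(nrow(trials)), function(i) {
      tr <- trials[i, ]
      key <- paste(tr$participant, tr$trial)
      if (!key %in% names(eparts)) return(NULL)
      ord <- fixation_order(events[eparts[[key]], ], rois,
                            w0 = tr$t_face_on, w1 = trial_end_ms(tr))
      if (is.null(ord)) return(NULL)
      ord$participant <- tr$participant
      ord$trial <- tr$trial
      ord$roi_class <- roi_class_of(ord$roi, tr$expected_roi,
                                    tr$unexpected_roi)
      ord
    })
    dplyr::bind_rows(out) |>
      dplyr::select("participant", "trial", "roi", "roi_class", "ordinal",
                    "fixated")
  })
}

#' Which ROI group was fixated first
#'
#' Compares the earliest first-fixation onset of two label groups within a
#' window. A group that was never fixated loses to one that was; if
#' neither was fixated the trial is not applicable.
#'
#' @param ev Events tibble of one trial.
#' @param group_a,group_b Character vectors of feature-ROI labels.
#' @param rois A [roiset()].
#' @param w0,w1 Analysis window in ms.
#' @return `"a_first"`, `"b_first"` or `"not_applicable"`.
#' @export
first_between <- function(ev, group_a, group_b,
                          rois = build_default_roiset(),
                          w0 = -Inf, w1 = Inf) {
  fx <- trial_fixations(ev, rois, w0, w1)
  ta <- suppressWarnings(min(fx$onset_ms[fx$roi %in% group_a], na.rm = TRUE))
  tb <- suppressWarnings(min(fx$onset_ms[fx$roi %in% group_b], na.rm = TRUE))
  if (is.infinite(ta) && is.infinite(tb)) return("not_applicable")
  if (ta < tb) "a_first" else "b_first"
}

#' Fixation-count and dwell-time proportions of one trial
#'
#' Count proportion: fixations on a class's ROIs divided by all fixations
#' during the face presentation. Dwell proportion: fixation time inside the
#' class's ROIs (clipped to the presentation window) divided by the
#' presentation duration.
#'
#' @param ev Events tibble of one trial.
#' @param expected,unexpected Feature labels of the expected/unexpected ROI
#'   (`unexpected` may be `NA`).
#' @param rois A [roiset()].
#' @param w0,w1 Face-presentation window in ms.
#' @return A tibble `roi_class`, `n_fix`, `count_pct`, `dwell_ms`,
#'   `dwell_pct`, or `NULL` when the trial has no fixation at all.
#' @export
sampling_proportions <- function(ev, expected, unexpected,
                                 rois = build_default_roiset(), w0, w1) {
  fx <- trial_fixations(ev, rois, w0, w1)
  if (nrow(fx) == 0) return(NULL)
  fx$roi_class <- roi_class_of(fx$roi, expected, unexpected)
  fx$clip_ms <- pmin(fx$offset_ms, w1) - pmax(fx$onset_ms, w0)
  total_fix <- nrow(fx)
  pres <- w1 - w0
  classes <- c("expected", "unexpected", "other")
  out <- lapply(classes, function(cl) {
    sel <- !is.na(fx$roi_class) & fx$roi_class == cl
    tibble::tibble(roi_class = cl, n_fix = sum(sel),
                   count_pct = 100 * sum(sel) / total_fix,
                   dwell_ms = sum(fx$clip_ms[sel]),
                   dwell_pct = 100 * sum(fx$clip_ms[sel]) / pres)
  })
  out <- dplyr::bind_rows(out)
  if (is.na(unexpected)) {
    out$count_pct[out$roi_class == "unexpected"] <- NA_real_
    out$dwell_pct[out$roi_class == "unexpected"] <- NA_real_
  }
  out
}

#' Time-binned fixation-count and dwell proportions of one trial
#'
#' Splits the face presentation into `n_bins` windows of `bin_ms` each. A
#' fixation contributes to every bin it overlaps; dwell time is split
#' across bin boundaries. Bins starting at or after the trial's actual
#' presentation end are marked missing.
#'
#' @inheritParams sampling_proportions
#' @param bin_ms Bin width in ms.
#' @param n_bins Number of bins from face onset.
#' @return A tibble `bin`, `roi_class`, `n_fix`, `dwell_ms`, `dwell_pct`,
#'   `available`.
#' @export
binned_sampling <- function(ev, expected, unexpected,
                            rois = build_default_roiset(), w0, w1,
                            bin_ms = 500, n_bins = 4) {
  classes <- c("expected", "unexpected", "other")
  fx <- trial_fixations(ev, rois, w0, w1)
  fx$roi_class <- roi_class_of(fx$roi, expected, unexpected)
  out <- lapply(seq_len(n_bins), function(b) {
    b0 <- w0 + (b - 1) * bin_ms
    b1 <- b0 + bin_ms
    avail <- b0 < w1
    res <- lapply(classes, function(cl) {
      sel <- !is.na(fx$roi_class) & fx$roi_class == cl &
        fx$offset_ms > b0 & fx$onset_ms < b1
      dwell <- sum(pmin(fx$offset_ms[sel], b1, w1) - pmax(fx$onset_ms[sel], b0))
      tibble::tibble(bin = b, roi_class = cl,
                     n_fix = if (avail) sum(sel) else NA_integer_,
                     dwell_ms = if (avail) dwell else NA_real_,
                     dwell_pct = if (avail) 100 * dwell / (min(b1, w1) - b0)
                                 else NA_real_,
                     available = avail)
    })
    dplyr::bind_rows(res)
  })
  dplyr::bind_rows(out)
}

#' Mean fixation duration per ROI class of one trial
#'
#' @inheritParams sampling_proportions
#' @return A tibble `roi_class`, `mean_duration_ms` (`NA` for classes
#'   without fixations).
#' @export
mean_fixation_durations <- function(ev, expected, unexpected,
                                    rois = build_default_roiset(),
                                    w0 = -Inf, w1 = Inf) {
  fx <- trial_fixations(ev, rois, w0, w1)
  fx$roi_class <- roi_class_of(fx$roi, expected, unexpected)
  classes <- c("expected", "unexpected", "other")
  dplyr::bind_rows(lapply(classes, function(cl) {
    d <- fx$duration_ms[!is.na(fx$roi_class) & fx$roi_class == cl]
    tibble::tibble(roi_class = cl,
                   mean_duration_ms = if (length(d) > 0) mean(d) else NA_real_)
  }))
}

#' Perceived-face-identity (assimilation) index
#'
#' For each of the 12 prior-by-morph combinations, expectation-noncompliant
#' responses are subtracted from expectation-compliant ones and divided by
#' that combination's response count; the per-combination scores are
#' averaged and mapped linearly to a 0-100% scale, so a perfectly balanced
#' responder scores 50%, a fully compliant one 100% and a fully
#' noncompliant one 0%. Compliance: choosing the expected identity
#' (pressing "expected", or naming the cued identity); noncompliance:
#' naming/choosing the other morph member (in the one-button experiment,
#' pressing "unexpected").
#'
#' @param trials Partial-condition trials with responses; other conditions
#'   are ignored.
#' @return A tibble `participant`, `assimilation_index` (%), `n_responses`.
#' @export
assimilation_index <- function(trials) {
  part <- trials |>
    dplyr::filter(.data$condition == "partial", .data$choice != "none",
                  !is.na(.data$choice))
  if (nrow(part) == 0) {
    stop("no partial-condition responses; index undefined", call. = FALSE)
  }
  part$compliant <- part$choice == "expected"
  if ("identity_choice" %in% names(part)) {
    # Two-stage responses: noncompliance requires naming the other morph
    # member; attributions to a third identity are neither. One-button rows
    # (no identity attribution) fall back to the button response.
    part$noncompliant <- ifelse(
      is.na(part$identity_choice),
      part$choice == "unexpected",
      part$choice == "unexpected" & part$identity_choice == part$partner)
  } else {
    part$noncompliant <- part$choice == "unexpected"
  }
  part |>
    dplyr::group_by(.data$participant, .data$prior, .data$stimulus) |>
    dplyr::summarise(
      score = (sum(.data$compliant) - sum(.data$noncompliant)) / dplyr::n(),
      n = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(assimilation_index = 100 * (mean(.data$score) + 1) / 2,
                     n_responses = sum(.data$n), .groups = "drop")
}

#' Mean reaction time per condition
#'
#' Arithmetic mean over responded trials; by default all responded trials
#' enter regardless of correctness.
#'
#' @param trials Design + response tibble.
#' @param correct_only If `TRUE`, restrict clear-face conditions to correct
#'   responses.
#' @return A tibble `participant`, `condition`, `mean_rt_ms`, `n`.
#' @export
rt_summary <- function(trials, correct_only = FALSE) {
  d <- dplyr::filter(trials, !is.na(.data$rt_ms))
  if (correct_only) {
    d <- dplyr::filter(d, is.na(.data$correct) | .data$correct)
  }
  d |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(mean_rt_ms = mean(.data$rt_ms), n = dplyr::n(),
                     .groups = "drop")
}

# The fixation whose interval contains t (saccade in flight -> NA label).
fixation_at <- function(ev, t, rois) {
  fx <- ev[ev$kind == "fixation" & ev$onset_ms <= t & ev$offset_ms > t, ,
           drop = FALSE]
  if (nrow(fx) == 0) return(NA_character_)
  classify_point(fx$x_centroid[1], fx$y_centroid[1], rois, role = "feature")
}

#' Accuracy and morph choice conditioned on the face-onset fixation
#'
#' Splits Experiment 1 trials by whether the fixation active at face onset
#' lay inside the expected ROI, and reports per-participant accuracy in the
#' clear-face conditions and the proportion of expected-identity choices in
#' partial trials, for each split.
#'
#' @param trials Validated Experiment 1 trials with responses.
#' @param events Events tibble.
#' @param rois A [roiset()].
#' @return A tibble: `participant`, `condition`, `onset_expected`
#'   (logical), `n`, `value` (accuracy, or expected-choice proportion for
#'   partial trials), as proportions in 0-100.
#' @export
onset_roi_linkage <- function(trials, events, rois = build_default_roiset()) {
  trials <- if ("expected_roi" %in% names(trials)) trials
            else roi_class_map(trials)
  eparts <- split_events(events)
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    key <- paste(tr$participant, tr$trial)
    if (!key %in% names(eparts)) return(NULL)
    lab <- fixation_at(events[eparts[[key]], ], tr$t_face_on, rois)
    if (is.na(lab)) onset_expected <- FALSE
    else onset_expected <- lab == tr$expected_roi
    val <- if (tr$condition == "partial") tr$choice == "expected" else tr$correct
    if (is.na(val)) return(NULL)
    tibble::tibble(participant = tr$participant, condition = tr$condition,
                   onset_expected = onset_expected, value = val)
  })
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$participant, .data$condition,
                    .data$onset_expected) |>
    dplyr::summarise(n = dplyr::n(), value = 100 * mean(.data$value),
                     .groups = "drop")
}

#' Last-fixation bias in morph identification
#'
#' For Experiment 2 partial trials with an identity attribution, finds the
#' final feature-ROI fixation before the response and reports the
#' per-participant proportion of trials in which that ROI belongs to the
#' chosen identity (chance 25%).
#'
#' @param trials Validated Experiment 2 partial trials with responses.
#' @param events Events tibble.
#' @param rois A [roiset()].
#' @return A tibble `participant`, `n`, `prop_last_chosen` (0-100), or zero
#'   rows when no trial is eligible.
#' @export
last_fixation_bias <- function(trials, events, rois = build_default_roiset()) {
  eparts <- split_events(events)
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    if (tr$condition != "partial" || is.na(tr$choice) || tr$choice == "none") {
      return(NULL)
    }
    chosen <- if (tr$choice == "expected") tr$prior
              else if (!is.na(tr$identity_choice)) tr$identity_choice
              else NA_character_
    if (is.na(chosen)) return(NULL)
    key <- paste(tr$participant, tr$trial)
    if (!key %in% names(eparts)) return(NULL)
    ev <- events[eparts[[key]], ]
    fx <- trial_fixations(ev, rois, tr$t_face_on, trial_end_ms(tr))
    fx <- fx[!is.na(fx$roi), , drop = FALSE]
    if (nrow(fx) == 0) return(NULL)
    last_roi <- fx$roi[which.max(fx$onset_ms)]
    tibble::tibble(participant = tr$participant,
                   hit = last_roi == unname(identity_features[chosen]))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(tibble::tibble(participant = character(),
                                            n = integer(),
                                            prop_last_chosen = numeric()))
  out |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(n = dplyr::n(), prop_last_chosen = 100 * mean(.data$hit))
}

#' Participant-level sampling summary for Experiment 2
#'
#' Convenience wrapper aggregating [sampling_proportions()],
#' [mean_fixation_durations()] and [binned_sampling()] over the validated
#' trials of each participant (trial-level values averaged per
#' participant).
#'
#' @param trials Validated Experiment 2 trials with responses.
#' @param events Events tibble.
#' @param rois A [roiset()].
#' @param bin_ms,n_bins Binning of the face presentation.
#' @return A list of tibbles: `overall` (count/dwell proportions and mean
#'   fixation durations per participant x class) and `binned`.
#' @export
sampling_summary <- function(trials, events, rois = build_default_roiset(),
                             bin_ms = 500, n_bins = 4) {
  trials <- if ("expected_roi" %in% names(trials)) trials
            else roi_class_map(trials)
  eparts <- split_events(events)
  overall <- list()
  binned <- list()
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    key <- paste(tr$participant, tr$trial)
    if (!key %in% names(eparts)) next
    ev <- events[eparts[[key]], ]
    w0 <- tr$t_face_on
    w1 <- trial_end_ms(tr)
    sp <- sampling_proportions(ev, tr$expected_roi, tr$unexpected_roi, rois,
                               w0, w1)
    if (!is.null(sp)) {
      md <- mean_fixation_durations(ev, tr$expected_roi, tr$unexpected_roi,
                                    rois, w0, w1)
      sp$mean_duration_ms <- md$mean_duration_ms
      sp$participant <- tr$participant
      sp$trial <- tr$trial
      overall[[length(overall) + 1]] <- sp
    }
    bs <- binned_sampling(ev, tr$expected_roi, tr$unexpected_roi, rois,
                          w0, w1, bin_ms, n_bins)
    bs$participant <- tr$participant
    bs$trial <- tr$trial
    binned[[length(binned) + 1]] <- bs
  }
  list(
    # Classes undefined in a trial (no unexpected ROI in match trials)
    # simply do not contribute to that class's average.
    overall = dplyr::bind_rows(overall) |>
      dplyr::group_by(.data$participant, .data$roi_class) |>
      dplyr::summarise(count_pct = mean(.data$count_pct, na.rm = TRUE),
                       dwell_pct = mean(.data$dwell_pct, na.rm = TRUE),
                       mean_duration_ms = mean(.data$mean_duration_ms,
                                               na.rm = TRUE),
                       n_trials = dplyr::n(), .groups = "drop"),
    binned = dplyr::bind_rows(binned) |>
      dplyr::group_by(.data$participant, .data$bin, .data$roi_class) |>
      dplyr::summarise(n_fix = mean(.data$n_fix, na.rm = TRUE),
                       dwell_pct = mean(.data$dwell_pct, na.rm = TRUE),
                       n_trials = sum(.data$available), .groups = "drop")
  )
}
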