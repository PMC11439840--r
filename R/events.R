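# Saccade / fixation / blink detection.
#
# Saccades are periods in which the angular velocity exceeds 30 deg/s OR
# the acceleration exceeds 8000 deg/s^2, provided the displacement of the
# period reaches the saccadic motion threshold of 0.1 deg. Velocity is
# estimated with a 5-point central difference on the gaze angle (the
# EyeLink-style estimator), acceleration as a central difference of the
# speed. Runs of invalid samples become blinks; everything else is
# fixation. The detected events tile the trial timeline exactly.

#' Event-detection parameters
#'
#' @param velocity_threshold Saccade velocity threshold in deg/s.
#' @param acceleration_threshold Saccade acceleration threshold in deg/s^2.
#' @param motion_threshold Minimum saccade displacement in deg.
#' @param min_predictive_latency Minimum saccade latency after face-outline
#'   onset for a saccade to count as anticipatory, in ms.
#' @param min_saccade_ms Supra-threshold runs shorter than this are treated
#'   as jitter and absorbed into the surrounding fixation.
#' @param min_fix_gap_ms Sub-threshold gaps shorter than this between two
#'   saccade runs are merged into one saccade; genuine fixations are never
#'   this brief, so such gaps are dips of a single movement.
#' @param blink_min_ms Invalid runs at least this long are padded, since
#'   the samples flanking a blink are unreliable.
#' @param blink_pad_ms Padding added to each side of a long blink.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(velocity_threshold = 30,
                             acceleration_threshold = 8000,
                             motion_threshold = 0.1,
                             min_predictive_latency = 100,
                             min_saccade_ms = 4,
                             min_fix_gap_ms = 10,
                             blink_min_ms = 20,
                             blink_pad_ms = 10) {
  vals <- c(velocity_threshold, acceleration_threshold, motion_threshold,
            min_predictive_latency)
  if (any(vals <= 0)) {
    stop("detection thresholds must be strictly positive", call. = FALSE)
  }
  structure(as.list(environment()), class = "detection_params")
}

# 5-point central difference with replicated ends; x in value units per
# sample, returns units per second.
central_diff5 <- function(x, rate) {
  n <- length(x)
  if (n < 5) return(rep(NA_real_, n))
  xp <- c(x[1], x[1], x, x[n], x[n])
  i <- 3:(n + 2)
  (xp[i - 2] - 8 * xp[i - 1] + 8 * xp[i + 1] - xp[i + 2]) / 12 * rate
}

central_diff3 <- function(x, rate) {
  n <- length(x)
  if (n < 3) return(rep(NA_real_, n))
  xp <- c(x[1], x, x[n])
  i <- 2:(n + 1)
  (xp[i + 1] - xp[i - 1]) / 2 * rate
}

#' Per-sample gaze kinematics
#'
#' Adds angular position, velocity (deg/s) and acceleration (deg/s^2)
#' columns to a samples table. Kinematics are `NA` at invalid samples and
#' at valid samples whose difference window touches an invalid one.
#'
#' @param samples Samples tibble (one or more trials; trials are processed
#'   independently).
#' @param screen A [screen_geometry()].
#' @param sampling_rate Samples per second.
#' @return The samples tibble with `theta_x`, `theta_y`, `vel` and `acc`
#'   columns appended.
#' @export
compute_kinematics <- function(samples, screen = screen_geometry(),
                               sampling_rate = 1000) {
  ang <- pos_to_deg(samples$x_px, samples$y_px, screen)
  samples$theta_x <- ang$theta_x
  samples$theta_y <- ang$theta_y
  key <- paste(samples$participant, samples$trial)
  parts <- split(seq_len(nrow(samples)), factor(key, unique(key)))
  vel <- rep(NA_real_, nrow(samples))
  acc <- rep(NA_real_, nrow(samples))
  for (idx in parts) {
    ok <- samples$valid[idx]
    tx <- samples$theta_x[idx]
    ty <- samples$theta_y[idx]
    # Interpolate over invalid gaps so the difference operator is defined,
    # then blank out anything whose window touches an invalid sample.
    if (any(!ok)) {
      if (!any(ok)) next
      tx <- stats::approx(which(ok), tx[ok], xout = seq_along(idx),
                          rule = 2)$y
      ty <- stats::approx(which(ok), ty[ok], xout = seq_along(idx),
                          rule = 2)$y
    }
    vx <- central_diff5(tx, sampling_rate)
    vy <- central_diff5(ty, sampling_rate)
    speed <- sqrt(vx^2 + vy^2)
    a <- central_diff3(speed, sampling_rate)
    if (any(!ok)) {
      bad <- !ok
      reach <- bad
      for (s in c(-2, -1, 1, 2)) {
        shifted <- rep(FALSE, length(bad))
        src <- seq_along(bad) - s
        keep <- src >= 1 & src <= length(bad)
        shifted[keep] <- bad[src[keep]]
        reach <- reach | shifted
      }
      speed[reach] <- NA_real_
      a[reach] <- NA_real_
    }
    vel[idx] <- speed
    acc[idx] <- a
  }
  samples$vel <- vel
  samples$acc <- acc
  samples
}

# Event detection for one trial's samples (already with kinematics).
detect_events_trial <- function(s, params, screen, rate) {
  n <- nrow(s)
  dt <- 1000 / rate
  t0 <- s$t_ms[1]
  lab <- rep("fixation", n)

  supra <- !is.na(s$vel) &
    (s$vel > params$velocity_threshold |
       (!is.na(s$acc) & abs(s$acc) > params$acceleration_threshold))
  lab[supra] <- "saccade"
  lab[!s$valid] <- "blink"

  # Pad long blinks.
  r <- rle(lab == "blink")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  pad <- max(1, round(params$blink_pad_ms / dt))
  for (k in which(r$values & r$lengths * dt >= params$blink_min_ms)) {
    lo <- max(1, starts[k] - pad)
    hi <- min(n, ends[k] + pad)
    lab[lo:hi] <- "blink"
  }

  # Demote saccade runs that are too short or move less than the motion
  # threshold.
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values == "saccade")) {
    i0 <- starts[k]; i1 <- ends[k]
    disp <- sqrt((s$theta_x[i1] - s$theta_x[i0])^2 +
                   (s$theta_y[i1] - s$theta_y[i0])^2)
    if (r$lengths[k] * dt < params$min_saccade_ms ||
        is.na(disp) || disp < params$motion_threshold) {
      lab[i0:i1] <- "fixation"
    }
  }

  # Merge saccade runs separated by an implausibly brief sub-threshold dip.
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values == "fixation" &
                  r$lengths * dt < params$min_fix_gap_ms)) {
    if (k > 1 && k < length(r$values) &&
        r$values[k - 1] == "saccade" && r$values[k + 1] == "saccade") {
      lab[starts[k]:ends[k]] <- "saccade"
    }
  }

  # Refine saccade boundaries to the surrounding local velocity minima:
  # the threshold crossing lags the true onset because saccades start
  # slowly, so walk back (and forward) while the velocity keeps falling.
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values == "saccade")) {
    j <- starts[k]
    while (j > 1 && lab[j - 1] == "fixation" && !is.na(s$vel[j - 1]) &&
           !is.na(s$vel[j]) && s$vel[j - 1] < s$vel[j]) {
      j <- j - 1
    }
    if (j < starts[k]) lab[j:starts[k]] <- "saccade"
    j <- ends[k]
    while (j < n && lab[j + 1] == "fixation" && !is.na(s$vel[j + 1]) &&
           !is.na(s$vel[j]) && s$vel[j + 1] < s$vel[j]) {
      j <- j + 1
    }
    if (j > ends[k]) lab[ends[k]:j] <- "saccade"
  }

  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- tibble::new_tibble(list(
    kind = r$values,
    onset_ms = t0 + (starts - 1) * dt,
    offset_ms = t0 + ends * dt,
    x_on = s$x_px[starts], y_on = s$y_px[starts],
    x_off = s$x_px[ends], y_off = s$y_px[ends]
  ), nrow = length(starts))
  ev$duration_ms <- ev$offset_ms - ev$onset_ms
  amp <- sqrt((s$theta_x[ends] - s$theta_x[starts])^2 +
                (s$theta_y[ends] - s$theta_y[starts])^2)
  ev$amplitude_deg <- ifelse(ev$kind == "saccade", amp, NA_real_)
  ev$peak_vel <- NA_real_
  ev$x_centroid <- NA_real_
  ev$y_centroid <- NA_real_
  for (k in seq_len(nrow(ev))) {
    i0 <- starts[k]; i1 <- ends[k]
    if (ev$kind[k] == "saccade") {
      ev$peak_vel[k] <- max(s$vel[i0:i1], na.rm = TRUE)
    } else if (ev$kind[k] == "fixation") {
      ev$x_centroid[k] <- mean(s$x_px[i0:i1], na.rm = TRUE)
      ev$y_centroid[k] <- mean(s$y_px[i0:i1], na.rm = TRUE)
    }
  }
  ev
}

#' Detect saccade, fixation and blink events
#'
#' Classifies every sample and merges runs into events. The events of one
#' trial are non-overlapping, ordered, and cover the trial's recorded
#' timeline exactly (partition property). Intervals are half-open
#' `[onset_ms, offset_ms)`.
#'
#' @param samples Samples tibble with kinematics (see
#'   [compute_kinematics()]; if `vel` is absent, kinematics are computed
#'   first).
#' @param params A [detection_params()].
#' @param screen A [screen_geometry()].
#' @param sampling_rate Samples per second.
#' @return A tibble of events: `participant`, `trial`, `kind`, `onset_ms`,
#'   `offset_ms`, `duration_ms`, onset/offset positions, `amplitude_deg`,
#'   `peak_vel`, and fixation centroids.
#' @export
detect_events <- function(samples, params = detection_params(),
                          screen = screen_geometry(), sampling_rate = 1000) {
  if (nrow(samples) == 0) {
    return(tibble::tibble(participant = character(), trial = integer(),
                          kind = character(), onset_ms = numeric(),
                          offset_ms = numeric(), duration_ms = numeric(),
                          x_on = numeric(), y_on = numeric(),
                          x_off = numeric(), y_off = numeric(),
                          amplitude_deg = numeric(), peak_vel = numeric(),
                          x_centroid = numeric(), y_centroid = numeric()))
  }
  if (!"vel" %in% names(samples)) {
    samples <- compute_kinematics(samples, screen, sampling_rate)
  }
  key <- paste(samples$participant, samples$trial)
  parts <- split(seq_len(nrow(samples)), factor(key, unique(key)))
  out <- lapply(parts, function(idx) {
    s <- samples[idx, ]
    ev <- detect_events_trial(s, params, screen, sampling_rate)
    ev$participant <- s$participant[1]
    ev$trial <- s$trial[1]
    ev
  })
  dplyr::bind_rows(out) |>
    dplyr::select("participant", "trial", "kind", "onset_ms", "offset_ms",
                  "duration_ms", "x_on", "y_on", "x_off", "y_off",
                  "amplitude_deg", "peak_vel", "x_centroid", "y_centroid")
}

#' Anticipatory saccades of one Experiment 1 trial
#'
#' Returns the first (up to) two saccades launched at least
#' `min_predictive_latency` ms after face-outline onset and before face
#' onset, in temporal order, numbered in `sacc_rank`.
#'
#' @param events Events tibble of a single trial.
#' @param outline_onset_ms Face-outline onset in ms.
#' @param face_onset_ms Face onset in ms.
#' @param params A [detection_params()].
#' @return A tibble with 0, 1 or 2 saccade rows.
#' @export
predictive_saccades <- function(events, outline_onset_ms, face_onset_ms,
                                params = detection_params()) {
  sac <- events[events$kind == "saccade" &
                  events$onset_ms >= outline_onset_ms +
                    params$min_predictive_latency &
                  events$onset_ms < face_onset_ms, , drop = FALSE]
  sac <- sac[order(sac$onset_ms), , drop = FALSE]
  sac <- utils::head(sac, 2)
  if (nrow(sac) > 0) sac$sacc_rank <- seq_len(nrow(sac))
  else sac$sacc_rank <- integer(0)
  sac
}
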