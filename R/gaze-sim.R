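# Synthetic 1000-Hz monocular gaze.
#
# A trial is rendered as a plan of alternating fixations and saccades.
# Saccades follow a minimum-jerk position profile, whose duration grows
# linearly with amplitude (main sequence); the peak velocity implied by the
# profile is 1.875 * amplitude / duration and is strictly increasing in
# amplitude for any positive duration slope/intercept. Temporally
# correlated AR(1) measurement noise is added to every sample, emulating
# video-oculography jitter without the broadband power that would trip the
# velocity threshold during fixations.

#' Gaze simulation parameters
#'
#' @param sampling_rate Samples per second (default 1000 Hz).
#' @param p_sacc1_expected,p_sacc2_expected Probability that the first /
#'   second saccade after the anticipation interval begins (Experiment 1:
#'   face-outline onset; Experiment 2: face onset) targets the expected
#'   feature ROI. The complement is spread uniformly over the alternatives.
#' @param p_second_saccade Probability that a second anticipatory saccade is
#'   launched at all (Experiment 1).
#' @param p_center_first Probability that the first face-period fixation is
#'   central rather than on a feature (central viewing tendency,
#'   Experiment 2).
#' @param fixation_duration_mean,fixation_duration_sd Face-scanning
#'   fixation durations in ms (normal, truncated at 60 ms).
#' @param mainseq_dur_intercept,mainseq_dur_slope Saccade duration model
#'   `duration_ms = intercept + slope * amplitude_deg` (defaults 21 ms and
#'   2.2 ms/deg, the classic main-sequence fit).
#' @param noise_sd Stationary standard deviation of the AR(1) positional
#'   noise in px.
#' @param noise_ar AR(1) coefficient of the positional noise.
#' @param blink_rate Blink events per second (used by [inject_artifacts()]).
#' @param loss_rate Fraction of samples dropped (used by
#'   [inject_artifacts()]).
#' @return An object of class `gaze_sim_params`.
#' @export
gaze_sim_params <- function(sampling_rate = 1000,
                            p_sacc1_expected = 0.5,
                            p_sacc2_expected = 0.35,
                            p_second_saccade = 0.7,
                            p_center_first = 0.5,
                            fixation_duration_mean = 250,
                            fixation_duration_sd = 80,
                            mainseq_dur_intercept = 21,
                            mainseq_dur_slope = 2.2,
                            noise_sd = 0.3,
                            noise_ar = 0.95,
                            blink_rate = 0.1,
                            loss_rate = 0.02) {
  probs <- c(p_sacc1_expected, p_sacc2_expected, p_second_saccade,
             p_center_first, loss_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (sampling_rate <= 0) stop("sampling_rate must be positive", call. = FALSE)
  if (mainseq_dur_intercept <= 0 || mainseq_dur_slope <= 0) {
    stop("main-sequence coefficients must be positive", call. = FALSE)
  }
  structure(as.list(environment()), class = "gaze_sim_params")
}

mainseq_duration_ms <- function(amplitude_deg, params) {
  pmax(12, params$mainseq_dur_intercept +
         params$mainseq_dur_slope * amplitude_deg)
}

#' Peak velocity implied by the main-sequence model
#'
#' For the minimum-jerk profile the peak velocity equals
#' `1.875 * amplitude / duration`.
#'
#' @param amplitude_deg Saccade amplitude in degrees.
#' @param params A [gaze_sim_params()].
#' @return Peak velocity in deg/s.
#' @export
mainseq_peak_velocity <- function(amplitude_deg, params = gaze_sim_params()) {
  1.875 * amplitude_deg / (mainseq_duration_ms(amplitude_deg, params) / 1000)
}

# Minimum-jerk position fraction on tau in [0, 1].
minjerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# Duration of a trial's sample record in ms: Experiment 1 runs to the end
# of the response window; Experiment 2 ends when the face disappears.
trial_end_ms <- function(trial) {
  if (trial$experiment == "exp1") return(trial$t_end_max)
  off <- trial[["t_face_off"]]
  if (!is.null(off) && !is.na(off)) off else trial$t_face_off_max
}

px_dist_deg <- function(p, q, screen) {
  sqrt(px_to_deg(abs(q["x"] - p["x"]), "x", screen)^2 +
         px_to_deg(abs(q["y"] - p["y"]), "y", screen)^2)
}

# Draw the next target point; re-draw until it is at least min_px away from
# the current position so the connecting saccade clears the motion
# threshold by a comfortable margin.
draw_target <- function(rois, lab, from, min_px = 30) {
  for (i in 1:20) {
    p <- roi_sample_point(rois, lab)
    if (sqrt(sum((p - from)^2)) >= min_px) return(p)
  }
  p
}

pick_feature <- function(expected, p_expected, alternatives) {
  if (stats::runif(1) < p_expected) expected
  else sample(alternatives, 1)
}

# Build the segment plan for one trial: a tibble of fixation/saccade
# segments with onset/offset in ms and start/end positions in px.
build_gaze_plan <- function(trial, params, rois) {
  screen <- roi_screen(rois)
  features <- unique(rois$label[rois$role == "feature"])
  expected <- trial$prior_feature
  others <- setdiff(features, expected)

  segs <- list()
  targets <- list()
  p_now <- roi_sample_point(rois, trial$prior_corner)
  t_now <- 0

  add_move <- function(to, t_start) {
    amp <- px_dist_deg(p_now, to, screen)
    dur <- round(mainseq_duration_ms(amp, params))
    list(t_sacc_on = t_start, t_sacc_off = t_start + dur, to = to, amp = amp)
  }

  trial_end <- trial_end_ms(trial)

  plan_fix <- function(t_on, t_off, p) {
    list(kind = "fixation", t_on = unname(t_on), t_off = unname(t_off),
         x0 = unname(p["x"]), y0 = unname(p["y"]),
         x1 = unname(p["x"]), y1 = unname(p["y"]))
  }
  plan_sacc <- function(mv, from) {
    list(kind = "saccade", t_on = unname(mv$t_sacc_on),
         t_off = unname(mv$t_sacc_off),
         x0 = unname(from["x"]), y0 = unname(from["y"]),
         x1 = unname(mv$to["x"]), y1 = unname(mv$to["y"]))
  }

  if (trial$experiment == "exp1") {
    # Anticipatory saccades during the face-outline interval.
    s1_on <- trial$t_outline_on + stats::runif(1, 150, 350)
    lab1 <- pick_feature(expected, params$p_sacc1_expected, others)
    mv1 <- add_move(draw_target(rois, lab1, p_now), round(s1_on))
    segs[[1]] <- plan_fix(0, mv1$t_sacc_on, p_now)
    segs[[2]] <- plan_sacc(mv1, p_now)
    p_now <- mv1$to
    t_now <- mv1$t_sacc_off

    do_second <- stats::runif(1) < params$p_second_saccade
    s2_on <- t_now + stats::runif(1, 200, 350)
    if (do_second && s2_on + 60 < trial$t_face_on) {
      lab2 <- pick_feature(expected, params$p_sacc2_expected, others)
      mv2 <- add_move(draw_target(rois, lab2, p_now), round(s2_on))
      segs[[3]] <- plan_fix(t_now, mv2$t_sacc_on, p_now)
      segs[[4]] <- plan_sacc(mv2, p_now)
      p_now <- mv2$to
      t_now <- mv2$t_sacc_off
    }
    segs[[length(segs) + 1]] <- plan_fix(t_now, trial_end, p_now)
  } else {
    # Fixate the prior corner, then scan the face until it disappears.
    s1_on <- round(trial$t_face_on + stats::runif(1, 150, 300))
    lab1 <- if (stats::runif(1) < params$p_center_first) "center"
            else pick_feature(expected, params$p_sacc1_expected, others)
    mv <- add_move(draw_target(rois, lab1, p_now), s1_on)
    segs[[1]] <- plan_fix(0, mv$t_sacc_on, p_now)
    nsac <- 1
    repeat {
      segs[[length(segs) + 1]] <- plan_sacc(mv, p_now)
      p_now <- mv$to
      t_now <- mv$t_sacc_off
      fix_dur <- max(60, stats::rnorm(1, params$fixation_duration_mean,
                                      params$fixation_duration_sd))
      next_on <- round(t_now + fix_dur)
      if (next_on + 30 >= trial_end) break
      nsac <- nsac + 1
      p_exp <- if (nsac == 2) params$p_sacc1_expected else params$p_sacc2_expected
      lab <- pick_feature(expected, p_exp, c(others, "center"))
      mv <- add_move(draw_target(rois, lab, p_now), next_on)
      segs[[length(segs) + 1]] <- plan_fix(t_now, mv$t_sacc_on, p_now)
    }
    segs[[length(segs) + 1]] <- plan_fix(t_now, trial_end, p_now)
  }

  plan <- tibble::tibble(
    kind = vapply(segs, `[[`, "", "kind"),
    t_on = vapply(segs, `[[`, 0, "t_on"),
    t_off = vapply(segs, `[[`, 0, "t_off"),
    x0 = vapply(segs, `[[`, 0, "x0"),
    y0 = vapply(segs, `[[`, 0, "y0"),
    x1 = vapply(segs, `[[`, 0, "x1"),
    y1 = vapply(segs, `[[`, 0, "y1"))
  plan$t_off <- pmin(plan$t_off, trial_end)
  plan[plan$t_off > plan$t_on, ]
}

# Render a segment plan into evenly spaced samples with AR(1) noise.
render_gaze_plan <- function(plan, trial_end, params) {
  dt <- 1000 / params$sampling_rate
  n <- floor(trial_end / dt)
  t_ms <- (seq_len(n) - 1) * dt
  x <- numeric(n)
  y <- numeric(n)
  for (i in seq_len(nrow(plan))) {
    idx <- which(t_ms >= plan$t_on[i] & t_ms < plan$t_off[i])
    if (length(idx) == 0) next
    if (plan$kind[i] == "fixation") {
      x[idx] <- plan$x0[i]
      y[idx] <- plan$y0[i]
    } else {
      tau <- (t_ms[idx] - plan$t_on[i]) / (plan$t_off[i] - plan$t_on[i])
      f <- minjerk(tau)
      x[idx] <- plan$x0[i] + (plan$x1[i] - plan$x0[i]) * f
      y[idx] <- plan$y0[i] + (plan$y1[i] - plan$y0[i]) * f
    }
  }
  if (params$noise_sd > 0) {
    innov_sd <- params$noise_sd * sqrt(1 - params$noise_ar^2)
    x <- x + as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                      params$noise_ar, method = "recursive"))
    y <- y + as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                      params$noise_ar, method = "recursive"))
  }
  list(t_ms = t_ms, x_px = x, y_px = y, n = n)
}

#' Simulate the gaze trace of one trial
#'
#' Renders a complete trial: fixation on the name-prior corner, anticipatory
#' saccades during the face-outline interval (Experiment 1) or face
#' scanning until the response (Experiment 2), at the configured sampling
#' rate. Returns both the samples and the ground-truth event plan, which
#' downstream detector tests compare against.
#'
#' @param trial A one-row design tibble (with response columns if available;
#'   Experiment 2 face offset defaults to the maximum when absent).
#' @param params A [gaze_sim_params()].
#' @param rois A [roiset()].
#' @param seed Integer seed for this trial.
#' @return A list with `samples` (tibble: `participant`, `trial`, `t_ms`,
#'   `x_px`, `y_px`, `valid`) and `events` (ground-truth segments with
#'   `kind`, `t_on`, `t_off`, positions, `target`).
#' @export
simulate_gaze <- function(trial, params = gaze_sim_params(),
                          rois = build_default_roiset(), seed) {
  stopifnot(nrow(trial) == 1)
  if (params$sampling_rate <= 0) {
    stop("sampling_rate must be positive", call. = FALSE)
  }
  withr::with_seed(as.integer(as.double(seed) %% 2147483647), {
    trial_end <- trial_end_ms(trial)
    plan <- build_gaze_plan(trial, params, rois)
    r <- render_gaze_plan(plan, trial_end, params)
    samples <- tibble::new_tibble(list(
      participant = rep(trial$participant, r$n),
      trial = rep(trial$trial, r$n),
      t_ms = r$t_ms, x_px = r$x_px, y_px = r$y_px,
      valid = rep(TRUE, r$n)), nrow = r$n)
    events <- tibble::new_tibble(
      c(list(participant = rep(trial$participant, nrow(plan)),
             trial = rep(trial$trial, nrow(plan))),
        as.list(plan)), nrow = nrow(plan))
    list(samples = samples, events = events)
  })
}

#' Simulate gaze for a whole table of trials
#'
#' Per-trial seeds are derived from the root seed by a fixed counter scheme
#' (`(seed * 7919 + row index) mod (2^31 - 1)`), so any single trial can be
#' re-simulated independently.
#'
#' @param trials Design (+ response) tibble.
#' @param params A [gaze_sim_params()].
#' @param rois A [roiset()].
#' @param seed Root integer seed.
#' @return A list with stacked `samples` and ground-truth `events` tibbles.
#' @export
simulate_gaze_cohort <- function(trials, params = gaze_sim_params(),
                                 rois = build_default_roiset(), seed) {
  res <- lapply(seq_len(nrow(trials)), function(i) {
    simulate_gaze(trials[i, ], params, rois,
                  seed = (as.double(seed) * 7919 + i) %% 2147483647)
  })
  list(samples = dplyr::bind_rows(lapply(res, `[[`, "samples")),
       events = dplyr::bind_rows(lapply(res, `[[`, "events")))
}

#' Inject data loss and blinks into gaze samples
#'
#' Marks samples invalid in two ways: isolated per-sample dropout with
#' probability `loss_rate` (so the realised invalid fraction concentrates
#' binomially around `loss_rate`), and contiguous blink spans arriving at
#' `blink_rate` events per second with log-normal durations around 120 ms.
#' Invalid samples have their coordinates set to `NA`.
#'
#' @param samples A samples tibble (possibly many trials).
#' @param loss_rate Fraction of samples dropped, in `[0, 1)`.
#' @param blink_rate Blink events per second.
#' @param seed Integer seed.
#' @param window Optional numeric `c(from, to)` in ms: restrict artifact
#'   injection to this time window of each trial.
#' @return The samples tibble with updated `valid`, `x_px`, `y_px`.
#' @export
inject_artifacts <- function(samples, loss_rate = 0.02, blink_rate = 0.1,
                             seed, window = NULL) {
  if (loss_rate < 0 || loss_rate >= 1) {
    stop("loss_rate must lie in [0, 1)", call. = FALSE)
  }
  if (loss_rate == 0 && blink_rate == 0) return(samples)
  withr::with_seed(as.integer(seed), {
    n <- nrow(samples)
    in_window <- if (is.null(window)) rep(TRUE, n)
                 else samples$t_ms >= window[1] & samples$t_ms < window[2]
    invalid <- logical(n)
    if (loss_rate > 0) {
      invalid <- stats::runif(n) < loss_rate
    }
    if (blink_rate > 0) {
      key <- paste(samples$participant, samples$trial)
      starts <- which(!duplicated(key))
      ends <- c(starts[-1] - 1, n)
      for (g in seq_along(starts)) {
        lo <- starts[g]; hi <- ends[g]
        dur_s <- (hi - lo + 1) / 1000
        k <- stats::rpois(1, blink_rate * dur_s)
        if (k == 0) next
        at <- sample(lo:hi, k)
        len <- pmax(20, round(stats::rlnorm(k, log(120), 0.3)))
        for (j in seq_len(k)) {
          invalid[at[j]:min(hi, at[j] + len[j] - 1)] <- TRUE
        }
      }
    }
    invalid <- invalid & in_window
    samples$valid[invalid] <- FALSE
    samples$x_px[invalid] <- NA_real_
    samples$y_px[invalid] <- NA_real_
    samples
  })
}
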