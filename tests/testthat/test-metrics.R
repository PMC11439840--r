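# Hand-built trial/event fixtures give exact enumeration oracles for each
# metric; simulated cohorts cover the stochastic properties.

mk_trial <- function(trial, prior = "A", condition = "match", partner = NA,
                     shown = NULL, choice = "expected", identity = NA,
                     experiment = "exp1", participant = "p1") {
  shown <- if (!is.null(shown)) shown
           else if (condition == "match") prior
           else if (condition == "mismatch") setdiff(c("A", "B"), prior)[1]
           else NA
  tibble::tibble(
    experiment = experiment, participant = participant, trial = trial,
    prior = prior, prior_feature = unname(identity_features[prior]),
    prior_corner = "corner_tl", condition = condition,
    stimulus = if (condition == "partial")
      paste(pmin(prior, partner), pmax(prior, partner), sep = "+")
      else shown,
    shown_identity = shown, partner = partner,
    t_prior_on = 0, t_outline_on = 750, t_face_on = 1750,
    t_face_off_max = 1850, t_end_max = 3350, t_face_off = 1850,
    choice = choice, rt_ms = 600, identity_choice = identity,
    correct = if (condition == "partial") NA else
      (condition == "match") == (choice == "expected"))
}

fix_at <- function(lab, onset, offset, trial = 1L, participant = "p1") {
  p <- feature_center(lab)
  make_event(participant, trial, "fixation", onset, offset, p["x"], p["y"])
}

sacc_to <- function(lab, onset, offset, trial = 1L, participant = "p1") {
  p <- feature_center(lab)
  make_event(participant, trial, "saccade", onset, offset,
             x = 0, y = 0, x_off = p["x"], y_off = p["y"])
}

test_that("roi class map partitions the four features per trial", {
  tr <- dplyr::bind_rows(
    mk_trial(1, "A", "match"),
    mk_trial(2, "A", "mismatch", shown = "C"),
    mk_trial(3, "B", "partial", partner = "D"))
  m <- roi_class_map(tr)
  expect_equal(m$expected_roi, c("forehead", "forehead", "chin"))
  expect_equal(m$unexpected_roi, c(NA, "ears", "nose"))
  expect_equal(m$other_rois[2], "chin,nose")
  expect_equal(m$other_rois[3], "forehead,ears")
})

test_that("predictive-saccade percentages equal hand enumeration on an 8-trial set", {
  # Priors: A,A,A,A,B,C,D,D. First-saccade landings chosen so the per-ROI
  # relative frequencies differ from the pooled frequency.
  priors <- c("A", "A", "A", "A", "B", "C", "D", "D")
  landings <- c("forehead", "forehead", "chin", "nose",
                "forehead", "ears", "nose", "forehead")
  trials <- dplyr::bind_rows(lapply(1:8, function(i) {
    mk_trial(i, priors[i], "match")
  }))
  events <- dplyr::bind_rows(lapply(1:8, function(i) {
    dplyr::bind_rows(
      fix_at("nose", 0, 900, trial = i),
      sacc_to(landings[i], 900, 930, trial = i),
      fix_at(landings[i], 930, 3350, trial = i))
  }))
  got <- predictive_saccade_table(trials, events, default_rois())
  g <- function(rank, exp) got$pct[got$sacc_rank == rank &
                                     got$expectation == exp]
  # Expected cell: forehead 2/4, chin 0/1, ears 1/1, nose 1/2 -> mean 50%.
  expect_equal(g(1, "expected"), mean(c(2 / 4, 0, 1, 1 / 2)) * 100)
  # Unexpected: forehead 2/4, chin 1/7, ears 0/7, nose 1/6.
  expect_equal(g(1, "unexpected"),
               mean(c(2 / 4, 1 / 7, 0 / 7, 1 / 6)) * 100)
  # No second saccades anywhere: both cells NaN-free count 0 -> NaN.
  expect_true(is.nan(g(2, "expected")))
})

test_that("fixation order ranks fixated ROIs and randomly fills the rest", {
  ev <- dplyr::bind_rows(
    fix_at("nose", 200, 400), fix_at("chin", 500, 700),
    fix_at("forehead", 900, 1100), fix_at("ears", 1300, 1500),
    fix_at("nose", 1600, 1700))
  ord <- fixation_order(ev, default_rois())
  expect_equal(ord$ordinal[match(c("nose", "chin", "forehead", "ears"),
                                 ord$roi)], 1:4)
  # Only nose fixated: nose first, others fill 2-4 uniformly.
  ev1 <- fix_at("nose", 200, 400)
  fills <- t(replicate(300, {
    o <- fixation_order(ev1, default_rois())
    o$ordinal[match(c("forehead", "chin", "ears"), o$roi)]
  }))
  o1 <- fixation_order(ev1, default_rois())
  expect_equal(o1$ordinal[o1$roi == "nose"], 1)
  expect_true(all(apply(fills, 1, sort) == 2:4))
  expect_gt(min(table(fills[, 1])), 60)   # roughly uniform fill
  # No feature fixation at all: not applicable.
  expect_null(fixation_order(make_event(kind = "fixation", onset = 0,
                                        offset = 100, x = 5, y = 5),
                             default_rois()))
})

test_that("first_between compares group onsets and flags empty trials", {
  ev <- dplyr::bind_rows(fix_at("forehead", 300, 500),
                         fix_at("ears", 450, 600))
  expect_equal(first_between(ev, "forehead", "ears"), "a_first")
  expect_equal(first_between(ev, "nose", "ears"), "b_first")
  expect_equal(first_between(ev, "forehead", "nose"), "a_first")
  expect_equal(first_between(ev, "nose", "chin"), "not_applicable")
})

test_that("sampling proportions match the worked example and a sample-wise oracle", {
  ev <- dplyr::bind_rows(fix_at("forehead", 100, 500))
  sp <- sampling_proportions(ev, expected = "forehead", unexpected = "chin",
                             w0 = 0, w1 = 2000)
  expect_equal(sp$count_pct[sp$roi_class == "expected"], 100)
  expect_equal(sp$dwell_pct[sp$roi_class == "expected"], 20)
  expect_equal(sp$dwell_pct[sp$roi_class == "other"], 0)
  # Fixations outside every feature ROI: class proportions all zero.
  ev0 <- make_event(kind = "fixation", onset = 0, offset = 300, x = 1, y = 1)
  sp0 <- sampling_proportions(ev0, "forehead", "chin", w0 = 0, w1 = 1000)
  expect_true(all(sp0$count_pct == 0))
  # Event-based dwell equals brute-force per-sample counting on a
  # simulated trial (within one sample per event boundary).
  co <- small_cohort("exp2", 1, seed = 502, n_trials = 6)
  tr <- roi_class_map(co$trials)[3, ]
  ev3 <- co$events[co$events$trial == 3, ]
  w0 <- tr$t_face_on; w1 <- tr$t_face_off
  sp3 <- sampling_proportions(ev3, tr$expected_roi, tr$unexpected_roi,
                              co$rois, w0, w1)
  s3 <- co$samples[co$samples$trial == 3 & co$samples$t_ms >= w0 &
                     co$samples$t_ms < w1, ]
  # Per-sample oracle: label each sample by the fixation event covering it.
  fx <- ev3[ev3$kind == "fixation", ]
  covered <- outer(s3$t_ms, fx$onset_ms, ">=") & outer(s3$t_ms, fx$offset_ms, "<")
  lab <- classify_point(fx$x_centroid, fx$y_centroid, co$rois)
  samp_lab <- apply(covered, 1, function(z) if (any(z)) lab[which(z)[1]]
                    else NA_character_)
  cls <- roi_class_of(samp_lab, tr$expected_roi, tr$unexpected_roi)
  n_boundaries <- nrow(fx) + 1
  for (k in c("expected", "unexpected", "other")) {
    oracle_ms <- sum(cls == k, na.rm = TRUE)
    expect_lt(abs(sp3$dwell_ms[sp3$roi_class == k] - oracle_ms),
              n_boundaries + 1)
  }
})

test_that("binned sampling splits dwell across 500 ms windows", {
  ev <- dplyr::bind_rows(fix_at("forehead", 400, 700))
  b <- binned_sampling(ev, "forehead", "chin", w0 = 0, w1 = 2000)
  e <- b[b$roi_class == "expected", ]
  expect_equal(e$dwell_ms, c(100, 200, 0, 0))
  expect_equal(e$dwell_pct[1:2], c(20, 40))
  expect_equal(e$n_fix[1:2], c(1, 1))   # overlap counts in both bins
  # Short trials lose late bins.
  b2 <- binned_sampling(ev, "forehead", "chin", w0 = 0, w1 = 1200)
  expect_equal(b2$available[b2$roi_class == "expected"],
               c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(is.na(b2$dwell_ms[!b2$available])))
  # Class dwell within a bin never exceeds the bin.
  agg <- stats::aggregate(dwell_pct ~ bin, data = b[b$available, ], sum)
  expect_true(all(agg$dwell_pct <= 100 + 1e-9))
})

test_that("mean fixation durations average per class and flag empty classes", {
  ev <- dplyr::bind_rows(fix_at("forehead", 0, 200),
                         fix_at("forehead", 300, 600),
                         fix_at("ears", 700, 800))
  md <- mean_fixation_durations(ev, "forehead", "chin")
  expect_equal(md$mean_duration_ms[md$roi_class == "expected"], 250)
  expect_equal(md$mean_duration_ms[md$roi_class == "other"], 100)
  expect_true(is.na(md$mean_duration_ms[md$roi_class == "unexpected"]))
})

test_that("assimilation index maps balanced/compliant/mixed responders correctly", {
  ids <- names(identity_features)
  combos <- tidyr::expand_grid(prior = ids, partner = ids) |>
    dplyr::filter(prior != partner)
  balanced <- dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    dplyr::bind_rows(lapply(1:12, function(r) {
      mk_trial(i * 100 + r, combos$prior[i], "partial",
               partner = combos$partner[i],
               choice = ifelse(r <= 6, "expected", "unexpected"))
    }))
  }))
  expect_equal(assimilation_index(balanced)$assimilation_index, 50)
  all_comp <- dplyr::mutate(balanced, choice = "expected")
  expect_equal(assimilation_index(all_comp)$assimilation_index, 100)
  # 9 compliant / 3 noncompliant in every combination:
  # score = (9 - 3) / 12 = 0.5 -> 75%.
  mixed <- dplyr::group_by(balanced, prior, stimulus) |>
    dplyr::mutate(choice = ifelse(dplyr::row_number() <= 9, "expected",
                                  "unexpected")) |>
    dplyr::ungroup()
  expect_equal(assimilation_index(mixed)$assimilation_index, 75)
  expect_error(assimilation_index(mk_trial(1, "A", "match")), "partial")
})

test_that("rt summary averages responded trials per condition", {
  tr <- dplyr::bind_rows(mk_trial(1), mk_trial(2), mk_trial(3, "B"),
                         mk_trial(4, condition = "mismatch", shown = "B"))
  tr$rt_ms <- c(600, 700, NA, 800)
  tr$choice[3] <- "none"
  s <- rt_summary(tr)
  expect_equal(s$mean_rt_ms[s$condition == "match"], 650)
  expect_equal(s$n[s$condition == "match"], 2)
  expect_equal(s$mean_rt_ms[s$condition == "mismatch"], 800)
})

test_that("face-onset fixation linkage reproduces a hand-enumerated table", {
  trials <- dplyr::bind_rows(
    mk_trial(1, "A", "match", choice = "expected"),     # onset on expected
    mk_trial(2, "A", "match", choice = "unexpected"),   # onset elsewhere
    mk_trial(3, "A", "mismatch", shown = "C", choice = "unexpected"),
    mk_trial(4, "A", "partial", partner = "B", choice = "expected"))
  events <- dplyr::bind_rows(
    fix_at("forehead", 1000, 2000, trial = 1),
    fix_at("nose", 1000, 2000, trial = 2),
    fix_at("forehead", 1000, 2000, trial = 3),
    fix_at("forehead", 1000, 2000, trial = 4))
  got <- onset_roi_linkage(trials, events, default_rois())
  pick <- function(cond, oe) got$value[got$condition == cond &
                                         got$onset_expected == oe]
  expect_equal(pick("match", TRUE), 100)    # trial 1 correct
  expect_equal(pick("match", FALSE), 0)     # trial 2 wrong
  expect_equal(pick("mismatch", TRUE), 100) # trial 3 correct
  expect_equal(pick("partial", TRUE), 100)  # trial 4 chose expected
  expect_length(pick("partial", FALSE), 0)  # empty cell missing
})

test_that("last-fixation bias counts chosen-identity final fixations", {
  trials <- dplyr::bind_rows(lapply(1:4, function(i) {
    mk_trial(i, "A", "partial", partner = "B", experiment = "exp2",
             choice = c("expected", "expected", "expected", "unexpected")[i],
             identity = c(NA, NA, NA, "B")[i])
  }))
  # Last feature fixation: forehead (A) in trials 1-3, nose in trial 4
  # (chosen B = chin, so a miss).
  events <- dplyr::bind_rows(lapply(1:4, function(i) {
    dplyr::bind_rows(
      fix_at("chin", 800, 1000, trial = i),
      fix_at(c("forehead", "forehead", "forehead", "nose")[i], 1100, 1400,
             trial = i))
  }))
  trials$t_face_on <- 750        # experiment 2 trial script
  trials$t_face_off <- 1500
  got <- last_fixation_bias(trials, events, default_rois())
  expect_equal(got$prop_last_chosen, 75)
  expect_equal(got$n, 4)
  # No eligible trials -> empty result.
  none <- last_fixation_bias(trials[0, ], events, default_rois())
  expect_equal(nrow(none), 0)
})

test_that("uniform scanning yields flat ordinals and 25% last-fixation bias", {
  # Null generator: first face fixation central, then every scan target
  # uniform over {4 features, centre} (p = 0.2 for the expected feature
  # equals the per-alternative share), so feature sampling is uniform and
  # independent of the prior and of the choice.
  rois <- default_rois()
  d <- generate_design("exp2", "p01", seed = 61)[1:120, ]
  b <- simulate_behavior(d, behavior_params(miss_rate = 0), seed = 62)
  null_gaze <- gaze_sim_params(p_sacc1_expected = 0.2,
                               p_sacc2_expected = 0.2,
                               p_center_first = 1)
  sim <- simulate_gaze_cohort(b, null_gaze, rois, seed = 63)
  ev <- detect_events(sim$samples, screen = roi_screen(rois))
  fo <- fixation_order_table(roi_class_map(b), ev, rois, seed = 64)
  tab <- table(fo$ordinal[fo$roi_class == "expected"])
  expect_equal(length(tab), 4)
  props <- as.vector(tab) / sum(tab)
  expect_true(all(abs(props - 0.25) < 3 * sqrt(0.25 * 0.75 / sum(tab))))
  lf <- last_fixation_bias(b, ev, rois)
  n <- lf$n
  expect_lt(abs(lf$prop_last_chosen - 25), 300 * sqrt(0.25 * 0.75 / n))
})
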