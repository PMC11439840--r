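# Generative model for button responses and reaction times.

#' Behavioural simulation parameters
#'
#' Ground-truth knobs for the simulated responder. Reaction times are drawn
#' log-normally (positive support) with the given per-condition mean and a
#' common standard deviation. `assimilation_q` is the probability of an
#' expectation-compliant response on partial (morph) trials, so the
#' perceived-face-identity index recovers `100 * assimilation_q`.
#'
#' @param rt_mean Named numeric: mean reaction time in ms per condition
#'   (`match`, `mismatch`, `partial`). Defaults reflect a modest
#'   facilitation effect for expected faces.
#' @param rt_sd Reaction-time standard deviation in ms (> 0).
#' @param p_correct_match,p_correct_mismatch Probability of the correct
#'   expected/unexpected button press in clear-face trials.
#' @param assimilation_q Probability that a partial trial is classified as
#'   the expected identity.
#' @param miss_rate Probability of no response in a trial.
#' @param p_identity_correct Experiment 2 only: probability that the
#'   identity attribution after an "unexpected" response names the shown
#'   identity (mismatch trials). In partial trials the attribution is always
#'   the non-prior morph member, since the percept is one of the two morphed
#'   identities.
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(rt_mean = c(match = 670, mismatch = 720,
                                        partial = 720),
                            rt_sd = 150,
                            p_correct_match = 0.95,
                            p_correct_mismatch = 0.92,
                            assimilation_q = 0.65,
                            miss_rate = 0.01,
                            p_identity_correct = 0.9) {
  probs <- c(p_correct_match, p_correct_mismatch, assimilation_q, miss_rate,
             p_identity_correct)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (rt_sd <= 0) stop("rt_sd must be positive", call. = FALSE)
  if (!all(c("match", "mismatch", "partial") %in% names(rt_mean))) {
    stop("rt_mean must name match, mismatch and partial", call. = FALSE)
  }
  structure(list(rt_mean = rt_mean, rt_sd = rt_sd,
                 p_correct_match = p_correct_match,
                 p_correct_mismatch = p_correct_mismatch,
                 assimilation_q = assimilation_q, miss_rate = miss_rate,
                 p_identity_correct = p_identity_correct),
            class = "behavior_params")
}

rlnorm_ms <- function(n, mean_ms, sd_ms) {
  sdlog2 <- log(1 + (sd_ms / mean_ms)^2)
  stats::rlnorm(n, meanlog = log(mean_ms) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Simulate button responses for a trial design
#'
#' Adds the response columns to a design table: the expected/unexpected
#' button `choice`, the reaction time `rt_ms` (from face onset), the
#' identity attribution `identity_choice` (Experiment 2, after "unexpected"
#' answers), and a `correct` flag for clear-face trials (`NA` for partial,
#' where any response counts as correct in Experiment 1 and correctness is
#' undefined in Experiment 2).
#'
#' @param design A design tibble from [generate_design()].
#' @param params A [behavior_params()].
#' @param seed Integer seed.
#' @return The design with response columns appended.
#' @export
simulate_behavior <- function(design, params = behavior_params(), seed) {
  if (nrow(design) == 0) stop("design is empty", call. = FALSE)
  if (!inherits(params, "behavior_params")) {
    params <- do.call(behavior_params, params)
  }
  withr::with_seed(as.integer(seed), {
    n <- nrow(design)
    u <- stats::runif(n)
    choice <- dplyr::case_when(
      design$condition == "match" & u < params$p_correct_match ~ "expected",
      design$condition == "match" ~ "unexpected",
      design$condition == "mismatch" & u < params$p_correct_mismatch ~ "unexpected",
      design$condition == "mismatch" ~ "expected",
      design$condition == "partial" & u < params$assimilation_q ~ "expected",
      TRUE ~ "unexpected"
    )
    miss <- stats::runif(n) < params$miss_rate
    choice[miss] <- "none"

    rt <- rlnorm_ms(n, unname(params$rt_mean[design$condition]), params$rt_sd)
    # Responses beyond the response window are misses.
    window <- design$t_end_max - design$t_face_on
    late <- rt > window
    choice[late] <- "none"
    rt[choice == "none"] <- NA_real_

    identity_choice <- rep(NA_character_, n)
    if (design$experiment[1] == "exp2") {
      ids <- names(identity_features)
      unexp <- which(choice == "unexpected")
      for (i in unexp) {
        if (design$condition[i] == "partial") {
          identity_choice[i] <- design$partner[i]
        } else {
          shown <- if (is.na(design$shown_identity[i])) design$prior[i]
                   else design$shown_identity[i]
          if (stats::runif(1) < params$p_identity_correct) {
            identity_choice[i] <- shown
          } else {
            identity_choice[i] <- sample(setdiff(ids, shown), 1)
          }
        }
      }
    }

    correct <- dplyr::case_when(
      choice == "none" ~ NA,
      design$condition == "match" & design$experiment == "exp2" ~
        choice == "expected" |
        (choice == "unexpected" & !is.na(identity_choice) &
           identity_choice == design$prior),
      design$condition == "match" ~ choice == "expected",
      design$condition == "mismatch" & design$experiment == "exp2" ~
        choice == "unexpected" & !is.na(identity_choice) &
        identity_choice == design$shown_identity,
      design$condition == "mismatch" ~ choice == "unexpected",
      TRUE ~ NA
    )

    dplyr::mutate(design,
                  choice = choice,
                  rt_ms = round(rt, 1),
                  identity_choice = identity_choice,
                  correct = correct,
                  t_face_off = dplyr::if_else(
                    .data$experiment == "exp2" & !is.na(.data$rt_ms),
                    .data$t_face_on + pmin(.data$rt_ms, .data$t_face_off_max -
                                             .data$t_face_on),
                    .data$t_face_off_max))
  })
}
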