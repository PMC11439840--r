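# Experiment design generation.
#
# Four face identities (A, B, C, D), each distinguished by one facial
# feature; the name prior cues one identity per trial. Conditions:
#   match    - the cued identity's face is shown
#   mismatch - one of the three other faces is shown
#   partial  - a 50/50 morph containing the cued identity and one other
# Experiment 1: 3 blocks x 144 trials (48 per condition per block), prior
# 750 ms, face-outline ISI, face 100 ms, response window 1500 ms.
# Experiment 2: 4 blocks x 72 trials (24 per condition per block), prior
# 750 ms, face up to 4500 ms (terminated by the button press).

#' Identity-to-feature map
#'
#' The four identities and the facial feature that distinguishes each from
#' the base face. The feature names double as feature-ROI labels.
#' @export
identity_features <- c(A = "forehead", B = "chin", C = "ears", D = "nose")

prior_corners <- c("corner_tl", "corner_tr", "corner_bl", "corner_br")

experiment_spec <- function(experiment_id) {
  switch(experiment_id,
    exp1 = list(n_blocks = 3, per_cond = 48, prior_ms = 750, isi_ms = 1000,
                face_ms = 100, response_ms = 1500),
    exp2 = list(n_blocks = 4, per_cond = 24, prior_ms = 750,
                face_max_ms = 4500),
    stop("unknown experiment_id: ", experiment_id, call. = FALSE)
  )
}

# Order a vector of prior labels so that no label appears more than
# `max_run` times consecutively. Sequential sampling proportional to the
# remaining counts, excluding a label that would extend a maximal run;
# restarts on the (rare) dead end.
constrained_prior_order <- function(priors, max_run = 2, init_lab = "",
                                    init_run = 0) {
  counts0 <- table(priors)
  labs <- names(counts0)
  n <- length(priors)
  for (attempt in 1:100) {
    counts <- as.vector(counts0)
    out <- character(n)
    run_lab <- init_lab
    run_len <- init_run
    ok <- TRUE
    for (i in seq_len(n)) {
      allowed <- counts > 0
      if (run_len >= max_run) allowed <- allowed & labs != run_lab
      if (!any(allowed)) { ok <- FALSE; break }
      cand <- which(allowed)
      j <- if (length(cand) == 1) cand
           else cand[sample.int(length(cand), 1, prob = counts[cand])]
      out[i] <- labs[j]
      counts[j] <- counts[j] - 1
      if (labs[j] == run_lab) run_len <- run_len + 1
      else { run_lab <- labs[j]; run_len <- 1 }
    }
    if (ok) return(out)
  }
  stop("could not order priors under the run-length constraint", call. = FALSE)
}

#' Generate a per-participant trial design
#'
#' Produces the complete pseudo-randomised trial list for one participant:
#' balanced condition counts per block, every prior paired equally often
#' with each of the three other identities in mismatch and partial trials,
#' no prior name more than twice in a row, and each prior presented equally
#' often in each screen corner across the session. Deterministic given
#' `seed`.
#'
#' @param experiment_id `"exp1"` or `"exp2"`.
#' @param participant_id Participant identifier (any scalar; stored as
#'   character).
#' @param seed Integer seed (mandatory; there is no default).
#' @param isi_ms Experiment 1 face-outline duration in ms. The outline is
#'   shown for 1000 ms; some analyses window the first 750 ms of it, so the
#'   duration is exposed as a parameter.
#' @return A tibble with one row per trial: `experiment`, `participant`,
#'   `block`, `trial_in_block`, `trial` (1-based across the session),
#'   `prior`, `prior_feature`, `prior_corner`, `condition`, `stimulus`
#'   (identity, or sorted `"X+Y"` morph pair), `shown_identity` (clear
#'   faces), `partner` (the non-prior morph member, partial only), and phase
#'   onsets `t_prior_on`, `t_outline_on` (exp1, `NA` otherwise),
#'   `t_face_on`, `t_face_off_max`, `t_end_max` in ms from trial start.
#' @examples
#' d <- generate_design("exp1", "p01", seed = 7)
#' dplyr::count(d, block, condition)
#' @export
generate_design <- function(experiment_id, participant_id, seed,
                            isi_ms = 1000) {
  spec <- experiment_spec(experiment_id)
  if (missing(seed) || !is.numeric(seed)) {
    stop("an explicit integer seed is required", call. = FALSE)
  }
  ids <- names(identity_features)

  blocks <- withr::with_seed(as.integer(seed), {
    tail_lab <- ""
    tail_run <- 0
    lapply(seq_len(spec$n_blocks), function(b) {
      per_pair <- spec$per_cond / 12  # prior x other-identity pairs
      pool <- dplyr::bind_rows(
        tibble::tibble(prior = rep(ids, each = spec$per_cond / 4),
                       condition = "match", other = NA_character_),
        tidyr::expand_grid(prior = ids, other = ids,
                           rep = seq_len(per_pair)) |>
          dplyr::filter(.data$prior != .data$other) |>
          dplyr::mutate(condition = "mismatch") |>
          dplyr::select("prior", "condition", "other"),
        tidyr::expand_grid(prior = ids, other = ids,
                           rep = seq_len(per_pair)) |>
          dplyr::filter(.data$prior != .data$other) |>
          dplyr::mutate(condition = "partial") |>
          dplyr::select("prior", "condition", "other")
      )
      # The run-length constraint also holds across block boundaries.
      ord <- constrained_prior_order(pool$prior, init_lab = tail_lab,
                                     init_run = tail_run)
      tail_lab <<- ord[length(ord)]
      tail_run <<- sum(cumprod(rev(ord) == tail_lab))
      # Realise the prior order, drawing each trial's condition/other
      # uniformly from the remaining pool rows of that prior.
      pool <- pool[sample.int(nrow(pool)), ]
      pool <- pool[order(match(pool$prior, ids)), ]
      idx <- integer(nrow(pool))
      nxt <- vapply(ids, function(p) min(which(pool$prior == p)), 1L)
      for (i in seq_along(ord)) {
        idx[i] <- nxt[ord[i]]
        nxt[ord[i]] <- nxt[ord[i]] + 1L
      }
      out <- pool[idx, ]
      out$block <- b
      out$trial_in_block <- seq_len(nrow(out))
      out
    }) |>
      dplyr::bind_rows() |>
      (\(d) {
        # Corner counterbalancing: per prior, a balanced shuffled corner
        # sequence over that prior's trials across the whole session.
        d$prior_corner <- NA_character_
        for (p in ids) {
          rows <- which(d$prior == p)
          corners <- rep(prior_corners, length.out = length(rows))
          d$prior_corner[rows] <- sample(corners)
        }
        d
      })()
  })

  out <- blocks |>
    dplyr::mutate(
      experiment = experiment_id,
      participant = as.character(participant_id),
      trial = dplyr::row_number(),
      prior_feature = unname(identity_features[.data$prior]),
      shown_identity = dplyr::case_when(
        condition == "match" ~ prior,
        condition == "mismatch" ~ other,
        TRUE ~ NA_character_
      ),
      partner = dplyr::if_else(.data$condition == "partial", .data$other,
                               NA_character_),
      stimulus = dplyr::case_when(
        condition == "partial" ~ paste(pmin(prior, other), pmax(prior, other),
                                       sep = "+"),
        TRUE ~ shown_identity
      )
    )

  if (experiment_id == "exp1") {
    out <- out |>
      dplyr::mutate(
        t_prior_on = 0,
        t_outline_on = spec$prior_ms,
        t_face_on = spec$prior_ms + isi_ms,
        t_face_off_max = .data$t_face_on + spec$face_ms,
        t_end_max = .data$t_face_on + spec$face_ms + spec$response_ms
      )
  } else {
    out <- out |>
      dplyr::mutate(
        t_prior_on = 0,
        t_outline_on = NA_real_,
        t_face_on = spec$prior_ms,
        t_face_off_max = .data$t_face_on + spec$face_max_ms,
        t_end_max = .data$t_face_off_max
      )
  }
  out |>
    dplyr::select("experiment", "participant", "block", "trial_in_block",
                  "trial", "prior", "prior_feature", "prior_corner",
                  "condition", "stimulus", "shown_identity", "partner",
                  "t_prior_on", "t_outline_on", "t_face_on",
                  "t_face_off_max", "t_end_max")
}

#' Generate designs for a cohort of participants
#'
#' @param experiment_id `"exp1"` or `"exp2"`.
#' @param n_participants Number of participants; ids are `"p01"`, `"p02"`, ...
#' @param seed Root integer seed; per-participant seeds are derived as
#'   `seed * 1000 + participant index`.
#' @param ... Passed to [generate_design()].
#' @return A tibble of stacked per-participant designs.
#' @export
generate_cohort_design <- function(experiment_id, n_participants, seed, ...) {
  purrr::map_dfr(seq_len(n_participants), function(i) {
    generate_design(experiment_id, sprintf("p%02d", i),
                    seed = as.integer(seed) * 1000 + i, ...)
  })
}
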