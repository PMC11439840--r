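# gazexpect

Tools for analysing how prior expectations guide eye movements during
face viewing — from raw 1000-Hz gaze samples to saccade/fixation events,
region-of-interest (ROI) metrics, behavioural scores, and the matching
statistical battery — together with a ground-truth gaze simulator so the
whole chain is testable without any recordings.

## Who this is for

Eye-tracking researchers running cueing paradigms in which a prior (here:
a name cueing one of four face identities, each distinguished by one
feature — forehead, chin, ears, or nose) may drive

* **predictive saccades**: anticipatory eye movements toward the expected
  feature ROI during the inter-stimulus interval, before the face
  appears;
* **biased information sampling**: earlier, more frequent, and longer
  fixations on the expected feature once the face is visible;
* **assimilation**: a perceptual bias to classify an ambiguous 50/50
  morph as the expected identity.

## The core quantities

* Saccades are detected where angular velocity exceeds 30°/s **or**
  acceleration exceeds 8000°/s², with a 0.1° motion threshold; degrees
  come from the display geometry via
  θ = atan(extent·pitch/distance). Detected events (saccade, fixation,
  blink) exactly partition each trial's timeline.
* Predictive saccades are the first two saccades launched ≥ 100 ms
  after outline onset; per-ROI *relative* frequencies (each feature is
  expected : unexpected 1:3 across trials) are averaged into a
  2 × 2 saccade-rank × expectation table per participant.
* The perceived-face-identity index scores each of the 12 prior × morph
  combinations as (compliant − noncompliant)/n, averages them, and maps
  the result to 0–100% (50% = no bias; > 50% = assimilation).
* Fixation order assigns ordinals 1–4 to the feature ROIs by first
  fixation (random fill for unfixated ROIs); fixation-count and
  dwell-time proportions are computed overall and in 500-ms bins.
* Inference: repeated-measures ANOVA with Greenhouse–Geisser-corrected
  dfs and generalized/partial η², exact Wilcoxon signed-rank tests with
  r = |z|/√n, and cluster-robust goodness-of-fit and proportion tests on
  unweighted per-participant proportions (Cramér's V, averaged Cohen's
  h) for clustered categorical outcomes such as ordinal distributions
  against uniform π = 0.25.

Preregistered-style exclusion rules are built in: trials without a prior
fixation or a response, > 30% data loss in the Experiment 1 outline
window, < 50% fixation coverage of the Experiment 2 face presentation;
participants with > 30% invalid trials or chance-level accuracy.

## Worked example

Simulate one participant of the predictive-saccade experiment, detect
events, apply the exclusion rules, and compute the headline metrics:

```r
library(gazexpect)
library(dplyr)

rois   <- build_default_roiset()
design <- generate_design("exp1", "p01", seed = 7)   # 432 trials, 3 blocks
trials <- simulate_behavior(design, behavior_params(), seed = 8)
sim    <- simulate_gaze_cohort(trials, gaze_sim_params(), rois, seed = 9)
events <- detect_events(sim$samples, detection_params(), roi_screen(rois))

validity <- validate_trials(trials, sim$samples, events, rois)
valid    <- roi_class_map(trials[validity$included, ])   # 3 of 432 excluded

predictive_saccade_table(valid, events, rois) |>
  group_by(sacc_rank, expectation) |>
  summarise(pct = mean(pct), .groups = "drop")
#>   sacc_rank expectation   pct
#> 1         1 expected     52.4
#> 2         1 unexpected   15.9
#> 3         2 expected     35.5
#> 4         2 unexpected   21.5

rt_summary(valid)
#>   participant condition mean_rt_ms     n
#> 1 p01         match           664.   144
#> 2 p01         mismatch        717.   142
#> 3 p01         partial         719.   143

assimilation_index(valid)
#>   participant assimilation_index n_responses
#> 1 p01                       64.3         143
```

Reading the numbers: with the default simulator (first anticipatory
saccade aimed at the expected ROI on 50% of trials) the first-saccade
expected cell sits near 52%, against ~16% for the same ROIs when their
feature was not expected — the 1:3-corrected signature of predictive
saccades. Responses to expected faces are ~53 ms faster than to
unexpected ones (facilitation), and the morph index of 64% reflects the
simulated assimilation bias (`assimilation_q = 0.65`; 50% would be
unbiased). `run_pipeline(run_config(...))` wraps the same chain,
including artifact injection, participant-level exclusion, the
statistical battery, and a TSV/JSON result bundle with provenance; a
thin command-line front end lives in `inst/cli/gazexpect.R`.

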