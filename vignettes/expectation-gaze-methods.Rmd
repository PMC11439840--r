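---
title: "Models and methods: expectation-guided gaze analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: expectation-guided gaze analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazexpect)
library(dplyr)
```

## The scientific problem

When an observer knows which face is likely to appear next, that
expectation can steer the eyes before and during face viewing: saccades
may be launched toward the facial feature that would disambiguate the
expected identity (predictive saccades), and once the face appears,
fixations may favour the expected feature (biased information sampling).
Expectations can also bias perception itself, pulling the perceived
identity of an ambiguous 50/50 morph toward the cued face (assimilation).

`gazexpect` implements the full analysis chain for a two-experiment
paradigm built around four face identities (A–D), each distinguished by
one feature — forehead, chin, ears, or nose. A name prior cues one
identity in a screen corner (750 ms). In Experiment 1, a face outline
follows (1000 ms), then the face is flashed for 100 ms and classified as
expected/unexpected within 1500 ms; the analysis targets anticipatory
saccades during the outline interval. In Experiment 2, the face stays up
to 4500 ms (terminated by the response), and the analysis targets the
order, number, and duration of fixations on feature regions of interest
(ROIs). Conditions are `match` (cued face shown), `mismatch` (another
face), and `partial` (a morph containing the cued identity).

Because the pipeline must be testable without human data, the package
includes a first-class synthetic-data generator with known ground truth:
every downstream stage — event detection, exclusion rules, metrics,
statistics — is validated against what the generator actually put into
the signal.

## The synthetic gaze model

A simulated trial is a plan of alternating fixations and saccades:

* **Fixations** hold a target point; scanning fixation durations are
  normal with mean 250 ms and SD 80 ms (truncated at 60 ms), typical of
  face viewing.
* **Saccades** follow a minimum-jerk position profile. Duration grows
  linearly with amplitude ($D = 21\,\mathrm{ms} + 2.2\,\mathrm{ms/°}
  \cdot A$, the classic main-sequence fit), which implies a peak
  velocity $v_{peak} = 1.875\,A/D$ that increases strictly with
  amplitude. Targets are sampled inside the inner 70% of the goal
  region so that measurement noise does not push landing points across
  an ROI border.
* **Noise** is AR(1) positional jitter (stationary SD 0.3 px,
  coefficient 0.95), mimicking the temporally correlated jitter of
  video-based eye tracking. White noise of realistic amplitude would
  put spurious power into the velocity band and is *not* what trackers
  produce.
* **Expectation knobs**: `p_sacc1_expected` / `p_sacc2_expected` set
  the probability that the first/second saccade after the anticipation
  interval targets the expected ROI (complement spread uniformly over
  the alternatives); `p_center_first` reproduces the central first
  fixation on a newly appearing face. Behavioural knobs set
  per-condition reaction-time means (log-normal; positive support),
  clear-face accuracies, a miss rate, and `assimilation_q`, the
  probability that a morph is classified as the expected identity, so
  the perceived-face-identity index recovers $100\,q$ by construction.

Artifacts are injected separately: per-sample dropout with probability
`loss_rate` (so the realised invalid fraction concentrates binomially)
plus contiguous blink spans at `blink_rate` events/s with log-normal
durations around 120 ms.

What the generator does *not* emulate: drift and slow head-movement
artifacts, pupil-size dynamics, saccadic undershoot with corrective
saccades, smooth pursuit, and any dependence of fixation durations on
content. Green tests therefore certify the pipeline's arithmetic and its
contracts, not robustness to every pathology of real recordings.

## Event detection

Saccades are defined as periods where angular velocity exceeds 30°/s
**or** acceleration exceeds 8000°/s², with a minimum displacement
(motion threshold) of 0.1°; these thresholds are the standard
video-oculography definition and are configurable. Velocity is a 5-point
central difference on the gaze angle (the estimator used by EyeLink-class
parsers); acceleration is a central difference of the speed. Degrees are
computed from pixels with the arctangent form
$\theta = \operatorname{atan}\!\big((x - c_x)\,s_x / d\big)$ for
positions and $2\operatorname{atan}(e/2d)$ for extents (41.0 × 31.0 cm
display, 1600 × 1200 px, 560 mm viewing distance by default; the
1064 × 736 px face then subtends about 27.4° × 19.3°).

Numerical choices that the thresholds alone do not fix:

* supra-threshold runs shorter than 4 ms are treated as jitter;
* sub-threshold dips shorter than 10 ms between two saccade runs are
  merged — genuine fixations are never that brief, and without the
  merge a noisy dip near the velocity peak could split one saccade
  into two;
* saccade boundaries are refined outward to the surrounding local
  velocity minima. The minimum-jerk profile starts slowly, so the
  threshold crossing lags the true onset by 2–3 ms; the walk-back
  recovers it (97% of ground-truth onsets within ±2 samples at
  1000 Hz);
* invalid runs become blinks; runs of at least 20 ms are padded by
  10 ms on each side because samples flanking a blink are unreliable;
* events are half-open `[onset, offset)` intervals and exactly
  partition each trial's timeline — a property tested on every
  simulated trial.

## Exclusion rules

Trials are excluded when the name prior was not fixated (no fixation
centroid inside the prior's corner region during the 750-ms prior), when
no response was given, and when data loss in the window of interest was
too high: more than 30% invalid samples during the Experiment 1 outline
interval, or less than 50% fixation coverage of the Experiment 2 face
presentation. Participants are excluded when more than 30% of trials are
invalid or when clear-face accuracy is at or below the 50% chance level
(the conservative level is used in both experiments; the
Experiment 2 mismatch-specific guessing level is
$0.5 \times 0.25 = 12.5\%$).

Two windows are defensible for the Experiment 1 loss rule because the
outline is shown for 1000 ms while the preregistered rule names a 750-ms
window; `exclusion_rules(exp1_isi_window_ms = )` exposes the choice and
the full interval is the default. The prior-corner region extent is not
published; the default is the central quarter-screen rectangle of each
quadrant, configurable in the ROI table.

## Metrics

* **Predictive saccades** (Experiment 1): among saccades launched at
  least 100 ms after outline onset and before face onset, the first two
  are classified by the ROI they land in. Because each feature is
  expected in only a quarter of trials (1:3), per-ROI *relative*
  frequencies are computed separately for expected and unexpected
  trials and then averaged over the four ROIs, giving the
  2 × 2 (saccade rank × expectation) table per participant. When a
  trial contributes fewer than two qualifying saccades, frequencies
  are computed per qualifying saccade.
* **Fixation order** (Experiment 2): feature ROIs are ranked 1–4 by
  first-fixation onset; unfixated ROIs receive the remaining ordinals
  uniformly at random (trials with no feature fixation are dropped).
  The random fill is seeded; by default a single fill is used,
  mirroring standard practice, and `fixation_order_table()` can be
  re-run over fill replicates if fill noise is a concern.
* **Sampling proportions**: fixation counts per ROI class divided by
  all fixations during face presentation; dwell time divided by
  presentation duration; also computed in four 500-ms bins (dwell is
  split across bin boundaries, a fixation counts in every bin it
  overlaps, and bins beyond the trial's actual presentation are
  missing). Classes are `expected`, `unexpected` (the morph's other
  identity in partial trials, the shown identity's feature in
  mismatch; undefined in match trials) and `other` (the remaining two
  ROIs).
* **Perceived-face-identity index**: per prior × morph combination
  (12 in total), noncompliant responses are subtracted from compliant
  ones and divided by that combination's response count; the
  12 scores are averaged and mapped linearly so 0 → 50%,
  all-compliant → 100%. The published description divides "by the
  number of possible combinations (N = 12)", which is ambiguous
  between pooled and per-combination normalisation; the
  per-combination reading keeps the index in [0, 100] for unbalanced
  counts and reproduces all published anchor points (balanced → 50%),
  and is isolated in `assimilation_index()`.
* **Eye–behaviour linkage**: accuracy conditioned on whether the
  fixation containing the face-onset timestamp lies in the expected
  ROI (a saccade in flight at onset counts as no ROI), and the
  proportion of partial trials whose chosen identity's ROI was the
  last feature ROI fixated before the response (chance 25%).
* Reaction-time summaries average all responded trials regardless of
  correctness (`correct_only = TRUE` restricts them).

## Statistics

Every test returns a one-row-per-effect tibble (statistic, corrected
dfs, p, effect size, CI, correction tag) with `tidy()`/`glance()`
methods.

* **Repeated-measures ANOVA** (one or two within factors, complete
  balanced designs only; missing cells are an explicit error).
  Sphericity is handled with the Greenhouse–Geisser epsilon estimated
  from the covariance of the orthonormalised effect contrasts,
  $\hat\varepsilon = \operatorname{tr}(\Sigma_C)^2 / (d
  \operatorname{tr}(\Sigma_C^2))$, applied to both dfs. Generalized
  $\eta^2$ follows the Olejnik–Algina convention (subject variance and
  all error strata in the denominator); partial $\eta^2$ is also
  reported. A two-level factor has $\varepsilon = 1$ by construction.
* **Wilcoxon signed-rank** uses the exact null distribution for
  $n \le 25$ without ties and the continuity-corrected normal
  approximation otherwise; the effect size is $r = |z|/\sqrt{n}$.
* **Cluster-robust tests** treat the participant as the cluster and
  estimate category proportions as *unweighted means of per-cluster
  proportions*, the choice that is robust to informative cluster sizes
  (participants with more valid trials carry no extra weight). The
  goodness-of-fit statistic is the Wald quadratic form in the first
  $k-1$ proportions with the empirical between-cluster covariance;
  with $M$ clusters it is referred to its Hotelling $T^2$ null (an F
  distribution after rescaling by $(M-k+1)/((k-1)(M-1))$). The
  one-sample proportion statistic is the z ratio of the mean cluster
  proportion against $\pi_0$ with the between-cluster variance,
  referred to $t_{M-1}$. These small-sample references are the
  package's calibration choice: with 34 clusters the naive
  $\chi^2_{k-1}$/normal references reject about 8%/6% of true nulls at
  nominal 5%, while the implemented references hold 4–5% (verified by
  simulation in the test suite, together with confidence-interval
  coverage and p-value uniformity). Cramér's V uses the total
  observation count ($V = \sqrt{\chi^2 / (N(k-1))}$, N = trials, not
  clusters — the convention consistent with published values of this
  design), and Cohen's h is averaged over per-cluster values.
* Bonferroni correction multiplies p by the family size and caps at 1;
  family sizes mirror the analyses (e.g. 6 for ordinal post-hoc
  comparisons).

Degenerate inputs are explicit, not silent: identical paired samples
give $t = 0, d = 0$; constant nonzero differences are flagged
(`degenerate_zero_variance`); all clusters exactly on the null give a
zero statistic with $p = 1$; a singular between-cluster covariance is an
error.

## A worked miniature

```{r mini, eval = FALSE}
rois <- build_default_roiset()
design <- generate_design("exp1", "p01", seed = 7)
trials <- simulate_behavior(design, behavior_params(), seed = 8)
sim <- simulate_gaze_cohort(trials, gaze_sim_params(), rois, seed = 9)
events <- detect_events(sim$samples, detection_params(), roi_screen(rois))
validity <- validate_trials(trials, sim$samples, events, rois)
valid <- roi_class_map(trials[validity$included, ])
predictive_saccade_table(valid, events, rois) |>
  group_by(sacc_rank, expectation) |>
  summarise(pct = mean(pct), .groups = "drop")
```

The same chain, with artifact injection and the statistical battery, is
wrapped in `run_pipeline()`.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds; cohort simulation
derives per-trial seeds by a fixed counter scheme
(`(seed * 7919 + trial) mod (2^31 - 1)`), so any single trial can be
re-simulated in isolation and two runs with the same configuration are
byte-identical apart from timestamps. The test suite validates the
detector on a 1000-trial set, parameter recovery on 34-participant
cohorts over the full Experiment 1 design at
$p \in \{0.25, 0.5, 0.9\}$ and $q \in \{0.25, 0.5, 0.75\}$ (recovery
within ±3 percentage points), and statistical calibration on 2000
simulated null cohorts of 34 clusters × 200 observations; these sizes
were chosen to put Monte-Carlo error well below the tolerances being
asserted.

## Known limitations

* The detector is offline and assumes a uniform sampling rate; no
  smooth pursuit or microsaccade classes.
* ROI placement inside the face box is proportional, not the published
  pixel layout (which is not printed); all analyses are
  placement-independent, but absolute dwell values depend on the
  layout.
* The printed face visual angle (27.44°) is not exactly reproduced by
  either the arctangent or the small-angle formula from the stated
  geometry; the package matches it to ±0.5° and does not guess the
  original rounding.
* Cluster-level tests assume enough clusters for a stable covariance
  (at least $k$ for the goodness-of-fit test; in practice ≥ 10).
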