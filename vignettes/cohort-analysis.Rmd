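---
title: "Methods: wearable kinematics, well-being classification and pre/post statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable kinematics, well-being classification and pre/post statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinewell)
```

## The study design this package analyses

kinewell implements the analysis pathway of a 4-week community exergame
intervention for older adults: participants play three motion-controlled games
for 10 minutes each in weekly supervised sessions, wearing five inertial
measurement units (IMUs) — one on each distal forearm, one at the L4 vertebral
level, and one on the dorsum of each foot. Alongside the movement data the
study collects a weekly 14-item Mental Health Continuum–Short Form (MHC-SF)
adaptation, daily nutrition logs (milk servings, cups of water, balanced-plate
entries), and a 7-item pre/post technology-acceptance and self-rated-health
survey from the subset of participants who complete both questionnaires.

The pipeline has five stages, each usable on its own:

1. **Synthetic cohort generation** (`simulate_*`) — seeded simulators for all
   four data streams, because the raw study data are not published.
2. **Kinematic metrics** (`compute_segment_metrics()` and the vector
   functions underneath) — peak detection and the activity/energy formulas.
3. **Well-being** (`score_mhcsf()`, `classify_mental_health()`,
   `weekly_group_trends()`).
4. **Nutrition** (`aggregate_nutrition_weekly()`, `goal_adherence()`).
5. **Pre/post statistics** (`paired_t_test()`, `cohens_d_pooled()`,
   `percent_change()`, `summarize_items()`, `metric_group_trends()`), stitched
   together by `run_pipeline()`.

## Kinematic metrics

All metrics operate on the scalar magnitude
$a_i = \lVert(a_{x,i}, a_{y,i}, a_{z,i})\rVert_2$ of the tri-axial
acceleration. Gravity is **not** subtracted by default — the MET regression
below was evidently fit on raw magnitudes, whose resting value sits near
$g \approx 9.81\,$m/s² — but `compute_segment_metrics(subtract_gravity =
TRUE)` removes it for users whose devices export gravity-free acceleration.

**Peak detection.** Samples are standardized as $z_i = (a_i - \mu)/\sigma$
with the *population* standard deviation ($N$ denominator). By default $\mu$
and $\sigma$ are taken over the whole game segment; a centred rolling window
(`peak_config(windowing = "rolling")`) is available for drifting baselines. A
sample is a detected peak when

* $z_i \ge$ `z_threshold` (default 2.0),
* it is a local maximum, $z_{i-1} \le z_i \ge z_{i+1}$, and
* it falls at least `min_separation_s` (default 0.25 s) after the previously
  kept peak, scanning left to right so the earlier peak wins.

Only the z-score formula is fixed by the method; the threshold, local-maximum
requirement and separation are detector choices, all exposed in
`peak_config()`. The minimum separation acts as a non-paralyzable dead time:
for Poisson-timed events of rate $\lambda$ the expected kept fraction is
$1/(1+\lambda\tau)$, about 89% at $\lambda = 0.5$ Hz and $\tau = 0.25$ s.
Tests that compare detected counts against the generator's event log
therefore either use the wide 3-standard-deviation Poisson band (at default
settings) or shorten the separation to 0.15 s, where the dead-time loss is
~7% and recovery within 10% is expected.

**Per-segment metrics.** For each (participant, week, game, sensor) segment of
$N$ samples and duration $D$ hours:

* action count $= |\text{peaks}| / N \in [0, 1]$;
* maximum acceleration $= \max_i a_i$;
* RMS acceleration $= \sqrt{\tfrac1N \sum_i a_i^2}$;
* METs $= \max(0,\; 1.8 \times \text{RMS} - 15)$;
* energy $= 1.05 \times \text{METs} \times D \times W$ kcal for body mass
  $W$ kg.

Two quirks of the MET/energy model are implemented as printed and flagged
here rather than "fixed": the regression's units are unstated (its $-15$
intercept implies device-specific scaling, which is why the coefficients are
arguments), and the energy formula is labelled as an hourly rate yet
multiplies by the duration — it is treated as total kcal. The line is
negative below RMS $= 8.3\overline{3}$ m/s², so METs are clamped at zero for
energy purposes while the raw value is kept in the `mets_raw` column for
auditing.

**Cross-sensor aggregation.** The source reports one value per metric per
game without stating a cross-sensor rule. The default here: mean of action
count and RMS across the five sensors, maximum of the per-sensor maxima, and
METs/energy recomputed from the aggregate RMS; the summary function is an
argument (`agg_fun`). Weekly values are means over that week's segments.

## Well-being classification

Subscale scores are sums of the raw frequency codes (0 = never … 5 = every
day): emotional = items 1–3 (0–15), social = items 4–8 (0–25), psychological
= items 9–14 (0–30). The 3 + 5 + 6 split follows the standard MHC-SF
structure; only the 3 hedonic + 11 eudemonic split is intrinsic to the
classification rule, so the mapping is configuration
(`mhcsf_subscales()`), not code.

A respondent is **mentally well** when at least 1 of the 3 hedonic items and
at least 6 of the 11 eudemonic items are experienced "every day" or "5–6
times a week" (code ≥ 4); otherwise **moderate**. The instrument's usual
third category (languishing) is deliberately absent: the analysis compares
exactly two groups. Missing items are a hard error — with 14 items and a
counting rule, silent imputation could flip the label.

Group-stratified trends default to classification from the week-1 response
(`basis = "week1"`): a fixed stratification is required for the weekly group
comparison to be interpretable. Per-week reclassification is available, and
the choice is explicit in every relevant function because the source design
never states which was used.

## Nutrition

Weeks are half-open 7-day bins anchored at the study start date. Weekly
summaries are descriptive cohort means with record counts; no significance
testing is applied to nutrition trends, matching the descriptive treatment
of these data. Milk, water and balanced-plate entries are treated as daily
counts (their exact units are unstated in the source). `goal_adherence()`
uses only logged days in its denominator and returns `NA` — never zero —
for a participant with no logs.

## Pre/post statistics

`paired_t_test()` tests the mean of the within-participant differences
$\text{pre} - \text{post}$ (so improvement gives negative $t$, matching the
sign convention of the published table), with $df = n - 1$ and a two-sided
p-value; it delegates the arithmetic to `stats::t.test()` and the tests
check it against the closed form $\bar d / (s_d/\sqrt n)$ computed
independently. Effect sizes use the pooled-SD Cohen's $d$:

$$d = \frac{\bar x_{post} - \bar x_{pre}}
           {\sqrt{(s_{pre}^2 + s_{post}^2)/2}}.$$

Summaries use the sample SD ($n-1$); the population SD appears only inside
the z-score detector. Reports round half away from zero to 2 decimals and
print $|d|$; the sign is kept internally. Recomputing $d$ from the published
moments reproduces five of the seven printed values exactly (0.55, 0.28,
0.96, 0.72, 0.64); the remaining two recompute to 1.09 and 0.66 against
printed 1.08 and 0.67 — a rounding inconsistency in the source table, which
is why those two rows are excluded from exact-reproduction checks. No
multiple-testing correction is applied (the source reports raw p-values
across 7 items); `stats::p.adjust()` is one line away for users who want it.

The published cohort-level "6.5% enhancement ($t_{47} = 3.82$)" in maximum
acceleration cannot be recomputed from printed inputs — the per-participant
data and the aggregation rule across the two groups are unpublished, and the
figure is not any simple combination of the two group changes (2.14% and
9.60%). It is therefore checked as parameter recovery instead: a synthetic
cohort of 48 participants with a configured 6.5% linear mean increase in
maximum acceleration is analysed with `metric_group_trends()`, and the mean
recovered change over 100 seeds must match the configured value within
Monte-Carlo error.

## The synthetic-data generator

The generator's defaults encode the study conditions: 48 participants in 4
arms, 30 survey completers (the published $df = 29$ implies 30 paired
observations), 4 weekly sessions of 3 games, 600-second segments, and 5
sensor sites. Values the source never states were chosen once, as follows,
and are all configurable:

* **Sampling rate 50 Hz** — typical for consumer IMUs of this class.
* **IMU signal model** — per-axis Gaussian noise (SD 0.3 m/s²), +g on the
  vertical axis, and Poisson-timed movement bursts (rate 0.5 Hz) shaped as
  0.3 s half-sine pulses of mean amplitude 6 m/s² with mild lognormal jitter
  (sdlog 0.15), scaled per site (forearms 1.0, feet 0.8, waist 0.6). The
  half-sine gives the detector one unambiguous local maximum per burst
  without dictating detector settings. Burst times are shared across the
  five sites — one body, one movement. True event times are attached to
  every simulated session for oracle-based tests.
* **Surveys** — per item, a bivariate normal (pre, post) pair with the
  published moments and within-subject correlation 0.5, discretized by
  rounding half away from zero and clipping to the Likert range (default
  1–5 for all items; per-item overrides exist because one item's mean of
  4.31 hints at a wider scale). The continuous latent pair is emitted
  alongside: configured moments hold exactly on the latent scale, while
  clipping and rounding bias the discretized moments, so recovery tests are
  defined pre-discretization.
* **MHC-SF** — each participant carries a latent `well`/`moderate` profile
  (mixing probability 0.5); items are drawn i.i.d. from the profile's
  category distribution. The default profiles classify their own group
  correctly ≥ 95% of the time, leaving realistic label noise.
* **Nutrition** — daily value = base + drift × (week − 1) + noise, rounded
  to a non-negative integer; defaults give flat milk, rising water
  (+0.5 cups/week) and rising balanced-plate (+0.3/week) trends.

What the generator does **not** emulate: biomechanically realistic gait or
arm kinematics, sensor orientation and drift, game-specific movement
signatures, item-level MHC-SF covariance, attrition mechanisms, or any
between-arm differences (arm labels are carried through but never analysed,
as in the source). Passing tests on simulated cohorts therefore demonstrate
correctness of the *computations* under the stated statistical structure,
not validity of the metrics on real sensor data.

## Numerical choices and degenerate inputs

* Zero-variance signals: `zscore_series()` errors; `detect_peaks()` returns
  an empty set with a warning (a flat signal has no activity peaks).
* Zero-variance paired differences: a degenerate test (error from
  `paired_t_test()`; flagged `NA` with a warning in `summarize_items()`).
* Ties in peak separation are broken in favour of the earlier peak; the
  sample-gap comparison uses a square-root-of-machine-epsilon slack so that
  exact multiples of the sampling interval are kept.
* Rounding for reports is half-away-from-zero (`round_half_out()`), applied
  only at the report layer; internal tables keep full precision (metrics
  CSVs print 4 decimals, survey tables 2).
* `percent_change()` is undefined at `before = 0` and errors rather than
  returning ±Inf.

## Problem sizes used by the test suite

The shipped tests run the full-length designs where the check depends on
them (600 s × 50 Hz sessions for Poisson count recovery; n = 10,000 for
survey moment recovery; 2,000 replicates for effect-size recovery and
type-I calibration; 1,000 random series up to n = 10,000 for the
brute-force peak oracle; all 2^14 binarized response patterns for the
classification rule) and a scaled demo cohort (6 participants, 30 s at
25 Hz) for end-to-end pipeline and determinism checks, where only structure
and byte-identity matter.

## Known limitations

* The MET regression is used as printed; without knowing its original units
  and device, absolute METs/kcal from other hardware should be treated as
  relative, not calibrated, quantities.
* Classification is per-response; test–retest reliability of the weekly
  MHC-SF is out of scope.
* The pipeline assumes at most one nutrition record per participant-day and
  complete 14-item questionnaires; both are validated, not repaired.
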