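---
title: "Methods: fixation detection, dynamic AOIs, and the cluster-mass permutation test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixation detection, dynamic AOIs, and the cluster-mass permutation test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazecourse)
library(dplyr)
```

gazecourse analyses how infants distribute gaze over the upper and lower
halves of a moving talking face. The pipeline runs from raw eye-tracker
samples to a familywise-corrected statement of *when in the trial* looking
to the lower face half differed from chance. This vignette explains each
stage's model and assumptions, the tunable parameters, the synthetic-data
generator used in place of raw infant data, and the numerical choices made
where the design was genuinely open.

## The analysis problem

An infant watches up to 8 video trials (two each of four stimulus types:
an Asian American or White woman using infant-directed or adult-directed
speech, audio replaced with music so only visual information remains). A
corneal-reflection eye tracker samples the point of gaze at 120 Hz on a
1680 x 1050 px screen. Because the face moves, screen position alone does
not determine what the infant looked at: the areas of interest (AOIs) —
two stacked rectangles bisecting the face, each about 16 cm wide and
8.5 cm high — move with the face, and the same screen point can belong to
the lower half at one moment and the upper half at another.

The pipeline produces, in order:

1. **Fixations** from the raw samples (dispersion-threshold I-DT filter).
2. **AOI labels** for every valid sample and every fixation.
3. **Trial inclusion**: at least 1000 ms of summed fixation time.
4. **Dependent variables**: per-trial looking totals by AOI, per-condition
   preference proportions, and a long fixation table (one row per
   fixation, with index, duration, AOI, condition, and subject
   covariates) for downstream mixed-model analyses, which are outside
   this package's scope.
5. **Binned time courses**: the proportion of in-AOI samples in each
   250 ms bin that fell in the lower half, averaged trial -> subject ->
   group.
6. **A cluster-mass permutation test** of the subject time courses against
   chance (0.50).

## Fixation detection (I-DT)

A fixation is any maximal window of consecutive valid samples whose
*dispersion* stays at or below 100 px and whose duration is at least
80 ms. Dispersion is the classic I-DT sum

$$ D = (\max_i x_i - \min_i x_i) + (\max_i y_i - \min_i y_i), $$

the metric the standard low-speed (< 200 Hz) fixation filters use. The
scan starts with the shortest window satisfying the duration minimum; if
its dispersion passes, the window is extended rightward while it still
passes, emitted, and the scan resumes after it; otherwise the start
advances one sample. Track-lost samples break candidate windows — there is
no gap bridging (a configurable choice; the default is the strictest
reading).

Duration counts one sample period per sample, so a 60-sample window at
120 Hz is 500 ms and the 80 ms minimum translates to 10 samples
(83.3 ms); a stable 8-sample (66 ms) episode is not a fixation. A
fixation's `end_ms` is its last sample time plus one period, making
`[start_ms, end_ms)` half-open on the sample grid.

The test suite holds the detector against an independently coded
brute-force oracle (full dispersion recomputation at every step) on
hundreds of random gaze sequences up to 300 samples; the two must agree
exactly on counts, boundaries, and centroids.

## Dynamic AOI assignment

AOI rectangles are looked up at each sample's timestamp (step-function
interpolation) and membership is a point-in-rectangle test, half-open on
the right and bottom except that the shared horizontal edge between the
halves belongs to the **upper** AOI. Testing upper first with an inclusive
bottom edge keeps the two halves a partition of the face box while
honouring that tie-break. Valid samples outside both rectangles are
labelled `none`; invalid samples are `NA`.

A fixation's AOI is the majority label of its member samples; an
upper/lower tie takes the label of the temporally first member sample in
either AOI; if `none` holds a strict plurality the fixation is `none`.
The vendor software the field uses does not publish its rule, so this one
is documented and deliberately simple.

## Exclusion, looking totals, experience classification

A trial is kept when its summed fixation duration is at least 1000 ms
(inclusive: exactly 1000 ms is kept). "Recorded looking" is fixation
time — the fixation file is the pipeline's unit of looking; whether raw
on-screen sample time was meant instead is not documented in the source
procedures, so the rule is a configurable default.

Per-trial looking totals sum fixation durations by AOI; `none` fixations
count toward neither. The per-condition preference defaults to the
duration-pooled ratio $\sum \text{lower} / \sum (\text{lower} +
\text{upper})$ across the condition's trials, which weights trials by how
much the infant actually looked and is robust to trials with little
looking; the unweighted mean of per-trial proportions is available via
`method = "mean"`. Subjects lacking any of the four conditions are
flagged, since a four-condition repeated-measures analysis needs all four.

Three experience classifications operate on parental reports:

* **Language**: exposure to English more than 75% of the time is
  monolingual English; another single language above 75% is monolingual
  for that language; several languages with none above 75% is
  multilingual.
* **Maternal race**: White (regardless of Hispanic ethnicity) is White;
  Asian American, alone or with White, is Asian American; any other race,
  or Hispanic with no reported race, is Other.
* **Diversity of face experience**: the count of distinct groups among
  the mother's classified race, a significant female caregiver's race,
  and questionnaire-reported regular exposure to White, Asian American,
  and Black women (an Other mother counts as her own group): three or
  more is high, two medium, one low. Only experience with women's faces
  is considered, and the classification is undefined when the
  questionnaire is missing.

## Binned time courses

The first 7500 ms of each kept trial is divided into 30 half-open 250 ms
bins of 30 samples each (bins indexed from 0; reported onsets/offsets lie
on this grid). Within a bin the proportion toward the lower half is the
number of lower-half samples divided by the number of samples in either
half; samples outside both halves and track loss never enter the
denominator, and a bin with an empty denominator is missing. Binning uses
all valid AOI-labelled samples rather than fixation-filtered samples —
the source procedure binned "the samples data" — so brief in-AOI episodes
shorter than a fixation still contribute.

Averaging is strictly two-stage and available-case: trial proportions are
averaged into a subject time course (per bin, over trials with data), and
subject time courses are averaged into the group time course, so every
subject counts equally regardless of trial count. With one trial per
subject the two stages coincide — a limit the tests check. No imputation
or smoothing is applied. Group summaries carry per-bin contributing-subject
counts and t-based 95% confidence intervals.

## The cluster-mass permutation test

Per bin, a one-sample t test compares the subjects' bin proportions to
chance (0.50), two-sided at $\alpha_{bin} = 0.05$, using subjects with
data in that bin. Two-sidedness matters: infants show below-chance
(upper-half) episodes early in some conditions as well as above-chance
ones. Bins with fewer than `min_subjects_per_bin` (default 2) subjects or
zero variance are untestable: excluded from clusters rather than assigned
an infinite t.

Clusters are maximal runs of consecutive, individually significant bins
whose t statistics share a sign (a mixed-sign mass would be
uninterpretable); the cluster mass is the summed t. Runs of length one
are allowed.

The null distribution is built by sign-flipping: each permutation draws
one sign $s_i \in \{-1, +1\}$ per subject and maps that subject's whole
time course to $0.5 + s_i\,(x_{ib} - 0.5)$, preserving the missingness
pattern and the within-subject autocorrelation across bins. Bin tests and
clusters are recomputed and the largest absolute mass stored (0 when no
cluster forms). What exactly to permute is not pinned down by the verbal
description of the procedure; per-subject sign flipping is the standard
exchangeable null for a one-sample test against chance and is the
documented, pluggable default here.

A cluster is significant when its absolute mass exceeds the significance
threshold of the null: the $\lceil(1-\alpha)(B+1)\rceil$-th order
statistic of the $B$ stored masses. At the reference $B = 1000$ and
$\alpha = 0.05$ this is the 951st of 1000 sorted masses — in practice the
value that 95% of the null masses lie below. The $+1$ accounts for the
observed statistic being exchangeable with the $B$ permutation draws and
bounds the familywise error at $\alpha$ exactly; without it the size is
$(\lfloor \alpha B\rfloor + 1)/(B+1)$, noticeably above $\alpha$ at small
$B$. A simulation with 2500 independent null datasets confirmed the
procedure's rejection rate matches this analysis.

Reported p-values are the pure proportion of null masses at least as
large as the observed mass, so a mass above every null entry prints as
0.000 — the convention of the field's cluster tables. The
(1 + exceedances)/(B + 1) variant is available via `plus_one = TRUE`.

## The synthetic-session generator

The generator (`simulate_session()`) stands in for raw infant data, which
are not redistributed with the package. It emulates:

* 120 Hz sampling over 7500 ms trials (900 samples), up to 8 trials per
  infant, two per stimulus type across the 2 x 2 design;
* alternating fixations and saccades: fixation durations are normal
  (mean 400 ms, SD 150 ms, floored at 100 ms — a plausible infant
  fixation-duration regime), separated by 40 ms saccade gaps (rounded to
  whole sample periods), with all boundaries on the sample grid;
* gaze that tracks the moving face: the face centre follows a smooth
  planar sinusoid (default amplitude 20 px) and both the AOIs and the
  planted gaze points move with it;
* within-fixation jitter, isotropic with SD 4 px;
* per-sample track loss at a configurable rate (default 5%);
* a configurable, time-varying probability that each fixation targets the
  lower AOI (the *bias profile*), the generator's ground-truth signal;
* subject covariates (age 217-320 days, maternal race reports, caregiver
  race, face-experience questionnaire, language exposure) with known true
  classification labels, generated by logic independent of the
  classifiers so label recovery is a genuine cross-check.

Three numerical couplings keep planted fixations exactly recoverable by
the I-DT filter, which the round-trip invariant (at zero track loss,
at least 95% of planted fixations of 120 ms or longer are recovered with
onset/offset error within 2 sample periods) requires:

* The dispersion of a long sample cloud is roughly five per-axis standard
  deviations *per axis*, and gaze additionally drifts with the face, so
  jitter SD (4 px) plus worst-case motion drift stays well under the
  100 px cap. A larger jitter SD (e.g. 10 px) breaches the cap for long
  fixations about a quarter of the time and splits them.
* Consecutive fixation targets are at least `min_saccade_px = 250` px
  apart, so two fixation clouds can never merge into one window.
* Saccade samples traverse only the mid-flight 0.4-0.6 portion of the
  path between fixation points, keeping every saccade sample at least
  100 px from both clouds; otherwise the greedy scan absorbs near-endpoint
  saccade samples and shifts or splits detected boundaries.

Each (subject, trial) pair draws from its own random stream derived from
the master seed, so output is bit-identical under a fixed configuration
and subject k's data are unaffected by adding or removing other subjects.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: calibration error and drift, head
movement beyond planar face translation, smooth pursuit, blink dynamics
(track loss is i.i.d. rather than bursty), systematic infant
inattention, heavy-tailed fixation durations, or any dependence of gaze
on stimulus content beyond the planted lower-half bias. Tests demonstrate
that the *pipeline* is correct and calibrated, not that the generator
reproduces infant behaviour.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_duration` | 80 | ms | fixation filter minimum (10 samples at 120 Hz) |
| `max_dispersion` | 100 | px | I-DT sum-of-ranges cap |
| `min_trial_looking` | 1000 | ms | trial inclusion, inclusive |
| `bin_width` | 250 | ms | 30 samples per bin at 120 Hz |
| `analysis_window` | 7500 | ms | first 7500 ms analysed; 30 bins |
| `chance` | 0.50 | — | equal looking to both halves |
| `alpha_bin` | 0.05 | — | two-sided per-bin t tests |
| `alpha_cluster` | 0.05 | — | familywise level of the max-mass null |
| `n_permutations` | 1000 | — | sign-flip draws |
| `px_per_cm` | 35 | px/cm | pins the cm-specified AOI sizes to the 1680 x 1050 panel; the true viewing-geometry conversion is not documented, so this is a package choice exposed in `sim_config()` |

## Problem sizes used by the test suite

The suite exercises the statistical properties at sizes chosen to give
informative Monte-Carlo error while remaining routine to run: type-I
calibration uses 600 null cohorts of 12 subjects x 4 trials x 2500 ms
(10 bins) at 300 permutations each, checked against the 99% binomial
interval around 0.05; power/recovery uses 20 cohorts at the full design
(30 subjects x 8 trials x 7500 ms) with a +0.2 bias planted in
2000-4000 ms at 200 permutations; exactness compares sampled p-values
with the exhaustive $2^n$ sign-flip enumeration for up to 8 subjects. The
detector-vs-oracle equivalence runs on random sequences up to 300
samples.

## Known limitations

* The dispersion metric, window-growth rule, and gap handling of the
  vendor's proprietary filter are unpublished; this package implements
  the classic I-DT reading and exposes the thresholds, but exact
  numerical agreement with vendor fixation files is not guaranteed.
* The trial-inclusion rule counts fixation time; if a study's 1000 ms
  criterion counted raw valid-sample time, set `min_trial_looking`
  accordingly and recompute — the pipeline does not decide this
  ambiguity.
* Between-group (experience-variable) cluster tests are deliberately not
  implemented: the motivating design lacked power for them, and the
  one-sample sign-flip null does not transfer to between-group
  comparisons unchanged.
* With very few subjects the per-bin t tests are fragile; bins fall back
  to untestable rather than extrapolating, so sparse cohorts can yield
  no testable bins at all.

## A complete run

```{r example, eval = FALSE}
cfg <- run_config(
  sim = inject_bias(sim_config(n_subjects = 30, seed = 1),
                    window = c(2000, 4000), magnitude = 0.2),
  perm = perm_config(n_permutations = 1000, seed = 2),
  out_dir = "run1"
)
res <- run_pipeline(cfg)
tidy(res$test_all)
plot_timecourse(res$group_tc_cond, res$cluster_report)
```
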