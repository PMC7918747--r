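# gazecourse

Infant eye-tracking studies of face scanning ask *where* on a talking
face an infant looks and *when during a trial* a preference emerges. When
the face moves, "where" must be defined relative to the face: gazecourse
implements the full analysis pipeline from raw 120 Hz gaze samples to a
familywise-corrected statement of when looking to the **lower half of the
face** differed from chance, with dynamic areas of interest (AOIs) that
move with the stimulus.

It is written for developmental and vision researchers who have
sample-level eye-tracker exports (or want to prototype an analysis before
collecting data — the package ships a synthetic-session generator with
known ground truth).

## What it computes

1. **Fixations** via the classic dispersion-threshold (I-DT) filter: a
   fixation is a maximal window of consecutive valid samples with
   duration ≥ 80 ms and dispersion
   `(max x − min x) + (max y − min y)` ≤ 100 px.
2. **Dynamic AOI labels**: each sample and fixation is assigned to the
   upper or lower face half using the AOI rectangles *at that sample's
   timestamp*, so the same screen point can flip halves as the face
   moves.
3. **Trial inclusion**: trials with less than 1000 ms of summed fixation
   time are dropped.
4. **Dependent variables**: per-trial looking totals by AOI, pooled
   per-condition preference proportions, a long per-fixation table for
   mixed-model analyses, and caregiver-experience classifications
   (maternal race; diversity of face experience; language exposure).
5. **Binned time courses**: per 250 ms bin (30 samples), the proportion
   of in-AOI samples in the lower half — e.g. 12 lower and 18 upper
   samples give 0.40 — averaged trial → subject → group so each subject
   counts equally.
6. **A one-sample cluster-mass permutation test** against chance (0.50):
   per-bin uncorrected t tests, clusters of consecutive same-signed
   significant bins with mass `sum(t)`, and a max-cluster-mass null from
   1000 per-subject sign flips of the deviation from chance. A cluster is
   significant when its |mass| exceeds the value that 95% of the null
   masses lie below; p-values are the proportion of null masses at least
   as large (printed `0.000` when none is).

## Worked example

Simulate a 30-infant cohort at the acquisition design (8 × 7500 ms trials
at 120 Hz, four stimulus types) with a known +0.2 lower-half bias planted
in the 2000–4000 ms window, then run the whole pipeline:

```r
library(gazecourse)

cfg <- run_config(
  sim  = inject_bias(sim_config(n_subjects = 30, seed = 1),
                     window = c(2000, 4000), magnitude = 0.2),
  perm = perm_config(n_permutations = 1000, seed = 2)
)
res <- run_pipeline(cfg)

res$log
#>   stage               n
#> 1 samples        216000
#> 2 fixations        7051
#> 3 trials_total      240
#> 4 trials_kept       240
#> 5 trials_dropped      0
#> 6 subjects           30

tidy(res$test_all)
#>   cluster_index sum_t onset_ms offset_ms p_value significant
#> 1             1 -2.16        0       250   0.612 FALSE
#> 2             2  7.42     1250      1750   0.053 FALSE
#> 3             3 57.0      2000      4250   0     TRUE
#> 4             4 -2.78     6250      6500   0.329 FALSE
```

All 240 trials clear the 1000 ms inclusion rule. The test finds one
significant cluster, mass 57.0 spanning 2000–4250 ms: the planted bias
window, recovered with a one-bin spillover because fixations that start
inside the window extend past its edge. The two small clusters elsewhere
stay below the permutation threshold (7.53 here, `glance(res$test_all)`),
which is the point of the max-mass correction. A figure in the style of
the field's time-course plots (mean with CI ribbon, chance line,
significance segments beneath, one panel per condition):

```r
plot_timecourse(res$group_tc_cond, res$cluster_report)
```

Setting `out_dir` in `run_config()` additionally writes the fixation,
trial-DV, condition-preference, time-course, cluster-report, and
null-distribution CSVs plus a JSON manifest that reproduces the run.
`run_config(samples_csv = ..., aoi_csv = ...)` runs the same pipeline on
your own exported data; schemas are documented in `?simulate_session` and
`?write_session`.

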