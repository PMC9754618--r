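# scanpath3d

Tools for analysing mobile eye-tracking data from viewers of free-standing
sculpture. A sculpture has no single canonical view: fixations recorded while
a visitor walks around it are mapped onto **eight reference images** (one per
45° step), and every analysis in this package respects that multi-perspective
structure. The package is aimed at researchers comparing **visual expertise**
— how laypersons, novices, semi-experts and professional sculptors look at
three-dimensional artwork — but the machinery applies to any fixation data
mapped onto a set of reference images.

## What it computes

**Global/local viewing.** Fixations are labelled *local* (focal, detailed
inspection) when their duration exceeds a threshold (default 187 ms, or a
cohort mean recomputed from the data), else *global* (ambient exploration).
Per participant: the global/local count ratio and the switching rate in
switches per second of inspection time.

**Scanpath similarity.** The distance between two participants' scanpaths is
a double-mapping nearest-neighbour distance in three dimensions — x, y (px)
and fixation duration rescaled to px so the longest fixation on a sculpture
spans its silhouette height:

    d(S, T) = [ Σ_{p∈S} min_{q∈T} ‖p − q‖ + Σ_{q∈T} min_{p∈S} ‖p − q‖ ] / max(|S|, |T|)

computed per reference image on which both participants fixated, then
averaged. Pairwise distances are summarised by the **divergence of expertise
levels** (|level_i − level_j| ∈ 0..3), the natural grouping for a measure
defined between participants.

**Basic-feature metrics.** Expert-defined polygonal areas of interest keep
one identity across all perspectives. Per participant: distinct features
fixated, percentage of fixations on features, and revisits per minute, where
a revisit requires leaving the feature (at least one fixation outside it)
and returning.

**Synthetic cohorts.** `generate_cohort()` produces fixation tables with the
full study structure (4 expertise groups × 5 participants × 2 sculptures × 8
perspectives) from a two-state Markov global/local process with lognormal
durations, feature attraction and revisit bias — with closed-form expected
metrics (`expected_metrics()`) so the whole analysis chain can be validated
by parameter recovery.

## Worked example

```r
library(scanpath3d)

co <- generate_cohort(cohort_config(seed = 42))   # synthetic museum cohort
profiles <- expertise_profiles(co$meta)

gl <- global_local_metrics(co$fixations)          # threshold 187 ms
moses <- gl[gl$sculpture_id == "moses", ]
group_summary(moses, profiles, "gl_ratio")
#>         level  n mean    sd degenerate
#> 1   layperson  5 1.81 0.288      FALSE
#> 2      novice  5 2.27 0.475      FALSE
#> 3 semi_expert  5 2.65 0.830      FALSE
#> 4      expert  5 2.20 0.590      FALSE
#> 5       Total 20 2.23 0.613      FALSE
```

Each row is the mean ± SD of the per-participant global/local ratio in one
expertise group (about two global fixations per local one); with equal group
sizes the Total mean is the mean of the four group means.

```r
fac <- conversion_factor(co$fixations, "moses", height_px = 900)
fac
#> <conversion_factor> moses: 0.9142 px/ms (computed)

dm <- pairwise_distances(co$fixations, profiles, "moses", fac)
divergence_summary(dm)
#>   divergence  n  mean    sd degenerate
#> 1          0 40 163.8 7.138      FALSE
#> 2          1 75 169.8 8.065      FALSE
#> 3          2 50 182.7 6.883      FALSE
#> 4          3 25 210.6 9.917      FALSE
```

The 0.9142 px/ms factor maps the longest fixation on this sculpture to its
900 px silhouette height. The 190 pairwise distances pool into the four
divergence groups (40/75/50/25 pairs); the mean distance rises from 164 px
between equally experienced participants to 211 px between laypersons and
experts — scanpaths diverge as expertise diverges, here because the
generator separates the groups' gaze centers.

```r
am <- aoi_metrics(co$fixations, co$aois)
head(am[am$sculpture_id == "moses",
        c("participant_id", "n_features_fixated", "pct_on_features",
          "revisits_per_min")], 4)
#>   participant_id n_features_fixated pct_on_features revisits_per_min
#> 2         exp_01                 11            13.4             24.2
#> 4         exp_02                 11            17.4             36.0
#> 6         exp_03                 10            13.9             29.2
#> 8         exp_04                  9            13.7             30.0
```

`run_pipeline(list(simulate = TRUE, seed = 42), "results/")` runs all of the
above end to end and writes `globallocal.csv`, `switching.csv`, one
`distances_<sculpture>.csv` per sculpture, `divergence_summary.csv`,
`aoi_metrics.csv` and a `manifest.json` recording the configuration hash,
conversion factors and every warning. A thin CLI lives in
`inst/scripts/scanpath3d.R`.

## Documentation

The methods vignette (`vignettes/sculpture-scanpath-analysis.Rmd`) describes
the model, every tunable parameter with units and defaults, the generator's
assumptions and what passing validation does and does not show about real
data.
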