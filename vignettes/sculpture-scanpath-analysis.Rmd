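---
title: "Comparing sculpture-viewing scanpaths across expertise levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing sculpture-viewing scanpaths across expertise levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanpath3d)
```

## The analysis problem

Mobile eye tracking in a museum produces, after manual mapping of the gaze
video, a table of fixations: for each participant and sculpture, an ordered
sequence of positions on one of eight reference images (photographs of the
sculpture at 45° steps), with onset and duration in milliseconds. The
questions this package answers about such data are comparative: do viewers
with different amounts of sculpting experience (laypersons, novices,
semi-experts, experts — more than 10 years of professional practice) differ
in how globally or locally they look, how often they switch between those
modes, how similar their scanpaths are to each other, and how they use
expert-defined *basic features* (areas of interest) of the sculpture?

## Expertise levels and divergence groups

`classify_expertise()` maps years of sculpting experience onto four ordered
levels: 0 years → layperson, under 5 → novice, 5–10 inclusive → semi-expert,
over 10 → expert. The published thresholds leave exactly 5 and exactly 10
years unassigned ("<5" and ">5<10"); we assign both boundaries to
semi-expert, since the observed semi-expert range (6–9 years) sits inside it
and the expert criterion is stated as *more than* 10 years. Both cut points
are arguments, so a different convention is one call away.

Scanpath distances are defined between participants, not per participant, so
group comparisons pool the `choose(n, 2)` unordered pairs by the *divergence*
of the two expertise levels, `|level_i - level_j|` (0–3). With four groups of
five this yields 40/75/50/25 pairs at divergence 0/1/2/3:

```{r}
profiles <- expertise_profiles(data.frame(
  participant_id = sprintf("p%02d", 1:20),
  years_experience = c(rep(0, 5), 1:5 - 0.5, seq(5, 10, length.out = 5),
                       c(14, 15, 24, 25, 29))))
divergence_groups(profiles)$counts
```

## Global/local classification

A fixation is *local* (focal — detailed inspection) when its duration
strictly exceeds a threshold, otherwise *global* (ambient — broad
exploration). The default threshold of 187 ms is a cohort mean fixation
duration; `threshold_ms = "cohort_mean"` recomputes it from the data at
hand, which is how such a threshold is obtained in the first place. The
boundary case (duration exactly equal to the threshold) is global, reading
"longer than" strictly; this too is configurable.

Per participant and sculpture, `global_local_metrics()` reports the
global/local count ratio and the switching rate: the number of transitions
between differing consecutive labels divided by the inspection time in
seconds. Inspection time defaults to the span from the onset of the first
fixation to the end of the last; summed fixation durations are available via
`inspection = "sum"` for recordings with long tracking gaps. A participant
with no local fixation has an undefined ratio; the value is flagged `NA`,
excluded from group means, and counted in the pipeline manifest rather than
silently dropped.

Group summaries use the sample standard deviation (n−1). With equal group
sizes the cohort "Total" mean equals the unweighted mean of the four group
means — an identity the test suite exercises, because it links the
per-level rows of a published summary table to its printed total.

## The double-mapping scanpath distance

The similarity of two scanpaths S and T is measured in three dimensions per
fixation: x, y (px on the reference image), and the duration mapped to px.
For each fixation of S the nearest fixation of T is found (plain Euclidean
distance in the 3-D space), and vice versa; the two directed sums are added
and divided by `max(|S|, |T|)`:

d(S, T) = [ Σ_{p∈S} min_{q∈T} ‖p − q‖ + Σ_{q∈T} min_{p∈S} ‖p − q‖ ] / max(|S|, |T|)

Double mapping lets both scanpaths contribute all their fixations even when
their lengths differ, and the normalisation makes the value a mean mapped
distance in px. Nearest-neighbour search is exact (full enumeration over the
at most a few hundred fixations per image); ties between equidistant targets
go to the lower ordinal, which cannot change the value but keeps mapping
traces deterministic.

The duration axis needs a scale. The convention implemented: the longest
fixation observed on a sculpture corresponds to the sculpture's silhouette
height in px, so the conversion factor is `height_px / max(duration_ms)`,
computed cohort-wide per sculpture (one factor per sculpture, matching how
such factors are published). `conversion_factor(..., value =)` accepts a
configured override, e.g. a published factor such as 1.097 px/ms. Two
algebraic consequences are tested: multiplying all durations by c while
dividing the factor by c leaves every distance unchanged, and a rigid
translation of one scanpath by a small δ shifts the distance by exactly 2δ.

Because fixations live on eight reference images, `scanpath_distance()`
computes the double-mapping distance per reference image and averages. A
reference image on which only one of the two participants fixated
contributes no distance and is skipped (the count of skipped images is
recorded); imputing a penalty instead would make the mean depend on an
arbitrary constant rather than on computed distances. If two participants
share no reference image at all, the pair is undefined: flagged `NA`,
reported as a missing cell, never imputed.

`pairwise_distances()` assembles the symmetric participant matrix (zero
diagonal — the self-comparison "valley" — excluded from all summaries), and
`divergence_summary()` pools the off-diagonal cells by expertise divergence.
Pooling raw pairwise distances and pair-count-weighting the level-pair cell
means are identical when group sizes are equal; the package pools raw
distances and exposes `pool_divergence_means()` for the cell-mean route.

## Basic-feature (AOI) metrics

Basic features are simple polygons per reference image, with one
`feature_id` shared by all views of the same physical feature (cross-view
identity is input, as it is produced by manual expert mapping).
`hit_test()` assigns each fixation the feature whose polygon on that
fixation's reference image contains it; the boundary is inclusive, and
overlaps resolve to the smallest area, then lexicographic id — so a small
detail nested in a larger region wins. Point-in-polygon uses the even-odd
rule with an explicit boundary test, valid for any simple polygon; polygon
simplicity (no self-intersection) is enforced when an AOI set is built.

Three metrics follow: the number of distinct features fixated, the
percentage of fixations on features, and revisits per minute. A *revisit*
requires leaving and returning: a feature was fixated, at least one fixation
landed outside it (anywhere outside — including inside another feature), and
a later fixation landed inside it again. Continuous dwelling counts once.
Equivalently, revisits per feature = (number of maximal runs of that
feature) − 1; the implementation is an explicit state machine and the test
suite checks it against the run-counting formulation on every hit sequence
of length ≤ 6 over two features. Revisits are summed across features and
divided by the inspection time in minutes, per sculpture.

## The synthetic cohort generator

No public recording of the original museum data exists, so validation runs
on synthetic cohorts whose structure mirrors the study design: four
expertise groups × five participants, two sculptures, eight reference
images. Per participant and sculpture the generator draws:

* fixation count ~ Poisson(`n_fix`), minimum 2;
* a global/local *mode* sequence from a two-state chain: stay with
  probability `switch_persistence`, otherwise redraw Bernoulli(`p_local`).
  This parameterisation keeps the stationary local share exactly `p_local`
  at any persistence, so the two dials are orthogonal;
* durations from the mode's lognormal (right-skewed, the standard shape for
  fixation durations), parameterised by median and log-SD;
* a reference image uniformly per fixation;
* a position: with probability `aoi_attraction` uniform inside a (biased
  towards previously visited, probability `revisit_bias`) basic feature,
  otherwise Gaussian around the group's gaze center with SD
  `spatial_jitter_px`. Group centers are offset per expertise level, which
  is what makes scanpath distance grow with expertise divergence;
* onsets accumulated as duration plus a fixed inter-fixation gap.

Defaults were chosen once to land on the magnitudes published for this kind
of cohort and then frozen: `p_local` 0.32, global durations lognormal
(median 110 ms, σ 0.3), local (350 ms, σ 0.3), persistence 0.75, gap 30 ms,
`n_fix` 300 (≈ 1 minute of inspection at ≈ 4.4 fixations/s), jitter 120 px,
`aoi_attraction` 0.08 and 12/20 features of ≈ 65 px (giving ≈ 10–15% of
fixations on features and ≈ 10–13 distinct features fixated), group center
offsets (50, 30) px per level. Sculpture silhouette heights (900 px Moses,
1100 px Daphne on 800 × 1200 px images) are synthetic stand-ins: no
published pixel heights exist.

`expected_metrics()` gives closed forms for what the analysis should
recover: the probability that a fixation is *labelled* local is
`p_local · P(dur_local > t) + (1 − p_local) · P(dur_global > t)` (the two
tail terms are the threshold leakage of the lognormals), the expected
global/local ratio is the corresponding odds, and the expected switching
rate combines the exact label-transition probability of the mode chain with
the mean per-fixation pitch. Parameter-recovery tests compare these against
*pooled* group counts (summed globals over summed locals, total switches
over total inspection time) rather than means of per-participant ratios:
the pooled estimator is consistent for the implied odds, whereas a mean of
ratios carries a Jensen bias of order Var(n_local)/E[n_local]² that is not
part of the closed form.

What the generator deliberately does not emulate: tracker noise and data
loss, saccade dynamics (30 Hz mobile tracking makes saccade measures
unusable anyway, which is why classification is by duration only),
perspective-dependent feature visibility (every feature is visible on every
reference image), and any systematic duration differences between expertise
groups. Passing recovery tests therefore show that the analysis measures
what the model puts in — not that real museum data satisfy the model.

## Numerical and degenerate-input choices

* Squared distances are accumulated per dimension
  (`outer(x_S, x_T, "-")^2 + …`), so self-distances are exactly zero and
  brute-force oracle agreement holds to 1e-9 relative.
* Printed tables round half *up* (5306.5 → 5307) to 2 decimals for ratios
  and rates, integers for distances, via `round_half_up()`; base R's
  half-to-even would print some published cells differently.
* Empty scanpaths, all-global participants, single-member groups, empty
  divergence groups and AOI-less reference images all produce flagged
  values or warnings, never silent drops; the pipeline manifest counts
  every warning so runs can be audited.
* Validation is front-loaded: a fixation table that reaches the analysis
  stage has positive durations, reference images in 1..8, consecutive
  ordinals and non-decreasing onsets per participant and sculpture.

## Problem sizes used in the validation suite

The test suite runs brute-force oracle comparisons up to 50 fixations per
path, point-in-polygon oracle agreement on 1,000 random points per polygon,
complete revisit enumeration over all 1,092 short hit sequences, parameter
recovery on 4 × 20 participants at `n_fix` 200, and offset-monotonicity on
4 × 5 participants at `n_fix` 60 — sizes at which the reference
computations are exact or their Monte Carlo error is far below the test
tolerances, while the whole suite stays fast enough to run routinely.

## Limitations

The package analyses fixations already mapped to reference images; it does
not detect fixations from raw gaze samples, parse proprietary tracker
exports, or map between perspectives automatically. Distances are not
computed across sculptures, and no inferential statistics are attached to
the descriptive summaries: with cohorts of this size, estimation and
description are what the data support.
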