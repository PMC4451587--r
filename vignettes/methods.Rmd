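---
title: "Methods: constraint-based IADL recognition, autonomy staging, and the synthetic scene"
author: "ecoadl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ecoadl` reconstructs a video-based autonomy assessment pipeline for older
adults across the healthy / mild-cognitive-impairment / Alzheimer's
spectrum. The original study population (49 participants: 14 HC, 23 MCI,
12 AD) performed two directed walking tasks and a 15-minute semi-guided
IADL scenario in an observation room; a monitoring system recognized the
activities and extracted gait features, from which autonomy was staged and
classified. The recordings themselves are not available, so this package
pairs the analysis pipeline with a calibrated scene simulator that plays
the role of the missing sensor data. This vignette explains the models,
the tunable parameters, what the simulator does and does not emulate, and
the design decisions taken where the published description is silent.

## 1. Event recognition model

The recognizer operates on a *track stream*: per-frame timestamps, the
person's floor-plane centroid (meters), a categorical posture
(`standing`, `sitting`, `bending`) and optional foot positions, at a
nominal frame rate (default 10 Hz).

Two layers:

* **Primitive states** are per-frame predicates: `Person_in_zone_<Z>`
  (centroid inside the polygon of contextual zone `Z`) and
  `Person_<posture>`. Maximal runs become intervals.
* **Composite events** name components (primitive states or other models,
  nested up to depth 4 with cycle detection) and impose constraints:
  `overlap` — all listed components active at the same instant — and
  `min_duration_before(c, d)` — component `c` continuously active for at
  least `d` seconds at the evaluated instant. The event is recognized on
  every maximal span where all constraints hold: recognition *starts* at
  the first instant the conjunction is satisfied (e.g. 2 s after entering
  the zone) and *ends* when any constraint ceases.

Numerical choices:

* Intervals are half-open `[t_start, t_end)` seconds; each frame covers
  `[t, t + 1/rate)`. Constraints are evaluated on the discrete frame grid.
  This makes recognition exactly reproducible by an instant-wise
  brute-force scan, which the test suite uses as an independent oracle.
* `gap_merge_s = 0.5` s: two same-state runs separated by less than this
  are merged. Tracking dropout shorter than half a second is a sensor
  artifact, not a real state exit. The value is a package decision; the
  source system's dropout handling is unpublished.
* Point-in-polygon uses the even-odd rule with boundary points counted as
  inside (a deterministic tie-break).

The shipped model library defines one model per protocol activity —
zone occupancy + activity posture + a 2 s minimum prior zone duration,
the pattern of the published drink-preparation example — over a default
6 m × 5 m scene with one zone per activity and a 4 m walking corridor.
Only that one example model and a scene snapshot were published; the
library is a faithful reconstruction in the same formalism, not a copy.
Because the two walking tasks use the same corridor, they are identical to
a zone + posture recognizer; recognized corridor walks are relabeled by
protocol order (first = single task, second = dual task) in
`label_walk_tasks()`. Answering vs. calling on the phone is likewise a
schedule attribute, not a recognizer distinction — one `using_phone`
model covers both.

**Detection evaluation** matches recognized to ground-truth intervals
one-to-one, greedily by decreasing overlap; a match requires overlap of at
least a threshold fraction (default 0.5) of the *truth* interval's length.
Precision = TP/(TP+FP), recall = TP/(TP+FN); recall is undefined (absent)
for models with no truth intervals.

## 2. Gait analysis

Steps are local maxima of the inter-feet Euclidean distance exceeding
`min_step_separation_m = 0.15` m, with retained peaks at least
`min_step_interval_s = 0.3` s apart (larger peak wins). When foot data are
missing in more than 20% of frames the function refuses and points to the
centroid-speed fallback (`method = "centroid"`, local minima of centroid
speed).

Derived parameters, per task: total duration (the analyzed slice is the
recognized walking interval rewound by the 2 s recognition latency, so it
covers the full corridor occupancy); cadence = steps / duration; step
lengths = centroid displacement between consecutive step instants; stride
length = 2 × mean step length (a stride is two consecutive steps);
distance traveled = summed centroid path over present frames; average
speed = distance / duration; gap duration = within-task time without a
person detection. Three interpretations are package decisions because the
source never defines them: *gap duration* as tracking-dropout time, and
the *SD / max / min "steps"* features as statistics over per-step lengths
(a per-task step count admits no max/min; step length does).

## 3. Behavioral profile and autonomy staging

The protocol expects 13 activity units inside the 15-minute window. The
published material gives the total (13) but never the decomposition; the
package counts finance (balance + check), phone (answer + call), drink
preparation, reading (article + questions) and medication preparation as
two units each, and plant watering, TV and bus-line search as one each.
Bus-line search appears in the published detection-performance table
although not in the protocol table, so it is included. The walking tasks
are protocol stages, not counted units — if they were, a "poor" mean of
1.54 completed units would be impossible since every participant walks.

Per model: frequency (recognized intervals, clipped to the window),
duration (summed lengths), `repetitions = max(0, frequency − expected)`,
`omissions = max(0, expected − frequency)`. A *unit* is one expected
occurrence; `activities_initiated = Σ min(frequency, expected)` and a unit
is *completed* when its interval also lasts at least the model's minimum
completion duration (default 10 s; 5 s for phone). The completion
duration stands in for the clinician's quality verification, which the
study describes but does not formalize. Unit-level (rather than
model-level) counting is the only reading under which the maximum of 13
completed activities is reachable.

Staging: completed ≥ 8 → good, 4–7 → intermediate, ≤ 3 → poor.

## 4. Classification

Gaussian naïve Bayes: class priors are empirical frequencies; per class
and feature, mean and *population* variance (denominator n), floored at
`1e-9 ×` the squared pooled feature scale so constant features keep
finite likelihoods. Posteriors are computed in log space and normalized
by log-sum-exp; ties go to the first declared class.

Cross-validation uses stratified folds (seeded within-class shuffle,
round-robin deal; default k = 20). Stratification is a package decision:
with 49 rows and 20 folds, unstratified splits of size 2–3 frequently
lose a class from a training split. When that still happens the fold is
predicted from the remaining classes and the condition is logged in the
report. The original fold assignment and seed are unrecoverable, so exact
reproduction of the published confusion counts is impossible by
construction; the acceptance analogs instead require the implementation
to reach the printed accuracies on simulated cohorts with stated
separations.

Feature selection is forward best-first: the open list holds frontier
subsets ordered by CV accuracy, each expansion grows the best open node by
one feature, and the search stops after 5 consecutive non-improving
expansions. Ties prefer smaller subsets, then lexicographic order. The two
published task-specific feature lists (7 features for autonomy, 6 for
diagnosis) ship as `default_feature_set()`; selection can also be re-run
from the full profile. Only the Gaussian variant is implemented — the
simplest reading of the source's classifier choice.

## 5. Statistics

`mann_whitney()` computes U from rank sums with midranks. For
`min(n_a, n_b) ≤ 8` without ties the two-sided p comes from full
enumeration of all C(n, n_a) group assignments (doubling the smaller
tail, capped at 1); otherwise from the normal approximation with
tie-corrected variance and a 0.5 continuity correction. Whether the
original analysis used a continuity correction is unstated, so it is a
flag (`continuity`, default TRUE). `spearman_cor()` is the product-moment
correlation of midranks with the two-sided t approximation. Significance
is conventionally read at p < 0.05, without multiple-testing correction
(mirroring the source's reporting); a Holm option exists but is off by
default.

## 6. The synthetic scene: a stated world

The simulator's defaults *are* the published cohort statistics:

* Joint composition: good = 13 HC + 9 MCI, intermediate = 1 HC + 10 MCI +
  5 AD, poor = 4 MCI + 7 AD (49 participants; 22/16/11 by autonomy,
  14/23/12 by diagnosis).
* Completed-activity counts per autonomy class: 10.04 ± 1.4 / 5.5 ± 1.2 /
  1.54 ± 1.4, drawn Gaussian then rounded and clipped to [0, 13]
  (draw → round → clip, applied identically everywhere; the raw draw is
  kept for calibration checks).
* Walk durations per diagnosis: single 10.79 ± 1.31 / 11.43 ± 2.97 /
  14.36 ± 3.83 s, dual 14.79 ± 4.26 / 18.35 ± 8.78 / 23.25 ± 8.65 s,
  dual resampled until ≥ single. Ages 74.1 ± 6.6 / 77.6 ± 6.2 / 82.0 ± 8.
* The initiated-minus-completed surplus is only published per diagnosis
  group (≈1.6 / 2.8 / 2.9); the per-autonomy defaults interpolate those
  values and are flagged as such.

Rendering: the person moves between zone staging points and centroids
along straight paths at 1 m/s; each scheduled unit dwells at the zone
centroid in the activity's posture — uniform 18–35 s for completed units,
uniform 4.2–5.4 s for initiated-but-not-completed units, long enough to
be recognized (> 2 s in zone) but short of the completion duration.
Walks traverse the corridor with scripted foot oscillation whose
inter-feet-distance peaks mark the steps (≈1 step/s). Noise is layered
on top: per-frame dropout probability and Gaussian position jitter.
Ground-truth intervals are computed from the scripted noiseless
trajectory with the recognizer's interval semantics (including the 2 s
latency), so on a noiseless render recognized events equal ground truth
*exactly* — the closed-loop acceptance criterion.

What a green closed-loop test does **not** establish: the simulator uses
piecewise-linear motion, hard posture labels, independent per-feature
Gaussians (no covariances are published), and noise that is white in time
and space. Real tracker output has correlated dropout, identity switches,
posture misclassification and occlusion structure; detection performance
under the simulator's mild noise is an upper bound, not a forecast of the
published field accuracies.

## 7. Known limitations

* The activity-unit decomposition, zone geometry, and model library are
  reconstructions constrained by the published total (13), zone names and
  the one published model; other reconstructions are possible.
* Profile-level simulation draws features independently; correlations
  between gait and IADL features are not emulated.
* Recognition is offline and single-person, matching the protocol (one
  participant alone in the room); streaming and multi-person scenes are
  out of scope.
* Exact replication of the published confusion tables is impossible
  without the original data; the package's accuracy claims are about its
  own stated simulation world.
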