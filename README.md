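# ecoadl

Ecological assessment of autonomy in instrumental activities of daily
living (IADL), reconstructed as an R package.

## The problem

Clinical autonomy scales for dementia patients (questionnaires, informant
reports) are coarse and observer-biased. An alternative is to record a
standardized protocol in an observation room — two directed walking tasks
(walking alone, and walking while counting backwards), then a 15-minute
semi-guided phase with a list of IADL such as preparing a pillbox, making a
phone call or watering a plant — and to score the performance from a
tracked-person stream produced by a video monitoring system. `ecoadl`
implements everything downstream of the person tracker:

* **Event recognition** (`detect_primitive_states()`,
  `recognize_composite_events()`): primitive states are per-frame predicates
  (`Person_in_zone_Z` from point-in-polygon tests against contextual scene
  zones, `Person_<posture>` from posture labels); composite activity models
  combine named components under temporal constraints — `overlap` (all
  components active at the same instant) and `min_duration_before`
  (a component continuously active for at least *d* seconds). An event is
  recognized on every maximal span where all constraints hold. Intervals are
  half-open `[t_start, t_end)`; evaluation is on the discrete frame grid.
* **Gait analysis** (`detect_steps()`, `compute_gait_parameters()`): steps at
  local maxima of the inter-feet distance; cadence = steps / duration,
  stride = 2 × mean step length, average speed from the centroid path.
* **Behavioral profile** (`build_profile()`): per activity, frequency,
  duration, omissions and repetitions against the protocol's expected
  counts; aggregate counts of initiated and completed units; gait features.
* **Autonomy staging** (`stage_autonomy()`): completed units ≥ 8 → good,
  4–7 → intermediate, ≤ 3 → poor.
* **Classification** (`fit_naive_bayes()`, `cross_validate()`,
  `select_features_best_first()`): Gaussian naïve Bayes
  (posterior ∝ prior × Π per-feature Gaussian density, in log space),
  stratified 20-fold cross-validation, forward best-first wrapper feature
  selection scored by CV accuracy.
* **Statistics** (`mann_whitney()`, `spearman_cor()` and batch tables):
  Mann–Whitney U with midranks, tie-corrected normal approximation and
  exact enumeration for small tie-free samples; Spearman rank correlation.
* **Synthetic scene simulator** (`simulate_cohort()`,
  `generate_schedule()`, `render_track_stream()`): the stand-in for the
  original (unavailable) clinic recordings — class-calibrated schedules
  rendered into noisy track streams with exact ground-truth event intervals.

## Worked example

```r
library(ecoadl)

cfg    <- cohort_config(seed = 7)          # 49 participants, noiseless
cohort <- simulate_cohort(cfg)

p  <- cohort$participants[[1]]
ev <- recognize_stream(p$stream, cfg$zones, cfg$models)
g  <- gait_from_events(p$stream, ev)
pr <- build_profile(ev, g, cfg$proto, age = p$schedule$age,
                    window_start = p$window_start,
                    participant_id = p$participant_id)
pr
#> <profile p01: age 63, initiated 12, completed 11 (good autonomy)>
g$mono
#> <gait mono: 10.9 s, 11 steps, cadence 1.01 /s, speed 0.37 m/s, gap 0.0 s>
```

The profile says participant `p01` started 12 of the 13 expected activity
units, finished 11 of them (≥ 8 completed stages the participant as a
"good" performer), and walked the single task at 0.37 m/s with 11 steps.
On a noiseless render the recognizer reproduces the simulator's ground
truth exactly, so `evaluate_detection(ev, p$truth)` reports precision and
recall 1.0 for every model.

The full pipeline (simulate → recognize → gait → profile → classify →
evaluate → stats, with a hash manifest) is one call —
`run_full_pipeline("out_dir", cfg)` — or, from a shell,
`Rscript inst/cli/ecoadl.R run-all --out out_dir --seed 7`.

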