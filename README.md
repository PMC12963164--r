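# drapewatch

Detecting the start of surgical **draping** from operating-room surveillance
video, and the interval statistics that make draping a useful trigger for
anticipatory (automated) anesthesia.

## Why

Closed-loop anesthesia systems still need a human to switch modes before the
skin incision, and the switch must happen minutes in advance for drug
effect-site concentrations to be ready. Among the preparatory actions of OR
staff visible to a ceiling surveillance camera — surgeons returning from
hand washing, sterilization, shadowless-lamp activation, bed-cradle set-up,
draping — the start of draping has the shortest and least variable interval
to incision (median ≈ 7.7 min), and it always follows hand washing and
sterilization in the workflow. Detecting draping therefore predicts the
start of surgery far enough ahead to act on.

## What the package does

A three-stage color-based detector, run per case by `run_case()`:

1. **Bed detection** — the operating bed is localized one minute before
   patient entry through a pluggable detector interface, retrying one minute
   earlier (five frames per attempt) until the video start; the winning
   bounding box is expanded 1.2-fold in area (`expand_box()`) to absorb bed
   movement.
2. **Color features** — after entry, the mean color of all ROI pixels is
   sampled every 30 frames (≈1 Hz), together with the custom *cyan-like
   value* `(G + B)/2 − R` (large for blue-green drapes, zero for gray), all
   normalized by subtracting an entry baseline.
3. **Classification + confirmation** — an RBF-kernel SVM labels each sample
   *before*/*after* draping; the event is confirmed after **10 consecutive
   positive seconds** (`confirm_draping()`), which suppresses premature
   triggers from isolated misclassifications.

Because hospital footage cannot be shipped, the package includes a
deterministic synthetic scene generator (`generate_scene()`) — static bed,
patient entry, linear drape-coverage ramp, staff occlusions, transparent
drapes and blocked-bed failure modes, pixel noise, variable frame rate — and
a cohort generator (`generate_cohort()`) reproducing the action-to-incision
interval distributions. The evaluation harness (`score_detections()`,
`error_histogram()`) and the interval statistics (`summarize_intervals()`,
`signed_rank_vs_draping()` — exact tie-aware Wilcoxon signed-rank with
Bonferroni ×4, `subgroup_summaries()`) complete the analysis.

## Worked example

Train a classifier on a few synthetic cases, then run an unseen scene whose
ground-truth draping onset is 240 s:

```r
library(drapewatch)

## training scenes -> normalized features + onsets
feats <- list(); onsets <- numeric(0)
for (s in 1:4) {
  cfg <- random_scene_config(100 + s, duration = 240, entry_time = 60,
                             noise_sd = 8, drape_ramp = 15)
  sc  <- generate_scene(cfg)
  box <- expand_box(detect_bed(sc$video, cfg$entry_time,
                               color_region_detector(cfg$pre_drape_color)),
                    1.2, c(sc$video$width, sc$video$height))
  feats[[s]] <- normalize_to_entry(extract_color_features(sc$video, box, cfg$entry_time))
  onsets <- c(onsets, cfg$drape_onset - cfg$entry_time)
}
model <- train_drape_classifier(assemble_training_set(feats, onsets, seed = 1))
model
#> <drape_classifier: RBF SVM (e1071 1.7.16), cost=1 gamma=7.42651e-05, trained on 223 before / 223 after>

## an unseen case: draping truly starts at 240 s, ramp 10 s
sc  <- generate_scene(scene_config(duration = 330, entry_time = 60,
                                   drape_onset = 240, drape_ramp = 10,
                                   noise_sd = 8, seed = 42))
det <- run_case(sc, model)
det
#> <draping_detection case_001: detected, onset 184.0 s after entry (video clock 244.0 s), confirmed 193.0 s>

score_detections(list(det), sc$annotation)
#> Detection: 1/1 cases (100.0%)
#> Timing error (s): median 4.0 (IQR 4.0-4.0), mean 4.0, sd 0.0
#>   within_120s: 100.0%
```

The detector fires 4 s after the annotated onset — partway up the 10 s
coverage ramp, once enough of the bed is blue for the classifier to flip.

Interval analysis on a synthetic 110-case cohort:

```r
coh <- generate_cohort(cohort_config(n_cases = 110, seed = 9))
compare_actions(compute_intervals(coh))
#>      action   n median    q1   q3  mean   sd sd_degenerate p_adjusted
#> 1  handwash 110  10.16  8.44 12.7 10.95 3.56         FALSE   3.55e-19
#> 2 sterilize 110  13.90 10.87 16.8 14.53 5.16         FALSE   3.55e-19
#> 3      lamp 110  12.57 10.29 16.4 14.31 6.07         FALSE   3.55e-19
#> 4    cradle 110  14.33 11.26 18.5 15.96 6.78         FALSE   3.55e-19
#> 5   draping 110   7.43  6.03  9.1  7.97 3.03         FALSE         NA
```

Draping has the smallest median interval to incision (≈7.4 min here), and
every other action differs from it significantly (Bonferroni-adjusted
paired signed-rank p ≪ 0.05).

Plot helpers: `plot_color_trace()` (R/G/B traces with the red value dropping
below green and blue at draping), `plot_error_histogram()`,
`plot_interval_boxplot()`.

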