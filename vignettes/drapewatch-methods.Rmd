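---
title: "Detecting surgical draping from operating-room surveillance video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting surgical draping from operating-room surveillance video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drapewatch)
```

## The problem

Automated (closed-loop) anesthesia systems need to switch modes a few
minutes *before* surgery begins — for example to raise analgesic effect-site
concentrations in time for the skin incision. The incision itself is too
late a trigger. Among the preparatory actions of operating-room staff that a
ceiling surveillance camera can see, the start of **draping** — covering the
patient with sterile, characteristically blue cloths — is the most useful
predictor: it always follows hand washing and sterilization in the surgical
workflow, and its interval to the skin incision is the shortest and least
variable of the candidate actions (median about 7.7 minutes).

`drapewatch` implements a full draping detector for such footage plus the
interval statistics that justify draping as the trigger, and — because
hospital surveillance video cannot be shipped — a synthetic scene and cohort
generator with the same statistical structure, so every stage is testable
end to end.

## The detection pipeline

Three stages, run per case by `run_case()`:

1. **Bed detection** (`detect_bed()`). The operating bed is localized one
   minute before the patient enters. If a detection attempt fails, the
   system retries one minute earlier, each attempt using five frames spaced
   one second apart, until the start of the video; exhaustion is reported as
   a `bed_detection_failed` case. The winning box is the highest-confidence
   candidate of the first epoch with any detection. The box is then
   **expanded 1.2-fold** (`expand_box()`) to absorb small bed movements. We
   read "1.2-fold" as an *area* factor (each linear dimension grows by
   `sqrt(1.2)`), since it is the box area that is described as expanded; a
   `mode = "linear"` switch is provided because the phrasing admits either
   reading. Expansion preserves the aspect ratio, is centered on the box,
   rounds outward to whole pixels (so the result always contains the input)
   and is clipped to the frame.

   The detector itself is pluggable: any function mapping a frame to
   candidate boxes with confidences. In production this slot holds a trained
   object-detection model; the built-in `color_region_detector()` is a
   color-matching stand-in adequate for synthetic scenes and is documented
   as such.

2. **Color features** (`extract_color_features()`,
   `normalize_to_entry()`). After patient entry the mean color of all ROI
   pixels is computed every 30 frames — about once per second at a nominal
   30 fps. Alongside the R, G, B means we compute the *cyan-like value*

   $$\mathrm{cyan} = \frac{G + B}{2} - R,$$

   which is large for the blue-green of sterile drapes, zero for any gray
   and negative for red-dominant sheet and skin tones. All four features are
   normalized to patient entry by subtracting the mean over a baseline
   window (default: the first 10 s after entry). Subtraction rather than
   division keeps the additive structure of the traces; a window mean rather
   than a single entry-instant sample buys noise robustness, and the window
   length is configurable because the original normalization granularity is
   not specified. Sampling is by *frame stride* (the acquisition is
   frame-wise) but timestamps are carried throughout, so under a variable
   frame rate downstream logic and evaluation still operate in seconds.
   Unreadable samples are dropped with a warning, never interpolated.

3. **Classification and confirmation** (`train_drape_classifier()`,
   `confirm_draping()`). An SVM with an RBF kernel classifies each sample as
   *before* or *after* draping on the four normalized features, with the
   SVM library's default regularization and kernel width (`e1071::svm`,
   `cost = 1`, `gamma = 1/4`); because such defaults drift across releases,
   the library version and effective parameters are stored in the model
   metadata. No further feature scaling is applied by default. Draping is
   *confirmed* when 10 consecutive samples — about ten seconds — are all
   classified "after"; any "before" sample resets the counter. This strict
   consecutiveness suppresses premature triggers from isolated
   misclassification. A gap between samples longer than twice the nominal
   spacing also resets the counter, since consecutiveness can no longer be
   vouched for; single dropped frames do not.

   The event time reported by default is the *first* sample of the
   confirming run (`onset`), with the confirmation instant also exposed;
   which timestamp the original system logged is not stated, and the first
   sample is the natural estimate of the onset itself.

Each case yields exactly one outcome: `detected` (with onset and
confirmation times), `not_detected`, or `bed_detection_failed`.

### Training-set assembly

Most of a case precedes draping, so labels are heavily imbalanced.
`assemble_training_set()` labels samples by the annotated onset, excludes a
±10 s ambiguity margin around the transition (how the original training
labels handled the transition is unknown), and downsamples the majority
class per case.

## The synthetic scene generator

`generate_scene()` renders, lazily and deterministically, a frame sequence
in which a static bed rectangle in red-dominant sheet tones is progressively
covered by a blue drape from `drape_onset` over `drape_ramp` seconds
(draping of a real patient can take over a minute; linear coverage growth is
the simplest monotone model). Optional elements:

* **transient occlusions** — left-anchored rectangles covering a stated
  fraction of the ROI for a time window, emulating staff blocking the bed;
* **transparency** — alpha-blending of the drape over the underlying color;
  `transparency = 1` reproduces the transparent-drape exclusion mode;
* **a static bed occluder** — equipment parked over the bed for the whole
  video, the other exclusion mode, which defeats bed detection;
* **pixel noise** and optional **timestamp jitter** (variable frame rate).

With zero noise the ROI mean color is a piecewise-constant-in-segments
function of time available in closed form (`scene_roi_mean()`), and the
renderer must match it exactly — the generator's core correctness invariant.
After drape completion the mean red value falls below green and blue, the
qualitative signature the detector exploits.

Default scenes are 640×360 at 30 fps with noise SD 8: large enough that
box geometry, sampling and detection are non-trivial, small enough that a
full case runs in seconds. What the generator does *not* emulate: real
illumination changes, camera auto-exposure, human pose, drape texture or
partial drapes. Passing tests therefore demonstrate the correctness of the
pipeline's mechanics and its behavior under the modeled failure modes — not
clinical performance on hospital footage.

## The synthetic cohort generator

`generate_cohort()` draws, per case, the interval from each of the five
candidate actions (hand-wash return, sterilization, shadowless lamp, bed
cradle, draping) to the skin incision from log-normal distributions whose
median equals the configured median and whose log-scale spread is set from
the configured quartiles, $\sigma = \log(q_3/q_1) / (2 z_{0.75})$. The
default parameters are the study cohort's values (draping 7.71 min, IQR
5.89–9.72, etc.), with subgroup parameter sets available via
`action_interval_defaults()`.

Two structural choices:

* **Case-level tempo correlation.** The five log-intervals of a case share a
  latent tempo factor (Gaussian copula, correlation 0.9 by default):
  preparations that run late run late across the board. Besides being
  realistic, this makes the workflow ordering — draping after both hand
  washing and sterilization — hold in ~98% of raw draws, so the whole-case
  rejection resampling that enforces it strictly is rare and perturbs the
  marginal medians by well under a percent. With independent draws the
  ordering would fail in roughly a third of cases and conditioning would
  visibly bias the marginals.
* **Exact stratum counts.** Department and robot-assistance labels are
  assigned as fixed counts (`round(n * proportion)`, randomly interleaved),
  so a configured cohort composition (e.g. 30 robot-assisted of 110) is
  reproduced exactly.

Only draping-after-handwash and draping-after-sterilization are enforced:
lamp activation and cradle set-up genuinely float around draping in real
workflows, which is exactly why they are more variable triggers.

## Interval statistics

`compute_intervals()` converts annotations to minutes;
`summarize_intervals()` reports median, quartiles, mean and SD per action;
`subgroup_summaries()` stratifies by department or robot assistance;
`signed_rank_vs_draping()` runs the paired two-sided Wilcoxon signed-rank
test of each action against draping with a fixed Bonferroni factor of 4
(four comparisons), significance at adjusted p < 0.05.

The signed-rank test is implemented in full rather than delegated, because
the reference routine (`stats::wilcox.test`) refuses exact p-values under
ties. Zero differences are discarded before ranking (Wilcoxon's original
policy; which policy the original software used is not stated), ties get
mid-ranks, and for up to 25 non-zero pairs the two-sided p comes from the
exact tie-aware null distribution — the full $2^n$ enumeration collapsed
into a generating-function convolution on doubled ranks. Above 25 pairs a
normal approximation with tie correction and continuity correction is used;
it matches `wilcox.test(exact = FALSE, correct = TRUE)` to numerical
precision, and the tests verify both branches against independent oracles.

Quartiles everywhere are type 7 (linear interpolation), the R default; the
original convention is unstated, so ours is documented for reproducibility.

## Evaluation

`score_detections()` compares detected event times with annotated onsets:
signed error in seconds (negative = early), median/IQR/mean/SD over detected
cases, detection failures counted separately in the detection rate, and the
fraction of cases within ±2 minutes by default. `error_histogram()` bins the
signed errors into right-open, origin-aligned bins whose counts sum to the
number of detected cases. Plot helpers draw the color traces, the error
histogram and the interval boxplots.

## Numerical and degenerate-input choices

* Boxes are 0-based, half-open, x rightward, y downward; expansion rounds
  outward (floor/ceil), guaranteeing containment at the cost of up to one
  pixel per edge.
* A single detected case reports SD 0 with an explicit degeneracy flag
  rather than `NA`, so summaries stay numeric.
* All-zero paired differences raise a degenerate-test error instead of
  returning a fabricated p-value.
* Negative action-to-incision intervals are excluded with a warning and
  flagged; zero intervals are kept but flagged.
* Every generator takes an explicit integer seed and restores the caller's
  RNG state; identical config + seed gives bit-identical output.

## Problem sizes used in the shipped checks

The test suite and the acceptance script train the SVM on ten noisy
synthetic scenes of 300 s (mirroring a ten-video training set), evaluate
onset recovery on 50 clean scenes with a 5 s drape ramp, exercise the
failure modes on 10 scenes each, compare the confirmation scan against a
brute-force oracle on 1000 random label streams, verify the exact
signed-rank p against full enumeration up to n = 12, and check the cohort
median round trip at n = 10,000. These sizes give stable statistics while
keeping a full run to a few minutes on one core.

## Known limitations

* The built-in detector matches the known synthetic bed appearance; it says
  nothing about object detection on real frames, where a trained model must
  be plugged into the detector interface.
* The bed position is detected only before patient entry and never updated,
  so bed repositioning after entry is out of scope.
* Long staff occlusions that *resemble drape colors* could still trigger
  early detection, as in the real system; the generator can express the
  scenario but no countermeasure (e.g. human detection) is implemented.
* Detection relies purely on color; drapes resembling skin/sheet tones (or
  transparent drapes) are by design undetectable.
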