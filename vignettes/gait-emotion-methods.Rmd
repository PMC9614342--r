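---
title: "Methods: emotion effects on gait from marker trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emotion effects on gait from marker trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis in one paragraph

`gaitmood` analyses 3-D optical-marker recordings of people walking freely
along roughly circular paths while experiencing an induced emotion. From
each trial it measures *walking straightness* — the signed planar angle
between consecutive step vectors, negative for clockwise turning — and 24
*body-part angles* defined by marker triples. Angle means and standard
deviations are aggregated within seven 10° straightness bins per trial,
and emotion effects are tested three ways: one-way ANOVA (with Tukey HSD
follow-up) of every angle statistic on the emotion label; multi-factor
ANOVA of *arm-swing magnitude* (the within-bin SD of the shoulder-arm
angle, catalogue indices 19/20) on emotion, signed curvature, arm side
and gender; and per-emotion linear regressions of arm-swing magnitude on
signed curvature. Because no public motion-capture dataset accompanies
this design, the package ships a synthetic cohort generator whose trials
carry known emotion effects, so every stage of the pipeline is testable
against ground truth.

# Data model and conventions

A trial is a `marker_series`: frame-indexed positions of up to 37 named
markers at 100 frames/s, in metres. X and Z span the horizontal (top-view)
plane and Y is vertical; this Y-up convention is what the arm-elevation
artifact filter assumes, and it is fixed package-wide. Frame indices are
0-based and the file column `frame` is authoritative. A marker
observation is all-or-nothing: a partially recorded triple is treated as
missing.

Marker naming follows the body-part-angle catalogue (`WaistLeftFront`,
`BackLeft`, `LeftThighFront`, ...). Marker-set listings spell some of
these differently (`ThightFront`, `LeftThigh`); an explicit alias map
(`resolve_marker()`) normalises every spelling to one canonical name
rather than trusting files to agree.

# Preprocessing

Two *independent* frame filters feed two feature paths:

* **Straightness path** — after trimming 60 s (6,000 frames) from each
  end of the trial, only frames where both `LeftAnkleOut` and
  `RightAnkleOut` are observed survive.
* **Angle path** — after the same trimming, frames showing non-gait arm
  elevation are removed: for each of the eight arm markers (left/right
  `HandOut`, `WristOut`, `WristIn`, `ElbowOut`) the mean and SD of its
  vertical coordinate are computed once over the whole trimmed trial,
  and any frame where any arm marker lies strictly outside
  mean ± 2·SD is dropped. Strict inequalities mean a constant signal
  (SD = 0) drops nothing. Missing arm markers are not dropped here;
  missingness is handled per angle later.

Each path is then split into *chunks*: a run of more than 25 consecutive
excluded frames starts a new chunk, shorter runs stay inside the chunk as
internal gaps, and chunks with fewer than 50 kept frames are discarded.
Two boundary conventions are deliberate: a gap of exactly 25 frames does
**not** split (the split rule is strictly "more than 25"), and the
50-frame minimum counts kept frames, not span length, since missing
frames carry no data.

# Feature extraction

**Steps.** Within each straightness chunk the top-view inter-foot
distance `sqrt((xL-xR)^2 + (zL-zR)^2)` is smoothed with a Savitzky-Golay
filter (window 31 frames ≈ 0.31 s, order 3) and its peaks — moments of
full stride — become step events. Peaks must be at least 0.25 s apart
and at least 0.02 m prominent; these values bracket plausible human
cadence (≤ 4 steps/s) and exceed coordinate jitter by an order of
magnitude, and all of them are configurable (`feature_params()`). Chunks
yielding fewer than three steps are unusable for straightness and are
discarded. The step's location is the leading foot's top-view position
(the natural footfall proxy; the inter-foot midpoint is available as a
configuration alternative).

**Straightness.** For consecutive steps *k*, *k+1*, *k+2* the signed
angle from the first step vector to the second is computed from
`atan2(cross, dot)`; counter-clockwise turning (seen from above) is
positive. Every frame spanned by a triple receives its angle; frames
spanned by two overlapping triples receive the average. For a walker on
a regular *N*-gon this statistic equals the exterior angle 360/*N*
exactly, which the tests exploit as a closed-form oracle.

**Angles.** The 24 catalogued angles are computed in full 3-D (several
triples are vertical, e.g. knee-thigh-waist, so a top-view projection
would destroy them) as the arc-cosine of the normalised dot product at
the vertex marker — in [0°, 180°] by construction.

**Aggregation.** Frames holding both a straightness bin and a valid
angle value are grouped by the seven half-open bins [−35°, −25°), ...,
[25°, 35°); the bin edges reuse boundary values, so half-open intervals
resolve ties deterministically (a value of exactly 5° belongs to
"5 to 15"). Values outside ±35° are discarded, not clamped. Per
(trial, bin, angle) cell the mean and *sample* SD (n−1; the denominator
choice is fixed and documented rather than inherited silently) are
reported for cells with at least two frames, so both moments are
defined.

**Arm swing and curvature.** The arm-swing table takes the SD of angle
19 (left) and 20 (right) per bin and converts each bin to a signed
curvature: outside arm positive, inside arm negative, so clockwise bins
give the left arm +|c| and counter-clockwise bins −|c|, with the
straight bin at 0 for both arms. Swing rows additionally require at
least 120 frames (~1.2 s) of support: one full arm-swing cycle at usual
cadence is ≈ 1.1 s, and an SD estimated from less than one cycle
measures phase, not amplitude. This threshold is a package-level quality
gate (configurable in `build_arm_swing_table()`).

# Statistics

* **One-way ANOVA** is run independently for every
  (angle 1–24) × (mean, SD) × (7 bins) dependent, at trial level, for
  both the stimulus label and the self-reported emotion. Degenerate
  cells (all values equal) report F = 0. No correction is applied
  across the 336 dependents by default — each test is reported
  marginally and Tukey adjusts only within a dependent's level pairs —
  but `adjust = "BH"` adds a Benjamini-Hochberg column. Treating trials
  (not subjects) as the observational unit ignores the repeated-measures
  structure; this matches the 2-degrees-of-freedom emotion factor the
  analysis is built around and is a known statistical caveat.
* **Tukey HSD** follows up only dependents whose ANOVA p-value passes
  the α = 0.05 screen.
* **Multi-factor ANOVA** models arm-swing magnitude on reported emotion,
  curvature *as a seven-level categorical factor* (its 6 degrees of
  freedom are part of the design), arm side and gender, plus the four
  interactions emotion:curvature, emotion:side, curvature:side and
  emotion:gender. The design is unbalanced, so Type II sums of squares
  are the default (Type III is available; on balanced data they agree,
  which the tests verify).
* **Curvature regressions** fit `swing = α + β·curvature` by OLS within
  each of the six (emotion, arm) strata, with curvature continuous.

# The synthetic cohort generator

The generator emulates the study design the analysis assumes: 49
subjects (41 male, 8 female), each walking three trials (neutral,
positive, negative stimulus) of 600 s — 147 trials, one flagged
corrupted, leaving 146. Self-reported emotion labels are assigned from
the observed stimulus-by-report contingency (row proportions
12/23/14, 13/19/17, 19/2/28 over 49; column totals 44 Happy / 44 Sad /
59 Neither), exactly when the cohort size matches and multinomially
otherwise.

Each subject draws a walking style held fixed across their trials: path
kind (circle 50%, rounded rectangle 30%, wandering circle 20%),
direction (counter-clockwise 68%, clockwise 14%, mixed 18% — the
proportions observed in the emulated design), cadence ≈ 1.8 steps/s,
step length ≈ 0.65 m, and a path radius drawn log-uniformly from
1.3–9 m. The radius range is chosen so the cohort populates all seven
straightness bins (step turn = step_length/radius spans ~4°–29°); it is
deliberately wider than an indoor capture volume would allow, because
bin coverage, not room geometry, is what the downstream statistics need.

The skeleton is a rigid torso frame translating along the path with
tangential heading, with limbs attached at anthropometric offsets:

* Feet oscillate fore-aft sinusoidally in anti-phase at the configured
  cadence, so the top-view inter-foot distance peaks exactly at full
  stride — the signal model the step detector assumes. The lateral
  distance between footfall lines is 0.04 m by default: footfalls
  nearly on a single line keep the step-vector zigzag (two times
  `atan(step_width/step_length)` ≈ ±3.5°) inside one straightness bin.
  This narrow-base simplification is the one place the generator
  deliberately departs from typical gait (real step width is ~0.1 m)
  so that the straightness statistic of a constant-curvature walk is
  constant to within a bin.
* Arms are pendulums in the sagittal plane through the shoulder. The
  back reference markers sit laterally in line with the shoulder
  markers, so the shoulder-arm angle (catalogue 19/20) is *exactly*
  linear in the swing phase, and a sinusoidal swing of amplitude
  √2·target gives the angle an SD of exactly the target.
* The emotion effect is injected solely through arm-swing amplitude:
  target SD = base(emotion) + slope(emotion) × signed curvature, with
  defaults Happy 4.5521 + 0.0259·c, Neither 3.8916 + 0.0017·c, Sad
  3.1764 + 0.0038·c (degrees). The per-frame curvature is the signed
  bin centre of the *step-window-averaged* turning angle — averaged
  over ±1 step, because that is what the step-triple straightness
  statistic measures at path transitions. The inside/outside asymmetry
  is carried entirely by the sign of the curvature; the separate
  `inside_damping` knob therefore defaults to 1 (an additional damping
  would make swing-versus-curvature piecewise and break the linear
  law the regressions estimate).
* Head nod, torso bob and leg geometry oscillate emotion-independently,
  so ANOVA specificity (effects concentrating on the arm angles) is a
  testable property rather than an artifact of everything else being
  static.
* Corruption processes: isotropic Gaussian coordinate noise (1 mm
  default, typical optical-capture jitter); full-body dropout bursts
  (1/min, 10–200 frames, spanning both sides of the 25-frame split
  threshold); and arm-raise artifacts (0.5/min): hand/wrist markers of
  one side rise 0.35–0.5 m in a ramp-hold-ramp profile for 1–2 s,
  emulating watch checks and glasses adjustments. On noise-free trials
  every artifact's core (elevation ≥ 0.3 m) is provably outside the
  2·SD band, so the arm-artifact filter catches it — a generator/filter
  cross-check in the tests.
* Between-subject variability is an additive per-subject swing-base
  offset (SD 0.3°, ~8% of the Sad–Happy gap), which is also the
  trial-level spread used by the statistical calibration simulations.

All randomness flows from one master seed: each trial derives an
independent substream seed, so cohorts are reproducible trial by trial
and the pipeline's outputs are byte-stable under a fixed seed.

**What the generator does not emulate** — and what passing tests
therefore do not show about real data: soft-tissue and marker-placement
artifacts, asymmetric or pathological gait, double-support timing,
speed-cadence covariation, fatigue drift, and any emotion effect beyond
arm-swing amplitude (e.g. posture, head pitch, stride variability).
Parameter recovery on this cohort demonstrates that the pipeline
measures what it claims to measure, not that real emotions behave this
way.

# Numerical choices and degenerate inputs

* Savitzky-Golay window/order and the peak separation/prominence are
  unstated by the analysis this package operationalises; the defaults
  above preserve ~2 Hz cadence peaks and are all exposed in
  `feature_params()`.
* Chunk-internal gaps (≤ 25 frames) are treated as contiguous for
  smoothing; peak separation is enforced in kept-sample units.
* `acos` arguments are clamped to [−1, 1]; zero-length vertex vectors
  yield missing angles with a warning; zero-length step vectors skip
  the triple with a warning.
* Trials shorter than twice the trimming window are refused outright
  (they would be empty after trimming), as are smoothing calls shorter
  than the filter window (passthrough with warning).
* The direction classifier calls a trial CW/CCW when ≥ 90% of curved
  binned frames (5° ≤ |θ| < 35°) share a sign, "both" otherwise; an
  all-straight trial is "both" with a warning.

# Problem sizes used by the tests and the acceptance script

The generator's scientific defaults (49 subjects, 600 s trials) describe
the emulated study. The test suite and `scripts/acceptance.R` run the
same cohort structure at shorter trial durations — 240 s for the
acceptance run (120 s of analysed walking per trial after trims), 150 s
for replicate studies — and 9-subject cohorts for the 20-replicate slope
recovery. These sizes keep per-bin frame counts in the thousands, where
the swing-SD estimator is stable to well under 1%, while an entire
147-trial cohort analysis completes in about a minute.

# Known limitations

* Trial-level (not subject-level) one-way tests overstate independence;
  a mixed-effects reanalysis would be the natural extension.
* The binned curvature design has the usual binning attenuation:
  regression slopes recovered from bin centres are biased slightly
  toward zero when the underlying curvature varies within a trial
  (path corners, wandering radii). The recovery tests bound this at
  well under the ±0.005 tolerance on the default cohort, but users
  fitting sharper curvature laws should prefer trials with sustained
  constant curvature.
* The straightness statistic inherits step-width zigzag from real
  alternating footfalls; on real data (step width ~0.1 m) single-triple
  frames at chunk edges can land one bin away from the walk's true
  curvature. The 120-frame swing-row support threshold exists largely
  to keep such slivers out of the arm-swing table.
* `classify_walk_direction` is threshold-based and will call highly
  unbalanced mixed trials CW or CCW.
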