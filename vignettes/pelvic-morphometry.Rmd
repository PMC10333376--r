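---
title: "Pelvic floor morphometry: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pelvic floor morphometry: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelvimetry)
```

## What is being measured

On dynamic pelvic MRI, prolapse severity is read off the positions of three
organ points — bladder base, external cervical os, anorectal junction — at
rest and at maximum straining, relative to a reference system built from bony
landmarks. This package works entirely in annotation space: its inputs are 3D
point coordinates in millimetres in an arbitrary rigid world frame (scanner
space), with the convention anterior+, caudal+, subject-left+. It never
touches images; landmark detection and its error budget live upstream.

## Reference systems

**PCL.** The pubococcygeal line runs from the most inferior point of the
pubic symphysis to the last coccygeal joint. The "tangent of the last
coccygeal joint" is represented by the single annotated joint point: a tangent
construction would require the joint's local surface, which an annotator does
not produce. Signed distances to the PCL are computed after projecting the
query point into the subject's sagittal plane, positive caudal. Because the
line alone does not define "caudal", the constructor stores an in-plane unit
vector oriented by a second landmark with known anatomy: the sacrococcygeal
joint lies cranial to the PCL (and the coccyx caudal to the SCIPP line). This
keeps `pcl_distance(line, p)` self-contained and, importantly, makes every
output invariant under rigid motions of the whole annotation set — the frame
of the scanner can never leak into a measurement.

**3D PICS frame.** The SCIPP line (symphysis to anterior sacrococcygeal
joint) is projected into the sagittal plane, whose normal is the
inter-ischial-spine direction, and rotated by 34° at rest or 29° during
straining. The literature calls this rotation "clockwise", which presupposes
a display convention; we operationalize it landmark-relatively as *the
posterior end of the line is displaced caudally, i.e. towards the coccyx
side*. This reproduces the intended inclination correction regardless of
image-display handedness and is what makes the rigid-invariance property
testable. The rotation pivot is the inferior symphysis point; whether the
original tooling pivots there or at the sacrococcygeal joint is not public,
and the pivot only shifts the plane along the line, not its orientation.
Axes: `axis_x` anterior-positive along the rotated line, `axis_z` the
right-to-left spine direction orthogonalized against `axis_x`, and
`axis_y = axis_z × axis_x`, caudal-positive — so a point above the PICS plane
has negative *y*, below positive, matching the clinical sign rule. The two
angles are configuration values (`pics_angles()`), not constants baked into
the code, since the underlying calibration may be refined.

Each phase uses its own landmark positions: the strain frame is rebuilt from
strain-phase landmarks. That is the point of an inclination-corrected system —
the pelvis tilts under straining, and the frame must follow it.

## Grading

Grading uses the maximal-strain position below the PCL. The default cut-offs
are the widely used rule of three for the anterior and middle compartments
(grade 0 ≤ 1 cm; grade 1 (1, 3]; grade 2 (3, 6]; grade 3 > 6 cm) and a
3/5 cm scheme for the anorectal junction. Lower bounds are exclusive: a
bladder point at exactly 1.0 cm below the PCL does *not* reach grade 1. These
defaults are simultaneously consistent with the standard worked examples
(1.0 cm → no grade, 1.5 cm → grade 1, 4.1 cm → grade 2 anterior, 3.1 cm →
grade 1 posterior) and are fully configurable through `study_config()`;
grades are capped only by the length of the cut-off vector.

## Agreement statistics

- **Wilcoxon signed-rank** (`wilcoxon_signed_rank()`): zero differences are
  dropped (classical handling, not Pratt's); the exact signed-rank null is
  used for effective n ≤ 25 when the absolute differences are untied,
  otherwise the normal approximation with continuity and tie correction.
  Exact enumeration under ties is non-standard and adds nothing at these
  sample sizes.
- **Bland–Altman** (`bland_altman()`): differences oriented single − multi,
  so positive values mean the single-slice protocol recorded the lower (more
  prolapsed) position; limits of agreement are mean ± 1.96 sd.
- **ICC** (`icc_absolute_agreement()`): two-way random effects, absolute
  agreement, single measures — ICC(2,1). Two specific readers each rated
  individual measurements and the clinical question is absolute closeness,
  not mere consistency. Confidence intervals use the F-distribution method of
  McGraw & Wong; with zero between-subject variance the ICC is defined as 0
  with a warning. Interpretation bands: < 0.40 poor, 0.40–0.59 fair,
  0.60–0.74 good, ≥ 0.75 excellent.
- **Normality** (`ks_normality()`): Lilliefors-corrected Kolmogorov–Smirnov,
  because location and scale are estimated from the data; it requires at
  least 5 observations (the implementation's minimum).
- Significance is two-tailed at 0.05 throughout `run_full_analysis()`, with
  no multiplicity correction — the battery mirrors a descriptive feasibility
  analysis, not a confirmatory trial.

Percentages in the qualitative summaries are rounded half-up to one decimal;
this reproduces standard printed frequency tables (1/45 = 2.2%).

## The synthetic cohort

`generate_study()` emulates a 23-patient / 22-volunteer two-protocol reader
study. Per subject and organ:

1. latent rest position ~ Normal with the cohort's rest mean/sd;
2. latent *full-strain* position ~ Normal with the cohort's strain mean/sd,
   clamped at the rest position (organs do not move cranially under strain
   beyond noise — note the clamping biases the realized strain mean upward
   relative to the configured marginal; the raw draw is kept in the
   ground-truth table for calibration checks);
3. each sequence draws a straining-effort category (single-slice
   38/6/1 ÷ 45 good/suboptimal/none; multi-slice 29/12/4 ÷ 45) and realizes
   `rest + attenuation(effort) × (latent strain − rest)`. The attenuation
   factors (good 1.0, suboptimal 0.5, none 0.1) are invented mechanism
   constants: they exist to reproduce the *direction* of protocol
   discrepancies (insufficient straining at acquisition time hides descent),
   not their magnitude;
4. every observed position receives acquisition noise (sd 0.15 cm). This knob
   models re-annotation/acquisition variability between sequences; without it
   the two protocols would be identical at rest, which no real study shows,
   and the rest-phase paired tests would be degenerate;
5. cervix visibility on the single-slice sequence is sampled per phase
   (rest 5/9/31, strain 6/9/30 of 45 not/partly/fully visible); not-visible
   positions are withheld, and paired analyses use complete cases only, with
   exclusion counts reported — never imputation;
6. a fixed 20-subject subset (patients first) is annotated by a second reader
   whose values add independent per-organ noise (defaults 0.2/0.3/0.5 cm for
   bladder/cervix/anorectum — the posterior point is hardest to place);
7. positions become 3D world points via `place_organ_at()` against the
   subject's own phase-specific PICS frame, built on a canonical pelvis
   (SCIPP inclination ≈ 32°) perturbed by a per-subject rigid motion and
   scale and tilted ~4° between phases.

Organ positions are sampled independently across organs: the available
cohort summaries report only marginals, so the simplest model consistent with
them omits inter-organ correlation. A common "laxity" factor could induce it
but would be uninformed guesswork. Randomness flows from a single master
seed through per-subject substreams, so subject k's data are identical
whatever the cohort size — useful when scaling simulations.

**What passing tests on synthetic data do and do not show.** They certify
that the geometry is exact (round-trip and rigid-invariance properties hold
to 1e−9), that the statistics match independent oracles, and that the
pipeline recovers the parameters it was fed. They do not validate the
annotation process on real images, the attenuation magnitudes, or any
inter-organ dependence — those require real data.

## Numerical choices and degenerate inputs

- Degenerate geometry (coincident line endpoints, spines parallel to the
  rotated line, orienting landmark on the line) raises an error naming the
  construction; thresholds use a 1e−9 mm norm floor.
- Frames are orthonormalized by construction (projection + cross product),
  not by iterative refinement; axes are exact to floating-point rounding.
- Outputs are centimetres (inputs millimetres): the factor 10 lives in
  exactly two functions, `pics_coordinates()` and `pcl_distance()`.
- Grading at a cut-off takes the lower grade (exclusive lower bounds), and
  `interpret_icc()` uses left-closed bands, so both are total monotone step
  functions — property-tested on fine grids.
- `run_full_analysis()` tolerates groups where every paired difference is
  zero (reports NA rather than failing) and marks the ICC section "not
  computed" for single-reader studies.

## Problem sizes used in the test suite

Property tests run 100 random rigid transforms and 100 random frames; the
Wilcoxon calibration uses 2000 replicates at n = 20 (empirical size ≈ 0.048
for the exact test); Bland–Altman coverage uses 10^5 normal pairs; generator
calibration uses 2000 subjects per cohort, at which the mean of a position
with sd 0.2 cm is determined to ± 0.013 cm (3 SE). For means with large
configured sd (up to 2.9 cm) the calibration check uses the mean's own
standard error as the band, since a fixed ± 0.05 cm band would be inside
sampling noise at this n. The whole suite runs in about a minute on one CPU.

## Known limitations

- The PICS-plane construction (rotated sagittal direction × orthogonalized
  spine axis, anchored at the symphysis) is the minimal plane using all five
  landmarks; published 3D implementations may differ in details that are not
  in the public record. The rotation pivot ambiguity is noted above.
- Grading of the middle compartment against the PCL is a convention choice;
  some centres reference the cervix differently.
- The generator's effort attenuation and noise magnitudes are plausibility
  constants, not fitted parameters.
- x- and z-axis cohort comparisons are out of scope; the pipeline measures
  them (they are in every `pics_coordinates()` call) but the analysis battery
  reports only the cranio-caudal axis.
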