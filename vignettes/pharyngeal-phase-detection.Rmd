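---
title: "Detecting the pharyngeal swallowing phase in untrimmed VFSS video"
author: "vfssdetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the pharyngeal swallowing phase in untrimmed VFSS video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A videofluoroscopic swallowing study (VFSS) records a lateral X-ray
view of a subject swallowing radio-opaque material. The clinically
decisive moment is the *pharyngeal phase*: a sub-second interval in
which the bolus is propelled from the oral cavity through the pharynx
while the airway is protected. Clinicians locate these intervals by
scrubbing through minutes of video per study; `vfssdetect` automates
that search. The input is an untrimmed grayscale video (nominally 30
FPS, processed at 15 FPS); the output is a set of `[start, end]` frame
intervals with confidences, plus the evaluation machinery to score
them against expert annotations.

The cascade has three stages, each usable on its own:

1. **Candidate generation.** Dense TV-L1 optical flow is computed
   between consecutive frames. The defining motion signature of a
   swallow is strong *vertical* motion through the center of the
   image (the pharynx sits mid-frame in the lateral view). Flow is
   truncated to ±10 px and divided by 10; any flow step whose maximum
   absolute vertical component inside the central region exceeds
   `fth = 0.4` casts a vote for itself and its eight nearest steps.
   Up to five non-overlapping 20-frame clips are selected around vote
   peaks exceeding `vth = 2.5`.
2. **Clip classification.** A 3D convolutional network classifies
   each 20-frame clip as *pharyngeal phase* vs *other motion* (head
   movement, coughing, preparation to swallow). Two architectures are
   implemented: the inflated Inception-V1 baseline, and a deeper
   variant that rearranges the inception modules into a 3/4/6/3 stage
   layout so that more capacity sits early, where the small fast
   bolus is still spatially resolved.
3. **Temporal detection.** A sliding window (20 frames, stride 5)
   scores the untrimmed video; window scores are averaged into
   per-frame scores, smoothed with a width-5 moving average, and
   maximal runs of frames scoring above `scoreth = 0.5` and longer
   than `frameth = 5` frames become detections with confidence
   `mean(score) + 0.001 × length`.

Evaluation uses temporal intersection-over-union (IOU) on inclusive
frame sets with a greedy, confidence-ordered assignment at
`IOU > 0.3`, yielding pooled precision/recall/F1, a start/middle/end
detection time error in seconds, and a per-video miss rate.

## Conventions that everything else depends on

* Frames are indexed **0-based**; intervals are **inclusive**
  `[start, end]` and are treated as the frame set
  `{start, …, end}` in every set operation, so an interval of one
  frame has length 1 and `IOU([0,9], [5,14]) = 5/15`.
* Flow step *t* pairs frames *(t, t+1)* and is mapped back to video
  frame *t* (the earlier frame) when a vote peak becomes a clip
  center. A candidate peak at *t* yields the clip
  `[t−10, t+9]`, clamped (not padded) at sequence boundaries so all
  clips have exactly 20 real frames.
* The vertical (Y) flow component is positive **down** the image;
  voting uses `|Y|`, so the sign convention cannot change results.
* Resampling 30→15 FPS keeps every second frame (uniform index
  subsampling; nearest-index selection for non-integer ratios).
  Frame averaging would blur exactly the motion the cascade keys on.

## Stage parameters

| parameter | default | unit | role |
|---|---|---|---|
| `fth` | 0.4 | normalized flow (= 4 px/frame) | vertical-motion vote trigger |
| center fraction | 0.5 | – | central crop voted over (per dimension) |
| vote radius | 4 | flow steps | “the frame and its eight nearest frames” |
| `vth` | 2.5 | votes | candidate peak threshold (strict `>`; with unit votes this demands a tally ≥ 3) |
| max candidates | 5 | clips/video | candidate budget |
| window / stride | 20 / 5 | frames | sliding-window detection grid |
| smoothing width | 5 | frames | moving-average width on frame scores |
| `scoreth` | 0.5 | probability | frame marking threshold (strict) |
| `frameth` | 5 | frames | minimum run length (strict) |
| `λ` | 0.001 | 1/frame | length bonus in the confidence |
| IOU threshold | 0.3 | – | TP criterion |
| pad | 10 | frames | review-export extension (never used in evaluation) |
| learning rate / batch | 0.1 / 6 | – | training operating point |

Where the procedure leaves a choice open, this package decides as
follows and treats the decision as part of its contract:

* **Central region extent** — the central 50% of each dimension,
  configurable. The pharynx occupies the mid-frame in lateral VFSS;
  a 50% crop excludes the image borders where head and jaw motion
  dominate.
* **“Eight nearest frames”** — radius 4 on each side with unit vote
  weight, the only symmetric reading. A non-integer `vth = 2.5` is
  honoured as a strict threshold, so with unit votes acceptance
  requires a tally of at least 3.
* **Vote ties** — equal tallies are visited earliest-frame-first,
  making selection deterministic.
* **Peak containment** — a frame is unavailable as a new peak when it
  lies inside a previously accepted candidate's 20-frame span (the
  containment test is on the peak, not on span overlap).
* **Per-frame score** — the mean over all windows covering the frame:
  unbiased, order-independent, and it naturally suppresses the
  half-covered windows at event borders. Frames beyond the last
  window inherit the nearest window's score.
* **Confidence formula** — `mean(run score) + λ·run length` with
  `λ = 0.001`. λ is listed among the detection hyper-parameters
  without an explicit formula; a small length bonus is the simplest
  role consistent with confidence-ranked evaluation, and at
  `λ = 0.001` it only breaks ties between otherwise equal runs.
* **Matching precedence** — a detection claims, among unclaimed
  ground truths above the IOU threshold, the one with (1) lowest
  start/middle/end time error, (2) highest IOU, (3) earliest start.
  The first two criteria are both stated for the protocol without an
  ordering; time error is put first because it is the quantity the
  protocol reports. Middle positions may be half-integral and are
  kept real-valued until the seconds conversion.
* **Ignored detections** are excluded from the precision denominator —
  otherwise the ignored category would be indistinguishable from a
  false positive and would have no reason to exist.
* **Annotator merging** averages the two annotators' endpoints with
  half-up rounding, pairing intervals in order of occurrence.

## The classifier

Both variants share the stem and pooling skeleton of the inflated
Inception-V1: conv 7×7×7 stride (2,2,2) → maxpool 1×3×3 stride
(1,2,2) → stage 2 → maxpool 1×3×3 (1,2,2) → stage 3 → maxpool 3×3×3
(2,2,2) → stage 4 → maxpool 3×3×3 (2,2,2) → stage 5 → average pool
2×7×7 → linear → softmax. The baseline's stage 2 is a plain
1×1×1 + 3×3×3 conv pair and its later stages hold 2/5/2 inception
modules; the proposed variant uses 3/4/6/3 inception modules
throughout. Each inception module concatenates `[1×1×1]`,
`[1×1×1 → 3×3×3]`, `[1×1×1 → 3×3×3]` and `[3×3×3 maxpool → 1×1×1]`
branches.

Numerical construction choices:

* **Padding.** Convolutions and pools use “same”-style padding
  (`out = ceil(in / stride)`), except that the final 3×3×3 max pool
  runs unpadded along time. This is forced by arithmetic: a 20-frame
  clip reaches temporal extent 5 before that pool, and a padded
  stride-2 pool would give 3, not the 2 that the closing 2×7×7
  average pool is sized for. Spatially, 224 → 7 needs same padding
  throughout. The avgpool stride difference between the variants
  ((2,2,2) vs (1,1,1)) has no effect at a 2×7×7 extent, where the
  pool covers the whole feature map; it is implemented as a global
  average over the remaining extent.
* **Channel widths** are not published. The schedule here uses
  per-stage exit widths (32 after conv1, then 96/144/208/256) with
  fixed Inception-style branch fractions (¼ to the 1×1 branch, ~0.4
  to the main 3×3×3 branch with a half-width bottleneck, the rest to
  the second 3×3×3 branch and the pool projection), module widths
  interpolating linearly across each stage. This lands the proposed
  variant at 1,464,906 parameters (published count: 1.422 M) and the
  baseline at 1,120,862 (published: 1.228 M). The published +15.8%
  growth is not exactly recoverable without the original widths; the
  implemented schedule gives +30.7%, and `countParameters()` logs the
  exact counts. Notably the published counts are far below typical
  inflated Inception-V1 sizes (≈12 M), so the original schedule must
  already have been heavily slimmed; it is documented here rather
  than guessed at.
* **Batch norm + ReLU** follow every convolution (the standard
  construction in this architecture family; the source is silent).
  Conv biases are kept and counted.
* **Optimizer** — momentum SGD (0.9), 2-class cross-entropy, cosine
  learning-rate decay with a linear warm-up to 0.1 (warm-up length
  30 iterations by default), batch size 6. Dropout and weight decay
  are not used (unstated in the source; the synthetic task does not
  need them). All randomness (He initialization, shuffling) derives
  from the schedule's seed, so training is bit-reproducible.
* The whole network (conv/pool/batch-norm forward and backward) is
  implemented in this package with im2col + BLAS matrix
  multiplication; gradients are verified against finite differences
  in the test suite.

## TV-L1 optical flow

The duality-based primal–dual TV-L1 solver is implemented in C++ with
the widely used parameter set τ = 0.25, λ = 0.15, θ = 0.3, 5 pyramid
levels at zoom 0.5, 5 warps per level, stopping tolerance 0.01, and
(a package choice) at most 10 fixed-point iterations per warp — 50
sweeps per level, a standard practical operating point that resolves
the 2–16 px/frame motions of interest here to well within the ±0.5 px
the voting threshold arithmetic tolerates. Frames are rescaled to the
0–255 intensity range the λ default is calibrated for. Flow is
computed at native resolution and truncated immediately after
computation (truncation before any resize); the flow-stream clip is
produced by resizing the already-dimensionless normalized fields, so
resizing does not rescale magnitudes. Three-channel input is
converted to grayscale by BT.601 luma weighting before flow.

## What the synthetic generator emulates — and what it does not

`generateVideo()` renders: a static background with a bright
off-center vertical column (the cervical spine) over a darker
soft-tissue field and low-frequency texture; per event a bright
elliptical blob entering the upper-center and descending through the
central region; whole-frame horizontal go-and-return translation
(head motion); small vertical oscillation with zero net displacement
("coughing"); and Gaussian sensor noise. All magnitudes are in
px/frame so the normalization arithmetic is analytically predictable:
a blob moving `v` px/frame produces normalized vertical flow ≈ `v/10`.

**Bolus kinematics.** Transit is modeled as an accelerating descent:
instantaneous speed ramps linearly from 0 to twice the drawn mean
(drawn uniformly from 3–8 px/frame), i.e. ballistic motion, which
matches the rapid acceleration of a real bolus entering the pharynx.
This matters for the voting stage: a hypothetical constant-speed
3 px/frame event would sit permanently below the 4 px/frame vote
trigger, whereas the accelerating profile carries every event past
the trigger in its second half. Slow events therefore vote on fewer
steps than fast ones — mirroring the real situation in which slow,
weak swallows are the hard cases.

**Default study conditions**: 105-frame videos (7 s at 15 FPS — a
typical trimmed swallow segment, and long enough that three
maximum-length events always fit with the required ≥ 20-frame
separations, which the constructive placement guarantees without
rejection sampling), 1–3 events of 8–20 frames, 224×224 frames,
distractor magnitudes 5 px/frame (horizontal), 1.5 px/frame peak
(oscillation — deliberately below the vote trigger; raise it above 4
to manufacture hard negatives), noise σ = 0.01.

**What passing tests do and do not show.** The generator is
deliberately easy: events are high-contrast, the background is
static, and distractors are cleanly separable from events. Passing
the end-to-end suite demonstrates that the cascade's *mechanics* are
correct — voting finds vertical motion, the classifier can learn a
motion-pattern discrimination from harvested candidates, the sliding
window localizes events to within a few frames, and the evaluation
protocol scores all of it exactly. It does not demonstrate clinical
performance: real fluoroscopy has anatomy-dependent contrast, camera
repositioning, swallows that barely move, and annotator ambiguity,
none of which are modeled. Real-data detection accuracy for this
family of methods (e.g. the 73.21% F1 that the published confusion
counts 466/184/157 yield through `precisionRecallF1()`) sits far
below what the synthetic task allows, and nothing here should be
read as reproducing clinical performance.

## Study sizes

The reference synthetic study (`runSyntheticStudy()`, also behind
`scripts/acceptance.R` and the end-to-end test) uses 20 training and
5 test videos per replicate, three replicates, 300 training
iterations, and a reduced classifier (width scale 0.25, 48×48 input)
— sizes chosen so a replicate completes in minutes on one CPU core
while still exercising every stage at full fidelity; the
architecture-contract checks run the full-width networks at the
nominal 20×224×224 input. Candidate recall, held-out clip accuracy
and detection F1 are each required to reach 0.9 in at least two of
the three replicates.

## Known limitations

* Container video (MP4/AVI) is not decoded; use a PNG frame
  directory (the lossless path used throughout).
* The published parameter counts cannot be matched exactly because
  Table-level channel widths are not recoverable; the schedule is
  documented and the counts are logged instead.
* Pre-training on large action corpora is out of scope; only the
  random-initialization training path is implemented.
* Single-class (pharyngeal vs other) detection only; oral and
  esophageal phases, aspiration scoring, and spatial localization are
  out of scope.
* The detection confidence formula honours the listed
  hyper-parameters but its exact published form is unknown; ranking
  behaviour, not absolute confidence values, is the meaningful
  output.
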