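---
title: "Detecting flapping pauses in hovering flight: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting flapping pauses in hovering flight: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoverpause)
```

## The signal model

Hummingbirds hovering at a feeder sometimes suspend wing motion for a few
tens of milliseconds, wings extended backwards near the mid-pronation
posture, before resuming flapping. `hoverpause` detects these pauses from
the bounding box of a tracked bird in high-speed video (500 fps is the
working assumption throughout; at the 35–45 Hz wingbeat of the species of
interest that is `framesPerWingbeat(500, 35)` ≈ 14 frames per wingbeat, so
even short pauses span several frames).

The detector never looks at pixels directly. For each consecutive-frame
pair it computes the Jaccard coefficient (intersection-over-union) of the
two boxes, giving a dimensionless motion proxy $J(k) \in [0, 1]$: while the
wings sweep, the projected wing envelope — and with it the tight box —
changes substantially between frames and $J$ oscillates deeply; while the
wings are held still the box changes only through body drift and detector
noise and $J$ plateaus near 1. The forward difference
$\Delta J(k) = J(k{+}1) - J(k)$ (per frame, not per second: both $J$ and
the thresholds derived from it are dimensionless, which keeps them directly
comparable) is then near zero exactly on those plateaus. Frames with
$|\Delta J|$ at or below a threshold are flagged, flagged runs are cleaned
up (gap bridging, minimum duration), and each surviving run becomes a pause
event labelled with the first frame of each consecutive-frame pair it
covers.

Assumptions worth stating explicitly:

* one subject per analysed track, detected in (nearly) every frame —
  detection gaps split the signal into segments that are analysed
  independently, because interpolating boxes across a gap would fabricate
  motion evidence;
* the subject fills a reasonable share of the frame. Box coordinates are
  continuous, but any real detector quantises to pixels; on a small
  subject, one-pixel box flicker produces $|\Delta J|$ comparable to the
  flapping signal itself (the end-to-end pixel test uses a ~60–300 px wide
  bird in a 400×300 px frame for this reason);
* boxes are axis-aligned with the half-open convention
  $[x_{\min}, x_{\max}) \times [y_{\min}, y_{\max})$, origin top-left, so
  that the area of an integer box equals its pixel count (verified against
  a rasterisation oracle in the tests). Degenerate boxes are rejected at
  construction, never clamped.

## The threshold: what is 90 % of the mean of?

The published description of this detector sets the cutoff at 90 % of the
*mean Jaccard coefficient*. Taken literally that compares a per-frame
*change* $|\Delta J|$ (typically ≪ 1) against a fraction of the *level*
$\bar J$ (typically 0.5–0.8). On clean synthetic sequences the literal rule
flags essentially every flapping frame — smooth symmetric wing motion never
changes $J$ by 90 % of its own mean within a single frame — so plateau
length alone cannot separate pauses from flapping, at any minimum-duration
setting.

`PauseDetectorParam()` therefore exposes the reference signal as an option
and defaults to the self-consistent choice:

* `thresholdReference = "derivative"` (default): threshold
  $= 0.9 \cdot \overline{|\Delta J|}$ — the same quantity that is being
  compared, so the cutoff adapts to how violently the box oscillates in
  that particular video. On synthetic scenes this cleanly separates
  flapping (sub-threshold runs of ≤ 2 frames) from pauses (runs spanning
  the full pause);
* `thresholdReference = "jaccard"`: the literal published wording,
  $0.9 \cdot \bar J$, retained for comparison studies.

The fraction 0.9 itself is kept from the published rule and works across
35–45 Hz without retuning. `meanWindow` (default `"global"`) switches the
mean to a centred running mean of a given window length, for long
recordings whose motion scale drifts; edge windows shrink symmetrically.

Two boundary conventions: the comparison is *inclusive*
($|\Delta J| \le$ threshold), so a threshold of exactly zero — which the
derivative reference produces on a perfectly still track — still flags the
exactly-zero derivatives rather than nothing; and the absolute value of the
derivative is thresholded, since a plateau is approached from either side.

## Plateau extraction parameters

* `minPauseFrames` (default 3, i.e. 6 ms at 500 fps): runs shorter than
  this are discarded. Real detectors occasionally produce one or two
  similar consecutive boxes mid-flap; three frames is comfortably above
  that and far below the ≈ 14-frame wingbeat, so genuine pauses (≥ ~10
  frames) are never suppressed.
* `gapToleranceFrames` (default 0): a non-flagged gap of at most this many
  frames *between two flagged runs* is bridged before the duration filter.
  Useful on pixel-quantised boxes, where a single spurious $|\Delta J|$
  spike can split a genuine plateau; gaps at segment edges are never
  bridged.
* Events are reported in original-video frame indices of the first frame
  of each pair. A pause frozen over frames $[s, e]$ yields zero derivative
  at indices $s \ldots e{-}2$, so the reported end sits up to two frames
  before the physical pause end — the tests accordingly allow a boundary
  error of two frames.

Raising the threshold fraction can only increase the number of flagged
frames, and raising `minPauseFrames` can only decrease the number of
events; both monotonicity properties are asserted in the test suite.

## Detection and tracking stages

The deep-learning front end used in the original study is deliberately out
of scope. In its place:

* a *detector* is any function `f(frame, frame_index)` returning boxes in
  frame coordinates. The shipped reference is median-background
  subtraction: per-pixel median across frames (robust to a transient
  subject; note that a perfectly stationary hoverer leaves a ghost, so a
  bird-free background plate is preferable when available —
  `renderBackground()` provides one for synthetic scenes), absolute
  grayscale differencing (luma weights; wing motion at 500 fps is a
  luminance phenomenon), 8-connected components (diagonal pixel chains on
  a blurred wing edge belong to the same blob; components are built from
  the pixel-adjacency graph), an area filter, and optionally
  largest-component selection since each analysed video contains a single
  flying bird.
* the *tracker* associates detections greedily by descending IoU with each
  active track's last box, optionally blended with an appearance cosine
  similarity (`w·cos + (1−w)·IoU`) — the seam where an external embedding
  model can plug in without the package shipping one. With one or two
  well-separated subjects per scene, greedy association is deterministic,
  easy to verify, and equivalent in practice to optimal assignment.
  Matches below `minIoU` (default 0.1) are rejected; a track unmatched for
  more than `maxMissedFrames` (default 5) is closed, and a later
  reappearance opens a new identity rather than resurrecting a stale one.
  Downstream pause analysis runs on the *primary* track: most frames
  covered, ties broken by larger mean box area, then lower id — perched
  birds form short or small tracks and are excluded by this rule.

## Event-level evaluation

A predicted pause counts as a true positive when it overlaps an annotated
pause by at least `minOverlapFrames` (default 1 — the weakest defensible
criterion, exposed as a parameter together with an overlap-fraction
variant) under one-to-one matching. `matchPauses()` defaults to an optimal
(maximum-cardinality bipartite) matching on the overlap graph rather than
greedy best-overlap-first: greedy can demonstrably under-count true
positives when one long prediction overlaps an annotation that a
neighbouring prediction should have claimed, and the test suite checks the
optimal matcher against an exhaustive enumeration oracle (and exhibits a
concrete case where greedy, kept as `method = "greedy"`, lags). Counts are
conserved by construction: TP + FP = predictions, TP + FN = annotations.

Precision, recall and F1 follow the usual definitions; zero-denominator
cases return 0 with a warning instead of erroring, so batch evaluation
over many videos never aborts. Percentages are conventionally reported
rounded to the nearest integer percent.

Pause statistics per video are the pause frequency (pauses per wingbeat)
and mean pause duration in ms. Wingbeat counts can be supplied manually or
estimated from the Jaccard series itself: `estimateWingbeatFrequency()`
returns the largest non-DC peak of the mean-removed spectrum, optionally
with pause intervals masked out first. One subtlety is built into its
interface: the IoU between consecutive frames is a *rectified* motion
proxy — a symmetric stroke envelope produces two dissimilarity dips per
full wingbeat, one per stroke — so for box-derived series the dominant
peak sits at twice the wingbeat frequency and callers pass
`peaksPerWingbeat = 2`; on a directly wingbeat-periodic signal the default
of 1 applies. The estimator resolves frequency to one spectral bin
(`frameRate / length` Hz, 1 Hz for a 1-s series at 500 fps).

## The synthetic scene generator

The simulator defines the study conditions under which the package's
claims are tested: 800×600 px frames at 500 fps, a 40 Hz wingbeat (the
35–45 Hz species band is covered by tests), and Poisson-scheduled pauses
at 1 s⁻¹ with uniform 20–80 ms durations (10–40 frames — the range over
which exact recovery is asserted). While flapping, the box half-width
follows $b + A\,|\sin \phi|$ with $b = 40$ px and $A = 160$ px (half-height
$30 + 50\,|\sin\phi|$ px): widest at both stroke extremes, approximating
the projected wing envelope, with an amplitude-to-body ratio chosen so
that consecutive-frame IoU collapses sharply near the narrow-box phase —
the regime real high-speed footage of a frame-filling bird operates in.
During a pause the wing phase freezes and the box is held at
`pausePostureFraction` (default 0.6) of the wing amplitude, an
intermediate extent matching the wings-extended-backwards posture. The
body centre performs a mean-reverting Gaussian jitter walk (AR(1),
coefficient 0.9, innovation SD 1 px) rather than a free random walk, since
a hovering bird station-keeps. Ground truth — per-frame boxes, pause
intervals, and the wingbeat count `round(f · active time)` — comes from
the generator's own bookkeeping. All randomness flows from one explicit
seed, and the generator restores the caller's RNG state.

The rendered tier rasterises a body ellipse and two wing ellipses (held at
the pause posture during pauses) on a uniform plate, adds Gaussian pixel
noise (SD 0.02 in [0, 1] intensity units), and takes the tight box of the
bird's pixels as ground truth, so detector and tracker are exercised
pixel-up.

What the simulator does *not* emulate — and hence what passing tests do
not establish about field recordings: plumage texture and iridescence,
motion blur, illumination changes, backgrounds with moving vegetation,
feeders and flowers, occlusion, more than two birds, and detector-specific
failure modes of a neural front end. The noisy-regime acceptance band
(event recall ≥ 0.9, precision ≥ 0.7 pooled over 50 seeded scenes) is a
property of these synthetic conditions, standing in for — not
reproducing — the published 74 %/74 % on real, undeposited videos.

## Numerical and degenerate-input choices

* Empty series, tracks with fewer than 2 (signal) or 3 (detection)
  usable detections, and constant series in the spectral estimator raise
  informative errors rather than returning empty results silently.
* A completely still track is one long pause: the inclusive threshold
  comparison makes the degenerate case behave continuously with its
  near-still neighbours.
* Within-list overlapping events are tolerated by the matcher (matching
  stays one-to-one) to accept merged multi-source prediction files;
  ground-truth files written by this package are always disjoint, and
  `PauseEvents` validates sortedness and disjointness at construction.
* Greedy tracker association breaks score ties by matrix order
  (track index, then detection index), making runs bit-reproducible.
* Pause schedules are de-overlapped by dropping any pause that starts
  before the previous one ends; at the default rate this removes about
  10 % of drawn onsets, which the schedule tests account for.

## Problem sizes in the test suite

Unit tests run on tracks of tens to hundreds of frames; the
exact-recovery property uses two 3-s box-tier scenes (1500 frames each,
ten pauses spanning onset phases); the noisy-regime band pools 50 2-s
scenes; the matching oracle runs 500 random event-list pairs (≤ 5 events
per side) against exhaustive enumeration; the IoU oracle 1000 random
integer box pairs; rendered-tier tests use 160×120 to 400×300 px frames
for 20–200 frames. The acceptance script simulates 25 2-s scenes at the
default conditions. These sizes were chosen so the whole suite completes
in well under a minute of compute per property while leaving each claim
statistically meaningful.

## Known limitations

* The Jaccard signal conflates wing motion with whole-body translation;
  a bird drifting quickly while holding its wings still shortens or
  erases the plateau. Station-keeping hover is assumed.
* Pause *duration* is reported with a structural bias of up to two frames
  (forward differencing), and the detector cannot resolve pauses shorter
  than `minPauseFrames` + 2 frames.
* The spectral wingbeat estimator assumes a quasi-stationary wingbeat
  frequency over the analysed series; masking handles pauses but not
  frequency modulation.
* Video-container input is not implemented — frames are read from
  numbered PNG/TIFF stills; codec support would come from an external
  I/O backend, not this package.
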