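# hoverpause

Detection and quantification of **intermittent hovering** — episodic
wing-flapping pauses — in high-speed video of hovering hummingbirds.

Several hummingbird species interrupt continuous hovering with momentary
pauses: the wings stop near the mid-pronation posture, extended backwards,
for a few tens of milliseconds between short bursts of wingbeats. At the
recording rates needed to resolve a 35–45 Hz wingbeat (500 fps, where one
wingbeat spans about 14 frames), annotating these pauses by eye is slow and
error-prone. `hoverpause` implements an automated detector for researchers
in animal locomotion and behavioural ecology, together with the evaluation
machinery to score it against expert annotations and a fully ground-truthed
simulator so every stage can be tested without any video data.

## Method

A tracked bird's axis-aligned bounding box oscillates with wing phase. For
consecutive frames *k*, *k*+1 with boxes *B<sub>k</sub>*, *B<sub>k+1</sub>*
the Jaccard coefficient

> *J(k)* = |*B<sub>k</sub>* ∩ *B<sub>k+1</sub>*| / |*B<sub>k</sub>* ∪ *B<sub>k+1</sub>*|

acts as a motion proxy: *J* ≈ 1 when the box barely moves, low when the
wings sweep. Its forward difference Δ*J(k)* = *J(k+1)* − *J(k)* is
near zero wherever the box holds still. Frames with |Δ*J*| below a
threshold — a fixed fraction (default 0.9) of the mean of a reference
signal — are flagged, and maximal flagged runs longer than a minimum
duration (default 3 frames, 6 ms at 500 fps) become pause events. Detected
events are matched one-to-one to annotated events by temporal overlap, and
performance is summarised as event-level precision, recall and F1 (with
pooled counts TP=55, FP=19, FN=19 these all equal 55/74 ≈ 0.743, i.e. 74%,
74%, 0.74). Per-video pause statistics — pause frequency (pauses per
wingbeat) and mean pause duration — complete the picture; wingbeat counts
can come from a spectral estimate of the same Jaccard series.

Around that core the package provides a pluggable per-frame detector
(reference implementation: median-background subtraction with 8-connected
blob extraction), a greedy IoU tracker with an appearance-feature hook, and
a two-tier synthetic scene generator (instant box sequences, or rendered
noisy frames for pixel-up pipeline tests).

## Worked example

```r
library(hoverpause)

param <- SceneParam(durationS = 2, seed = 23)   # 500 fps, 40 Hz wingbeat
scene <- generateBoxSequence(param)
scenePauses(scene)
#> PauseEvents: 2 events @ 500 fps
#>   start_frame end_frame duration_frames duration_ms
#> 1         223       254              32          64
#> 2         331       366              36          72

events <- detectPauses(sceneTrack(scene))
events
#> PauseEvents: 2 events @ 500 fps
#>   start_frame end_frame duration_frames duration_ms
#> 1         223       252              30          60
#> 2         331       365              35          70

matchPauses(events, scenePauses(scene))
#> ConfusionCounts: TP=2 FP=0 FN=0
#>   precision=1.000 (100%)  recall=1.000 (100%)  F1=1.00

js <- jaccardSeries(sceneTrack(scene))
estimateWingbeatFrequency(js, peaksPerWingbeat = 2, excludeEvents = events)
#> [1] 40.04004
pauseStats(events, nWingbeats = sceneWingbeatCount(scene))
#>   n_pauses n_wingbeats pause_frequency mean_pause_duration_ms
#> 1        2          75      0.02666667                     65
```

Both injected pauses (64 and 72 ms) are recovered within two frames of
their true boundaries; the spectral wingbeat estimate matches the
generating 40 Hz, and the video shows one pause per ~37 wingbeats with a
mean duration of 65 ms.

`plotPauseDiagnostics()` draws the standard inspection figure: the Jaccard
curve with detected pauses shaded and annotated pauses marked, above the
derivative with its threshold band.

## Command line

A thin driver over the same functions ships with the package:

```sh
script=$(Rscript -e 'cat(system.file("scripts/hoverpause.R", package = "hoverpause"))')
Rscript $script simulate      --out sim/ --duration 2 --seed 23
Rscript $script detect-pauses --boxes sim/boxes.csv --fps 500 --out det/
Rscript $script evaluate      --predicted det/pauses_detected.csv \
                              --truth sim/pauses.csv --fps 500 --out metrics.json
```

CSV dialects are fixed (comma, header, 0-based inclusive frame intervals)
and documented in the script header.

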