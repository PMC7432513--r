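# JointMotion

Objective quantification of body movement for seated, multi-subject sessions
recorded with a marker-less depth camera, aimed at researchers who study
hyperactivity (e.g. in ADHD) and need an instrument-grade alternative to
observer impressions.

A Kinect V2-class sensor tracks up to six people at once, reporting a
25-joint skeleton per body — each joint a 3D point (x, y, z) in metres, z
being the distance to the sensor. JointMotion turns such skeleton streams
into the study's core quantity, the **movement matrix**: for each analysed
joint *j* and session minute *m*, the path length

&nbsp;&nbsp;&nbsp;&nbsp;D\[j, m\] = Σ ‖p(t\_{i+1}) − p(t\_i)‖

summed over consecutive observed positions whose later endpoint falls in
minute *m*. Only 17 of the 25 joints are analysed (hands, hand tips, thumbs
and feet are rejected — the sensor tracks them poorly on seated subjects);
subjects keep persistent identities 1–6 across occlusions by nearest-anchor
re-identification, short joint drop-outs are linearly interpolated, and
minutes without valid data are missing, never zero.

On top of the matrices sits the validation statistics battery:
Levene-gated two-sample *t*-tests (pooled Student's form, or Welch's form
when Levene rejects variance homogeneity at α = 0.05), unsigned Cohen's
*d* = |m₁ − m₂| / s\_pool with magnitude bands (< 0.20 below threshold,
0.20–0.50 small, 0.50–0.80 moderate, > 0.80 large), rank-based ROC AUC
(the normalized Mann–Whitney U, with 0.5 chance / < 0.7 lower / 0.7–0.9
moderate / > 0.9 higher accuracy bands), and unweighted Cohen's kappa for
dual-observer behaviour counts. A fully seeded synthetic session generator
with analytically calibrated movement intensities stands in for the
hardware.

## Worked example

Effect-size arithmetic on published-style group summaries — "squirm in
seat" counts for a clinical group (M 8.50, SD 4.71, n 32) versus controls
(M 5.27, SD 4.65, n 33):

```r
library(JointMotion)

d <- cohensD(8.50, 4.71, 32, 5.27, 4.65, 33)
cat("d =", round(d, 2), "->", classifyD(d), "\n")
tt <- twoSampleTSummary(8.50, 4.71, 32, 5.27, 4.65, 33)
cat(sprintf("t(%d) = %.2f, p = %.3f\n", tt$df, tt$t, tt$p))
```

```
d = 0.69 -> moderate
t(63) = 2.78, p = 0.007
```

A moderate effect (*d* = 0.69): the clinical group squirms significantly
more. End to end on synthetic data — simulate a 5-minute session of one
clinical and one control subject, track, and quantify:

```r
profiles <- list(
  subjectProfile("exp_1", group = "experimental"),
  subjectProfile("ctl_1", group = "control"))
sim <- simulateSession(profiles,
  simConfig(nSubjects = 2, sessionLength = 5, frameRate = 10, seed = 42))
sim$stream
ms <- quantifySession(sim$stream, setNames(
  lapply(sim$slotMap$subject_id, sessionMeta, sessionLength = 5),
  as.character(sim$slotMap$persistent_id)))
round(pathLength(ms[["1"]])[1:4, ], 2)
```

```
SkeletonStream: 149425 joint samples, 5977 frames, 2 body slot(s), 299.9 s span
           minute_1 minute_2 minute_3 minute_4 minute_5
spine_base     2.15     3.34     3.37     2.41     3.84
spine_mid      1.62     2.29     2.43     1.64     1.97
neck           3.31     3.88     1.66     3.32     3.63
head           2.45     2.90     4.21     5.66     4.47
```

Each cell is metres moved by that joint in that minute (the stream has
fewer than 2 × 3000 frames because simulated occlusions removed a few
seconds). `compareGroups()` then yields the per-joint comparison table —
Levene F/p, group summaries, the gated *t*, df, *p*, *d* and its band —
and `rocTable()` the per-joint AUCs; `runPipeline()` wires the whole chain
(simulation or recorded CSV streams in, report TSVs out) behind a single
YAML-configurable call, and `exec/jointmotion` exposes it all as shell
subcommands (`simulate`, `quantify`, `compare`, `roc`, `kappa`,
`pipeline`).

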