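---
title: "Quantifying seated movement from multi-subject skeleton streams"
author: "JointMotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seated movement from multi-subject skeleton streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(JointMotion)
```

## The measurement problem

Hyperactivity is a core symptom of ADHD, yet its clinical assessment rests on
observer impressions that are known to be noisy and poorly standardized.
Marker-less depth cameras offer an unobtrusive alternative: a Kinect V2-class
sensor tracks up to six human bodies at once, reporting for each a 25-joint
skeleton with 3D coordinates (x, y in the image plane, z the distance to the
sensor, all in metres) at a nominal 30 Hz, with no device attached to the
child. JointMotion implements the analysis layer of such a system for
classroom-style sessions of seated subjects: it turns raw per-frame joint
coordinates into a per-subject **movement matrix** — for each analysed joint,
the distance covered in 3D space during each minute of the session — and runs
the group-comparison statistics used to validate the measure against observer
counts of "squirms in seat" and "leaves seat" behaviours.

The package deliberately consumes already-skeletonized joint streams in a
documented plain-text format (long CSV or JSON-lines); depth-image processing
and the device's proprietary capture format are out of scope.

## The 17-joint analysis set

The sensor reports 25 joints, but for seated subjects who are not presenting
their hands to the camera the four hand-region joints per side (hand, hand
tip, thumb) are tracked poorly, and of the lower extremity the ankle is
tracked much better than the foot. The analysis set therefore keeps 17
joints: the wrist represents each arm's distal end and the ankle each leg's.
`selectAnalysisJoints()` applies this rule; all report tables use a fixed
row order (trunk, left arm, right arm, hips and legs, spine shoulder) for
comparability.

## Persistent identities and gap repair

The device reports bodies in volatile slots 0–5 and loses a body whenever a
subject is occluded or leaves the field of view. `assignIdentities()`
reproduces the behaviour of the original capture software: skeletons are
numbered 1–6 in order of first detection and each identity's *location* is
remembered, so a skeleton that reappears near its remembered location
receives its old number.

Two details of that behaviour are under-specified and are fixed here as
package design choices:

* **The anchor.** "Location" is represented as an exponential moving average
  (half-life 2 s) of the spine-base position. A smoothed seat location is
  robust to fidgeting but still follows a subject who shifts their chair.
* **The re-identification radius** (`reidRadius`, default 0.5 m). Seated
  subjects in writing-pad chairs sit at least a chair width apart, so their
  seats are unambiguous at 0.5 m. Ties between equidistant anchors break
  toward the lower identity, for determinism.
* **Continuity.** A slot absent for longer than `maxInterpGap` (default
  0.5 s) is treated as lost; in addition, slot continuity is *spatial*: a
  slot whose detection jumps beyond `reidRadius` of its identity's anchor
  between consecutive sightings is treated as a fresh appearance, because
  the device hands freed slots to whichever body appears next. The converse
  limitation is intentional: a subject genuinely teleporting more than
  `reidRadius` between consecutive frames would be split into two
  identities — impossible for seated children at realistic frame rates.

Needing a seventh concurrent identity is a hard capacity error, mirroring
the sensor's six-body limit.

`interpolateGaps()` repairs short joint drop-outs (a crossed leg hiding an
ankle, say): runs of `not_tracked` samples bounded by observed samples and
spanning less than `maxInterpGap` are filled by linear interpolation per
coordinate and marked `inferred`, which is what the sensor SDK itself does
for occluded joints. Longer runs and runs touching a track end are left
missing — extrapolation would fabricate motion. Because the SDK interpolates
too, `inferred` samples count as observed in the kinematics by default;
`includeInferred = FALSE` excludes them for sensitivity analyses.

## Path length per minute

For one joint, consecutive observed samples define trajectory segments. A
segment is **valid** if both endpoints are observed and its duration does not
exceed `maxInterpGap`; longer spacings mean the subject was absent and the
spanned interval is excluded rather than bridged (bridging a 10 s absence
would register a spurious "teleport" distance). Each valid segment
contributes its Euclidean length to the minute bin containing its **later**
endpoint (bin *k* is [60*k*, 60(*k*+1)) seconds). Assigning by the later
endpoint counts every segment exactly once, so the minute values conserve
the total path length exactly — a property the test suite checks against a
brute-force oracle at 1e-9.

A minute in which a joint contributed no valid segment is reported missing
(`NA`), never zero: zero would fabricate stillness during occlusion, biasing
group means downward. Missing minutes propagate as exclusions through all
statistics. No temporal smoothing is applied before differencing — the
measure is the raw point-to-point distance sum; an optional centred
moving-average filter (`smoothWindow`) exists but is off by default, because
smoothing shrinks path lengths and its window would become an undocumented
scale factor on every reported value. For the same reason the package treats
the *absolute* movement magnitudes as instrument-specific: they depend on
the capture frame rate and the sensor's jitter spectrum, neither of which is
standardized, and files therefore always declare their units.

## The statistical battery

For two groups of movement matrices, `compareGroups()` produces one row per
analysis joint:

* **Levene's test** (mean-centred: a one-way ANOVA on absolute deviations
  from the group means) gates the variance assumption at `alpha` (default
  0.05).
* **Student's *t*** with pooled variance when homogeneity is not rejected,
  **Welch's *t*** with Welch–Satterthwaite degrees of freedom when it is.
  The sign convention is `t > 0` when the first group's mean is larger.
* **Cohen's *d***, unsigned, with the pooled SD weighting the group
  variances by their degrees of freedom (`weighting = "df"`); an
  equal-weight form (mean of the two variances) is provided for re-deriving
  published values whose per-group sizes are unknown. Magnitude bands:
  below 0.20 no relevant effect, 0.20–0.50 small, above 0.50 up to 0.80
  moderate, above 0.80 large. The printed band endpoints leave (0.50, 0.51)
  unassigned; values in that sliver are classified moderate.
* **ROC AUC** (`rocAuc()`), computed as the normalized Mann–Whitney U from
  midranks — identical to the area under the empirical ROC curve with exact
  tie handling. Bands: 0.5 chance, below 0.7 lower, 0.7–0.9 moderate, above
  0.9 higher accuracy; an AUC below 0.5 is reported as chance-level with an
  `inverted` flag rather than silently reflected.
* **Cohen's kappa** (`cohensKappa()`, unweighted, exact-agreement
  categories) measures dual-observer agreement on behaviour counts.

The default comparison unit is the **subject-minute**: every non-missing
minute of every subject is one observation, pooled per group. This mirrors
the degrees of freedom of the published per-minute tables (thousands of
minutes across ~30 subjects), at the cost of ignoring within-subject
correlation; `unit = "subject"` (session means, one observation per subject)
is the statistically conservative alternative and is exposed everywhere. No
multiple-testing correction is applied across the 17 joints, matching the
reporting convention the tables follow; `holm = TRUE` adds a clearly
labelled Holm-adjusted column as an extension.

Degenerate inputs are signalled, not hidden: zero pooled variance with equal
means gives `t = 0`, `d = 0`; with unequal means it gives an explicit
infinite-separation result; a kappa table where both observers are constant
is flagged degenerate.

## The session generator

`simulateSession()` replaces the camera for testing, calibration and power
analysis. Each joint follows a **tethered random walk**: an AR(1) process
around the joint's rest pose relative to the subject's seat, with
mean-reversion half-life 2 s. Seated children fidget about a fixed pose;
free Brownian motion would diffuse them away from their chairs, and the
tether also makes reappearance-at-the-seat realistic, which exercises the
re-identification logic.

The calibration is analytic. A 3-D Gaussian step with per-coordinate SD *s*
has expected norm (chi distribution with 3 df)

E‖Δ‖ = *s* · √2 · Γ(2)/Γ(3/2) = 2 *s* √(2/π) ≈ 1.5958 *s*,

so with *n* = 60 · frameRate steps per minute, a target intensity λ (metres
per minute) fixes the stationary per-coordinate step SD at
*s* = λ / (2 *n* √(2/π)). For the AR(1) with coefficient φ the stationary
step variance is 2σ²/(1+φ), giving the innovation SD σ = *s*√((1+φ)/2), and
the walk is started from its stationary distribution so the calibration
holds from the first minute. Additive observation noise ν contributes 2ν²
per coordinate to the step variance and is subtracted from the dynamic part,
keeping E[path/minute] = λ at any frame rate and noise level. The constant
is re-verified by Monte Carlo in the test suite before anything depends on
it. Two second-order effects are knowingly ignored: the small negative
lag-1 correlation of AR(1) steps (−(1−φ)/2 per coordinate, under 2 % at
10 Hz and above) affects only the *variance* of per-minute values, not
their mean; and per-minute intensity changes create a one-step transient at
minute boundaries.

Minute-to-minute intensity varies as an additive Gaussian effect
(`minuteSd`, default 25 % of the intensity, truncated at zero — negligible
truncation at the default 4 SD distance). `simulateTwoGroups()` shifts group
2's intensities by *d* times the total per-minute SD (minute-level variance
plus the analytic within-minute path-length variance, Var‖Δ‖ = (3 − 8/π)s²
per step) while both groups share the same absolute `minuteSd`. Per-minute
values are then equal-variance Gaussians to good approximation, so the
programmed *d* is recovered by `compareGroups()` and the binormal identity
AUC = Φ(d/√2) applies — the package's end-to-end acceptance property.

Occlusions arrive as a Poisson process per subject (default 0.3 events per
minute, exponential durations of mean 3 s — a child bending behind a
neighbour for a few seconds a few times per session), removing the body's
frames entirely; reappearing bodies take the lowest free device slot, which
is exactly the slot-churn behaviour the tracker must survive. Optional
per-joint drop-outs mark samples `not_tracked` for the interpolator.
Everything is reproducible bit-for-bit from the seed.

Default intensities encode the study conditions being emulated: trunk and
head joints around 2–3.5 m/min, elbows 6–10, wrists 13–17, ankles 8–9, with
the clinical preset uniformly above the control preset and medication
modelled as a single multiplicative factor 0.55 — reproducing the uniform
direction of the with/without-medication contrast. What the generator does
**not** emulate: correlated motion across joints of one limb, posture
changes, walking, sensor-specific depth noise spectra, or systematic joint
mislocalization during partial occlusion. Passing tests therefore validate
the pipeline's arithmetic and its statistical calibration, not the sensor's
fidelity on real children.

## Problem sizes used by the test suite

Simulation-backed checks are sized to be decisive yet quick, as the
package's own choice of problem size: calibration uses 50 replicates of
2-minute single-subject sessions at 30 Hz with `minuteSd = 0` (isolating the
calibration constant; minute effects are mean-zero by construction and
would only add sampling noise); type-I calibration uses 2000 replicates of
30-vs-30 minute samples drawn from the generator's stationary minute-value
distribution (`simulateMinuteValues()`, the analytic shortcut the
frame-level generator realizes); end-to-end recovery uses 34 subjects per
group in 30-minute sessions (1020 minute-observations per group) at 2 Hz,
asserting the across-joint mean of the recovered *d* within ±0.1 of the
programmed 0.8 and the mean AUC within ±0.03 of Φ(0.8/√2).

## Known limitations

* Per-minute pooling treats minutes of one subject as independent; with few
  subjects and long sessions this overstates degrees of freedom. Use
  `unit = "subject"` when inference, not reproduction, is the goal.
* Absolute path-length magnitudes depend on frame rate and sensor jitter;
  only within-study contrasts are interpretable without instrument
  calibration.
* The tracker assumes seated subjects: re-identification is by seat
  proximity, and a subject who swaps chairs during an occlusion will take
  over the other chair's identity.
* One stream is processed at a time; fusing two simultaneously recording
  devices is a manual choice of the better stream, not a data-level merge.
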