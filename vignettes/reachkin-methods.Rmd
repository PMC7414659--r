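---
title: "Methods: reach-to-target kinematics and their statistical battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reach-to-target kinematics and their statistical battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`reachkin` analyzes 3D reach-to-target movements recorded with an
optical motion-capture system in upper-extremity stroke rehabilitation
studies. This vignette documents the models, conventions and numerical
choices the package commits to, and what its validation does and does
not establish.

## The task and coordinate conventions

A seated subject reaches from a start target to one of twelve targets
arranged like a clock face (20 cm from the panel center) and back, with
a closed fist, at self-selected speed. The panel center is aligned with
the acromion of the tested arm and placed at fist-closed arm distance;
the start target sits at forearm distance from the panel center along
the line to the shoulder. A 20-marker upper-body set is tracked at
120 frames/s: C7, T10, suprasternal notch (CLAV), xiphoid (STRN), and
bilaterally acromion, upper arm, lateral epicondyle, forearm, radial
and ulnar styloids, first and second metacarpal heads.

Coordinates are right-handed, +Z vertical, +Y anterior (toward the
panel), +X to the subject's right; units are cm and seconds everywhere.
The endpoint marker is the second metacarpal head (the marker on the
metacarpal head of the index finger). Left-arm trials are mirrored
about the sagittal plane to a canonical right-arm configuration before
any angle is computed, so sign conventions are comparable across sides.

One deliberately open point in the protocol is whether parameters are
computed over the outbound reach only or the full out-and-back cycle.
Both modes are implemented (`phase` argument); the default is
`full_cycle`, because movement time is defined from movement onset to
end of a movement that runs start → target → start, and every output
table records which phase was used. Velocity-peak counts roughly double
between the two modes; they are not comparable across phases.

## Preprocessing

**Filtering.** Marker trajectories are low-pass filtered with a
4th-order zero-phase Butterworth (a 2nd-order filter run forward and
backward), cutoff 6 Hz by default — the standard conditioning for
120 frames/s upper-limb capture before numerical differentiation. The
series is extended by even (mirror) reflection before filtering; this
is exact for recordings that start and end at rest and lets the filter
average out boundary noise. The input is also centered about its mean
so a constant series passes through unchanged. The cutoff is
configurable; noiseless simulated data can skip filtering entirely
(`cutoff = NULL`), which is what the noiseless recovery tests do, since
any low-pass slightly clips the extremes of fast submovements (up to
~0.7° on joint ranges at the defaults).

**Speed.** Endpoint speed is the Euclidean norm of the
central-difference derivative of position (one-sided at the ends).

**Segmentation.** The analyzed movement is bracketed with a relative
speed threshold, 5% of peak speed by default: onset is the last
sub-threshold frame before the first crossing of 5% of the outbound
peak, and the end is the symmetric event after the last crossing of 5%
of the return-phase peak (for outbound-only analyses, the first
sub-threshold frame after the outbound peak, optionally gated on the
endpoint being within 2 cm of the target). First/last crossings rather
than the dips adjacent to the tallest peak are used so that fragmented
movements — where speed returns to near zero between submovements —
are not truncated. The out/return phases are separated at the apex,
the endpoint's most distant point from its starting position. A
relative threshold makes segmentation invariant to uniform speed
scaling; as the threshold shrinks the detected movement time converges
monotonically to the generating duration (at 5% a minimum-jerk profile
loses the ~5.9% of its duration below threshold at each tail — an
inherent property of threshold segmentation, not an implementation
error).

## The eleven parameters

Six endpoint parameters: movement time MT (s); trajectory directness
CurvI, the ratio of traversed path length to the straight-line distance
between the segment's endpoints (for a full cycle, whose endpoints
coincide, it is computed per half-cycle at the apex split and
averaged); peak velocity V_max (cm/s) and its timing T%V_max (% of
movement duration, ties to the earliest frame); the number of velocity
peaks NVP; and the log dimensionless jerk

$$\mathrm{LDJ} = -\ln\left(\frac{MT^3}{V_{max}^2}\int_0^{MT} j(t)^2\,dt\right),$$

with $j$ the second time-derivative of the (filtered) speed series,
i.e. jerk along the path. Several variants of this metric family exist;
the package fixes the duration-cubed, peak-speed-squared, natural-log
form and validates it against the closed form for a minimum-jerk reach:
$\int_0^1 (60 - 360\tau + 360\tau^2)^2 d\tau = 720$, so
DLJ $= 720/1.875^2 = 204.8$ and LDJ $= -\ln 204.8 \approx -5.322$. The
metric is dimensionless: rescaling amplitude or duration leaves it
unchanged (exactly so when the rescaled movement is sampled on the same
relative grid; across different grids the discretization of the third
derivative differs at the $10^{-3}$ level). Jerk is computed from the
filtered speed series, not raw positions, because third derivatives of
noisy 120 Hz positions are unusable unconditioned.

NVP counts local maxima of the speed profile with topographic
prominence of at least 5% of peak speed and at least 0.1 s apart.
Peak-counting criteria are rarely reported in the field; both settings
are configuration keys and are echoed in the report tables. With these
defaults, generated submovement counts of 1–4 are recovered perfectly
in noiseless trials and in ≥ 95% of trials at 0.05 cm marker noise.

Five joint/trunk parameters, replacing proprietary capture-suite models
with an explicit convention shared between the analyzer and the
simulator. The thorax frame has vertical axis from midpoint(T10,
xiphoid) to midpoint(C7, CLAV), lateral axis the inter-acromion line
orthogonalized against it, and anterior axis their cross product. The
shoulder is treated as a two-axis (universal) joint: the humerus
direction is expressed in the thorax frame and decomposed into
projection angles — flexion/extension in the sagittal plane,
abduction/adduction in the frontal plane, both zero for an arm hanging
along the thorax vertical; no axial humeral rotation is computed (no
reported parameter needs it). Frames where a projection degenerates
(humerus parallel to the decomposition axis) are flagged `NA`, warned
about, and excluded from ranges. Elbow flexion is the angle between the
upper-arm vector (acromion → lateral epicondyle) and the forearm vector
(epicondyle → midpoint of the styloid markers), 0° at full extension.
ShFE, ShAA and ElFE are max − min of these series over the analyzed
segment. Th is the transverse-plane rotation of the inter-acromion line
relative to its orientation at segment onset (range = max − min). The
wording of the thorax-rotation parameter in the field is ambiguous;
this onset-relative reading is the package's documented choice. TExc is
the peak displacement of the CLAV marker from its onset position; the
full 3D norm is used, since the transverse and sagittal planes jointly
span all axes. Missing marker frames are linearly interpolated up to
10% of a segment; beyond that the trial is refused rather than guessed.

All parameters are invariant to rigid translation and rotation of the
entire marker set (angles are relative; TExc and CurvI are norms of
differences).

Per-movement values are aggregated to subject × session × arm means
(medians optional) over the session's battery — 36 movements per arm
(12 targets × 3 repetitions) in the emulated design — before entering
the statistics.

## The statistical battery

**Correlation grids.** Spearman rank correlations between kinematic
aggregates and clinical outcome measures (FMA-UE, WMFT-FAS, WMFT-Time;
MAL scores can be included), each against total and proximal
(shoulder/elbow-item) score variants. The cross-sectional scope pools
pre- and post-intervention observations — two rows per subject, a
deliberate echo of the emulated study design whose non-independence is
acknowledged rather than corrected; the longitudinal scope correlates
post − pre changes, dropping (with a warning) subjects missing a
session. P-values come from `cor.test`; cells whose correlation is
undefined (constant column, too few pairs) are reported `NA` with a
warning rather than failing the grid. Holm step-down adjustment is
applied per grid by default (one family per scope; per-variant families
and no adjustment are options — the family definition is a reporting
choice the analyst must own). Magnitudes are labeled by the Hinkle rule
of thumb — negligible < 0.30 ≤ low < 0.50 ≤ moderate < 0.70 ≤ high —
with boundaries assigned to the higher class; published uses of this
rule sometimes state the boundaries both ways, so the tie policy is
fixed and documented here.

**Bootstrapped paired t-tests.** For small samples (n = 10 subjects at
the group level; 36 paired movements at the subject level, paired by
target and repetition since the target order is fixed and shared across
sessions), pre/post comparisons use the t statistic on paired
differences plus a nonparametric bootstrap over pairs, B = 1000 by
default, with percentile confidence intervals for the mean difference.
Two p-value constructions are offered. The *studentized* (bootstrap-t)
construction — comparing the observed t with the bootstrap distribution
of centered, re-studentized t statistics — is the default because it is
well calibrated at these sample sizes: measured type-I error 0.050 at
n = 10, B = 1000 over 1000 Gaussian-null replicates (the package's
calibration tests require [0.03, 0.07]). The *percentile* construction,
$p = 2\min(P(\bar d^* \le 0), P(\bar d^* \ge 0))$ with add-one
continuity, is retained as an option for comparability but measured at
~0.11 type-I under the same null, so it is not the default. Zero-
variance differences yield a degenerate result with an `NA` p-value
rather than a fabricated one.

**Effect sizes.** Cohen's d uses the pre-intervention SD as denominator,
d = (mean_post − mean_pre)/SD_pre, with the sign flipped for
decrease-is-better measures (WMFT-Time, MT, CurvI, NVP, Th, TExc) so
improvement is positive; magnitudes are labeled small/medium/large at
0.20/0.50/0.80.

**MCID flags and responders.** Per-subject improvements are flagged
when they meet or exceed the minimal clinically important difference
(boundary inclusive); a responder has at least one flagged measure. The
shipped MCID table (FMA-UE 5.25 points, WMFT-FAS 0.37, WMFT-Time 1.5 s,
MAL 0.5) holds literature-typical values and is explicitly
user-editable — MCIDs are population-specific.

**Non-paretic reference bands.** For each parameter, mean ± 1 SD of the
pooled non-paretic aggregates; a subject's significant pre-to-post
change whose pre and post means both lie inside the band is marked not
noteworthy, since the values are already comparable to unaffected-arm
performance.

## The synthetic-trial generator

The generator exists because raw study recordings of this kind are
rarely publishable; it provides data with the statistical and geometric
structure the analysis assumes, plus complete ground truth.

A reach is a composition of minimum-jerk submovements
$x(\tau) = A(10\tau^3 - 15\tau^4 + 6\tau^5)$ along the start–target
chord — the canonical smooth model of point-to-point reaching, with
submovement fragmentation as the impairment mechanism (it directly
generates the constructs the smoothness metrics measure). The return
phase replays the schedule time-reversed, so a k-submovement
configuration yields k velocity peaks per phase. Curvature is an
out-of-chord half-sine bump whose apex is `path_curvature_gain` × chord
length, chosen because it admits a closed-form/quadrature path-length
oracle. Trunk compensation translates the four trunk markers (and both
shoulders) along the reach direction and rotates them about the
vertical through the mid-acromion point, time-locked to movement
progress; the arm is then posed by two-link inverse kinematics
(upper arm acromion→epicondyle, distal segment epicondyle→MCP2) with a
planar-elevation convention — the elbow drops as far "down" as the
reach line allows — shared with the ground-truth angle computation.
I.i.d. zero-mean Gaussian noise (default 0.05 cm, typical optical
calibration residual) is added per marker, axis and frame. Trials are
pure functions of (configuration, geometry, target): the RNG is seeded
from the configuration and restored afterwards.

Ground truth records the generating movement window, chord length and
quadrature path length, per-phase submovement count, the CLAV-path
trunk excursion (equal to the injected translation when rotation is
zero; the two combine non-additively otherwise), the injected thorax
rotation, and joint ranges computed from the noiseless chain.

Defaults emulate the study conditions: 120 frames/s; 12 targets × 3
repetitions per arm and session; panel radius 20 cm. Where the
protocol gives no value the package fixes a documented assumption:
arm 60 cm (acromion–fist), forearm 25 cm, hand 8 cm, shoulder width
35 cm; per-phase movement durations 0.8–2.0 s (full cycles of
1.6–4.0 s); subject–panel distance $\sqrt{\mathrm{arm}^2 - r^2} - 1$ cm
so that all targets stay reachable by the arm alone with a 1 cm margin
(the physical protocol places the panel at full arm distance and lets
trunk motion make up the deficit; the simulator must keep the
no-compensation configuration feasible); 0.25 s of rest padding around
the movement. Cohort generation drives everything from a per-subject
latent impairment z ~ N(0,1): submovement count ⌈2.5 + z⌋ clamped to
1–4 (with per-trial jitter, SD 0.5), duration 1.2 + 0.25 z s, curvature
gain 0.35 + 0.15 z, trunk translation 8 + 4 z cm, trunk rotation
5 + 2.5 z°, all clamped to sane ranges; the non-paretic arm uses fixed
mild settings. Clinical scores observe the session's latent impairment
through measure-specific noise on each scale (reliability 0.85), and
`sim_linked_clinical()` instead ties one measure to a chosen kinematic
aggregate through a Gaussian copula at
$\rho = 2\sin(\pi r_s/6)$, so the expected Spearman correlation equals
its target — the generative oracle for correlation recovery (measured:
mean recovered $r_s$ 0.70 at target 0.70).

**What passing tests show — and what they do not.** The generator
reproduces the *structure* real impaired reaching data: fragmented
bell-shaped speed profiles, curved paths, trunk substitution,
plausible parameter magnitudes (MT ≈ 2.4 s, V_max ≈ 50–80 cm/s,
TExc ≈ 8–13 cm). It does not reproduce soft-tissue artifact, marker
occlusion/swaps, tremor or spasticity dynamics, inter-trial learning,
or the exact magnitudes of any particular study population (e.g. its
smoothness values are less extreme than severely impaired recordings).
Recovery and calibration results therefore validate the pipeline's
correctness and statistical behavior, not clinical conclusions about
any real cohort.

## Numerical choices and degenerate inputs

Ties in peak location go to the earliest frame. Angle computations
clamp cosines to [−1, 1] before `acos`. Quadrature uses `integrate`
at relative tolerance 1e-10; derivatives are central differences (exact
for affine signals, including the one-sided ends). Degenerate inputs
raise typed conditions (`reachkin_error_*`): all-zero speed, thresholds
never crossed, coincident directness endpoints, constant correlation
inputs, zero pre-intervention SD, fewer than two non-paretic
observations, missing markers beyond the interpolation tolerance.
Derived seeds stay below 2^31 and simulation code never perturbs the
caller's RNG state.

Validation problem sizes, chosen to exercise each claim at meaningful
resolution: the minimum-jerk analytic suite at 1000 frames/s; 200
seeded trials for submovement/joint recovery and 100 for trunk-excursion
recovery; 1000 replicates each for test calibration (n = 10, B = 1000)
and Holm family-wise error (66-cell grids, n = 20); 100 ten-subject
null cohorts (12 movements per subject-session) for the end-to-end
false-positive check; one 20-subject cohort with 50 copula draws for
correlation recovery.

## Known limitations

* C3D ingestion is not provided; marker data travel as long-format CSV
  (`write_markers_csv()` / `read_markers_csv()`, with an alias table
  for common label synonyms). No C3D reader is available in this
  package's dependency footprint, and the CSV interface is lossless.
* No marker gap-filling beyond short linear interpolation, no swap
  correction; inputs are assumed reconstructed.
* No axial humeral rotation, wrist or finger kinematics; no
  musculoskeletal modeling or EMG.
* Cross-sectional pooling of pre/post observations ignores their
  within-subject dependence, by design of the emulated analysis; treat
  those grids as descriptive.
* Subject-level inference resamples movements within subject; with one
  session per time point there is no subject-level replication to do
  better.
* No regression or mixed-effects modeling, no responder clustering, no
  imputation of missing sessions.

The interface for scripted use is R itself: the pipeline is one
configured call (`run_reach_pipeline(pipeline_config(...))`), and
`scripts/acceptance.R` shows the pattern for non-interactive runs.
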