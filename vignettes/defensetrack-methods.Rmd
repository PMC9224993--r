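---
title: "Methods: behavior classification, assay scoring, and photometry processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavior classification, assay scoring, and photometry processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(defensetrack)
```

This vignette explains the models and procedures behind `defensetrack`: the
kinematic behavior definitions and how they are computed, the assay-scoring
conventions, the photometry correction, what the synthetic session generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## Kinematics

Pose input is a per-frame table of nose, left-ear, right-ear and tail-base
coordinates with tracking likelihoods, at a nominal 30 frames/s. Coordinates
are converted to cm with the origin at the arena's lower-left corner.
Frames whose likelihood falls below `likelihood_min` (default 0.9) are
replaced by linear interpolation between the nearest confident frames and
flagged; a bodypart with no confident frame at all is an error rather than a
guess.

The *head* point is the centroid of the nose and both ears. A single
bodypart definition of the head (the nose alone) would inherit every nose
dropout; the three-point centroid is robust to any one of them. Positions
are smoothed with a centered boxcar over `smoothing_window` frames (default
5, about 0.17 s) *before* differentiation, and speeds are forward
differences of the smoothed positions. Smoothing before differentiation
matters because the freezing threshold, 0.25 cm/s, corresponds to less than
0.01 cm of per-frame movement at 30 frames/s — far below the jitter of any
video tracker. The body length is the session median of the nose–tail-base
distance, which is insensitive to the minority of stretched frames. When a
threat reference point is defined, the signed velocity toward the threat is
`−d(distance to threat)/dt`, positive while approaching; note this is a
*radial* quantity, so lateral movement near the threat also contributes to
it.

Speeds are invariant to translation, rotation, and (linearly) to the
cm-per-pixel calibration; smoothing can never increase the maximum speed.
These are tested properties.

## Behavior classification

Four behaviors are defined purely kinematically, with thresholds collected
in `classifier_params()`:

| behavior | condition | minimum duration |
|---|---|---|
| freeze | head **and** tail-base speed < 0.25 cm/s | 0.33 s |
| stretch-attend | nose–tail distance > 1.2 body lengths, tail-base < 1 cm/s | — |
| approach | signed velocity toward threat > 3 cm/s | — |
| escape | signed velocity toward threat < −3 cm/s | — |

Conditions are evaluated per frame and maximal runs of TRUE frames become
bouts; a single supra-threshold frame splits a bout, with no tolerance
frames. `postprocess_bouts()` optionally merges same-label bouts separated
by less than `merge_gap_s` and drops bouts shorter than `min_dur_s`; it is
the sensitivity-analysis knob and defaults to doing nothing.

`classify_session()` — the entry point the analysis scripts use — applies
one non-default postprocessing step: approach and escape bouts shorter than
0.15 s are dropped. The rationale is concrete: interpolating a
low-likelihood frame across a velocity corner (a stop, a turn) displaces
the head estimate by a fraction of a centimeter for one or two frames,
which is enough to cross the 3 cm/s signed-velocity threshold briefly.
Locomotor runs at 15–25 cm/s last hundreds of milliseconds; sub-150-ms
supra-threshold blips are tracking artifacts, not behavior. Freezing
already carries its own 0.33-s minimum and needs no debounce.

The escape-velocity metric reported per bout is the mean tail-base speed
during the bout, so it reflects whole-body flight vigor rather than head
movement.

`bout_robustness()` recomputes percent-time-freezing per session under two
minimum bout durations (0.33 s and 1 s by default) and reports the Pearson
correlation across sessions. With realistic heavy-tailed bout durations the
two scores differ only through the minority of bouts between 0.33 and 1 s,
so the correlation should be near 1; a cohort whose bouts all fall inside
that window makes the second vector identically zero, and the function
reports an undefined correlation with a diagnostic instead of a number.

## Assay scoring

Zone maps are named polygons in arena coordinates. Defaults follow the
standard conventions: open-field corners are squares of a quarter side
length and the center is the central half-side square; the latency-to-enter
box has a 13 × 7 cm burrow in one corner and a holding zone in the opposite
corner; the 70-cm predator corridor defines the threat zone as the third
nearest the rat wall and the safe zone as the third nearest the safe wall;
the two-chamber place-test box splits in half. Zone membership uses the
head centroid and closed polygons — a point exactly on the boundary counts
as inside. Zone entries are debounced: an entry requires 0.2 s of sustained
presence, so a single-frame boundary graze does not count.

Latency-to-enter trials start at barrier removal; the latency is the first
head entry into the burrow polygon, and a trial without entry before the
60-s limit scores 61 s. Trial blocks alternate laser OFF/ON starting with
OFF, five trials each, and the per-animal score is the ON-mean minus the
OFF-mean. Burrow-preference screening passes an animal only when burrow
time *strictly* exceeds the time in each of the other three corners; an
exact tie fails. Epoch-based scoring (`epoch_metrics()`) computes each
metric separately within ON and OFF epochs — counts are reported per
condition, not rates — and the elevated-plus-maze protocol analyzes only
the first four of its five 2-min epochs, which is exposed as the
`n_epochs` argument.

## Photometry

The recording interleaves a 470-nm calcium-dependent channel with a 405-nm
calcium-independent reference at a nominal 20 Hz total; the per-channel
rate is read from the timestamps, never assumed. Each signal sample is
paired with its nearest reference sample in time — its multiplexing
partner. Averaging the two surrounding reference samples instead would put
the same reference noise into two consecutive corrected samples and color
the residual (lag-1 autocorrelation around 0.2–0.3 in noise-only
simulations); with nearest-sample pairing the corrected, z-scored residual
of a transient-free recording is white.

Correction fits `signal ≈ a·reference + c` by ordinary least squares over
the whole session and takes `dF/F = (signal − fit)/fit`. Because bleaching
and motion artifacts enter both channels multiplicatively through the same
slow processes, the fitted series tracks them and the fractional residual
isolates calcium transients. A Theil–Sen variant (median of slopes over
subsampled pairs) is available for artifact-heavy sessions. The z-score
window is the whole session by default and uses the sample standard
deviation; both choices are recorded in the output attributes. No low-pass
filtering is applied. Behavior frames are assigned the nearest photometry
sample within one sample period; frames outside coverage are flagged
missing rather than extrapolated.

Event analyses operate on the frame-aligned series: ±5-s windows around
bout *onsets* (onset rather than offset, since the onset is the decision
point; events too close to the recording edges are dropped and counted),
1-s post-entry means for maze-arm entries, tuning curves over 10
equal-width bins of distance from the safe wall restricted to approach or
escape bouts, and safe-third versus threat-two-thirds zone means. The
tuning correlation is reported two ways: the Pearson correlation of the 10
bin means against the bin centers (matching how such curves are presented,
with empty bins excluded pairwise and flagged), and a sample-level
correlation over all masked frames, which weighs every sample equally and
is the better-powered estimator for per-session sign questions. The zone
means use the exact thirds partition, so the occupancy-weighted
recombination of the two zone means equals the whole-corridor mean to
machine precision — a tested invariant.

## Statistics

Group comparisons are two-tailed t-tests on per-animal contrast scores (ON
minus OFF, drug minus vehicle). Unpaired tests use the classical
pooled-variance form with `df = n1 + n2 − 2`, which is the convention these
assays report. Normality screening uses the Lilliefors statistic (the
Kolmogorov–Smirnov statistic against a normal with estimated mean and sd)
with a Monte-Carlo p-value: 10,000 seeded normal samples of the same n,
cached per sample size. The Monte-Carlo null is exact up to simulation
error at any n, unlike table approximations. Multiple comparisons use
Benjamini–Hochberg. One property worth noting: BH-adjusted values are not
themselves p-values, and re-adjusting them changes them — the adjustment is
monotone and capped at 1 but not idempotent.

Histology count fractions are computed two ways, since pooled counts and
per-animal means genuinely differ: `pooled` divides summed overlap counts
by summed denominator counts; `per_animal_mean` averages per-animal
fractions, excluding (with a warning) animals with a zero denominator.
Lateral and ventrolateral column counts are pooled into a combined region
before dividing.

## The synthetic session generator

The generator exists so that every downstream stage has a test surface with
known truth. A session is a semi-Markov chain over behavior states —
locomote, freeze, stretch-attend, approach, escape, burrow dwell — in which
every special state alternates with a short "pause" hub state (slow
ambling at 1 cm/s). Dwell times are exponential except freezing, which is
log-normal (median 2 s, log-sd 0.8) so that the bout-duration robustness
analysis sees a realistic heavy-tailed distribution.

The central design problem is that the planted labels must be recoverable
from the emitted trajectory *by the package's own kinematic formulas* to
within one frame. Three mechanisms make that exact rather than
approximate:

1. **Analytic boundary shifts.** The smoothed forward-difference speed at
   frame *i* is the mean of the raw per-frame speeds over a window around
   *i*, so for a transition between two known speeds the frame at which a
   threshold is first crossed can be computed in closed form. The
   generator shifts each raw motion transition by exactly that offset, so
   the classifier's crossing lands on the planted boundary.
2. **The pause hub.** Because every threshold crossing is a transition
   between a special state and the 1-cm/s pause, the speeds on both sides
   of every boundary are known constants and the shifts above are
   well-defined. The pause ambles at constant speed along straight
   segments with semicircular turnarounds — the speed never dips, so the
   smoothed speed near a freeze boundary cannot graze the 0.25-cm/s
   threshold early.
3. **Head-pivot turning.** Reorientation rotates the body about the head
   centroid. The head does not move during a pivot, so orienting toward
   the rat never produces signed velocity toward it, and rotations are
   additionally delayed after a freeze so the swinging tail-base stays out
   of the freeze-offset smoothing window.

Stretch-attend bouts fix the tail-base, extend the nose along a safe
direction at 8 cm/s timed so the 1.2-body-length crossing lands on the
planted onset, hold at 1.35 body lengths with a slow radial nose bob (so
the posture is never classified as freezing), and retract symmetrically.
In the corridor the stretch runs laterally and, like locomotion, is
restricted to the far two-thirds of the corridor: the signed velocity is
radial, so fast lateral motion close to the rat would otherwise cross the
3-cm/s run threshold. In the plus maze the stretch snaps to the arm axis;
a bout whose heading cannot be aligned, or whose stretched pose would not
fit inside the arena, is degraded to a pause and the planted truth updated
— the truth always describes what was actually emitted.

Emitted bodyparts get Gaussian tracking jitter (0.005 cm), Beta(20, 1)
likelihoods, and occasional glitches (probability 0.01 per bodypart-frame)
that teleport the coordinate to a random arena location with likelihood
below 0.6, exercising the interpolation stage. Bodyparts pressed against a
wall are clamped into the arena polygon, as an occluded marker would be;
the head path itself always stays inside, and clamping can only shorten
the nose–tail distance, so it cannot create a classifier condition.

Photometry is synthesized at the pair level: both channels share a
double-exponential bleach and an AR(1) motion artifact (τ = 0.3 s, 2%
amplitude), while Poisson calcium events — convolved with a
0.1-s-rise/1-s-decay kernel, 5% peak dF/F — enter the signal channel only.
The baseline event rate is 2 Hz, representative of population-level
recordings where fluorescence fluctuates continuously. In the corridor the
rate is modulated linearly by distance to the threat with configurable
sign: `+1` raises the rate near the rat (the canonical pattern), `−1`
raises it far from the rat (the avoidance-like pattern), with 80%
modulation depth. The modulation can be gated to specific behavior states;
gated modulation begins 1.5 s *before* each gated bout, reflecting
activity that ramps up ahead of flight initiation — without that lead the
1-s indicator kernel would lag a 1–2-s escape so much that the escape-gated
spatial profile inverts.

What the generator does **not** emulate, and what passing tests therefore
do not show about real data: real tracking jitter is larger and
state-dependent (the 0.25-cm/s threshold on real video depends on the
tracker and smoothing); real behavior transitions are graded rather than
piecewise-constant, so real bout boundaries are intrinsically fuzzier than
one frame; posture is rigid here (no body bends, gait or grooming); real
photometry artifacts can be sharper than AR(1) and bleach can drift
non-monotonically; and no attempt is made to model the behavioral
*sequencing* of real threat encounters beyond the state weights. Exact
ground-truth recovery demonstrates the correctness of the analysis code,
not the field validity of the thresholds.

## Problem sizes and tolerances

The standing in-silico experiments use 40 ten-minute sessions for the
bout-duration robustness analysis (heterogeneous freezing propensity drawn
uniformly from 10–60% of session time), 20 two-minute corridor sessions
for label-recovery checks, 10 ten-minute sessions for transient-trace
recovery (requiring r > 0.95 per session against the planted trace, with
the raw signal strictly worse), and 20 ten-minute sessions per tuning sign
for spatial-tuning recovery. These sizes give stable verdicts while
keeping the whole suite fast. Statistical routines are verified against
brute-force formula implementations at 1e-9 over a thousand random
instances; the Lilliefors Monte-Carlo null reuses one seeded 10,000-sample
table per sample size. Boundary-recovery tolerance is one frame
everywhere, which is the intrinsic quantization of frame-sampled
behavior.

## Known limitations

Jump counting is not computed kinematically — no defensible kinematic
definition separates jumps from rears in 2-D pose, so jumps enter only as
an optional manual annotation. The pose reader consumes the CSV layout the
generator writes (plus a calibration argument); HDF5 containers are out of
scope. The Theil–Sen fit subsamples pairs for tractability and is
seed-stable rather than exact. Pupil measurements, hardware control, and
multi-animal tracking are out of scope.
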