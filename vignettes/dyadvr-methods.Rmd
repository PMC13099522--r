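---
title: "Methods: dyadic VR interaction metrics in dyadvr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic VR interaction metrics in dyadvr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadvr)
```

# The measurement model

`dyadvr` analyzes trials in which two agents move through a circular arena
of radius 100 VR units, logged at 10 Hz as frame-aligned series of position,
heading, forward speed and turning speed. All analyses assume kinematic
point-agents with an orientation: the logged position is taken to be the
body center, the body axis is the heading, the mouth is a point half an
avatar length (12.5 units) ahead of the center, and body geometry enters
only through the avatar length (25 units) and the collision model described
below. Angles are degrees, counterclockwise from the +x axis, wrapped to
(−180°, 180°].

A relative bearing is the angle from an observer's heading to the
observer-to-target direction, with the sign chosen so that **negative
bearings put the target on the observer's left**. This makes the left
monocular field the interval [−135°, −30°), the binocular field [−30°, 30°]
and the right field (30°, 135°], together tiling the 270° the three VR
screens cover; the remaining 90° behind the fish is the blind spot. The
stated endpoint conventions (left closed-open, binocular closed, right
open-closed) give every bearing exactly one label; the source ranges share
endpoints, so some convention is required and any choice differs only on a
measure-zero set.

## Per-frame classifiers

**Attack posture.** A frame counts when the forward ray from the mouth
along the heading intersects the disk of radius 25 units centered on the
opponent's body center. The test is exact ray–disk geometry (inside the
disk, or positive projection with perpendicular miss distance at most the
radius), so it is invariant under global rotation and translation — a
property the tests verify directly.

**Bites.** The VR rig delegates collision to a 3D physics engine whose
collider shapes are not part of the logs, so the package models the bitable
"mid-body" as the central third of the body axis with a lateral half-width
of 2 units; both parameters are exposed in `arena_config()` and should be
read as a 2D stand-in for the engine's collider. A candidate collision
requires the biter's mouth point within that region **and** an approach
inclination within ±75° of the perpendicular to the opponent's body axis
(equivalently, at least 15° off the axis itself — a parallel, glancing
contact is not a bite). Events are rising-edge: a bite is scored at frame t
only if no candidate existed at t−1 for the same ordered pair, so an
n-frame contact counts once.

**Near / center occupancy.** Near uses distance ≤ 50 (the boundary counts
as near); center occupancy uses strict |pos| < 70. Both boundary choices
are measure-zero in continuous data and are fixed here for determinism.

## Approach episodes

The mutual-distance series is segmented at its local extrema. Plateaus
collapse to their first frame; a monotone run that reaches either end of
the series makes that endpoint an extremum, so peaks and valleys strictly
alternate. Extremum detection takes an optional prominence threshold but
defaults to zero — the distance series is analyzed unsmoothed.

Within each peak-to-valley window, a fish's candidate episodes are the
maximal frame spans in which the opponent stays inside its ±90° front
cone. A candidate becomes an episode when it spans at least 3 frames (a
configurable floor that suppresses single-frame artifacts at 100-ms
sampling), the distance is non-increasing with a strict net decrease over
the span, and the fish's span-mean speed strictly exceeds the opponent's.
Exact speed ties are assigned to no one. "Kept reducing" is implemented as
non-increasing per frame with a strict net decrease, rather than strictly
decreasing per frame, which is too brittle against sampling jitter.

Because the facing spans of the two fish can partially overlap inside one
window, the per-frame approacher assignment could in principle be claimed
twice. The package resolves this by accepting candidates in start order
and trimming a later overlapping candidate to begin after the accepted one
ends, then re-checking all three conditions on the trimmed span. The
result is a partial function from frames to at most one approacher, which
the tests verify on batches of random synthetic dyads. An episode's
`remaining_distance` is the distance at its last frame, and
`terminal_bite` flags a bite by the approacher anywhere within the span.

## Attraction

Attraction compares the observed mean inter-fish distance against a
shuffled null: one fish's position series is permuted uniformly over whole
frames (never blocks or rotations), 10 times by default, and the statistic
is (mean(d_shuffled) − d_real)/mean(d_shuffled). Which fish to shuffle is
not fixed by the definition; the package shuffles fish b by default and
offers shuffling fish a or averaging the statistic over both choices. The
permutations are driven by an explicit seed, and the caller's RNG state is
restored afterwards. A time-constant partner makes every shuffle a no-op,
so the statistic is exactly zero — the tests assert identity, not
approximate equality.

One dynamical caveat, documented because the synthetic generator exposes
it: attraction measures proximity *relative to the pair's own spatial
occupancy*. Two agents glued into a tight mutual orbit occupy a small
cloud, so shuffling barely increases their distance and the statistic
saturates — single orbiting trials can even go slightly negative because
the orbit holds them at anti-correlated positions on opposite sides of a
common center. The statistic is therefore most informative in the weak-to-
moderate coupling regime where the pair tracks while still roaming, and
the package's monotonicity checks operate there (gains 0, 0.05, 0.2).

## Eye-use statistics

LEP, FBVP and REP share one denominator — left + right + binocular frame
counts — so they sum to 100 whenever any visible frame exists; blind
frames never enter. LEI = (N_left − N_right)/(N_left + N_right) uses
monocular frames only. Degenerate sets (all blind; no monocular frames)
yield `NA`, and missing values propagate as missing into group statistics,
never as zeros. Distance-resolved profiles bin frames by
floor(distance/10) into 20 bins covering [0, 200); empty bins are `NA`.
Episodes split by terminal proximity at ≤ 20 units (just under one body
length: contact range) and > 100 units (the arena radius), with the
interval between deliberately in neither class.

These are field-of-view occupancy measures: a frame with the opponent in
the ±30° frontal sector says the opponent *could* be seen binocularly, not
that binocular fusion occurred.

# Transfer entropy

Directional influence is estimated as discrete plug-in transfer entropy,
T(P→Q) = H(Q_t | Q_hist) − H(Q_t | Q_hist, P_hist), with history length
L = 1 frame (one 100-ms step) for both series, computed from empirical
joint frequencies with 0·log 0 = 0 and clamped at zero against floating
round-off. Logarithms are base 2; the base is a free choice (all
comparisons within an analysis are base-invariant) and bits are the most
interpretable unit. No bias correction is applied: at the trial length of
18000 frames and alphabet sizes 4–5 the plug-in bias is far below the
effect sizes of interest, and the package's null checks (independent pairs
at n = 10⁵ staying under 0.001 bits) bound it empirically.

Three symbolizations feed the estimator:

- **Merged ethogram (K = 4).** Symbol t combines the signs of
  speed_t − speed_{t−1} and of the wrap-corrected heading change
  heading_t − heading_{t−1}. The source definition covers only increase
  and decrease; a zero change is mapped to '+', a convention covered by a
  dedicated test. The output is one shorter than the input.
- **Speed and turn (K = 5).** Each series is cut at its own 5th, 35th,
  65th and 95th percentiles (linear-interpolation quantiles, boundary
  values to the lower bin — "at or below the lowest 5%"). A constant
  series degenerates to a single occupied level and, being constant,
  carries zero transfer entropy.

ΔTE = T(P→Q) − T(Q→P) is antisymmetric by construction, and the estimator
inherits this exactly (both directions are computed from the same counts).
The estimator is validated against an independent brute-force evaluator of
the conditional-probability form — exhaustively over every ordered pair of
sequences at sizes where full enumeration is feasible (all binary pairs of
length 5 and 6, all ternary pairs of length 4) and over randomized batches
of longer sequences, including L = 2. The full cross product at length 12
over a ternary alphabet (≈ 3×10¹¹ ordered pairs) is combinatorially out of
reach for any implementation; the randomized batches cover that regime.

# The shock-protocol simulator

The stimulation schedule is reconstructed as piecewise-constant voltage
segments per fish. From t = 0 both fish receive 0.5 V for 300 ms at the
start of every 1000-ms cycle, phase-locked to trial start. A bite inserts
a 100-ms 4-V segment for the bitten fish — overriding any overlapping part
of a mild pulse (higher voltage wins), with the remainder of the pulse
continuing — and suppresses the biter's periodic pulses for 120 s.
Suppression removes pulses; it never phase-shifts the cycle, so pulses
resume on the global phase. Three situations the protocol description
never addresses are fixed as conventions: a repeat bite inside an open
relief window restarts the window (the union of per-bite windows); mutual
same-frame bites shock and relieve both fish; and a pulse truncated by the
trial end keeps its delivered portion. Traces are guaranteed
non-overlapping and time-ordered, with floor(length/period) pulses in a
bite-free trial.

# The synthetic generator

`generate_dyad()` emulates the statistical structure the analyses assume,
not fish biomechanics. Per frame, each agent turns by
attraction_gain × wrap(θ_opponent − heading − lateral_bias) plus Gaussian
heading noise, then advances along its heading; fish b's speed mixes fish
a's previous-frame speed with weight coupling_gain into its own autonomous
speed. Defaults are the study's trial conditions: 18000 frames at 100 ms,
starts at (50, 0)/(−50, 0) facing +y (side by side, parallel), base speed
20 units/s with speed noise SD 5 and heading noise SD 10°/frame — chosen
once as a plausible adult-zebrafish cruising regime in arena units, and
kept fixed. Walls either steer the agent toward the center (default) or
reflect its heading; in both modes positions stay strictly inside the
arena. Positive lateral_bias relaxes the preferred bearing to the left of
the opponent, producing positive LEI; coupling_gain > 0 produces positive
speed-TE a→b; attraction_gain > 0 produces positive attraction. All
randomness flows from one seed through R's default Mersenne-Twister, and
the caller's RNG state is untouched.

What the generator does **not** emulate: tail kinematics, body bending,
collision pushback, wall-following behavior, fatigue or motivational
state, and the heavy-tailed burst-and-glide speed profiles of real fish.
Passing recovery tests therefore demonstrates that the estimators detect
the structure they claim to detect under controlled conditions — not that
real trials contain that structure.

`generate_scripted_approach()` builds deterministic single-approach
fixtures: the approacher closes linearly from a start to a stop distance
on a static target while its bearing follows a prescribed profile —
right-eye-then-binocular ending in a bite-range contact, or persistent
left-eye ending short — giving exact ground truth for episode boundaries,
view sequences and terminal bites. `generate_coupled_symbols()` produces
the copy-with-probability-c channel whose true transfer entropy is
available in closed form (`coupled_symbols_te()`), enabling quantitative
estimator checks rather than sign checks only.

# Group statistics

Condition contrasts use the Wilcoxon signed-rank test on per-unit paired
values; group contrasts use the rank-sum test. The harness enforces the
unit-of-analysis convention — one averaged value per fish or per pair —
by aggregating duplicate unit/condition records before testing, and uses
exact small-sample p-values whenever the data allow. Identical paired
samples leave no signed differences to rank; that degenerate case reports
p = 1. Tests are two-sided.

The effect size is E = (μ₁ − μ₂)/σ. "Based on both populations" admits two
readings; the package defaults to the population SD of the concatenated
samples and exposes the classical pooled within-group SD as an option. The
two coincide when group means are equal, and published values alone cannot
disambiguate them; the choice is therefore documented rather than hidden.
No multiple-testing correction is applied, matching the analysis the
package reproduces.

# Numerical conventions and problem sizes

- All angle arithmetic wraps to (−180°, 180]; 180° is preferred over
  −180°.
- Trial CSVs are written at 6 decimal places; a written trial re-reads
  bit-identically at that precision, and writing it again is idempotent.
- Validation is report-only and total: any input yields a violation table,
  never an error.
- Stochastic test sizes were fixed when the tests were designed: the
  attraction null uses 200 independent-walk trials at the full 18000-frame
  length; gain-monotonicity and lateral-bias recovery use 100 replicates
  per condition at 3000 and 2000 frames respectively, lengths at which the
  per-trial estimators are already stable; the rank-test type-I
  calibration uses 10⁴ replicates of n = 20 per group, where the exact
  test's discrete achievable levels sit close to the nominal 0.05.

# Limitations

- The collision model is a 2D approximation with invented mid-body
  parameters; absolute bite counts on real logs depend on how closely
  those parameters match the rig's collider, though rising-edge counting
  and the inclination rule do not.
- Whether the logged position of a real trial is the head, centroid or
  mouth is a property of the deposited data, not of the package; the
  body-center assumption is configurable but must be checked against the
  archive before absolute geometric statistics are compared.
- The plug-in TE estimator is consistent but biased upward at short trial
  lengths; comparisons should be within-design, between conditions of
  equal length.
- The eye-field indices quantify where the opponent sits in the visual
  field, not eye movements or binocular fusion.
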