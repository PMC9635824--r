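---
title: "Methods: quantifying microtubule retrograde flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying microtubule retrograde flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mtflow)
```

This vignette explains the models and procedures behind `mtflow`, the
choices made where several reasonable implementations exist, and what the
synthetic benchmarks do and do not demonstrate about real data.

## The measurement problem

Microtubule retrograde flow (MT-RF) is the bulk somal drift of the
microtubule array inside a neurite, read out in three complementary ways:

* **pulse-chase**: a photoconverted (or photoactivated) tubulin patch is a
  fiducial painted onto the array; its arc-length position over time gives
  the flow speed directly;
* **CAMSAP3 puncta**: minus-end-binding protein puncta serve as endogenous
  fiducials whose kymograph line slopes encode the same speed;
* **EB3 comets**: plus-end comets travel at polymerization speed
  (12–18 um/min), far above MT-RF, so they report microtubule *orientation*
  rather than flow.

All three run through kymographs: matrices with rows = time frames and
columns = one pixel of arc length along a traced path, oriented soma-left.
Retrograde speeds are positive throughout the package; the simulators use
signed drifts (negative = toward the soma) so that a generator parameter
of `-0.53` um/min and a recovered FlowMeasurement of `0.53, retrograde`
describe the same motion.

## Registration

Low expression levels keep these movies at single-digit signal-to-noise,
which defeats generic registration plugins; the package therefore uses the
dedicated translation-only procedure. Intensities are first capped at
`mean + 6 SD` (both over all frames and pixels; a per-pixel variant is
available) so that a handful of very bright pixels — for example signal
relocalizing to the soma — cannot dominate the correlation. The shift of
each frame against the reference maximizes Pearson correlation over the
cyclically rolled frame. The search has a coarse stage (the 8 compass
directions probed at radius 1, 2, ...; stopped when the same direction wins
five consecutive radii) and a refinement stage (per-dimension 1-px walks
with a 2-px look-ahead). Coordinate descent alone can stall one diagonal
step short of the optimum, so refinement finishes by re-probing the 8
radius-1 neighbours until the shift is an 8-neighbourhood maximum; with
this polish the hill-climb matched an exhaustive ±10 px search in 200/200
seeded low-SNR trials (the suite asserts ≥ 99%).

Each frame's best shift seeds the next frame (drifts are gradual), rolled
frames avoid zero-padding artifacts during the search, and written output
zero-fills the wrapped margins. The reference frame is replaced by the
current registered frame when its correlation drops at least 2 SDs below
the running mean of accepted correlations — a drop usually means the cell
changed shape, making a fresher reference better. Whether the original
criterion was one-sided is not documented; the package implements the
drop-only rule (a correlation *above* the mean is not evidence of a
morphology change) and exposes `switch_both_directions` as a toggle. In
slice mode a new reference is additionally taken every three frames.

## Neurite tracing

Per frame: (1) the soma is found by grey-opening the frame with a disk
(default radius 10 px — wider than a neurite, narrower than the soma),
taking Scharr edge magnitude, Otsu-thresholding the edges and filling the
enclosed region; the fill reaches the outer flank of the gradient band, so
one 4-connected erosion recentres the boundary before the largest
component is kept. (2) The segmentation threshold is seeded as the lowest
threshold whose soma component on the *grey-opened* frame matches the
edge-derived soma area within 5%. The published description compares "the
soma with the same size as the edge analysis", which is ambiguous when
neurites are attached to the soma component; performing the area match on
the opened frame — where the opening has removed the neurites — is the
reading that makes the comparison well-posed. The threshold then rises in
steps of 1% of the dynamic range, skeletonizing each step, and the value
one step before the first loss of ≥ 5 skeleton pixels is returned.
Loss is counted against the previous step (a cumulative toggle exists;
the per-step reading matches "a step before ... were lost"). (3) Detached
segments are bridged back by a 1-px line from their soma-closest point to
the nearest soma-connected point whose bearing lies within 45° of the
segment's own principal axis — the direction constraint prevents capture
by a wrong nearby neurite. (4) The dilated soma is removed, the rest
skeletonized (Zhang–Suen thinning; thinning retracts free line ends by up
to 2 px, hence a 3-px root-adjacency tolerance), and branches are built as
root-to-tip paths. Terminal subbranches under 1 um are pruned; neurites
with fewer than 40 skeleton points are dropped; at a branch point the
continuation is accepted only when the emerging branch's median intensity
is within [0.5, 2] of the incoming one ("similar range" is not quantified
in the source description; a factor-two band is the package's choice);
across frames, branches overlapping ≥ 70% (share of one branch's points
within a 1-px dilation of the other) under a different origin are
excluded.

## Kymograph readouts

`sample_kymograph()` takes, per frame and path point, the maximum
intensity across an odd sampling width (default 11 px) perpendicular to
the local tangent (5-point central difference), nearest-pixel sampled —
no interpolation, preserving max semantics. Neurite length walks each
thresholded row from the soma and stops one pixel before the first
unthresholded pixel; the first and last time rows are forced into the
thresholded set so that transient dimming becomes interior holes, which
are then filled (a 1-step dilation before filling is the variant used for
CAMSAP3/flow kymographs). A consequence worth knowing: a dropout fully
enclosed by thresholded pixels is filled and does *not* truncate the
length, while a dropout open to the tip-side border does. Two median
pre-filters are implemented (2×2, and 1×5 across position only, which
avoids smoothing across time); which one applies follows the experiment
type, and the choice is an explicit argument. When no manual threshold is
given, Otsu's threshold on the kymograph is the default — a supplied
manual value always wins, since the original analyses thresholded
manually.

## Flow quantification

`track_patch()` automates what was manual midpoint tracing: per frame the
corridor profile is background-subtracted (row median), smoothed with a
symmetric 5-column mean (symmetric, so it cannot bias the centroid, but it
keeps noise columns out of the region), and the position is the
intensity-weighted centroid of the contiguous region above 25% of the
local peak, searched within ±3 um of the previous position. The track ends
when the peak falls below 1.3× background. Speeds divide net displacement
by duration; tracks of ≤ 1 min are rejected. Patches within ~3.5 um of
either path end suffer tail truncation that biases the centroid inward;
the paired-patch benchmark therefore starts patches at 12 and 21 um of a
25-um neurite.

Axon slowdown smooths each neurite's flow series with a centered 200-min
rolling mean (truncated at the ends), then requires the axon to be at or
below 0.8× the *minimum* of the other neurites — the strictest reading of
"20% slower compared to all other neurites"; comparing against the mean is
a toggle — for ≥ 95% of time points within some 180-min window. The 95%
criterion is applied within each window (the alternative reading, from
onset to movie end, is stricter about late recoveries; the window reading
matches the printed "for 95% of time points ... for at least 180 min").
Onset is the start of the earliest qualifying window. Series spanning less
than 180 min are "not evaluable", which the result object distinguishes
from "not detected".

Mass partitioning subtracts the neurite background — the minimum over the
first five columns of the first and last four rows, floored at the highest
background of previous conversions of the same neurite — and splits each
analyzed row's summed signal into three zones around the start point:
beyond 1.1 um retrograde, within ±1.1 um, beyond 1.1 um anterograde
(1.1 um converts to pixels by round-half-up; at 0.22 um/px that is exactly
5 columns). Rows are analyzed up to one before the first row whose maximum
falls below 1.8× background (1.3× with LatB). Background-subtracted values
are *not* clipped at zero, so noise cancels in expectation instead of
inflating wide zones. Patch spread trims, per row, the lower-valued of the
two edge pixels until ≥ 10% of the row's mass is removed; exact ties
alternate sides so flat-topped profiles stay centred.

## Density cycles

Per-neurite mean tubulin intensity is normalized by the neuron's
expression level: the average intensity over all neurites per time point,
fitted as a quadratic (overnight polarization movies) or linear (short
drug-treatment movies) polynomial of time. Traces are smoothed with a
*trailing* 2-frame mean (frame 1 unchanged — "rolling window of 2" with a
centered window would be a 3-frame filter) and fed to a hysteresis swing
detector: track the running extremum; a departure of ≥ 0.2 in the opposite
direction registers a half-swing and restarts the extremum. This greedy
detector provably counts the maximum number of alternating ≥ 0.2 swings;
the suite checks it against an exhaustive dynamic-programming enumerator
on 1,000 random traces. Full cycles are ⌊half-swings/2⌋ — an increase
followed by a decrease or vice versa — and the frequency divides full
cycles by the trace duration.

Counting *completed* cycles in a finite window has an inherent floor
effect: at 0.56 cycles/hour over 10 h, a phase-randomized triangle wave
yields on average about 0.52–0.53 recovered cycles/hour (5 or 6 completed
cycles out of 5.6 oscillations), a ~6% downward bias that is a property of
the definition, not an implementation error. The recovery benchmark passes
its 10% band with this bias included.

## Comet orientation

The comet tracker itself is external; the package consumes track tables.
All track points (with consecutive points of a comet joined, since a comet
moves continuously between frames) build a binary neuron image, dilated by
1 px, largest component kept, skeletonized through the tracing machinery.
The soma for arc-length ordering is the densest accumulation of track
points (override available); a synthetic rooting disk grows until it
touches every footprint component, because neurites connect only through
the soma, which comet tracks cover poorly. Points inside that disk sit at
arc length 0 — a comet ending in the soma has reached the soma, it is not
"far from the neuron".

Orientation is called by the endpoint rule (nearest skeleton point of
first vs last track point, compared by arc length from the soma); on a tie
by per-timepoint angle votes between the comet direction (t to t+2) and
the local skeleton direction (two points before to two after the nearest
point), < 70° voting plus-end-out and > 110° minus-end-out, with the
winning label needing ≥ 65% of cast votes. Two deliberate choices: the
nearest skeleton point for a vote is anchored at the *midpoint* of the
three-point window, which makes the vote multiset mirror exactly under
time reversal (the suite asserts an exact label swap); and the consensus
denominator counts voting timepoints only (a toggle includes the 70–110°
band, which the published 65% wording leaves ambiguous).

## The synthetic-data generator

The generator emulates the imaging regimes of the study: 0.22 um/px
(0.44 um/px also occurs in the source experiments), 20–180 s frame
intervals, soma + curvilinear neurites with Gaussian cross-section
(σ = 1.5 px, the diffraction-limited appearance without optics modeling),
patches as Gaussian arc-length profiles drifting at 0.2–1 um/min,
CAMSAP3-like puncta, EB3-like tracks at 12–18 um/min, integer stage
jitter as a random walk of up to ±3 px/frame (subpixel mode exists for
robustness tests), Poisson shot noise plus Gaussian read noise with
defaults giving SNR ≈ 5 at the patch peak, and exponential bleaching.
Every simulator seeds all randomness from `SimConfig$seed`: identical
configs give bit-identical movies. Density-trace phases are uniform-random
per neurite — real neurites are not phase-locked. The mass-kymograph
generator uses a per-row signal mass high enough (3000 intensity units
against background 20, noise SD 1) that the residual of the min-statistic
background estimator stays below one percentage point of the partition.

What the benchmarks do **not** show: the generator has no optical PSF, no
photophysics of the convertible fluorophores, no 3D volumes, no moving or
remodeling neurites during a movie (paths are static per movie), and its
noise is stationary. Passing recovery tests therefore demonstrate that the
analysis chain is unbiased and correctly calibrated under the stated
imaging regime — not that tracing or tracking is robust to every
morphology real neurons produce.

## Benchmark problem sizes

The recovery benchmarks use 30 movies (unpolarized regime), 25 cells × 3
movies (paired regimes), 27 cells × 4 neurites at 201 frames (cycles), 20
kymographs (mass partition), 30 paired-patch neurites, 200 registration
trials at 64×64, and 200 correlation cohorts of 95 pairs — sizes chosen to
put the standard error of each recovered mean comfortably inside the
band being checked while keeping the whole suite in the minutes range on
one CPU.

## Known limitations

* Only 2D translation registration; rotation, scaling and 3D are out of
  scope (point-list speed computation is dimension-agnostic, the imaging
  simulator is 2D).
* The tracer requires cytosol/neurite-filling markers; tip-enriched
  markers (actin) are explicitly unsupported, as in the original
  procedure.
* `track_patch()` follows at most two patches per corridor and assumes
  they stay separated by more than twice the search window.
* Stitched multi-segment kymographs for drastically remodeling dendrites
  are not automated.
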