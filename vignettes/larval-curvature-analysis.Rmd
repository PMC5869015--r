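---
title: "Quantifying larval body curvature, calcium responses, and connectome structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying larval body curvature, calcium responses, and connectome structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvacurv)
```

## The measurement problem

When a *Drosophila* larva executes its nocifensive escape — a deep C-shaped
bend followed by corkscrew rolling — the depth of the bend is the behavioural
variable of interest, but it is awkward to score by eye. `larvacurv`
quantifies it from thresholded silhouette video. Each frame is reduced to a
closed ring of 300 boundary points, every point gets a signed **curvature
index** (CI), points are put in correspondence across frames, and each animal
is summarised by how much of its concave (inner-bend) boundary sits above a
low/high curvature cutoff. Two companion analyses cover the physiology and
anatomy that usually accompany such behavioural work: ratiometric calcium
imaging under a thermal ramp, and synapse-count summaries of connectome edge
lists.

## The curvature index

At boundary point $i$, a circle is fitted through the point and its two
neighbours 10 index positions away on the ring (with 300 points, one tenth
of the perimeter apart in arclength). The CI is the reciprocal of that
circle's radius, in units of 1/pixel, so tighter local bending gives a
larger magnitude:

$$\mathrm{CI}_i = \pm\,\frac{1}{R(p_{i-10},\, p_i,\, p_{i+10})}$$

The sign encodes concavity: if the midpoint of the chord joining the two
flanking points falls **outside** the body outline, the boundary is locally
concave (the inside of a bend) and the CI is positive; otherwise it is
negative. Both choices at the margins are deterministic and documented:

* the in/out test is the even-odd rule against the full 300-point polygon
  (the same object the point indices refer to);
* a midpoint lying exactly on an edge (within $10^{-9}$ px) counts as
  *inside*, i.e. convex — the "otherwise" branch;
* a near-collinear triple (twice the triangle area below $10^{-6}$ px²,
  configurable) returns CI = 0 rather than overflowing.

For points sampled from a perfect circle of radius $R$ the circumcircle
construction is exact, so every CI equals $-1/R$ to floating precision;
this is the suite's strongest oracle. For a circular bend of midline radius
$1/\kappa$ and half-width $w$, the inner edge is an offset curve of radius
$1/\kappa - w$, so the expected inner-edge CI is $+1/(1/\kappa - w)$ — the
basis of the parameter-recovery tests.

## From frame to boundary

Frames are thresholded (Otsu by default; the acquisition threshold can be
supplied), and a size filter removes debris: components smaller than
`min_area` (default 1% of the image) are dropped and, of those remaining,
only the largest is kept, ties going to the component nearest the image
centre. The outer contour is traced at the 0.5 iso-level of the binary
mask, which places vertices at foreground pixel-edge midpoints —
sub-pixel, and less staircase-biased than pixel-centre tracing. Two passes
of a circular three-point vertex average then remove the marching-squares
ripple: on rasterised disks the raw traced polyline overestimates the
perimeter by 3–4%, while the smoothed one is within 2% for radii down to
20 px and moves no vertex by more than half a pixel. The outline is
oriented consistently, started at the canonical vertex (minimal y, then
minimal x), and resampled to 300 points uniformly spaced in arclength.
Note that chord spacing contracts slightly wherever the outline turns
sharply (a square's corners, the larva's pointed tips); arclength spacing
along the traced path is exact by construction.

Curvature smoothing, by contrast, is deliberately absent: the CI profile is
reported raw. Per-point CI on rasterised shapes carries visible
quantisation noise (unbiased — the profile mean on a disk is accurate to
about 0.1% — but with per-point spread up to tens of percent at small
radii). Summaries therefore use medians or pooled counts, never single
points: the "peak" concave curvature of a constant-curvature bend is
estimated as the median CI over its inner-edge plateau, which is also what
the per-animal percentage summaries effectively do.

## Kymographs and point correspondence

A kymograph needs the 300 points to mean the same body locations in every
frame. Successive frames are aligned by exhaustive search over all 600
candidate correspondences (300 cyclic shifts, with and without index
reversal), choosing the one minimising the summed squared distance between
matched points. The search space is tiny, so the optimum is exact and ties
break towards the smallest non-reversed shift. Index reversal is included
because a mirrored parametrisation is a genuine failure mode of contour
tracing. Offsets chain multiplicatively (each is an affine map
$i \mapsto \pm i + b$ on the ring), so every frame is re-indexed into
frame-1 coordinates.

Head and tail are the two sharpest convex points: the two most negative
strict local minima of the CI profile at least 100 index positions apart,
with a prominence requirement (the profile must rise by at least 2% of its
range within ±5 indices) so that featureless shapes such as disks are
rejected rather than assigned arbitrary tips. The head label is propagated
by proximity to the previous frame's head; if the aligned head drifts by
more than 15 points between frames the offset is re-anchored to pin it —
an automated replacement for correcting head/tail slippage by hand.

## Per-animal quantification and the group test

Quantification uses only concave (positive-CI) points, excluding every
index within 25 positions of either tip (their curvature reflects tip
shape, not body bending). With 300 points this leaves exactly
$300 - 2(2\cdot 25 + 1) = 198$ indices per frame. The low/high cutoff is
the median of pooled positive included CI across the control group —
recomputed per study because a CI cutoff in 1/pixels is only meaningful at
one magnification (a literal cutoff can be supplied when the resolution
matches the one it came from). Per animal, `pct_low` and `pct_high` are
the percentages of positive included point-frames below and above the
cutoff; a value exactly at the cutoff counts as high, and the two
percentages sum to 100 by construction. The denominator is the positive
included count by default; counting all included points instead is a
documented switch, since either convention is defensible for the published
figure style this mirrors. Whether to summarise per animal then average,
or pool across animals, is equally underdetermined; per-animal is the
default and pooling is available through the same primitives.

Because the two percentages are complements, a multivariate test over both
would be rank-deficient; the group comparison is a Welch two-sample t-test
on `pct_high`, with an exact permutation test (all group relabellings) as
the fallback when within-group variance degenerates. For the synthetic
study conditions — two cohorts of six animals whose final bend curvature
differs twofold — the test separates groups at $p < 0.01$, and an
exhaustive 924-split permutation oracle agrees with the decision.

## Calcium analyses

Two baseline conventions, matching the two experiment styles:

* **Ramp imaging**: $F_0$ is the mean of the lowest 10% of samples
  (count rounded up, so exactly the minimum at $n = 10$). With additive
  zero-mean noise of s.d. $\sigma$ this estimator is biased low by
  $\approx 1.75\sigma$ independent of trace length — at 1% noise the bias
  is under 2% of baseline, at 5% noise it approaches 9%, which is worth
  remembering whenever low-decile baselines are compared across noise
  regimes. The recovery tests therefore run the joint baseline-and-gain
  check at 1% noise and verify gain recovery separately up to 5% noise,
  where the bin *difference* (below) is insensitive to the bias.
* **Activation imaging**: $F_0$ is the mean over a pre-stimulus window of
  at least 3 s ending at stimulus onset.

$\Delta F/F_0 = (F_t - F_0)/F_0$ in both cases. Probe temperature is
digitised at 4 Hz asynchronously from the frames, so per-frame temperature
comes from piecewise-linear interpolation, with out-of-range frame times
clamped to the endpoint values and flagged. Binned summaries split the
recording at the global temperature maximum — the conventional printed bin
labels (25–38 °C heating, 39–49 °C heating, post-peak cooling) presuppose
phase knowledge, and the peak split makes that unambiguous. The gap
between 38 and 39 °C belongs to neither printed bin; the default edge
38.5 °C splits it, and the edges are configurable. Empty bins are reported
as missing, never zero.

The synthetic ramp generator drives fluorescence as
$F = F_{\mathrm{base}}(1 + g\,\mathrm{logistic}((T - \theta)/0.5))$ plus
Gaussian noise, with the probe rising linearly to its peak over 60% of the
recording and falling linearly afterwards. The 0.5 °C logistic width makes
the response rise at threshold and saturate within about 3 °C above it —
the behaviour described for these neurons, whose responses begin near
39 °C and plateau by roughly 42 °C. Under these conditions the
supra-minus-sub-threshold bin difference recovers about 93% of the
generative gain analytically (the supra bin averages over the rising
flank), comfortably inside the 10% recovery property; a broader logistic
would make that property unattainable for any implementation.

## Connectome summaries

Edge lists are directed (presynaptic id, postsynaptic id, synapse count)
with an id-to-class map; duplicate pairs are aggregated on construction.
Three summaries:

* **input fractions** — per upstream class, the percentage of all
  synapses received by a target set; sums to 100 exactly;
* **top hits** — downstream neurons receiving *strictly* more than 3
  synapses (aggregated over the source set before thresholding); both
  natural denominators (all output synapses, top-hit synapses only) are
  reported because the published convention is ambiguous;
* **path enumeration** — all simple directed paths between two classes up
  to a hop bound, over edges at or above a synapse threshold, in
  lexicographic order. The implementation delegates to igraph; the test
  suite checks it against an independent recursive depth-first search.

Segment restriction (e.g. "inputs from any segment onto the A1 pair") is a
caller-side choice of id sets, never hardcoded. Dendritic-compartment
fractions would need a compartment column the plain edge list lacks, and
are omitted.

## What the synthetic data does and does not emulate

The generator sweeps a midline of prescribed curvature with a half-width
profile that is flat mid-body and tapers to a point over the terminal 15%
of the body by a raised cosine — pointed, convex tips like a real larva,
so tip detection is exercised honestly. Bend-deepening sequences ramp a
constant curvature linearly across frames, standing in for the deepening
C-bend of an escape bout; rolling itself (a rotation about the body axis)
is not simulated, because from below a roll is a sequence of silhouette
shapes, which the bend ramp already provides. Debris blobs with a clear
margin around the animal exercise the size filter. Frames are rendered as
two-level images, the worst case for contour quantisation; real video has
soft edges, motion blur, partial occlusion and illumination gradients that
none of this models, so passing tests certify the geometry and
bookkeeping of the pipeline, not robustness to real-world segmentation
failures. Cohorts jitter body length and final curvature by 8% between
animals; image scale is arbitrary, which is exactly why the CI cutoff is
recomputed from controls rather than inherited.

## Numerical choices and problem sizes

Collinearity tolerance $10^{-6}$ px² on twice the triangle area; on-edge
tolerance $10^{-9}$ px for the sign test; component labelling is
8-connected; size-filter ties go to the centre-most component; alignment
ties to the smallest non-reversed shift; the lowest-decile count rounds
up. The test suite runs scenes of 2–8 frames at 250–420 px images, cohorts
of up to 6 animals, 100-trace calcium ensembles and 50-graph connectome
ensembles; the full suite completes in well under a minute on one core.

## Limitations

Single animal per frame; no hole filling, background subtraction, or
multi-animal tracking. The boundary must be a simple closed curve at least
a pixel wide. The alignment model is rigid re-indexing (no elastic
correspondence), which is the published convention but will lag badly
deforming outlines — the tip re-anchoring exists precisely for that case.
CI values are resolution-bound; comparisons across magnifications must go
through the control-derived cutoff, not raw CI.
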