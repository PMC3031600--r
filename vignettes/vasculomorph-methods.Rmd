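---
title: "Methods: models, generators and numerical choices in vasculomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generators and numerical choices in vasculomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`vasculomorph` quantifies abnormal tumor vasculature from four
complementary measurement types, as used in longitudinal small-animal
brain-tumor studies (the emulated system is the 9L gliosarcoma rat model
under a five-day corticosteroid course):

1. **DSC-MRI perfusion** — relative cerebral blood volume (rCBV) from
   dynamic susceptibility contrast signal time-series;
2. **micro-CT vessel morphometry** — branch density (branches/mm³) and
   branching angle-to-length tortuosity (deg/mm) from binary vessel
   volumes;
3. **IHC morphometry** — microvessel count and cross-sectional area (µm²)
   from endothelial-stain photomicrographs;
4. **growth kinetics** — exponential rate and doubling time from tumor
   volume tables.

Because no raw animal data accompany the emulated study, every analysis
stage is validated by *parameter recovery*: a synthetic-data generator
plants known ground truth with the published group values as parameters,
and the pipeline must recover them. A green test therefore establishes
that the analysis is a faithful implementation measuring what it claims on
data of known structure — not that it would reproduce any particular
animal experiment.

# DSC perfusion model

The signal model is the standard intravascular susceptibility relation

$$S(t) = S_0 \, e^{-TE\, \Delta R_2^*(t)},\qquad
\Delta R_2^*(t) = -\frac{1}{TE}\ln\frac{S(t)}{S_0},$$

with $S_0$ the per-voxel mean over a pre-bolus baseline window (default:
the first 10 time points; the window must precede bolus arrival).
Cerebral blood volume is the trapezoidal area under $\Delta R_2^*(t)$ and
rCBV is the tumor-ROI mean divided by the contralateral-ROI mean.

Numerical choices:

* **Integration window** — the full post-baseline acquisition. The
  emulated agent is an iron-oxide blood-pool agent, so there is no
  leakage correction and no gamma-variate fitting before integration;
  recirculation stays in the integral by design (it is proportional to
  blood volume for an intravascular tracer).
* **Negative lobes retained** — noise on $\Delta R_2^*$ is symmetric
  around zero at baseline; clipping would bias the area.
* **Validity flags** — voxels with non-positive signal at any time point
  (where the log transform is undefined) are flagged invalid and excluded
  from ROI means; an ROI errors out if fewer than half its voxels remain.
* **Bonferroni threshold** — exposed as the exact `alpha / n_tests` rule.
  For the acquisition geometry used in the emulated study (64×64×5) this
  gives 2.441×10⁻⁶; published figures sometimes round such thresholds
  differently, and the exact rule is kept.

The DSC generator plants a gamma-variate concentration curve
$C(t) = A (t-t_0)^\alpha e^{-(t-t_0)/\beta}$ (defaults $\alpha = 3$,
$\beta = 3$ s, $t_0 = 20$ s, peak $\Delta R_2^* \approx 29\,s^{-1}$),
scaled by the planted tumor:contralateral ratio in tumor voxels, at TE
34.5 ms, 1.02 s temporal spacing and 118 time points. Noise is additive
Gaussian on the magnitude signal (SD 10 on a baseline of 1000, i.e. SNR
100), not Rician: at this SNR the difference is negligible, and the
simpler model keeps tests stable. In the noise-free limit the planted
ratio is recovered to machine precision because the ratio of integrals of
proportional curves is the proportionality constant; this is asserted at
1e-10 relative error.

# Vessel-tree morphometry

## Skeletonization

Binary volumes are thinned to one-voxel-wide curves with a sequential
six-subiteration border thinning in C++. A voxel may be deleted only if
it is *simple* under the (26, 6) connectivity pair — exactly one
26-connected foreground component in its 26-neighborhood and exactly one
6-connected background component in its 18-neighborhood touching a face
neighbor — and is not a curve endpoint (≤ 1 foreground neighbor).
Deletions are re-checked sequentially, so each individual removal
preserves topology; the fixed point is idempotent by construction. The
commercial tool used in the emulated study implements an unpublished
thinning; any topology-preserving curve thinning is acceptable here, and
correctness is established against generator ground truth rather than
against a particular algorithm.

## Graph extraction

Skeleton voxels with ≥ 3 skeleton neighbors form junction clusters
(26-connected components, merged to their centroid); voxels with ≤ 1
neighbor are endpoints. Segments are maximal chains between nodes, with
Euclidean path length in mm. Terminal spur segments shorter than 2 voxel
steps are pruned (configurable): these arise as thinning artifacts on
tube surfaces, while any genuine branch resolvable at the scanner
resolution is longer. Parentage is assigned by breadth-first traversal
from the root — the user-supplied entry point if given, otherwise an
endpoint of the longest segment (a cropped VOI has no anatomical entry
vessel).

A **branch** is a daughter segment (a segment with a parent), counted in
a VOI when its proximal node lies inside; density is branches per VOI
volume. The **branching angle** is measured between the parent's
direction of travel into the shared junction and the daughter's outgoing
direction, each estimated as the chord over k = 5 skeleton voxels
(≈ 0.23 mm at the default spacing) to suppress voxel jitter.
**Tortuosity** is angle/length in deg/mm per branch, with zero-length
branches excluded and counted. The published definition does not state
whether the daughter's own length or a longer path length enters the
denominator; the daughter segment length is used, consistently in the
generator truth and the measurement.

## Tree generator

Trees grow inside a cubic domain from a root at a face: a random open
segment end is chosen and a bifurcation is spawned — two daughters with
planted branching angles (truncated normal, default 50° ± 15°) and
planted lengths (truncated normal, default 0.26 ± 0.04 mm, floor
0.2 mm) — until the daughter count equals `round(density × volume)`; a
trifurcation absorbs an odd remainder. Two design points matter:

* **Bifurcations only.** A lone daughter continuing from a segment end is
  a degree-2 skeleton point, invisible to any branch-point-based
  morphometry; planting it would make the truth unrecoverable by
  construction. If a sibling cannot be placed, the first daughter is
  undone and another site is tried.
* **Centerline clearance.** Non-adjacent centerlines keep a minimum
  distance (2·radius + half a voxel) so that rasterized tubes do not
  fuse; fused tubes would create spurious junctions and inflate measured
  density. Crowded configurations occasionally jam; growth restarts
  deterministically from derived sub-seeds before a density is declared
  unreachable, and tube packing above ~30% volume fraction fails
  explicitly.

The geometric defaults are chosen once so that the planted structure is
*resolvable at the stated 45.19 µm resolution*: with tube radius one
voxel, a junction's merged blob spans ~1.5 radii and the free end of a
tube erodes by ~1 radius during thinning, so the 0.2 mm length floor
(≈ 4.4 voxels) leaves every daughter at least ~2 skeleton voxels of its
own. Branches shorter than a tube diameter are not resolvable branches at
this resolution for any skeleton-based method. Rasterization marks a
voxel foreground iff its center lies within the tube radius of a segment
line — deterministic and resolution-independent.

Sibling daughters are additionally required to separate by at least 50°:
below that, at the default lengths, their tubes stay within the
two-radius contact distance for most of their length, fuse in the
rasterized volume, and one daughter disappears from any skeleton-based
count. Measured density then carries a small systematic error budget
(junction clusters merging close branch points, occasional pruned short
daughters, boundary effects), empirically within ±5% of the planted
density at both published group densities in 1.5 mm domains; the
acceptance band is 10%. Sub-millimeter domains undercount by 10–15%
(boundary effects dominate) — acceptable where only group separation is
asserted, and noted where used.

Angle measurement has two further resolution limits. Chords over ~5
voxels quantize to the lattice, giving ±10–15° per-branch noise, and
noise on small angles folds at zero, biasing narrow-angle trees upward.
At dense packings, junction clusters occasionally merge two nearby
branch points, attaching a grand-daughter directly to its grandparent
and mixing generations. Mean-angle recovery within 5° therefore holds on
sparse resolvable trees (the oracle setting); tortuosity contrasts
between groups remain detectable at full density because lengths are
measured accurately.

## What the tree generator does not emulate

Radius tapering along generations, curved vessels, anastomoses/loops,
contrast-filling artifacts, and reconstruction noise are absent. Green
density tests therefore establish skeleton/graph correctness on clean
tubular trees, not robustness to segmentation noise.

# IHC morphometry

Fields are square (default 510 µm ≈ 0.26 mm² at 20×, 0.5 µm pixels).
The generator plants non-overlapping ellipses (mild eccentricity 1–1.5,
uniform orientation) whose analytic areas follow a lognormal with the
requested mean and SD; foreground/background intensities are separable
(200 vs 40, noise SD 5). The per-object SD is a simulation choice (the
emulated tables print only mean ± SEM of per-animal means); 35% of the
mean is used in acceptance runs, a typical within-field spread for
capillary cross-sections.

Measurement is a global Otsu threshold per field (256-bin histogram),
8-connected component labeling, removal of objects below 4 µm², and
per-object area = pixel count × pixel area. Pixel-center counting is
nearly unbiased for randomly placed smooth objects; the area error is
below 2% at 0.25 µm pixels for radii ≥ 2 µm and within 10% at the
default pixel size. Border-touching objects are retained (and flagged)
since the published protocol is silent; discarding them would bias areas
downward.

The published per-field counts (29 under treatment vs 16 under saline)
contradict the reported sparser treated vasculature and are likely
transposed; counts are produced but not used as an acceptance surface.

# Growth kinetics

The model is $y = y_0 e^{kt}$, fitted by nonlinear least squares on the
untransformed volumes (Gauss–Newton via `nls`), with the log-linear
regression used only to seed the optimizer — log-transforming would
reweight the residuals and change the estimator. $r^2 = 1 -
SS_{res}/SS_{tot}$ is reported on the volume scale. Doubling time is
$0.69/k$, keeping the conventional rounded constant (not $\ln 2$) so the
arithmetic matches the preclinical literature exactly. The generator
multiplies the exponential by unit-mean lognormal noise of a given CV;
with CV = 0.1 and five time points over eight days, the mean fitted
doubling time over 200 seeds recovers the planted value within 10%
(small upward bias from the nonlinearity of $0.69/k$ is part of that
budget). A flat series converges to $k = 0$ and is flagged rather than
reported with an undefined doubling time.

Cohort fits can be pooled (one fit to all animals' points; the default
for reproducing cohort-level numbers, whose published $r^2$ of ~0.5
suggests pooling) or per-subject.

# Cohort statistics

Two-sided tests throughout (sidedness is not stated in the emulated
protocols). The per-day rCBV comparison is a classical one-way ANOVA
followed by Bonferroni-adjusted pairwise pooled-variance t-tests
(`alpha/n_pairs`; Welch available by flag — pooled matches the
era-standard defaults of the original analysis software). Morphometry
uses an unpaired t-test on per-subject densities and a Mann-Whitney U on
pooled per-branch tortuosity: exact enumeration of all
$\binom{n_a+n_b}{n_a}$ mid-rank assignments when $n_a+n_b \le 12$
(two-sided p by doubling the smaller tail, capped at 1), otherwise a
normal approximation with tie correction and continuity correction. The
exact path is verified against an independent permutation oracle, and
the approximate path against its nominal 5% rejection rate under the
null. A stated significance level of "0.5 (95% confidence intervals)" in
the emulated protocol is treated as a typo for 0.05.

In cohort simulations the printed ± values are used directly as
per-subject SDs. The source prints mean ± SEM, but no variance model is
stated anywhere, and the published within-cohort significance pattern
(day-3 vs day-5 contrast significant after Bonferroni at n = 13) is only
reproducible with subject-level spreads of that magnitude; this is
documented as a simulation choice, not a claim about the data.

# File formats and environment notes

Volumes are single-file NIfTI-1 (.nii/.nii.gz) written and read by a
minimal in-package implementation (fixed 348-byte header, little-endian,
datatypes uint8/int16/int32/float32/float64, spacing in `pixdim`),
because the target environment provides no R NIfTI bindings. Stained
fields use plain-text PGM (P2) with the pixel size in a comment, in place
of TIFF, for the same reason. Graphs and configs are JSON. All
randomness flows through per-generator seeds; identical spec + seed gives
bit-identical outputs, including byte-identical files.

# Known limitations

* The tree generator's clearance constraint caps reachable densities for
  a given segment-length distribution; well above ~75 branches/mm³ at the
  default geometry, growth fails explicitly rather than degrading.
* Skeleton-based lengths shorten by roughly one tube radius at each free
  end (medial-axis cap erosion); length-dependent statistics inherit this
  small negative bias.
* The DSC module quantifies relative blood volume only — no arterial
  input function, CBF/MTT, or leakage correction.
* IHC segmentation assumes a single stain channel with bimodal intensity;
  no stain unmixing or normalization is provided.
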