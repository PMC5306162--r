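---
title: "Probabilistic artery atlases: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic artery atlases: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascatlas)
```

This vignette explains the models and numerical choices behind
`vascatlas`, the way the synthetic phantoms emulate angiographic
cohorts, and the limits of what phantom-based validation can show.

## The atlas model

For each named artery $a$ and template-space voxel $v$, the atlas
stores the overlap proportion

$$p_a(v) = \frac{n_a(v)}{N_a},$$

where $n_a(v)$ is the number of cohort subjects whose (re-inflated,
normalized) artery $a$ occupies $v$, and $N_a$ is the number of
subjects that possess artery $a$ at all. The denominator is
*per-artery*: a communicating artery present in 38% of a population
still gets map values up to 1 where those subjects agree, rather than
being diluted by subjects who simply lack the vessel. Consequently
$p_a(v) \in \{0, 1/N_a, \dots, 1\}$ exactly, and the total probability
mass satisfies $\sum_v p_a(v)\, N_a = \sum_s |a_s|$ (a conservation law
the test suite checks exactly).

Alignment quality is summarized per artery by:

* **Concatenated volume** — physical volume of $\{v : p_a(v) > 0\}$ in
  cm³; the union footprint of the artery across the cohort.
* **Arterial volume ratio (AVR)** — concatenated volume divided by the
  mean per-subject artery volume over the $N_a$ included subjects.
  Perfect alignment gives 1.0; larger values mean inter-subject
  scatter. Inside `build_atlas()` the ratio is formed from voxel
  counts, so the voxel-volume factor cancels and an identical cohort
  yields exactly 1.
* **Dominating volume** — percentage of the map's support where
  $p_a(v)$ *strictly* exceeds every other map; ties do not dominate,
  so two identical maps both score 0 on their shared support.
* **Maximum probability** — $\max_v p_a(v)$; 1.0 means some voxel is
  occupied by every included subject.

The whole-atlas AVR aggregates as
$\sum_a \mathrm{conc}_a / \sum_a \overline{\mathrm{vol}}_a$ — the ratio
of summed volumes, not the mean of ratios, which is the aggregation
that reproduces both published whole-atlas values from their
per-artery columns.

## Segmentation and skeletonization

The angiographic volume is smoothed with a $3^3$ box filter
(zero-padded at the borders, so the operation is linear and preserves
the intensity sum of interior-supported images) and thresholded at 18%
of the *smoothed* maximum, inclusive. Smoothing precedes the maximum
because denoising before thresholding is what makes a global fraction
meaningful; the inclusive comparison keeps the stated level itself.

Thinning is sequential simple-point removal organised in six
directional sub-iterations. A voxel may be deleted only if

1. its face neighbour in the current direction is background and the
   opposite face neighbour is foreground (a genuine border voxel of
   that direction — this stops one-voxel-thick structures from eroding
   lengthwise during orthogonal sub-iterations);
2. it is *simple*: its 26-neighbourhood foreground has exactly one
   26-component and its 18-neighbourhood background has exactly one
   6-component touching a face neighbour, so deletion provably
   preserves local topology;
3. it is not a curve endpoint (at most one foreground neighbour).

Because every deletion is individually topology-preserving, the result
has exactly the mask's 26-components and tunnels, whatever the order.
A final unrestricted cleanup pass removes residual staircase voxels —
safe at that stage because deleting an essential voxel of a digital
curve disconnects it and is therefore never simple. Conformance is
property-tested (subset, component counts, torus cycle, no $2^3$
block, fixed-point on lines) rather than tied to one published
deletion schedule.

Branch decomposition marks voxels with $\ge 3$ skeleton neighbours as
junction voxels, merges mutually adjacent ones into junction clusters
(a thick T-joint is one junction), and traces the remaining voxels
into maximal paths. Ids are assigned in scan order of each branch's
smallest endpoint, so decomposition is deterministic. Pruning then
(a) removes terminal branches shorter than eight voxels — one at a
time, shortest first, rebuilding the graph in between, because
removing a side spur can reunite the branch it interrupted, and that
reunited branch must be re-measured before it is judged; and (b)
breaks every cycle by deleting its shortest participating branch. An
isolated closed ring is *opened* (one voxel removed) rather than
deleted: removing "the" branch of a junction-free ring would erase the
whole component. After each removal the voxel set is re-thinned, which
dissolves former junction voxels left diagonal to a straight run.
Pruning is idempotent.

## Re-inflation and normalization

Labeled skeleton branches are dilated with a $7^3$ cube and clipped to
the binary vessel tree; where two labels compete, the voxel takes the
Euclidean-nearest labeled skeleton voxel (ties to the lower id). The
paper's workflow normalizes images non-linearly into template space;
here the phantom's stored warp plays that role, and "rigid-body
alignment" is its polar-decomposition reduction (`rigid_only()`:
rotation factor of the 3×3 block, translation kept, displacement field
dropped). Binary arteries resampled with trilinear interpolation are
re-binarized at the threshold that conserves each subject-artery's
native voxel count, keeping threshold ties, so partial-volume blur
does not inflate volumes. We conserve the per-subject, per-artery
count (not each final map's concatenated volume), because that is the
quantity rigid resampling distorts.

## Automatic identification (AAIM)

Each branch of the target subject's pruned skeleton is mapped to
template space through the inverse warp and scored by the mean of each
artery's probability map (trilinear interpolation) along its voxels.
The branch is assigned to the argmax artery if the score reaches
$\tau = 0.1$; an artery is *found* when at least one branch is
assigned. Ties break by summed (voxel-weighted) probability and then
lexicographically, keeping the procedure fully deterministic. The
scoring rule is exposed as parameters because the choice (mean vs sum,
threshold level) is a reconstruction of common practice, not a law;
raising $\tau$ can only lose arteries, never find new ones — a
monotonicity the tests enforce.

## Validation

Each (subject, artery) pair receives exactly one of six categories.
For present-and-found arteries the decision runs: purity, then segment
criterion. Purity is the fraction of automatically labeled voxels
inside the truth artery, with the truth dilated by one voxel
(`boundary_tolerance_vox = 1`): inter-artery borders are drawn at
skeleton junctions, whose position differs by about a voxel between a
subject's own skeleton and the warped template, and a one-voxel border
shift moves an entire tube cross-section between labels. The human
evaluation this replaces was an explicit judgment of whether
mislabeling was "relevant"; a genuinely misassigned branch lies far
outside one voxel of tolerance and is still flagged (the tests include
a deliberately swapped-label case). The purity threshold (default
0.9) and the tolerance are both parameters.

Segment criteria translate "a $\ge L$ mm segment in region R" into: an
assigned branch must contain a connected run of path length $\ge L$
inside R. Run length is one voxel size plus the summed inter-voxel
step lengths (diagonal steps scaled by $\sqrt2$, $\sqrt3$), i.e. a
straight $n$-voxel run at spacing $h$ measures $nh$ — each voxel
contributes its own extent, so a 12-voxel run at 0.7 mm is 8.4 mm.

Leave-one-out validation rebuilds the atlas without the target subject
— implemented by subtracting the subject from precomputed occupancy
sums, which is algebraically identical to a rebuild — labels the
subject, categorizes, and tabulates per-artery confusion counts.
Sensitivity, specificity (undefined without negatives) and accuracy
are rounded half-up to integers; the summary accuracy is the
unweighted mean over arteries, the aggregation that reproduces the
published column means.

The Wilcoxon signed-rank test drops zero differences, average-ranks
ties, and computes the exact two-sided p-value from the permutation
distribution of the positive-rank sum over all $2^n$ sign assignments,
enumerated by dynamic programming over doubled ranks (exact and
practical to $n = 50$; property-tested against a brute-force $2^n$
oracle). Spearman's rho is the Pearson correlation of average ranks.

## The synthetic phantom

`generate_cohort()` emulates the statistical structure the pipeline
assumes, not the appearance of real angiography:

* **Geometry** — tubes swept along polylines; the default
  `example_artery_specs()` lays out seven tubes as a schematic circle
  of Willis analogue (paired carotid-like trunks, a basilar-like
  trunk, paired middle-cerebral-like branches, an anterior bridge, one
  posterior connector) on a 64³ grid at 0.7 mm isotropic voxels, the
  resolution of high-resolution 4D flow angiography.
* **Intensity** — flat core with a cosine rim over at most one voxel,
  reaching zero exactly at the tube radius, so the 18% threshold
  recovers the tube from inside and ground truth can contain the mask.
  Radii are free parameters set to 1.2–1.8 mm — thick enough that a
  tube survives 3-voxel box smoothing; sub-voxel radii would vanish at
  the global threshold, which is a real phenomenon (slow-flow vessels
  disappearing from thresholded angiograms) but not one the phantom is
  meant to study.
* **Prevalence** — artery presence is Bernoulli per subject. The
  posterior connector uses 0.38, the published population prevalence
  of a posterior communicating artery; the junction-forming anterior
  bridge stays at 1.0 because branch-level labeling cannot split a
  junction-free curve — when the bridge was absent, the middle branch
  merged with its trunk and became structurally unfindable, a border
  case the original workflow resolved by manual morphology decisions
  that are out of scope here.
* **Deformation** — per subject, a Gaussian-smoothed white-noise
  displacement field (smoothness 8 mm, maximum magnitude
  `deform_amplitude_mm`, default 2 mm) composed with a small random
  rigid transform (≤3° per axis, ≤2 mm translation) about the grid
  centre, stored in pull form on the template grid. Warping to subject
  space inverts the field by 10 fixed-point iterations (free-form
  warps have no closed-form inverse); intensities are trilinear,
  labels nearest-neighbour. Additive Gaussian noise (sd 4 against peak
  100) is clamped at zero.
* **Ground truth** — the noise-free template is segmented with the
  pipeline's own smoothing and threshold, thinned, each skeleton voxel
  labeled by its nearest artery, and the labels re-inflated into the
  one-voxel-dilated vessel tree — the same constrained dilation a
  manual rater's branch labels undergo. Truth is therefore defined on
  the segmented tree (tubes plus their segmentation halo), which is
  what purity must be measured against.

What phantom validation shows: that segmentation, skeletonization,
branch decomposition, probability-map accumulation, the AVR machinery,
AAIM scoring and the leave-one-out harness compose correctly, and that
known-warp normalization dominates rigid alignment exactly as the
model predicts. What it does not show: robustness to real angiographic
artifacts — flow voids, intensity inhomogeneity, touching vessels,
anatomical variants beyond presence/absence — nor anything about the
quality of an *estimated* (rather than known) registration, which in
real data is the dominant error source.

## Problem sizes and numerics

The shipped tests run cohorts of 5–8 subjects on 64³ grids for module
checks and one 20-subject 64³ cohort at 2 mm deformation for the
end-to-end comparison; these sizes make the full suite complete in a
few minutes while leaving every mechanism exercised at realistic voxel
counts. Degenerate inputs fail loudly: empty masks cannot be thinned,
all-zero volumes cannot be thresholded, arteries absent from every
subject cannot form maps, and pruning that would empty a skeleton
raises an error rather than returning nothing. Exact identities (AVR
of identical cohorts, probability-mass conservation) are computed so
that floating-point factors cancel and the tests can assert equality,
not closeness.
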