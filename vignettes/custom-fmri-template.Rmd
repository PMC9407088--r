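---
title: "Building subject-specific 3D fMRI templates from slice sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building subject-specific 3D fMRI templates from slice sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

fMRI registration needs a reference image. There is no standard fMRI
template the way there is for structural MRI, and for subjects whose
anatomy departs from the adult standard templates (children, elderly
patients), normalising to a standard space introduces large errors.
Within-subject registration avoids that, but the usual practice — picking
one time point of the series as the reference — makes the reference
arbitrary and noisy.

`fmritemplate` builds the reference from the subject's own 4D series
instead. Each axial layer of the brain is treated as a 2D image sequence
over time; the frames of each sequence are aligned into the first frame's
coordinate system and fused into a single low-noise slice; the fused
slices are stacked into a subject-specific 3D template that preserves the
information shared across the whole series.

## The pipeline

For one slice sequence the stages are:

1. **Scale-space keypoints.** Each slice is min-max normalised to [0, 1]
   and a Gaussian pyramid is built; the difference-of-Gaussians (DoG)
   between adjacent blur levels defines a scale space whose strict
   26-neighbour extrema are keypoint candidates. Candidates are refined
   to sub-pixel/sub-scale position by a second-order Taylor fit, and
   rejected when the interpolated |DoG| response is below a contrast
   threshold or when the ratio of principal curvatures of the spatial
   Hessian marks them as edge responses (keep iff
   $\mathrm{Tr}(H)^2/\mathrm{Det}(H) < (r+1)^2/r$). Each keypoint gets a
   single dominant orientation from a 36-bin (10°) magnitude-weighted
   gradient histogram over a $3\sigma$ disc, with parabolic interpolation
   over the peak bin.
2. **GLOH descriptors.** A log-polar grid rotated to the keypoint
   orientation — an undivided central disc of radius $6u$ plus two annuli
   ($6u$–$11u$, $11u$–$15u$) split into 8 sectors, $u = \sigma/\sigma_0$ —
   holds an 8-bin histogram of relative gradient orientation per spatial
   bin: $17 \times 8 = 136$ dimensions, L2-normalised, clipped at 0.2,
   re-normalised.
3. **Ratio-test matching.** Exhaustive nearest/second-nearest Euclidean
   search; a match is accepted when the distance ratio is below 0.9, and
   one-to-one correspondence is enforced by keeping the best candidate
   per reference keypoint. The matching-similarity statistic
   $100 \cdot \text{matches}/\min(n_\text{ref}, n_\text{mov})$ quantifies
   how well two slices share features.
4. **RANSAC planar transforms.** Minimal 4-point samples fit a projective
   homography (normalised DLT); inliers are counted at a transfer-error
   threshold `TR` (2 px default) and the iteration budget adapts as
   $k = \log(1-p)/\log(1-w^m)$ with $p = 0.995$, $m = 4$ and $w$ the best
   inlier fraction so far. The final model is refit by least squares on
   the best inlier set. Affine (3-point) and rigid (2-point) families are
   available via `model =`; rigid is the physically apt choice for
   within-subject motion, the homography is the general default.
5. **Transform chaining.** Adjacent frames share the most structure, so
   transforms are estimated between neighbours and composed
   recursively, $T = T_1 \times T_2 \cdots \times T_{i-1}$, to map frame
   $i$ into frame 1's grid; frames are then inverse-warped with bilinear
   interpolation, carrying validity masks.
6. **Fusion.** Three rules: `direct` (plain average on overlaps),
   `weighted` (the gradual-in/gradual-out ramp: on each pairwise overlap
   the weights run linearly from 1 to 0 along x between the overlap
   bounds, $\omega_1 = (x_2 - x_i)/(x_2 - x_1)$, $\omega_2 = 1-\omega_1$),
   and `mean` (mask-weighted per-pixel mean of all frames).
7. **Stacking.** Fused slices are stacked in z and written as NIfTI with
   the source affine.

Registration quality is assessed with MSE, NCC (Pearson), mutual
information and NMI $=(H_a + H_b)/H_{ab}$ on a shared 32-bin min-max
intensity binning (natural log), so `nmi(a, a) = 2` and independent
images approach 1.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `intervals_s` | 3 | scales per octave doubling; 6 Gaussian / 5 DoG levels |
| `base_sigma` | 1.6 px | blur of the first pyramid level |
| `contrast_threshold` | 0.03 | min interpolated DoG response on [0,1] slices |
| `edge_r` | 10 | curvature-ratio bound, i.e. $(r+1)^2/r = 12.1$ |
| `match_threshold` | 0.9 | nearest/second-nearest distance ratio |
| `TR` | 2 px | RANSAC inlier transfer error |
| `ransac_p` | 0.995 | confidence in the adaptive bound |
| `n_discard` | 4 | unstable leading frames dropped |
| `motion_limit_mm` / `_deg` | 2 / 2 | scrubbing limits with a motion table |

The octave count follows `floor(log2(min(w, h))) - 2` (smallest octave at
least 16 px); no initial 2x upsampling is applied, since 96 x 96 fMRI
slices carry little sub-pixel detail worth the fourfold cost.

## Design choices where the design was open

- **One orientation per keypoint.** No 80%-secondary-peak duplication:
  the dominant gradient direction alone defines the reference frame.
- **GLOH binning.** Radial bins are hard at the defining radii
  {6, 11, 15} (scaled by the keypoint's relative scale, making the
  descriptor scale-covariant); angular sectors and orientation bins use
  bilinear soft assignment. Softening the radial dimension too would make
  the printed radii mere interpolation nodes rather than bin boundaries.
- **RANSAC consensus floor.** A minimal sample always fits itself
  exactly, so "has $\ge m$ inliers" cannot distinguish signal from
  noise. A model is accepted only with at least `max(m + 2, 0.1 n)`
  inliers; below that the estimator raises a classed failure condition
  and the sequence layer records the identity for that pair, excluding
  the frame from fusion rather than aborting the layer.
- **Fusion fold order.** The weighted rule is defined pairwise; for a
  sequence it is folded in temporal order (frame 1 outward). For
  near-fully-overlapping registered slices the x-ramp makes this
  asymmetric, so the symmetric `mean` rule is provided and recommended
  when statistical efficiency matters more than literal gradual-in/out
  blending.
- **Reference frame.** The first retained time point; per-layer
  transforms are estimated independently per layer (a shared-transform
  variant across layers of a volume would be a natural extension).
- **Numerical guards.** Scale-space samples with |DoG| ≤ 1e-12 are not
  extremum candidates (a constant image blurred in floating point is
  numerically, not exactly, flat); squared descriptor distances below
  1e-12 are clamped to zero so identical descriptors match at ratio
  exactly 0; degenerate RANSAC samples (any collinear source triple at
  tolerance 1e-6 x bbox span squared) are re-drawn.

## What the synthetic phantoms emulate — and what they do not

`make_textured_phantom()` builds a head-shaped ellipse with ring
structure, a dark core, two-scale smoothed noise and a dense
jittered-grid blob field, textured so that a 96 x 96 slice (the in-plane
size the pipeline targets) carries a dense keypoint set (~45–60; the
packing limit of strict scale-space extrema at these scales).
`animate_phantom()` applies per-frame in-plane motion — a bounded random
walk of up to 2 px translation, 2° rotation and 2% scale by default,
which is the small-motion regime of a cooperative resting-state subject —
plus additive Gaussian noise (2% of range), optional unstable leading
frames with decaying low-frequency intensity drift, and optional
large-jump outlier frames for scrubbing tests. All ground-truth
transforms are recorded.

Geometric motion alone does not reproduce one empirical property of real
series: adjacent frames matching better than distant ones. The
descriptor pipeline is deliberately invariant to the motion, so matching
similarity stays flat under pure geometry. In real fMRI the effect comes
from temporally accumulating content change (BOLD fluctuation, slow
scanner drift); the optional `content_drift` field adds a smooth
random-walk intensity field per frame to emulate exactly that regime,
and is off by default.

Passing tests on these phantoms therefore demonstrate correct geometry,
robust estimation and the statistical benefits of fusion — not
robustness to through-plane motion, spin-history effects, susceptibility
distortion or physiological noise, none of which the planar model
represents. Through-plane motion in particular is a limitation of the
slice-wise method itself, not just of the phantom.

## Problem sizes used in the checks

The test suite runs phantoms at 96 x 96 in-plane with 1–2 layers and
4–20 frames for module-level checks, and one full-geometry build at
96 x 96 x 47 x 6 for the pipeline-shape check; parameter-recovery suites
use 60–100 point correspondences over 20 seeds. These sizes were chosen
so the whole suite exercises every path at the method's native slice
geometry while completing in a few minutes.

## Known limitations

- Planar (in-plane) transforms only; no z-aware or non-rigid model.
- The weighted fold is order-dependent on near-full overlaps (see above).
- Metrics assume single-modality intensity comparability; the MI/NMI
  binning is min-max per image over the evaluation mask.
- No slice-timing or motion *correction*: frames are excluded, never
  resampled; upstream correction tools remain appropriate before
  template construction.
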