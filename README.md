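# fmritemplate

Subject-specific 3D fMRI reference templates built from the subject's own
4D time series.

## Why

fMRI registration needs a reference image, but there is no standard fMRI
template, and normalising subjects whose anatomy departs from the adult
structural standards (children, elderly patients) into a standard space
introduces large errors. Within-subject registration avoids that — yet the
common practice of picking a single arbitrary time point as the reference
makes the reference noisy and researcher-dependent.

`fmritemplate` builds the reference from the whole series instead. Each
axial layer is treated as a 2D image sequence over time; frames are
aligned into the first frame's coordinate system and fused; the fused
slices are stacked into a 3D template that keeps the information shared
across all time points while averaging down the noise of any single one.

## Method

Per slice sequence:

1. **Keypoints** — difference-of-Gaussians scale space (base σ = 1.6,
   3 intervals/octave); strict 26-neighbour extrema, sub-pixel Taylor
   refinement, contrast threshold, and the principal-curvature edge test
   Tr(H)²/Det(H) < (r+1)²/r with r = 10. One dominant orientation per
   keypoint from a 36-bin (10°) gradient histogram over a 3σ disc.
2. **GLOH descriptors** — log-polar grid rotated to the keypoint
   orientation: 1 central disc + 2 annuli × 8 sectors, ring radii
   {6, 11, 15}·(σ/σ₀), 8 orientation bins per spatial bin → 17 × 8 = 136
   dimensions (L2-normalised, clipped at 0.2, re-normalised).
3. **Matching** — exhaustive nearest/second-nearest search with the
   ratio test (threshold 0.9), one-to-one by best distance per reference
   keypoint; similarity statistic 100·matches/min(n_ref, n_mov).
4. **RANSAC** — 4-point homography hypotheses (normalised DLT), inliers
   at transfer error < 2 px, adaptive iteration bound
   k = log(1−p)/log(1−wᵐ) with p = 0.995, m = 4; least-squares refit on
   the best inlier set. `affine` and `rigid` families are available.
5. **Chaining** — adjacent-frame transforms composed recursively,
   T = T₁ × T₂ ⋯ × Tᵢ₋₁, into frame 1's grid; bilinear inverse warping
   with validity masks.
6. **Fusion** — gradual-in/gradual-out weighted average
   (ω₁ = (x₂−xᵢ)/(x₂−x₁), ω₂ = 1−ω₁ across each overlap), plain direct
   average, or the symmetric mask-weighted mean.

Fused slices are stacked in z and written as NIfTI with the source
affine. Registration quality metrics: MSE, NCC (Pearson), mutual
information and NMI = (H₁+H₂)/H₁₂ on a 32-bin joint histogram.

A seeded phantom generator (`make_textured_phantom()`,
`animate_phantom()`) provides brain-like volumes with known ground-truth
motion, so the whole pipeline is testable without any imaging data.

## Worked example

```r
library(fmritemplate)

clean <- make_textured_phantom(96, 96, 4, seed = 3)          # ground truth
an    <- animate_phantom(clean, phantom_spec(t = 8, max_translation = 3,
                                             noise_sigma = 0.05, seed = 11))
tpl   <- build_template(an$sequence,
                        build_config(n_discard = 0, fusion_method = "mean",
                                     seed = 1))
dim(tpl$data)
#> template dims: 96 x 96 x 4

f  <- compute_slice_features(an$sequence$data[, , 2, 1])
#> keypoints on layer 1, frame 0: 39 | descriptor length: 136

f2 <- compute_slice_features(an$sequence$data[, , 2, 2])
ms <- match_features(f$descriptors, f2$descriptors)
matching_similarity(ms$n_ref, ms$n_mov, nrow(ms$pairs))
#> adjacent-frame matches: 25 | similarity: 64.10%
```

How good is the template as a reference? NCC against the noise-free
phantom on layer 2:

```
median single frame  0.9475
unregistered mean    0.9758
fused template       0.9947
```

The single frame carries the full noise, the unregistered mean is blurred
by the uncorrected motion, and the registered fused template recovers the
underlying structure best — which is the point of building one.

`save_template(tpl, "template.nii.gz")` writes the result;
`export_slices_png(tpl, "slices/")` dumps per-layer PNGs. The same
pipeline is scriptable from a shell via `inst/cli/fmritemplate.R`
(`build`, `evaluate`, `simulate` subcommands).

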