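---
title: "Detecting and measuring microtissue lumens in 3D image stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and measuring microtissue lumens in 3D image stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Glandular epithelial microtissues (for example MCF7 breast-cancer spheroids
grown in non-adhesive hydrogel micro-wells) form internal fluid-filled
cavities — lumens. The number and total volume of these lumens are
biologically meaningful endpoints: they respond to estrogen-receptor
signaling and thus to estrogenic endocrine-disrupting chemicals. `lumenr`
implements a fully automated pipeline that takes calibrated two-channel
fluorescence z-stacks (nuclei + F-actin) and returns, per microtissue, the
number of lumens and their individual and total volumes and surface areas.

```{r, eval = FALSE}
library(lumenr)
gen <- generate_stack(random_synthetic_spec(seed = 7))
report <- analyze_stack(gen$stack, run_config(),
                        clf = oracle_classifier(gen$truth))
report
```

# The detection model

A lumen on a single optical section is a *void*: a region with the same
(dark) intensity as the background, enclosed by bright cellular signal.
Detection therefore works on the background phase of a binarized slice:

1. **Fusion.** The nuclei and actin channels of a slice are min–max
   normalized and combined pixelwise (maximum by default). A constant
   channel normalizes to zeros rather than erroring, so degenerate slices
   flow through.
2. **Binarization.** After light Gaussian smoothing (sigma 1 px), a global
   threshold maximizing between-class variance (Otsu) separates cellular
   foreground from background. The original system's binarization method is
   not documented; Otsu is the standard choice for bimodal
   foreground/background histograms, and a fixed threshold is available for
   two-level synthetic inputs.
3. **Iterative closing.** Real lumen walls have imaging gaps. Morphological
   closing (dilation then erosion) with a Euclidean disk seals gaps narrower
   than the disk. A single large disk would also destroy small lumens, so
   closing is iterated with growing radii — 6 µm, then +5 µm per iteration
   for 8 iterations (6 … 41 µm) — each iteration sealing larger gaps while
   earlier iterations have already captured the small, clean voids.
4. **Void extraction.** 4-connected components of the background are
   labeled; the single largest component is the image background and is
   discarded; remaining components are candidate 2D lumens. Components
   smaller than 25 µm² are treated as noise specks (the area floor is
   configurable; the original description specifies no minimum).
5. **Superimposition.** A void sealed at iteration *k* reappears at all
   later iterations with non-increasing area (larger disks shrink it in
   place). Candidates from different iterations that share at least one
   pixel are therefore the same physical void; each overlap class is
   represented once, by its maximum-area member. Ties break deterministically
   (earliest iteration, then smallest component label).

Two conventions in step 3 are genuinely ambiguous in the original
description and are configurable here: "disk size" is read as the disk
*radius* (the common structuring-element convention; a diameter mode
exists), and the µm→pixel conversion rounds to the nearest integer with a
1 px floor for any positive radius. Void connectivity is 4-connected and
foreground 8-connected, the standard complementary pairing that avoids
topological paradoxes.

The closing itself is computed with exact squared Euclidean distance
transforms: dilation by a disk of radius *r* is exactly the set of pixels
with squared distance ≤ *r*² from the foreground, and erosion is the
complementary threshold on the dilated set. On a canvas padded by *r* pixels
this reproduces full-plane closing exactly — the implementation is tested
for bit-identity against a brute-force offset-loop oracle.

# Candidate screening

Phase-I candidates include true lumens but also background pockets and
texture holes. Each candidate is standardized into a classifier patch: its
bounding box is dilated by a 5 µm margin (so the classifier sees the wall,
not just the void), cut from the fused image, min–max rescaled, and
resampled to 64×64 px preserving aspect (zero-padded). The margin, the
rescaling interpretation of "remapped", and the 64 px side are package
choices; the original system fed 227 px patches to a transfer-learned deep
convolutional network whose weights and ~1000 manual labels are not
available.

The classifier is an interface with four interchangeable backends:

* **trained** (default for users): a random forest on radial-zone intensity
  features of the patch, trained from labeled patches with a seeded,
  stratified 80/20 split; held-out accuracy is logged.
* **heuristic**: a fixed logistic rule
  `p = plogis(-2 − 3·interior + 2·solidity + 5·rim_contrast)` on the mean
  interior intensity, candidate solidity, and rim-minus-interior contrast —
  a dark, compact void with a bright rim scores high. Requires no data.
* **oracle** (tests only): ground-truth lookup on synthetic stacks — a
  candidate is a true lumen iff ≥ 50 % of its pixels fall inside a
  ground-truth true void.
* **constant**: accepts everything (pure phase-I behaviour).

Raising the decision threshold can only shrink the accepted set; this
monotonicity is tested.

# 3D grouping and reconstruction

Accepted 2D lumens are grouped by the vertical-view rule: two lumens on
nearby slices belong to the same 3D lumen when their xy bounding boxes
intersect. With `max_gap = 0` (default, the strictest reading) any z-level
without a member splits the group, since such gaps most likely separate
vertically stacked lumens; `max_gap` is configurable because a 5 µm step can
plausibly skip a thin lumen waist.

Each group is reconstructed as an **alpha hull** of its boundary point
cloud. Rather than a Delaunay-based alpha complex, `lumenr` uses the exact
geometric identity that the alpha hull of a point set (complement of the
union of all open alpha-balls avoiding the points) *is* the morphological
closing of the set by a ball of radius alpha. On an isotropic voxel grid
both steps are again exact Euclidean distance thresholds. Volume is the
voxel count times the voxel volume; surface area integrates the gradient
magnitude of the Gaussian-smoothed indicator (coarea formula, accurate to a
few percent on smooth shapes).

Numerical choices that matter:

* **Slab semantics.** A 2D lumen is a `z_step`-thick optical slab, not an
  infinitely thin contour. Boundary points are placed on both slab faces
  (z ± `z_step`/2), and the outermost faces are sampled filled (not just at
  their rings) so the alpha ball cannot dive through open end caps. This
  makes multi-slice volumes consistent with the single-slice convention
  below and removes a systematic half-slab truncation at the top and bottom
  of every lumen, which is severe for lumens only 2–3 slices tall.
* **`alpha = "auto"`** bisects for the smallest alpha whose hull is a single
  connected solid enclosing the cloud: one connected foreground component, a
  connected complement (no internal cavity), and the cloud centroid inside.
  The centroid condition rejects thin leaky shells, which are connected and
  cavity-free yet enclose nothing. A fixed alpha in µm can be supplied; the
  original alpha parameter is unstated, so volumes are comparable within a
  configuration, not across implementations.
* **Single-slice lumens** get the extrusion convention: volume =
  area × `z_step`, surface = 2·area + perimeter·`z_step`. Coplanar points
  have zero alpha-shape volume, yet such lumens plainly count; extrusion by
  one z-step is the minimal consistent assignment. Multi-slice groups with
  fewer than 4 points fall back to extrusion with a warning.
* **Grid resolution** defaults to the xy pixel size, capped at 128 voxels
  per axis (the voxel grows for very large lumens). All reconstruction
  steps scale exactly: scaling the calibration by *s* multiplies volumes by
  *s*³ and areas by *s*² bit-for-bit.
* **Determinism.** Point clouds above 20 000 points are subsampled with a
  fixed seed; every tie-break in detection and grouping is deterministic, so
  identical inputs, config and classifier give byte-identical reports.

Known biases, measured on synthetic ground truth: the voxelized hull
carries roughly a half-voxel outward skin (≈ +6 to +12 % volume for
10–30 µm voids on a 1 µm grid), while sections thinner than the 6 µm
starting disk are closed away entirely, truncating the sharpest caps of
small lumens (an inherent floor of the iterative-closing design, not of
this implementation). The two effects partially cancel; the test suite
pins total recovered volume within ±15 % of analytic truth on seeded
stacks with lumens of 10–30 µm radius, and a digitized 20 µm ball within
10 %.

# The synthetic generator

Because the original study deposits no image data, every stage is validated
against a generator with full ground truth. It renders a spherical cell
mass (radius 65 µm by default) over a 160×160 px, 30-slice volume at 1 µm
pixels and the 5 µm acquisition step, with:

* **true lumens**: dark axis-aligned ellipsoidal voids (semi-axes 10–30 µm
  in the randomized study conditions), fully rimmed by the actin signal,
  optionally with a boundary-gap channel (≤ 8 µm) connecting them to the
  exterior — these exercise the iterative gap sealing;
* **decoy voids**: rimless holes (the surrounding wall signal is suppressed)
  inside the spheroid, and optional bright shell "pockets" outside it —
  enclosed voids that are not lumens, for classifier training and false
  positive accounting;
* **texture**: seeded nuclei speckle dots and Gaussian intensity noise
  (s.d. 0.05 on a [0, 1] scale).

Ellipsoids give analytic volumes (4/3 π a b c), so expected counts and
total volumes are exact. All randomness flows from a single spec seed; the
same spec renders bit-identical stacks.

What the generator does **not** emulate: point-spread-function blur, depth
attenuation, anisotropic optical sectioning, irregular (non-ellipsoidal)
lumen shapes, and touching/merging lumens. Passing tests therefore
demonstrate correctness of the pipeline's geometry and logic under
idealized optics, not segmentation robustness on raw microscope output;
on real data the binarization step and the classifier carry the burden
that the generator's clean contrast removes.

Test and acceptance problem sizes — 20 random stacks for geometry recovery,
200 patches for classifier training, ≤ 64×64 masks for oracle equality —
were chosen so the full suite exercises every property at desk scale.

# Limitations

* Lumens thinner than the starting disk radius (6 µm) on every slice are
  invisible by construction; lowering `r0` trades this against noise.
* Two lumens whose bounding boxes overlap on adjacent slices merge into one
  group even if their masks are disjoint (bbox overlap is the documented
  rule; a stricter mask-overlap mode is a natural extension).
* Volumes carry the voxelization skin described above; comparisons should
  be made within a fixed configuration.
* The trainable classifier ships untrained: real-data use requires labeling
  patches (the patch archive export and labels CSV exist for this) or
  accepting the heuristic baseline.
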