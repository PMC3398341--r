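---
title: "Reconstructing 3D heart volumes from 2D planning radiographs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing 3D heart volumes from 2D planning radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartnc)
```

## The problem

Estimating late cardiac toxicity after mediastinal radiotherapy requires 3D
dose-volume information, but patients with decades of follow-up were
planned on 2D simulator films: no CT, no 3D heart contour. `heartnc`
implements a reconstruction pipeline that recovers a patient-specific 3D
heart model from a single anterior planar radiograph by *adapting* a
deformable heart model built from other patients' CT data. The key idea is
that a small number of 1D edge measurements on the 2D image - taken in
rectangular regions of interest called *navigator channels* (NCs) - carry
enough information to re-shape an already-plausible 3D deformation field.

The pipeline, end to end:

1. **Population model.** Binary heart masks from several base patients are
   combined with a voxelwise logical OR and the union surface is extracted
   (`mask_union()`, `mask_to_mesh()`). The union *encompasses* every
   contributing heart, which matters later (see *Conditioning*, below).
2. **Reference registration.** The population surface is deformed onto a
   Reference patient's heart surface (`register_surface()`), giving a
   per-node displacement field $\Delta$ (population $\to$ Reference).
3. **Matching.** For a new Test patient (2D data only), the most similar
   Reference is found by thorax measurements: the inner-rib gaps $W_1$
   (upper row), $W_2$ (lower row) and the row distance $L$, compared by the
   least-squares difference
   $\mathrm{LSD} = \sqrt{(W_1^t - W_1^r)^2 + (W_2^t - W_2^r)^2 + (L^t - L^r)^2}$
   within the patient's own group (`measure_thorax()`, `lsd()`,
   `select_matches()`).
4. **Edge shifts.** The Test radiograph is scaled to the Reference
   magnification (`scale_to_reference()`) and rigidly aligned on bony
   landmarks (`rigid_align_2d()`, translation-only). Six channels are
   placed on the Reference image: four horizontal ones (NC1-NC4,
   2.0 x 0.5 cm) at the lateral circumflexes of the four chambers and two
   vertical ones (NC5, NC6, 0.5 x 4.0 cm) at the superior and inferior
   edges. Each channel reduces to a 1D mean intensity profile; the organ
   edge is the profile's point of inflection (POI), and the per-channel
   shift $\partial NC = POI_{test} - POI_{ref}$ (`extract_profile()`,
   `detect_poi()`, `compute_shift()`).
5. **Adaptation.** The field $\Delta$ is converted into a
   population-to-Test field $\partial$ by per-node rescaling with the
   channel ratios (see next section), then applied to the population model
   (`adapt_field()`, `reconstruct()`).
6. **Evaluation.** Volume overlap of meshes/masks by the Dice coefficient,
   $\mathrm{Dice} = 2|V_1 \cap V_2| / (|V_1| + |V_2|) \times 100$, after
   center-of-mass alignment; cohorts are compared with a paired Student
   t-test (`dice()`, `paired_t()`, `summarize_cohort()`).

## The adaptation model

Let $k_x, k_y \in [0,1]$ be a node's normalized position in the heart's
bounding box in the image plane ($k_x = 0$ at the patient-right edge,
$k_y = 0$ at the superior edge), computed from the *Reference-deformed*
model - the Test anatomy is unknown at deployment time. Each channel
contributes a ratio term

$$ t_i \;=\; \Delta(x_0)\,\frac{\Delta NC_i + \partial NC_i}{\Delta NC_i}, $$

where $\Delta NC_i$ is the mean channel-axis displacement of the nodes
projecting into channel $i$'s rectangle (`field_at_channel()`). Nodes are
updated as convex combinations of these terms:

* **Longitudinal** (all nodes): superior and inferior channel terms
  blended with weights $(1 - k_y)$ and $k_y$.
* **Lateral, upper region** (above the NC3/NC4 row): NC3/NC4 terms with
  weights $(1 - k_x)$ and $k_x$.
* **Lateral, lower region** (below the NC1/NC2 row): NC1/NC2 terms, same
  weights.
* **Lateral, middle region**: bilinear blend of all four lateral terms
  with weights $(1-k_x)(1-k_y),\, k_x(1-k_y),\, (1-k_x)k_y,\, k_x k_y$
  for the (right-upper, left-upper, right-lower, left-lower) channels -
  the outer product of the two linear weight pairs, summing to 1.
* **Anterior-posterior**: $z$-displacements pass through untouched. No
  lateral film exists, so nothing constrains this direction; residual
  reconstruction error concentrates here by construction.

**Weight orientation.** The source formulas for this scheme are internally
inconsistent about which channel carries which weight (the superior channel
is weighted by the coordinate that is *zero* at the superior edge, and
likewise laterally). We resolve the ambiguity with the only reading that
makes the blends interpolating: *each channel's weight is one minus its
normalized distance to the node*, so the nearer channel dominates and the
middle-region formula continuously matches the upper/lower formulas in the
$k_y \to 0, 1$ limits. Which of NC5/NC6 means "superior" is configuration
(`superior_channel`, default NC5).

**Degenerate denominators.** $\Delta NC$ can vanish; the ratio form then
explodes. Below $\varepsilon$ = 1e-6 cm the term switches to the additive
correction $t_i = \Delta(x_0) + \partial NC_i$, the unique finite limit
that preserves the zero-shift identity.

**Exact identity.** All blends are evaluated in lerp form
$a + w\,(b - a)$. When every $\partial NC = 0$, every ratio is exactly 1
and the adapted field is *bit-for-bit* the input field - the central sanity
property of the scheme, asserted in the tests without tolerance.

**Conditioning.** The ratios are only informative when $|\Delta NC|$ is
substantial. This is not left to luck: a *union* population model is
strictly larger than every heart it is registered to, so $\Delta$ points
inward with magnitude comparable to the anatomical differences everywhere.
During development we observed exactly the predicted failure when a
merely-similar (non-encompassing) population model was used: a local
$\Delta NC \approx 0.04$ cm turned a $-0.57$ cm edge shift into a 14-fold
displacement amplification. The phantom cohort therefore builds its
population model the same way the real pipeline does, by voxel union of
base hearts.

## What stands in for what

* **Registration.** The original platform solves a biomechanical
  finite-element model (linear elastic interior). Only the *surface*
  displacement field feeds the adaptation, so `register_surface()` uses
  iterative closest-point projection with Laplacian smoothing of the
  displacement field and step damping that makes the mean-residual log
  non-increasing by construction. Non-convergence is a warning carrying the
  residuals, not an error. This is a documented stand-in, not a
  re-implementation of the FEM engine; typical phantom residuals are
  below 0.01 cm against a 0.2 cm contract.
* **Meshes.** Heart models are closed triangulated surfaces, not
  tetrahedral volume meshes: the adaptation acts on surface nodes and the
  evaluation needs only enclosed volume.
* **Projection.** DRRs are parallel projections (attenuation line
  integrals along the anterior-posterior axis). Both images of a pair are
  normalized to a common magnification before any measurement, so
  divergent-beam magnification would cancel anyway; the source-to-axis
  distance is carried as metadata.
* **Rigid 2D alignment** is translation-only: the three bony landmarks are
  nearly collinear along the midline, so a fitted rotation would be
  ill-conditioned. Known limitation.

## Signal processing choices

* **POI detection.** Profiles are Gaussian-smoothed before
  differentiation. The kernel is truncated and renormalized at the window
  ends; mirror or extrapolation padding fabricates curvature there and
  biases POIs of edges that sit off-center (exactly the large-shift case
  that matters). The default `smoothing_sigma` is **1 sample**: with the
  2.0 cm horizontal channels at 0.1 cm pixel pitch (20 samples), a sigma-2
  kernel spans 80% of the window and produced ~1-pixel POI bias for
  0.5 cm shifts; sigma 1 recovers imposed shifts of up to 0.5 cm to well
  under half a pixel on all six channels. Raise it for genuinely noisy
  film digitizations.
* **Edge gate.** An edge must *dominate* the channel: the profile's net
  change must be at least `edge_frac` (default 0.5) of its total
  variation, and the curvature must be significant relative to the
  intensity range. The gate is invariant to affine intensity rescaling
  $aI + b$; linear ramps (constant slope) and flat or noise-only profiles
  raise a no-edge error instead of returning a number.
* **Inner-rib measurement.** On each row, the rib's inner border is the
  innermost *outward-rising* gradient peak on each side of the midline.
  The sign rule is what makes this robust: walking outward, soft tissue
  to bone (rib inner border) rises, while the spine border and the heart
  silhouette fall, so neither can be selected. No midline exclusion zone
  is needed.

## The phantom world

Phantom hearts are superellipsoids with four Gaussian radial bulges at the
lateral circumflex positions where NC1-NC4 sit - curvature structure the
multi-channel scheme exists to capture - plus optional smooth seeded
roughness. The thorax is an elliptical soft-tissue cylinder (attenuation
1) whose half-width interpolates between the two rib rows, with rib blocks
(attenuation 3) whose inner borders are placed exactly at $\pm W_1/2$ and
$\pm W_2/2$ on the voxel lattice, a posterior spine column, and the
voxelized heart (attenuation 1.5). No beam physics: the downstream stages
need edge contrast, not dosimetric realism. All generators are pure
functions of their parameter records.

The evaluation cohort (`make_phantom_cohort()`) states one world:

* 15 Reference/Test pairs (the cohort size of the clinical study this
  emulates), hearts of semi-axes about (5.0, 6.0, 4.2) cm varied by a few
  percent, lobes 0.3-0.9 cm, roughness 0.1 cm;
* Test = Reference through composite scale (0.82-1.18 laterally and
  longitudinally), translate (up to 0.4 cm), bend (up to 0.5 cm);
  anterior-posterior scale fixed at 1;
* a population model built by union of 6 generously sized base hearts;
* 0.2 cm grids throughout (desk scale; the planning grid
  0.1 x 0.1 x 0.3 cm is available via arguments and is used where
  sub-pixel accuracy is itself under test).

The scale spread is chosen so the *un-adapted* Reference-vs-Test overlap
lands in the mid-80s to low-90s - the regime the clinical baseline reports.
The translation budget is deliberately small: matched patients are aligned
on bony landmarks, and a pure heart translation is a known blind spot of
the multiplicative adaptation (nodes with $\Delta(x_0) \approx 0$ cannot be
translated by rescaling) while simultaneously costing nothing in the
COM-aligned Dice. A world dominated by translation would therefore test
the method against a deformation class it is documented not to represent.

What a green cohort test establishes: on smooth, single-component,
noise-free anatomy with exactly known ground truth, the full pipeline
(registration + channel detection + adaptation) strictly improves mean
Dice over the un-adapted Reference model with a paired-t p below 0.05.
What it does not establish: performance on real film (noise, scatter,
overlapping structures), multi-chamber internal anatomy, breathing motion,
or any dosimetric claim. The clinical study's patient numbers
(89.4 +/- 2.8% with vs 85.4 +/- 6.8% without adaptation) are not
reproducible without patient CTs and are deliberately not asserted;
the qualitative property suite replaces them.

## Numerical choices

* Voxel (i, j, k) centers sit at `origin + (i + 1/2) * spacing` (0-based);
  world frame is +x patient-left, +y patient-inferior, +z
  patient-posterior, so "superior" is always the smallest y.
* Surface extraction is watertight boundary-face ("cuberille")
  extraction; with no smoothing the enclosed volume equals the mask volume
  exactly. Edge-adjacent diagonal voxel pairs (non-manifold) are resolved
  by filling one voxel - material is only ever added, preserving the union
  model's encompassing property. Optional Laplacian smoothing shrinks
  volume slightly and is off by default.
* Inside/outside for voxelization is ray-casting parity along +x; rays
  that graze a triangle edge (or return odd crossing counts) are recast
  with a deterministic half-voxel * 1e-3 offset, *incommensurate* in y and
  z so rays also leave the diagonals of axis-aligned cuberille faces.
  Counts are exactly reproducible.
* Dice evaluation defaults to a 0.2 cm isotropic grid; halving the spacing
  moves phantom Dice values by well under one point (asserted). COM
  alignment uses exact mesh volume centroids (divergence theorem) for
  meshes and nearest-voxel shifts for masks.
* Ties in reference selection break lexicographically by reference id;
  ties among POI candidates break toward the channel center.

## Known limitations

* Anterior-posterior shape is uncorrected by construction; Dice gains come
  from the in-plane directions only.
* Pure in-plane translation of the heart relative to the skeleton is only
  captured near the channels (see above).
* The ICP-projection registration has no volumetric regularization; for
  wildly dissimilar shapes (beyond ~20% scale differences) its residual
  contract is not guaranteed.
* `rigid_align_2d()` ignores rotation.
* Voxelization is O(triangles x in-bbox rays) in plain R; grids much finer
  than the planning grid get slow before they get inaccurate.
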