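---
title: "Methods: how vesseg detects and measures synaptic vesicles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how vesseg detects and measures synaptic vesicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`vesseg` treats a synaptic vesicle in a stained, plastic-embedded
electron tomogram as a *clear core inside a dark ring*: an
electron-lucent lumen of 30–60 nm bounded by a ~4–5 nm electron-dense
membrane shell, embedded in cytosol that is on average darker than the
lumen because it is crowded with stained macromolecules. The pipeline
never models image formation; it is a morphological chain whose stages
each assume only this ordering of intensities:

1. **Per-slice mean threshold.** Foreground = pixels strictly brighter
   than the slice mean. This works because the slice mean sits *between*
   the cytoplasm bulk and the lumen level; the mass that puts it there
   is largely the electron-lucent extracellular space, which the
   hand-traced cell boundary later excludes from analysis while it still
   contributes to the mean. The selected pixel set is invariant under
   positive affine intensity changes, so the preceding contrast stretch
   cannot change the result — it exists for the human eye and for the
   fixed-scale bilateral range sigma.
   The thresholded particles are the vesicle **lumina**; this is why the
   measured diameters are *inner* diameters and why a membrane offset is
   added at the end. (The alternative polarity — treating the dark
   membranes as foreground — cannot reproduce inner diameters: membrane
   shells segment as hollow rings and polar caps, and no downstream
   stage reassembles them into per-vesicle particles.)
2. **Cell-boundary masking.** The wall polygon is traced on the first
   and last slice only; intermediate slices use the vertex-wise linear
   blend of the two polygons after arc-length resampling to 128 vertices
   (counterclockwise, starting at the maximal-x vertex, so vertex
   correspondence is well defined). Pixel inclusion is
   center-in-polygon by the even-odd rule.
3. **Bounded hole filling.** Each slice is dilated by a 1-px disk, then
   enclosed background regions with areas of 0–575 px are filled. The
   upper bound is what protects the membrane annulus around a
   normal-sized vesicle (area well above 575 px at 1 nm/px) from being
   swallowed while real defects inside lumina are repaired. The
   dilation is not undone; its ~+1 px bias roughly cancels the later
   1-px erosion.
4. **Two-stage watershed.** A per-slice distance-transform watershed
   first draws 1-px separation lines between touching 2D basins; an
   erosion plus removal of 2D components above 6000 px then deletes the
   large interconnected cytoplasmic masses. The surviving foreground
   gets an anisotropic 3D Euclidean distance map (physical spacing
   (1, 1, voxel depth) nm), smoothed with a physically isotropic
   Gaussian (sigma 3.45 px in x/y, divided by the voxel depth in z).
   Seeds are voxels that attain the local maximum within a 2.3 nm ball;
   maxima closer than that merge into one seed (single linkage), which
   is what keeps the flat ridge of a tubular structure from seeding a
   fragment chain. Flooding proceeds by decreasing map value through
   26-neighbourhoods, restricted to foreground with map value >= 2, with
   ties broken by seed label then linear index — the output is fully
   deterministic.
5. **Basin fill-in.** After flooding, each basin annexes the
   below-threshold rind of its own particle. Without this the distance
   threshold plus smoothing erodes every label by about 2 nm of radius
   and all diameters come out ~4 nm small — a measured, structural bias
   that would defeat the point of the inner/outer diameter bookkeeping.
   The map threshold keeps its two real roles (seed gating and flood
   order); set `segment_params(fill_basins = FALSE)` for the strict
   thresholded-domain behaviour.
6. **Morphometry.** Volume = voxel count (1 x 1 x depth nm voxels);
   centroid = mean voxel center; fitted-ellipsoid diameters from the
   eigenvalues of the voxel-coordinate covariance with the intra-voxel
   moment added, using the uniform-ellipsoid relation
   `semi-axis_i = sqrt(5 lambda_i)`; Feret = maximum pairwise distance
   between boundary-voxel centers; elongation = d1/d2 (major over
   *second* axis, so flat oblate debris is not caught by it — that is
   the sphericity rule's job); sphericity
   `pi^(1/3) (6V)^(2/3) / A` with the surface area A estimated by the
   coarea method: smooth the label indicator with a small physically
   isotropic Gaussian (sigma 1.25 nm) and integrate the gradient
   magnitude. Plain exposed-face counting with a single global
   correction factor is calibrated for spheres but underestimates flat,
   axis-aligned surfaces by up to a third, which inflates the
   sphericity of plate- and lens-shaped debris past the 0.5 cutoff; the
   coarea estimate is within ~1–2 % for digitized spheres and ~10–15 %
   for plates, which is what the filter actually needs. A closed-form
   caveat worth knowing: a 10:1 rod has sphericity 0.579, *above* the
   0.5 cutoff — rods are removed by the elongation and volume rules,
   not by sphericity.
7. **Exclusion criteria.** Remove when `volume_vx < minimum` OR
   `sphericity < 0.5` OR `elongation > 2.0`. Presets: `celegans`
   (3000 vx), `zebrafish_20k` (5000), `zebrafish_30k` (6500). Volumes
   are voxel counts at the working scale, configurable.
8. **Measurement.** `mean_diam = (d1+d2+d3)/3` is the inner diameter
   estimate; `corrected_diam = mean_diam + 8.9 nm` (twice the membrane
   thickness) estimates the membrane-inclusive outer diameter that
   manual annotation measures. Pool density is the ascending list of
   center-to-center distances to the n closest neighbours.

# Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `target_px_nm` | 1.0 | nm/px | working scale; all later pixel thresholds assume it |
| `saturation_fraction` | 0.004 | — | contrast stretch clipping, split between tails |
| `mean_radius_px` | 3.45 | px | noise smoothing; 37-offset circular kernel |
| `bilateral_spatial_sigma` / `range_sigma` | 3 / 50 | px / 0–255 units | edge-preserving denoising (range sigma on the stretched scale) |
| `dilation_radius_px` | 1 | px | pre-fill dilation (smallest possible) |
| `hole_min_px` / `hole_max_px` | 0 / 575 | px | hole-fill area band |
| `erosion_radius_px` | 1 | px | pre-removal erosion |
| `max_particle_area_px` | 6000 | px | 2D large-component removal |
| `dmap_gauss_sigma` | 3.45 | px | distance-map smoothing (physically isotropic) |
| `dmap_threshold` | 2 | nm | seed/flood gate on the smoothed map |
| `seed_radius_px` | 2.3 | nm | maxima detection + merge radius |
| `fill_basins` | TRUE | — | annex the below-threshold rind after flooding |
| `min_volume_vx`, `min_sphericity`, `max_elongation` | preset | vx, —, — | exclusion criteria |
| `n_neighbors` | 3 | — | neighbour distances reported |
| `membrane_offset_nm` | 8.9 | nm | inner-to-outer diameter correction |

# What the phantom emulates — and what it does not

`generate_phantom()` renders, with 3x3x3 sub-voxel anti-aliasing on an
anisotropic grid (default 1.6 nm slices):

* vesicles: dark shells (4.45 nm, level 60) around uniform lumina
  (level 150), inner diameters N(40 nm, 5 nm) truncated at 3 SD;
* cytoplasm: bright matrix (level 100) darkened by correlated granules
  (fraction 0.3, grain 8 nm, at shell darkness) — realized bulk ~88;
* extracellular space at level 130 outside an irregular 16-gon cell
  boundary with a dark wall, traced ROIs on the first and last slice;
* confounders: dark-walled bright-cored tubules (interior radius
  6.5 nm — chosen so *any* watershed fragment of a tubule fails either
  the volume minimum or the elongation cap), vesicle-like shells below
  the volume minimum, and oversized compartments clipped at a z face;
* additive Gaussian noise (sd 8).

Placement is dart throwing followed by staged-growth pair-repulsion
relaxation, because a realistic pool (40 vesicles in a
300 x 300 x 96 nm cell) sits at random-close-packing density where
sequential rejection sampling provably jams. Membranes may touch
(center distance down to `r_in_i + r_in_j + shell`, with a 40 nm floor);
lumina always stay separated by a shared dark wall — which is exactly
the structure the algorithm segments. Vesicle centers may approach the
z faces to half an inner radius, as in any real tomogram slab.

The phantom deliberately does **not** model tilt-series physics: no
missing wedge, no CTF, no reconstruction streaks, no membrane blur
beyond voxel anti-aliasing, and its intensity classes are cleaner than
any real tomogram. A green phantom test therefore establishes that the
*algorithmic chain* is correct and well-calibrated at the stated
contrasts and density — it does not promise the same precision/recall
on low-quality tomograms, where the original workflow also degrades and
relies on the manual proof-reading step. Oversized round organelles are
the structural counterexample: a hemispherical remnant has sphericity
~0.85 and passes every automatic criterion; it is precisely what the
edit list (`delete <id>`) is for.

# Numerical choices and degenerate inputs

* Contrast-stretch clip points are inverse-ECDF (type 1) quantiles of
  the whole stack; a constant stack is returned unchanged; a constant
  slice thresholds to empty foreground (strict inequality).
* The 2D watershed detects maxima on a lightly smoothed (sigma 1) EDT so
  digitization ripples do not over-seed; plateau maxima are grouped.
* Seeded-3D-watershed ties (equal map values) resolve by lower seed
  label, then lower linear index: outputs are byte-reproducible.
* EDT treats volume borders as *not* background, so particles clipped by
  the reconstruction boundary keep their interior distances.
* Moment eigenvalues are floored at 1e-12 and include the intra-voxel
  uniform moment (1/12 per in-plane axis, depth^2/12 along z), so a
  single-voxel label still has positive diameters.
* Matching pads the assignment problem with dummy rows/columns
  (unmatched penalty far below the forbidden-pair cost), so leaving a
  too-distant pair unmatched is always preferred to a forced bad match.
* Undefined metrics (zero denominators) are reported as `NA`, never 0.

# Design decisions that were genuinely open

* **Threshold polarity.** Not stated by the method's published
  description; resolved to bright-is-foreground because only lumen
  segmentation reproduces inner diameters and the +8.9 nm correction
  (see section 1).
* **ROI file format** is a minimal plain-text format (`slice <i>`, then
  `x y` lines) rather than a binary ROI container, to stay
  language-agnostic.
* **Volume criteria in voxels** at the 1 nm/px working scale (their
  original unit is not documented); exposed in the configuration.
* **Elongation uses d1/d2** literally (major over second radius), not
  d1/d3.
* **Distances are center-to-center**, not surface-to-surface.
* **The matcher is an explicit optimal assignment with a distance
  cutoff** (default: half the mean ground-truth inner diameter); the
  original evaluation matched by human inspection, which is not
  reproducible.

# Known limitations

* Quality is texture-dependent: if the cytoplasm's bright pockets reach
  vesicle scale (poor staining/reconstruction), false positives rise and
  the proof-reading step becomes necessary — mirroring the original
  tool's behaviour across tomogram quality.
* Vesicles clipped by more than about half a radius at the volume faces
  bias their own measured z diameter low.
* The per-slice mean threshold assumes a lucent extracellular region (or
  comparably bright mass) within the field of view; a field of view
  entirely inside dense cytoplasm would need an explicit threshold
  offset.
* Labels above 65535 fall back to 32-bit TIFF output; readers that only
  support baseline 16-bit grayscale TIFF will not open those maps.
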