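---
title: "Quantifying hard- and soft-tissue displacement between superimposed 3D scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hard- and soft-tissue displacement between superimposed 3D scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispquant)
```

## The measurement problem

Orthognathic-surgery outcome studies need to know how far the jaws moved and
how far the overlying skin followed. With cone-beam CT at two time points
(pre-surgical T1 and a post-surgical follow-up T2), the measurement decomposes
into four steps, each of which this package implements:

1. **Rigid superimposition.** T2 is mapped into T1's frame by a rigid 6-DOF
   transform estimated from voxel intensities restricted to the cranial base —
   a region surgery does not touch — so that everything that *did* move shows
   up as displacement rather than head pose.
2. **Label-separated surface extraction.** The maxilla (with upper teeth),
   mandible (with lower teeth) and soft tissue are segmented as distinct
   labels and converted to separate triangle meshes. Keeping the labels
   separate is load-bearing: a closest-point search from a lip region must
   never match against teeth, nor an upper jaw against the lower.
3. **Region-restricted closest-point displacement.** An operator paints a
   small surface region (an "area") on the reference mesh; each region vertex
   is assigned the distance to its closest point on the same-label mesh at
   the other time point, signed by the vertex's outward normal (outward
   change positive). The region's minimum, maximum and mean are reported;
   the mean is the study quantity.
4. **Statistics.** Intra-rater repeatability of the area means across two
   measurement sessions (ICC), descriptive tables, and Spearman rank
   correlations between hard- and soft-tissue areas, split into maxillary
   and mandibular sets.

No patient data ship with this package. Every claim the test suite makes is
validated on synthetic phantoms with analytically known ground truth.

## Why regions, and when closest-point means are trustworthy

A closest-point distance is a lower bound on the true motion of a surface
point. Where the two surfaces overlap (the lateral walls of an advanced jaw),
the closest point lies on the overlapping wall at distance near zero, so a
mean over the full surface is grossly underestimated; the
`full_surface_summary()` diagnostic and `analytic_box_advance_mean()` make
this quantitative. For a box with `a x b` faces advanced by `d` along its
depth `c`, the area-weighted full-surface unsigned mean is

$$\bar{d}_{100\%} = \frac{2abd + \tfrac{4}{3}d^{3}}{2ab + 2(a+b)c},$$

far below `d` for elongated shapes (3.0 mm versus 5 mm for a
60 x 60 x 20 mm jaw advanced 5 mm). Two geometric conditions must hold for a
painted region's mean to equal the true displacement `d`:

* **Edge distance.** Every region vertex must be farther than `d` from the
  silhouette edges of its face, or the displaced side walls are closer than
  the displaced face.
* **Thickness.** The structure must be thicker than `2d` along the motion,
  or the closest point jumps to the displaced *inner* surface of the
  structure (at distance `t - d < d`). This is why thin shells and large
  advancements are a poor combination for closest-point assessment, and it
  is enforced by construction in the phantom geometry.

Curved regions that mix inward and outward change (negative and positive
signs) underestimate in a different way — the signed contributions cancel —
so `region_summary()` warns whenever the negative fraction falls between 5%
and 95%. Signed means are the primary report; unsigned means are carried
alongside.

## The phantom generator

`phantom_spec()` / `make_phantom()` / `apply_surgery()` / `make_cohort()`
generate two-time-point subjects with known per-label rigid transforms:

* A **primitive skull**: cranial-base slab, maxilla and mandible boxes with
  flat anterior faces, a soft-tissue shell in front of each jaw, and a small
  separate "nose" shell. Flat faces are deliberate: translation along the
  face normal makes the expected region mean exactly the advancement.
  Structure depths obey the thickness rule above for the largest advancement
  the cohort distribution can draw.
* **Surgery** as rigid per-label translations: each jaw advances sagittally;
  each soft shell moves by `coupling x (its jaw's advancement)` plus an
  isotropic per-subject jitter (3-vector, sd `soft_noise_sd_mm`); the nose
  gets an independent small shift, so it is genuinely uncoupled from the
  jaws. Jitter is per subject rather than per vertex so the soft label stays
  rigid and every region has an exact expected value.
* A whole-head **nuisance pose** (default up to 2 degrees / 2 mm) applied to
  the T2 subject, forcing the registration stage to do real work.
* An **imaging model**: intensity volumes are rendered analytically as boxes
  convolved with a Gaussian scanner point-spread function
  (`psf_sigma_mm = 0.4`), i.e. a separable product of normal CDFs per axis
  evaluated at inverse-transformed voxel centres, plus additive Gaussian
  noise (`noise_sd = 30` on bone 1200 / soft 300 / air 0). Rendering the
  band-limited field analytically matters: nearest-neighbour voxelization of
  a rotated box leaves staircase artifacts no real scan has, and those
  artifacts displace the mutual-information optimum by several tenths of a
  millimetre.
* Cohort defaults mirror the study design: maxillary advancement U[1, 5] mm,
  mandibular U[5, 15] mm, coupling U[0.8, 1.0], eight subjects. These are
  the generating conditions of the validation experiments, not a calibration
  claim about any particular sample.

What the phantom does **not** emulate: anatomical shape, CBCT physics
(beam hardening, metal artifacts from brackets — a known limitation of the
real measurements around teeth), segmentation error, and genuinely non-rigid
soft-tissue deformation. Label maps are still stored as integer grids, so a
*rotated* subject's labels carry voxel quantization: flat faces become long
staircase treads, and a small painted region samples a single tread. Under
the default 2-degree poses this adds a per-region offset of up to roughly
0.3 mm — a realistic stand-in for segmentation quantization, and the reason
exact-value tests use unrotated poses while cohort-level tests rely on rank
statistics.

## Registration internals

`register_rigid()` maximizes mutual information (32 bins per image) over the
cranial-base mask with a derivative-free Nelder-Mead simplex, coarse-to-fine
(mask subsampled by stride 4, then full, capped at 15,000 points), with a
restart on non-convergence; non-convergence after restart is flagged on the
result, never silently accepted. Three implementation details matter:

* The mask is **dilated 3 mm** so it straddles the bone/air boundary —
  intensities interior to one tissue are featureless noise and carry no
  alignment signal.
* Sample positions are **jittered off-grid** once (deterministic seed).
  Sampling exactly at voxel centres makes trilinear interpolation smooth the
  moving image more at half-voxel offsets than at aligned ones, which
  inflates mutual information away from the true pose by ~0.3 mm; jittered
  positions equalize the smoothing across poses.
* The internal objective bins the moving intensities with **partial-volume
  (linear) weights**, keeping the objective continuous in the pose
  parameters. The exported `mutual_information()` uses hard binning instead,
  because the public score should be exactly symmetric in its arguments.

On default phantoms the recovered pose lands within ~0.01 mm / 0.01 degree
of ground truth; the acceptance suite requires a median under
0.1 mm / 0.1 degree across twenty random poses up to 5 degrees / 5 mm, with
jaw surgery applied, and `resample()` reproduces the 0.4 mm to 0.5 mm
reformatting step with trilinear interpolation (labels: nearest-neighbour).

## Surface extraction internals

Surfaces are extracted per label at the 0.5 iso-level by **marching
tetrahedra** on the translation-invariant Kuhn 6-tetrahedron cube
decomposition. The tetrahedral cases are unambiguous, faces on shared cube
boundaries coincide, and crossing vertices are welded through an edge hash,
so extracted phantom surfaces are watertight (Euler characteristic 2 is
asserted in the tests). Winding is fixed locally so normals point out of the
labelled solid.

The binary indicator is first **anti-aliased** with a Gaussian of sigma
1 voxel. An isosurface of a raw binary mask carries only axis- and
diagonal-quantized facet normals and overestimates a 20 mm sphere's area by
about 9%; anti-aliasing reduces that to about 0.3%, while a symmetric blur
leaves flat boundaries exactly in place, so distances are unaffected. This
is indicator anti-aliasing, not mesh smoothing — no vertex of the extracted
mesh is ever moved afterwards (smoothing would change distances), and
`antialias_sigma = 0` restores the raw binary behaviour.

Closest-point queries run through an axis-aligned bounding-box tree with
lower-bound pruning; pruning is non-strict, so exact ties are never
discarded, and among exactly equidistant triangles the lowest index wins —
determinism over geometric preference. The tests assert bit-level agreement
with an exhaustive all-triangles scan written independently in R.

## Statistical choices

* **ICC form.** One operator measured twice, and the question is whether the
  two sessions agree in absolute value, so the package uses ICC(A,1) —
  two-way, absolute agreement, single measurement — with the F-based 95%
  confidence interval. An offset between sessions lowers this coefficient,
  which is the conservative reading of a repeatability table. The model tag
  is printed in every result. The implementation computes the mean squares
  directly; the test suite checks it against `aov()` to 1e-10.
* **Exact permutation p for Spearman at n <= 9.** At n = 8 the t
  approximation is visibly coarse: enumerating all 40,320 rank permutations
  shows worst-case two-sided discrepancies of 0.024 even for |rho| < 0.7.
  Exactness is cheap (the tie-free null distribution is cached per n), so
  exact p-values are used whenever n <= 9; ties fall back to full
  per-sample enumeration with average ranks, larger n to the t
  approximation, and the method used is recorded in the result.
* **No multiple-testing correction by default**, matching the per-pair
  alpha = 0.05 convention of the correlation tables; Holm adjustment is
  available behind `adjust = "holm"`. The rendered matrix places r below
  and p above the diagonal with significant cells starred, and the type-I
  error of the marked cells is verified by simulation to sit near the
  nominal level (the discreteness of the exact null makes it slightly
  conservative, ~0.04-0.05).
* The t-based confidence interval of the mean between-session difference
  (`difference_report()`) is `mean ± t(n-1, 0.975) * sd / sqrt(n)`.

## Degenerate inputs and tie-breaks

Empty masks, absent labels, zero-triangle meshes, zero rank variance,
zero between-subject variance, seeds farther than 2 mm from a surface,
cross-label queries and stale region checksums are all hard errors naming
the offending object. Zero-dot-product displacement signs tie to positive.
A null surgical plan with no seed returns its inputs unchanged, bit for bit.

## Problem sizes

The default phantom grid is 128 x 224 x 208 voxels at 0.5 mm (a 64 x 112 x
104 mm field of view); registration uses at most 15,000 mask samples; the
validation cohort has eight subjects, matching the study design. These sizes
keep a full cohort analysis — registration, twelve surface extractions,
thirty region measurements and the statistics — around two minutes on one
CPU, and they are stated here as the package's reference configuration.

## Known limitations

* Advancements are pure translations; pitch/yaw components of real surgery
  (explicitly called out as limiting factors for the closest-point method)
  are representable through `head_pose` but not part of the per-jaw model.
* Geodesic painting uses shortest edge paths, not exact geodesics.
* The per-region voxel-quantization offset under rotated poses (~0.3 mm)
  bounds how precisely a rotated subject's regions can be measured; the
  registration itself is an order of magnitude more accurate.
* Closest-point correspondence is not a motion field: it underestimates
  wherever its geometric preconditions (edge distance, thickness, sign
  purity) fail. The package surfaces these failure modes as diagnostics
  rather than hiding them.
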