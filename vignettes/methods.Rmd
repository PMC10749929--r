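---
title: "Montaging and elastic alignment of serial-section mSEM stacks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Montaging and elastic alignment of serial-section mSEM stacks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`emstitch` assembles serial-section multibeam SEM volumes: per-section 2D
tile mosaics with beam-artifact correction, then a 3D alignment staircase
(coarse → rough → fine → ultrafine) that deliberately constrains each step
as much as possible, so that only the residual the previous stage could not
express is handed to the next, more flexible one. This vignette explains
the models, the parameters and their defaults, what the synthetic fixtures
emulate, and the design decisions taken where the design was genuinely
open. All lengths are stored in nm internally; images are processed at a
working pixel size (default 16 nm), and transforms scale linearly to any
export pixel size.

## Coordinate conventions

Images are numeric matrices `m[row, col]` in `[0, 255]`. Public pixel
coordinates are 0-based pixel centers, `x = col - 1` rightward and
`y = row - 1` downward; for even dimensions the image center falls on a
half pixel, and the same center convention is used by the 2D and 3D
matching stages. All stage transforms are stored as
**destination-to-source** lookups in the rough-bounding-box frame: sampling
section *i* at `q + u_i(q)` produces the content that belongs at `q`.
Export therefore applies stage "inverses" by direct composition in reverse
measurement order (ultrafine warp, fine warp, rough affine, coarse affine)
— there is no numerical inversion of elastic fields, by construction.

## The difference-system solver

Every reconciliation step in the pipeline is a weighted linear least
squares problem over a *difference system*: one row per measured delta,
`+1` at the destination entity and `-1` at the source, so that
`A x = delta` encodes `x[dst] - x[src] = delta`. The x and y axes share
the adjacency and are solved independently (`solve_deltas()`,
sparse normal equations via Matrix). Three bias policies are used,
matching the topology of each application:

* **2D tile coordinates** (planar hexagonal adjacency): only an offset
  bias arises; it is removed by subtracting the solution mean.
* **Rough z-chains** (per-grid-point, purely 1D adjacency along z): the
  weakly constrained chain admits offset, linear-trend and low-frequency
  oscillation biases. The solve runs blockwise in z (721 sections of
  context per 241 solved, production values) and the per-grid-point linear
  trend including offset is removed from each block's solution.
* **Fine/ultrafine z-chains**: as rough but without trend removal;
  neighbor comparisons are weighted (1.0, 1.0, 0.4, 0.1) for |Δz| = 1..4,
  replaced deltas are down-weighted 0.5, and the ultrafine solve adds L2
  (ridge) regularization with factor 0.05 as a further deformation
  constraint.

With `l2 = 0` the gauge freedom is fixed by appending the exactly
satisfiable constraint `sum(x) = 0`, which reproduces the minimum-norm
least-squares solution; the test suite checks equivalence with a dense
pseudo-inverse oracle to 1e-8 on systems up to 30 nodes. Connectivity is
checked before solving; the histogram-shift application (below) is the one
place responsible for augmenting connectivity, via a minimum spanning
tree.

## Normalized cross-correlation

Deltas are measured by template matching: the correlation numerator is
computed in the frequency domain, and per-window normalization uses
integral images of the main image. Peak localization is integer-pixel at
the working pixel size; ties are broken toward the smallest y, then
smallest x. Inputs are preprocessed with CLAHE (clip limit 30 on the
absolute OpenCV-style scale, mapped to EBImage's normalized scale by a
factor of ten; 32 × 32 px tiles at 16 nm), Laplacian-of-Gaussian whitening
(σ = 4 px at 16 nm), and zero-normalization to zero mean and unit energy.
CLAHE tile size and LoG σ scale inversely with pixel size. Images with
grayscale variance below 1 are flagged invalid rather than normalized.

Two matching modes exist: `"valid"` requires the template fully inside the
main image; `"full"` zero-pads the image so the template may hang off the
borders, with each window normalized over the padded extent and a minimum
in-image overlap fraction (25% of the template area). The full mode is
what makes partial-overlap comparisons — inter-mFOV tile pairs whose
overlap is a fraction of the template — scoreable. The 3D stages sweep the
template through rotations (±15° in 3° steps by default), cropping each
rotated template symmetrically to its valid interior so the center
convention is preserved; a best angle of +a means the template content had
to be rotated by +a (counter-clockwise in pixel axes) to match.

## 2D montaging

Tile adjacency follows the hexagonal layout: interior beams have six
lattice neighbors; facing perimeter tiles of adjacent mFOVs are connected
within a distance cutoff. For each edge, the full destination tile is the
main image and the source tile's half-by-half quadrant nearest the
destination is the template. Both intra- and inter-mFOV comparisons use
the quadrant template (an edge template cannot exceed the image size;
the inter comparison simply searches the full destination in full mode
under its much larger tolerance).

Outliers are handled in two passes with box tolerances interpreted as
centered boxes (deviation beyond half the stated side length flags the
edge): pass 1 against the acquisition-expected delta (768 nm intra,
15,440 × 13,440 nm inter), pass 2 against per-direction medians (64 nm
intra, 4,480 nm inter). Medians are computed per lattice direction over
all mFOVs of the section (the time-sequential window is configurable);
flagged edges receive the median (falling back to the nominal overlap with
a warning) and weight 0.5. The solved coordinates (offset removed) place
the origin near the mosaic center. Rendering feathers overlaps with linear
ramps — 0.5 µm within an mFOV, 3 µm between mFOVs — normalized so blend
weights sum to one; tile placement rounds the top-left corner, which is
integer-valued for exact solutions even when tile centers fall on half
pixels.

## Gradient and brightness correction

The two-pass correction averages tiles per beam position (rejecting tiles
whose histogram mode leaves the section-histogram quantile range
0.5%–99.5%, or that contain an out-of-range connected component over 20%
of the tile area), box-filters the mean tiles (1 × 1 µm at production
scale; the box is meant to be a small fraction of the tile, so desk-scale
configurations scale it with tile size), and divides by the mode to get a
multiplicative gradient raster per beam. A second averaging of
gradient-corrected tiles yields one integer brightness offset per beam
(mode minus mean of modes). Modes are taken on a lightly smoothed 256-bin
histogram with ties toward the lower intensity — the smoothing stabilizes
the estimator when only tens of tiles are averaged per beam.

The sub-tile refinement splits tiles 3 × 3, compares all pairwise sub-tile
histograms by ZNCC over gray-level lags (batched via FFT), and solves the
histogram-shift difference system built from the top-32 neighbors per
sub-tile below a correlation-distance ceiling (default 0.2) plus the MST
edges of the full distance graph, which guarantee one connected component.
Solved offsets (mean removed) are fitted per tile with a quadratic 2D
surface — the lowest order that can bow a 3 × 3 grid — and subtracted.
Groups beyond 5,000 sub-tiles are solved independently. Correction quality
at desk scale is estimator-noise limited: with N tiles averaged per beam
the residual shrinks like 1/√N, so fixtures with ~19 mFOVs land at a mean
absolute residual of 3–4 gray rather than the ~1 gray achievable at
production mFOV counts.

## 3D contrast balancing

A pluggable tissue-mask provider (the built-in classical provider
thresholds block mean and block texture at a 1,024 nm mask pixel size with
morphological cleanup; a learned mask can be substituted) restricts
256-bin histograms to tissue. All sections are matched to the histogram of
a manually selected high-contrast template section by monotone CDF
inversion. Among target bins of equal cumulative mass the lowest intensity
is chosen: midpoint tie-breaking across empty-bin runs would shift
self-matching by several gray levels, whereas the lower-bin rule keeps
matching a section to its own histogram an identity — which is the
observed behavior the method relies on. Matching is idempotent up to
one gray level and preserves rank order within a section.

## Coarse and rough alignment

Coarse alignment rotates each section by its acquisition-ROI angle about
the ROI center and translates that center to the center of the rough
bounding box — the fixed reference frame for everything downstream.
Feature-based rough alignment then estimates one constrained affine per
section: features are detected per coarse-aligned section, matched for all
(i, i±n) pairs (n ≤ 4) with the Lowe ratio test (second-nearest over
nearest ≥ 1.42), and fitted with seeded rigid RANSAC (tolerance 5.12 µm,
1000 iterations, refit-on-inliers until stable). Pairs with fewer than 32
consensus matches or fitted translations beyond 196 µm are flagged bad.

The feature provider is injectable; the default is a package-authored
multi-scale difference-of-Gaussians blob detector with orientation-
normalized patch descriptors (8 × 8 samples at 1.5 σ spacing, rotated to
the intensity-centroid angle), which tolerates the few-degree
section-to-section rotations left after coarse alignment. Fitted affines
are evaluated on a hexagonal grid (25 µm spacing) to produce vector
fields; grid points farther than 60 µm from an inlier source keypoint are
invalidated, and the grid is replaced by its Voronoi-cell centroids
(implemented as the centroid of each point and its available lattice
neighbors — interior points are unchanged) before the blockwise
per-grid-point z-solve with trend removal. Each section's resolved field
is refitted with the zero-shear affine.

The no-shear fit is the closed-form solution of the orthogonal,
non-orthonormal Procrustes problem: after centering, writing the linear
part as `R(θ) diag(s_x, s_y)` makes the objective separable — the optimal
scales are linear in `(cos θ, sin θ)` and the optimal angle direction is
the leading eigenvector of a 2 × 2 quadratic form. Its decomposition has
shear exactly zero (to machine epsilon), while an unconstrained refit of a
sheared field faithfully reports the shear — the pathology the constraint
exists to remove. The closed form is validated against a numerical
constrained optimizer in the test suite. The affine decomposition uses a
sign-fixed QR factorization, `linear = R(angle) diag(s_x, s_y) [[1,
shear_x], [0, 1]]`, which is unique and round-trips to 1e-9; reflections
surface as negative `scale_y`.

One accuracy limit is worth stating: the delta solve treats pairwise
displacement fields additively, which linearizes the composition of finite
rotations. For smooth rigid perturbation series at the coarse error
envelope (±15°), the reconciled affines carry a residual mutual
registration error of one to two pixels at the fixture pixel size, growing
with the product of relative rotation and relative translation between
compared sections; the fine stage absorbs it.

## Fine and ultrafine alignment

Both elastic stages share one machinery, differing only in parameters:
hexagonal grids of 16 µm (fine) or 2.0 µm (ultrafine) spacing, restricted
to the intersection of the acquisition ROI scaled by 110% and a dilated
tissue mask; source/template crops of 32/4.8 µm (fine) and 12.8/3.2 µm
(ultrafine); ±4 versus ±2 neighbors. Per active grid point and neighbor
pair the template is rotation-swept and matched; the stored delta follows
the same z-chain sign convention as the rough stage.

Outlier handling is a cascade: RANSAC against a quadratic-affine field
model (basis 1, x, y, x², xy, y² per axis; minimal sample 6; tolerance
12 µm; linear fallback with a warning when points are scarce); then
re-admission of rejected deltas that agree — in angle (≤ 30°) and relative
magnitude (≤ 0.3, with a 2-px absolute floor) — with a **majority of all
measured neighbors** inside the 57 µm reconsideration diameter. The
majority-vote form is deliberate: a coherent locally warped patch
re-admits its members because most of their neighbors are in-patch, while
an isolated gross vector cannot recruit a majority even if a couple of
nearby outliers happen to point the same way (selecting only the
most-similar k neighbors can be fooled exactly that way). Rejected and
unmeasured active points are filled by rigid MLS interpolation from the
inliers (weights 1/d⁴, i.e. exponent α = 2) and down-weighted 0.5. Rigid
MLS is implemented as the per-query weighted rigid (Kabsch) fit, which
interpolates controls exactly, reproduces any global rigid transform at
all queries, and extrapolates without blow-up. The fine stage then applies
the affine filter — a full-affine fit in overlapping 61 µm windows
replacing each center delta with the fit's prediction, a fixed point for
globally affine fields — before the weighted solve; the ultrafine stage
skips the filter and uses ridge regularization instead. Tears are healed
before the fine stage by pipeline ordering.

Ultrafine alignment runs on the exported fine-aligned stack, so the final
export composes the ultrafine inverse on top of the fine export, exactly
as the chain stores it.

## Tear healing

Stitch annotations (paired control points straddling the tear) define the
midline as the interpolation of pair midpoints, linearly projected from
the terminal segments to the image border; the path must be monotone along
one image axis (chosen automatically from the midpoint spread), which
partitions the section into exactly two pieces. Each half is warped
separately — control sources are points interpolated along that half's
tear edge at ~12 px arclength spacing, destinations the corresponding
midline points — avoiding presenting the MLS model with the discontinuity.
Displacements are blended to identity between 40 and 96 px from the
midline, so healing is strictly local and the far field is untouched;
small gaps can remain between stitches and are reported as a mask.

## Blockwise export

Output blocks (4 × 4 at 16 nm, 16 × 16 at 4 nm in production, 8 px
overlap) push their destination pixel lattice through the inverse chain
and sample the source bilinearly; blocks are assembled after trimming the
overlap and are identical to an unblocked export. Warp fields are
densified by piecewise-linear interpolation adapted to the offset hex
lattice — linear along each row in x, then linear blending between
bracketing rows — which is exact at grid points and for fields linear in
(x, y); rows extend linearly past their end points so staggered rows stay
consistent, and exports are cropped to the grid bounding box to avoid
extrapolation. Hex grids are generated to fully cover their rectangle
(the outermost row/column may lie just beyond it) so interpolation inside
the frame never clamps.

## Synthetic fixtures: what they emulate, and what they do not

The generator produces EM-like phantoms (band-limited noise thresholded
into dark membrane ridges with ~2–3 px softened edges, low-texture "cell
body" regions, a sharply peaked histogram around the neuropil gray),
hexagonal tilings with integer-pixel positional jitter, per-beam vignette
gradients (mostly flat with smooth border rolloff, plateau gains ≤ 1.05,
range 0.8–1.2), zero-mean integer brightness offsets (±10), blank tiles,
rigid perturbation stacks (band-limited smooth series within the ±15° /
10%-of-frame coarse error envelope), elastic stacks (smooth zero-mean-in-z
fields with z-correlated neighbors and spatial wavelength on the order of
the section, mimicking the local rigidity of real sectioning warps; RMS
magnitude ~30 px), and torn sections (y-monotone sinusoid cut, halves
pulled apart, auto-generated stitch pairs). All randomness flows through
recorded seeds; truth (cut positions, gradients, offsets, transforms,
fields, tear geometry) is returned alongside.

What the fixtures do **not** emulate: charging and focus artifacts,
section-thickness variation, true biological z-continuity (sections share
one texture plus independent noise), knife chatter, or the sheer scale of
production data — a fixture section is hundreds of pixels, not hundreds of
thousands. Passing tests therefore demonstrate the correctness and
stability of the algorithms under controlled deformations, not production
throughput or robustness to every acquisition pathology.

Desk-scale problem sizes used by the acceptance checks (chosen once, as
proportional analogs of the production geometry): 19-mFOV sections of
7-tile mFOVs with 112 × 128 px tiles (15%/25% overlap fractions) for
montaging and corrections; 30-section stacks at 512 nm pixels for the
rough stage; 8–10-section stacks of 384 × 384 px at 16 nm with fine grid
36 px, crops 192/24 px, ±3 neighbors, sweep ±6°, and ultrafine grid 16 px,
crops 72/16 px, ±2 neighbors for the elastic stages. Registration
statistics are RMS over probes and section pairs; fixture-level scatter is
reduced by averaging over multiple independent stack realizations where a
single realization's rigid series would dominate the statistic.

## Known limitations

* Correction quality (gradient/brightness) is bounded by per-beam
  averaging noise at small mFOV counts, as discussed above.
* The rough stage linearizes finite-rotation composition; large smooth
  rotation series leave a 1–2 px mutual registration residual for the fine
  stage to absorb.
* Tear midlines must be monotone along one image axis; multi-branch tears
  and tears with missing tissue are out of scope.
* The elastic stages assume pairwise section differences within the crop
  capture range, `(src_crop - dst_crop) / 2`; grossly deformed sections
  should be healed or excluded first, mirroring the intended pipeline
  order.
* Peak localization is integer-pixel by design; sub-pixel accuracy comes
  from averaging many measurements in the solver, not from sub-pixel
  interpolation of correlation surfaces.
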