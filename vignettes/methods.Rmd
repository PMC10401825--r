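---
title: "Dynamic lung CT aeration and strain: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic lung CT aeration and strain: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lungstrain` quantifies how a mechanically ventilated lung is aerated and
deformed over a breath, from a pair of respiratory-gated CT volumes at
end-expiration (EE) and end-inspiration (EI) with lung-parenchyma masks.
This vignette describes the models behind each stage, the tunable
parameters, the synthetic phantom that provides ground truth, and the
numerical choices made where the design was open.

## Aeration densitometry

CT attenuation in lung parenchyma is, to good accuracy, a linear mixture of
gas (-1000 HU) and water-equivalent tissue (0 HU). The voxel gas fraction is
therefore

$$F_{gas} = \frac{HU}{-1000},$$

with HU clamped to [-1000, 0] first so that residual dense material inside
the mask (vessel fragments, debris) cannot produce gas fractions outside
[0, 1]. Voxels are classified as non-aerated ($F_{gas} < 0.1$), poorly
aerated ($0.1 \le F_{gas} < 0.5$), normally aerated
($0.5 \le F_{gas} < 0.9$) or hyper-aerated ($F_{gas} \ge 0.9$); every
boundary belongs to the higher category. Tissue mass per voxel is
$(1 - F_{gas})\,v$ grams for voxel volume $v$ ml, taking tissue density as
1 g/ml (water-equivalent; reported masses scale linearly with this choice).
The total in-mask gas volume of the EE image is the end-expiratory lung
volume (EELV). Tidal recruitment is the drop in whole-lung non-aerated mass
from EE to EI divided by the whole-lung mass; the denominator uses the EE
total mass (mass is conserved over a breath up to noise, and EE is the
reference frame; a mean-of-phases denominator is available via
`denominator = "mean"`).

Spatial heterogeneity of aeration or strain is the normalized variance,
equivalent to a coefficient of variation: the in-mask SD over the in-mask
mean, computed after Gaussian in-plane filtering to an effective in-plane
resolution equal to the slice thickness (2.5 mm by default). The added
in-plane FWHM is $\sqrt{2.5^2 - d^2}$ for native in-plane spacing $d$; no
through-plane smoothing is applied because the slices are already at the
target resolution. Filtering is mask-normalized so out-of-lung values do
not bleed into the statistic. Percentiles (the 95th percentile summaries)
use linear interpolation between closest order statistics so results are
bit-reproducible.

## Registration-based volumetric strain

The deformation is represented by a dense displacement field $u$ on the EE
grid, in millimetres, with $T(x) = x + u(x)$ mapping each EE location to
its EI correspondent. The Jacobian determinant $J = \det(I + \nabla u)$ is
then the local EI/EE volume ratio and the volumetric strain is $s = J - 1$:
zero for no local volume change, positive for expansion. Derivatives are
spacing-aware central differences (one-sided at the grid boundary), and
strain is reported inside the EE mask eroded by one voxel to avoid boundary
derivative artifacts. Any non-positive in-mask Jacobian is a hard error —
the estimated map must be a diffeomorphism.

### Preprocessing

Intensities are rescaled so that, over the parenchyma, the HU maximum
(tissue density) maps to 0 and the minimum (air) to 1. Each dimension is
cropped to the EI-mask bounding box and padded with a 50-voxel zero margin;
a crop record maps working-grid coordinates back to the original grid.
Internally the optimizer iterates only over the mask neighbourhood
(bounding box plus `active_margin`, default 12 voxels); the remaining pad
is static background.

### Similarity and optimization

Density transport changes intensities between phases: a voxel that expands
by $J$ becomes darker as $1 - F^{EI} = (1 - F^{EE})/J$. Within a small
window this is an affine intensity change, so the similarity must be
invariant to local affine maps — the reason a windowed (local)
cross-correlation is the standard choice for lung CT. The implementation
realizes this by locally standardizing both images (windowed mean and SD
over a box window, default radius `c(2, 2, 1)` stage voxels, a
near-isotropic 4-5 mm window matched to the scale of parenchymal texture)
and driving a pointwise-damped demons update

$$\delta = \frac{r \, \nabla \hat M}{|\nabla \hat M|^2 + r^2 / K},
\qquad r = \hat F - \hat M,$$

where $\hat F, \hat M$ are the standardized fixed and warped-moving images
and $K$ caps the per-iteration step at `step_frac` (default 0.8) of the
smallest stage voxel spacing. Standardization also removes the systematic
half-voxel bias that interpolation smoothing otherwise imprints on
correlation metrics. Updates are smoothed with a cubic B-spline kernel
whose scale follows the knot schedule — 26 mm initially, halved at each of
three subsequent stages (26, 13, 6.5, 3.25 mm) while the image resolution
increases (downsampling factors 4, 3, 2, 1) — and are weighted by texture
confidence so informative voxels drive their homogeneous neighbours.
Updates are accumulated additively in this regularized space; a Jacobian
fold guard rejects any step that would drive the map's minimum Jacobian
below 0.05, which together with the step cap keeps the accumulated
transform diffeomorphic. Each stage tracks the best metric value and stops
after `patience` (8) iterations without improvement; because the iterates
oscillate around the optimum once converged, the stage returns the
exponential tail average of its iterates, a lower-variance estimate than
any single iterate.

### Homogeneous regions, mass consistency, and volume calibration

Atelectatic parenchyma sits at soft-tissue density and is radiologically
indistinguishable from the chest wall: no image-driven method can track it.
Three physically motivated steps handle this honestly:

1. **Weighted harmonic infill.** Each voxel's displacement is tethered to
   its registered value in proportion to a confidence combining local
   texture SD (above `sd_floor`, default 0.02 in rescaled intensity units)
   with the locally achieved correlation; low-confidence voxels relax to
   the weighted average of their neighbours (multiscale Jacobi iterations,
   domain restricted to the dilated lung so values cannot leak around the
   surface). This is the continuum assumption that contiguous tissue moves
   smoothly.
2. **Density-based divergence correction.** Mass conservation makes CT
   density itself a volume meter: $J = (1 - F^{EE}) / (1 - F^{EI}(T(x)))$.
   Where texture cannot constrain volume change, the field's divergence is
   steered toward this density-implied Jacobian by solving a Poisson
   equation for a correction potential — the tissue-volume-preservation
   constraint familiar from lung CT registration.
3. **Global volume calibration.** By the divergence theorem, the Jacobian
   integral over the EE mask equals the volume of the warped lung, which
   the EI segmentation measures directly. A smoothly tapered radial field
   about the lung centroid calibrates the flux so the two agree.

Finally the field is smoothed with a small Gaussian (`final_smooth_mm`,
default 4 mm SD, domain-weighted so background cannot drag the lung
surface) for derivative stability before the Jacobian is computed.

### What the defaults achieve

On the default phantom (96 x 96 x 48 voxels at 1 x 1 x 2.5 mm, 10 HU
noise, peak true strain about 0.3) the full pipeline recovers the
displacement field with a median endpoint error below 0.5 mm, median
absolute strain error below 0.05, whole-lung mean strain error below 0.01,
and a Jacobian volume integral within 1% of the EI lung volume; one run
takes one to two minutes on a single core. These problem sizes are the
package's validation conditions; the same code runs unchanged on clinical
512 x 512 matrices, only more slowly.

## Strain analytics

End-inspiratory aeration is pulled back to the EE grid through the
registration transform (linear interpolation at $T(x)$, with out-of-mask
gas fraction taken as 0), so that strain and aeration live on a common
grid. The joint structure is summarized two ways:

- **Interval summaries**: median and interquartile range of strain for
  voxels in the EI-aeration intervals 0.1-0.3, 0.3-0.5, 0.5-0.7, 0.7-0.9
  and >0.9, over aerated lung ($F_{gas} > 0.1$), plus a 2-D histogram of
  50 strain bins (spanning the 5th-95th strain percentile range) by the 5
  intervals.
- **Parametric response map**: voxels binned on a 100 x 100 grid of EE
  versus EI gas fraction in [0, 1] (half-open bins, the last closed at 1),
  recording per bin the fraction of lung volume and the mean strain; bins
  holding less than 0.05% of the lung volume are suppressed from the
  reported map.

Regional strain uses the median over the regional mask (robust to the
skewed voxel strain distributions). Delta aeration is the EI minus EE mean
gas fraction; across deformation magnitudes it moves together with mean
strain, which the tests verify on phantom families.

## Vertical distributions

The supine gravitational axis is the package's y axis
(ventral-to-dorsal). The lung's y-extent is split into 10 contiguous
iso-gravitational slabs of equal height; when the row count does not
divide evenly the remainder rows are assigned one per slab starting
dorsally (a deterministic tie-break). ROI 1 is the most dorsal, ROI 10 the
most ventral. Partitions are computed on each image's own mask, since the
two lungs differ in extent. A consequence worth knowing: because the lung
expands between phases, per-ROI differences of EE and EI quantities mix a
boundary-shift component into regional tidal recruitment profiles; the
whole-lung statistic is unaffected (it equals the ROI-mass-weighted mean
of the regional values by construction), and comparisons between matched
conditions cancel the shift.

## Respiratory mechanics

Each breath is fitted by ordinary least squares to the single-compartment
equation of motion

$$P(t) = \frac{V(t)}{C} + R\,\dot V(t) + P_0,$$

over the full cycle (pressure in cmH2O, volume in litres, flow in l/s),
giving compliance (reported in ml/cmH2O), resistance (cmH2O/l/s) and the
pressure offset. Breaths arrive pre-segmented; per-PEEP-level aggregation
is the mean over the provided breaths. The maximal-compliance PEEP of a
decremental trial is the level with the largest fitted compliance, ties
broken toward the higher PEEP (the more recruitment-preserving choice) and
flagged. The synthetic breath generator uses a constant inspiratory flow
and passive exponential expiration with defaults reflecting an injured,
surfactant-depleted lung (compliance 9 ml/cmH2O, resistance 14 cmH2O/l/s,
tidal volume 172 ml, rate 26/min); its volume channel is the discrete
integral of its flow channel, keeping the channels consistent to machine
precision.

## Statistics

Paired comparisons use the paired two-tailed Student t-test; associations
use Pearson or Spearman correlation (average ranks for ties, p-values via
the t transform); vertical profiles are compared with a two-way
(region x strategy) repeated-measures ANOVA in which each within-subject
effect is tested against its own subject-by-effect interaction stratum. No
sphericity correction is applied — a known limitation for profiles with
many regions. Effects whose sum of squares vanishes to rounding are
reported as F = 0 rather than a 0/0 ratio.

## The synthetic phantom

The phantom emulates a surfactant-depleted, partly atelectatic supine
lung and provides exact ground truth for every stage:

- **Geometry**: an ellipsoidal lung (semi-axes 35, 38, 50 mm) in a
  96 x 96 x 48 grid at 1 x 1 x 2.5 mm.
- **Aeration**: gas fraction falls linearly from 0.75 at the ventral
  boundary to 0.15 at the dorsal boundary; a dorsal slab covering 25% of
  the lung height is atelectatic ($F_{gas} = 0.02$). The slab's ventral
  boundary is bowl-shaped (4 mm more dorsal at the lung periphery),
  following how dependent atelectasis tracks the dorsal lung surface; a
  flat plane would also make category masses hypersensitive to voxel
  discretization.
- **Texture**: a smooth random field (SD 0.04 gas-fraction units, 4 mm
  FWHM, regenerated deterministically from the seed) models the
  vascular/parenchymal heterogeneity that real CT shows; without it the
  interior of a synthetic lung is featureless and registration is
  ill-posed in a way real data is not. Texture is suppressed in and near
  the non-aerated range so the slab stays homogeneous, as a fluid-filled
  region is.
- **Warp**: an anisotropic expansion about the lung center (factors 1.02,
  1.02, 1.012) composed with a smooth axial stretch whose linear strain is
  a Gaussian bump along y (amplitude 0.24, SD 7 mm, peak at 45% of lung
  height). Both parts are strictly monotone with closed-form Jacobian
  $J = s_x s_y s_z (1 + A e^{-(y-y_m)^2/2\sigma^2})$ — peak local strain
  about 0.3 mid-lung, decaying dorsally so the atelectatic slab stays
  non-aerated at EI. The C-infinity form matters: a stretch with a
  derivative kink cannot be checked against central differences at the
  10^-3 level.
- **Transport**: the EI image is evaluated in closed form through the
  inverse warp with mass-consistent density transport,
  $1 - F^{EI}(T(x)) = (1 - F^{EE}(x))/J(x)$ (only the texture field is
  interpolated), so tissue mass is conserved to voxelization accuracy
  (measured mismatch about 0.1-0.3%).
- **Recruitment**: an optional dorsal block — the dorsal-most shell of
  constant gravitational depth accumulating a target fraction of EE tissue
  mass — is overwritten at EI with gas fraction 0.4; the achieved EE mass
  fraction is recorded as truth.
- **Noise**: independent additive Gaussian HU noise (default SD 10 HU,
  clipped to [-1024, 100]) on both volumes, with separate deterministic
  seed substreams for texture, EE noise and EI noise so identical specs
  give bit-identical phantoms.

What passing tests on the phantom do **not** show about real data: the
phantom has no cardiac motion, no CT reconstruction artifacts or beam
hardening, a single smooth warp family rather than sliding interfaces
(fissures, chest wall), an analytic mask rather than an imperfect
segmentation, and stationary Gaussian texture rather than vascular trees.
Registration accuracy on real lungs should be validated against landmarks,
as the wider literature does; the phantom validates the implementation,
not the imaging physics.

## Degenerate inputs and tie-breaks

Geometry mismatches are rejected by every cross-image operation
(tolerance 1e-6 mm on spacing). Empty masks, zero-mean maps (undefined
CoV), zero-variance paired differences, constant correlation inputs,
rank-deficient mechanics designs, non-decreasing PEEP sequences and
unbalanced ANOVA designs raise errors rather than returning silent
nonsense. Remainder ROI rows go dorsal-first; compliance ties go to the
higher PEEP; classification boundaries belong to the higher category;
F_gas = 1 falls in the last parametric-response bin.
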