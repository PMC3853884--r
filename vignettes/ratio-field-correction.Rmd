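---
title: "Prior-CT ratio-field correction of cone-beam CT: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-CT ratio-field correction of cone-beam CT: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctcorr)
```

## The problem

Cone-beam CT (CBCT) acquired on a linac is the natural image for verifying
what was actually delivered during a radiotherapy fraction, but its voxel
values are not trustworthy Hounsfield units: scatter produces a smooth
"cupping" depression toward the object center, the HU scale drifts with
patient size, and partial-arc breast acquisitions (about 200 degrees, to
avoid gantry-couch collisions) reconstruct only a truncated cylindrical field
of view (FOV). Dose calculation needs both correct HU-to-density values and
complete anatomy.

`cbctcorr` implements a planning-CT-prior correction: the planning CT of the
same patient, rigidly registered to the CBCT, tells us what the voxel values
*should* be, and the quotient of the two images — restricted to its smooth,
low-spatial-frequency component — is a multiplicative field that removes the
CBCT's intensity distortions while preserving the anatomy of the day. The
missing FOV is completed from the planning CT.

## The correction model

Let $x$ be the planning CT and $y$ the CBCT after rigid resampling onto the
planning-CT grid, both expressed on an attenuation-proportional scale
$\mu = \max((\mathrm{HU} + 1000)/1000,\ 0)$ (air $= 0$, water $= 1$). The raw
HU quotient is ill-defined because HU cross zero at air; the attenuation
scale makes the degradation multiplicative and strictly positive.

Both images are segmented into four tissue classes — air, lung, soft tissue,
bone — by HU thresholds inside a morphological body mask. For each class $c$
the correction estimates a smooth ratio field on the joint mask
$J_c = C^{CT}_c \cap C^{CBCT}_c \cap \mathrm{FOV}$:

$$ R_c(v) \;=\; \frac{\big(G_\sigma * (x \cdot 1_{J_c})\big)(v)}
                    {\big(G_\sigma * (y \cdot 1_{J_c})\big)(v)}, $$

a quotient of two mask-weighted Gaussian convolutions (normalized
convolution). The corrected image is reassembled from the CBCT's own class
masks — the anatomy of the day — as
$\hat{x}(v) = R_{c(v)}(v)\, y(v)$ with $c(v)$ the CBCT class of $v$,
converted back to HU, and finally every voxel outside the FOV is copied from
the planning CT unchanged.

Per-class estimation matters because the HU bias is tissue-dependent (the
scatter-to-primary ratio differs in lung and bone) and because a single
global field would smear corrections across the sharp lung/soft and
soft/bone interfaces; the masked convolution never mixes classes.

### Why a quotient of smoothed fields, not a smoothed quotient

Filtering the voxelwise quotient $x/y$ and filtering the two fields before
dividing agree exactly when the true ratio is locally constant, but they
behave differently under noise: the mean of $x/y$ is inflated by the
denominator's variance (for lung-like attenuation, $cv \approx 0.12$ at
15 HU noise, the voxelwise mean overshoots the ratio of means by several
percent). The normalized-convolution form is unbiased in that sense, exactly
linear in $y$ (so any global gain cancels), and reproduces constants
exactly. The package also exports the voxelwise operations
(`compute_ratio_field()`, `smooth_ratio_field()`) for diagnostics; the
pipeline itself uses the quotient-of-smoothed-fields estimator.

### The air class

On the attenuation scale the air quotient is $0/0$; clamped division turns
it into the arbitrary lower bound. The pipeline therefore assigns the air
part a unit ratio: true air is unchanged (it is zero attenuation either
way), and a body-boundary voxel that one segmentation mistakes for air
passes through rather than being driven hundreds of HU dark. This is also
what a raw-HU quotient would give in air ($-1000/-1000 = 1$).

### Global gain normalization

Before segmentation, the CBCT's attenuation values are rescaled by a single
factor so that their mean over the FOV equals the planning CT's mean over
the same region. The region is purely geometric (the resampled CBCT
footprint), so the factor scales exactly with any global intensity scale:
segmentation thresholds then see a gain-stabilized image, and a CBCT
acquired with a different global calibration produces an identical
correction. Any residual gain is absorbed by the ratio fields, which are
exactly gain-equivariant.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `width_mm` (`filter_spec`) | 20 | mm FWHM | scale of the Gaussian low-pass; scatter/cupping varies over several cm, so the field must be smoother than anatomy but sharper than the FOV |
| `ratio_floor`, `ratio_ceiling` | 0.2, 5 | — | clamp on the ratio; bounds the influence of residual misregistration at interfaces |
| `mu_offset_hu` | 1000 | HU | attenuation-scale offset; 1000 puts air at zero |
| `lung_upper_hu` | −400 | HU | lung/soft split inside the body |
| `bone_lower_hu` | +200 | HU | soft/bone split inside the body |
| `body_threshold_hu` | −500 | HU | body-surface threshold (largest component, closed, hole-filled) |
| `min_component_mm3` | 500 | mm³ | lung/bone components below this are speckle and become soft tissue |

The thresholds are deliberately ordinary thoracic values and are exposed as
configuration: threshold segmentation is the weakest link of the method and
any clinic will tune them. A 2-voxel ring at the FOV boundary is excluded
from lung/bone eligibility because partial-object truncation corrupts
thresholds there; ring voxels inside the body fall back to soft tissue.

## Rigid registration

When no clinical registration is supplied, `register_rigid()` estimates the
6-DOF transform by maximizing mutual information (32 bins, moving values
linearly binned so the objective is smooth) over seeded random samples of
the fixed body region, with a 3-level coarse-to-fine sampling pyramid.
Mutual information is the default because CBCT HU are biased relative to the
CT, which defeats intensity-difference metrics. Each level runs a BFGS step
with coarse numeric gradients followed by a Nelder-Mead polish, keeping the
better result; initialization aligns the body-mask centers of mass, which is
robust to FOV truncation. Everything is deterministic given the seed. On
seeded random-offset studies with the degraded phantom the recovered
transforms are accurate to a fraction of a voxel (median errors around
0.4 mm and 0.3 degrees). The transform convention is fixed: Euler angles applied in
Z–Y–X order about a stated center, LPS millimetre world coordinates, and a
three-line plain-text file format, so clinically supplied registrations are
reproducible inputs.

## The digital phantom

`phantom_spec()` renders an elliptical torso (semi-axes 140 × 95 × 75 mm)
with two lung ellipsoids, a spine cylinder, six rib spheres and a left
anterior breast protrusion, on a 128 × 128 × 64 grid at 2.5 mm (a second or
two to render). Class HU means are air −1000, lung −750, soft +40, bone
+700, with 20 HU Gaussian texture in tissue (air is uniform: sub-air HU is
not physical and would clip on the attenuation scale).

`degradation_spec()` adds, on the attenuation scale, a multiplicative radial
cupping field (15% amplitude, 80 mm length scale — darker core, brighter
rim), a 5% smooth angular shading surrogate for the 200-degree arc, additive
per-class HU shifts (lung −30, soft −40, bone −60), 15 HU Gaussian noise,
and truncation to a 110 mm FOV cylinder (roughly 70% of the body). The
realized multiplicative field is returned as ground truth. The
`standard_fixture()` packages phantom, degradation and a fixed rigid offset
((3, −2, 1) mm, 2 degrees axial) with the CT resampled into the CBCT frame
*before* degradation, because cupping, arc shading and truncation are
scanner-frame effects.

What the simulator does *not* emulate: projection-space physics (no
Monte-Carlo scatter, no FDK reconstruction, no streaks or beam hardening),
anatomical change between scans, and partial-volume class mixtures at
interfaces. Passing tests therefore demonstrate that the algorithm removes
smooth multiplicative and per-class additive intensity distortions under
noise and truncation — the artifact classes the method targets — not that it
handles every failure mode of clinical CBCT.

## Evaluation surrogates

Dosimetric endpoints require a treatment planning system; the package
replaces them with image-level quantities that drive dose engines:

* HU error metrics (MAE/RMSE over body ∩ FOV, signed per-class means);
* intensity-histogram distances (L1, chi-squared, earth mover's) between
  corrected/original CBCT and the CT, computed on frequencies so differing
  voxel counts compare fairly;
* water-equivalent path length (WEPL): a trapezoidal line integral of
  relative electron density (fixed piecewise-linear HU-to-density surrogate
  curve) along anterior-to-posterior parallel rays at 5 mm spacing — the
  radiological depth a dose algorithm consumes. Step size defaults to half
  the smallest voxel; halving the step changes results by well under 0.5%.

## Numerical choices and degenerate inputs

* Ratio division guards the denominator at $10^{-3}$ on the attenuation
  scale and clamps to [0.2, 5] before any averaging.
* Mask-normalized smoothing falls back to the defined-region mean where the
  smoothed mask weight underflows (isolated islands).
* A tissue class present in the CBCT but absent from the joint mask (e.g. no
  bone inside a small FOV) falls back to the soft-tissue mean ratio.
* An empty body mask (nothing above −500 HU) is an error, as is a degenerate
  reference grid or an entry point outside the grid for ray tracing.
* A null degradation (all amplitudes zero, infinite FOV) returns the input
  bit-identically; the multiplicative path is skipped rather than performing
  a multiply-by-one round trip that would perturb the last ulp.
* The FOV is detected as the resampled footprint of non-padding CBCT voxels;
  outside it the corrected volume *is* the planning CT, copied exactly.

## Configuration and reproducibility

The pipeline (`run_pipeline()`, or the `inst/cli/cbctcorr.R` script with
`simulate` / `register` / `correct` / `evaluate` / `run` subcommands) takes
a YAML configuration of overrides on top of package defaults; unknown keys
are rejected. YAML was chosen as the config dialect because it is the
key-value format with first-class support in this R stack. Every stage
writes a JSON manifest with the tool version, the effective configuration,
seeds, and MD5 checksums of inputs and outputs — enough to re-run the stage.
All stochastic stages (texture, noise, metric sampling) are seeded, and
fixed seeds reproduce outputs bit-identically.

## Known limitations

* Threshold segmentation cannot separate tissues with overlapping HU
  (internal gas lands in the lung class by attenuation equivalence), and
  its errors at class boundaries are the dominant residual after
  correction.
* The correction is multiplicative and low-frequency by construction: it
  cannot restore high-frequency information the CBCT never recorded
  (streaks, severe undersampling), and anatomy that genuinely changed
  between CT and CBCT is — by design — kept from the CBCT, uncorrected
  toward the prior.
* Rigid registration only; breast deformation between scans is out of
  scope.
* The HU-to-density curve is a fixed surrogate, not a fitted clinical
  calibration; WEPL numbers are comparative, not absolute clinical values.
* Default problem sizes (128 × 128 × 64 phantom, 20-offset registration
  study) were chosen so the full pipeline and its property suite run on a
  single desktop core in minutes.
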