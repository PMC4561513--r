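---
title: "Quantifying micro-vascular networks and collagen organization: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying micro-vascular networks and collagen organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microvasq)
```

`microvasq` implements two analysis chains for engineered-bone
constructs: quantification of the 3D micro-vascular network from
propagation-based phase-contrast micro-tomography, and mapping of
collagen organization from scanning X-ray micro-diffraction. This
vignette documents the underlying models, the parameters that matter, the
numerical conventions that make results reproducible, and what the
synthetic validation does and does not demonstrate.

## The imaging model and phase retrieval

In-line propagation imaging of a weakly absorbing object is modeled under
the homogeneous-object assumption: a single material with refractive
index $n = 1 - \delta + i\beta$, projected thickness $T(x,y)$, linear
attenuation $\mu = 4\pi\beta/\lambda$. To first order in the
transport-of-intensity expansion, the flat-normalized intensity a
distance $z$ downstream is

$$ I_z/I_0 \;=\; \mathcal{F}^{-1}\!\left[\,\mathcal{F}\!\left[e^{-\mu T}\right]\,
\bigl(1 + \tfrac{z\delta}{\mu}\,4\pi^2 |u|^2\bigr)\right], $$

with $u$ the spatial frequency in cycles per length. `paganin_retrieve()`
divides by the same factor and takes $-\log(\cdot)/\mu$; because
`forward_propagate()` is built from the identical filter, retrieval is an
*exact algebraic inverse* of the forward model on a periodic domain. The
test suite exploits this: for band-limited thickness maps the round trip
is verified below $10^{-6}$ relative error (it sits at $\sim 10^{-12}$ in
practice). This is a validation of the operator pair, not of the
linearization itself — the model remains a first-order approximation of
Fresnel propagation and undershoots at very sharp, high-contrast edges,
where simulated intensities can even become non-physical (negative). The
pipeline clips such values at a configurable floor (`intensity_floor`,
default $10^{-6}$) before retrieval.

Key parameters (`imaging_geometry()`): photon energy 24 keV, propagation
distance 5 cm, detector pixel 0.64 μm — the acquisition geometry the
package targets. $\delta$ and $\beta$ of the single material are free
configuration (only the ratio $\delta/\mu$ enters the filter); the
retrieval default is $\delta = 10^{-7}$, $\beta = 10^{-10}$. The phantom
vessel compartment uses $\delta = 10^{-7}$, $\beta = 5\times10^{-10}$
($\delta/\beta = 200$), a contrast consistent with a radiopaque-perfused
lumen; with the 5 cm / 24 keV geometry this also keeps the linearized
edge fringes of voxelized tubes within the physical intensity range.

**Conventions.** Frequencies are in cycles per length on the standard
FFT-ordered grid. Before filtering, images are mirror-padded to a
composite (2·3·5-smooth) size at least 1.5× the image — mixed-radix FFTs
make power-of-two padding unnecessary — and cropped back; `pad = "none"`
selects the strictly periodic operator used by the round-trip tests.

## Tomographic reconstruction

`radon_project()` computes parallel-beam line integrals by bilinear
sampling on the rotated grid, scaled by the pixel size so projections of
binary objects are chord lengths in physical units. `fbp_reconstruct()`
applies the ramp filter (optional Hann apodization) in frequency space
after zero-padding the detector axis to twice its length — the ramp
kernel has slowly decaying tails, and circular convolution without
padding produces a visible cupping bias — then back-projects with linear
interpolation and weight $\pi/n_{\text{angles}}$. Acquisitions covering
more than 180° are folded onto the half turn by flipping the detector
axis of the extra projections, so a full 360° scan is supported while the
simulated default acquires 0–180° (sufficient for parallel beam; 200
angles by default at desk scale). A disk phantom at 400 angles
reconstructs with RMSE below 5% of the dynamic range; most of the
residual is Gibbs ringing at the discontinuous edge.

## Vessel segmentation and size classes

Segmentation is a global threshold — Otsu on the full volume histogram by
default, a fixed value otherwise — followed by a radius-1 morphological
opening (6-connected cross) and removal of 26-connected components
smaller than `min_component_voxels` (default 27 ≈ a 3³ speck). A volume
with zero dynamic range yields an empty mask rather than an arbitrary
Otsu split. On the clean simulated chain (96³ phantom, 200 angles) this
recovers ≥ 95% of true vessel voxels with ≤ 5% false positives; noise,
ring artifacts and partial staining in real data will degrade this, which
is why the threshold and cleanup are exposed as parameters.

Each slice perpendicular to the analysis axis is decomposed into
8-connected 2D components; a component of area $A$ gets the equivalent
circular diameter $d = 2\sqrt{A/\pi}$. Classes are half-open: small
vessels $d \in [10, 15)$ μm, large $d \in [15, 20]$ μm — a vessel of
exactly 15 μm is *large*; the convention is a deliberate resolution of an
ambiguity and is stated here rather than hidden. Components outside
$[10, 20]$ μm count toward `v_total` only. Vessels crossing a slice
obliquely have elliptical sections, inflating $d$ by roughly
$1/\sqrt{\cos\alpha}$ at tilt $\alpha$; counts are unaffected, and the
inflation is part of what the per-slice convention measures.

The section weights default to the circle area at the class-midpoint
diameter: $\pi(12.5/2)^2 = 122.7$ and $\pi(17.5/2)^2 = 240.5$ μm²,
reported as 123 and 240 under the package's rounding rule (nearest
integer below 200 μm², two significant figures above). Internally full
precision is kept. The vascularization factor

$$ VF = \frac{S_{small}\int V_m(z)\,dz + S_{large}\int V_M(z)\,dz}{D_{norm}} $$

uses slice sums × slice thickness for the integrals. $D_{norm}$ defaults
to the analyzed depth, so a single small vessel spanning the volume gives
exactly $S_{small}$; `total_depth_norm = 1400` reproduces the fixed-depth
convention useful when comparing samples whose vessels span slightly
different depths.

## Skeletonization and branch counting

The centerline skeleton is computed by sequential removal of *simple
points* — voxels whose deletion changes neither the 26-connected object
topology nor the 6-connected background topology of their neighborhood —
so the skeleton is homotopy-equivalent to the mask by construction.
Voxels with a single object neighbor (curve endpoints) are never removed.
Two scheduling safeguards matter in practice and are worth recording:

1. **Distance ordering.** Deletion proceeds from the surface inward, in
   ascending order of the exact Euclidean distance transform. Without
   this, the six-directional peeling stays synchronized on jagged tube
   surfaces and can freeze diagonally packed voxel bundles that no single
   simple-point deletion can dissolve (every candidate would open a
   tunnel).
2. **Thickness support and ridge cleanup.** Within each directional
   sub-iteration a voxel is deleted only where the object is at least two
   voxels thick along that direction; this prevents the "zipper" failure
   of fully sequential thinning, in which a one-voxel-thick diagonal
   ladder is eaten from its end — every deletion simple, topology intact,
   centerline destroyed. (The widely used Lee-style reference
   implementation removes such degenerate shapes entirely.) A final phase
   dissolves the redundant one-voxel ridges this rule leaves behind,
   deleting voxels only where object voxels face each other across one of
   the 13 neighborhood axes — a condition curve endpoints can never meet,
   so centerlines are not shortened.

Graph extraction classifies skeleton voxels by 26-neighbor count
(endpoint = 1, slab = 2, junction ≥ 3), clusters adjacent junction voxels
into nodes, walks slab chains into edges, and represents closed loops as
anchored self-loops so the cycle count is the first Betti number
$E - V + C$. Per-node radii are distance-transform values × voxel size.
`count_branches()` prunes endpoint-terminated spurs shorter than
`min_branch_length` (default 5 μm — thinning artifacts at tube caps are
shorter, true side branches of resolvable vessels are longer), re-joins
the branches the pruned spurs interrupted, and counts remaining edges at
least that long. Branch counts are "skeleton edges after pruning"; a
junction-to-junction segment convention would differ only when spur
pruning merges segments, and the pruning threshold is the single knob
controlling it.

## The synthetic phantom

`generate_phantom()` emulates the geometry the tomography chain must
quantify: a porous scaffold matrix (solid minus overlapping spherical
pores, carved until a target solid fraction — default 0.35, a typical
porous-ceramic solid fraction — with the pore radius capped near the
target so the final fraction does not overshoot) crossed by tubular
vessel trees. Trees grow from an entry face as a biased random walk
(per-step direction jitter 0.12, axial pull 0.15) with branch events as a
Poisson process per unit length (default 0.015 μm⁻¹, giving a handful of
branches across a ~60 μm desk-scale volume); both children take the
parent radius × `taper_factor` (0.85), clamped so diameters stay within
the 10–20 μm class span. Root diameters are drawn uniformly from the
upper half of the class span so both classes occur. Entry points are
placed with radius-aware margins and separations so tubes are distinct
and fully interior. Vessel voxels are all voxels within the local radius
of the centerline, stamped at quarter-voxel spacing (coarser stamping
leaves helical surface ridges that disturb thinning), and the last
centerline point of each segment is clamped onto the exit boundary so the
analytic truth and the voxel mask agree in every slice.

The default scale is 256³ voxels at 0.64 μm (≈ 164 μm cube) — a
desk-scale stand-in for millimeter-scale samples; every statistic is
per-depth, hence scale-free, and tests run at 40³–96³. The generator is
deterministic given `rng_seed` (bit-identical volumes).

`truth_depth_profile()` counts analytic centerline crossings of the slice
planes at $(k - \tfrac12)\,\Delta z$ with the interpolated local
diameter; on unbranched axis-aligned phantoms it agrees with the
voxel-based `per_slice_counts()` *exactly*, slice by slice, which is the
package's strongest internal oracle.

**What passing tests do not show.** The phantom has sharp two-level
contrast, no detector noise, no ring or motion artifacts, no partially
filled vessels, and scaffold that is invisible to the simulated contrast
(the forward model projects the vessel compartment of a single material).
Segmentation recall near 100% on this phantom demonstrates the
correctness of the chain, not expected performance on beamline data.

## The diffraction model and fits

Synthetic patterns place an equatorial ring at $q_c$ (default 5.6 nm⁻¹,
the collagen lateral-packing reflection; instrument range 0.5–30 nm⁻¹)
with Gaussian radial width $\sigma_q$ (0.35 nm⁻¹) on an isotropic
background, modulated azimuthally by
$(1-f) + f\,[\text{wrapped Gaussians at } \Phi_0, \Phi_0 + 180^\circ]$,
and optional Poisson counting noise. The synthetic detector default
(256² pixels of 1.1 mm at $L = 110$ cm, $\lambda = 0.0976$ nm) keeps the
full ring inside a compact grid while preserving the q range of interest;
geometry, including the real 2048² / 50 μm detector, is fully
configurable. Noise-free patterns are exactly symmetric under
$\Phi \to \Phi + 180^\circ$.

`fit_collagen_peak()` fits $A\,e^{-(q-q_c)^2/2\sigma^2} + B(q)$ over a
window (default 4.6–6.6 nm⁻¹, ≥ 8 bins) with `minpack.lm`. Both
background models are first-class — second-order polynomial (default) and
power law $a\,q^{-k}$ — because both are defensible descriptions of the
diffuse scattering under the ring; neither is privileged. Initialization:
$q_c^0$ at the argmax of the 3-bin median-smoothed window, $\sigma^0$ =
window/6, background from the outer 25% of window bins. Windows without
an interior local maximum, vanishing amplitudes and non-convergence yield
*flagged* results (`no_peak`, `no_convergence`), never exceptions, so
scan grids survive empty positions; flagged positions are masked in
`build_collagen_map()` output. `lateral_spacing` is defined as $2\pi/q_c$
(the identity $D\,q_c = 2\pi$ holds to the last bit).

`fit_orientation()` fits $c + A[G(\Phi-\Phi_0) + G(\Phi-\Phi_0-180)]$
with shared width and amplitude (the symmetry of an equatorial
reflection) and wrapped tails; the orientation degree is
$A_\Phi/A_{BKG} = 2A\sigma\sqrt{2\pi} / (360\,c)$. Angles are measured
counterclockwise from the detector +x axis and reported mod 180°. A flat
profile returns degree exactly 0 (flag `flat`); a negative fitted
background is flagged. Because the isotropic scattering background
contributes to $A_{BKG}$, the fitted degree is a diluted, monotone proxy
of the generator's aligned fraction rather than an unbiased estimate of
it; tests therefore assert monotonicity and angle recovery (within 2°),
not equality.

Validated recovery at the default noise level (peak SNR well above 10):
median $|\hat q_c - q_c|/q_c \approx 0.01\%$ over 100 seeded noisy
patterns, orientation angles within ~0.3°, and a 0°/90° step edge in a
scan grid reproduced within 2° away from the edge.

## Pipelines, determinism and problem sizes

`run_tomo_pipeline()` chains phantom → per-slice radon → forward
propagation → retrieval → FBP → segmentation → counting → skeleton →
summary; `run_diffraction_pipeline()` chains grid simulation →
integration → fits → maps. Configurations are validated lists (unknown
keys rejected) that round-trip losslessly through YAML; manifests record
the package version, a config hash, per-stage timings and MD5 checksums
of every written output, and reruns with the same seed reproduce outputs
bit for bit. Volumes are stored z-major with slice 1 at the vessel entry
face; depth = slice index × slice thickness. All lengths are micrometers
except the diffraction side (nm, nm⁻¹, detector geometry in mm).

The validation suite runs the full tomographic chain at 96³ voxels with
200 angles and the statistical diffraction checks on 100 patterns of
256² pixels — sizes chosen so the complete suite and the acceptance
script each finish in about a minute on a single core while exercising
every stage at full fidelity.

## Known limitations

- The forward imaging model is the linearized single-material filter, not
  full Fresnel wave propagation; flat-field structure, ring artifacts and
  cone-beam geometry are out of scope.
- Equivalent-diameter classing inflates oblique crossings (documented
  above); no tilt correction is applied.
- The skeleton branch count depends on the spur-pruning threshold near
  marginal (≈ threshold-length) side branches.
- Beam center and detector geometry are taken from metadata; there is no
  auto-centering, and the meridional (axial period) collagen signal is
  not analyzed — only the equatorial lateral-packing reflection.
- The orientation degree is background-diluted (see above); comparisons
  should use it as a relative measure across positions of one scan.
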