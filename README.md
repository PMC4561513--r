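# microvasq

Quantitative analysis of 3D micro-vascular networks in engineered-bone
scaffolds imaged by propagation-based X-ray phase-contrast
micro-tomography, together with scanning X-ray micro-diffraction mapping
of the collagen matrix.

When porous ceramic scaffolds seeded with bone marrow stromal cells are
implanted in vivo, the newly formed vascular tree determines whether the
construct can be nourished. Synchrotron phase-contrast tomography resolves
vessels of 10–20 μm diameter at sub-micron voxels without contrast agents,
and scanning micro-diffraction maps the packing and orientation of the
collagen matrix around them. This package implements the complete
computational chain for both readouts, plus synthetic generators with
analytic ground truth so that every stage is testable without measured
data.

## What it computes

**Tomography → vascular quantification**

- Single-distance phase retrieval under the homogeneous-object model:
  `T = -(1/μ) ln( F⁻¹[ F[I/I₀] / (1 + (zδ/μ)·4π²|u|²) ] )`, with
  `μ = 4πβ/λ`, plus the matched linearized forward propagator (its exact
  adjoint), so the retrieval filter is validated by round trip.
- Parallel-beam radon projection and ramp-filtered back projection.
- Vessel segmentation (global Otsu or fixed threshold, radius-1 opening,
  small-component removal at 26-connectivity).
- Topology-preserving 3D skeletonization (distance-ordered sequential
  thinning of simple points), centerline graph extraction, spur pruning,
  and branch counting.
- Depth-resolved vessel counts by equivalent-diameter class: small
  `V_m` (10–15 μm) and large `V_M` (15–20 μm) vessels per slice.
- The vascularization factor, a proxy for network flow capacity under the
  assumption that flow scales with vessel section:

  `VF = [ S_small ∫ V_m(z) dz + S_large ∫ V_M(z) dz ] / D_norm`,

  with default section weights at the class-midpoint circle areas,
  `S_small = π(12.5/2)² ≈ 123 μm²` and `S_large = π(17.5/2)² ≈ 240 μm²`.

**Scanning micro-diffraction → collagen maps**

- Detector q-mapping (`q = 4π sin θ / λ`, `2θ = atan(r/L)`), radial and
  azimuthal integration.
- Equatorial collagen peak fit (Gaussian over a second-order polynomial or
  power-law background) around `q ≈ 5.6 nm⁻¹`; the lateral molecular
  spacing is `D = 2π/q_c`.
- Azimuthal orientation fit (two wrapped Gaussians 180° apart over a
  constant background); the orientation degree is the area ratio
  `A_Φ / A_BKG` of aligned to randomly oriented material.
- Per-scan-position collagen amount / angle / degree rasters with a
  quality mask and a vector-plot export.

**Synthetic data** — labeled scaffold + vessel-tree phantoms (biased
random-walk trees with Poisson branching, analytic per-point radii) and
diffraction patterns with known ring and orientation parameters, both
bit-reproducible from a seed.

## Worked example

```r
library(microvasq)

cfg <- tomo_config(phantom = list(shape_voxels = c(96L, 96L, 96L),
                                  n_trees = 2L, rng_seed = 5L),
                   n_angles = 200L)
res <- run_tomo_pipeline(cfg)
res$summary
#> quant_summary:
#>   max section       344.1 um^2
#>   min diameter      16.69 um
#>   branches          6
#>   total small (V_m) 0
#>   total large (V_M) 57
#>   VF                142.8 um^2
```

The phantom here grows two vessel trees (diameters 10–20 μm at 0.64 μm
voxels) through a porous scaffold, simulates 200 propagation-based
projections at 24 keV and 5 cm, retrieves thickness maps, reconstructs,
segments and quantifies. `max section` is the largest vessel cross-section
encountered in any slice, `min diameter` the smallest classed equivalent
diameter, and `VF` the section-weighted depth integral above (in μm²,
normalized by the analyzed depth). The per-slice profile is in
`res$profile` (columns `v_small`, `v_large`, `v_total` per depth).

The diffraction side round-trips the same way:

```r
p   <- simulate_diffraction_pattern(diffraction_sim_spec(rng_seed = 1))
fit <- fit_collagen_peak(radial_integrate(p, n_bins = 150,
                                          q_range = c(0.5, 8)))
fit
#> collagen_peak_fit: q_c = 5.601 1/nm (D = 1.122 nm), sigma = 0.345, area = 103.6
fit_orientation(azimuthal_integrate(p))
#> orientation_fit: angle = 30.22 deg, degree A_Phi/A_BKG = 0.144 (ok)
```

The generator placed the ring at 5.6 nm⁻¹ with a 30° preferred
orientation; the fits recover both, and `D = 2π/q_c ≈ 1.122 nm` is the
collagen lateral packing distance.

## Package layout

- `R/phantom.R`, `R/diffraction-sim.R` — synthetic generators with ground
  truth
- `R/paganin.R`, `R/tomo.R` — phase retrieval and reconstruction
- `R/segment.R`, `R/skeleton.R`, `R/vf.R` — vessel quantification
- `R/diffraction-fit.R` — q-mapping, integration, peak/orientation fits,
  collagen maps
- `R/pipeline.R`, `R/io.R` — end-to-end workflows, YAML configs, TIFF/CSV/
  JSON interchange
- `src/core.cpp` — connected components, exact distance transform,
  distance-ordered 3D thinning, radon/back-projection kernels
- `vignettes/microvascular-quantification.Rmd` — model assumptions,
  parameter choices and limitations
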