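---
title: "Methods: equivolumetric depth profiling of the neonatal cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equivolumetric depth profiling of the neonatal cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In the weeks around birth, intracortical myelin-sensitive MRI contrast
(typically the T1w/T2w ratio) changes rapidly, at different paces in
different cortical territories and at different cortical depths. `neolaminar`
implements the depth-profiling analysis of that process: it reduces a
volumetric myelin-sensitive image and a reconstructed cortical ribbon to
per-region *microstructure profiles* (intensity as a function of cortical
depth), summarizes each profile by two central moments, models how those
moments depend on gestational age (GA, weeks in utero), postnatal age (PNA,
weeks since birth) and their sum, postmenstrual age (PMA), and asks whether
the resulting regional effect maps align with the cortex's coarse geometric
eigenmodes.

Because the real neonatal imaging data this class of analysis is run on is
access-restricted and enormous, the package ships a synthetic
neonatal-cortex *phantom* with analytically known depth structure. Every
stage of the pipeline is exercised and validated against that ground truth;
the same code paths accept real GIFTI/NIfTI inputs.

## Equivolumetric depth surfaces

Twelve intracortical surfaces are placed between the matched pial and white
meshes. Plain fractional-distance placement misassigns laminae in curved
cortex: a lamina occupies relatively more of the ribbon's thickness on a
gyral crown than in a sulcal fundus. The equivolumetric construction instead
fixes the *volume fraction* between consecutive surfaces. Under a
linear-in-depth local area model `A(rho) = A_in + rho (A_out - A_in)`,
solving `V(rho) = alpha V(1)` gives the closed form

    rho(alpha) = (-A_in + sqrt(alpha A_out^2 + (1 - alpha) A_in^2)) / (A_out - A_in)

with the flat-sheet limit `rho = alpha` taken whenever
`|A_out - A_in| < 1e-9 max(A_in, A_out)` to avoid cancellation. Local
curvature enters through the pial/white **vertex-area ratio** (barycentric
lumped areas, one third of incident triangle area); no curvature tensor is
computed. `build_depth_surfaces()` evaluates `rho` per vertex with
`A_in` the white-side and `A_out` the pial-side area and places each depth
vertex on the straight segment between its white and pial positions.

Conventions chosen here, where more than one reading was defensible:

* **Depth index orientation**: depth 1 = pial, depth 12 = white, so a larger
  profile center of gravity always means signal balance toward *deeper*
  cortex.
* **Boundary surfaces**: the default volume-fraction grid spans [0, 1]
  inclusive of both boundary surfaces, matching the usual depiction of
  profiles spanning pial to white. An `offset` argument shrinks the grid to
  an interior band for users who want to avoid boundary partial-voluming.
* **Accuracy of the linear-area model**: on a concentric-sphere ribbon with
  a 4:9 area ratio (far more curved than cortex at these scales) the shells
  between consecutive surfaces depart from exact equality by at most 2.3%,
  which is the intrinsic error of the linear-area closed form at that
  curvature; at cortex-like curvature (pial/white area ratio ~1.4 for a 2 mm
  cortex on a 12 mm sphere) the departure is well under 2%. The test suite
  pins the construction to the analytic linear-area prediction to 1e-7.

## Sampling and central moments

`trilinear_sample()` maps world coordinates through the inverse voxel
affine (0-based indices, voxel centers at integer coordinates) and blends
the eight surrounding voxels. Points outside the hull of voxel centers are
*masked*, never clamped or zero-filled, because silent zeros would corrupt
moment estimates; trilinear interpolation is exact on affine intensity
fields, which the tests exploit as an oracle. A vertex is dropped if any of
its 12 depth samples is invalid.

Each profile `I_1..I_12` (non-negative; negative inputs are rejected unless
explicitly clamped) is treated as a histogram over depth bins `d = 1..12`
with weights `w_d = I_d / sum(I)`:

* `mu1 = sum(w_d d)` — the **center of gravity**, in depth-index units;
  higher is deeper.
* `mu2 = sqrt(sum(w_d (d - mu1)^2))` — conventionally called the
  **variance** of the profile but reported, deliberately, as the standard
  deviation of the depth distribution; the name is kept for fidelity with
  the field's usage and the definition is documented here.

Both moments are invariant to positive rescaling of the profile, so no
intensity normalization is applied before sampling. Depths are integer
indices rather than millimetres or normalized fractions: the moments then
have transparent bounds (`mu1` in [1, 12]; `mu2` in [0, 5.5]).

A note on interpretation: `mu2` *indexes* flatness — flat profiles score
high, single-depth concentrations score zero — but the uniform profile is
not the global maximizer; mass split between the two extreme depths attains
the bound 5.5. Across realistic smooth profile families the association
between `mu2` and flatness is strong and monotone, and the test suite
checks exactly that (plus the closed-form mixture-variance oracle for
central concentration), not a false extremal claim.

Aggregation is **profiles first, moments second**: parcel profiles are
unweighted means over masked-in vertices and the moments are taken of the
mean profile. Masked-aware averaging is used because the original ordering
of masking and averaging is not documented for this analysis family; the
choice is explicit and tested. `sliding_window_profiles()` (1.5-week
windows, 50% overlap by default) and `moment_sorted_bins()` (100
rank-preserving bins) reproduce the two standard profile visualizations.

## Developmental models and inference

All models are ordinary least squares with an intercept, fitted per parcel.
The two model families mirror the analysis they implement: `PMA + sex`
(cumulative maturation) and `GA + PNA + sex` (dissecting pre- from postnatal
contributions; the two ages are negatively correlated by design, and the
joint model reports each age's association conditional on the other). A
`GA x PNA` interaction model computes the product after mean-centering both
ages, making the interaction t-statistic invariant to covariate shifts.
Specs containing PMA together with both GA and PNA are rejected up front:
PMA = GA + PNA exactly, so the design would be singular. Thickness can be
appended to any model as a covariate; it is the same engine behind a flag.

Multiplicity is controlled by Benjamini-Hochberg step-up across the
analyzed parcels at `alpha = 0.025` per moment (two moments at an overall
0.05). The FDR family is the narrowest defensible reading — one family per
(response moment, term, model) triple — and is configurable. Degrees of
freedom and two-sided p-values follow the standard OLS t framework; no
robust errors. When the residual sum of squares is at rounding-noise level
relative to the response (an exact fit), t is defined as 0 for a zero
coefficient and signed infinity otherwise, so degenerate phantom runs have
well-defined output.

Global model comparison fits candidate predictor sets to the cortex-wide
mean moment and reports R², AIC ranking and nested F-tests; AIC is used
because no particular criterion is canonical here and the F-tests carry the
nested comparisons.

## Geometric eigenmodes

`build_fem_matrices()` assembles the linear finite-element Laplace-Beltrami
operator: cotangent-weighted stiffness (row sums zero) and the consistent
mass matrix (entries summing to the surface area); a lumped-mass option
exists for comparison. `compute_eigenmodes()` solves `K v = lambda M v` for
the smallest eigenpairs. The generalized problem is reduced by a Cholesky
factor of the mass matrix and solved densely with LAPACK: at the mesh sizes
used here (hundreds to a few thousand vertices) this is exact, fast
(seconds at 2562 vertices) and free of iterative-solver convergence
concerns. Eigenvector signs are fixed by requiring the largest-magnitude
loading to be positive (ties to the lowest index), because downstream
correlations are sign-sensitive and must reproduce bit-for-bit.

Mode 1 is the constant; "modes 2-4" are indices 2-4 in this 1-based
counting. On the unit icosphere the spectrum follows the spherical-harmonic
law `l(l+1)`: modes 2-4 near 2 and 5-9 near 6, within 0.3% at subdivision 4
— the package's strongest external anchor for the discretization. For
phantom studies the eigenmodes are computed on the phantom's own
midthickness mesh; with real data one would typically use a population
template surface, and the two choices are not asserted equivalent.

## Spin permutation inference

`spin_correlation_test()` measures the Pearson correlation between two
vertex maps and builds a null that preserves spatial autocorrelation:
uniformly random rotations (QR orthonormalization of a Gaussian matrix with
determinant correction — exactly Haar) are applied to the first map's
spherical projection, values are reassigned by exact nearest neighbour, and
the correlation is recomputed. The p-value is
`(1 + #{|r_null| >= |r_obs|}) / (1 + n_perm)`, two-tailed. Conventions
chosen where the method family leaves room:

* rotation is applied to one map only (the effect map), the eigenmode map
  staying fixed;
* rotated assignments drawing on missing-source vertices propagate
  missingness and the pair is dropped for that permutation (imputing from
  the nearest valid vertex is available behind a flag-free alternative:
  drop is the default because imputation biases boundary regions);
* nearest-neighbour lookup is exact (max dot product), not approximate.

Because nearest-neighbour reassignment is piecewise-constant in the
rotation, rotations close enough to the identity reproduce the map exactly;
on coarse meshes this gives self-correlation ties a small positive
probability, which shrinks rapidly with mesh resolution. The calibration
tests therefore run the self-correlation check on a subdivision-3 sphere.
`eigenmode_variance_explained()` completes the alignment analysis with
uni- and multivariate regressions of an effect map on mode subsets,
reporting monotone-by-construction R² for nested subsets.

## The synthetic phantom: what it emulates, and what it does not

`simulate_cohort()` draws GA from a two-component (preterm + term) Gaussian
mixture truncated to [23, 42.3] weeks (term component centered at 39.6,
preterm at 32, preterm weight 0.27), giving the long left tail of a
preterm-enriched sample. PNA is a monotone map of a latent Gaussian onto a
right-skewed Beta(1, 5) shape over [0, 7] weeks (median ~0.9 weeks — most
infants scanned in their first week). The latent correlation is calibrated
by deterministic Gauss-Hermite quadrature so the *observed* GA-PNA Pearson
correlation hits its target (default -0.43) despite the non-linear margins;
the generator errs rather than silently missing an infeasible target. PMA
is exactly GA + PNA; sex is balanced 0/1.

`simulate_phantom_geometry()` builds a closed "cortex": a white icosphere
(default radius 12 mm, neonatal-scale curvature) modulated by a smooth
low-order angular field (amplitude 8%), a pial surface at a smoothly varying
thickness (2 mm +- 15%) along each vertex ray, spherical-Voronoi parcels
(default 33, matching a per-hemisphere atlas after exclusions), and a
0.5 mm isotropic sampling grid, the working resolution of processed
neonatal data. Because radius and thickness are closed-form functions of
direction, every voxel's fractional cortical depth is known analytically —
sampling error is measurable independently of any mesh processing.

`simulate_subject_volume()` fills the ribbon with a per-parcel-group
12-depth template evaluated at the voxel's analytic depth plus Gaussian
noise. The default effect specification plants a deep-layer GA slope in one
contiguous sector of parcels, a superficial PNA slope in a second, and no
age effect in a third (0.012 intensity units per week at the affected
depths, voxel noise SD 0.05, on a baseline profile rising 1.0 to 1.6 from
pial to white). Group territories are contiguous azimuthal sectors rather
than interleaved parcels: regional developmental effects cluster spatially
in real cortex, and contiguity also keeps the unavoidable trilinear mixing
at parcel borders mostly within a group. Covariates enter as deviations
from a term-birth reference (GA 40, PNA 0), so the baseline template *is*
the expected term-newborn profile; the spec constructor proves the expected
profile positive over the whole configured covariate box before it will
simulate.

Two deliberate idealizations:

* **Boundary intensities.** The default background continues the baseline
  template across the pial and white boundaries. With sharp contrasting
  backgrounds (CSF ~0.3, white ~1.8 — also supported), the boundary depth
  surfaces sample ~50% background and `mu1` acquires a ~0.3 depth-unit
  partial-volume bias; that is a property of sharp-boundary imaging, not of
  the sampler, and continuing the template lets the noiseless pipeline
  fidelity (measured: `mu1` within ~0.03, tolerance 0.15 depth units on a
  0.5 mm grid) isolate sampling and placement error.
* **No acquisition physics.** No bias fields, motion, folding beyond smooth
  radial perturbation, or tissue-boundary blur. Passing tests demonstrate
  the *pipeline's* correctness on known truth — not that effects in real
  neonatal cohorts would be recovered at these effect sizes.

## Validation sizes and numerical choices

The shipped validation exercises, sized to run comfortably on one CPU:
equivolume closed form vs numeric inversion on a 50^3 grid (agreement
~1e-12); sphere spectrum at subdivision 4; 500-replicate null-calibration
of BH-FDR at 66 parcels (empirical FDR ~0.028 against a 0.039 Monte-Carlo
bound); 200 smooth-map pairs x 500 spins for p-value uniformity; 100
phantom cohorts of n = 150 for planted-effect recovery (hit rate 1.00,
false-positive rate ~0.01-0.02, and a sign flip when the planted depth is
swapped); noiseless end-to-end fidelity at subdivision 4; and byte-identical
pipeline reruns under a fixed seed. Seeds derive from one master seed via
fixed substreams (all below 2^31); every simulate function is a pure
function of its arguments.

## Known limitations

* The equidistant placement model is available only as the equal-area
  degenerate case; no alternative laminar models.
* Higher profile moments (skewness, kurtosis) and profile-covariance
  analyses are out of scope.
* Mixed-effects/longitudinal models are deliberately absent — the analysis
  is cross-sectional by design.
* The dense eigenmode solver is intended for meshes up to a few thousand
  vertices; very large meshes would need an iterative sparse solver.
* The spin test operates on a single closed surface; paired-hemisphere
  mirrored rotation is stubbed for real-data use but not exercised by the
  phantom.
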