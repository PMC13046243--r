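# neolaminar

Equivolumetric depth profiling of the neonatal cortex.

In the weeks around birth, myelin-sensitive MRI contrast (T1w/T2w ratio)
reorganizes across cortical regions *and* across cortical depths.
`neolaminar` implements the full analysis pipeline for studying that
process, exercised end to end on a synthetic neonatal-cortex phantom with
analytically known ground truth:

1. **Equivolumetric depth surfaces** — 12 intracortical surfaces between
   matched pial/white meshes, placed so each pair of consecutive surfaces
   encloses an equal fraction of local cortical volume. Curvature is
   compensated through the pial/white vertex-area ratio via the closed form
   `rho = (-A_in + sqrt(alpha A_out² + (1-alpha) A_in²)) / (A_out - A_in)`.
2. **Depth profiles and central moments** — trilinear sampling of a volume
   at every vertex of every depth surface; each profile is treated as a
   histogram over depths `d = 1..12` (1 = pial) with weights
   `w_d = I_d / ΣI`, giving the center of gravity `μ1 = Σ w_d d` (higher =
   deeper signal balance) and the spread `μ2 = sqrt(Σ w_d (d - μ1)²)`
   (higher = flatter profile).
3. **Parcel-wise developmental models** — OLS fits of each moment on
   postmenstrual age + sex, or gestational + postnatal age + sex (with an
   optional GA×PNA interaction after mean-centering), with
   Benjamini–Hochberg FDR control at α = 0.025 per moment.
4. **Geometric eigenmodes and spin tests** — linear-FEM Laplace–Beltrami
   eigenmodes of the cortical mesh (cotangent stiffness, consistent mass),
   and spatial-autocorrelation-preserving spin permutation tests aligning
   effect maps with modes 2–4, plus eigenmode variance decomposition.

The phantom module (`simulate_cohort()`, `simulate_phantom_geometry()`,
`simulate_subject_volume()`) generates cohorts with the GA/PNA structure of
a preterm-enriched neonatal sample (GA 23–42.3 weeks, PNA 0–7 weeks,
correlation −0.43 by calibrated copula) and 0.5 mm ribbon volumes whose
depth profiles carry known region- and depth-specific age effects, so every
downstream stage is testable without imaging data. Real GIFTI surfaces and
NIfTI volumes run through the same functions.

## Worked example

A small phantom study: simulate 40 neonates, sample depth profiles, reduce
to parcel moments, fit the GA + PNA + sex model, and test the GA effect map
against the second geometric eigenmode.

```r
library(neolaminar)
library(dplyr)

cohort <- simulate_cohort(n = 40, seed = 7)
head(cohort, 3)
#> # A tibble: 3 × 6
#>   subject_id ga_weeks pna_weeks pma_weeks   sex thickness_mm
#>   <chr>         <dbl>     <dbl>     <dbl> <int>        <dbl>
#> 1 sub-0001       42.0     0.896      42.9     0           NA
#> 2 sub-0002       31.3     0.859      32.2     0           NA
#> 3 sub-0003       36.6     0.983      37.5     0           NA

geom  <- simulate_phantom_geometry(subdivision = 3, n_parcels = 33, seed = 8)
spec  <- default_effect_spec()        # deep GA slope in one parcel sector
stack <- build_depth_surfaces(geom$ribbon, n_depths = 12)

moments <- bind_rows(lapply(seq_len(nrow(cohort)), function(i) {
  vol <- simulate_subject_volume(geom, cohort[i, ], spec, seed = 100 + i)
  pm  <- parcel_mean_profiles(sample_profiles(vol, stack), geom$labels)
  mm  <- profile_moments(as.matrix(pm[, grep("^depth_", names(pm))]))
  tibble::tibble(subject_id = cohort$subject_id[i], parcel_id = pm$parcel_id,
                 mu1 = mm$mu1, mu2 = mm$mu2)
}))

effects <- parcelwise_effects(moments, cohort, c("ga", "pna", "sex"),
                              term = "ga", response = "mu1", alpha = 0.025)
arrange(effects, desc(statistic))[1:4, ]
#> # A tibble: 4 × 8
#>   parcel_id term  estimate       se statistic  p.value  q.value significant
#>   <chr>     <chr>    <dbl>    <dbl>     <dbl>    <dbl>    <dbl> <lgl>
#> 1 16        ga     0.00770 0.000298      25.8 8.25e-25 2.41e-23 TRUE
#> 2 27        ga     0.00760 0.000300      25.4 1.46e-24 2.41e-23 TRUE
#> 3 28        ga     0.00791 0.000319      24.8 3.19e-24 3.51e-23 TRUE
#> 4 20        ga     0.00737 0.000315      23.4 2.30e-23 1.90e-22 TRUE
sum(effects$significant)
#> [1] 11
```

Exactly the 11 parcels of the planted deep-GA sector are recovered
(estimates ≈ the per-week μ1 shift the planted slope implies), and the
other 22 parcels stay non-significant. The effect map can then be tested
against cortical geometry:

```r
mid   <- surface_mesh((geom$ribbon$pial$vertices + geom$ribbon$white$vertices) / 2,
                      geom$ribbon$pial$triangles)
basis <- compute_eigenmodes(mid, k = 10)
tmap  <- upsample_parcel_map(effects, geom$labels)
tidy(spin_correlation_test(tmap, basis$modes[, 2], geom$sphere,
                           n_perm = 1000, seed = 9))
#> # A tibble: 1 × 4
#>   estimate p.value n_perm  seed
#>      <dbl>   <dbl>  <int> <int>
#> 1   -0.128   0.830   1000     9
```

The planted sector is azimuthal, so it does not align with mode 2 — the
spin test correctly reports a correlation indistinguishable from the
spatial null (r = −0.13, p = 0.83).

`run_pipeline(pipeline_config(n = 40, seed = 7, out = "run"))` executes all
of the above (plus the PMA model, model comparison, and eigenmode variance
decomposition) and writes every artifact with a manifest;
`inst/cli/neolaminar.R` exposes the stages as shell subcommands.

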