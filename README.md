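# dentract

Multi-fiber diffusion MRI tractography of the pathways connecting the
cerebellar cortex to the dentate nuclei, with the group and single-subject
statistics used to compare them.

## The problem

Purkinje cells are the only efferent neurons of the cerebellar cortex; their
axons project to the dentate nuclei. Post-mortem studies of autism spectrum
disorder report reduced Purkinje cell number and size in the
posterior-lateral cerebellar cortex, predicting a loss of directional
coherence in the white matter between that cortex and the dentate.
`dentract` implements the in vivo test of that prediction on
diffusion-weighted MRI: it resolves crossing fibers per voxel, tracks
streamlines from cortical seed regions, sorts them into pathways reaching
the dorsal and ventral dentate nuclei (DDN/VDN) of each hemisphere, and
compares per-pathway metrics between groups with age and head-motion
covariates. It is aimed at neuroimaging researchers who need the complete
chain — multi-fiber fitting, deterministic tracking, ROI sorting, motion QC,
robust tensor maps, statistics — as reusable, tested R functions, plus a
synthetic phantom generator so everything is verifiable without clinical
data.

## The model

Each voxel's signal follows a multi-compartment ball-and-stick model with up
to three sticks sharing one diffusivity *d*:

    S(b, g) = S0 [ (1 - Σ_j f_j) e^{-bd} + Σ_j f_j e^{-bd (g·v_j)²} ]

Orientations `v_j` and fractions `f_j` are estimated per voxel by
alternating two steps over an 11-voxel local window: FastICA decomposition
of the window's attenuation matrix into independent source profiles, and
constrained ball-and-stick fitting of the sources at the centre voxel.
Deterministic tracking then propagates streamlines at 0.2-voxel steps, a 60°
turning-angle threshold, trilinear interpolation over sticks with fraction
> 0.15, and equal smoothing of previous and incoming directions. Pathway
voxels are those visited by more than 5 streamlines; each pathway reports
SC (streamline count), SV (volume), and mean FA/AD/RD from a robust
(outlier-rejecting) tensor fit. A unitless motion index — the summed mean
absolute between-frame displacement of six rigid registration parameters —
quantifies head motion and enters the group models as a covariate.

## Worked example

Simulate one subject with a degraded right-VDN pathway (30% lower stick
fraction plus 20° orientation dispersion), run the full pipeline, and read
off the per-pathway metrics:

```r
library(dentract)

gtab    <- default_gradient_table(30)           # 30 directions at b = 1000
phantom <- make_cerebellum_phantom(grid_shape = c(30, 30, 8), gtab = gtab,
                                   effect = 0.3, dispersion_deg = 20,
                                   snr = 30, rng_seed = 1)
cfg <- run_config(n_seeds = 1000, rng_seed = 2)
res <- run_subject(phantom$dwi, gtab, phantom$truth$seed_mask,
                   phantom$truth$target_masks, mask = phantom$truth$mask,
                   config = cfg, motion = "none")
res$metrics[, c("pathway", "SC", "SV", "FA", "AD", "RD")]
#> # A tibble: 4 × 6
#>   pathway    SC    SV    FA      AD       RD
#>   <chr>   <int> <dbl> <dbl>   <dbl>    <dbl>
#> 1 L_DDN      53  382. 0.739 0.00179 0.000402
#> 2 L_VDN      55  392. 0.742 0.00177 0.000393
#> 3 R_DDN      42  350. 0.735 0.00179 0.000408
#> 4 R_VDN      19  170. 0.567 0.00181 0.000660
```

The three intact pathways agree (FA ≈ 0.74, SC 42–55); the degraded right
VDN pathway shows exactly the predicted signature — fewer streamlines
(SC 19), smaller volume, lower FA and higher RD — because dispersed, weaker
sticks attenuate the signal less anisotropically and derail the tracker.
SV is in mm³ (pathway voxels × 10.6 mm³ at the 1.88 × 1.88 × 3 mm voxel
size); AD/RD are in mm²/s.

Cohort-level analysis wraps the same call per subject and adds the
statistics (covariate-adjusted group tests per pathway, single-subject flag
percentages, per-group CDFs):

```r
cohort <- simulate_cohort(n_per_group = c(14, 15), effect = 0.3,
                          grid_shape = c(30, 30, 8), gtab = gtab,
                          snr = 30, rng_seed = 7)
out <- run_cohort(cohort, cfg, motion = "truth")
tidy(out$group_tests$FA)     # per-pathway adjusted effects and p-values
out$flags                    # % of group B below mean-3·SE / lower decile
plot_cdf(out$records, "FA")  # per-group empirical CDFs per pathway
```

A thin command-line wrapper (`inst/cli/dentract.R`) exposes the stages as
subcommands (`simulate`, `motion`, `fit-tensor`, `fit-icabsm`, `track`,
`metrics`, `stats`) over standard formats: NIfTI volumes, FSL bvals/bvecs,
TRK/TCK tractograms, TSV tables.

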