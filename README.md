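# alongtract

Along-tract ("tractometry") statistics for diffusion tensor MRI, built for
studies of limbic white-matter bundles such as the fornix and cingulum:
whole-bundle averages can hide abnormalities that are confined to one
segment of a tract, so this package tests group differences and clinical
correlations *point by point along the bundle* instead.

The pipeline, end to end:

1. **Tensor fitting** — per voxel, the diffusion tensor `D` is estimated
   from the single-shell signal model `S = S0 exp(-b g' D g)` by
   log-linear least squares, and the scalar maps are derived from its
   sorted eigenvalues:
   `FA = sqrt(3/2) ||lambda - mean(lambda)|| / ||lambda||`,
   `RD = (lambda2 + lambda3)/2`, `AD = lambda1`.
2. **FACT tractography** — deterministic streamline propagation along the
   per-voxel principal eigenvector (direction updated at each voxel
   entry), seeded from every voxel with FA >= 0.15, terminated below that
   threshold or at turning angles above 50 degrees.
3. **Bundle extraction** — multi-ROI AND logic: a streamline belongs to a
   bundle iff it crosses every ROI of that bundle's protocol
   (`limbic_roi_protocol()` records the published atlas slice indices);
   anterior/middle/posterior cingulum splitting and Dice/Jaccard overlap
   reliability included.
4. **Mean curve** — each bundle is summarized by a single curve
   parameterized at 30 equal arc-length points (orientation alignment +
   resampling + pointwise averaging + re-parameterization), the common
   coordinate frame for all subjects.
5. **Profiles and statistics** — every subject's FA/RD/AD maps are
   sampled along the curve, smoothed with a 6-point moving window, and
   analysed per point by linear regression on diagnostic group with
   covariates age, years of education and illness duration, Bonferroni
   corrected over the 30 points (overall alpha 0.05); partial
   correlations with PANSS scores are run the same way in patients only.

Because the motivating study's scans are not public, the package includes
a first-class synthetic module: curved-tube tensor phantoms with known
centerlines, the 16-volume b = 800 s/mm^2 acquisition, Rician noise,
and two-group cohorts (31 controls / 33 patients with the published
covariate distributions) carrying a localized FA/RD effect and an
FA-coupled PANSS score — so every stage is tested against ground truth.

## Worked example

Simulate the default cohort (31 controls, 33 patients, FA reduced in
patients over profile points 12–18 at raw Cohen's d ~ 1.2) and run the
whole pipeline in memory:

```r
library(alongtract)

cfg <- pipeline_config(seed = 1)
ex  <- tract_experiment(cfg, metrics = "fa")

ex$cohort
#> Simulated cohort: 31 controls, 33 patients; grid 24x10x10
ex$curve
#> Mean curve of 'tube': 30 points, 44.5 mm, oriented origin->terminus

pw <- ex$pointwise
pw[pw$significant, c("point", "coefficient", "t", "p")]
#>  point coefficient     t        p
#>     14     -0.0148 -3.62 6.21e-04
#>     15     -0.0191 -4.93 7.03e-06
#>     16     -0.0223 -6.65 1.06e-08
#>     17     -0.0222 -6.94 3.39e-09
#>     18     -0.0186 -5.66 4.78e-07
#>     19     -0.0143 -4.39 4.69e-05
```

The flagged points sit inside the injected segment: the group coefficient
is the FA difference (patients minus controls) at that arc-length point
after covariate adjustment — about −0.02 at the effect center — and a
point is flagged when its two-sided p falls below 0.05/30. The ROI-level
(whole-bundle mean) analysis of the same cohort dilutes the localized
effect, which is the argument for along-tract analysis:

```r
ex$roi[ex$roi$metric == "fa", ]
#>  bundle metric coefficient     t       p
#>    tube     fa     -0.0052 -3.24 0.00195
```

The same analysis runs file-based: `run_simulate(cfg)` writes per-subject
NIfTI volumes, FSL bvec/bval sidecars, the subject CSV and ground-truth
JSON; `run_full(cfg)` executes average → fit → track → extract → curve →
profiles → statistics with content-hash stage caching and writes TSV/JSON
results under `<output_dir>/results`.

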