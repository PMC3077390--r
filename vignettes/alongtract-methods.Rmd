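---
title: "Along-tract analysis of diffusion tensor MRI: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Along-tract analysis of diffusion tensor MRI: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alongtract)
```

`alongtract` implements a tractometry pipeline for limbic white-matter
bundles -- fornix and cingulum in the motivating study -- from
diffusion-weighted volumes to pointwise group statistics, together with a
synthetic-phantom module that makes every stage verifiable against known
ground truth. This vignette is the package's own account of the science:
the models, the tunable parameters and why their defaults are what they
are, what the simulations emulate and deliberately do not, and where the
method's detection limits lie.

## The diffusion tensor and its scalar maps

Water diffusion in each voxel is modelled by a symmetric positive 3x3
tensor $D$ (mm^2/s). A single-shell acquisition measures, per gradient
direction $g$ (unit vector) and b-value $b$ (s/mm^2),

$$S = S_0 \, e^{-b \, g^\top D g}.$$

The acquisition emulated throughout is one baseline ($b=0$) plus 15
diffusion-weighted volumes at $b = 800$ s/mm^2. `fit_tensor()` estimates
the six unique coefficients of $D$ by ordinary (unweighted) log-linear
least squares on $\ln(S_i/S_0)$. The estimator is deliberately the
closed-form one: it is deterministic, solvable in a single matrix
operation for a whole volume, and exactly checkable against the forward
model (the noise-free round trip recovers coefficients at machine
precision, asserted in the tests at 1e-8 relative). Weighted or robust
(outlier-rejecting) variants are out of scope.

From the sorted eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$:

* **FA** $= \sqrt{3/2}\,\|\lambda - \bar\lambda\| / \|\lambda\|$, in [0, 1];
* **RD** $= (\lambda_2 + \lambda_3)/2$, the radial diffusivity;
* **AD** $= \lambda_1$, the axial diffusivity.

Noisy background voxels can yield negative eigenvalue estimates and hence
FA > 1; eigenvalues are clamped to zero before the metric formulas and the
affected voxels flagged (`scalar_maps()$clamped`). Whole-volume
eigenvalues use the closed-form trigonometric solution for symmetric 3x3
matrices, vectorized across voxels; eigenvectors (needed only for
tracking) are computed per voxel on the suprathreshold mask.

## FACT tractography

`track_all()` implements Fiber Assignment by Continuous Tracking in its
original voxel-boundary form: a streamline is seeded at the center of
every voxel with FA at or above the threshold, propagates along the
voxel's principal eigenvector until it crosses a voxel boundary, adopts
the next voxel's eigenvector there (sign chosen to continue the incoming
direction), and terminates on (i) entering a voxel with FA below
threshold, (ii) a turning angle above the limit, or (iii) leaving the
grid. Seeding is bidirectional and the two halves are concatenated.
Defaults follow the protocol the pipeline reproduces: FA threshold 0.15,
angle threshold 50 degrees. The minimum streamline length (default 10 mm)
suppresses single-voxel fragments; the protocol source is silent on this
value. Nearest-voxel direction assignment (not trilinear-interpolated
vectors, not Runge-Kutta integration) was chosen because it matches the
cited method's definition and is exactly oracle-checkable on phantoms:
on a straight tube every in-tube seed must span the tube, and at a
90-degree crossing no streamline may turn, because 90 > 50.

Bundles are extracted by multi-ROI AND logic (`select_by_rois()`): a
streamline belongs to the bundle iff it intersects every ROI. The atlas
slice indices of the published fornix/cingulum protocol ship as
`limbic_roi_protocol()` for real atlas-space data; phantom tests define
analogous plane ROIs on their own grids. The cingulate cingulum can be
split into anterior/middle/posterior parts by clipping at two coronal
planes (`partition_cgc()`), and segmentation reliability can be
quantified with `overlap_ratio()` (Dice by default, Jaccard by flag --
the protocol source never states its overlap formula algebraically, so
its printed 87.5% figure is not treated as reproducible).

## The 30-point mean curve

The bundle's geometric representation is a single curve parameterized at
30 equal arc-length points. The original protocol computed it by
diffeomorphic (LDDMM) curve mapping; that machinery is out of scope here
and is replaced by a documented, deterministic procedure:

1. orient every streamline consistently (first point nearest an origin
   ROI, `orient_bundle()`);
2. resample each streamline to 30 equal-arc-length points;
3. average the point sets coordinate-wise across streamlines;
4. re-parameterize the averaged polyline to exactly 30 uniform
   arc-length points.

On coherent, tube-like bundles -- which is what the multi-ROI extraction
produces by construction -- the two constructions agree to well within a
voxel, and the substitution buys an exact phantom oracle: the mean curve
of a simulated tube must lie within one voxel of the true centerline
(asserted in the tests; endpoint comparisons use the centerline extended
by the tube radius, since the voxelized tube physically reaches one
radius beyond the parametric centerline's last point).

Per-subject profiles sample each subject's FA/RD/AD map at the 30 shared
curve points by trilinear interpolation (`extract_profile()`). Sampling
was chosen over per-streamline projection because all subjects share the
atlas frame in this design; trilinear interpolation is continuous and
reproduces affine fields exactly, which the tests exploit. Profiles are
smoothed along the curve by averaging each point with its five nearest
neighbours by index. Five neighbours of a center point are necessarily
asymmetric; the tie at distance three is resolved toward the curve start,
giving the 6-point window of offsets -3..+2, truncated at the profile
ends. The symmetric centred 5-point window is available via
`smooth_profile(window = "five")` for users who prefer the
linearity-preserving variant.

## Statistics

Group comparisons use ordinary least squares of the outcome on an
intercept, the diagnostic-group indicator (control = 0, patient = 1) and
the covariates age, years of education and illness duration, with
two-sided p values from the t distribution on $n - 5$ df:

* `roi_analysis()` -- one regression per bundle x metric on the
  whole-bundle mean value, reported uncorrected (matching how ROI-level
  results were presented in the motivating study);
* `tractwise_analysis()` -- one regression per arc-length point on the
  smoothed profiles, with Bonferroni correction. The correction family
  defaults to the 30 points within one bundle x metric; the overall
  "0.05 after Bonferroni correction" statement in the protocol source
  never defines the family, so the family size is a configuration knob.

Illness duration is coded 0 for controls so that a single model covers
both groups; the alternative (two-group models without duration) would
preclude the single pooled regression the protocol describes. A
consequence worth understanding is quantified below.

Clinical associations use `partial_correlation()` (residualize both
variables on the covariates, Pearson correlation of residuals,
$t = r\sqrt{(n-2-k)/(1-r^2)}$) applied at every profile point in patients
only (`clinical_correlation()`), again with Bonferroni over the 30
points.

## The synthetic cohort: what it emulates

`make_cohort()` simulates the study end to end:

* **Geometry.** A curved tube (default: a gentle arc, 40 mm long, radius
  3 mm, in a 24 x 10 x 10 grid of 2 mm voxels) of anisotropic tensors
  with eigenvalues (1.5, 0.3, 0.3) x 10^-3 mm^2/s -- FA 0.7698 -- in an
  isotropic background of 0.7 x 10^-3 mm^2/s. The grid is deliberately
  compact: it is the smallest geometry in which tracking, bundle
  extraction and 30-point profiles are all nondegenerate, and it keeps
  500-replicate null simulations affordable on one CPU.
* **Acquisition.** The 16-volume scheme above, with a fixed
  electrostatic-repulsion direction set (minimum pairwise angle 37
  degrees); the study's scanner-specific direction table is not public,
  so a reproducible standard set is used instead.
* **Noise.** Rician: $\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}$ with
  Gaussian $\epsilon$, the standard magnitude-MRI model. The default
  sigma is 3% of the baseline signal (SNR ~ 33), a typical value for a
  3T single-shot EPI acquisition at this b-value.
* **Group effect.** Patients have $\lambda_2, \lambda_3$ raised by
  `effect_delta` inside an arc-length segment covering profile points
  12-18, so that RD rises and FA falls with AD unchanged there --
  mirroring the fornix signature reported in the motivating study (FA
  down, RD up, AD flat). The default
  `effect_delta = 1.89e-5` mm^2/s was calibrated once by Monte Carlo so
  that the raw standardized group difference (Cohen's d) of the smoothed
  locus FA is approximately 1.2 at the default noise level.
* **Covariates and scores.** Age, education, illness duration and the
  PANSS/GAF scores are drawn from normal distributions with the
  published group means and SDs (duration fixed at 0 for controls;
  education and duration clamped at 0). The PANSS total score can be
  coupled to the subject's *measured* smoothed FA at the effect locus:
  `panss_coupling` is defined directly as the target correlation, via
  score = mean + sd (rho z_FA + sqrt(1-rho^2) eps) with z_FA the
  within-patients standardized locus FA -- so the generative parameter
  is scale-free and equals the true association being recovered.

What the phantom deliberately does **not** emulate: head motion, eddy
currents, susceptibility distortion, partial-volume mixtures, crossing
fibers inside one bundle, registration error between subjects, and
non-normal covariate distributions. Passing tests therefore demonstrate
the correctness of the pipeline's computations and calibration of its
inference under the stated generative model, not robustness to real-data
artifacts; on real scans the upstream corrections (motion/eddy, spatial
normalization) are assumed to have been applied before this pipeline.

## Numerical choices

* Coordinates: voxel (i, j, k) is the axis-aligned box with center
  (i - 1/2) h for voxel size h; world coordinates are mm.
* Tensor fits floor the measured signal at 1e-6 before the log; voxels
  with nonpositive baseline get a zero tensor and a flag.
* Eigenvector sign at tracking time follows the incoming direction
  (nonnegative dot product); the first step uses both signs.
* Voxel membership of a polyline is decided by segment midpoints after
  half-voxel densification, so termination vertices that lie exactly on
  a voxel boundary are not attributed to the out-of-bundle voxel.
* Streamline orientation ties (endpoints equidistant from the origin
  within 1e-6 mm) keep their order and warn.
* Profile points within the outer half-voxel of the grid clamp to the
  edge voxel value; points outside the grid raise an error naming the
  point index.
* Stage caching in `run_full()` keys each stage on a hash of its
  parameters plus the md5 sums of its input files; deleting any
  intermediate file triggers exactly the recomputation needed.

## Detection limits of the design

Two properties of the study design bound what pointwise inference can
achieve, and both are visible in the package's own simulations:

```{r vif, eval = FALSE}
# Collinearity of the group indicator with the covariate set, under the
# published demographics (duration = 0 for all controls):
co <- make_cohort(phantom_spec(grid_shape = c(16L, 8L, 8L)),
                  cohort_spec(seed = 1))
s <- co$subjects
summary(lm(I(group == "patient") ~ age + education + duration,
           data = s))$r.squared
```

Because illness duration is zero for every control and education and age
differ by group, the group indicator is strongly collinear with the
covariates (R^2 around 0.5 in draws from the published demographics).
The standard error of the group coefficient is inflated by
$1/\sqrt{1-R^2}$ (about 1.4x) relative to an unadjusted comparison, so an
injected effect of raw Cohen's d = 1.2 reaches only moderate per-point
power at the Bonferroni-corrected threshold -- the covariate adjustment
the protocol prescribes is paid for in sensitivity. Similarly, a true
partial correlation of 0.6 in 33 patients with three covariates sits near
the Bonferroni-corrected critical value (|r| = 0.55 at alpha/30), so
single-point recovery of clinical couplings of that size is intrinsically
borderline at this sample size. The family-wise error rate, by contrast,
is conservatively controlled: smoothing correlates neighbouring points,
and Bonferroni over 30 positively correlated tests keeps the empirical
FWER well under the nominal 0.05 (recomputed from scratch by
`scripts/acceptance.R`).

## Simulation sizes used by the tests

The shipped test suite runs the full pipeline on 100 effect replicates
and 500 null replicates (each a 64-subject cohort on the default grid),
plus smaller cohorts for geometry and determinism checks; these sizes
put Monte-Carlo standard errors near 0.01 for the rates being checked
while keeping the default suite practical on a single CPU. The same
sizes are used by `scripts/acceptance.R`.

## Known limitations

* Voxel-boundary FACT is faithful to the original method but coarser
  than interpolated-vector tracking; on strongly curved, thin bundles it
  needs curvature per voxel step below the angle threshold.
* The mean-curve construction assumes a coherent bundle; it is not a
  substitute for diffeomorphic curve matching on fanning or branching
  tracts.
* The pipeline assumes all subjects are already in one common (atlas)
  space; no registration is performed.
* Single-shell, single-tensor modelling only: no free water
  elimination, no multi-compartment or HARDI models.
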