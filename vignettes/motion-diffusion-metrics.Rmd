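---
title: "Head motion and white-matter diffusion metrics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Head motion and white-matter diffusion metrics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

In-scanner head motion is a pervasive nuisance in diffusion-weighted MRI
(DWI). Even after affine realignment, residual motion biases the scalar
metrics that white-matter studies report — fractional anisotropy (FA),
mean diffusivity (MD), and the model-free local diffusion homogeneity
(LDH). Because motion correlates with age, clinical status and attention,
a motion-driven bias masquerades as a biological effect. This package
implements, as reusable and tested components, the full analysis chain
needed to quantify motion/metric associations: motion scoring from rigid
transforms, tensor and LDH metric computation, a simplified tract-based
spatial statistics (TBSS) skeleton with perpendicular projection, voxelwise
test-retest reliability (ICC), and a permutation GLM with threshold-free
cluster enhancement (TFCE) and family-wise error (FWE) control — together
with a synthetic cohort generator so every stage is testable end to end
without any data download.

## Motion scoring

Each volume of a DWI series carries a volume-to-reference rigid transform
(estimated by registration, or supplied as ground truth by the simulator).
Motion between consecutive volumes is summarised by the RMS deviation of
the difference transform $\Delta = T_i T_{i-1}^{-1}$ over a sphere of
radius $R$:

$$\mathrm{RMS} = \sqrt{\tfrac{1}{5} R^2\,\mathrm{Trace}(A^\top A) + t^\top t},
\qquad A = M_\Delta - I,$$

with $R = 80$ mm by default (approximately the mean cortex-to-head-centre
distance). The $\tfrac{1}{5}R^2$ factor is exactly the average of
$x x^\top$ over a uniform ball of radius $R$, so the formula equals the
root mean squared displacement of brain tissue — a property the test suite
verifies against a Monte-Carlo ball-sampling oracle. Two choices deserve
comment:

* $A$ is the deviation of the linear part from the identity; reading the
  linear part itself as "a rotation matrix" would score identity motion as
  $R\sqrt{3/5} \neq 0$.
* The translation is corrected for the rotation centre,
  $t' = t + A\,c$. Synthetic grids in this package place the world origin
  at the field-of-view centre, so the default $c = (0,0,0)$ is
  simultaneously the literal formula and the sensible geometric choice.
  For off-centre data, pass the FOV centre explicitly.

A subject's per-session motion is the mean RMS over all consecutive-volume
transitions ("relative to the preceding volume"), and the subject-level
summary is the mean across sessions.

Registration (`rigid_register()`) maximises normalised cross-correlation
over a x4/x2/x1 multi-resolution pyramid with Nelder-Mead, starting at the
identity. One implementation detail matters for accuracy: sample points
are fixed on the *moving* image's grid and the *reference* is interpolated
at their transformed positions. The moving image — the one already
carrying the motion (and hence one trilinear interpolation) — is never
re-interpolated, which removes an interpolation-blur bias that otherwise
shrinks rotation estimates by up to a degree. With this scheme, injected
rigid motions of up to 2 mm / 2 degrees on a 32^3 phantom are recovered
with per-transition RMS errors of a few micrometres.

## Diffusion metrics

The tensor is fitted voxelwise by ordinary least squares on the
log-attenuation, $\ln(S_0/S_g) = b\,g^\top D g$, the standard log-linear
fit (no weighting, no nonlinear refinement). Signals are clamped to
$10^{-6} S_0$ before the log; clamped voxels are flagged in a QC mask but
not excluded. FA and MD come from the eigenvalues; negative noisy
eigenvalues are kept for MD, and FA is clipped to $[0, 1]$ so that noise
excursions never propagate NaNs into the skeleton stage.

LDH is Kendall's coefficient of concordance ($W$) of the raw per-direction
apparent diffusion coefficients, $\mathrm{ADC}_g = -\ln(S_g/S_0)/b$,
across a voxel's neighbourhood ($n = 27$ by default; 19 and 7 supported).
Each neighbourhood member ranks the gradient directions by diffusivity and
$W \in [0,1]$ measures their agreement. Numerical conventions: ties get
average ranks with *no* tie-correction factor (ADC data are continuous, so
ties have measure zero — and the independent test oracle implements the
same convention); all-constant neighbourhoods return the sentinel 0 rather
than a fake perfect concordance; boundary voxels use their in-mask
neighbours only, with at least 4 members required. Under row independence
$E[W] = 1/m$, which the tests verify by simulation.

## Skeleton and projection

Cohorts generated by this package live in a common space, so the nonlinear
template registration of full TBSS is out of scope; the skeleton stage
starts from the voxelwise mean FA. Voxels above the FA threshold (0.2)
form the white-matter mask, and the skeleton is the ridge of the smoothed
mean FA: a voxel survives when its value is not exceeded one voxel away
along $\pm$ the across-tract direction (the dominant-curvature eigenvector
of the smoothed-FA Hessian), with at least one strict inequality. Two
guards keep the ridge clean: smoothing is kernel-renormalised at the array
boundary (otherwise the artificial falloff tilts edge directions), and
both comparison points must lie inside the FA mask (otherwise rim voxels
whose perpendicular points out of the white matter survive spuriously).
For a straight 5-voxel slab the result is exactly the one-voxel mid-plane
sheet; at structure ends small oblique sheets can appear, as they do in
FSL skeletons.

Projection fills each skeleton voxel by searching the subject's FA along
$\pm$ the across-tract direction (up to 6 mm, half-voxel steps, offset 0
included) and taking the *metric* value at the FA-maximum location — the
FA-derived location is reused for MD and LDH, mirroring the practice of
applying FA-derived transforms to the other maps.

## Reliability

Test-retest reliability is the consistency intraclass correlation from a
two-way ANOVA with random subjects and fixed sessions:

$$\mathrm{ICC} = \frac{\mathrm{BMS} - \mathrm{EMS}}
{\mathrm{BMS} + (k-1)\,\mathrm{EMS}}.$$

The session mean square (JMS) is computed and reported but never enters
the ICC — session effects are removed, not penalised, which is what makes
this the consistency form. Negative estimates are reported as such
(truncation is opt-in) because truncating biases map means upward. The
implementation is verified against the hand-worked ANOVA of a 3x2 table
and against the variance-component identity
$\mathrm{ICC} = \hat\sigma_b^2 / (\hat\sigma_b^2 + \hat\sigma_e^2)$.

## Inference

The GLM regresses each skeleton voxel on head motion with age, gender and
handedness as nuisance covariates (continuous predictors mean-centred;
binary ones 0/1). TFCE integrates cluster extent$^E$ x height$^H$ over all
thresholds (midpoint rule, step = max/100; volume preset H = 2, E = 0.5
with 26-connectivity, skeleton preset H = 2, E = 1), implemented as an
incremental union-find sweep in C++ and cross-checked against a dense
igraph-based integrator. FWE correction uses the permutation distribution
of the maximum TFCE statistic under the Freedman-Lane scheme (permute
reduced-model residuals, refit the full model); with $n \le 8$ subjects
and enough requested permutations the enumeration is exhaustive and
p-values are exact. Both one-sided contrasts (positive and negative motion
effects) are evaluated and thresholded at corrected $p < 0.05$, since the
report format is a signed association table; no additional two-sidedness
correction is applied, matching common skeleton-analysis practice.

## The synthetic cohort generator

The generator emulates the study design the pipeline targets: 20 subjects,
two sessions about a week apart, 137 diffusion directions at
$b = 1500\ \mathrm{s/mm^2}$ plus one $b=0$ volume, 2 mm isotropic voxels.
The anatomy is a desk-scale phantom — a high-FA slab (FA 0.8, axis x)
crossing an isotropic ellipsoidal brain (FA 0, MD $0.7\times10^{-3}$
mm²/s) on a 24x24x16 grid — chosen because it is skeletonisable, has an
analytic mid-plane, and keeps a full cohort simulation in seconds.

**Motion levels.** Subject mean motion is lognormal with location 1.18 mm.
The between-subject sd (0.243 mm) and within-subject session sd (0.224 mm)
were derived jointly from three constraints on the two-session design: the
session-averaged motion should have sd 0.29 mm, session-level sds should
sit near 0.33 mm, and the analytic motion ICC
$\sigma_b^2/(\sigma_b^2+\sigma_w^2)$ should be about 0.54 — the reliability
regime reported for scan-to-scan motion. These are modelling choices
matched to summary statistics, not observed distributions.

**Couplings.** In the default *parametric* mode, per-subject metric maps
are the base phantom maps plus (i) a motion coupling $\beta_m \cdot
\mathrm{motion}_{ij}$ inside a known effect region (the central half of
the slab), (ii) a per-subject random field with sd $\sigma_b s_m$, and
(iii) a per-session random field with sd $\sigma_e s_m$, where $s_m$ is a
per-metric unit scale (FA 0.02, MD $2\times10^{-5}$ mm²/s, LDH 0.02).
Defaults $\sigma_b = 1$, $\sigma_e = 0.6$ give an analytic voxelwise
metric ICC of $1/1.36 \approx 0.735$, and
$\beta_{\mathrm{MD}} = +1.1\times10^{-4}$ mm²/s per mm,
$\beta_{\mathrm{LDH}} = -0.11$ per mm, $\beta_{\mathrm{FA}} = 0$ encode
the signed association pattern (MD positive, LDH negative, FA null) at
about 1.5 residual SDs per between-subject motion SD — strong enough that
a 20-subject cohort detects it, which is the generator's purpose:
controllable, detectable ground truth. Because couplings are applied to
metric maps *after* metric computation, ground truth for GLM and ICC
recovery is exact.

**Mechanistic mode** instead injects per-volume rigid motion into the DWI
signal itself (independent small absolute poses calibrated to the target
per-transition RMS; trilinear resampling; Rician noise at SNR 50) and
recomputes all metrics. Associations then emerge physically: apparent MD
rises with motion and slab LDH falls — but only beyond an interpolation
floor. Below roughly one voxel of per-transition motion, sub-voxel
resampling *smooths* the data, suppresses noise and slightly raises LDH;
mechanistic comparisons should therefore contrast moderate against high
motion. Mechanistic FA also falls with motion (blur), which is where the
phantom departs from the real-data finding of a null FA association; the
parametric mode encodes the null directly.

**What passing tests do and do not show.** The generator reproduces the
*statistical* structure of a two-session DWI study — seeded, with known
couplings and variance components — but not eddy currents, susceptibility
distortion, slice-wise dropout, cardiac pulsation, or real anatomical
variation, and the common-space assumption removes registration error.
Green tests demonstrate that the estimators and the inference chain are
correct and calibrated on data whose truth is known; they do not certify
effect sizes on real cohorts.

## Numerical choices and degenerate inputs

* Noiseless GLM fits (RSS = 0) produce a capped $t = \pm 10^6$ rather
  than infinities.
* Permutation p-values use $(1 + \#\{\max \ge \mathrm{obs}\})/(1 +
  n_\mathrm{perm})$, never 0; exhaustive enumeration divides by $n!$.
* The TFCE integration uses midpoint thresholds, making the step error
  second order; `dh_frac` defaults to 0.01 of the map maximum.
* ICC with zero denominator (no variance at all) returns 0 by convention.
* Skeleton-map ICCs in the pipeline run *below* the generative 0.735:
  on a flat-FA slab the projection argmax is noise-driven, so projection
  resamples the subject/session noise fields at session-dependent
  locations and adds within-subject variance. This is a real property of
  maximum-FA projection on plateau profiles, not an estimator bias; the
  ICC estimator itself recovers analytic values on direct two-way
  simulations to within 0.05.

## Problem sizes

Default problem sizes were chosen so that a full pipeline run (cohort
simulation, skeletonisation, reliability, three metrics x 500 permutations)
completes in well under a minute on one core: a 24x24x16 grid (~4800 brain
voxels, ~170 skeleton voxels), 137 directions, 20 subjects. The type-I
error calibration in the test suite uses 200 null replicates of a
1000-voxel support at 500 permutations, and registration tests use 32^3
phantoms. All sizes scale up by changing `cohort_spec()` arguments.

## Known limitations

* The perpendicular-line projection is equivalent to FSL's
  distance-map search on slab-like phantoms but can differ on complex
  real anatomy; the exact FSL rule is deliberately not re-implemented.
* Affine (12-DOF) transform files are accepted and run through the same
  RMS formula (shear/scale then contribute to $A$), but no affine
  registration or eddy-current estimation is provided.
* Only single-shell acquisitions with a mono-exponential tensor forward
  model are simulated; no multi-shell or non-Gaussian models.
* The information-theoretic regional-coherence variant of LDH is not
  implemented (it has no published definition to implement).
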