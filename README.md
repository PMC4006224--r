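# motiondiff

Quantifying how in-scanner head motion associates with white-matter
diffusion MRI metrics — and testing that the whole analysis chain is
correct and calibrated before it ever touches real data.

Residual head motion biases the scalar maps that diffusion studies
compare between groups: fractional anisotropy (FA), mean diffusivity
(MD), and the model-free local diffusion homogeneity (LDH, the
Kendall-concordance of raw per-direction diffusivities across a voxel's
neighbourhood). Because motion itself correlates with age and clinical
status, such bias imitates biology. `motiondiff` implements the complete
pipeline needed to measure and control this:

* **Motion scoring** — per-volume rigid registration and the RMS
  deviation of consecutive-volume transforms,
  `RMS = sqrt(R²/5 · Tr(AᵀA) + tᵀt)` with `R = 80` mm, averaged over all
  transitions.
* **Metrics** — log-linear tensor fit (FA, MD), per-direction ADC series,
  and LDH via Kendall's W over 27/19/7-voxel neighbourhoods.
* **Skeleton** — a simplified TBSS stage: mean-FA > 0.2 mask, ridge
  thinning, and perpendicular maximum-FA projection of subject maps.
* **Reliability** — voxelwise consistency ICC,
  `(BMS − EMS) / (BMS + (k−1)·EMS)`, from a two-way ANOVA with random
  subjects and fixed sessions.
* **Inference** — voxelwise GLM of skeletonised metrics on motion with
  age/gender/handedness nuisances, TFCE enhancement (C++ union-find
  sweep) and FWE correction by the permutation distribution of the
  maximum TFCE statistic (Freedman–Lane; exhaustive for ≤ 8 subjects).
* **Synthetic cohorts** — a seeded generator producing 20-subject,
  two-session DWI cohorts (137 directions, b = 1500 s/mm², 2 mm voxels)
  with controllable motion levels and known motion→metric couplings, so
  every stage above is testable against exact ground truth.

It is aimed at methodologists who need a trustworthy, desk-scale testbed
for motion-confound analyses, and at anyone reusing the individual
components (RMS scoring, LDH, TFCE permutation inference, ICC maps).

## Worked example

```r
library(motiondiff)

config <- pipeline_config(
  spec  = cohort_spec(n_subjects = 20, n_sessions = 2, seed = 1),
  n_perm = 500, seed = 1)
res <- run_pipeline(config)
print(res)
```

```
<pipeline_result>
  motion: mean 1.24 mm (sd 0.31), ICC 0.41
  mean ICC: FA 0.64, MD 0.42, LDH 0.45
  motion-brain association:
 analysis metric association n_pos pct_pos n_neg  pct_neg skeleton_voxels
 averaged     FA        n.r.     0  0.0000     0 0.000000             172
 averaged     MD           +   128 74.4186     0 0.000000             172
 averaged    LDH           -     0  0.0000    11 6.395349             172
```

Reading the output: the simulated cohort moved 1.24 ± 0.31 mm per volume
transition on average, with moderate scan-to-scan reliability of the
motion estimate itself (ICC 0.41 at n = 20). Mean test-retest ICCs of the
skeletonised metric maps follow. The association table is the study's
headline result format: after TFCE-corrected permutation testing at
p < 0.05 on the 172-voxel skeleton, MD shows a *positive* motion
association (128 voxels, 74%), LDH a *negative* one (11 voxels, 6%), and
FA none ("n.r.") — exactly the signed pattern the generator's couplings
encode (β_MD > 0, β_LDH < 0, β_FA = 0), recovered through the complete
registration-free analysis chain.

The methods vignette (`vignettes/motion-diffusion-metrics.Rmd`) documents
the models, the generator's variance structure, numerical conventions and
known limitations.

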