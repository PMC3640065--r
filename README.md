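# dtiqa — automated quality assurance for diffusion tensor imaging

Diffusion tensor imaging (DTI) estimates a 3×3 symmetric diffusion tensor
**D** per voxel from J diffusion-weighted volumes and a b0 reference
volume via the Stejskal–Tanner relation
S_j = exp(−b ĝ_jᵀ D ĝ_j). The derived scalars — fractional anisotropy
FA = √(3/2)·‖λ − λ̄‖/‖λ‖ and mean diffusivity MD = λ̄ — are noise- and
artifact-sensitive, and with 30–90 volumes per session manual quality
control does not scale. `dtiqa` is a pipeline for neuroimaging
researchers and QA engineers that turns one DTI session into:

* **tensor fits** by log-linear least squares, with FA/MD/principal
  eigenvector maps and per-voxel squared fitting error;
* **goodness-of-fit surfaces**: the signal-normalized pixel chi-squared
  χ²_pix = Σ_j (S_m,j − S_f,j)²/S_m,j² and its slice adaptation
  χ²_slice(z, j) = (J/K) Σ_k (S_m,jk − S_f,jk)²/S_m,jk², whose
  slices-by-DWI matrix makes corrupted gradients (vertical stripes) and
  corrupted slices (hot cells) visible at a glance;
* a **regional noise estimate** (second-smallest per-region signal SD);
* **wild-bootstrap σ_FA** (residual sign-flip resampling, 1000 reps) and
  **SIMEX FA bias B_FA** (re-corrupt with Rician noise at variance
  multipliers ω = 2, 4, 6, 8, fit an order-2 trend in expected FA,
  extrapolate to the zero-total-noise point ω = −1);
* **bias-aware power curves** for a two-sided two-sample t-test from the
  noncentral t with df = 2n − 2 and noncentrality
  (ES + ΔB)/(s√(2/n)) — bias shifts the curve minimum to ES = −ΔB;
* **regional summaries**, a **112-element QA feature vector**
  (14 pooled regions × 4 metrics × {mean, SD}) and a z-scored **PCA
  cohort embedding** with robust within-protocol outlier flagging;
* a **four-page PDF QA report**.

A synthetic DTI phantom generator (25 labeled regions with ground-truth
tensors, stacked Rician noise, injectable gradient/slice/motion
corruption) makes every metric testable end-to-end with no external data.
See `vignettes/dtiqa-methods.Rmd` for the statistical details and design
choices.

## Worked example

```r
library(dtiqa)

ph  <- generate_phantom(phantom_spec(seed = 42))   # 32^3, J = 32, b = 700
ph$study
#> <dwi_study> 32x32x32 grid, J = 32, b = 700 s/mm^2, 14328 in-mask voxels,
#>   25 regions, motion table present

res <- run_qa_pipeline(ph$study, out_dir = "qa_out", seed = 1,
                       config = qa_config(fast = TRUE))
res
#> <qa_result> 14328 voxels fit, sigma = 24.8, 1279 sampled voxels, total 14.7s

res$metrics$noise
#> <noise_estimate> sigma = 24.76 (region 13, second smallest of 25)
```

The noise estimate 24.76 recovers the phantom's true σ = 25 to 1%. The
uncertainty table holds the Monte-Carlo estimates at the sampled voxels —
here a median σ_FA of 0.020 and median B_FA of 0.002 over 1279 sampled
voxels (every region contributes ≥ 50) — and `qa_out/` now contains the
FA/MD/e1/tensor/squared-error NIfTI maps, the noise, uncertainty, power
and feature-vector CSVs, a JSON manifest, and the four-page
`qa_report.pdf`. The first four feature-vector entries, for instance:

```r
round(res$metrics$feature_vector[1:4], 4)
#> midline_inferior.md.mean   midline_inferior.md.sd
#>                   0.0030                   0.0001
#> midline_inferior.fa.mean   midline_inferior.fa.sd
#>                   0.1215                   0.0348
```

— the inferior midline region is CSF-like in the phantom's truth
(MD 3.0e-3 mm²/s, FA 0.1), and the summary recovers both.

Cohort screening: build one vector per dataset, embed, and flag.

```r
emb <- embed_cohort(do.call(rbind, feature_vectors))
flag_outliers(emb, protocol_labels)   # robust distance > 3.5 = suspect
```

A command-line wrapper for phantom generation, pipeline runs and report
rendering is in `inst/cli/dtiqa.R`
(`Rscript inst/cli/dtiqa.R run --in study_dir/ --out qa_out/ --fast`).

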