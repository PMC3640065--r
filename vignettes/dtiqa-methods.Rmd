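---
title: "Statistical methods behind the dtiqa pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind the dtiqa pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtiqa)
```

# The problem

Diffusion tensor imaging estimates a 3x3 symmetric tensor **D** per voxel
from J diffusion-weighted volumes (DWIs) plus a non-diffusion-weighted b0
volume. The estimation is sensitive to noise, subject motion, and hardware
artifacts, and with 30-90 volumes per session visual quality control does
not scale. `dtiqa` computes a battery of complementary quality metrics --
fitting-error surfaces, a data-driven noise estimate, Monte-Carlo estimates
of the variance and bias of fractional anisotropy (FA), bias-aware power
curves, and regional distribution summaries -- and condenses them into a
graphical report and a per-dataset feature vector suitable for cohort-level
outlier screening.

# Diffusion model and tensor estimation

Normalized signals are $S_j = \mathrm{DWI}_j / b_0$ and follow the
Stejskal--Tanner relation

$$S_j = \exp(-b\, \hat g_j^\top D\, \hat g_j),$$

with b-value $b$ (s/mm^2) and unit gradient directions $\hat g_j$. Taking
logs gives a linear model in the six unique tensor elements, solved by
ordinary (unweighted) least squares. We deliberately use plain log-linear
least squares rather than an iterative robust fit: the downstream
bootstrap and SIMEX stages refit tensors hundreds of thousands of times
and share this single fitting code path, so estimator and uncertainty
machinery agree exactly.

Numerical choices:

* **Positivity clamp.** Signals that are non-positive or non-finite
  (possible under noise) are replaced by half the voxel's smallest
  positive signal before the log. The identical clamp is applied inside
  every bootstrap/SIMEX refit.
* **Eigenvalues.** FA and MD derive from the eigenvalues
  $\lambda_1 \ge \lambda_2 \ge \lambda_3$. MD is their mean, computed on
  the raw (possibly negative) values so it remains unbiased; for FA,
  negative eigenvalues are clamped at zero and the result clamped into
  [0, 1], keeping FA in its defined range under noise. The FA of the
  zero tensor is defined as 0. Monte-Carlo inner loops use a vectorized
  closed-form (trigonometric) eigenvalue solution for symmetric 3x3
  matrices; eigenvectors -- needed only for the principal-direction maps
  -- use `eigen()` per voxel with ties resolved by forcing the
  largest-magnitude component positive.
* **Degenerate designs.** A gradient table that cannot determine six
  tensor elements is rejected with its design condition number.

Fitted tensors are not forced positive-definite; the per-voxel count of
negative eigenvalues is itself a quality signal and is recorded.

# Goodness of fit: pixel and slice chi-squared

With fitted signals $S_{f}$, the pixel chi-squared normalizes squared
residuals by the measured signal rather than its variance:

$$\chi^2_{\mathrm{pix}} = \sum_{j=1}^{J}
  \frac{(S_{m,j} - S_{f,j})^2}{S_{m,j}^2}.$$

This maps both poor fits and high noise to large values, so the histogram
separates a "signal lobe" (clean voxels, near zero) from a "noise lobe"
(noise-dominated voxels). The slice adaptation sums the same normalized
terms over the K in-mask voxels of one axial slice of one DWI and rescales
by $J/K$ to stay comparable across slices of different size:

$$\chi^2_{\mathrm{slice}}(z, j) = \frac{J}{K} \sum_{k=1}^{K}
  \frac{(S_{m,jk} - S_{f,jk})^2}{S_{m,jk}^2}.$$

The slices-by-DWI matrix of these values is the report's central artifact
display: a corrupted gradient shows as a vertical stripe, a corrupted
slice as a single hot cell, and out-of-brain slice rows render as a blank
band. Choices worth noting:

* $S_{m,j}$ is floored at $10^{-6}$ before division, preventing blow-ups
  at signal voids while preserving "high noise implies large chi".
* The display saturates at a fixed 0.2 so reports are comparable; values
  well beyond 0.2 are common for air or severely corrupted voxels and all
  render as saturation.
* The form does not divide by J (it is not a reduced chi-squared); the
  J/K slice factor is the natural rescaling between a J-term and a K-term
  sum under this convention.
* The histogram's "noise-lobe magnification" window is
  [95th percentile, max] of the in-mask values; the signal- and
  noise-lobe modes are computed on the partition below/above that bound.
  On a noiseless fit the window is degenerate and no noise mode is
  reported.

The per-DWI outlier count shown on page 1 is this package's own
residual-threshold definition (a voxel/DWI pair is an outlier when its
un-normalized absolute residual exceeds 3 times the noise SD); it stands
in for the outlier maps a robust-fitting engine would emit and is labeled
as such. Because the unweighted fit spreads part of a severely corrupted
gradient's misfit onto other volumes, counts for clean gradients rise
somewhat too; the corrupted gradient still dominates clearly.

# Noise estimation

The noise SD sigma (image-intensity units) is estimated from the labeled
regions: for each region and each DWI volume, take the SD of the
un-normalized intensities over the region's voxels; take the median over
DWIs, giving one estimate per region. Such estimates mix true noise with
anatomical variability, so small is better -- but to guard against one
artifact-contaminated region, the *second smallest* regional estimate is
chosen. The b0 is excluded (its SNR differs). On homogeneous-region
phantoms this bracket [0.8, 1.5] times the true sigma comfortably; on real
anatomy the upper side is looser because within-region structure inflates
regional SDs.

# Wild bootstrap for sigma_FA

At each sampled voxel the tensor is fit once, residuals
$\varepsilon_j = |S_{m,j} - S_{f,j}|$ retained, and each of 1000 (default)
Monte-Carlo replicates forms $S_{bs} = S_f \pm \varepsilon_{shuffle}$: the
residuals are randomly permuted across gradients and each given an
independent random sign (the random sign is what makes the bootstrap
"wild"; the permutation is retained as part of this pipeline's definition
even though canonical wild bootstrap omits it). Each replicate is clamped,
refit, and its FA recorded; sigma_FA is the SD of the FA population. No
leverage or heteroscedasticity correction is applied to the residuals.

Two properties matter for interpretation. First, log-space OLS residuals
slightly understate the noise (six parameters absorb part of it), so
sigma_FA runs modestly low. Second, the bootstrap resamples *DWI*
residuals only: variance contributed by noise in a single shared b0 is a
common-mode component it cannot see. In validation we therefore emulate
acquisitions whose b0 is averaged over five repeats, as the reference
protocol this pipeline's comparison cohort uses does; under that
convention the bootstrap tracks the repeated-acquisition SD of FA to
within about 15-20% at SNR 10. With a single noisy b0 the gap is larger
(the estimator is unchanged; the acquisition simply contains variance
outside its model).

# SIMEX for FA bias

Magnitude MRI noise is Rician, and fitting log-transformed Rician data
inflates anisotropy: FA is biased upward, most strongly at low SNR and low
true FA. SIMEX (simulation-extrapolation) estimates this bias from a
single dataset by *adding* noise: the un-normalized DWIs and the b0 are
corrupted with additional Rician noise of variance $\omega \hat\sigma^2$
for $\omega = 2, 4, 6, 8$ (2000/4000/6000/8000 Monte-Carlo iterations at
the full settings), the mean refit FA traces the trend of expected FA
against $\omega$, an order-2 polynomial is fit to the trend -- anchored at
the uncorrupted point $\omega = 0$, which is standard SIMEX practice and
stabilizes the quadratic -- and extrapolated to $\omega = -1$, where the
total noise variance $(1 + \omega)\hat\sigma^2$ vanishes. The bias
estimate is measured FA minus extrapolated FA. The polynomial fit is
unweighted across the omega points. If $\hat\sigma = 0$ the estimate is 0
by definition and is flagged.

**Validity domain.** The quadratic extrapolation is a small-noise
approximation. In the regime where FA bias is the few-percent scale seen
in vivo (b0 SNR around 15-20 and above), SIMEX recovers the brute-force
empirical bias essentially exactly (our tests assert agreement at SNR 20
to 0.01). At very low SNR (b0 SNR around 5) the expected-FA trend
saturates toward the noise-floor FA ceiling, the empirical bias grows to
the 0.2 scale, and a quadratic extrapolated from the saturated region
recovers only a small fraction of it -- a structural limitation of
polynomial SIMEX, not a Monte-Carlo artifact (it persists with arbitrarily
many replicates). The acceptance suite records this honestly: the SNR-5
recovery check fails at its stated 0.02 tolerance and is left failing.

# Bias-aware power curves

For two groups of size n with common SD $s$ (the voxel's sigma_FA) and a
between-group bias difference $\Delta B$, the two-sided two-sample t-test
statistic follows a noncentral t with $2n - 2$ degrees of freedom and
noncentrality $(ES + \Delta B) / (s\sqrt{2/n})$, so

$$\mathrm{power}(ES) = 1 - T_{2n-2,\delta}(t_{1-\alpha/2})
  + T_{2n-2,\delta}(-t_{1-\alpha/2}).$$

This formulation satisfies every property the construction demands: with
$\Delta B = 0$ it reduces to the textbook power equation (verified against
a simulated t-test oracle), its minimum sits at $ES = -\Delta B$ where the
power equals the nominal alpha, and it is symmetric about that minimum. A
shifted-central-t approximation was considered and rejected as less exact.
The worst case $\Delta B = B_{FA}$ (comparison group unbiased) and the
unbiased companion $\Delta B = 0$ are both reported, for per-group sizes
n = 5, 15, 30 on a 101-point effect-size grid spanning [-0.1, 0.1] FA
units. Regional curves take the per-effect-size *median* across the
region's sampled voxels, using only voxels with finite positive sigma_FA.

# Subsampling and the 50-voxel rule

Bootstrap and SIMEX are too expensive for every voxel. A uniform random
draw of 4% (default) of in-mask voxels is topped up region-by-region until
every region has at least min(50, region size) sampled voxels, without
replacement, under a mandatory seed. On small grids the 50-per-region
floor dominates and the realized fraction rises toward tens of percent;
on large clinical grids the 4% base dominates.

# The synthetic phantom

The generator builds a brain-like ellipsoid tiled by 25 regions -- 3
midline bands (whose foot-to-head id order doubles as an orientation
marker) and 11 bilateral pairs (quantile sectors of each hemisphere) --
with one ground-truth tensor per region. Defaults emulate a 32-direction,
b = 700 s/mm^2 pediatric-style protocol: region FA spans 0.1-0.9 and MD
(0.6-3.0)e-3 mm^2/s with principal axes sweeping orientation, white
matter-like sectors anisotropic and gray-matter/CSF-like ones isotropic.
Noiseless signals come from the forward model scaled by a b0 intensity of
1000; stacked Rician noise (independent Rician corruption of every DWI
and the b0, default sigma 25, i.e. b0 SNR 40 and DWI SNR roughly 10-15 --
a realistic 3T regime) is applied, then injected corruption: per-gradient
signal dropout, per-slice intensity offsets, and motion-table rows. Left
and right partners share a tensor so bilateral pooling is exact in truth.
Gradient tables are generated by seeded electrostatic repulsion when not
supplied.

What the phantom does *not* emulate: real anatomy and partial-volume
mixtures, EPI/eddy-current geometric distortion, spatially correlated or
multi-coil (non-central chi) noise, cardiac/flow artifacts, and
registration error. Tests passing on the phantom therefore validate the
statistical machinery under its stated noise model, not robustness to
every failure mode of in vivo data.

# Regional summaries, the 112-element vector, and cohort PCA

MD and FA are summarized over all in-mask voxels per region, sigma_FA and
B_FA over the sampled voxels, as Tukey boxplot statistics plus mean and
SD, for the full 25-region set and the bilateral-pooled 14-region set.
"Mean and SD" of each of the 4 metrics in each of the 14 pooled regions
gives the 14 x 4 x 2 = 112-element feature vector, region-major in
alphabetical region order. The 25-to-14 pooling map is configuration (the
phantom ships 11 pairs + 3 midline regions); users with their own label
dictionaries supply their own map.

Cohort exploration z-scores each feature column (NA entries are
mean-imputed and counted; constant columns dropped and recorded) and
extracts principal components by SVD, with signs fixed by making each
loading's largest entry positive so embeddings are fully deterministic.
Datasets cluster by acquisition protocol in PC1-PC2, so *within*-protocol
distance is the quality signal: each dataset's componentwise robust
z-score (median/MAD per component within its protocol group) is combined
in quadrature, and distances above 3.5 are flagged. The threshold is this
package's choice; with 8-member groups the MAD is noisy enough that an
occasional borderline false flag occurs -- flags rank suspects for review
rather than classify. Groups below 4 members are skipped.

# The report

Four pages rendered with base graphics to PDF: (1) acquisition header,
translation/rotation traces, per-DWI residual-outlier counts and the
chi-slice heatmap sharing one horizontally aligned DWI-index abscissa,
the chi-pix histogram with noise-lobe zoom, and best/worst slice
thumbnails per axial fifth; (2) per-region boxplots of MD, FA, sigma_FA,
B_FA with optional reference-cohort boxplots alongside; (3) mid-axial MD
and FA maps, regional-median sigma_FA and B_FA maps (medians obviate
displaying subsampled scatter), power curves, and principal-eigenvector
RGB colormaps in three planes (R = right-left, G = anterior-posterior,
B = foot-head, intensity weighted by FA); (4) eigenvector line-segment
overlays at three magnifications, included as a self-check on gradient
and image orientation handling. Missing optional inputs (motion table,
reference cohort) render as labeled placeholders; rendering is a pure
function of the stored outputs.

# Problem sizes and Monte-Carlo settings

Full settings follow the method definitions: 1000 bootstrap replicates;
SIMEX 2000/4000/6000/8000 iterations at omega = 2, 4, 6, 8. The package's
"fast" configuration (100 bootstrap replicates, 200 per omega) is used
throughout the test-suite and example runs on 24^3-32^3 phantom grids,
sizes at which every stage's Monte-Carlo error is already far below the
effects being asserted. Single-voxel oracle studies use 500-2000
independent re-acquisitions as the brute-force reference.

# Known limitations

* The unweighted log-linear fit is not robust to gross outliers; severely
  corrupted gradients contaminate the fit (visible in the outlier-count
  panel) where a robust engine would reject them.
* sigma_FA excludes single-b0 common-mode variance (see above).
* SIMEX underestimates bias outside its small-noise domain (see above).
* Registration, eddy-current correction, brain extraction and anatomical
  segmentation are out of scope: masks, label volumes and (pre-rotated)
  gradient tables are inputs, and stored volumes are the inputs as-is.
* Single-shell tensor data only; multi-b-value or non-tensor models are
  rejected rather than approximated.
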