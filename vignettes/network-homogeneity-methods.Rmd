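---
title: "Resting-state fALFF and network homogeneity: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state fALFF and network homogeneity: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restnh)
```

# The analysis

`restnh` implements a complete region- and network-level resting-state
fMRI analysis within a labeled network mask, of the kind used to compare
a patient group against matched controls:

1. **Temporal preprocessing** of each subject's spatially normalized 4D
   BOLD series: discarding initial volumes, Gaussian smoothing,
   nuisance regression, ideal band-pass filtering, and
   framewise-displacement (FD) scrubbing.
2. **Per-subject feature maps**: fractional amplitude of low-frequency
   fluctuations (fALFF) and network homogeneity (NH), z-standardized
   within the mask.
3. **Voxelwise group inference** with a linear model (group + age + sex
   + mean FD), Gaussian-random-field (GRF) cluster-level correction, and
   extraction of significant clusters.
4. **Clinical correlations** between cluster means and symptom scores
   (Pearson, Bonferroni-corrected).
5. **Classification**: leave-one-out SVM over single clusters and
   cluster pairs with a `(C, gamma)` grid search.

Because resting-state patient cohorts are rarely shareable, the package
also contains a first-class synthetic-cohort generator that implants
*known* effects, so that every downstream stage can be validated by
recovery experiments rather than by eyeballing.

# The two statistics

**fALFF.** For a voxel series $x_t$ with repetition time $TR$ and $N$
volumes, let $a_k = |\mathrm{DFT}(x)_k|$ be the amplitude spectrum at
frequencies $f_k = k/(N \cdot TR)$, $k = 1, \dots, \lfloor N/2 \rfloor$.
Then

$$\mathrm{fALFF} =
  \frac{\sum_{0.01 \le f_k \le 0.08} a_k}{\sum_{k \ge 1} a_k} \in [0, 1].$$

The DC term ($k = 0$) is excluded from both sums; including it would
make the ratio depend on the signal offset, which the detrending step
has removed anyway. "The whole frequency range" is interpreted as the
full positive DFT grid up to Nyquist. fALFF is computed on the branch of
the preprocessing chain that is *not* band-pass filtered — after an ideal
0.01–0.08 Hz filter the denominator would equal the numerator and the
ratio would be meaningless.

**NH.** For voxel $v$ inside the mask of $V$ voxels,

$$\mathrm{NH}(v) = \frac{1}{V - 1} \sum_{u \ne v} r(x_v, x_u),$$

the mean Pearson correlation with all *other* mask voxels
(self-correlation excluded; including it would shift the statistic by
$(1 - \mathrm{NH})/V$). It is computed by chunked standardized matrix
products whose result is numerically identical to the pairwise loop
(asserted in the tests at $10^{-10}$). NH maps receive one extra 4 mm
mask-renormalized smoothing pass (`nh_smooth_passes = 2` reproduces a
literal double pass; by the Gaussian semigroup property two passes at
FWHM $f$ equal one at $f\sqrt 2$).

# Preprocessing choices

Defaults: discard 10 volumes, 8 mm FWHM smoothing, Friston-24 motion
expansion + WM + CSF nuisance regression with intercept and linear
trend, ideal (hard DFT) band-pass at 0.01–0.08 Hz, Power-FD scrubbing at
0.2 mm with a 50 mm rotation sphere. Notable decisions:

* **Ideal filter.** A hard frequency-domain mask rather than an IIR
  design: it is linear, exactly idempotent, and makes Parseval-based
  tests exact.
* **Scrub modes.** `delete` (default) removes high-motion volumes after
  filtering; `censor` instead absorbs them with per-volume spike
  regressors during the nuisance regression. Deletion is also applied to
  the fALFF branch by default; the spectral estimate then treats the
  series as evenly sampled, a caveat shared by every scrubbing pipeline
  that feeds a DFT.
* **Zero columns** in the nuisance design (e.g. zero motion) are
  dropped, so degenerate inputs reduce to detrending; an error is
  reserved for genuinely collinear regressors and names them.
* **Mask-renormalized smoothing.** When the pipeline knows the analysis
  mask, smoothing is renormalized within it
  (`smooth(data*mask)/smooth(mask)`), so no signal is exchanged with
  out-of-network tissue. On the desk-scale masks used for validation
  every region voxel is near the boundary, and unrestricted smoothing
  would dilute group effects with background noise in a group-dependent
  way; on whole-brain grids the choice is nearly immaterial. Volumetric
  smoothing without a mask remains available.
* **NH on the unsmoothed series.** Series-level smoothing mechanically
  induces correlations between neighboring voxels; the homogeneity
  statistic then saturates, and on small masks the induced component
  swamps genuine coupling differences (in our validation cohorts an
  implanted raw-NH group gap of $+0.056$ survived as $+0.004$ after 8 mm
  series smoothing). NH is therefore computed on the unsmoothed
  residual series by default, with the NH map's own 4 mm smoothing
  supplying spatial regularization; `nh_smooth_series = TRUE` restores
  the literal order with smoothing first. fALFF keeps the 8 mm series
  smoothing.
* **Regression/smoothing order.** Both are linear operators acting on
  different array dimensions, so they commute exactly; the
  `smooth_before_regression` flag therefore changes nothing numerically
  and exists for symmetry with conventional pipeline descriptions. This
  commutation also underlies the mask-space fast path
  (`subject_feature_maps(fast = TRUE)`), which is asserted equal to the
  volumetric chain at $10^{-10}$.

# Group inference

The voxelwise model is ordinary least squares of the standardized
feature value on an intercept, a patient indicator, and covariates (age,
sex, mean FD by default); the reported map is the $t$ statistic of the
group coefficient with $df = n - p$. With no covariates this reduces
exactly to the pooled two-sample $t$ (asserted at $10^{-8}$).

**Smoothness** is estimated from the model residuals: each residual map
is scaled to unit within-mask variance, and the variance of adjacent
in-mask voxel differences per axis gives
$\lambda_i \approx \mathrm{Var}(\partial r / \partial x_i)$, from which
$\mathrm{FWHM}_i = \sqrt{4 \ln 2 / \lambda_i}$.

**GRF cluster correction.** The voxel threshold is
$z = \Phi^{-1}(1 - p_{voxel}/2)$ per tail (two-tailed by default). The
expected number of suprathreshold clusters uses the full expected-Euler-
characteristic sum $E[m] = \sum_{d=0}^{3} R_d \, \rho_d(z)$ over Worsley
lattice resel counts $R_0..R_3$ of the mask — the lower-dimensional
terms matter because validation masks are small relative to the
smoothness; the 3D-only approximation would be anticonservative there.
The cluster-size tail uses $P(n \ge k) = \exp(-\beta k^{2/3})$ with
$\beta = (\Gamma(5/2)/E[n])^{2/3}$ and $E[n] = S \, p_{tail} / E[m]$,
and the familywise probability of any cluster of size $\ge k$ is
$1 - \exp(-2 E[m] P(n \ge k))$; `k_min` is the smallest $k$ pushing this
below `cluster_p`. A group-label permutation alternative
(`permutation_cluster_extent`, max-cluster-size null) serves as the
empirical cross-check; the two agree within the tolerance a mixed
analytic/empirical comparison permits, and the analytic threshold's
familywise error is calibrated directly on matched null simulations in
the acceptance suite.

Cluster peaks are the extreme $t$ within each connected component
(18-connectivity by default; 6 and 26 available), ties broken by lowest
linear voxel index, and peak coordinates come only from the NIfTI affine
applied to 0-based voxel indices.

**Correlations.** Pearson $r$ between patients' cluster means and
clinical scores, with $p$ from $t = r\sqrt{n-2}/\sqrt{1-r^2}$ and
Bonferroni correction over clusters × scores by default. Missing scores
are dropped pairwise, never imputed. Both uncorrected and corrected
values are always reported side by side: published "Bonferroni
corrected" claims are often irreconcilable with any family size larger
than one, and silently relabeling results would hide that.

# Classification

Patients are the positive class (sensitivity = patient detection). Two
cross-validation modes exist:

* `paper_loocv` (default): the `(C, gamma)` grid point maximizing the
  whole-set LOOCV accuracy is selected and reported — the literal
  single-loop procedure commonly reported with LIBSVM. Its accuracy is
  *optimistically biased* because the selection has seen every fold; the
  report says so.
* `nested_loocv`: an inner LOOCV per outer fold selects the parameters —
  unbiased, slower. The test suite asserts that the single-loop estimate
  dominates the nested one on average, documenting the optimism rather
  than hiding it.

Feature scaling is fit on training folds only; a leakage test asserts
that an outlier in the held-out subject cannot move the scaler.
`combination_search` evaluates all $K$ singles and $K(K-1)/2$ pairs
(6 runs for $K = 3$), ranking by accuracy with ties broken by higher
sensitivity, then fewer features.

# The synthetic cohort generator

Each voxel's series is

$$x_v(t) = \sqrt{1 - s_v}\, U_v(t) + \sqrt{s_v}\, C_{r(v)}(t) + 100,$$

where the voxel-unique part $U_v$ and the region-common part $C_r$ are
both built as $\sigma_n \cdot \mathrm{AR1} + g \cdot \sigma_l \cdot
\mathrm{bandlimited}(0.01\text{–}0.08\,\mathrm{Hz})$ with identical
spectral mix. Consequently:

* the shared fraction $s$ equals the expected pairwise correlation
  within a region *without* changing the voxel spectrum — the NH effect;
* the amplitude multiplier $g$ (applied to patients in the fALFF effect
  region) changes the in-band spectrum *without* changing correlations —
  the fALFF effect.

The two implanted effects are orthogonal by construction, so recovery
tests can attribute findings unambiguously. The noise component is
stationary with an AR(1)-shaped power spectrum (coefficient 0.3 —
realistic temporal autocorrelation that does not dominate the band of
interest), synthesized in the frequency domain; the realized power
inside and outside the band is rescaled per subject to the spectrum's
theoretical split, so implanted variance fractions are realized exactly
rather than only in expectation (a variance-reduction device for
recovery experiments). For the same reason each voxel's unique signal is
in-band-orthogonalized against its region-common signal: the realized
voxel-common covariance is zeroed (and the in-band power restored), so
the implanted shared fraction is the exact in-band correlation rather
than a noisy estimate of it. Effects are implanted on variance
components, not added means, because fALFF and NH are both
mean-invariant.

Default study conditions: 40 patients vs 38 controls, TR 2 s, 240
volumes (230 retained after discarding), 3 mm isotropic voxels on a
16×16×12 grid, and a six-region mask of radius-2 spheres (33 voxels
each) named for the fronto-limbic regions they stand in for. Three
regions carry effects — amplitude ratio 1.5 in `r_ofc`, shared fraction
0.45 vs 0.25 in `l_ofc` (NH up), 0.05 vs 0.25 in `r_putamen` (NH down) —
and three are null, so that within-mask z-standardization is not
dominated by the effect regions themselves. The shared-fraction levels
place the ±0.2 group gaps symmetrically inside $[0,1]$ so the
per-subject clinical perturbation cannot clip. Patients' Y-BOCS totals
and the per-subject perturbation of the `r_putamen` shared fraction are
drawn from one latent effect, mapped linearly into both, so their
correlation targets $-|\rho|$ (default $-0.35$) — simpler than joint
distribution fitting and sufficient for recovery tests. Clinical score
means and spreads emulate a medication-free OCD cohort (total
$24.9 \pm 5.7$ with the $\ge 16$ inclusion floor, controls near zero).
Motion is a per-axis random walk (0.01 mm translation scale, rotations
1/100 of that in radians), giving mean FD near 0.03–0.04 mm.

**What the generator does not emulate:** hemodynamic response
convolution, physiological (cardiac/respiratory) noise, scanner drift
beyond a linear trend, spatial anatomy, or motion-correlated artifacts.
Passing recovery tests therefore demonstrates the *pipeline's*
correctness and calibration under a known truth, not robustness to every
artifact of real data.

# Validation strategy and problem sizes

Every core computation has an independent oracle test: fALFF against an
explicit two-loop DFT, NH against a nested-loop mean correlation, FD and
regression against longhand formulas, cluster labeling against
flood-fill, summary-statistic tests against their raw-data equivalents.
Published summary statistics that are arithmetically reproducible (a
demographics table from printed means/SDs/counts; a two-tailed $p$ from
a printed $r$ and $n$) are asserted at printed precision.

The stochastic validation experiments run at desk scale, chosen to keep
the full suite in tens of minutes on one core: effect localization on 50
cohorts of 78 subjects at the default conditions; familywise-error
calibration on 500 matched null simulations (bound $1.6\times$ nominal,
acknowledging the documented slack of the closed-form cluster-size
tail); classification-pair recovery on 30 cohorts with a 3×3
`(C, gamma)` grid spanning the conventional range at coarser steps; and
20 null-configuration end-to-end runs that must come back empty. The
mask-space fast path makes these loops affordable; its exact equality
with the volumetric chain is itself a test.

# Known limitations

* The GRF cluster-size tail is an asymptotic approximation; on masks of
  a few hundred voxels it is kept honest by the expected-EC correction
  and the empirical calibration bound, but exact control should not be
  assumed — the permutation mode exists for when it matters. NH maps in
  particular carry region-coherent estimation noise (every voxel's NH
  shares correlation estimates with its neighbors' NH), a long-range
  dependence the gradient-based smoothness estimator cannot see; at
  desk scale this gives the null cluster-size distribution a heavier
  tail than the Gaussian-field prediction. On our null-configuration
  runs the measured per-map familywise rate is statistically compatible
  with the analytic target but not reliably below it, and an analysis
  that must guarantee an empty table under the null at better than
  nominal rates should use `correction = "permutation"`.
* FD is the Power formulation; other conventions (Jenkinson) are out of
  scope, as are slice-timing, realignment, and spatial normalization —
  inputs are assumed already on a common grid.
* The `paper_loocv` accuracy is a replication of a biased procedure and
  must not be quoted as an unbiased performance estimate; use
  `nested_loocv` for that.
* Scrubbing by deletion distorts the spectral estimate when many
  volumes are removed; subjects retaining under half their volumes are
  flagged for exclusion rather than silently analyzed.
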