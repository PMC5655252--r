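---
title: "Coordinate-based meta-analysis of gray-matter differences with sdmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate-based meta-analysis of gray-matter differences with sdmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmeta)
```

## The problem

Voxel-based morphometry (VBM) compares gray-matter volume between a
patient group and controls at every voxel of the brain. Individual VBM
studies of the same disorder often disagree: samples are small, scanners,
smoothing kernels and statistical thresholds differ, and only the peaks
that survive each study's own threshold are published. Coordinate-based
meta-analysis (CBMA) pools such studies using only what they publish —
peak coordinates and test statistics — to ask which regions show
*consistent* group differences.

`sdmeta` implements the effect-size flavour of CBMA: instead of counting
peak co-occurrence (as activation-likelihood methods do), it reconstructs
a signed effect-size map per study and applies standard random-effects
meta-analytic statistics at every voxel. The packaged study table
describes 18 VBM studies of progressive supranuclear palsy (PSP; 284
patients, 367 controls), the cohort on which the workflow's availability
rules and demographic comparisons are exercised.

## The model

### Per-study reconstruction

For a study comparing $n_1$ patients with $n_2$ controls, a reported peak
$t$ statistic is converted to a Hedges-$g$ standardized mean difference

$$g = t\,\sqrt{1/n_1 + 1/n_2}\;J,\qquad J = 1 - \frac{3}{4(n_1+n_2-2)-1},$$

with sampling variance

$$v = \frac{n_1+n_2}{n_1 n_2} + \frac{g^2}{2(n_1+n_2)}.$$

Reported Z statistics are mapped through their two-tailed p value to the
equivalent t quantile at $n_1+n_2-2$ df. Peaks published without any
statistic receive the *lower-bound* effect size implied by the study's own
voxel threshold (the t quantile at its threshold p), signed by the
reported direction and flagged as imputed. Talairach peaks are brought
into MNI space with the inverse of the Lancaster `icbm2tal` affine (SPM
flavour), a deterministic, invertible choice recorded in the conversion
code.

Around its peaks, the study's map is rebuilt with an un-normalised
Gaussian proximity kernel

$$w(d) = \exp\!\left(-\frac{4\ln 2\; d^2}{\mathrm{FWHM}^2}\right),$$

FWHM 20 mm by default, truncated to exactly zero beyond 30 mm (the weight
there is below 0.002). The kernel does not smooth an image — its value at
the peak is 1 — it grades how confidently a nearby voxel can be assumed to
share the peak's effect. Where several peaks reach a voxel the
kernel-weighted *mean* of their effects is used; being a convex
combination it can never exceed the largest contributing magnitude. Voxels
outside every kernel are zero, and the variance map applies the variance
formula to the reconstructed value, with the floor $v(0, n_1, n_2)$ at
zero voxels so that pooling weights exist everywhere.

### Voxel-wise pooling

At each in-mask voxel the study effects $g_i$ with variances $v_i$ are
pooled under a DerSimonian–Laird random-effects model:
$\hat\tau^2 = \max\{0, (Q - (k-1))/C\}$ from fixed-effect weights
$w_i = 1/v_i$, then $w_i^* = 1/(v_i + \hat\tau^2)$, pooled mean
$\sum w_i^* g_i / \sum w_i^*$, SE $(\sum w_i^*)^{-1/2}$, and a standard
normal Z and two-tailed p. Sample size, within-study variability and
between-study heterogeneity all enter through the weights. Cochran's $Q$
with $k-1$ df gives the heterogeneity map; meta-regression replaces the
pooled mean by a weighted least-squares fit of $g_i$ on an intercept and
one study-level covariate with the same random-effects weights.

### Inference

Voxels with $p < 0.005$ and nonzero Z form 26-connected components;
components with peak $|Z| < 1$ or fewer than 10 voxels are discarded, and
reductions and increases are processed separately. These defaults follow
the method literature's recommendation as balancing false positives and
negatives for this class of estimator; they are *uncorrected* thresholds,
so isolated false-positive clusters are possible and the robustness
analyses matter:

* **Jackknife**: the pooled analysis is repeated leaving out one study at
  a time; a main cluster "replicates" in a repeat when a same-sign
  suprathreshold cluster shares at least one voxel with it. Overlap is our
  operationalisation — published jackknife tables report only yes/no.
* **Egger tests**: at each cluster peak, the per-study $g_i/s_i$ is
  regressed on $1/s_i$; a nonzero intercept (two-tailed t, $k-2$ df)
  flags funnel-plot asymmetry, i.e. small-study/publication bias.
* **Meta-regression availability rule**: a covariate analyzed must be
  non-missing in at least 10 studies; on the packaged PSP table this
  admits age, UPDRS-III, MMSE, illness duration, male ratio and field
  strength, and excludes H&Y stage (7/18) and FAB (6/18). Regression maps
  are thresholded more conservatively (p < 0.0005, extent > 10).

### Cohort-level comparisons

Group comparability is summarized study-wise: the age difference as a
Hedges-g SMD, and the sex composition as the relative risk of being male
(patients over controls, delta-method variance on the log scale, 0.5
continuity correction for zero cells), both pooled by DerSimonian–Laird.
On the packaged table, 15 studies have complete age summaries (SMD 0.19,
95% CI −0.07 to 0.44) and 17 report male counts (RR 1.05, 95% CI 0.91 to
1.21); the orientation (male, patients vs controls) is ours, as the
source tables of such meta-analyses rarely state one.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| kernel FWHM | 20 mm | proximity scale of reconstruction |
| truncation radius | 30 mm | hard kernel cutoff (weight < 0.002) |
| voxel p | 0.005 | cluster-forming threshold of pooled Z |
| peak \|Z\| | 1 | minimum cluster peak height |
| extent | 10 voxels | minimum cluster size |
| meta-regression p / extent | 0.0005 / > 10 | conservative regression threshold |
| covariate minimum | 10 studies | availability rule |
| Egger alpha | 0.05 | asymmetry significance |
| grid | 2 mm isotropic MNI | analysis space |

The default analysis mask is a coarse gray-matter ellipsoid (centre
(0, −18, 8) mm, semi-axes 70/85/75 mm) — an explicitly synthetic geometric
proxy, replaceable by any NIfTI mask via `read_mask_nifti()`.

## The synthetic-data generator

`truth_spec()`/`simulate_dataset()` emulate the *reporting process* CBMA
inverts: each synthetic study draws group sizes (default 10–24 per group,
matching the PSP study pool), builds a true effect field (signed spheres,
default one 10 mm-radius reduction of magnitude 0.8, plus optional
between-study heterogeneity and covariate links), adds independent
Gaussian voxel noise with the sampling variance the effect-size model
implies, thresholds its own t field at a per-study p (default 0.001), and
publishes the surviving local maxima as peaks.

Two deliberate simplifications matter for interpreting green tests:

* **Independent voxel noise.** Real VBM statistics are spatially smooth;
  the generator's noise is white. Simulated studies therefore report more,
  smaller, spikier false peaks than real ones, which is conservative for
  cluster-level inference but unrealistic for peak counts.
* **Winner's curse is real and reproduced.** Because studies publish
  thresholded local maxima, reported peak effects overstate true effects.
  The pipeline inherits this bias: with the default generator the pooled
  peak value for a planted 0.8 magnitude is around 1.2–1.3. Recovery of
  *location* is excellent (the significant cluster overlaps the planted
  sphere in every seeded run we compute), but the pooled peak *amplitude*
  approaches truth only in the high-SNR limit (large samples), which a
  dedicated test demonstrates. Users should read pooled effect magnitudes
  as upper bounds, exactly as with the published tools.
* **Peak-location precision is plateau-limited.** A planted sphere has a
  flat interior, so the pooled argmax jitters across it; at a 10 mm
  radius about nine in ten seeded runs put the peak within 6 mm of the
  centre, and all runs put it inside the sphere. Sharper planted profiles
  would localize more tightly; the flat sphere is kept because it makes
  the ground truth unambiguous.

A t-quantile threshold applied to asymptotically normal effect noise also
makes the null suprathreshold fraction $2\Phi(-J t_{\mathrm{crit}})$,
slightly below the nominal p — the calibration test asserts that analytic
value rather than the nominal one.

## Numerical and design choices

* 26-connectivity (the most inclusive neighbourhood) for clusters; peak =
  maximum |Z|, ties broken by smallest linear array index.
* Analytic standard-normal p values on pooled Z by default — deterministic
  and reproducible; a randomization null would add little at the scales
  the tests exercise.
* Missing covariates: listwise deletion per covariate, never imputation;
  study metadata missing in the source table stays missing.
* Degenerate inputs: pooling needs at least 2 studies, meta-regression at
  least 3 with a non-constant covariate, Egger at least 3 usable studies
  (fewer is flagged not-computable rather than an error); identical
  studies give an Egger intercept of 0 by convention (a single funnel
  point carries no asymmetry information).
* Peaks outside the mask are snapped to the nearest in-mask voxel with a
  warning — dropping them silently would bias reconstruction near the
  mask edge.
* Problem sizes in the test-suite simulations (a 2 mm, 34 mm-radius
  spherical mask; 100 seeded repetitions for recovery rates; 500 scalar
  repetitions for slope and Egger calibration) were chosen as the smallest
  scales at which the Monte-Carlo error is comfortably below the asserted
  tolerances.

## Limitations

Beyond the generator simplifications above: the package analyses
coordinates, never raw images; anatomical labelling of clusters is out of
scope (coordinates only); the exact reconstruction and capping rules of
the original seed-based mapping software are not published in full, so the
rules here are declared substitutes, not claims about that software; and
no multiple-comparison correction beyond the extent rule is provided,
mirroring the published defaults.
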