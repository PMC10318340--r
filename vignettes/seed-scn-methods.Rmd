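---
title: "Seed-based structural covariance networks of hippocampal subdivisions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based structural covariance networks of hippocampal subdivisions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscn)
```

## The model

Structural covariance network (SCN) analysis treats the correlation of
regional gray-matter volume (GMV) across subjects as a proxy for
anatomical connectivity. `seedscn` implements the seed-based variant:
the per-subject mean modulated GMV of a seed region, $V_{\mathrm{seed}}$,
enters a voxel-wise ordinary-least-squares model of every gray-matter
voxel $i$,

$$Y_i = \beta_0 + \beta_1 V_{\mathrm{seed}} + \beta_2\,\mathrm{Age} +
\beta_3\,\mathrm{Sex} + \beta_4\,\mathrm{Edu} + \beta_5\,\mathrm{BDI} +
\beta_6\,\mathrm{ISI} + \beta_7\,\mathrm{TIV} + \varepsilon_i ,$$

fitted separately within each study group (HC, SCD, MIG). The t map of
$\beta_1$ is the group's seed-covariance network. Between-group
differences in covariance strength are tested with a two-group
interaction model that adds a 0/1 group indicator and the product
$V_{\mathrm{seed}} \times \mathrm{Group}$; the interaction coefficient
is the difference in seed-covariance slope between groups, and its t
map is thresholded for inference.

Seeds are built by cutting a hippocampus atlas label along the long
(posterior–anterior, world-y) axis: voxels whose centre falls in
$[-18, -2]$ mm form the anterior subdivision and $[-42, -24]$ mm the
posterior one, left and right merged into one bilateral seed each.
Both interval endpoints are inclusive and membership is decided by the
voxel-centre coordinate; the gap $(-24, -18)$ belongs to neither. The
atlas itself does not state an endpoint rule for resampled voxels, so
the inclusive voxel-centre convention is this package's documented
choice (`long_axis_split()` exposes the intervals as arguments).

### Design coding

The printed interaction model does not determine a coding, so the
package uses: group coded 0/1 (second listed group = case = 1), sex
coded 0/1, $V_{\mathrm{seed}}$ mean-centred before forming the product
term, no other standardisation. With this coding the interaction
coefficient is the case-minus-reference slope difference and a
covariance *drop* in the case group drives it negative; the test suite
verifies that the interaction t value is invariant to affine recodings
of either factor, so this choice affects interpretation only, not
inference.

## Cluster-extent family-wise-error correction

Voxel-wise maps are thresholded one-sided at voxel-level
$p < 0.005$ separately for each direction (increase/decrease), and
suprathreshold components (26-connectivity by default; 6 and 18 are
available) are retained only when they reach a critical extent
$k_{\min}$. $k_{\min}$ is the smallest extent whose exceedance
probability, under a Monte-Carlo null distribution of maximum cluster
sizes, is at most $\alpha = 0.05$. The null simulates white Gaussian
noise, smooths it to the residual smoothness estimated from the fitted
model, standardises within the analysis mask, and records the largest
suprathreshold component per simulation (10,000 simulations by
default; experiments in this package use 2,000, stated with each
result).

Two numerical choices matter here:

* **Stationarity of the null field.** The simulated noise is generated
  on a grid padded by the kernel radius and cropped back, so the null
  field is stationary with exactly the stated kernel FWHM. Smoothing on
  the analysis grid directly (with any boundary rule) yields fields
  smoother than stated near edges and hence an inflated $k_{\min}$.
* **Two one-sided directions.** Thresholding each direction at
  voxel $p$ and cluster $\alpha$ mirrors the separate
  "reference > case" and "reference < case" cluster tables; it is not a
  Bonferroni-split two-sided test, so the familywise rate over both
  directions can reach $2\alpha$ in principle. In calibration runs the
  realised rate stays near $\alpha$ because the residual-smoothness
  estimate is conservative for fields with parcel-coherent structure
  (see below) and the empirical critical extent is discrete.

Residual smoothness is estimated with the classical Gaussian-field
first-difference estimator: residual maps are standardised within the
mask, and the lag-one autocorrelation along axis $d$ is recovered from
the variance of first differences, giving
$\mathrm{FWHM}_d = v_d \sqrt{-2\ln 2 / \ln(1 - \mathrm{var}(\Delta_d)/2)}$
with voxel size $v_d$, pooled over residual maps; the geometric mean
feeds the null simulation. This is a deliberate, documented deviation
from AFNI's mixed autocorrelation-function model, which is not
reproducible from its description alone; `estimate_smoothness()` is the
single hook to replace if another estimator is wanted. The estimator
recovers an applied 6 mm kernel on a 3 mm grid to within a few percent
and reports white noise as far below one voxel.

Conjunction maps are plain voxel-wise intersections of the
FWE-corrected significant masks of the two case-control contrasts,
taken separately for shared decreases and shared increases.

## Spin permutation spatial similarity

Spatial similarity of two unthresholded t maps is the Pearson
correlation over vertices of a spherical projection. Significance uses
a spin permutation null that preserves spatial autocorrelation: each
permutation draws a rotation uniform over SO(3) (normalised Gaussian
quaternions), rotates one map's vertex coordinates, reassigns values to
the nearest original vertex by great-circle distance (ties to the
lowest index), and recomputes the correlation over pairwise-valid
vertices. The two-sided p value uses $|r|$ with the add-one convention
$p = (1 + \#\{|r_{\mathrm{null}}| \ge |r_{\mathrm{obs}}|\}) / (1 +
n_{\mathrm{perm}})$, so $p$ is never exactly zero. The sidedness is the
package's choice (unstated in the standard description); the add-one
convention is the usual permutation-test safeguard.

The volume-to-sphere step is an explicit input — a vertex-to-voxel
lookup table — rather than a computed surface projection:
`volume_sphere_lookup()` provides a deliberately simple nearest-voxel
stand-in for synthetic studies, and real cortical-surface lookups can
be supplied in its place. The provided vertex set is treated as a
single sphere; mirrored bilateral handling is out of scope.

## Per-subject integrity (deconstructed Pearson correlation)

Group-level covariance between a seed and a cluster is a single
correlation $r$ over the group's subjects; to attach a value to each
subject, $r$ is decomposed through standard scores:

$$r = \frac{1}{N-1} \sum_{i=1}^{N} z_{X_i} z_{Y_i}, \qquad
\mathrm{partial\_p}_i = z_{X_i} z_{Y_i},$$

with $z$ scores using the group mean and sample (N−1) standard
deviation. The identity $\sum_i \mathrm{partial\_p}_i = (N-1)r$ holds
exactly and is asserted to $10^{-10}$ over a thousand random pairs.
`partial_p` is invariant to affine rescaling of either regional
measure. Clinical associations use partial Pearson correlations of
`partial_p` with symptom variables, residualising both on age, sex,
education, BDI, ISI and TIV and testing with $t = r\sqrt{(n-2-q)/(1-r^2)}$
on $n-2-q$ degrees of freedom ($q$ covariates) — the standard
residualise-both estimator, since the analysis is named but not
specified formula-by-formula. These correlations are exploratory and
uncorrected, and the report labels them so. Subject exclusion by
extreme values of a clinical variable is a configurable trim rule
(`trim_exclusions()`, default 3 lowest / 4 highest on SCD duration):
only the counts of such exclusions are conventionally reported, never a
numeric threshold, so the rule itself must remain explicit
configuration.

## The synthetic cohort generator

`generate_cohort()` draws, per subject $i$ in group $g$, a latent
standard-normal factor $L_i$. Seed-parcel voxels receive
$\mathrm{base} + a L_i$; each target parcel receives
$\mathrm{base} + a(\rho_g L_i + \sqrt{1-\rho_g^2}\, U_i)$ with an
independent latent $U_i$, so the planted seed–target correlation in
group $g$ is exactly $\rho_g$. Linear covariate effects (centred age,
sex, TIV) and voxel-wise Gaussian noise are added before convolution
with a normalised Gaussian kernel using half-sample-symmetric
(reflective) boundaries, which conserves each subject's total GM mass
to machine precision on small grids.

Defaults define the emulated study conditions: group sizes 37/38/48
(HC/SCD/MIG); age $\sim N(43, 11)$ truncated to 20–65; 65% female; TIV
$\sim N(1.43, 0.15)$ litres; education $\sim N(15, 3)$; BDI and ISI
group-specific clipped normals matching the cohort's reported means and
spreads; GM base 0.5 with latent loading $a = 0.1$ and noise SD 0.05 —
a signal-to-noise ratio at which parcel means are nearly noiseless
after smoothing, as real parcel-mean GMV is; smoothing FWHM 6 mm on a
30×36×30 grid of 3 mm voxels. The desk-scale grid (not a 1.5 mm
full-brain grid) keeps whole simulation studies at minutes scale and is
fully configurable. Planting covariance at parcel level (then
smoothing) rather than as voxel-level covariance fields gives an exact
ground-truth region for detection and localisation checks.

What the generator does **not** emulate: anatomy, tissue boundaries,
registration error, scanner artifacts, non-Gaussian intensity
distributions, or spatially varying covariance. Passing calibration and
power checks on this generator therefore demonstrates correctness of
the statistical machinery under its stated assumptions, not performance
on real MRI cohorts.

One consequence of parcel-level planting deserves emphasis: all voxels
of a target parcel share the subject-level latents, so the realised
interaction t values rise and fall together across a parcel.
Replicate-level detection power for a planted drop is then bounded by
the power of a *single* slope-difference test. For $\rho = 0.6$ vs
$0.0$ at 40 subjects per group and voxel $p < 0.005$ this bound is
$\approx 0.61$ (noncentral t, ncp $\approx 2.9$, 70–76 df), and the
pipeline's measured detection rate (~0.6) sits at the bound —
cluster-extent correction cannot manufacture power beyond it. Larger
detection rates require larger samples, stronger drops, or voxel-level
(not parcel-level) covariance planting.

## Problem sizes and determinism

Every stochastic stage takes an explicit integer seed, and identical
configuration plus seed reproduces reports bit-identically (asserted in
the test suite). The packaged experiments use: 2,000 Monte-Carlo null
simulations per smoothness value (cached with FWHM rounded to 0.5–1 mm,
since replicate cohorts share smoothness up to estimation noise); 200
replicate cohorts for false-positive calibration; 50 replicates for
power; 500 repetitions × 200 permutations on 2,000-vertex spheres for
spin-test calibration. These sizes are the package's chosen compromise
between Monte-Carlo precision and desk-scale runtimes; production
analyses should raise `n_sim` to 10,000 and `n_perm` to 1,000 (the
defaults in `study_config()`).

## Degenerate inputs and edge rules

* All-zero volumes have undefined entropy (EFC errors); single-voxel
  point masses give EFC 0 and uniform volumes EFC 1. The EFC mask
  convention (whole volume vs analysis mask) is a flag, default whole
  volume.
* Constant subject vectors make homogeneity and correlation undefined:
  such subjects are flagged with an explicit reason rather than
  silently dropped.
* Voxels with zero residual variance receive a signed-infinite t
  sentinel and a flag; they threshold like any suprathreshold voxel.
* `critical_cluster_size` returns at least 1; when no null simulation
  reaches extent 1, every non-empty cluster is significant.
* Axes with fewer than two in-mask voxels report missing smoothness;
  out-of-range variance ratios clip the FWHM at 0 (rough) or `Inf`
  (flat), and flat axes are excluded from the geometric mean.
* Spin permutations drop vertices invalid in either map pairwise per
  permutation; nearest-vertex ties break to the lowest index.

## Known limitations

* The Monte-Carlo null uses a stationary Gaussian kernel at the
  geometric-mean FWHM; non-Gaussian or non-stationary autocorrelation
  (as AFNI's ACF model addresses) is out of scope.
* Degrees of freedom are $n - p$ with no smoothness-based correction,
  matching plain OLS.
* The per-direction cluster threshold is not corrected across the two
  directions, across seeds, or across contrasts.
* Clinical partial correlations are exploratory by design; no
  multiplicity correction is applied and reports are labelled
  accordingly.
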