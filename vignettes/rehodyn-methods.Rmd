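---
title: "Static and dynamic regional homogeneity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic regional homogeneity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The two statistics

**Regional homogeneity (ReHo)** quantifies how synchronously a voxel's
BOLD time series evolves with its immediate spatial neighbourhood. For a
voxel with the $K$ series of its $3\times3\times3$ cube (the centre plus
its 26 neighbours, $K \le 27$ inside the mask) over $n$ time points,
rank each series over time and compute Kendall's coefficient of
concordance

$$
W \;=\; \frac{12\sum_{t=1}^{n}\left(R_t - \bar R\right)^2}
             {K^2\left(n^3-n\right) - K\sum_j T_j},
$$

where $R_t$ is the rank sum across the $K$ series at time $t$,
$\bar R = K(n+1)/2$, and $T_j = \sum_g (g^3-g)$ over the tie groups of
series $j$ (midranks are used for ties). $W \in [0,1]$: 1 means all
neighbours share one rank ordering. $W$ is invariant under strictly
monotone transforms of any single series, which makes it robust to
voxelwise scaling and drift-free monotone distortions. `kendalls_w()`
exposes the kernel; `reho_map()` applies it voxelwise.

**Dynamic ReHo** asks how stable that local synchronization is over the
scan. Static ReHo is recomputed in sliding windows of $L$ volumes
stepped by $S$ (defaults $L = 50$ TRs $= 100$ s, $S = 5$ TRs, giving 37
windows for a 230-volume series), and the per-voxel variability over
windows is summarized by the coefficient of variation

$$
CV_i \;=\; \frac{\sqrt{\tfrac1n\sum_{t=1}^{n}(x_t-\bar x)^2}}{\bar x},
$$

with $x_t$ the *raw* (untransformed) $W$ of voxel $i$ in window $t$.
Two conventions are fixed here deliberately: the standard deviation is
the population form (divide by $n$, not $n-1$), and the CV is taken on
raw $W$ rather than Fisher-transformed values; a `transform_windows`
flag exists for sensitivity analyses. The CV is scale invariant and
equals zero for a single full-length window.

After computation, static maps are standardized by the Fisher transform
$z=\operatorname{atanh}(W)$ (with $W$ clipped at $1-10^{-7}$ so perfect
concordance stays finite; a mask-mean/SD `zscore` alternative is also
provided since toolboxes differ in what they call "Fisher z" for KCC
maps) and CV maps are z-standardized over the mask; both are then
smoothed with a 6 mm FWHM Gaussian
($\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis, kernel weights
renormalized inside the mask so values never bleed across its edge).
ReHo is always computed on *unsmoothed* data; smoothing follows
standardization.

## Preprocessing

The in-scope chain is fixed and ordered: discard the first 10 volumes
(T1 saturation), regress nuisance covariates, bandpass. The nuisance
model contains an intercept, a linear trend (detrending is folded into
the regression), mean white-matter and CSF signals supplied as columns
(tissue segmentation is out of scope), and the Friston-24 motion
expansion: the 6 rigid-body parameters, their one-volume lag (first row
zero), and the squares of both sets. Residuals are exact least-squares
residuals, orthogonal to every confound column; rank-deficient confound
sets are resolved by pivoted QR with a warning naming the dropped
columns.

The bandpass (default 0.01–0.08 Hz) is an ideal FFT-domain mask rather
than a Butterworth filter: Fourier coefficients outside the band,
including DC, are zeroed. This convention has exact passband edges and
is idempotent, which makes its contract directly testable (filtering
twice equals filtering once to numerical precision).

Motion is summarized by the Jenkinson framewise displacement: for each
consecutive volume pair the relative rigid-body transform
$M = T_i T_{i-1}^{-1}$ is decomposed into $A = M_{3\times3} - I$ and
translation $t$, and
$\mathrm{FD} = \sqrt{\tfrac{r^2}{5}\operatorname{tr}(A^\top A) + t^\top t}$,
the RMS displacement of a solid sphere of radius $r$ (default 50 mm —
the algorithm's usual head-size proxy; the radius is configurable
because published descriptions name the algorithm but rarely the
radius). Exclusion applies three rules — maximum absolute translation
$> 1.5$ mm, maximum absolute rotation $> 1.5^\circ$ (rp files carry
radians; conversion is internal), mean FD $> 0.2$ — each read with a
*strict* inequality ("exceeding" taken literally), so a subject exactly
at a threshold is retained. "Displacement" is interpreted as the
per-axis maximum absolute translation; a Euclidean alternative would be
easy to add but the per-axis reading matches how realignment parameters
are usually screened.

## Group inference

Group differences are tested voxelwise with an OLS GLM: intercept, 0/1
group indicator, and mean-centred covariates (age, sex, mean FD,
education, gray-matter volume by default; GM volume is a per-subject
scalar from the clinical table). With intercept + group only, the GLM t
equals the pooled two-sample t exactly, which is one of the unit
tests. Cluster-forming uses two one-tailed thresholds at the voxel p
(default 0.001 per tail, the usual convention for signed contrasts;
`tail = "two.sided"` gives a single $|t|$ threshold), and components
are labelled at 26-connectivity by default (6 and 18 available — the
choice is not dictated by the method, so it is explicit and logged).

Two cluster-level corrections are provided:

* **Permutation (default, reference method).** Freedman–Lane: residuals
  of the reduced model (covariates only) are permuted over subjects,
  the reduced fit is added back, the full model is refit, and the
  permuted t map is thresholded and clustered identically; the observed
  extents are compared with the null of the maximum extent, so p-values
  are familywise-corrected by construction. 500 permutations by
  default; fewer than 100 warns, zero errors.
* **Gaussian random field.** The classical expected-cluster
  approximation from the Euler characteristic density, using residual
  smoothness estimated from the lag-one autocorrelation of standardized
  residuals per axis
  ($\mathrm{FWHM} = \Delta\sqrt{-2\ln 2/\ln\rho}$, floored at one voxel
  because a sampled field cannot be rougher than its grid) and the
  RESEL count of the mask. Published pipelines differ in their exact
  GRF variant; this implementation documents its formula and defers
  exactness claims to the permutation route, against which it is
  cross-checked on simulations.

Known limitation: when very large true effects exist somewhere in the
volume, Freedman–Lane reduced-model residuals still contain that
signal, so permuted maps produce large null clusters and p-values for
*other* clusters become conservative. On synthetic cohorts with peak
|t| near 10 this can push a genuinely affected secondary region just
above a 0.01 cluster threshold. This is a property of max-statistic
permutation generally, not of this implementation.

## The synthetic cohort generator

The generator exists so that every stage has ground truth. Each voxel's
series is a shared-source mixture
$x_v(t) = w_v\,g(t) + \sigma\,\varepsilon_v(t)$: $g$ is a subject-level
source signal, $w_v \in [0,1]$ the local synchronization weight, and
$\varepsilon_v$ independent noise. Expected pairwise correlation is
$w^2/(w^2+\sigma^2)$, so expected ReHo is monotone in $w$ — verified by
simulation at three sync levels. The construction is $O(\text{voxels})$
and gives direct control of KCC without building covariance matrices.
On top of the signal go a linear drift, autoregressive WM/CSF-like
signals and a small motion-coupled component, each with per-voxel random
weights; all are recoverable by the preprocessing chain because the
true regressors are supplied with the subject. Motion traces are
bounded random walks (a `spiky` flag injects a mid-scan jump that
violates the exclusion rules, to exercise the screening logic).

Patients differ from controls in cubic effect regions: `reho_down` /
`reho_up` shift $w$ by $\mp$ the configured magnitude (defaults 0.3
around a base of 0.5, noise SD 0.6), and `dreho_up` regions modulate
$w$ in time, $w_v(t) = w_v\,[1 + m\sin(2\pi t/P + \phi)]$, creating
window-to-window ReHo variability with stationary regions as contrast.
The modulation period default is $P = 200$ s. This was a genuinely open
choice: a period close to the window length is averaged out within each
100-s window (the window mean of a sinusoid attenuates by
$\operatorname{sinc}(\pi L/P)$, only ~0.18 at $P = 80$ s, and simulated
in-region CV was then indistinguishable from background), whereas
$P = 200$ s retains ~64% of the modulation at window scale while still
completing more than two cycles per 460-s scan. With the defaults the
in-region CV is ~0.26 against a background of ~0.18, and the
in-/out-of-region separation held in every simulated subject during
development.

A subtlety worth knowing: because $CV = \mathrm{SD}/\text{mean}$, a
*static* sync shift also moves the CV (higher mean $W$ lowers CV and
vice versa), so sync-shifted regions produce mirrored secondary
clusters in the dynamic contrast. That is a property of the CV
statistic itself, not a generator artifact.

Clinical covariates copy the marginal distributions of an acute
unilateral sudden hearing-loss cohort (ages ~39 ± 12–16 y, patient PTA
73.7 ± 10.4 dB HL vs control 13.3 ± 5.1, duration 9.0 ± 4.3 days
truncated at half a day, THI 47.5 ± 26.4 clipped to [0, 100], affected
side ~55% left; units: years, days, dB HL, THI points, cm³). A
configured link `(roi, covariate, rho)` shares a standard-normal latent
factor between the subject's regional ground truth (sync weight for
static regions, modulation depth for dynamic ones) and the covariate,
so the population correlation equals `rho` exactly at the ground-truth
level (the defaults use 0.39 for THI and −0.35 for duration as
simulation targets); clipping of THI attenuates the realized
correlation by well under 0.01. Affected side is carried as a pure
covariate: no side-specific imaging effect is simulated, since there is
no usable quantitative description of one.

Determinism: the cohort seed fixes the clinical table and latent
factors, and each subject's BOLD is drawn under a seed derived
arithmetically from the cohort seed and subject index, so a
configuration reproduces bit-identical arrays and on-disk files.

What the generator does *not* emulate: scanner physics (slice timing,
distortion, spatial autocorrelation of thermal noise), anatomical
images, spatially varying hemodynamics, or non-sinusoidal
nonstationarity (regime switching). Passing tests on this generator
therefore demonstrate the *statistical machinery* — monotone recovery,
calibrated false positives, parameter recovery — not performance on
real scanner data.

## Numerical choices and degenerate inputs

* Midranks with the standard tie correction; filtered float data
  rarely tie, but synthetic integer edge cases must be exact.
* A voxel whose neighbourhood has fewer than `min_in_mask` members
  (default: all 27) is `NA`, never silently zero; group analyses
  restrict to voxels defined for every subject.
* All-constant neighbourhoods make $W$ undefined (`NA`); constant maps
  make z-scoring an error rather than a zero map.
* `atanh` clipping at $1-10^{-7}$; CV undefined where the window-mean
  $W \le 0$.
* Window length is checked against the inverse of the passband's lower
  edge (100 s for 0.01 Hz) and shorter windows warn.
* Quasi-separated logistic fits fall back to a weakly ridge-penalized
  Newton solver (L2 on slopes only, $\lambda = 10^{-3}$) with a
  warning; exactly duplicated feature columns are dropped before
  fitting.
* Classifier hyperparameters are fixed (RBF SVM at unit cost, CART
  defaults, 500-tree random forest, $k = 5$ KNN on standardized
  features) — no tuning loops, so a seed fixes the whole AUC table.
  Both stratified 5-fold cross-validated AUCs (default) and in-sample
  AUCs (closer to how single-cohort analyses are often reported) are
  available, labelled by scheme.
* ROI–covariate correlation tables apply no multiplicity correction by
  default (the ROIs are preselected by the group contrast); a
  Bonferroni option exists.

## Problem sizes used in the validation suite

The test suite and the acceptance script run entirely on synthetic
data: cohorts of 20 + 20 subjects on a 24 × 24 × 16 grid of 3 mm
voxels, 240 volumes at TR 2 s (a full-size run is a configuration
change only); false-positive calibration uses 200 null cohorts of
12 + 12 subjects with 500 permutations each; correlation recovery uses
the emulated full cohort size of 102 patients + 73 controls at the
clinical level. These sizes were chosen so that each property is
measured with enough replicates to be meaningful while the whole suite
stays convenient to run on a laptop.
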