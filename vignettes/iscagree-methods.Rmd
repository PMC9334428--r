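---
title: "Inter-subject synchronization with the ICC agreement index: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-subject synchronization with the ICC agreement index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a group of subjects experiences the same timeline of events — here, an
auditory instruction to rest with eyes closed (EC) for four minutes and then
with eyes open (EO) for four minutes — their fMRI time courses can become
synchronized around the condition transitions. Inter-subject correlation
(ISC) analysis quantifies this synchronization voxel by voxel. Instead of
averaging Fisher-transformed Pearson correlations over all subject pairs,
`iscagree` uses a single intraclass correlation: the *agreement* index
ICC(A,M) over the n-by-M matrix `X` of one voxel's time courses (n time
points, M subjects). Unlike pairwise Pearson correlation, the agreement
index is sensitive to between-subject differences in mean intensity and
amplitude — differences which can themselves be informative — and it has a
tractable asymptotic standard error, which is what makes brain-wide
standardized maps possible.

## The estimators

Let `S` be the M-by-M column-wise (between-subject) cross-covariance matrix
of `X` at zero lag, and `V` the n-by-n row-wise covariance matrix, both with
divide-by-count divisors (n for `S`, M for `V`). Write `s = 1'S1`,
`t = tr(S)`, and
\[
\Gamma = \frac{1'V1/n^2}{1'S1/M^2},
\]
the ratio of row to column covariance mass. \(\Gamma\) estimates
\(\gamma = \sigma_r^2/\sigma_c^2\) (the means of the elements of `V` and
`S`) and grows with between-subject offset variance. The agreement index is

\[
\hat{A} = \frac{\frac{M}{M-1}\,(s - t)}
{s\left[1 + \frac{(n-1)\Gamma}{n(M-1)} - \frac{M}{n(M-1)}\frac{t}{s}
 + \frac{1}{n(M-1)}\right]},
\]

which is algebraically identical to the Shrout–Fleiss two-way
random-effects ICC(2,M); the consistency index
\(\hat{C} = \frac{M}{M-1}(s-t)/s\) is ICC(3,M) and is invariant to
per-subject mean shifts. With the divisors above both identities are exact,
which the test suite verifies against the ANOVA mean-squares construction to
1e-8 over matrices spanning n from 10 to 240 and M from 2 to 49; divisor
choices that mix n−1 with M−1 break the agreement identity, which is why
population-style moments are used throughout. The two indices are linked by

\[
\hat{A} \simeq \hat{C}\,\frac{M-1}{(M-1)+\Gamma} + O\!\big(\tfrac{1}{nM}\big),
\]

and both lie in \((-\infty, 1]\); negative values are reported as-is, never
truncated. The package exposes the remainder
\(|\hat{A} - \hat{A}_{approx}|\); on synthetic data its median halves when
n doubles, the expected \(O(1/nM)\) decay.

## The delta-method variance

The sampling variance of \(\hat{C}\) follows from the delta method applied
to the half-vectorization of `S`:

\[
\mathrm{Var}(\hat{C}) = \tfrac{2}{n}\,
\eta' K_M (\Sigma \otimes \Sigma) K_M' \eta \Big|_{\Sigma = S},
\qquad
\eta' = \frac{M}{(M-1)(1'\Sigma 1)^2}
\big[-(1'\Sigma 1)\,\mathrm{vec}'(I_M) + \mathrm{tr}(\Sigma)(1'\otimes 1')\big] G_M ,
\]

where \(G_M\) is the duplication matrix and \(K_M\) a left inverse of it
with \(\mathrm{vech}\,\Sigma = K_M\,\mathrm{vec}\,\Sigma\). Two details are
worth recording.

* **Which left inverse.** Any matrix satisfying the vech identity could be
  called \(K_M\); the 0/1 elimination matrix and the Moore–Penrose inverse
  \((G'G)^{-1}G'\) both do. Only the Moore–Penrose choice makes the
  quadratic form equal \(\eta'\,\mathrm{Cov}(\mathrm{vech}\,S)\,\eta\) for
  Gaussian data, so that is the one implemented (and exported as
  `elimination_matrix()`). Monte-Carlo calibration confirms it: over 5000
  replications at n = 240 with compound-symmetric subject covariance
  (correlation 0, 0.3, 0.6; M = 5 and 10), the formula tracks the empirical
  variance of \(\hat{C}\) well inside the 20 percent margin the test
  suite enforces.
* **Never materialize \(\Sigma \otimes \Sigma\).** Writing
  \(A = \mathrm{tr}(\Sigma)J - (1'\Sigma 1)I\) (so that
  \(\eta = c\,G_M'\,\mathrm{vec}\,A\) with \(c = M/((M-1)s^2)\)), the form
  collapses to
  \(\mathrm{Var}(\hat{C}) = \tfrac{2}{n}c^2\,\mathrm{tr}(A\Sigma A\Sigma)
  = \tfrac{2}{n} c^2 (t^2 s^2 - 2tsu + s^2 v)\)
  with \(u = 1'S^2 1\) and \(v = \mathrm{tr}(S^2)\). This is exact (tested
  against the explicit-transform route to 1e-10) and keeps the voxelwise
  map loop at \(O(nM^2)\) per voxel instead of \(O(M^4)\), which matters at
  M = 49.

The agreement variance follows as
\(\mathrm{Var}(\hat{A}) = \mathrm{Var}(\hat{C})\,
\big(\frac{M-1}{(M-1)+\gamma}\big)^2\) with \(\gamma\) evaluated at
\(\Gamma\), and the standardized statistic is
\(t_{\hat{A}} = \hat{A}/\sqrt{\mathrm{Var}(\hat{A})}\). A computed variance
below −1e-12 raises an error rather than being clamped; values within
rounding of zero are clipped to zero.

## Stationarity screening

The variance derivation assumes the voxel series are strictly stationary
and weakly dependent (rho-mixing: the maximal lagged correlation decays to
zero). `stationarity_screen()` checks this per (voxel, subject) series:
KPSS with a deterministic trend (null: trend-stationarity), ADF with
constant and trend (null: unit root), and `lagged_corr_profile()` for the
mixing diagnostic. KPSS rejections are aggregated across subjects at 50/60/70
percent quorums, optionally after weak-FDR correction of each subject's
voxelwise p-values; the screen is reported, never used to mask voxels.

Because no stationarity-test package is part of this stack, both tests are
implemented here: OLS detrending, Bartlett long-run variance with
`trunc(4(n/100)^(1/4))` lags for KPSS, `trunc((n-1)^(1/3))` lagged
differences for ADF, and p-values interpolated within the published
critical-value tables (clamped to [0.01, 0.10] and [0.01, 0.99]
respectively). The ADF regression includes the trend term: with a constant
only, the test cannot reject its null for a series that is stationary
around a nonzero slope, which would contradict the KPSS trend-stationarity
framing used here.

## Surrogate null and weak FDR

Significance of the voxelwise \(t_{\hat{A}}\) map is judged against a
Fourier phase-randomization null: each subject's series at each voxel is
replaced by a surrogate with identical amplitude spectrum and iid uniform
phases (conjugate symmetry enforced; for even n the real Nyquist coefficient
gets a random sign — a detail the method leaves open, resolved here so the
surrogate stays real-valued). Phases are drawn independently per subject and
per voxel because the null hypothesis is the absence of *inter-subject*
synchronization; each subject's autocovariance survives, alignment does not.

The 50-replicate default pools all voxels into one brain-wide null
distribution. A pooled null (one common critical value, as opposed to
voxelwise nulls) is a deliberate choice: 50 surrogates per voxel cannot
estimate a per-voxel 5 percent tail, while the pooled distribution rests on
hundreds of thousands of draws. Empirical p-values use the add-one rule
\(p = (1 + \#\{t_{null} \ge t_{obs}\})/(1 + N)\) so p is never zero.
Supra-threshold voxels are selected by the step-up rule that compares the
i-th smallest p-value with \((i/K)\,\alpha/C(K)\), \(C(K) = \sum_{i=1}^K
1/i\) — the weak-control variant valid under arbitrary dependence between
voxels. On 20 global-null synthetic datasets (K = 2000, M = 10, n = 240,
AR(1) noise), the mean false-positive proportion of the whole chain stays
at or below the nominal 5 percent within Monte-Carlo error; this is also
what `scripts/acceptance.R` recomputes.

## Networks, connectivity, cortisol

Supra-threshold voxels are averaged within atlas regions per subject.
Regions mixing two response types are split by 2-means on the z-scored
voxel mean series, accepting the split only when the mean Silhouette width
reaches 0.5 — the conventional lower edge of "reasonable structure"; the
method itself fixes no numeric rule, so that band is adopted here. Group
mean series are clustered by multi-restart K-means ("iterative" K-means is
read as 100 restarts of Lloyd's algorithm with best-inertia selection) on
z-scored series, with K chosen from 2–6 by the mean Silhouette width.
z-scoring makes shape rather than amplitude decisive, matching the intent
of grouping like-shaped responses; Euclidean distance on z-scored series is
then equivalent to correlation distance up to a monotone map.

Connectivity is Pearson correlation between subject-level region series
over a window (full session, or the EC/EO halves), Fisher-transformed and
standardized by the square root of the *actual* window length (240, or 120
per condition) — the nominal-standard-error convention, in preference to
the exact-Fisher \(1/\sqrt{n-3}\). Group-level tests are one-sample
Student's t on the Fisher values with weak-FDR flags over the joint family
of all pairs. Temporal dependence within a window makes the nominal
standardization optimistic about the effective sample size; the tests are
nonetheless computed exactly in this form, as the convention dictates, and
readers should treat the absolute scale of `z_std` accordingly. Per-subject
left/right/inter-hemispheric means feed partial correlations with pre- and
post-scan salivary cortisol controlling age, sex, trait anxiety and the
stress-questionnaire score (state anxiety is excluded: it does not alter
the associations and costs a degree of freedom at N = 25). Degrees of
freedom are N − 2 − (number of covariates).

## The synthetic generator

`simulate_dataset()` emulates the study conditions: 240 volumes at TR = 2 s,
EC onset at volume 1, EO onset at volume 121, up to 49 subjects, three
response networks (positive transient, negative transient, limbic
biphasic — a slow EC decrease, then a dip and sustained rise after EO) with
transients lasting about 60 s, AR(1) noise (coefficient 0.3), per-subject
per-voxel mean offsets (SD 1, which drives \(\Gamma > 0\) and separates
\(\hat{A}\) from \(\hat{C}\)), and per-subject response amplitudes (25
percent relative spread). Templates are difference-of-exponential bumps and
exponential drifts — parameterized shapes, since only empirical shapes are
reported for the real data. Each non-null template is normalized to unit
time-course SD so that the `amplitude` parameter is the shared-response SD
in noise units, identical across network shapes; the covariance-based index
sees variance, not shape, so this makes one SNR dial govern all three
networks. The default amplitude 0.5 makes the shared response a
fifth of total variance (a pairwise inter-subject correlation near 0.19,
hence an agreement index near 0.55 at M = 10 after the usual
average-measures boost), and is declared here once; the recovery requirements
(sensitivity at least 0.9, specificity at least 0.95, correct three-network
partition) are met with margin at this SNR.

The default grid is 12 x 12 x 8 (1152 voxels) so that a full pipeline run
takes tens of seconds; the validation suite uses 20 such datasets plus 20
flat 2000-voxel null blocks, sizes chosen to keep the whole suite in the
tens of minutes while leaving Monte-Carlo error well below the tested
margins. What the generator does *not* emulate: hemodynamic convolution,
cardiac/respiratory noise, head motion, spatial smoothness of real BOLD
fields, or scanner drift. Passing tests therefore demonstrate the
statistical machinery — estimator identities, variance calibration,
false-positive control, recovery at a declared SNR — not robustness to
those artifacts.

`simulate_cortisol()` draws demographics with the saliva-subsample moments
(N = 25 scale), builds pre-scan cortisol from configurable covariate
loadings plus a connectivity term calibrated so the population partial
correlation equals a target (0.5 by default), and couples post-scan to
pre-scan cortisol at r = 0.417. Covariate loadings (200, 500, 150, 150
pg/ml per SD of age, male sex, trait anxiety, stress score) are design
choices creating genuine confounding for the partial correlation to remove.

## Numerical and design notes

* Symmetry of `S`/`V` is exact by construction; constant subject columns are
  rejected as degenerate voxels before any ratio is formed.
* `kmeans` ties and restarts: fixed seeds are plumbed through every
  clustering call; the partition is invariant to entry order and to affine
  rescaling of individual series (tested).
* Perfectly correlated region pairs (|r| = 1, infinite Fisher Z) are
  skipped with an explicit warning rather than clamped.
* Midline or unlabeled-hemisphere regions are excluded from left/right and
  inter scopes.
* The pooled-null choice and the add-one p-value correction are the two
  places where the published description is silent; both are flagged above
  with their rationale.
* All randomness flows from a single master seed: dataset generation,
  surrogate phases (drawn sequentially from R's generator inside the
  compiled loop), K-means restarts and cortisol simulation use seeds
  derived from it by fixed offsets.

## Limitations

The agreement index inherits the stationarity assumption; the screen
reports violations but does not correct for them. The surrogate null
preserves each series' spectrum only up to FFT circularity. The t-tests on
standardized Fisher Z treat time points as exchangeable within the window.
And the acceptance-grade guarantees are demonstrated on synthetic data at a
declared SNR — they quantify the machinery, not performance on any
particular scanner's data.
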