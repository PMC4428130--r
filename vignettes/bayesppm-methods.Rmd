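---
title: "Methods: spatial variational-Bayes PPMs and the automated effect-size threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial variational-Bayes PPMs and the automated effect-size threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bayesppm)
```

This vignette is the package's account of its statistical machinery: the
model and its assumptions, the estimation scheme, the tunable parameters,
what the phantom simulator does and does not emulate, and the numerical and
design choices made where more than one defensible option existed.

## 1. Model

Each voxel's time series follows the GLM

$$y_i = X\beta_i + e_i,$$

with a shared design matrix $X$ (HRF-convolved task boxcar, its temporal
derivative, optional confounds, constant) and voxel-specific coefficients
$\beta_i$. The error $e_i$ is AR(2) with voxel-specific coefficients $a_i$
and innovation precision $\lambda_i$; second-order autoregression is a good
compromise for EPI noise, capturing both thermal and slow physiological
correlation without over-parameterising short runs.

Spatial structure enters through the prior, not the likelihood: for each
regressor $k$, the coefficient image $\beta_{\cdot k}$ carries an improper
Gaussian prior with precision $\alpha_k L$, where $L = D - A$ is the
unweighted graph Laplacian (UGL) of the in-mask voxel adjacency. The prior
penalises squared differences between neighbouring coefficients —
$\tfrac{\alpha_k}{2}\sum_{i\sim j}(\beta_{ik}-\beta_{jk})^2$ — so each
effect image is smoothed adaptively, with its own spatial precision
$\alpha_k$ estimated from the data (empirical Bayes via broad
Gamma(10^-2^, 10^-4^) hyperpriors on every $\alpha_k$ and $\lambda_i$).
The prior neighbourhood is 6-connectivity (faces): the smallest stencil,
standard for UGL priors, and deliberately distinct from the 18-connectivity
used for *cluster* analysis of thresholded maps.

Contrasts give a Gaussian effect-size posterior per voxel,
$\mu_i = c^\top\hat\beta_i$, $\sigma_i^2 = c^\top\hat\Sigma_i c$, converted
to percent signal change by dividing by the posterior-mean constant
coefficient (the task regressor is peak-normalised upstream, so "2.0" means
a 2% peak excursion over the temporal mean).

## 2. Variational estimation

`vb_fit()` maximises a variational free energy over the factorised family
$q(\beta_i)\,q(a_i)\,q(\lambda_i)\,q(\alpha_k)$ (Gaussian, Gaussian, Gamma,
Gamma). All four updates are exact full-conditional coordinate-ascent steps
under the conditional AR likelihood (the first $p$ samples are conditioned
on), including the $V_a$ cross-terms in the whitened quadratic forms, so
the free energy is non-decreasing by construction — the test suite asserts
this on every phantom it fits. All time-axis work is reduced, once per fit,
to lagged cross-product blocks ($X_j^\top X_k$, $X_j^\top y_k$,
$y_j^\top y_k$ for lags $0..p$), after which each iteration costs a few
K×K operations per voxel.

Numerical choices:

* **Update order** $q(\beta) \to q(a) \to q(\lambda) \to q(\alpha)$, with
  the $\beta$ sweep done Gauss–Seidel (freshest neighbour means), which
  keeps each voxel update an exact conditional maximiser.
* **Warm start**: $\beta$ from OLS, $a$ from Yule–Walker on OLS residuals,
  $\lambda$ from the residual variance. The spatial precisions are
  initialised by evaluating the $q(\alpha)$ update at the OLS maps rather
  than at a fixed constant: $\alpha$ has units of 1/β², so a fixed init is
  not scale-free and leaves a visible imprint when iteration stops early;
  the data-driven init makes shallow and deep runs approximately
  equivariant under global intensity rescaling.
* **Stopping**: relative free-energy change below `tolerance` (default
  10^-4^) or `max_iterations` (default 64); stopping at the iteration cap
  flags the fit non-converged, never silently.
* **Degenerate noise**: in the noise-free limit the AR factor's expected
  lag cross-products can pick up cancellation jitter that a huge $\lambda$
  then amplifies; the $q(a)$ system is clamped to positive definite
  (non-negative diagonals, off-diagonal bounded by the geometric mean)
  before inversion.
* **Determinism**: there are no stochastic steps; repeated fits are
  bit-identical.

The prior-free limit is a built-in oracle: clamping
`fixed_spatial_precision = 1e-10` with `ar_order = 0` reproduces per-voxel
OLS to better than 10^-4^ (observed ~10^-9^), which validates the whole
update machinery independently of the prior.

## 3. Classification and thresholds

`ppm_maps()` computes PPMa/PPMd/PPMn from the Gaussian posterior; PPMn is
evaluated as a difference of Gaussian cdfs (not as one minus the others),
so the normalisation check in the tests is informative. Tail probabilities
are computed by `pnorm`'s log-scale-capable tails: at LBT = 10 the
complement 1 − p\_T ≈ 4.54×10^-5^ must not round away. The four-category
rule labels a voxel activated / deactivated / non-activated when the
corresponding probability exceeds p\_T, and low-confidence otherwise; with
p\_T > 2/3 the categories cannot collide, and smaller p\_T values produce a
warning plus a largest-probability tie-break.

One printed correspondence in the source literature equates a *probability*
of 4.5×10^-5^ with LBT = 10; the log-odds transform makes clear this must
be read as 1 − p\_T (the log-odds of p = 4.5×10^-5^ is ≈ −10). The package
implements the transform itself and documents the discrepancy rather than
reproducing it.

The frequentist path deliberately cannot feed the classifier: a
point-estimate percent-signal-change map carries no posterior sd, and
`ppm_maps()` rejects it with a message naming the missing field. Eqs of the
classification need a full posterior; silently classifying a frequentist
map would be wrong, not just lossy.

## 4. The automated effect-size threshold

The threshold model is one number per clinical scenario:
$\gamma = s \cdot \mathrm{median}\{\text{top }0.1\%\text{ positive effects}\}$,
with packaged slopes $s = 0.497$ (*loci*: pinpoint the activation site) and
$s = 0.144$ (*extent*: delineate the full activated area), top fraction
0.001. The `n_top = max(1, ceiling(fraction × count))` rule makes the
statistic well-defined on small masks and never empty.

The calibration engine reproduces, without an operator, the procedure that
produced such slopes:

1. **Reference cluster**: connected components (18-connectivity) of the
   suprathreshold frequentist t-map; the component with the largest overlap
   with a region-of-interest is taken as $C_{Ref}$. ROI-overlap selection
   replaces the original manual erasure of non-target clusters — the one
   operator-dependent step — with a deterministic rule (ties: larger
   component, then smallest linear voxel index).
2. **Jaccard sweep**: for γ on a grid from 0 with step Δγ = 0.01, classify
   at LBT = 10, pool all activation clusters overlapping $C_{Ref}$ into
   $C_{Bayes}$ (whole clusters, including voxels outside the reference),
   and record $J = |C_{Ref}\cap C_{Bayes}| / |C_{Ref}\cup C_{Bayes}|$. The
   grid ends at the first γ whose activated set is empty; a
   non-monotonically vanishing activated set is truncated at that first
   empty point. The curve is smoothed with a box kernel of width 8 —
   implemented as a centred moving average (3 left / 4 right) with windows
   shrinking at the edges, avoiding phase shift, since the original recipe
   fixes only the width — and the smoothed argmax, ties toward smaller γ,
   is the optimal threshold.
3. **Slope fit**: optimal γ against top-0.1% median across acquisitions,
   intercept-free (a region with no activation has effect size zero),
   by iteratively reweighted least squares with Tukey bisquare weights
   (tuning constant 4.685, MAD scale, ≤50 iterations, relative slope
   change < 10^-8^). If the MAD collapses to zero — at least half the
   points fit exactly — the exact-fitting points keep weight 1 and the
   rest drop to 0, which handles a gross outlier among otherwise exact
   points. The fit is hand-written (it is part of the method) and
   cross-checked against `MASS::rlm` in the tests.

Where the statistic is computed was genuinely open: the top-0.1% median
could be taken from the frequentist beta map or the Bayesian posterior-mean
map. The package uses the Bayesian map, so the threshold is self-contained
at inference time when no frequentist fit exists; the two are one
configuration switch apart.

## 5. The phantom simulator

`generate_phantom()` emulates the targeted acquisition: 142 volumes at
TR 2.26 s, ten cycles of 16 s task / 16 s rest, a constant baseline (100),
spatially compact regions of known percent signal change (default: one
sphere of radius 2.5 voxels at +2%), AR(2) noise with coefficients
(0.3, 0.2) generated independently per voxel with a 100-sample burn-in, and
optional low-order cosine drift (default 0, matching a model with no drift
regressor). The task course is `baseline × (1 + psc/100 × x_t)` with the
HRF-convolved regressor scaled to unit peak, so "percent signal change"
means peak-to-baseline percent.

The default innovation scale is calibrated in closed form so the in-blob
OLS t statistic is about 6 — comfortable 3T-like detection — using the
residualised task-regressor norm and the stationary AR(2) variance
identity; the calibration ignores the autocorrelation inflation of the OLS
t, so the realised value is approximate (observed ≈ 6.1).
`emulate_snr_regime(spec, 0.5)` doubles the innovation sd to mimic a
lower-field intra-operative scanner.

What the phantom does **not** emulate: motion, susceptibility distortion,
spike artifacts, physiological noise structure, multi-coil profiles, or
spatially correlated noise (the analysis model assumes voxel-wise noise, so
spatial structure is injected only through the signal). Tests passing on
phantoms therefore validate the estimation and thresholding machinery, not
robustness to real-scanner artifacts — those corrections live upstream of
this package.

## 6. Known limitations

* **Boundary shrinkage of the UGL prior.** A piecewise-constant blob is
  maximally mismatched to a smoothness prior. At the default SNR (t ≈ 6)
  the empirical-Bayes spatial precision settles near α ≈ 1, comparable to
  the per-voxel data precision, and the posterior mean of in-blob voxels is
  pulled toward the inactive surround: the acceptance suite measures a mean
  in-blob percent effect of ≈ 1.72 for an injected 2.0 (≈ 14% low), with
  the bias concentrated at, and diffusing inward from, the blob boundary.
  This is the exact posterior mean under the stated model (the mean-field
  means are exact for the Gaussian subproblem), not an implementation
  artifact — the prior-free limit recovers OLS to 10^-9^. On smooth
  amplitude profiles (the calibration phantoms' linear ramps) the bias is
  negligible. Practically: peak effect sizes are trustworthy; sharp-edged
  effect magnitudes are conservative.
* **Mean-field variances.** The across-voxel factorisation underestimates
  posterior variances where spatial coupling is strong; classification at
  LBT = 10 is correspondingly slightly anti-conservative in smooth regions.
* **Conditional AR likelihood.** The first `ar_order` scans are conditioned
  on rather than modelled; with 142 volumes the information loss is
  negligible.
* **Bonferroni FWE.** The frequentist reference converts t thresholds with
  Bonferroni rather than random-field theory: reproducible without
  smoothness estimation, but conservative; no numeric equivalence with
  random-field-corrected values is claimed.

## 7. Study conditions used by the tests

The suite fits hundreds of small phantoms; sizes were chosen as the
smallest grids on which the spatial prior has a real neighbourhood
structure: 8×8×3 (80 volumes) for unit tests, the default 10×10×6 (142
volumes) for recovery and SNR comparisons (20 seeds each), 14×14×10 for the
six ramped calibration phantoms, and 10⁴ random 3×3×3 maps for the
connected-component oracle. The low-SNR sensitivity comparison applies the
4 mm FWHM Gaussian pre-smoothing to both arms — the same pre-processing
both frameworks receive in the intended workflow — and evaluates the
classifier at the extent threshold γ_ex, the scenario that measures
recovered activation area, against Bonferroni-thresholded t-maps at
p_FWE = 0.05.
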