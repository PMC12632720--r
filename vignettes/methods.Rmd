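---
title: "Brain-age modelling from static and dynamic FNC: methods and design"
author: "fncBrainAge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-age modelling from static and dynamic FNC: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fncBrainAge)
```

## The model and its assumptions

The pipeline estimates, for every scan, how old a brain "looks" from its
functional network connectivity, and then asks whether the gap between
that estimate and chronological age carries cognitive information.

**Connectivity.** A scan enters as a T×C matrix of independent-component
time courses with repetition time TR. Static FNC is the Pearson
correlation between every pair of components over the whole scan; with
the shipped 53-component, 7-network template partition this gives
53·52/2 = 1378 unique features. Dynamic FNC repeats the computation
inside a tapered sliding window — a rectangular window of L = 20 TR
convolved with a Gaussian kernel of σ = 3 TR, cropped to its central L
samples and peak-normalized — using a *weighted* Pearson correlation in
which the taper weights enter the mean, covariance and variances
identically. Windows are 0-based, half-open, advance by a 1-TR stride by
default, and number `floor((T−L)/stride)+1`. Within a multi-scan cohort
all scans are truncated to the common minimum T first, so every subject
yields the same window count.

The 20-TR default follows the dynamic-connectivity convention of
focusing each estimate on a ~40 s neighbourhood at TR = 2 s (14.7 s at
TR = 0.735 s); because window choice is a known sensitivity in this
literature, the length, kernel width and stride are all plain
configuration fields, and a 40-TR window is available by overriding
`windowLength`.

**Brain-age regression.** Three architectures share one training
contract: grouped K = 5-fold cross-validation (scans of one subject
never straddle a fold boundary), an adaptive-moment (Adam) optimizer
minimizing mean absolute error at learning rate 1e-3 and batch size 64,
per-epoch validation MAE recorded in a fold×epoch report, selection of
the epoch minimizing mean CV MAE, and a final refit on all training data
with that epoch budget. The `"paper"` profile uses 128 hidden units, 3
recurrent layers and 100 epochs; the default `"desk"` profile shrinks
width and epochs to 32/10 so that the full suite runs on a laptop —
every empirical claim in this package's tests is made at desk scale.

* `linear_baseline`: ridge regression on standardized features (closed
  form via SVD; penalty `ridgeLambda`, default 1). Deterministic, fast,
  and the reference model for the statistical tests. For window
  sequences it consumes the temporal mean of the window features.
* `bilstm`: a bidirectional LSTM over the sequence of vectorized window
  matrices, temporal mean pooling over the final layer's outputs, linear
  head. Implemented natively (forward, backprop-through-time, Adam) with
  inverted dropout between stacked layers during training only.
* `connectome_gcn`: a two-layer graph convolution on the sFNC matrix,
  using |R| row-normalized as the weighted adjacency and R itself as
  node features, ReLU activations everywhere except the linear output,
  global mean pooling. Any connectome-convolution variant satisfying
  that activation contract would be acceptable; this one was chosen for
  its simplicity and exact hand-derivable gradients.

Two numerical choices matter at desk scale. The output-layer bias is
initialized at the training-mean age, so small-step optimization learns
age *deviations* rather than the age scale itself. And the GCN applies a
fixed input gain of 10 to its node features: correlations live on a
±0.1-ish scale, and without the gain the function moves too slowly under
bias-corrected Adam steps to train in tens of epochs.

**Normative design.** Models are fit on healthy-control scans only and
applied to everyone, mirroring the design of brain-age studies that
train on population cohorts and test in clinical samples. Controls
receive out-of-fold predictions, so no reported prediction is in-sample.
No post-hoc bias correction of BAG is applied; age and age² covariates
in the association model absorb the usual regression-to-the-mean
artefact.

**Association model.** For each (modality, scope) the brain-age gap
BAG = predicted − chronological age is regressed together with the fixed
covariate set {age, sex, site, age², age×sex, diagnosis} on each
cognitive score, by ordinary least squares, restricted to participants
strictly older than 38 years. Site enters as treatment dummies against
the lexicographically first site. Age is mean-centered before squaring —
a pure affine reparameterization that tames the age/age² collinearity
without changing the BAG coefficient. The reported effect is the BAG
coefficient β with its SE, a normal-approximation 95% CI (β ± 1.96·SE),
and `r`, defined here as the **partial correlation of outcome and BAG
given the covariates** (`t/√(t²+df)`, sign-consistent with β) — the
"r" accompanying β in this literature is rarely defined, so the package
states its definition prominently. Two FDR families are corrected
separately per outcome with Benjamini–Hochberg: the wide-brain family
(sFNC, dFNC: 2 tests) and the sub-network family (7 networks × 2
modalities: 14 tests). Outcomes are separate families.

## The synthetic cohort generator

Real data in this area are access-controlled, so the generator is a
first-class, tested module rather than a fixture. It emulates exactly
the structure the analysis assumes:

* **Phenotypes.** Ages uniform on [40, 80] by default — deliberately
  flatter than real cohorts, to maximize identifiability in recovery
  tests. Sex, site and diagnosis are categorical draws; patients carry a
  latent brain-age acceleration `true_bag` centered at δ = 5 years
  (controls at 0), both with SD `bagSd` = 4 years, matching the spread
  of empirical BAG distributions. Cognitive scores are
  `50 + γ·true_bag + N(0, 3)` with γ = −0.5 per year for both attention
  and working memory.
* **Connectivity.** A fixed set of "aging edges" (20% of pairs, slopes
  ±0.012/year around a zero base) moves linearly with *effective age* =
  age + true_bag, so patient connectivity looks δ years older — the
  simplest mechanism consistent with an "older-appearing" brain. Edited
  matrices are repaired to valid correlations by eigenvalue clipping at
  0 and re-normalization to unit diagonal (tolerance 1e-8). The slope
  and fraction were calibrated once so that the desk-scale ridge model
  attains held-out age correlations in the range such studies report
  (≈0.87 at full scale; ≈0.75–0.99 here depending on noise settings);
  weaker signatures produce cohorts in which no BAG analysis would have
  power, which would test nothing.
* **Time courses.** Zero-mean Gaussian draws whose instantaneous
  covariance drifts slowly: the Cholesky factor of the target is
  perturbed multiplicatively by an entrywise Gaussian random walk
  (per-step SD `dynamicDriftSd` = 0.02) and renormalized to unit
  variances, so every instantaneous matrix is a valid correlation by
  construction. With drift 0 the process is stationary at the target
  exactly — the property the stationarity tests exploit.

What the generator does **not** emulate: temporal autocorrelation of
hemodynamics, head motion, scanner drift, site-dependent noise, skewed
age distributions, or ICA estimation error. Passing tests therefore
show that the statistical machinery is correct and powered under the
assumed generative structure, not that the effect sizes transfer to any
real cohort.

## Degenerate inputs and numerical edges

Zero-variance series raise explicit degenerate-input errors everywhere
(plain, weighted and windowed correlation — the windowed error names the
offending window). Low-pass cutoffs at or above the Nyquist frequency
1/(2·TR) are rejected with the computed Nyquist in the message.
Rank-deficient association designs (e.g. a single site colliding with
the intercept) fail with the collinear columns named. Correlation
outputs are clipped to [−1, 1] against floating-point overshoot, taper
weights are symmetrized against FFT noise, and Cholesky factorizations
add a 1e-10 diagonal jitter because PSD-projected targets can be exactly
singular. Fisher z-transformation of features is available but off by
default, since the correlation scale is the one used throughout.

## Problem sizes used by the tests

All empirical tests run at desk scale, chosen as the package's own
standard study sizes: powered recovery at n = 400 subjects (C = 20,
T = 150, 20 replicate seeds), null calibration over 20 cohorts of
n = 200 (640 tests), stationarity at T = 5000, and model sanity checks
on a strong-signal cohort of n = 160 (C = 12, T = 120, slopes 0.015,
drift 0). The recovery check asks for directional significance of the
wide-brain dFNC BAG–attention association (FDR < 0.05 within the
two-modality family) in ≥80% of seeds; the attenuated β (model error
shrinks BAG relative to the latent gap) is expected and not a failure of
the fit — coverage of γ itself is tested separately with oracle access
to the latent gap.

## Known limitations

* Desk-scale recurrent/graph models are demonstrations that the
  architectures train and beat a mean-age predictor; their accuracy
  ceiling is well below the ridge baseline at these sizes.
* The ridge baseline's predictability saturates near r ≈ 0.75 on
  default-noise cohorts (p ≈ 190 features on ≈160 training scans);
  stronger signal or larger cohorts are needed to reproduce r ≈ 0.87.
* β from the model chain is attenuated toward zero relative to γ, as in
  any errors-in-variables regression; only its sign and significance
  are interpreted.
* The generator's white-in-time sampling slightly inflates the
  effective degrees of freedom per window relative to autocorrelated
  fMRI; tapered-window estimates on real data are noisier than here.
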