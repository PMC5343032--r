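---
title: "Methods: trait prediction and elite-genotype classification from canopy reflectance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait prediction and elite-genotype classification from canopy reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectrait)
```

## The problem

Field phenotyping programmes measure canopy spectral reflectance
(350--2500 nm at 1-nm resolution) over hundreds of wheat plots because a
single sweep of a spectroradiometer is enormously cheaper than harvesting,
counting kernels, or running isotope mass spectrometry. The question the
package addresses is how best to turn a plot's spectrum into breeding
information, comparing three families of approach on equal terms:

1. **Spectral reflectance indices (SRIs)** — scalar combinations of a few
   bands (e.g. the water index NWI-3 = (R970 − R920)/(R970 + R920)),
   screened one at a time by simple linear regression against each trait.
2. **Full-spectrum multivariate regression** — principal component
   regression (PCR), partial least squares regression (PLSR), ridge
   regression (RR) and epsilon-insensitive support vector regression
   (SVR), which use all retained bands at once to predict the trait value.
3. **Direct classification of elite genotypes** — instead of predicting a
   trait value, predict membership of the top 20% of the trait's observed
   range (PCA-LDA, PLS-DA, kNN).

The traits are grain yield (GY), spikes per m² (SM2), kernels per spike
(KPS), thousand-kernel weight (TKW), SPAD chlorophyll (Chl), water-soluble
carbohydrate concentration and content (WSC, WSCC), carbon isotope
discrimination (Δ¹³C) and leaf area index (LAI), each tagged with its
measurement stage (anthesis *an*, grain filling *gf*, maturity *m*).
Spectra are taken at two canopy stages (AN, GF) under two hydric regimes —
fully irrigated (FI) and water-stressed (WS) — modelled separately and
pooled (WS+FI).

## Pipeline and models

### Spectra handling

Spectra live in wide tibbles (metadata columns, then one column per
integer wavelength). Repeat scans of one plot are averaged per band
(`average_scans()`); noisy atmospheric-water and detector-edge regions are
removed by inclusive intervals (`trim_noise_bands()`, defaults 350--399,
1350--1480, 1800--1980, 2401--2500 nm — configurable, since instrument
set-ups differ). Reflectance is stored as a fraction in [0, 1];
percent-scale exports are detected (bulk of values above 1.5) and rescaled
with a warning, while an isolated out-of-range cell is an error naming the
cell. Inputs on grids other than 1-nm integers are rejected rather than
resampled, so index formulas always see the bands they name.

### Index registry

`sri_registry()` is a declarative table: name, kind (normalized
difference, ratio, or explicit expression over `R<nm>` symbols),
wavelengths and a provenance note. Indices published only as a name plus
wavelengths are instantiated from their standard literature forms at those
wavelengths; the provenance column says which form. Zero denominators
evaluate to missing values so screening continues on degenerate spectra.
`screen_indices()` ranks indices by the in-sample r² of a simple linear
regression of the trait on the index (ties: RMSE, then name), annotating
how many indices were tested — no multiplicity correction is applied, so
the best-of-many r² is read as a screening statistic, not a test.

### Preprocessing

The canonical order is missing-value exclusion, Local Outlier Factor
screening, then normalization (`preprocess()` records all counts so
`n_input = n_missing_dropped + n_outliers_dropped + n_retained`). LOF uses
the standard reachability-distance definition with `k = 20` neighbours and
a drop rule of score > 1.5 — the method's common defaults, configurable,
since the protocol names the method without parameters. Regression
pipelines z-score each column (sample SD, zero-variance columns centred
only); classification pipelines mean-centre, the one normalization detail
stated for the categorical family. Normalization statistics are estimated
on training folds only and replayed on held-out rows. Outlier screening is
applied per modelling dataset (per trait × stage × environment set), since
pooled and single-regime clouds have different geometry.

### Regressors

All four regressors share one protocol: seeded 10-fold cross-validation
selects the single hyperparameter by RMSE, the model is refit on all data
at the selected value, and the out-of-fold predictions at that value are
kept as the validation set.

* **Ridge** is solved in closed form: one SVD of the centred predictor
  matrix yields the coefficient path for the whole grid of 100 penalties
  log-spaced over [1e−2, 1e10].
* **PCR** regresses the response on the leading principal component
  scores (component count searched over 1--20); **PLSR** uses NIPALS PLS1
  with deflation (latent factors searched over 1--20). Both map
  coefficients back to band space, so predictions are invariant to
  component sign flips, and both reproduce ordinary least squares at full
  rank.
* **SVR** fixes C = 1 and ε = 0.1 and tries four kernels (linear,
  polynomial of degree 3, radial basis, sigmoid) under the same folds,
  keeping the kernel with minimum CV RMSE. The kernel scale is the median
  heuristic (1/median squared pairwise distance). The response is
  standardized internally — a fixed C and ε are only meaningful on a
  common response scale when trait units range from ~1 (GY, ton ha⁻¹) to
  several hundred (SM2) — using the population SD, which keeps the fit
  invariant to row duplication; predictions are returned in trait units.

Interpreting "automatically tested and selected based on a minimization
criterion" as minimum cross-validated RMSE (rather than training error)
was a design choice; CV error is the selection rule used everywhere else
in the protocol.

### Elite dichotomization and classifiers

`dichotomize()` cuts at `min + fraction × (max − min)` of the observed
values (default fraction 0.80): values below the threshold are Class1,
values at or above it are Class2, the elite group — the closed upper tail,
so the maximum is always elite. Labels are invariant to increasing affine
transforms of the trait, and the threshold belongs to the modelling
dataset (computed after preprocessing, per environment set), so pooling
WS+FI genuinely changes who counts as elite.

The three classifiers mean-centre inputs and search their hyperparameter
(principal components 1--20, latent variables 1--20, k 1--10) by 10-fold
cross-validation minimizing the macro error rate. Folds are stratified by
class: at 20% prevalence and modest n, plain random folds can lose the
elite class entirely from a training fold. PCA-LDA feeds PC scores to a
linear discriminant with class means and pooled covariance. PLS-DA
regresses the elite indicator on the spectra and converts scores to labels
by fitting class-conditional Gaussians to the calibration scores and
assigning by maximum posterior with equal priors (proportional priors and
a plain 0.5-threshold `argmax` rule are available by flag); equal priors
were chosen so the minority elite class remains recoverable, which is the
behaviour the categorical approach exists to deliver. kNN is Euclidean
majority voting with fully deterministic tie rules: distance ties keep
training order, vote ties go to the nearer neighbour.

### Metrics

Regression is scored by r² (squared Pearson correlation of observed and
predicted), RMSE in trait units, and Willmott's Index of Agreement

$$d = 1 - \frac{\sum_i (P_i - O_i)^2}{\sum_i (|P_i - \bar O| + |O_i - \bar O|)^2},$$

which the triangle inequality bounds to [0, 1] (the implementation clamps
floating-point dust at the boundaries; constant observations are an
error). Classification is scored by accuracy, per-class prediction rates
(class-wise recall) and an **error rate defined as 1 − the macro-averaged
class sensitivity**. The macro definition is the one under which a
classifier can be 81% accurate and still have a 0.42 error rate — high
accuracy earned on the majority class while missing the elite group — and
it is the definition consistent with published accuracy/error pairs for
this protocol; `1 − accuracy` is reported alongside, and the two coincide
exactly for balanced classes.

Validation metrics are computed on pooled out-of-fold predictions (not
averaged per fold; at n/10 fold sizes per-fold r² is too unstable), and
both calibration and validation values are always reported, labelled.
Hyperparameter selection and validation share the same single-level
10-fold CV — the protocol's own design — which makes validation metrics
mildly optimistic relative to nested CV; this is documented rather than
changed so that results remain comparable with the protocol.

## The synthetic study generator

No field data ships with the package; `generate_traits()` and
`generate_spectra()` emulate the study instead, and every claim the test
suite makes about recovery is a claim about this generator.

**Traits.** Each trait × stage × environment has a target range, mean and
SD (the published values for 384 genotypes, two replicates, one season;
`default_trait_params()`). A standard-normal latent per genotype —
correlated 0.5 between FI and WS, and across traits through a shared
"vigor" latent with weight 0.5 — is mixed with replicate noise (genotype
share 0.7) and mapped through a scaled-Beta quantile transform to the
target marginal. Beta marginals keep every value inside the published
range by construction (clip rate 0) and give the trait a genuinely thin
upper tail, so the 80/20 range split produces a small but non-empty elite
class rather than the degenerate exactly-20% of a uniform. The FI/WS
correlation of 0.5 and the variance split are defaults chosen as
plausible for replicated field trials; neither is reported in the study.
Δ¹³C is generated by simulating plant δ¹³C and applying the
discrimination formula Δ¹³C = (δ¹³Cₐ − δ¹³Cₚ)/(1 + δ¹³Cₚ/1000) with
δ¹³Cₐ = −8.0‰ — the conventional signed value, which is the only reading
under which field discrimination values of 12--20‰ arise.

**Spectra.** Each plot's spectrum is a logistic-weighted mixture of
smooth soil and vegetation endmembers with Gaussian absorption wells:
chlorophyll deepens the 670/490 nm pigment wells and shifts the red edge;
water status deepens the 970/1200/1450/1940 nm water wells; canopy
structure sets the soil/vegetation mixing weight. Drivers are the
standardized traits (Chl at the matching stage; Δ¹³C for water; GY for
structure — LAI is observed under FI only, so it cannot drive the mixing
weight across regimes, though it can be selected instead). Standardizing
drivers over the pooled table is what reproduces the study's headline
pattern: the FI/WS contrast dominates the pooled driver range, so pooled
models see a far larger signal than single-environment models.

Two noise terms control realism. Band noise (SD 0.004 reflectance) is
ordinary sensor noise. A **driver mismatch** term (SD 0.7 on each
standardized driver) models the physiological slack between a measured
trait and its spectral expression; without it the forward model makes
traits spectrally noise-free and single-environment R² saturates near 1,
which no field study shows. With both defaults the 64-genotype fixture
yields pooled WS+FI cross-validated R² ≈ 0.8 for GY against ≈ 0.1--0.2
within a single environment — the qualitative shape of the real
comparison. Setting a coupling to 0 makes the corresponding feature
independent of its trait (the null used by the test suite); note that a
trait can still correlate with the spectra through the *other* channels
when their drivers co-vary with it, which is a property of the design, not
a bug in the generator.

What the generator does **not** emulate: radiative-transfer physics
(PROSAIL-class realism is a non-goal), spatial field structure and the
α-lattice design, weather, genotype × environment interaction beyond a
single correlation, and measurement error in the traits themselves.
Passing tests therefore demonstrate that the pipeline recovers structure
of this idealized kind; they do not certify performance on any particular
field dataset.

## Numerical choices and degenerate inputs

* Fold assignment is a seeded uniform partition (stratified for
  classification); the same folds are shared across methods within one
  benchmark run so method comparisons share variance, and per-cell seeds
  derive from a hash of the cell coordinates so adding a method never
  shifts another method's folds.
* Ties in hyperparameter selection go to the smaller value (the simpler
  model); `which.min` on the CV curve.
* Zero-variance responses are an error for component models; ridge is
  defined for any λ > 0 even with singular predictors; component counts
  beyond the rank are reduced with a warning.
* Undefined index evaluations (zero denominators) propagate as missing
  values; an index whose bands were trimmed yields an all-missing column
  with a warning, not a failure.
* LOF handles duplicate-heavy data by the standard convention that
  infinite local densities cancel (ratio 1).

## Problem sizes

The test suite and examples run on a reduced scene of 64 genotypes × 2
replicates × 2 environments × 2 canopy stages (512 spectra of 2151 bands;
`make_benchmark_fixture()`), with 16-genotype scenes for unit tests —
sizes chosen so the full suite exercises every stage end-to-end in about
two minutes. Conclusions about the generator's statistical behaviour were
checked at the study scale (384 genotypes) where the trait marginals are
asserted.

## Known limitations

* Validation metrics reuse the hyperparameter-selection folds (see
  above).
* The index screening r² is in-sample by design, mirroring the screening
  step it reproduces; it is not a validated performance estimate.
* PLS-DA's Gaussian score calibration assumes roughly unimodal class
  score distributions; heavily multimodal classes would favour the
  `argmax` rule.
* The forward model's endmembers are synthetic smooth curves; absolute
  index values are in realistic ranges but are not calibrated to any
  instrument.
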