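---
title: "Selecting mule-duck fatty-liver quality from near-infrared spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting mule-duck fatty-liver quality from near-infrared spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mulard)
```

## The scientific problem

The quality of "foie gras" is defined by its melting rate (MR): the
percentage of fat a fatty liver loses during a standardized cooking test.
Measuring MR destroys part of the liver, so breeders have never been able to
select directly on it. Two things make selection possible: (1) a chemometric
calibration that predicts MR (and the liver's dry matter, ash, lipid and
protein content) from near-infrared (NIR) reflectance spectra taken either
on the intact liver surface or on ground samples, and (2) a quantitative
genetic analysis showing that the measured and NIRS-predicted melting rates
are, genetically, the same trait.

The genetic analysis is complicated by the production animal itself. The
mule duck is a sterile hybrid of a Muscovy drake and a common-duck female,
so the phenotype exists only in crossbreds while selection happens in the
two purebred parental lines. `mulard` implements both stages — the NIRS
calibration pipeline and the Bayesian crossbred genetic analysis — plus a
synthetic-data generator that reproduces the statistical structure of the
original design, so the whole analysis is testable end to end without the
(never deposited) experimental data.

## The crossbred sire–dam model

For crossbred $i$ with common-line dam $d(i)$ and Muscovy sire $s(i)$,

$$\mathbf{y}_i = \mathbf{X}_i \mathbf{b} + \mathbf{u}^{dam}_{d(i)} +
\mathbf{u}^{sire}_{s(i)} + \mathbf{e}_i ,$$

where $\mathbf{y}_i$ holds one or more traits, $\mathbf{b}$ are systematic
effects (the year x batch x force-feeder combination, 12 levels in the
original design), and $\mathbf{u}^{dam}, \mathbf{u}^{sire}$ are the
parents' line-specific additive effects *as expressed in the crossbred*,
with priors

$$\mathbf{u}^{dam} \sim N(0, \mathbf{A}_{dam} \otimes \mathbf{G}_{dam}),
\qquad
\mathbf{u}^{sire} \sim N(0, \mathbf{A}_{sire} \otimes \mathbf{G}_{sire}),$$

where $\mathbf{A}$ is each line's pedigree relationship matrix. The
residual $\mathbf{e}_i \sim N(0, \mathbf{R})$ deliberately absorbs the
crossbreds' Mendelian sampling along with environmental noise: the
crossbred's own genetic effect is half of each parental breeding value plus
a Mendelian deviation, and only the transmitted parts are identifiable from
crossbred data.

Because each line contributes only a transmitted effect, the quantity
$h^2_{line} = \sigma^2_{line} / (\sigma^2_{dam} + \sigma^2_{sire} +
\sigma^2_e)$ is a **partial** heritability. Crossbreds are full sibs
through the dam and a full/half-sib mix through the sire, so a conventional
heritability scale is recovered by multiplying by 2 for the common (dam)
line and by a factor between 2 and 4 for the Muscovy (sire) line
(`rescale_heritability()`).

### Gibbs sampler

`cross_gibbs()` samples the joint posterior under flat priors on the fixed
effects and on all three covariance matrices (an improper inverse-Wishart
with density proportional to a constant, i.e. prior degrees of freedom
$-(t+1)$ for $t$ traits). Each iteration:

1. draws the **complete location vector** — all fixed and genetic effects,
   all traits — in a single block from its multivariate-normal full
   conditional, using a sparse Cholesky factorization of the mixed-model
   equations whose symbolic pattern is computed once and refilled
   numerically each iteration;
2. draws $\mathbf{R}$ from its inverse-Wishart full conditional with
   degrees of freedom $n - t - 1$ and scale $\mathbf{E}'\mathbf{E}$;
3. draws $\mathbf{G}_{dam}$ and $\mathbf{G}_{sire}$ from inverse-Wisharts
   with degrees of freedom $q_{line} - t - 1$ and scale
   $\mathbf{U}'\mathbf{A}^{-1}\mathbf{U}$.

Joint-block location sampling was chosen over single-site updating: it
removes the mixing penalty of highly correlated effects (families share
information through the pedigree) and it is the only scheme that is fast in
interpreted R at chains of $10^4$–$10^5$ iterations. One consequence is
that exchanging the two lines' roles reproduces the swapped estimates in
distribution but not bit for bit, because the random-number stream maps
onto a differently ordered location vector; the symmetry is verified
statistically in the test suite.

Starting values are 1 for every variance and 0.01 for every covariance —
read as chain initialization, not as prior information. Defaults follow
the original protocol (chain 100 000, burn-in 20 000); the recovery
analyses in this package use 20 000 / 4 000, which the test suite shows is
sufficient at these data sizes. Component samples are small ($t \times t$
matrices), so they are stored unthinned by default (`thin = 1`); posterior
means of the genetic effects (EBVs) always accumulate over every retained
iteration. Derived quantities — partial heritabilities and genetic
correlations — are computed per retained sample and summarized afterwards
(ratio-then-average). Effective sample sizes (Geyer initial positive
sequence) and a split-chain scale-reduction diagnostic are reported by
`summary()`; genetic-correlation chains mix the slowest and dominate the
chain-length requirement.

Degenerate situations are handled explicitly: a singular scale matrix in a
covariance update is jittered with a warning; a non-finite location draw
aborts with diagnostics; traits are screened (non-blockingly) for
approximate normality with a Kolmogorov–Smirnov test (`check_normality()`),
mirroring the screen applied to the original 11 traits.

### Pedigree machinery

`build_A()` uses the tabular method with exact inbreeding accumulation;
`build_A_inverse()` uses Henderson's rules with the Quaas correction, so
inbred matings in the up-to-five-generation pedigrees are handled exactly.
Both are validated against a two-allele gene-dropping Monte-Carlo oracle
and dense inversion in the tests.

## The chemometric stage

Spectra enter as replicate scans (six surface scans per liver with the
portable instrument, three aliquot scans with the bench instrument), are
trimmed to 800–2500 nm (the visible band is discarded), averaged within
sample, normalized, and derivatized. The retained pre-treatment is the
first derivative calculated on 10 data points with 5-point smoothing on
SNV-normalized spectra; the full grid explored by `default_recipe_grid()`
crosses derivative orders 0/1/2, 0/5/10/15/20 data points, and
none/SNV/detrend/MSC treatments.

Two conventions in that sentence are not defined by their names, so the
package fixes them explicitly:

* **"Calculated on 10 data points"** is read as the gap–segment convention:
  the first derivative at point $i$ is the mean of the `gap` points to the
  right minus the mean of the `gap` points to the left, divided by `gap`
  (point units); order 2 applies the operator twice. A centered
  Savitzky–Golay variant is available behind the same interface
  (`method = "savitzky-golay"`) for sensitivity checks. Edge points without
  full support are dropped — no padding is invented.
* **Operator order** is normalization first, then derivative/smoothing
  ("first derivative … on normalized spectra"), with smoothing applied
  after derivation; the alternative order is a one-line recipe change.

Calibration selects a representative subset (default 198 samples) by
Kennard–Stone on PCA scores retaining 99% of the spectral variance, picks
the number of PLS latent variables by five-group cross-validation
(contiguous blocks of a seeded shuffle), and validates externally on all
remaining samples. The error conventions, which the field names but rarely
defines, are fixed as:

* SEC: $\sqrt{RSS / (n - k - 1)}$ with $k$ latent variables;
* SECV: uncorrected root-mean-square cross-validation residual;
* SEP: standard deviation of external prediction residuals about their
  mean (bias-corrected, $n-1$ denominator), with the bias reported
  separately;
* $R^2$: squared Pearson correlation of fitted vs observed on the
  calibration set (the cross-validated alternative is available from the
  SECV table).

The number of latent variables uses a one-standard-error parsimony
tie-break: the smallest count whose SECV is within one SE (across folds) of
the minimum. PLS1 itself is NIPALS with deflation; at full rank it
reproduces ordinary least squares, and it is cross-checked against an
independent implementation in the tests.

## The synthetic-data generator

`simulate_study()` generates, under one seed: two parental pedigrees, true
breeding values, crossbred phenotypes, and NIR spectra. It is first-class,
tested code — the study conditions, not a tuning knob.

* **Design defaults** mirror the experimental population: 1422 crossbreds
  from 382 common-duck dams and 56 Muscovy sires; pedigrees of 596 and 201
  animals over five generations; 12 systematic levels; melting rate with
  mean 35.6 and SD 14.7.
* **Pedigree shape.** Ancestor generations are allocated with geometric
  decay (each generation roughly half the size of the next: 14/29/57/114
  ancestors behind the 382 dams), the shape real traced-back pedigrees
  have; equal-size ancestor generations would force an implausible
  bottleneck and inflate drift between nominal and realized genetic
  variance. Matings draw sires among males and dams among females of the
  previous generation, producing full- and half-sib structure.
* **Variance split.** The published SD of 14.7 is a total phenotypic SD.
  The systematic-effect SD defaults to 3 (a plausible scale for
  year-batch-feeder differences, in MR percentage points), and the
  genetic-plus-residual total is $14.7^2 - 3^2$, so the phenotypic SD
  matches and the partial heritabilities — which exclude the systematic
  variance — equal the generating fractions exactly. Generating components
  default to the published point estimates (dam 0.20, sire 0.10 for
  measured MR), which is what makes recovery tests against the printed
  values meaningful.
* **Transmitted effects** are simulated exactly as the model assumes: each
  crossbred receives its dam's and sire's full line-specific effect, with
  crossbred Mendelian sampling folded into the residual. Levels are
  assigned in interleaved balanced blocks so families spread across levels.
* **Assumptions the source does not state** (and which are therefore
  package choices, documented here once): residual correlation 0.8 between
  a measured trait and its NIRS prediction (consistent with calibration
  $R^2 \approx 0.85$); the liver-composition relations (lipid regressed on
  MR calibrated to $R^2 \approx 0.58$, dry matter on lipid, protein weakly
  negative on MR, ash uncorrelated); and the spectral forward model —
  absorbance linear in composition through fixed Gaussian bands placed at
  standard NIR features (water/O–H 1450/1940 nm, lipid C–H 1210/1725/2310
  nm, protein N–H 2055/2180 nm) on top of a fixed tissue-matrix absorption
  background common to all samples — real tissue spectra are dominated by
  matrix absorption, and the stable intensity scale it provides is what
  keeps SNV approximately affine in composition — plus per-scan
  multiplicative scatter
  (mean 1, SD 0.05), a random quadratic baseline, an additive offset and
  i.i.d. noise. Spectra are generated directly in absorbance; a
  reflectance conversion would be removed identically by the preprocessing.
* **What passing tests do and do not show.** The generator emulates the
  *statistical* structure the analysis assumes — linear mixed inheritance,
  linear spectral response, well-behaved noise. Real spectra have
  nonlinear scatter, temperature and water-condensation artifacts, and
  real pedigrees have selection and non-random mating. Recovery on
  synthetic data validates the estimators and their implementation, not
  the biology; the published experimental estimates cannot be reproduced
  because the raw data were never deposited.

## Selection-index accuracy

`index_accuracy()` implements classic index theory: weights
$\mathbf{b} = \mathbf{P}^{-1}\mathbf{g}$ and accuracy
$\sqrt{\mathbf{b}'\mathbf{g} / \sigma^2_A}$.
`index_from_components()` assembles $\mathbf{P}$ (phenotypic covariance of
the predictors, $\mathbf{G}_{dam} + \mathbf{G}_{sire} + \mathbf{R}$) and
$\mathbf{g}$ from a fitted model. Which covariances populated the original
calculation is not fully specified, so both coherent readings are exposed:
the default targets a line-specific breeding value
($\mathbf{g} = \mathbf{G}_{line}[,\mathrm{target}]$, target variance
$G_{line}$), the alternative targets the trait's phenotype (both from the
phenotypic covariance). The published accuracy values themselves are not
reproducible — the full covariance matrices behind them were never
published — so the module is verified structurally: the single-predictor
identity (accuracy $= h$), a brute-force grid-search oracle, monotonicity
under added predictors, and unit invariance.

## Problem sizes and numerical choices

The recovery analyses run at the design scale (1422 records; bivariate
runs at 1000) with chains of 20 000 and 4 000 burn-in — sizes at which the
test suite shows posterior means are stable against an independent
numerical-integration oracle (a 30-animal toy integrated on a 3-D grid with
fixed effects marginalized analytically agrees within a few tenths of a
percent). The one-standard-error rule, the Kennard–Stone tie-break (lowest
index on exact ties), the PSD jitter ($10^{-8}$ on the diagonal scale), and
the 1e-8/1e-12 oracle tolerances are all fixed in code and exercised by the
suite.

A note on reproducibility: every stochastic stage takes a seed, a fixed
seed reproduces results bit for bit, and the pipeline driver (`run_all()`)
writes plain-text CSV plus a manifest so any stage can be rerun
independently.

## Known limitations

* Correlation chains mix slowly near $|r| = 1$; at the published values
  (0.95–0.97) effective sample sizes are an order of magnitude below the
  variance chains, and posterior SDs for correlations should be read with
  that in mind.
* With few sires the flat prior leaves a heavy right tail on the sire-line
  variance; posterior means are then tail-sensitive (the oracle comparison
  uses designs where all components are well identified).
* The multi-trait sampler is exercised pairwise, mirroring how the
  original tables are laid out; higher-dimensional joint runs work but are
  not routinely tested.
* No REML estimator is provided; the Bayesian machinery is the product,
  with ANOVA moments and direct integration used only as test oracles.
* Unknown-parent groups, genomic relationships, maternal-environment
  effects and outlier-elimination passes are out of scope.
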