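---
title: "Combining genomic and spectral phenomic information for trait prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining genomic and spectral phenomic information for trait prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Breeding programmes select lines for quantitative traits -- grain yield and
grain protein content (GPC) in spring wheat are the motivating pair -- that
are expensive to phenotype: a line must be grown to maturity, harvested and
assayed. Genomic selection (GS) predicts a line's genetic merit from
genome-wide markers alone, so selections can be made before (or instead of)
field testing. Canopy spectral reflectance adds a second, cheap information
channel: indices computed from a few wavebands (NDVI, GNDVI, water indices,
pigment indices) are heritable, genetically correlated with the primary
traits, and measurable on every plot in minutes. This package implements
the full analysis chain that combines the two sources:

1. plot-level reflectance is averaged and converted to eight spectral
   reflectance indices (SRIs);
2. plot phenotypes from an augmented complete block design (ACBD) are
   adjusted to genotype-level BLUEs per environment;
3. markers are quality-filtered, imputed, and condensed into a VanRaden
   genomic relationship matrix (GRM) $G$;
4. four prediction models are fitted and compared by replicated
   cross-validation and across-environment validation.

# Models

All models operate on genotype-level BLUEs $y$ for $n$ lines.

**Univariate GS (unigs).** The rrBLUP / GBLUP model
$y = \mu + Zu + e$, $u \sim N(0, I\sigma^2_u)$, $e \sim N(0, I\sigma^2_e)$,
whose marker solution is the ridge closed form
$\hat u = Z'(ZZ' + \lambda I)^{-1} y_c$, $\lambda = \sigma^2_e/\sigma^2_u$.
The equivalent line-level form uses $g \sim N(0, G\sigma^2_a)$ with
$G = WW'/(2\sum p_j q_j)$; the identity between the two forms is asserted
numerically in the tests. Variance components come from restricted maximum
likelihood, profiled to a one-dimensional search over
$\delta = \sigma^2_e/\sigma^2_a$: after projecting the fixed effects out
with an orthonormal contrast basis and eigendecomposing the projected
kinship, each likelihood evaluation is $O(n)$, and a bounded Brent search
on $\log\delta \in [-10, 10]$ (tolerance $10^{-8}$) finds the optimum. A
grid oracle in the test suite verifies the optimiser. The basis-projection
formulation (rather than eigenvalue ordering of $SKS$) matters when the
kinship is singular, e.g. the genotype-incidence kinship used for
broad-sense heritability.

**Index-only regression (srir).** Ordinary least squares of $y$ on the
SRIs with intercept -- the phenomics-only baseline.

**Covariate GS (gs_sri).** $y = \mu + X\beta + Zu + e$ with the SRIs as
fixed covariates. The covariates are absorbed into the REML projection;
fixed effects are then GLS estimates at the optimum, and prediction for an
unharvested line is $x'\hat\beta + \hat g$. Cross-validation accuracy uses
this full prediction: dropping $x'\hat\beta$ would discard exactly the
secondary-trait signal the model exists to carry (a flag restores the
centred-GEBV convention).

**Multi-trait GS (multigs).** Primary trait and SRIs are joint responses:
$$ y_j = \mu_j + g_j + e_j, \qquad g \sim N(0, H \otimes G), \qquad
   e \sim N(0, R \otimes I), $$
with unstructured $t \times t$ genetic ($H$) and residual ($R$)
covariances. $H$ and $R$ are estimated by EM-REML on the lines with
complete records. Two transformations make the EM cheap: the projected
GRM is eigendecomposed once, making its rows independent with covariance
$d_i H + R$; and each iteration simultaneously diagonalises $(H, R)$
through a generalised eigendecomposition, so the E-step is a vectorised
$O(nt^2)$ pass. EM stops when the relative log-likelihood change falls
below $10^{-6}$ (500-iteration cap, configurable); $H$ and $R$ are
projected to the PSD cone (eigenvalue floor $10^{-8}$) every step, and the
likelihood trace is retained so monotonicity can be asserted. Prediction
is the conditional BLUP from the multi-trait system including partially
observed lines: a line whose primary trait is missing still contributes
its observed SRIs, which is precisely how secondary information transfers
-- the "spectra collected, plots not harvested" scenario. Test-line
secondary traits enter only this prediction step, never the variance
estimation, so no test primary phenotype leaks into training.

Genetic correlations are read off $H$ as
$r_G = H_{12}/\sqrt{H_{11}H_{22}}$, clamped to $[-1, 1]$ with a boundary
flag when EM overshoots numerically.

**Heritability scale.** Inbred panels (RILs are near-homozygous) have
VanRaden diagonals near $1 + F \approx 2$, so per-line genetic variance is
$\bar{\mathrm{diag}}(G)\,\sigma^2_a$. Heritability is therefore reported
as $h^2 = \bar d\,\sigma^2_a / (\bar d\,\sigma^2_a + \sigma^2_e)$ with
$\bar d$ the mean kinship diagonal; for outbred-coded kinships
($\bar d \approx 1$) this reduces to the familiar ratio.

# Field-trial adjustment

The ACBD model $Y_{ij} = \mu + Block_i + Check_j + e_{ij}$ is fitted to
the replicated check plots with sum-to-zero constraints; each unreplicated
entry's BLUE is its observation minus the estimated block deviation, so
within-block rankings are preserved by construction. A published variant
of the broad-sense heritability formula is dimensionally inconsistent as
printed; the standard plot-basis form
$H^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_e)$ is implemented, with the
genotype variance from the same profiled REML machinery (genotype
incidence kinship; lme4 serves as an independent oracle in the tests).

# The synthetic NAM population

No field data ship with the package, so every claim is calibrated on a
simulator that emulates the study system: a nested association mapping
panel of 32 half-sib families of RILs, one common inbred parent crossed to
inbred founders, each F1 advanced by five rounds of selfing. Meiosis uses
the Haldane no-interference model, implemented as the equivalent
inter-marker Markov chain ($r = (1-e^{-2d})/2$ per adjacent-marker gap,
$r = 1/2$ across chromosome boundaries), which vectorises across lines;
the single-locus selfing Markov chain supplies the oracle for the expected
residual heterozygosity $0.5^g$. Founder haplotypes are i.i.d.
Bernoulli with locus frequencies uniform on $(0.1, 0.9)$ -- linkage
disequilibrium fine-structure and the selection steps applied during real
population development are deliberately not emulated, because the
machinery under test (QC, GRM, REML, CV) is sensitive to relationship
structure, not LD decay. Missingness and single-founder rare alleles can
be injected to exercise QC.

Traits are generated by inverting the analysis model: marker effect
vectors are multivariate normal with covariance equal to the target
genetic correlation matrix, true breeding values are the centred dosages
times these effects (recorded exactly as ground truth), each trait is
scaled so the realised genetic variance equals its target $h^2$ on a unit
total-variance scale, and residuals with the configured residual
correlation are drawn independently per environment.

**Noise enters once.** The genotype-level residual already represents all
non-genetic variation, so the field layout adds block effects (default sd
0.5 trait-sd units) and, by default, no extra plot error. With the
replicated checks then error-free, block deviations are estimated exactly
and the BLUE chain does not double-count noise -- this is what makes
"recover the simulated $h^2$" a well-posed calibration target. Setting
`plot_error_sd > 0` breaks that idealisation on purpose when the
adjustment machinery itself is under test.

Reflectance is generated from three latent axes -- greenness (driven by
the NDVI target), water status (NWI) and pigment composition (PRI) --
mapped log-linearly onto a 16-band baseline canopy spectrum. Exact
inversion of all eight index formulas is over-determined because indices
share bands, so generation is latent-axis based and the calibration is
asserted in tests: recomputed indices correlate above 0.9 with their
latent targets, and all emitted reflectances lie in $(0, 1)$.

# Pre-registered benchmarks

Three simulation experiments, with scales chosen once for statistical
resolution and desk-scale runtimes, back the package's headline claims
(`benchmark_parameter_recovery`, `benchmark_cv_advantage`,
`benchmark_null_calibration`; `scripts/acceptance.R` reruns all three):

* **Parameter recovery.** 20 independent datasets of 500 RILs x 2000
  markers, truth $h^2 = (0.5, 0.8)$ and $r_G = 0.7$ (values mirroring the
  moderate/high-heritability trait pair of interest), through the full
  simulate -> layout -> BLUE -> GRM -> REML chain. Mean $\hat h^2$ lands
  within $\pm 0.05$ and mean $\hat r_G$ within $\pm 0.10$ of truth.
* **Secondary-trait advantage.** One canonical dataset of 600 RILs x 2000
  markers, primary $h^2 = 0.3$, secondary $h^2 = 0.8$, $r_G = 0.7$,
  residual correlation 0.2 (a realistic low-heritability primary /
  high-heritability index pair); 50 replicates of five-fold CV. The
  multi-trait model beats the univariate model (one-sided paired
  comparison), and multi-trait and covariate models agree within 0.03 --
  the configuration's two qualitative headline findings.
* **Null calibration.** With $h^2 = 0$ the CV accuracy must be
  statistically zero. A single dataset's null accuracy carries sd
  $\approx 0.07$ of family-structured kinship noise (the quadratic form
  $y' (G - \mathrm{diag}\,G)\, y$ does not shrink with more replicates),
  so calibration is judged on the mean across 12 independent null
  datasets, which is required to sit within $\pm 0.05$ of zero.

Passing these shows the chain is internally consistent and correctly
calibrated under its own generative assumptions. It does not certify
behaviour on real field data, whose LD structure, spatial trends,
genotype-by-environment interaction and non-Gaussian errors the generator
deliberately omits.

# Numerical and interface decisions

* **QC order and idempotence.** Lines with excess missingness are removed
  before markers, then low-MAF markers (MAF $\ge 0.1$ kept, below
  discarded). Because each removal changes the other dimension's missing
  fractions, the three filters iterate to a fixed point, making the
  filter idempotent; the report accumulates per-step counts.
* **GRM.** VanRaden method 1 with eigenvalue flooring at $10^{-8}$ so a
  Cholesky always exists downstream; mean imputation precedes it.
* **Band matching.** The radiometer's 16 band centres need not equal the
  wavelengths the index formulas cite; each required wavelength resolves
  to the nearest available band within 15 nm (error beyond). Denominator
  bands at or below $10^{-9}$ make the index missing, never infinite.
  Readers accept percent or fractional reflectance and normalise when the
  maximum exceeds 1.5. Averaging precedes index computation
  (index-of-mean, not mean-of-index). All eight indices are invariant to
  a common scale factor -- including the anthocyanin index, whose leading
  $R_{800}$ factor cancels the scale of its inverse-reflectance
  difference.
* **Cross-validation.** Per replicate, lines are shuffled into five folds
  (sizes within one), held-out predictions are pooled, and one Pearson
  accuracy is recorded; means and SEs aggregate over 100 replicates
  organised as two 50-replicate sets. Every replicate draws its own
  substream of the root seed, so any stage reruns identically.
* **Improvement reporting.** Percent improvements are reported raw and at
  reporting precision (whole percent; one decimal below 10), and the
  cross-environment mean is computed from the unrounded values. A
  non-positive baseline makes the improvement undefined (reported
  missing), not infinite.
* **Checks** are excluded from prediction and training sets by default
  (they are replicated controls, not selection candidates); the BLUE
  tables retain them behind their flag.

# Known limitations

Single-environment fits only (no across-year combined model and no
genotype-by-environment covariance); block designs without spatial row /
column modelling; mean imputation rather than haplotype-aware methods;
rrBLUP-family models only -- Bayesian variable-selection and kernel
models are out of scope. EM-REML converges slowly when an optimum lies
near the PSD boundary (e.g. duplicated traits); the iteration cap then
returns the last iterate with a warning and the boundary genetic
correlation is clamped and flagged.
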