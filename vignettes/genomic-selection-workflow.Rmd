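---
title: "Models and methods: genomic prediction and selection response in gsresp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: genomic prediction and selection response in gsresp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gsresp` implements a complete genomic-selection analysis for a diverse crop
collection evaluated in multi-environment field trials: marker quality
control and genomic relationships, two-stage mixed-model analysis (spatial
adjustment, then GBLUP variance components), cross-validated prediction
accuracy under multi-trait scenarios, and the comparison of selection
indices through expected selection response. The motivating use case is a
safflower diversity panel — roughly 350 accessions genotyped at ~7,000
GBS-derived SNPs and phenotyped for eight agronomic traits (days to
flowering DF, days to maturity DM, flowering time FT, plant height PH,
seed weight SW, grain yield GY, seed protein PC, oil content OL) in
replicated row–column trials at four environments — but every function is
panel-agnostic.

This vignette records the models, the estimation machinery, the design of
the synthetic-data generator, and the choices made where the design was
genuinely open.

## The two-stage model

**Stage 1 (per trial).** Plot values are modelled with fixed accession and
replicate effects and a separable spatial residual,

$$y = X\beta + \varepsilon,\qquad
  \varepsilon \sim N\!\big(0,\ \sigma^2\, \mathrm{AR1}(\rho_r)\otimes
  \mathrm{AR1}(\rho_c)\big),$$

where the AR1 factors act along the row and column indices of the field
grid (1-based indices; "distance" is index difference, not metres). The two
autocorrelations are estimated by profiling the restricted likelihood on a
grid (step 0.05 by default) followed by Nelder–Mead refinement on the
atanh scale; fixed effects are then generalized least squares at the
optimum. Replicates use sum-to-zero contrasts so an accession's BLUE is its
estimated mean at the average replicate. Missing plots are handled by
observed-submatrix GLS: the Kronecker precision is corrected by a Schur
complement on the missing cells rather than imputing them. Stage 1 is
deliberately minimal — no nugget, no random row/column terms — because the
BLUEs it feeds forward absorb any remaining smooth trend into the AR
parameters; the plot-level multivariate fit (below) is the place where row
and column effects are modelled explicitly.

**Stage 2 (across accessions).** Accession BLUEs are treated as phenotypes
(unweighted, i.e. stage-1 standard errors are not carried forward). The
univariate genomic model for one trait at one site is

$$y = \mu + g + e,\qquad g \sim N(0,\, G\,\sigma^2_A),\quad
  e \sim N(0,\, I\,\sigma^2_e),$$

with $G$ the VanRaden (method 1) genomic relationship matrix,
$G = WW' / (2\sum_j p_j(1-p_j))$, $W$ the dosage matrix centred at twice
the observed allele frequencies. Narrow-sense heritability is
$h^2 = \sigma^2_A/(\sigma^2_A + \sigma^2_e)$; with an identity
relationship the same ratio is the broad-sense $H^2$.

The multi-trait model stacks 2–3 traits with genetic covariance
$T \otimes G$ and residual covariance $R$ per accession; the additive
genetic correlation between traits $x$ and $y$ is
$r_A = \mathrm{cov}_A(x,y)/\sqrt{\sigma^2_{Ax}\sigma^2_{Ay}}$ and the
phenotypic correlation uses $P = T + R$. The genotype-by-environment model
for one trait across $S$ sites adds site-specific interaction deviations,

$$y = X b + Z g + Z_2\, gE + e,\qquad
  gE \sim N\!\big(0,\ (I_S \otimes G)\,\sigma^2_{g\times e}\big),$$

with site as a fixed effect and the main additive effect $g$ shared across
sites.

## REML estimation

All balanced fits use two diagonalizations. The relationship matrix is
eigendecomposed once, $G = U D U'$, and the data rotated by $U'$. For the
multi-trait model, $(T, R)$ are then simultaneously diagonalized
($W'RW = I$, $W'TW = \Lambda$), which turns every per-eigencomponent
covariance $d_m T + R$ into a diagonal matrix: a full restricted-likelihood
evaluation costs $O(nt)$ flops. The g×E covariance
$d_m(\sigma^2_A J_S) + (d_m \sigma^2_{g\times e} + \sigma^2_e) I_S$ has a
closed-form inverse by the Sherman–Morrison identity, so the same applies.

Variance parameters are optimized on a log-Cholesky parameterization
(which cannot leave the positive-definite cone): a short Nelder–Mead phase
for robustness, then BFGS with the *analytic* REML gradient, derived in the
rotated basis where each parameter's gradient collapses to one entry of a
small matrix product. The quasi-Newton phase pins the optimum to near
machine precision, which is what makes REML estimates reproducible and
exactly equivariant to trait rescaling (traits are standardized internally
and components mapped back, so the optimization problem is literally
identical under rescaling). We chose this direct-maximization design over
classical average-information REML with EM safeguarding: with $O(nt)$
evaluations the optimizer's robustness/cost trade-off favours simple
quasi-Newton steps, and there are no AI updates that can leave the
parameter space. The univariate model needs only a one-dimensional profile
likelihood in the variance ratio, optimized by Brent search.

Convergence: relative log-likelihood change below $10^{-15}$ in the BFGS
phase (effectively gradient-limited), maximum 4000 evaluations. Variance
floors are $10^{-8}\times$ the phenotypic variance; estimated correlations
are clipped to $[-0.999, 0.999]$ so boundary fits remain usable. Unbalanced
data (records missing for a subset of traits) fall back on a dense
multivariate-normal restricted likelihood over the observed records — the
same machinery that produces conditional GEBV predictions for partially
phenotyped accessions.

Degenerate inputs: a constant phenotype vector returns floor variances and
exactly zero GEBVs; an all-missing marker is an explicit error in
imputation; a GRM that is only positive *semi*-definite should be passed
through `condition_grm()`, which ridges the diagonal by $10^{-6}$ without
touching off-diagonal relationships.

## Cross-validation

`make_folds()` builds five-fold plans repeated five times (fold sizes
differing by at most one; 349 accessions split 70/70/70/70/69), fully
determined by a seed. Within every training fold the variance components
are re-estimated from scratch — the training data are balanced, so the fast
rotated path applies — and validation GEBVs are conditional means given the
visible records. Under MT-CV1 the validation accessions' secondary-trait
BLUEs are visible at prediction time (they enter the conditional mean, not
the component estimation); under MT-CV2 they are masked, leaving only the
genomic relationship to the training fold. Accuracy is the plain Pearson
correlation between predicted GEBVs and the held-out BLUEs, not divided by
$\sqrt{h^2}$; means and SDs are over all 25 validation sets.

## Selection indices and response

Seven selection strategies are compared, all selecting the top 20%
(`floor(0.2 n)`, ties broken towards the lexicographically smaller
accession id):

* **PS** — phenotypic selection on the site's BLUEs;
* **SGS** — univariate-GBLUP GEBVs;
* **MGS** — GEBVs for the target trait from the bivariate fit with plant
  height;
* **MTGS1** — equally weighted sum of *standardized* GEBVs of grain yield
  and oil content;
* **MTGS2** — Smith–Hazel weights $b = P^{-1} g$ applied to *raw* GEBVs
  ($P$ the phenotypic covariance of the two traits, $g$ the vector of
  their additive genetic variances; the weights already carry units, hence
  no standardization);
* **g×EGS** — the across-site main-effect GEBVs from the g×E model;
* **g×EMTGS1** — MTGS1 built from g×E main-effect GEBVs of both traits.

For a selected set $s$ evaluated at a site, the selection differential is
$S = \bar y_s - \bar y$, the response follows the breeder's equation
$R = h^2 S$ with that site's univariate narrow-sense $h^2$ (even when the
selection used an index of several traits), and the percentage gain is
$100\,R/\bar y$ with $\bar y$ the evaluation site's population mean.
Cross-site response scores the *same* candidates against every other
site's values with that site's $h^2$.

Two open points were settled as follows. The "combined" g×E GEBVs used for
g×EGS are the main effects only, not main plus site deviation: the main
effect is the across-site transferable component, which is what a
selection targeting all environments should rank on. And $b = P^{-1}g$ is
implemented with $g$ as the vector of additive genetic variances — the
definition stated with the index — rather than the classical
genetic-covariance-times-economic-weights form; the two coincide when
genetic covariances vanish.

## The synthetic-data generator

The generator is first-class, tested code that emulates the study's
structure so that the whole pipeline is exercisable without any download:

* **Genotypes.** 349 accessions × 6,911 biallelic SNPs by default; allele
  frequencies uniform on [0.05, 0.5], dosages as two binomial draws per
  line (Hardy–Weinberg), calls masked completely at random at rate 0.2.
  The defaults emulate the *post-QC* panel, so the filtering stage retains
  everything at the default thresholds; tests exercise the filter on
  hand-built panels instead.
* **Genetic effects.** Additive values are sums of i.i.d. normal marker
  effects over the centred dosages, then linearly rescaled so the
  in-sample covariance of the true breeding values equals the target $T$
  exactly. Exact scaling removes Monte-Carlo drift from recovery tests:
  estimator error is then attributable to the estimator, not the
  generator. Interaction deviations gE are likewise marker-effect sums,
  drawn independently per site and scaled to their target variance —
  i.i.d. per-line deviations would be statistically indistinguishable from
  residual error, and no interaction model could (or should) recover them.
* **Trait structure.** The default $T$ and $R$ diagonals follow published
  per-trait estimates for such a panel at an optimal irrigated site (e.g.
  GY: $\sigma^2_A = 0.682$, $\sigma^2_e = 0.557\ \mathrm{t^2/ha^2}$; PH:
  176.3 and 61.8 cm²); genetic correlations encode the reported pattern
  (GY–PH ≈ 0.45, GY–OL ≈ 0.19, SW–OL and SW–PC ≈ −0.45, OL–PC ≈ 0.3,
  PC–GY ≈ −0.3). Site means step grain yield from 3.0 t/ha (optimal,
  irrigated) to 1.7, 1.0 and 1.1 t/ha under increasing water stress; the
  g×E variance defaults to 0.4 σ²A per trait.
* **Field trials.** Each site is a 25 × 28 grid of 1-based row/column
  positions; each of the two replicates occupies a contiguous block of
  columns (complete randomization within replicate — the source design is
  an RCBD without a published plot map, and two replicates is our default
  for its "2–3 replications"). Plot values add site mean, additive effect,
  site interaction, random row and column effects (variance 0.25 σ²e
  each), and a separable AR1(0.4) ⊗ AR1(0.4) residual field with marginal
  trait covariance $R$.
* **Accession-level phenotypes.** `simulate_blues()` generates
  BLUE-like records directly (site mean + g + gE + residual with
  covariance $R$) for experiments where stage 1 is not under study.

**What the generator does *not* emulate — and what that implies.** Markers
are unlinked and lines unrelated: there is no LD and no population
structure. GBLUP prediction into unrelated validation lines then works
only through marker-effect estimation, so absolute cross-validation
accuracies are low (≈0.05–0.2 at the default scale) compared with values
reported for real panels (≈0.3–0.6), where relatedness and LD carry most
of the signal. Scenario *contrasts* (CV1 > UV when the secondary trait is
informative; CV2 ≈ UV; accuracy increasing with $h^2$) are preserved, and
those contrasts — not the absolute level — are what the test suite
asserts. Likewise, a single realization of the genetic effects is shared
by all sites, so per-site heritability estimates are correlated across
sites and can sit collectively above or below their targets for a given
trait; recovery tests therefore average over independent genotype
realizations (20 seeds). Finally, the generator keeps the genetic variance
constant across sites while the site means differ, whereas in the real
study the genetic variance shrinks with the mean under stress. Because
percentage gain divides by the site mean, this single-$T$ design inflates
the stressed sites' percentages and confounds the cross-site "balanced
gain" comparison; the g×E-balance property is therefore evaluated on
simulations with equal site means and moderate interaction variance
(σ²g×e = 0.5 σ²A), which isolates the transfer effect the claim is about.

Imputation interacts with the relationship matrix: marker-mean filling
shrinks marker variance by ≈(1 − missing rate), deflating the GRM diagonal
(≈0.8 at 20% missingness) and inflating fitted additive variances by the
reciprocal; kNN filling with discrete dosages keeps the diagonal near 1
(≈0.97) and is used in the analysis scripts. Neither filler attempts the
LD-based imputation used on real GBS data — imputation quality is not this
package's contribution, and all downstream tests are imputation-agnostic
(simulation-based checks use complete panels).

## Problem sizes and tolerances used by the tests

Parameter-recovery and CV property checks run at 300 lines × 2,000 markers
over 20 seeds — large enough that mean recovery errors stay within ±0.1
(heritability) and ±0.15 (genetic correlation) while the full suite runs
in a few minutes; oracle-equivalence checks run at 20 lines against dense
linear algebra (grid of 200 ratio values, agreement to 10⁻⁴) and a 2 × 2
field against dense GLS (10⁻⁸). The Hardy–Weinberg GRM diagonal check uses
300 × 2,000 (±0.1). Marker-level arithmetic (MAF, filters, VanRaden
entries, Smith–Hazel weights, selection differentials) is asserted
exactly against hand-computed values.

## Known limitations

* Multi-trait fits support 2–3 traits (direct parameterization of $T$ and
  $R$); larger trait sets would want factor-analytic structures.
* The g×E model assumes a common interaction variance across sites
  (compound-symmetry-free, one $\sigma^2_{g\times e}$) and requires the
  accession set to be observed at every site (others are dropped with a
  warning).
* The plot-level multivariate fit with row/column effects uses a dense
  covariance and is intended for modest trial sizes (hundreds of plots).
* Stage-2 fits are unweighted: stage-1 BLUE standard errors are not
  propagated.
* No dominance or epistasis, no Bayesian marker-effect alternatives —
  GBLUP through the GRM throughout.
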