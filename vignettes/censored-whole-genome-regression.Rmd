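---
title: "Censored whole-genome regression of years of life: model, priors and evaluation"
author: "wgplife"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored whole-genome regression of years of life}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(wgplife)
```

This vignette documents the statistical model behind `fit_wgp()`, the
choices the package makes where several defensible options exist, what the
synthetic cohort generator does and does not emulate, and the numerical
safeguards in the sampler. Nothing here reports an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The model

Years of life (YL, age at death) of individual $i$ is modeled as

$$ y_i = \mu + w_i'\beta_F + \sum_{j=1}^p x_{ij}\beta_j + u_i + \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma^2_\varepsilon), $$

where $x_{ij} \in \{0,1,2\}$ counts copies of the minor allele at SNP $j$
(columns are centered before sampling; the intercept absorbs the
centering). The model is a standard whole-genome regression except that
$y_i$ is latent whenever the record is censored: a participant alive at
age $C_i$ when follow-up ends contributes only $y_i > C_i$. Left- and
interval-censored records are handled symmetrically. Ignoring censoring —
treating ages at censoring as ages at death — biases the location
parameters downward, which the test suite demonstrates on a Tobit fixture
with 50% fixed-point censoring.

**Data augmentation.** Each Gibbs sweep draws the latent outcome of every
censored record from its normal full conditional truncated to the
censoring interval. With the latent vector in hand, all remaining updates
are the conjugate updates of an uncensored Gaussian model, which is the
entire appeal of the augmentation scheme.

**Priors.** Fixed effects (intercept, sex and smoking dummies, spline
coefficients, optional PC covariates) carry flat priors, so their
posterior means essentially reproduce likelihood-based estimates. Marker
effects follow the Park–Casella Bayesian LASSO with the marker variance
scaled by the residual variance:

$$ \beta_j \mid \tau^2_j, \sigma^2_\varepsilon \sim N(0, \tau^2_j
\sigma^2_\varepsilon), \qquad \tau^2_j \sim \mathrm{Exp}(\lambda^2/2),
\qquad \lambda^2 \sim \mathrm{Gamma}(s, \delta), $$

$$ \sigma^2_\varepsilon \sim \text{scaled-inv-}\chi^2(df, S), \qquad
u \sim N(0, A\,\sigma^2_u) \text{ (optional)}. $$

The $\sigma^2_\varepsilon$-scaling of the marker variances (the original
Park–Casella parameterization, also used by the BLR/BGLR software family)
keeps the shrinkage scale-free; its consequence is that the residual
variance full conditional pools the residual sum of squares with
$\sum_j \beta_j^2/\tau_j^2$ and degrees of freedom $df + n + p$.

**Full conditionals.** $1/\tau^2_j$ is inverse-Gaussian with mean
$\sqrt{\lambda^2\sigma^2_\varepsilon/\beta_j^2}$ and shape $\lambda^2$;
$\lambda^2$ is Gamma with shape $p + s$ and rate $\sum_j \tau^2_j/2 +
\delta$; marker effects are updated by single-site Gibbs in fixed column
order with running-residual bookkeeping (cost $O(np)$ per sweep,
implemented in C++); the pedigree effect is parameterized as $u = L\alpha$
with $L$ the Cholesky factor of $A$, so the $\alpha_k$ are conditionally
independent and reuse the same single-site kernel. The update cycle is:
augment outcomes, location effects (fixed, marker, pedigree), $\tau^2$,
$\lambda^2$, variances. Every update is verified against its analytic
conjugate density by Kolmogorov–Smirnov tests on a small fixed instance,
and the joint sampler passes a successive-conditional (Geweke-style)
comparison with forward simulation from the prior on a tiny proper-prior
model.

## 2. Hyper-parameter defaults

The four hyper-parameters follow the weakly-informative guideline of
centering the prior on a plausible variance partition with prior
heritability $h_0^2 = 0.25$ — the classical twin/familial estimate for
human lifespan:

* $df = 5$, and $S$ set so the prior mode of $\sigma^2_\varepsilon$
  equals $(1-h_0^2)\,V_y$, i.e. $S = (1-h_0^2)V_y(df+2)$, with $V_y$ the
  sample variance of YL among observed deaths;
* $s = 1.1$, and $\delta$ set so the prior mode of $\lambda^2$ equals
  $\lambda_0^2 = 2\frac{1-h_0^2}{h_0^2}\sum_j \mathrm{var}(x_j)$.

All four are overridable through `bl_hyper()`. At the sample sizes the
package targets these priors have little influence on predictions; they
mainly stabilize the chain when marker counts exceed the sample size.

**Chain defaults** (`chain_control()`): 30,000 sweeps, 5,000 burn-in,
thinning 10, a single chain, and an explicit integer seed from which runs
are bit-reproducible. Tests and the acceptance script use shorter,
explicitly stated chains sized to their fixtures.

## 3. Model ladder and design matrix

Models are named `<A|B>-<suffix>`: `A` = intercept + sex + 4-df natural
cubic spline of age at entry; `B` = `A` + smoking + 4-df spline of BMI;
the suffix adds markers (`2.5K` etc., thinned evenly over the map by the
floor-index rule `floor(j*p/k)`), the first two genotype principal
components (`GWPC`), or a pedigree effect (`PED`). With 4 df the spline
places interior knots at the 25th/50th/75th sample percentiles and
boundary knots at the range; natural splines are linear beyond the
boundary, so out-of-range evaluation on held-out folds is well defined
(and logged). Knots are stored at fit time and reused verbatim for
prediction — fold predictions never re-knot.

Decisions worth recording:

* *Anchoring of "evenly spaced" marker subsets* is by array index over the
  map order (the floor rule above); genomic-coordinate anchoring would
  need physical positions the inputs do not require.
* *BMI* enters as the single provided (baseline) measurement.
* *Smoking* is a binary ever/never contrast; *sex* is a female-vs-male
  dummy, so both published-style contrasts are single coefficients.
* The *R² baseline* (intercept + entry age) uses the same 4-df spline as
  model `A`, and is refit inside each training fold so the denominator
  never sees held-out data. A full-data baseline variant exists for
  fidelity experiments.
* *DIC* uses the **observed-data** deviance (normal density for deaths,
  tail/interval probabilities for censored records), with posterior means
  of all location parameters and of $\sigma^2_\varepsilon$ plugged in for
  $\hat D$. An augmented-data deviance would reward the model for
  imputations it generated itself.

## 4. Evaluation metrics

* **CV R²** $= 1 - \sum_{\text{dead}}(y_i-\hat y_i)^2 /
  \sum_{\text{dead}}(y_i-\bar y_i)^2$ with $\bar y_i$ the out-of-fold
  baseline prediction. Observed deaths are not a random sample of the
  cohort, which motivates the second metric.
* **Longitudinal AUC(τ)** for τ = 60, 65, …, 95: cases died before τ,
  controls known alive at τ, records censored before τ are undetermined
  and excluded. The risk score is fixed as *minus* the predicted YL
  rather than auto-oriented — auto-direction can silently flip across
  folds, and a fixed orientation is falsifiable. Ties count ½
  (Mann–Whitney convention); the computation delegates to pROC and is
  tested against exhaustive pair enumeration.
* **Absolute-error profiles** over the bins YL ≤ 65, (65,70], …, (90,95],
  YL > 95, with ±1.96·SE intervals.
* **Folds** hold out individuals or entire families, where a family is a
  connected component of the parent–offspring graph. PC covariates are by
  default computed once on the full panel before splitting — mirroring a
  whole-cohort analysis — and the report flags this leakage; a strict
  within-fold PCA mode is available.
* `count_training_relatives()` reports, for each subject, how many direct
  relatives (father, mother, offspring, full sib — full sibs share both
  known parents) sit in other folds, overall and restricted to uncensored
  relatives: the diagnostic for how much familial information a CV
  actually exposes.

## 5. The synthetic cohort generator

`sim_config()` defaults emulate the demographic skeleton of the classic
longitudinal heart-study cohort this methodology targets: ~5,100 adults
(1,900 unrelated singletons plus 800 two-offspring nuclear families),
entry age normal(37, 9) truncated at 18, 55% female, 64% ever-smokers,
BMI normal(25.0, 4.1). Years of life are generated **on the scale of the
analysis model itself** — a covariate surface (sex +3.1 y, smoking
−4.1 y, a quadratic BMI penalty of 0.043 y per (kg/m²)² around an optimum
of 22.5) plus an additive genetic value scaled to $h^2 = 0.25$ of a
110 y² genetic-plus-residual variance, plus Gaussian noise — rather than
through hazard functions. That choice makes recovery tests sharp (the
generating process is the fitted model) at the cost of demographic
realism.

Censoring is administrative: enrollment years are uniform over 1958–1982
and survival is ascertained through 2007, so the censoring age
$C_i = \text{age}_i + (2007 - \text{entry year}_i)$ depends only on entry
information, never on the genetic value or the residual — the
independent-censoring property the model assumes. The window was
calibrated once so that about two thirds of default-demography records
are censored, matching the emulation target; the historical two-wave
enrollment of the real cohort is deliberately simplified to a uniform
window. Note that whether a subject *is* censored necessarily depends on
their lifespan; the ignorability audit in the tests therefore checks that
the censoring *time* is uncorrelated with the genetic value within
entry-year strata.

Genotypes: ancestral allele frequencies uniform on the configured MAF
range; optional subpopulations diverge by the Balding–Nichols Beta
construction at a configured $F_{st}$; founders are in Hardy–Weinberg
equilibrium within subpopulation; offspring descend by Mendelian gene
dropping (each parental transmission Binomial(1, dosage/2), valid for
unlinked loci). A configurable fraction of markers (default 10%) carries
Gaussian effects, allowing sparse through infinitesimal-like regimes.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: linkage disequilibrium (marker panels tag
causal variants only through themselves, so thinned panels capture
proportionally less signal than LD-rich real panels), age-dependent
hazards and competing risks, assortative mating, genotyping error, and
any dependence of YL on birth cohort beyond the enrollment window.

## 6. Numerical choices

* **Truncated normal draws** use CDF inversion after reflecting the
  interval into the lower tail, where `pnorm`/`qnorm` keep full relative
  accuracy; this is exact and stable for bounds beyond 30 standard
  deviations. If an interval's normal mass underflows entirely, a
  shifted-exponential rejection sampler takes over.
* **Inverse-Gaussian draws** use the Michael–Schucany–Haas
  transformation, with the quadratic root written in a
  cancellation-free form.
* $1/\tau^2_j$ is **capped at $10^{12}$** when $\beta_j$ underflows,
  guarding the division by $\beta_j^2$.
* **Monomorphic markers** (zero variance after imputation) are retained
  but flagged; their effects are pinned at zero and their columns are
  skipped by the sweep.
* Missing dosages are **mean-imputed per marker** at load time; the
  package deliberately does no further genotype QC or imputation.
* The Gibbs state is checked for non-finite values each sweep; a failure
  aborts with the iteration index. Retained draws additionally assert
  that no latent outcome violates its censoring bounds.
* The single-site C++ kernel updates the coefficient vector and running
  residual **in place**; `fit_wgp()` always passes freshly allocated
  buffers, and the kernel is internal for exactly this reason.

## 7. Problem sizes used by the tests

The suite exercises the full pipeline at desk scale, chosen so the whole
suite runs in a few minutes: conjugate-oracle KS checks on a 5-observation,
3-marker instance ($10^5$ draws each); Tobit recovery at $n = 500$ with
50% censoring; genetic-value recovery at $n = 800$, $p = 1{,}000$,
$h^2 = 0.25$, ~30% censoring with a 30,000-sweep chain; the model-ladder
monotonicity experiment at $n = 2{,}000$, $p = 2{,}000$ causal markers
(heritability 0.5 for this experiment, so that each ladder rung adds
resolvable signal in the absence of LD); cross-validation orderings at
$n \approx 1{,}500$ over ten seeds with lighter (~30%) censoring so that
enough observed deaths enter the R² sums. These sizes are the package's
own choices for its fixtures, stated here so results are interpreted at
the scale they were computed.

## 8. Known limitations

* A single chain per fit; convergence assessment beyond seed-replication
  and the Geweke-style test is left to the user.
* No alternative whole-genome priors (BayesB, GBLUP kernels) and no
  genomic relationship matrices — the pedigree comparator uses expected,
  not realized, relatedness.
* The observed-data DIC convention plugs in posterior means of location
  parameters and $\sigma^2_\varepsilon$; other plug-in conventions exist
  and give slightly different $p_D$.
* CV R² is computed over observed deaths only and inherits their
  non-random selection; the longitudinal AUC is the counterweight, and
  both are reported per fold as well as pooled.
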