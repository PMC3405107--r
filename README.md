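# wgplife

Whole-genome prediction of human **years of life (YL)** — age at death —
under censoring.

Most participants of a longitudinal cohort are still alive when a survival
snapshot is taken, so their YL is only known to exceed the age attained at
that point. `wgplife` fits a Bayesian LASSO whole-genome regression that
treats such records correctly, and ships the full evaluation stack needed
to ask *how much of the inter-individual variation in lifespan can dense
SNP panels predict, beyond sex, age at entry, smoking and BMI?* — the
question this model family was developed for in a cohort of ~5,100 adults
genotyped on a 500K array, where whole-genome markers raised the
cross-validated R² from about 12% to about 21% and most of the gain came
from better prediction of early mortality.

## The model

For individual *i* with SNP dosages `x_ij` (minor-allele counts 0/1/2):

```
y_i = mu + w_i' beta_F + sum_j x_ij beta_j + u_i + e_i ,   e_i ~ N(0, sigma2_e)
```

* `y_i` — years of life; observed for the deceased, otherwise **latent**.
  A record censored at age `C_i` contributes the constraint `y_i > C_i`
  (right), `y_i < C_i` (left) or `a_i < y_i < b_i` (interval). Each Gibbs
  sweep imputes latent outcomes from their truncated-normal full
  conditionals (Tobit-style data augmentation), after which every other
  update is conjugate.
* `w_i' beta_F` — fixed effects with flat priors: intercept, sex dummy,
  4-df natural cubic spline of age at entry (interior knots at the sample
  quartiles), smoking dummy, 4-df spline of BMI, optionally the first
  genotype principal components.
* `beta_j` — marker effects under the Park–Casella Bayesian LASSO:
  `beta_j ~ N(0, tau2_j sigma2_e)`, `tau2_j ~ Exp(lambda2/2)`,
  `lambda2 ~ Gamma(s, delta)`; the reciprocal `1/tau2_j` has an
  inverse-Gaussian full conditional.
* `u_i` — optional additive infinitesimal (pedigree) effect,
  `u ~ N(0, A sigma2_u)` with `A` the pedigree relationship matrix,
  sampled through its Cholesky factor.

Model comparison uses the **observed-data DIC** (normal densities for
deaths, normal tail/interval probabilities for censored records).
Prediction accuracy uses a **cross-validated R²** against an
intercept + entry-age baseline computed over observed deaths only, the
**longitudinal AUC(τ)** for survival status at thresholds τ = 60, …, 95
(records censored before τ are undetermined and excluded), and
absolute-error profiles by age-at-death bin. Folds can hold out
individuals or entire families (pedigree connected components).

A synthetic cohort generator (Balding–Nichols population structure,
Mendelian gene dropping through nuclear families, additive marker effects
scaled to a target heritability, administrative right-censoring driven by
an enrollment window) provides ground-truth data for every test.

## Worked example

```r
library(wgplife)

cfg <- sim_config(n_founders = 300, n_families = 100, p = 500,
                  h2 = 0.25, seed = 42)
sim    <- simulate_cohort(cfg)
cohort <- sim$cohort
cohort
#> cohort_data: 700 individuals, 500 markers (0 monomorphic)
#>   outcomes: observed=220, right=480
#>   pedigree: 700 rows

models <- list(
  "B-0"   = model_spec(c("sex", "age_spline", "smoking", "bmi_spline"),
                       name = "B-0"),
  "B-500" = model_spec(c("sex", "age_spline", "smoking", "bmi_spline"),
                       markers = 1:500, name = "B-500"))

fit <- fit_wgp(cohort, models[["B-500"]],
               chain = chain_control(4000, 1000, 3, seed = 7))
unlist(dic(fit))
#>           DIC            pD mean_deviance
#>    1956.75738      49.19847    1907.55892
round(fit$posterior$beta_F[c("sexF", "smokingEver")], 2)
#>        sexF smokingEver
#>        3.98       -5.26
```

About two thirds of the cohort is censored (the administrative default),
so the 4,000-sweep chain imputes 480 latent lifespans per sweep. The DIC
decomposition shows ~49 effective parameters for 511 location effects —
the LASSO prior is shrinking hard. The sex and smoking contrasts recover
the generating values (+3.1 and −4.1 years) within posterior uncertainty
at this sample size.

```r
plan <- make_folds(cohort$ids, k = 5, unit = "individual", seed = 1)
cv <- run_cv_experiment(cohort, models, plan,
                        chain = chain_control(1500, 400, 4, seed = 1),
                        thresholds = c(70, 80, 90))
cv
#> cv_report: 5-fold (individual units)
#>  model    overall
#>    B-0 0.05206763
#>  B-500 0.05863140
round(cv$auc, 3)
#>       tau70 tau80 tau90
#> B-0   0.608 0.643 0.772
#> B-500 0.623 0.642 0.786
```

Out-of-fold predictions from the covariate model explain ~5% of the
variance in YL among the 220 observed deaths beyond the entry-age
baseline; adding 500 markers nudges R² and the early-threshold AUC
upward — at n = 700 the genomic gain is real but small, and it grows with
cohort size (see the methods vignette for the scaling experiments).

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/wgp-yl.R simulate --config run.yaml
Rscript inst/scripts/wgp-yl.R fit      --config run.yaml
Rscript inst/scripts/wgp-yl.R cv       --config run.yaml
```

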