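---
title: "Modelling common and substance-specific liability with polygenic scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling common and substance-specific liability with polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsoPGS)
```

## The scientific problem

Adolescents and young adults who use one class of psychoactive substance
tend to use others. The common-liability model attributes this
co-occurrence to a single latent propensity shared across substances,
over and above substance-specific liabilities (for example, variation in
nicotine metabolism that matters for cigarettes only). tsoPGS implements
a genetically informed test of that model: repeated substance-use scores
are decomposed into a common factor, substance-specific factors and
occasion factors by a trait-state-occasion (TSO) structural equation
model, and polygenic scores (PGSs) indexing substance-use behaviours and
broader vulnerabilities are regressed on the latent factors, not the raw
scores.

The measurement design mirrors a longitudinal cohort: four substance
classes — cigarettes (an FTND-type severity score, 0-10), alcohol
(AUDIT-type, 0-40), cannabis (CAST-type, 0-24) and a count of other
illicit substances (0-15) — each measured at three ages (17, 20, 22),
giving 12 bounded, right-skewed, partially missing indicators.

## The model

Write $y_{kt}$ for the score of substance $k$ at occasion $t$. The
baseline measurement model is

$$ y_{kt} = \nu_{kt} + \lambda^{C}_{kt}\, C + \lambda^{S}_{kt}\, S_k +
   1 \cdot O_t + \varepsilon_{kt}, $$

with a common liability $C$ loading on all 12 indicators, one specific
factor $S_k$ per substance loading on its three repeated scores, and one
occasion factor $O_t$ per wave with loadings fixed to 1 on the four
same-wave indicators. All factor variances are fixed to 1, factors are
mutually orthogonal, and the 12 residual variances and 12 intercepts are
free. The covariance structure therefore spends
$12 + 12 + 12 = 36$ free parameters on $12 \cdot 13/2 = 78$ unique
moments, leaving **42 degrees of freedom**. `buildTSOSpec(4, 3)`
constructs exactly this pattern; `modelDf()` returns 42.

Classic TSO parameterisations allow autoregression among the occasion
factors. We fix occasion loadings and variances and omit autoregressive
paths: this is the unique constraint set consistent with 42 degrees of
freedom for this design, and with the occasion factors' role of
absorbing wave-specific covariance.

In the association stages the latent factors are regressed on observed
exogenous predictors (a MIMIC structure): standardised PGSs, sex and 10
genetic principal components. A regressed factor keeps residual variance
1, so its model-implied variance is $1 + \gamma^\top S_x \gamma$;
reported coefficients are fully standardised,
$b_{std} = b \cdot sd(x) / sd(\eta)$, so $b_{std}^2$ is the share of
factor variance the predictor explains.

## Estimation

* **FIML.** The log-likelihood sums, over missingness patterns, the
  Gaussian log-density of each row's observed sub-vector under the
  corresponding sub-moments. Predictors are treated as fixed regressors
  (conditional likelihood), matching common SEM software defaults. The
  pattern-grouped evaluation is algebraically identical to row-wise
  evaluation (asserted to 1e-10 in the tests) but costs per pattern, not
  per row.
* **Optimisation.** Quasi-Newton (`nlminb`) on a transformed space with
  log residual variances, analytic gradients (verified against
  numerical differentiation), one deterministic start (loadings at half
  the indicator SD, residual variances at half the indicator variance,
  intercepts at the means, structural coefficients at zero), and up to
  five deterministically jittered restarts on non-convergence.
  Convergence requires the per-observation-scaled gradient
  $\max_j |\partial \ell / \partial \theta_j| / n < 10^{-5}$; scaling by
  $n$ keeps the criterion comparable across sample sizes. Factor signs
  are canonicalised (free loadings sum positive).
* **Standard errors.** Naive SEs come from the inverse observed
  information (central-difference Hessian of the analytic gradient).
  Robust SEs use the sandwich $A^{-1} B A^{-1}$ with $B$ the sum of
  outer products of analytic casewise scores — the substance-use scores
  are bounded counts, so the normal working likelihood is deliberately
  misspecified and the sandwich keeps Wald tests calibrated (type-I
  error is checked by simulation). Satorra-Bentler-type scaled test
  statistics are out of scope; the likelihood-ratio statistic is
  reported unscaled.
* **Saturated and baseline models.** The saturated mean/covariance under
  missingness is fitted by EM (relative log-likelihood change below
  1e-8); on complete data the closed-form ML moments are returned. The
  independence baseline factorises per variable. Fit indices:
  $T = 2(\ell_{sat} - \ell_{model})$,
  $CFI = 1 - \max(T - df, 0) / \max(T_b - df_b, T - df, 0)$,
  $RMSEA = \sqrt{\max(T - df, 0) / (df \cdot n)}$ (the $n$ convention;
  `rmsea_n = "n-1"` is available), and SRMR as the root mean square
  correlation-metric residual against the saturated moments. With
  $df = 0$ RMSEA is reported as undefined with a reason.
* **Delta method.** Standardisation is a smooth map of the free
  parameters with the predictor sample moments held fixed; its
  numerical Jacobian propagates the (robust) covariance to the
  standardised scale.

## Polygenic scoring

Summary statistics are harmonised to the panel (effect alleles aligned,
betas sign-flipped where needed, strand-ambiguous A/T and C/G SNPs
dropped — the simplest defensible policy; frequency matching is out of
scope). Clumping is greedy: SNPs are ranked by ascending p-value (ties:
position, then id); each index SNP removes same-chromosome SNPs within
the window whose dosage $r^2$ exceeds 0.10. The window default is
**250 kb**: a 250-basepair clumping window is not meaningful at GWAS SNP
densities, so the printed "250-bp" figure is treated as a kilobase
typo; the parameter is configurable. Scores are
$\sum_j \beta_j \cdot dosage_{ij}$ over retained SNPs with $p \le 1$
(a single inclusive threshold, limiting multiple testing), missing
dosages mean-imputed, and every score standardised to mean 0, variance 1.

## Association stages and multiplicity

Single-PGS models regress all five trait factors ($C$, $S_1..S_4$)
simultaneously on one PGS plus covariates — one fit per PGS, keeping the
factor decomposition intact. Benjamini-Hochberg FDR correction is
applied per factor across the PGSs (5 families of 18 under the default
design); a single global family is available via `family = "global"`,
since the original family definition is ambiguous. PGSs with
$p_{FDR} < 0.05$ enter the multivariable stage, split into substance-use
scores (set A) and trait/vulnerability scores (set B); each multi-PGS
model regresses the focal factor on all selected PGSs of one set plus
covariates jointly, with the other factors regressed on covariates only,
yielding mutually adjusted estimates. With a single selected PGS the
multivariable model agrees with the single-PGS model statistically but
not numerically — the single-PGS fit carries PGS paths to the other
factors that the multivariable fit omits by construction.

## The synthetic-data generator

The generator is the package's ground-truth instrument; its defaults are
the conditions the analysis code is validated under:

* **Design**: 4000 individuals (typical of the motivating cohort designs, ~4200 analysed individuals), 400 SNPs in
  LD blocks of 10, 18 discovery GWAS with $N = 20000$ (the smallest
  discovery sample a selective GWAS inclusion rule would admit).
* **Genotypes**: two haplotypes per individual from a first-order
  autoregressive Gaussian-threshold copula (default $\rho = 0.8$) within
  blocks, independent across blocks; allele frequencies uniform on
  (0.05, 0.5]; Hardy-Weinberg by construction. Positions place each
  block well inside one clumping window and separate blocks by 1 Mb —
  the simplest mechanism that gives clumping something real to remove.
  By default allele pairs are never strand-ambiguous, as in a
  quality-controlled panel; `ambiguous_fraction` raises ambiguous pairs
  to exercise the harmonisation drop rule.
* **Summary statistics**: reported betas are the true per-SNP effects
  plus noise with the single-SNP standard error
  $1/\sqrt{N \cdot 2f(1-f)}$; two-sided Wald p-values; a configurable
  fraction of rows (default 10%) is written in the opposite allele
  orientation to exercise harmonisation.
* **Latent structure**: unit-variance factors; $C$ and the $S_k$ are
  linear in the true standardised PGSs (and optionally covariates) with
  an independent residual completing the variance to 1 — a coefficient
  set implying variance above 1 is rejected. Default structural truth:
  risk-taking on $C$ at 0.14 (the magnitude reported for the strongest
  common-liability predictor in this literature), cigarette- and
  alcohol-frequency scores on their substance factors at 0.12.
* **Loadings**: default common loadings average $\bar\lambda_C^2$ at 22%
  and specific loadings at 34% of total indicator variance, with
  occasion (fixed unit) variance at 14% and residuals at 30% — the
  study's average variance decomposition. The loadings deliberately vary
  across indicators: if $\lambda_C/\lambda_S$ were constant, the MIMIC
  regression would have an exactly flat ridge (a common-factor effect
  and compensating specific-factor effects become indistinguishable
  through the means), and real instruments differ in reliability anyway.
* **Marginals**: continuous indicators are mapped to bounded counts by
  rank-preserving quantile discretisation onto a truncated
  negative-binomial shape (size 0.6, mean 15% of the scale ceiling) —
  right-skewed and zero-heavy like substance-use scores. Cohorts rarely
  publish these marginals, so this is a stand-in, not a calibration;
  rank mapping approximately preserves the latent correlation structure.
* **Missingness**: per-indicator MCAR at 25% by default (longitudinal
  attrition scale), or MAR with logistic dependence on sex; rows with
  all 12 indicators missing are dropped; covariates stay complete.
* **Covariates**: sex is Bernoulli(0.5); the 10 "principal components"
  are standard normals — the pipeline needs covariates with the right
  role, not realistic population stratification.

What passing tests on these data do **not** show: robustness to
realistic human LD maps, imputation error, ancestry admixture,
instrument-specific item structure, or non-ignorable (MNAR) attrition.

## Validation design and problem sizes

The test-suite checks were sized to be decisive yet quick: parameter
recovery and CI coverage use 50 replicates at $n = 4000$ with continuous
indicators (so the injected loadings are exactly the truth); the
likelihood-ratio calibration uses 200 replicates at $n = 4000$ drawn
exactly from the model; the null calibration of the robust Wald tests
uses 200 replicates of the full 18-PGS single-PGS stage on discretised
scores (18 000 tests); clumping and FDR brute-force comparisons run on
all random instances tested. Smaller property checks (for example MCAR
recovery with missingness on half the indicators) state their own sizes
in the test code; replicate means are compared with tolerances that
include the Monte-Carlo error of the replicate count used.

## Known limitations

* The normal working likelihood treats bounded counts as continuous;
  point estimates on the standardised scale are mildly attenuated
  relative to a categorical-indicator estimator (WLSMV is out of scope).
* Fit indices with exogenous predictors require complete indicators
  (the conditional saturated model is closed-form OLS); without
  predictors, missingness is handled by the EM saturated fit.
* The FDR family definition and the occasion-factor constraint set
  follow one defensible reading of the field's standard design; both are
  configurable or documented where they are inferences.
* Robust standard errors protect inference, not point estimates, under
  misspecification.

## A worked example

```{r example, eval = FALSE}
library(tsoPGS)

res <- runPipeline(list(
  seed = 11,
  simulate = list(n_individuals = 1000, n_snps = 120,
                  traits = c("risk_taking", "cig_frequency",
                             "alc_frequency"))),
  out_dir = tempfile("tso_run"))

res$indices[c("chisq", "df", "cfi", "rmsea", "srmr")]
res$decomposition$average
head(res$single)
```

The run writes every stage's outputs (genotype and phenotype text files,
per-trait PGS tables, the fitted parameter table, association tables and
a truth-versus-estimate report) under the output directory together with
a manifest recording parameters, derived seeds and checksums.
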