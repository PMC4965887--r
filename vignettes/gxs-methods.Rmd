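---
title: "Sex-stratified bivariate GREML: model, estimation and design choices"
author: "gxsreml"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-stratified bivariate GREML: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxsreml)
```

## The question and the model

Autosomal genetic effects on a quantitative trait may differ between men
and women, either in scale (different heritabilities) or in kind (a
cross-sex genetic correlation below one). `gxsreml` quantifies both by
treating the male and female observations of one phenotype as two traits
in a bivariate linear mixed model that share a genomic relationship matrix
(GRM):

$$
\mathbf{y} =
\begin{pmatrix}\mathbf{y}_m\\\mathbf{y}_f\end{pmatrix} =
\begin{pmatrix}X_m & 0\\ 0 & X_f\end{pmatrix}
\begin{pmatrix}\beta_m\\\beta_f\end{pmatrix} +
\begin{pmatrix}G_m & 0\\ 0 & G_f\end{pmatrix}
\begin{pmatrix}\mathbf{a}_m\\\mathbf{a}_f\end{pmatrix} +
\begin{pmatrix}\mathbf{e}_m\\\mathbf{e}_f\end{pmatrix},
$$

where $G_x$ holds standardized allele counts, the per-SNP effect pairs
$(a_{mj}, a_{fj})$ are i.i.d. zero-mean bivariate normal with variances
$\sigma^2_{g_m}/M$, $\sigma^2_{g_f}/M$ and correlation $\rho$, and the
residuals are independent with sex-specific variances $\sigma^2_{e_m}$,
$\sigma^2_{e_f}$. Marginally, the phenotypic covariance between
individuals $i$ (sex $x$) and $j$ (sex $z$) is
$c_{xz} K_{ij} + \delta_{ij}\sigma^2_{e_x}$ with
$c_{mm}=\sigma^2_{g_m}$, $c_{ff}=\sigma^2_{g_f}$,
$c_{mf}=\rho\sqrt{\sigma^2_{g_m}\sigma^2_{g_f}}$ and
$K = ZZ^\top/M$ the GRM over $M$ standardized SNPs. Heritability per sex
is $h^2_x = \sigma^2_{g_x}/(\sigma^2_{g_x}+\sigma^2_{e_x})$.

Two constrained fits support one-degree-of-freedom likelihood ratio
tests (LRTs):

* $\rho = 1$ — proportional genetic effects between the sexes
  (`fit_rho1()`), testing whether the genetic correlation differs from
  one;
* $h^2_m = h^2_f$ — enforced exactly by reparametrizing to
  $(\sigma^2_m, \sigma^2_f, \lambda, \rho)$ with residual variances
  $\lambda\sigma^2_m$, $\lambda\sigma^2_f$ (`fit_equal_h2()`), so
  $h^2 = 1/(1+\lambda)$ in both sexes.

A sex-agnostic comparator (`fit_univariate()`) pools both sexes with one
genetic and one residual variance; its fixed effects include a sex main
effect and sex-by-covariate interactions so the mean structure is
identical to the bivariate model (same column span). This matters for the
prediction comparison: differences between the models are then purely in
the covariance structure, never in the mean adjustment.

## Restricted likelihood and its convention

The restricted log-likelihood is
$$
\ell_R = -\tfrac12\left[\log|V| + \log|X^\top V^{-1}X| +
\mathbf{y}^\top P\mathbf{y} + (n-p)\log 2\pi\right],
\qquad
P = V^{-1} - V^{-1}X(X^\top V^{-1}X)^{-1}X^\top V^{-1}.
$$
The $(n-p)\log 2\pi$ constant is included and fixed, so any difference of
two evaluations on the same data is convention-free; LRT statistics never
depend on it. Fixed effects are always estimated jointly inside REML
(never pre-residualized), matching the projection definition above.

## Estimation: average-information REML

Fitting uses average-information (AI) REML: analytic first derivatives
$\partial\ell_R/\partial\theta_k = -\tfrac12[\mathrm{tr}(P\,dV_k) -
\mathbf{y}^\top P\,dV_k P\mathbf{y}]$ and the average-information matrix
$\tfrac12 \mathbf{y}^\top P\,dV_k P\,dV_l P\mathbf{y}$ as a Newton-type
metric, with step-halving whenever a step fails to improve the objective
or leaves the positive-definite region. This is the same algorithm family
used by the standard variance-component tools in this field; it reaches
the optimum in typically 4–8 iterations of one $O(n^3)$ factorization
each, where a numeric-derivative quasi-Newton scheme would need an order
of magnitude more likelihood evaluations at the same cost per evaluation.
Constrained variants are handled by chain rule through each
parametrization's Jacobian, so all four model variants share one engine
and one likelihood code path. A derivative-free Nelder–Mead restart on
log-transformed parameters backs up the rare non-convergent case, and
three deterministic jittered restarts precede it.

Defaults (all overridable through `options`): convergence when the
relative objective change is below `1e-8` *and* the relative parameter
change below `1e-6`; at most 200 iterations; variance floors at
`1e-8 * var(y)`; initialization splits each sex's phenotypic variance
evenly between genetic and residual components with $\rho$ started at
0.5. Standard errors come from the inverse AI matrix at the optimum,
mapped to the natural scale by the delta method — including for the
derived quantities $h^2_m$, $h^2_f$ and $r_g$.

### The admissible region for the cross-sex covariance

The genetic covariance $c_{mf}$ is optimized directly rather than through
$\rho$, and it is *not* hard-clamped to the positive-semidefinite cone
$|c_{mf}| \le \sqrt{c_{mm}c_{ff}}$. Two failure modes motivate the actual
rule:

* a hard clamp at $|\rho| = 1$ places the null value of the
  genetic-correlation LRT on a boundary; under a true $\rho = 1$ roughly
  half the estimates pile up at the bound, the LRT statistic degenerates
  to a mixture with mass at zero, and the nominal 5% test rejects at
  roughly 2.5% — a miscalibration the package's own calibration suite
  would flag;
* a fully unconstrained $c_{mf}$ admits a degenerate optimum in which one
  genetic variance collapses to its floor while the cross-covariance
  persists, driving the implied $|\hat\rho|$ to absurd values and
  corrupting the equal-$h^2$ LRT.

The compromise is $|c_{mf}| \le \rho_{\max}\sqrt{c_{mm}c_{ff}}$ with
$\rho_{\max} = 1.5$ (option `rho_max`): wide enough that sampling noise
around $\rho = 1$ almost never touches the bound at realistic sample
sizes, tight enough to exclude the degenerate region. The calibration
suite verifies that under this rule both null LRTs reject at their
nominal rate and produce uniform p-values. Reported $\hat r_g$ may therefore
slightly exceed 1 in magnitude, exactly as variance-component estimates
may sit at zero; consumers who need a bona fide correlation should
truncate at publication time, not at estimation time.

The LRT against $\rho = 1$ is referred to $\chi^2_1$, which is exact here
because the null is interior to the enlarged region. The equal-$h^2$ null
is interior in any case.

## Quality control

The QC module reproduces a genotyping-array cohort protocol, with every
threshold overridable and echoed into an audit `qc_report`: SNP
missingness > 2%; platform-differential missingness by two-sided Fisher
exact test at $P < 10^{-100}$; individual missingness > 5%; a 1-df
chi-square Hardy–Weinberg goodness-of-fit filter at $P < 10^{-50}$
computed in the designated unrelated reference (the chi-square form is
used rather than the exact test: at thresholds this extreme the two are
interchangeable and the chi-square is far cheaper; monomorphic SNPs are
kept with $P = 1$ and flagged); a minor-allele-frequency band of
$(0.05, 0.5]$ for common-variant analyses or $(0.0037, 0.5]$ when rare
variants are included; greedy relatedness pruning above 0.0625 (remove
the individual in the most offending pairs, ties by lexicographically
smallest ID — deterministic though not necessarily minimal); an ancestry
window of $\pm 3$ SD on each of the leading 20 principal components,
applied once, not iteratively; per-sex phenotype outlier removal at
$\pm 3$ SD around the sex mean with moments computed in a single pass on
the pre-filter cohort; ratio and unit-SD phenotype transforms; a
composite score as the first principal component of several measures
after a 5 SD pre-exclusion; an offspring-count cap at 15 (exclusion, not
truncation); rank-based inverse-normal transformation
($\Phi^{-1}((r-1/2)/n)$, average ranks for ties, optionally within sex);
and distribution matching for categorical phenotypes (per stratum, keep
all of the minority sex and a seeded uniform subsample of equal size from
the majority sex).

Principal-component signs are fixed by making each component's
largest-magnitude loading positive, so PCs used as covariates are
reproducible across linear-algebra backends.

## GRM construction

Standardization statistics $\mu_j$, $\sigma_j$ (population-form SD) are
always computed on a designated reference population — the training
cohort, for prediction — and frozen into the effect sets used to score
new individuals. Missing calls are mean-imputed before standardization
and therefore contribute exactly zero. The GRM divides by the SNP count
$M$, not by per-pair non-missing counts: together with mean imputation
this keeps the GRM formulation exactly equivalent to the per-SNP-effect
formulation with effect variance $\sigma^2_g/M$, an identity the test
suite verifies numerically. The population-form SD affects only a global
scale absorbed by the variance parameters.

## Genomic prediction

SNP effects are back-solved as their posterior mean with variance and
fixed-effect parameters held at the REML estimates:
$\hat{\mathbf a} = \mathrm{Cov}(\mathbf a, \mathbf y)V^{-1}(\mathbf y -
X\hat\beta)$. Under the bivariate model the cross-sex covariance blocks
make each sex's effects borrow information from both sexes' residuals.
Test individuals are scored as
$\hat y_i = \sum_j (s_{ij}-\mu_j)/\sigma_j \cdot a_j$ with the effect
vector of their own sex (sex-matched scoring; the shared vector under the
univariate model), SNPs matched strictly by identifier — allele-flip
reconciliation is out of scope because simulated and real pipelines here
share one variant annotation. Accuracy is the Pearson correlation between
predictions and phenotypes adjusted by the *training* fixed-effect
estimates, reported pooled over sexes (one headline number per
phenotype) with per-sex correlations alongside as diagnostics, and the
relative improvement
$(\mathrm{acc}_{\text{specific}}-\mathrm{acc}_{\text{agnostic}})/
\mathrm{acc}_{\text{agnostic}}\times 100\%$ derived from the pooled pair.

## The synthetic-cohort generator

Real individual-level biobank genotypes cannot ship with a repository,
so every stage is exercised against a generator with a fully known
gene-by-sex architecture (`gxs_truth()`, `simulate_genotypes()`,
`simulate_phenotypes()`). Per SNP, an allele frequency is drawn uniformly
on [`maf_low`, `maf_high`] and counts are two Bernoulli draws
(Hardy–Weinberg). Causal effect pairs are drawn bivariate normal with
variances $\sigma^2_{g_x}/n_{\text{causal}}$ and correlation $\rho$ *on
standardized genotypes*, so the total genetic variance equals
$\sigma^2_{g_x}$ regardless of the MAF spectrum — matching the $h^2$
definition above. The generator standardizes by the *true* allele
frequencies so that recorded truth is exact; estimation-side code always
uses sample statistics. Sex is assigned deterministically (first
`n_male` individuals male) and one master seed drives a documented
stream order (frequencies → genotypes → missingness → causal selection →
effects → covariates → residuals), so replicates are bit-reproducible
and experiment suites use the ladder `seed = base + replicate`.

The defaults encode the package's canonical study condition: 1500 males
and 1500 females, 2000 SNPs with 500 causal, MAF uniform on [0.05, 0.5],
unit phenotypic variance per sex with $h^2_m = 0.3$, $h^2_f = 0.4$ and
$\rho = 0.7$, plus one standardized age-like covariate with coefficient
0.1 in both sexes.

What the generator deliberately does *not* emulate: linkage
disequilibrium between SNPs (so prediction accuracies here are not
attenuated by tagging), X-chromosome effects, assortative mating or
spouse structure, and enrolment/ascertainment bias. Passing tests
therefore demonstrate correctness of the estimation machinery under the
model's own assumptions — not robustness to the full messiness of real
cohort data. Two consequences are worth keeping in mind when reading the
validation suite: with a causal subset (500 of 2000 SNPs) the GRM is a
noisy proxy for the causal-SNP relationship matrix, which inflates
replicate-to-replicate spread slightly beyond the model-based standard
errors; and with no LD the distinction between "SNPs used" and "causal
variants tagged" disappears.

## Validation suite and problem sizes

The acceptance tests re-derive the method's key properties at fixed,
seeded study conditions, chosen to complete on a single CPU in tens of
minutes:

* oracle equivalence of the restricted likelihood against an
  independently coded dense projection-matrix implementation, all four
  variants, 50 parameter draws, tolerance $10^{-8}$;
* parameter recovery at the canonical condition (n = 3000, M = 2000, 20
  replicates): every natural parameter and both heritabilities within 3
  reported SEs of truth in at least 95% of replicates;
* null calibration of both LRTs at n = 800 over 200 replicates
  (rejection rates inside the exact binomial 95% interval around 0.05,
  p-values uniform by Kolmogorov–Smirnov at $\alpha=0.01$);
* no spurious $r_g$ deflation when the sexes differ fourfold in
  phenotypic variance and in heritability (100 replicates, mean
  $\hat r_g$ within 3 SEM of 1);
* delta-method SEs of $h^2_m$, $h^2_f$, $r_g$ within 30% of empirical
  replicate SDs at n = 2000 (100 replicates);
* prediction ordering: under $\rho = 0.5$ the sex-specific model's mean
  pooled accuracy exceeds the sex-agnostic model's over 20 train/test
  replicates (train 3000, test 1000), while under $\rho = 1$ the mean
  relative improvement is statistically indistinguishable from zero;
* exactness of every QC filter on hand-computed toy fixtures, and
  nesting/determinism invariants (constrained fits never beat the free
  fit; identical configurations produce byte-identical JSON).

## Known limitations

* The model is strictly additive: no dominance, epistasis, or
  multi-trait (beyond the two sexes) extensions.
* LRT calibration was verified at the suite's sample sizes; at very
  small n (a few hundred) REML LRTs can drift from $\chi^2_1$.
* The greedy relatedness pruning is deterministic but can remove more
  individuals than the minimum vertex cover.
* Scoring assumes the test panel shares variant identifiers and allele
  orientation with the training panel.
* Memory is $O(n^2)$ (several dense $n \times n$ matrices); cohorts of
  $10^5$ individuals need the out-of-core solvers this package does not
  provide.
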