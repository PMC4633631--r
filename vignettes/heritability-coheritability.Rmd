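---
title: "SNP heritability and co-heritability of case-control traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP heritability and co-heritability of case-control traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models behind `coherit`, the
assumptions they make, the tunable parameters and their defaults, what the
bundled simulator does and does not emulate, and the numerical choices that
shape the results. The package targets the standard analysis arc for
genome-wide SNP data on multiple disease cohorts sharing a control pool:
quality control, structure correction, association, variance-component
estimation of SNP heritability and genetic correlation, a threshold-free
test for shared association signals, and cross-validated genetic risk
prediction.

## The liability-threshold model

Each binary trait is modelled through a latent liability
$l = g + e$, with additive genetic value $g \sim N(0, h^2)$ built from SNP
effects and residual $e \sim N(0, 1 - h^2)$. An individual is affected iff
$l$ exceeds the threshold $t = \Phi^{-1}(1 - K)$, where $K$ is the
population prevalence. Everything downstream assumes additive genetics and
an independent residual: no dominance, no shared environment, no
gene-environment interaction.

## GREML: variance components on the observed scale

The 0/1 phenotype is analysed with the linear mixed model
$$y = X\beta + \textstyle\sum_c g_c + \varepsilon,\qquad
  g_c \sim N(0, A_c\,\sigma^2_c),\quad \varepsilon \sim N(0, I\sigma^2_e),$$
where each $A_c$ is a genetic relationship matrix (GRM) over a SNP subset
(all autosomes; autosomes excluding the extended MHC, chr6:26.5–34 Mb with
both boundaries inside the window; the MHC alone; chromosome X). GRM
entries average $(x_{ij} - 2f_i)(x_{ik} - 2f_i) / (2f_i(1-f_i))$ over SNPs
non-missing in both individuals, with allele frequencies taken from the
full analysis cohort after QC (the package's choice; cases plus controls).
The diagonal uses the same cross-product form as the off-diagonal entries
rather than the inbreeding-adjusted variant some tools use — a deliberate,
documented divergence that keeps the matrix identical to its brute-force
definition. On chromosome X, full dosage compensation is assumed: male
allele counts $w \in \{0, 1\}$ are scored
$\sqrt{2}\,(w - f)/\sqrt{f(1-f)}$, females as on the autosomes.

Restricted maximum likelihood is maximised by average-information (AI)
updates. Where the model has exactly one GRM plus an iid residual, the GRM
is eigendecomposed once and every iteration costs $O(np^2)$; the
multi-component and bivariate models use the dense path. Numerical policy:

* convergence when the restricted log-likelihood changes by less than
  `1e-6` (cap 100 iterations);
* variance components floored at `1e-6 * var(y)`;
* if the AI step would decrease the likelihood, the driver falls back to
  an EM step, then to step halving; accepted iterations therefore never
  decrease the likelihood (asserted in the tests);
* significance of the genetic variance uses the boundary mixture
  $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (a plain $\chi^2_k$, conservative,
  for $k > 1$ genetic components);
* standard errors come from the inverse AI matrix, ratios (heritability,
  component shares, $r_G$) by the delta method.

## Liability-scale transformation

Observed-scale estimates from an ascertained case-control sample with case
proportion $P$ are rescaled with the full ascertainment correction
$$h^2_{liab} = h^2_{obs}\,
  \frac{K^2(1-K)^2}{P(1-P)\,z^2},\qquad z = \varphi(t),$$
and the standard error is multiplied by the same factor ($K$ and $P$
treated as fixed). At $K = P = \tfrac12$ the multiplier is exactly
$\pi/2$. Values above 1 are reported unclamped with a warning, because
clamping silently would hide model misfit.

**Known limitation.** Under strong ascertainment this transform does not
fully undo the distortion REML suffers from case oversampling: with cases
at 50% of the sample drawn from a 5% prevalence population and a true
liability $h^2$ of 0.6, the package's own acceptance checks measure a mean
recovered value of roughly 0.51 — a downward bias of about 0.09 that no
amount of replication removes, and the reason dedicated ascertainment-aware
estimators exist. The same checks show the estimator is essentially
unbiased for quantitative phenotypes and for binary traits under random
sampling, and that the bias shrinks as $P$ approaches $K$. We report the
biased value honestly rather than recalibrating to truth.

## Bivariate model and genetic correlation

Two disease cohorts (disjoint case sets, a shared control pool split
evenly and at random between them, the larger half to the first disease)
are stacked into one mixed model with per-trait genetic variances, a
genetic covariance carried by the cross-cohort GRM block, and per-trait
residual variances. The residual covariance is structurally zero — no
individual is phenotyped for both traits — which is what makes the split
design identifiable. The genetic correlation is
$r_G = \sigma_{g12}/\sqrt{\sigma^2_{g1}\sigma^2_{g2}}$, kept inside
$(-1, 1)$ by clipping the covariance during optimisation; its significance
is a 1-df likelihood-ratio test against the fit with $\sigma_{g12} = 0$.
Because $r_G$ is invariant to linear rescaling of either phenotype
(checked numerically in the tests), the observed-scale estimate is also
the liability-scale estimate. Pairwise p-values are Bonferroni-adjusted
for 9 tests per disease (relaxed) and for all 45 pairs of a 10-cohort
design (strict); when both adjusted columns are reported, the adjustment
is applied to the MHC-excluded nominal p.

## Genome-wide pairwise sharing (GPS)

For two traits' association scans over a common SNP universe, p-values are
converted to two-sided magnitude Z-scores $Z = \Phi^{-1}(1 - p/2)$
(direction is irrelevant to the construction; $Z$ is clipped at the
$p = 10^{-300}$ quantile) and the statistic is
$$\gamma = \max_j \min(X_j, Y_j),$$
the maximum over SNPs of the pairwise minimum. With
$a = \#\{X_j \ge \gamma\}$ and $b = \#\{Y_j \ge \gamma\}$ (non-strict
exceedance, so both counts are at least 1), the permutation null — Y
re-paired against X uniformly at random — gives
$$p = 1 - \binom{n-a}{b}\Big/\binom{n}{b},$$
evaluated in log space. The tests verify this expression against full
factorial enumeration for every fixture with $n \le 7$ and against
10,000-draw Monte-Carlo permutation at $n = 500$. The test is threshold
free and most powerful for *sparse* sharing, where the top signals of both
traits coincide at few SNPs; many moderately shared SNPs inflate $a$ and
$b$ and dilute it. Linkage disequilibrium violates the independent
re-pairing null, so extended-MHC SNPs are excluded by default and
pre-pruned input is supported.

## Disease prediction

Ten-fold cross-validation stratified by case status; within each fold the
GWAS, the SNP selection at each threshold of
$\{10^{-5},\dots,10^{-9}\}$, the mean imputation and the standardisation
are all fitted on the nine training folds only. A linear SVM (cost 1,
inverse-frequency class weights — without which control:case ratios far
from 1 collapse the decision function) is trained per threshold, and
held-out decision values are scored with the rank-statistic AUC (ties one
half). Cells whose threshold selects no SNPs are recorded missing rather
than failing; summaries (mean, max) are taken over all non-missing
threshold-by-fold cells.

## The simulator: what it emulates, and what it does not

`simulate_genotypes()` draws allele frequencies uniformly on a configurable
interval (default 0.05–0.5) and genotypes binomially, independent across
SNPs; an optional LD mode copies adjacent SNPs with flip noise, and an
optional extended-MHC block on chr6:26.5–34 Mb carries a configurable
share of genetic variance. Causal effects are drawn on *standardised*
dosages — matching the GRM standardisation, so each causal SNP's expected
variance contribution is MAF-independent — with trait pairs drawn from a
bivariate normal at the target genetic correlation. X-chromosome males are
fully dosage-compensated with dosages in $\{0, 2\}$. QC artifacts
(missingness, case-differential missingness, Hardy-Weinberg violations via
a heterozygote deficit, Mendelian offspring, Balding-Nichols $F_{st}$
drift between subpopulations) are injected on demand.
`simulate_case_control_study()` and `simulate_case_control_pair()`
ascertain cases and controls from a large source population in two stages
(causal SNPs first, noise SNPs only for the ascertained individuals),
which is distributionally identical to full-population simulation.

Not emulated: realistic human LD maps and haplotype structure, rare
variants (MAF below 0.01 is excluded throughout), imputation artifacts,
shared environment. Passing tests therefore demonstrate the estimators'
statistical behaviour under their own assumptions — not robustness to the
LD heterogeneity that is known to move SNP-heritability estimates on real
arrays.

## Defaults that matter

| Parameter | Default | Why |
|---|---|---|
| SNP call rate | $\ge$ 0.95 | standard array QC |
| MAF | $\ge$ 0.01 | rare variants out of scope |
| HWE exact p (controls only; X in females only) | $\ge$ 0.01 | cases may deviate under true association |
| differential-missingness Fisher p | $\ge$ 10^-3^ | unstated upstream; conservative, configurable |
| sample call rate | $\ge$ 0.95 | standard |
| LD pruning | window 50, step 10, $r^2 \le 0.2$ | the standard `--indep-pairwise 50 10 0.2` setting; lists above 100,000 SNPs are thinned deterministically |
| ancestry outliers | any of top 10 PCs beyond 6 SD, 1 pass | the common EIGENSTRAT-style rule; iteration count configurable |
| relatedness cutoff | GRM $> 0.05$, greedy max-retention | on the GRM scale; with small simulated panels (null GRM noise $\approx 1/\sqrt{m}$) analyses raise it explicitly |
| PCs as covariates | 10 (association), 20 (REML) | common practice for this design; both are config keys |
| SVM | linear, cost 1, class weights | hyperparameters deliberately not tuned |

## Problem sizes used by the checks

The test suite and the acceptance script size their simulations so the
whole battery runs on a single CPU in minutes while keeping each check
statistically meaningful: univariate recovery at $n = 2000$, $m = 5000$,
25 replicates (the spectral REML path makes this cheap); bivariate
recovery at $n = 1000$ per side, $m = 3000$, 10 replicates; null
calibration from 200 REML replicates at $n = 400$, $m = 800$, 500 GPS
replicates at $n = 500$ SNPs, and one 20,000-SNP null scan for
$\lambda_{GC}$; prediction on a 4,000-sample cohort with 20 causal SNPs
carrying 2% of liability variance each ($h^2 = 0.4$, prevalence 0.1),
whose analytic liability-$R^2$ AUC ceiling is about 0.84. The SVM null
check uses a lenient selection threshold ($p < 0.01$), since at the
production thresholds a null simulation of this size selects no SNPs at
all.

## Other design choices made where the design was open

* HWE is tested with the exact conditional test, in controls only, because
  the upstream convention is unstated and cases legitimately deviate under
  association.
* The relatedness rule is interpreted on the GRM scale (the "identity"
  scale differs), greedy by over-threshold pair count with call-rate and
  lexicographic tie-breaks, which provably retains chains' endpoints.
* Comorbid individuals are assigned to the smaller cohort by
  post-assignment size, iterated to a fixed point, ties broken by disease
  code.
* Wald tests per SNP in the association scan (not score or LRT); the
  $\chi^2_1$ median in $\lambda_{GC}$ is taken from `qchisq(0.5, 1)` at
  full precision, not the 4-decimal constant.
* The prediction AUC is summarised over folds and thresholds jointly, and
  the per-cell matrix is always reported, because "mean and maximum" is
  ambiguous between the two axes.
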