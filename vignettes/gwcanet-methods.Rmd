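---
title: "Differential metabolite networks and genome-wide correlation analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential metabolite networks and genome-wide correlation analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwcanet)
```

## The question the package addresses

Conventional GWAS asks whether a genetic variant shifts the *mean* of a
trait. Complex physiological states can, however, reorganize the
*dependence structure* among molecular phenotypes without large mean
shifts: in serum metabolomics, the correlation between two lipoprotein
measures may strengthen or weaken between lean and obese individuals even
when neither measure moves much on average. `gwcanet` implements a
two-stage strategy that treats such differences in association as a
phenotype in their own right:

1. **Differential network stage.** Estimate the partial-correlation
   network of $M$ metabolites separately in two physiological groups
   (e.g. non-obese vs obese), and keep the metabolite pairs whose partial
   correlation differs more than chance allows.
2. **Genome-wide correlation analysis (GWCA).** For each replicated
   differential pair and each SNP, split the samples by carrier status of
   the minor allele and test whether the pair's correlation differs
   between the genotype groups.

## Stage one: shrinkage partial correlations and the permutation test

With $M$ metabolites measured on $n$ samples (sex-residualized,
complete cases), the empirical correlation matrix $R$ is shrunk toward
the identity,

$$R^\* = \lambda I + (1 - \lambda) R,$$

with the analytic intensity

$$\lambda^\* = \frac{\sum_{i<j} \widehat{\mathrm{Var}}(r_{ij})}
                    {\sum_{i<j} r_{ij}^2}, \qquad
  \widehat{\mathrm{Var}}(r_{ij}) = \frac{n}{(n-1)^3}
  \sum_k (w_{kij} - \bar w_{ij})^2,$$

where $w_{kij}$ is the product of sample $k$'s standardized values of
metabolites $i$ and $j$, and $\lambda^\*$ is clipped to $[0,1]$. Partial
correlations are read off $\Omega = (R^\*)^{-1}$ as
$\rho_{ij} = -\Omega_{ij} / \sqrt{\Omega_{ii}\Omega_{jj}}$. Shrinkage
keeps $R^\*$ positive definite (inverted by Cholesky factorization, with
a pseudo-inverse fallback only at $\lambda = 0$) and stabilizes the
estimate when $n$ is not large relative to $M$. The identity shrinkage
target is the conventional default for correlation matrices and the only
one implemented. `shrinkage_intensity()` is verified in the test suite
against a brute-force oracle that evaluates the formula pair by pair
from per-sample products.

The observed statistic for each pair is
$\Delta_{ij} = \rho_{ij}^{(2)} - \rho_{ij}^{(1)}$. Significance comes
from a two-sample permutation test: samples are pooled and relabeled
uniformly at random into groups of the original sizes; both
partial-correlation matrices are recomputed per replicate, **including
re-estimation of $\lambda$ within each relabeled group**, so the null
distribution reflects the full estimation pipeline. One shared
permutation ensemble serves all $M(M-1)/2$ pairs, which is what a
permutation of group labels means and is hundreds of times cheaper than
per-pair ensembles. Two-tailed p-values use the add-one estimator
$p_{ij} = (1 + \#\{b: |\Delta^{(b)}_{ij}| \ge |\Delta_{ij}|\})/(B+1)$,
which never returns 0 and is valid for any $B$. The differential network
connects every pair with $p < 0.01$ (strict inequality; the uncorrected
threshold acknowledges that power for correlation differences is low
compared to mean differences). The shipped configuration default is
$B = 100\,000$; simulation work in this package uses $B = 1000$, which
bounds the attainable p-value at $1/1001$ and is ample for ranking
candidates.

**A degenerate case worth knowing about.** If the data carry no
correlation signal at all, $\lambda$ clips to exactly 1 in every subset,
all partial correlations are exactly 0, every permuted difference ties
the observed 0, and all p-values equal 1 by the tie convention. This is
conservative, not anti-conservative; but it means the textbook
"uniform p-values under the null" property holds for exchangeable nulls
with a non-trivial *shared* correlation structure (the realistic case
for metabolites), and the calibration tests are written that way.

Replication across two cohorts is assessed by intersecting the two edge
sets on unordered pairs and computing the hypergeometric tail
probability of the overlap among $N = M(M-1)/2$ candidate pairs. The
package default is the **strict** upper tail $P(X > x)$: with the
worked sizes $(N, M_{\text{edges}}, K_{\text{edges}}, x) =
(703, 36, 19, 5)$ the strict tail equals $1.97\times10^{-4}$ while the
inclusive tail is $1.8\times10^{-3}$; both conventions were checked
against a direct enumeration oracle, and the strict one reproduces the
reference value, so it is the default (`strict = TRUE`).

## Stage two: GWCA

For each SNP, samples split into genotype group A (0 copies of the minor
allele) and B (1 or 2 copies) — dichotomization keeps the carrier group
as large as possible for low-MAF variants. For a metabolite pair
$(m_1, m_2)$, the groupwise Pearson correlations $r_A, r_B$ on
sex-residualized concentrations are compared with the Fisher $z$
transform:

$$Z = \frac{\operatorname{atanh}(r_A) - \operatorname{atanh}(r_B)}
           {\sqrt{1/(n_A-3) + 1/(n_B-3)}}, \qquad
  p = 2\Phi(-|Z|).$$

Stage two deliberately uses the *marginal* correlation of the pair (the
stage-one machinery conditions on all other metabolites; the pairwise
test does not need to, and the marginal version is what the $z$ method
applies to). A configuration switch
(`groupwise_pair_correlation` on residuals of the pair given the rest)
is intentionally **not** provided: users wanting a partialled stage two
can residualize the pair on the remaining metabolites upstream and feed
the residuals through the same interface.

Genome-wide significance uses the strict threshold
$p < 5\times10^{-8}/D$, where $D$ is the number of differential
connections actually tested (the replicated overlap when two cohorts are
available, the full edge set otherwise). SNPs with an empty or
undersized genotype group ($n \le 3$ makes the $z$ variance term
undefined; the package requires $n \ge 4$) or a constant metabolite are
reported as untestable with a reason rather than dropped silently.
Significant records are assigned to the nearest annotated gene within
1 Mb (inclusive); a SNP inside a gene interval has distance 0, and
equidistant genes are broken lexicographically with all tied symbols
reported.

## Preprocessing and quality control

* **Residualization** replaces each metabolite by OLS residuals on the
  configured covariates (default: sex), fitted on all samples jointly
  before any group split — the covariate effect is a property of the
  assay, not of the physiological group. Residuals are exactly
  orthogonal to the covariates (tested to $10^{-10}$).
* **Group assignment** uses BMI cutoffs: obese strictly above
  30 kg/m², non-obese within $[18.5, 25]$ kg/m² inclusive, everything
  else excluded; sex-specific cutoff vectors support percentile-based
  definitions for adolescent cohorts.
* **Marker QC** removes SNPs with call rate $< 0.95$, minor allele
  frequency $< 0.01$, or Hardy–Weinberg equilibrium $p < 10^{-4}$. The
  HWE test is the asymptotic 1-df chi-square goodness-of-fit against
  $(\hat p^2, 2\hat p\hat q, \hat q^2)$ — the conventional array-era
  default, chosen over the exact test because it is desk-verifiable and
  adequate at the MAF/sample sizes this filter targets; monomorphic
  markers return $\chi^2 = 0$, $p = 1$ by convention.
* **Dosage coding** counts the minor allele, with allele frequency
  recomputed from the data per marker; a frequency tie at exactly 0.5
  keeps the alternate allele, making the recode deterministic and
  idempotent.
* Samples with any missing metabolite are dropped listwise before
  correlation estimation (the shrinkage estimator assumes a complete
  matrix).

## Baselines

Two conventional analyses are included for contrast: per-metabolite OLS
of BMI on the metabolite with sex as covariate (standardized $\beta$
from z-scored BMI and metabolite, Bonferroni flag at $\alpha/M$ with
$\alpha = 0.01$ by default — the family level is configurable because
published descriptions of this analysis vary between 0.01 and 0.001 —
and Benjamini–Hochberg q-values across the $M$ tests), and a
single-SNP additive GWAS of BMI flagged at $5\times10^{-8}$. The
regression direction (BMI on metabolite vs metabolite on BMI) is a
switch, defaulting to BMI on metabolite.

## The simulation framework: what it emulates and what it does not

The generators reproduce a four-scenario validation grid crossing minor
allele frequency $\{0.30, 0.05\}$ with a large and a small
between-group difference in the focal-pair correlation, at $n = 3000$
samples and 50 true + 950 null candidates per arm — sizes of the same
order as the motivating cohort analyses.

* **GWCA arm.** Dosages are Binomial$(2, \text{MAF})$ per sample
  (Hardy–Weinberg proportions). Each truly associated SNP gets its own
  focal pair, drawn bivariate normal with correlation $r_A$ for
  non-carriers and $r_B$ for carriers; null SNPs get a pair correlated
  $r_A$ for everyone. Candidates are ranked by Fisher-z p-value.
* **Differential-network arm.** Two multivariate normal samples of
  $n/2$ each over $M = 2 n_{\text{true}}$ variables whose correlation
  matrices differ only on $n_{\text{true}}$ **vertex-disjoint**
  designated pairs ($r_A$ vs $r_B$). Disjointness is a geometric
  necessity, not a convenience: fifty pairs at $|r| = 0.8$ cannot share
  vertices without destroying positive definiteness of the target
  matrix. With 50 true pairs this gives 100 variables and 4900 null
  pairs — more null candidates than the GWCA arm's 950, which only makes
  the ranking task harder. Candidates are ranked by permutation p-value
  at $B = 1000$.

Scenario parameters were fixed once, before any evaluation, from a
normal-theory power calculation. The strong arm uses
$r: 0.2 \to 0.8$, for which the Fisher-z noncentrality at $n = 3000$
exceeds $15$ standard errors — AUC must be 1 up to the rare tie of a
null candidate with the saturated minimal p-value. For the weak arm, a
difference of $0.2 \to 0.4$ at these sample sizes would still give
noncentralities near 6 and AUC $\approx 1$, which would not reproduce
the qualitative "accuracy drops to moderate" behavior this grid is
meant to exhibit; the small difference is therefore set to
$r: 0.2 \to 0.25$, whose predicted AUCs (roughly 0.6–0.85 depending on
MAF and step) fall genuinely between chance and perfection at
$n = 3000$. ROC curves and AUC use the Mann–Whitney formulation (ties
count one half), verified in tests against a brute-force pairwise
oracle and equal to the trapezoidal integral of the curve by
construction.

What the generators do **not** emulate: non-Gaussian metabolite
marginals, missingness, population structure or relatedness among
genotypes, linkage disequilibrium between SNPs, and covariate
confounding (the simulated data are born "residualized"). Passing
simulations therefore demonstrate the statistical machinery — ranking,
calibration, thresholds — not robustness to those real-data
complications.

## Problem sizes and numerical choices

* Permutation runs in the tests and the acceptance script use
  $B = 1000$ (minimum attainable $p = 1/1001$); the pipeline default
  config ships $B = 100\,000$ for production analyses.
* The strong/weak scenario evaluations run at the full grid sizes
  ($n = 3000$, 1000 candidates per arm; the network arm tests 4950
  pairs at $n = 1500$ per group). Property tests use reduced sizes
  (tens of variables, hundreds of samples) chosen so each block runs in
  seconds.
* Correlation-scale outputs are written with 6 significant digits,
  p-values in scientific notation; positions are 1-based everywhere
  (VCF convention, annotation intervals inclusive).
* Missing tokens: `NA` or empty cell in tables, `./.` and `.` in VCF
  genotypes. Multiallelic VCF records are skipped with a warning, not
  split.
* In YAML configuration the simulation sample size is spelled
  `n_samples`: a bare `n` is a boolean in YAML 1.1.

## Known limitations

* Stage one's permutation test assumes exchangeability of samples
  between groups under the null; confounders that differ between groups
  and affect correlations (beyond the residualized covariates) violate
  it.
* The add-one permutation p-value cannot fall below $1/(B+1)$; with
  $B = 1000$ and thousands of candidate pairs, saturated true pairs and
  the occasional extreme null pair can tie at the minimum, costing a
  sliver of AUC (observed as values like 0.9999 rather than exactly 1).
* GWCA tests SNPs one at a time with no linkage-disequilibrium
  clumping; nearby significant SNPs are reported individually.
* No genotype imputation, dosage (fractional) genotypes, or
  population-structure correction; genotype input is limited to GT-field
  VCF and additive 0/1/2 matrices.
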