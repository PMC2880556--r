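---
title: "Pedigree-based fertility association and selection signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based fertility association and selection signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertsel)
```

## The scientific problem

In founder populations practicing natural fertility, family sizes are large
enough that a common variant with a modest effect on male reproductive
output is detectable from civil and interview records. The analytical
difficulty is that everyone in such a population is related: a
quantitative-trait association that ignores the pedigree confounds genotype
sharing with phenotype correlation among relatives. This package implements
the full chain needed for such a study — phenotype construction from birth
records, relatedness-corrected association, nonparametric survival
comparison of birth timing, rule-based haplotype phasing — together with
the population-genetic statistics (Weir–Cockerham Fst, EHH, iHS) used to
ask whether the favored allele shows a signature of positive selection,
and synthetic generators that stand in for the private cohort data.

## Phenotype: birth rate

For a man with births at years $b_1 \le \dots \le b_n$ ($n \ge 2$), the
birth rate is

$$r = \frac{n - 1}{\sum_{i=2}^{n} (b_i - b_{i-1})} = \frac{n-1}{b_n - b_1}$$

births per year. Men with fewer than two births are excluded (flagged, not
dropped silently), as is the degenerate case of a zero span (a lone twin
pair). Years are decimal, so month-resolution records are representable;
the definition is invariant to shifting all dates. Two covariates are
removed by ordinary least squares before (or jointly with) the genetic
analysis: wife's birth year (a cohort-trend proxy, nearly collinear with
husband's year) and the number of years from marriage to last birth.
Constant covariate columns are dropped rather than treated as errors, so
the residualization degenerates gracefully to centering.

`normality_check()` reports moments and a Shapiro–Wilk p-value for the
residuals. It is advisory only: the association test's F reference
distribution assumes Gaussian residuals, and the check tells the analyst
how far the data are from that ideal without blocking the pipeline.

## Kinship and the polygenic covariance

Kinship coefficients are computed by the classical recursion over a
topological order: $\phi(i,i) = \tfrac12(1 + \phi(f_i, m_i))$ and
$\phi(i,j) = \tfrac12(\phi(f_i,j) + \phi(m_i,j))$ for $j$ earlier than
$i$, with founders unrelated and non-inbred. This is exact and $O(n^2)$,
comfortable at the few-thousand-individual scale of deep founder
pedigrees; no path-counting or sparse approximation is needed. Sex is
ignored (autosomal locus), and unknown-sex parents are allowed. The
additive relationship matrix used everywhere downstream is $A = 2\Phi$
(diagonal $1 + f$).

The gene-drop simulator doubles as an independent oracle: dropping
uniquely labelled founder alleles down the pedigree and sampling one
allele per individual, the probability that two individuals' sampled
alleles share a label converges to $\phi$. The test suite checks the
recursion against this Monte-Carlo estimate at $10^5$ replicates.

## Association model

The working model for the (possibly covariate-adjusted) rate $y$ is

$$y \sim N(X\beta,\; \sigma^2_a\, A + \sigma^2_e I),$$

with the polygenic and environmental variances estimated by maximum
likelihood: $A$ is eigendecomposed once, the likelihood is profiled over
the ratio $\gamma = \sigma^2_a/\sigma^2_e$ on the log scale, and a
boundary check at $\gamma = 0$ handles samples with no usable relatedness
signal. On a flat likelihood (e.g. $A \propto I$, where the two components
are not separately identifiable) the boundary is preferred, which is the
parsimonious reading. A dominance component is deliberately not included
by default: the minimal faithful covariance is additive-plus-environment,
and the choice is recorded in the fitted object.

Genotype tests are GLS fits under a fixed covariance. Three codings are
supported: *general* (allele dosage $g$ plus heterozygosity indicator
$h$, 2 df), *recessive_ref* (carrier indicator $c = 1[g \ge 1]$,
reference-homozygote vs carrier, 1 df), and *additive* ($g$ alone).
Significance is the F statistic on the whitened scale,

$$F = \frac{(RSS_0 - RSS_1)/q}{RSS_1 / (n - p_1)},$$

and the share of phenotypic variance attributed to the locus is
$100\,(RSS_0 - RSS_1)/RSS_0$. With $\Sigma \propto I$ the whole procedure
reduces exactly to OLS — the suite asserts this to machine precision.
Variance components are estimated once under the null and reused across
codings at a locus, the standard measured-genotype practice. A genotype
class that is absent in the sample (founder cohorts routinely lack one
homozygote) causes the collinear design column to be dropped with a
warning rather than an error. The replication-style analysis
(`wald_t_additive()`) is the same machinery with an additive dosage and a
t-test of its coefficient. Bonferroni correction is a plain
$\min(1, p \cdot n_{tests})$ with $n_{tests}$ supplied by the analyst
(four in the motivating design: two codings at the missense locus, one
test at each repeat locus).

Both the joint fit (covariates in the null model) and the residual-first
variant (pass the residual as `y` with `X_cov = NULL`) are supported; the
joint fit is the default because it propagates covariate uncertainty
correctly.

## Survival comparison

Time from marriage to the $k$th birth (default $k = 6$, the cohort's
median and mean family size in the motivating study) is an event if the
man reached $k$ births and is otherwise censored at his last birth —
implemented literally; using the interview date instead would lengthen
censored times and is a documented alternative the analyst can encode
upstream. Kaplan–Meier curves and the log-rank test are delegated to the
`survival` package behind the package's own record interface; the tie
convention (events precede censorings at equal times) is the product-limit
standard. Completed family sizes are compared by a rank-sum test, exact
when the combined sample is at most 12 and tie-free, normal-approximated
otherwise. The "long-married" subset rule recomputes its threshold as the
sample mean marriage-to-last-birth span rather than hard-coding a value,
since the motivating cohort derived its 11.5-year cut the same way.

## Haplotype phasing

The three-locus system — (TG)m and polyT in one intron, the missense site
in a nearby exon — is phased without any statistical model:

1. The intron repeats are sequenced on one amplicon, so their cis pairing
   is observed, not inferred (`phase_intron8()` is a validating
   pass-through).
2. Homozygosity at the missense site, or identical intron haplotypes,
   force the phase outright.
3. Otherwise candidates are pruned by Mendelian transmission through the
   pedigree (each child receives one whole haplotype from each parent; the
   region is short enough that recombination is ignored), iterating
   family-wise until a fixed point, so a newly phased parent can phase a
   child on the next sweep.

The procedure never guesses: a man whose candidate set stays larger than
one is reported ambiguous — the motivating study has exactly one such man
(double heterozygous at the missense site and (TG)m, homozygous 7T) — and
an emptied candidate set raises a Mendelian-inconsistency error naming the
family. Population-frequency (EM) phasing is deliberately not used, to
reproduce the observational character of the original haplotype
assignment. Frequencies are counted over resolved chromosomes only, with
the ambiguous count reported; the pruning is arc-consistent, so its fixed
point does not depend on processing order.

LD between two dichotomized loci is $D = p_{AB} - p_A p_B$ normalized by
its frequency-bound maximum ($D' = D / D_{max}$), with the
dichotomization stated explicitly in the call — for multi-allelic repeat
loci there is no canonical 2×2 collapse, so the package refuses to pick
one silently.

## Selection statistics

*Weir–Cockerham theta.* The default variant is the allele-frequency
(haploid) form — mean squares among and within populations with the
variance-corrected sample size $n_c$ — matching an analysis that starts
from published allele frequencies; a genotype-level variant with the full
$a/b/c$ components is available when heterozygote counts exist, and the
two are labelled in the result. When both samples are fixed for the same
allele the estimator is undefined and says so. A subtlety worth stating:
at *identical sample frequencies* the unbiased estimator returns not 0 but
$-1/(n_c - 1)$, because the among-population mean square is corrected by
the within-population one; tests treat "no differentiation" as zero up to
that sampling term.

*EHH and iHS.* EHH at distance $x$ from the core SNP is the probability
that two carriers of the core allele, drawn without replacement, are
identical at every SNP between the core and $x$ — computed by maintaining
identical-prefix classes marker by marker, $\sum_h \binom{n_h}{2} /
\binom{n_c}{2}$, and verified in the tests against a brute-force all-pairs
oracle. iHH is the trapezoidal integral of the decay curve over physical
distance (a genetic map can be supplied), upstream and downstream summed,
truncated at the first marker where EHH falls below a cutoff (default
0.05; the below-cutoff marker's trapezoid is included, so lowering the
cutoff never shrinks the area). A curve that never reaches the cutoff
inside the panel is integrated to the edge and flagged, since such scores
are biased toward zero. The unstandardized score is
$\ln(iHH_A / iHH_D)$ — negative when the derived background is longer —
and is exactly antisymmetric under swapping allele labels.
Standardization subtracts the mean and divides by the SD of the
unstandardized scores within derived-allele-frequency bins (20 equal-width
bins by default; sparse or zero-spread bins are merged with their nearest
occupied neighbor and the merge reported). Empirical percentiles of an
observed (Fst, iHS) pair against a genome-wide reference are plain tail
fractions, with the $1/N$ resolution bound reported when the value is
beyond every reference entry.

## Synthetic data: what it emulates and what it does not

The generators produce every input with known truth, under defaults chosen
once to match the motivating study's stated conditions:

- **Pedigree**: 13 generations from 62 founders, Poisson sibships (mean
  3), within-generation mate choice that consults the growing kinship
  matrix. With `cousin_mating_prob = 0` consanguinity is impossible (used
  by tests as a negative control); at the default 0.3 the deep pedigree
  accumulates the loops characteristic of an endogamous isolate (around
  70% of individuals inbred, mean $f$ among them a few percent, cohort
  size in the low thousands — the generation couple-cap of 60 keeps the
  population near the real study's ~3,000). Mates are never first-degree
  relatives.
- **Fertility**: latent rate $\mu + \text{genotype effect} +
  \text{covariate terms} + \text{polygenic} + \text{environment}$, with
  $\mu = 0.5$ births/yr, a recessive deficit of 0.049 births/yr at
  derived-allele frequency 0.29, $h^2 = 0.3$, total residual SD 0.15,
  marriage spans $N(11.5, 5^2)$ years, and wife's birth year tracking the
  husband's with SD 2 (reproducing the near-collinearity of the real
  covariate). Births are realized as Gamma interbirth intervals
  (shape 4, mean $1/\text{rate}$) until the span is exhausted. The
  phenotyped sample is drawn from the most recent generations, as a field
  cohort would be.
- **Sweep panels**: 1 Mb of markers at 1 kb spacing; derived-background
  haplotypes copy one template over a 600 kb tract with per-site deviation
  probability $1.2 \times 10^{-3}$ — chosen from the closed form so
  derived-background EHH decays through 0.5 near 300 kb, the scale
  reported for the motivating locus — while ancestral haplotypes are
  site-independent draws. Setting the tract to zero gives an exchangeable
  (neutral) panel used for calibration.

Known divergences from real data, and hence limits on what green tests
show: realized birth rates are right-skewed (the rate is the inverse of a
small-sample mean of Gamma intervals), so the generator's *realized*
phenotype is heavier-tailed than the Gaussian working model even when the
latent rate is exactly Gaussian; recombination, mutation and genotyping
error are absent from the panels (the sweep tract has hard edges);
haplotype drop ignores recombination across the short three-locus region
(realistic there, but it means the phasing code is never exercised against
recombinants); and the pedigree generator marries within generations only.
Parameter-recovery results on these generators therefore validate the
estimators' algebra and calibration, not robustness to skew, genotyping
error or model misspecification. One further property carries over from
the real design: the marriage-to-last-birth covariate is itself a
consequence of the rate being modelled, so adjusting for it absorbs a few
percent of the genotype effect — recovered effect sizes sit slightly
below the injected truth, in the generator exactly as they would in the
field data.

## Numerical choices and problem sizes

Whitening uses the Cholesky (full `Sigma`) or the eigenbasis of $A$
(variance-component route, preferred for repeated fits on one pedigree).
Eigenvalues of $A$ are floored at zero against roundoff; the polygenic
draw in the generator adds $10^{-8}$ to the diagonal before factoring.
The likelihood profile is optimized on $\log\gamma \in [-12, 8]$ with a
$10^{-8}$ tolerance. Ties at the $\gamma = 0$ boundary go to the
boundary. The test and acceptance suites run the calibration experiments
at the scales the methods target: 2,000 null replicates for the F-test's
type-I error (n = 200, $h^2 = 0.3$), 200 simulated cohorts of 204 men for
effect-size recovery in the acceptance script (20 inside the test suite),
$10^5$ gene drops for the kinship oracle, 100 panel seeds for sweep-sign
recovery — sizes at which every Monte-Carlo tolerance used is at least
three standard errors.

## Interfaces

The numbered scripts under `analysis/` are the pipeline's narrative form:
simulate the cohort, run the association, the survival comparison, the
phasing, and the selection statistics, each writing provenance-headed TSVs
under `results/`. The same stages are available programmatically through
`run_pipeline()` with a `run_config()` whose single seed drives every
stage substream, making full reruns byte-identical. Declared input paths
are checked before any computation.
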