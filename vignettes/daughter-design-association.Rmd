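---
title: "Mixed-model candidate-gene association in daughter designs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model candidate-gene association in daughter designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedassoc)
```

# The setting

A daughter design genotypes the daughters of a modest number of sires and
uses each daughter's estimated breeding value (EBV) as the phenotype.
EBVs are predictions, not raw records: their sampling error depends on
how much information went into each prediction, summarised by the
reliability `REL` (the squared accuracy, in (0, 1]). Two consequences
shape every model in this package:

* daughters are related (paternal half-sibs at least), so a pedigree
  polygenic effect is required to avoid spurious association driven by
  family structure;
* residual variances differ across animals, so the residual is weighted
  by `1/REL`.

# The association models

## Single-SNP model

For one SNP with minor-allele dosage `x` in {0, 1, 2},

$$ y = \mathbf{1}\mu + x b + a + e, \qquad
   a \sim N(0, A\sigma^2_a), \qquad e \sim N(0, W\sigma^2_e), $$

with `A` the additive relationship matrix from the pedigree and
`W = diag(1/REL_i)`. Solutions come from Henderson's mixed model
equations (MME) with residual precision `diag(REL_i)` and penalty
`lambda A^{-1}`, `lambda = sigma2_e / sigma2_a`. The sampling covariance
of the fixed effects is the fixed block of the inverse coefficient matrix
scaled by `sigma2_e`, which equals `(X' V^{-1} X)^{-1}` for
`V = Z A Z' sigma2_a + diag(1/REL) sigma2_e`; the test suite verifies the
identity against an explicit-V generalised-least-squares fit on hundreds
of random instances. `b = 0` is tested by the Wald statistic
`b^2/\mathrm{Var}(b) \sim \chi^2_1`, and significance is declared at the
Bonferroni threshold `alpha / N` over the `N` SNPs scanned.

The contribution of a SNP is summarised as the fraction of phenotypic
variance it explains, `2p(1-p)\alpha^2/\sigma^2_P`: with 0/1/2 coding the
fitted regression coefficient *is* the average allele-substitution effect
`alpha`, and `p` is taken as the sample frequency of the analysed allele
in the animals actually analysed for that SNP. `sigma2_P` is an external
input — in routine use it comes from the national evaluation that also
produced the EBVs, not from this data set.

Variance components are user-supplied for the same reason. An EM-REML
estimator (`reml_em`) is included for synthetic-data work, but the
analysis path treats `sigma2_a`, `sigma2_e`, `sigma2_P` as configuration.

## Genotype-class means

`genotype_class_lsm` refits the same mixed model with the SNP as a
cell-means class effect, giving each genotype's estimable mean and
standard error plus all pairwise Wald z-tests. Letter groupings are built
at the 0.05 (lower case) and 0.01 (upper case) levels from the maximal
cliques of the "not significantly different" graph; classes with fewer
than two animals are reported but excluded from letters, since their
contrasts are dominated by a single record.

## Haplotype trend regression

Within a block, each animal's expected dosage of each haplotype (rows sum
to 2) forms the design matrix `X` of

$$ y = \mathbf{1}\mu + X h + a + e . $$

Because the rows of `X` sum to a constant, `X` is collinear with the
intercept; the most frequent haplotype is dropped as the reference, which
maximises the stability of the remaining contrasts, and the joint Wald
statistic $\hat h' [\widehat{\mathrm{Var}}(\hat h)]^{-1} \hat h$ is
referred to `\chi^2_{k-1}`. The `k - 1` degrees of freedom follow from
the intercept absorbing the row-sum constraint; the statistic is invariant
to which haplotype is the reference (tested to 1e-6), so the choice is
purely a parameterisation. The pooled rare-haplotype class is treated as
an ordinary haplotype column. Bonferroni correction is over the number of
blocks tested; per-trait analyses run independently with no correction
across traits.

# Haplotype frequencies, LD and blocks

## Exact EM phasing

Candidate-gene panels are small, so phasing uses an exact EM over the
enumeration of haplotype pairs compatible with each multi-SNP genotype
(missing genotypes are marginalised over both alleles). The window is
capped at 12 SNPs, where enumeration is still trivial; larger regions
must be split into blocks first. Frequencies start uniform over the
observed-compatible haplotypes; because that uniform point can be a
saddle of the likelihood (the classic all-double-heterozygote case), the
default adds 4 seeded jittered restarts and keeps the best likelihood.
Convergence is declared at a log-likelihood change below 1e-8; the trace
is checked to be non-decreasing on every run, and an internal decrease
beyond rounding noise is treated as a bug, not a warning. Haplotypes
whose fitted frequency falls below 1e-8 are numerical zeros of the EM and
are dropped; the per-animal posterior dosage rows are rescaled to sum to
exactly 2. Ties between restarts are broken by likelihood, then
lexicographic haplotype order.

## D', confidence intervals, blocks

Pairwise LD uses the two-locus EM haplotype frequencies:
`D = p_AB - p_A p_B`, `D' = |D|/D_max`, `r2 = D^2/(p_A p_a p_B p_b)`.
The D' confidence interval is a likelihood interval: the multinomial
likelihood of the 3x3 genotype table is evaluated on a D' grid (step
0.001, configurable) with allele frequencies held at their MLEs and the
sign of D fixed at the point estimate; bounds are the 5th and 95th
percentiles of the normalised cumulative likelihood. That one-sided-style
convention is deliberate: the 0.70/0.98/0.90 block thresholds below were
calibrated under it.

Blocks follow the Gabriel rule: a pair is "strong LD" if its CI is
[>= 0.70, >= 0.98], "strong recombination" if the upper bound is < 0.90;
a contiguous range qualifies when at least 95% of its informative pairs
are strong LD, and non-overlapping blocks are chosen greedily from
longest to shortest (ties to the leftmost). Haplotypes below 5% relative
frequency within a block are pooled into a single class before
association testing; if every haplotype is rare the pooling errors out
rather than fabricating a one-class design.

Block membership is always data-driven. On the default synthetic panel
the generating 6-SNP and 2-SNP blocks are usually recovered exactly, but
an edge SNP can drop out of a block in some replicates — that is a
property of CI-based block definitions, not an error.

# The synthetic generator

The generator emulates the study conditions the analysis assumes: 14 sire
families totalling 638 daughters (652 animals), dams unknown and treated
as unrelated founders; a 13-SNP candidate-gene panel on chromosome 14
organised as a 6-SNP block (common haplotypes at 33.5/33.1/25.6% plus six
rare ones totalling 7.8%), a 2-SNP block (44.0/38.8/17.2%) and five
unlinked SNPs with minor-allele frequencies from 0.013 to 0.469.
Founders draw two haplotypes per block from the pool; offspring inherit
one haplotype per parent, blocks transmitted intact and independently of
each other. Phenotypes follow the analysis model exactly:
`y = mu + x alpha_true + a + e`, polygenic values gene-dropped (founders
`N(0, sigma2_a)`, offspring mid-parent plus Mendelian sampling, variance
reduced by a quarter per known non-inbred parent), and
`e ~ N(0, sigma2_e/REL)` with `REL` uniform on (0.5, 0.99) — a plausible
range for daughter EBVs, since no empirical reliability distribution is
available to copy. Reliabilities are drawn once per animal and shared
across traits, as one animal's information content is trait-generic to
first order.

Remaining defaults: `sigma2_a = 0.3`, `sigma2_e = 0.7`, `sigma2_P = 1`
(so effects are in phenotypic-SD units) and `alpha_true = 0.1`, a small
substitution effect in line with the variance fractions a replication
candidate typically explains. The five traits are simulated
independently — no genetic correlations — which is sufficient for the
single-trait analyses implemented here and is a stated limitation.
Everything is deterministic given (config, seed) through per-stage
derived sub-seeds.

What passing tests on these data do **not** show: robustness to
genotyping error, pedigree errors, multi-trait correlation structure,
reliability heterogeneity beyond a uniform band, or selection within
families. None of those are modelled.

## Expression data

`simulate_expression` draws per-sample relative quantities
`N(mean, sd)` (redrawn if non-positive) and converts them to Ct values,
so the 2^-ddCt group means match the requested means in expectation,
exactly when `sd = 0`. Relative quantification averages technical
replicates on the Ct scale, subtracts the calibrator group's mean dCt
(which fixes the calibrator's geometric mean RQ at exactly 1 — the
arithmetic mean coincides only when calibrator samples agree), and the
two-group comparison reports the fold change of arithmetic group means
with a Welch t-test by default (a pooled-variance flag exists; the
equal-variance assumption is rarely defensible for 4-vs-4 qPCR groups).
No amplification-efficiency correction is applied.

# Numerical choices and degenerate inputs

* Minor alleles are defined from the observed sample frequency, ties
  broken toward the alt allele; a SNP monomorphic in the analysed subset
  yields p = 1 with a warning rather than an error, so scans over panels
  with rare alleles complete.
* The MME coefficient matrix is solved by one Cholesky factorisation per
  fit, yielding solutions and the fixed block of the inverse together.
  Rank-deficient fixed designs and non-positive `lambda` are rejected.
* `A^{-1}` is built directly by Henderson's rules with inbreeding-aware
  Mendelian-sampling variances; the tabular `A` is the cross-check
  (`max |A A^{-1} - I| < 1e-8` at study scale, and `A` itself is verified
  against a Wright path-counting oracle on small pedigrees).
* Pedigree readers insert parent-only animals as founders, reject
  duplicate ids, and topologically sort with cycle detection naming an
  offending id.
* HWE uses the df = 1 Pearson test without continuity correction,
  including for SNPs with an unobserved genotype class; monomorphic loci
  return chi-square 0, p = 1.

# Scale of the verification runs

The calibration checks run at the design's own scale: type-I error of
both Wald tests from 1000 null replicates of the 638-daughter design
(empirical size expected within the binomial 99% band around 0.05),
substitution-effect recovery from 200 replicates at `alpha_true = 0.5`
SD and MAF 0.3, EM frequency recovery on a 638-animal unrelated panel,
and block-structure recovery over 50 replicates of a planted
two-block/spacer panel. These sizes give each check useful power while
keeping the whole suite in the minutes range.

# Known limitations

* Phasing is exact-enumeration EM: right for candidate regions, unusable
  genome-wide (no HMM/PBWT phasing).
* `A` is stored dense; fine to ~1e4 animals, after which a sparse
  `A^{-1}` path would be needed.
* Haplotype tests report the block-level joint p-value only, not
  per-haplotype significance with sign conventions.
* Variance components are inputs; mis-specified `lambda` biases the Wald
  calibration, and the package does not try to detect that.
* VCF support is read-only, biallelic SNPs with GT only.
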