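---
title: "Post-GWAS analysis of TGCT susceptibility loci: models and methods"
author: "tgctrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-GWAS analysis of TGCT susceptibility loci: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgctrisk)
```

# Scope

Testicular germ cell tumors (TGCT) are the most heritable of the common
cancers, and genome-wide association meta-analyses of the disease follow a
well-worn sequence: per-study quality control and additive logistic
association, fixed-effects pooling with heterogeneity control, credible-set
construction from linkage disequilibrium, conditional analysis for
independent signals, heritability-explained accounting against familial
relative risk, polygenic risk scores, and finally a multi-evidence scoring
exercise that turns associated intervals into named candidate genes.
`tgctrisk` implements each of those stages as an ordinary R function with a
documented contract, plus a synthetic-cohort generator so the whole chain
can be exercised and tested without access to any consortium genotypes.

This vignette records the models, the tunable parameters, the numerical
choices, and the places where a design decision was genuinely open.

# Association and meta-analysis

Per-study association is additive logistic regression of case status on
allele dosage (0/1/2), optionally adjusted for genotype principal
components and a study-center factor; the reported statistic is the Wald
test on the dosage coefficient. Missing dosages are mean-imputed at 2f.
Two implementation paths exist and are tested against each other: a
`stats::glm` fit for models with covariates, and a vectorised
Newton–Raphson solver that fits every variant at once from the
case/control counts at each dosage level when no covariates are present.
The two agree to numerical precision; the count solver is what makes
2,000-variant calibration scans affordable. Non-convergence or separation
yields a flagged record with missing estimates, never a fabricated one.

Studies are pooled by fixed-effects inverse-variance weighting
(`meta_fixed`, `meta_scan`):

$$\hat\beta = \frac{\sum_i w_i \beta_i}{\sum_i w_i},\qquad
\mathrm{SE} = \Big(\sum_i w_i\Big)^{-1/2},\qquad w_i = \mathrm{SE}_i^{-2},$$

with Cochran's $Q = \sum_i w_i(\beta_i - \hat\beta)^2$ and
$I^2 = \max(0, (Q - (k-1))/Q)\cdot 100$. Variants with Q-test
$P < 0.001$ are flagged as heterogeneity failures *before* significance
is declared at $P \le 5\times 10^{-8}$ — the removal precedes the
significance call, while $I^2 > 50$ is only reported, never filtered.
All P-value bookkeeping runs in log space, so associations on the order
of $10^{-150}$ are representable.

Effect alleles are harmonised across studies before pooling
(`align_alleles`): swapped A1/A2 records get $\beta \to -\beta$ and
$f \to 1-f$; variants absent from any study, or with more than two
alleles, are dropped. Strand-ambiguous A/T and C/G variants are dropped
in the default strict mode; a permissive mode keeps them with
frequency-based orientation, requiring the frequency difference from the
reference study to stay below 0.2. Strict-by-default is standard
meta-analysis practice when per-study strand provenance is uncertain.

Genomic inflation (`genomic_inflation`) is the median association
$\chi^2_1$ divided by 0.4549364, the exact median of the 1-df chi-square
distribution.

# Quality control

Variant filters run in a fixed order — call rate, differential
missingness by case status (two-sided Fisher exact), Hardy–Weinberg
equilibrium, minor allele frequency, duplicate position — and a dropped
variant carries the first reason it fails, which makes reason codes
deterministic and the filter auditably total. The HWE exact test is the
conditional test that sums the probabilities of all heterozygote counts
no more probable than the observed one, computed in log space and checked
against a full-enumeration oracle in the tests. HWE is evaluated in
controls only: the source analyses do not say which samples entered the
test, and controls-only is the standard choice because true risk variants
can distort genotype frequencies among cases.

Sample filters are call rate, heterozygosity-rate outliers beyond 3
standard deviations, and an ancestry filter that projects samples onto
the first two genotype principal components and drops samples more than 6
standard deviations of Euclidean distance from the main-cluster centroid.
The reference analyses ran k-means before the distance cut; with a
single-population synthetic panel k-means is degenerate, so the number of
clusters is a parameter with default 1.

# LD, credible sets, and conditional analysis

LD is the signed Pearson correlation of mean-imputed dosage vectors
against a reference panel. A locus's credible-risk-variant (CRV) set is
the lead variant plus every variant within a ±1 Mb window with
$r^2 \ge 0.80$ to it. Published descriptions of such sets state the
threshold both as $\ge 0.80$ and as $> 0.80$; this package uses
$\ge 0.80$ and exposes it as a parameter. A lead with no
strong proxies forms a singleton set whose region degenerates to the lead
position; gene counting still applies, and zero genes in the region is a
legitimate outcome. Genes overlap a region if their 1-based inclusive
span intersects it by at least 1 bp (interval arithmetic via
`GenomicRanges`).

Conditional analysis (`cojo_joint`, `cojo_select`) follows the
summary-statistics-plus-LD-reference approach: marginal per-allele
log-odds are standardised by $\sqrt{2f(1-f)}$, solved jointly through the
inverse of the candidates' LD correlation matrix, and mapped back; joint
standard errors scale the marginal ones by $\sqrt{(R^{-1})_{jj}}$. For a
binary trait this is a linear approximation, and the package treats it as
such: the test suite verifies that on two-variant systems with
$|\beta| \le 0.3$ and $n = 20{,}000$ the approximate joint estimates stay
within 15% of a direct two-variant logistic fit, and that an exactly
orthogonal pair reproduces the marginals to $10^{-10}$. Candidate pairs
with $r^2 \ge 0.9$ are refused as collinear (condition-number cap
$10^8$). Stepwise selection starts from the smallest marginal P, adds the
best remaining variant whose conditional P keeps genome-wide
significance, breaks ties by (P, then position) so the outcome is
invariant to input ordering, and sets aside collinear candidates rather
than testing them.

# Heritability explained

The heritability a single SNP explains, relative to what familial
relative risk implies, is

$$h = \frac{\beta^2 \cdot 2f(1-f)}{\log(\lambda^2)},$$

with $\beta$ the log-odds ratio, $f$ the effect-allele frequency, and
$\lambda$ the familial relative risk — 4 for affected fathers, 8 for
brothers. The logarithm's base is not stated where the formula is
printed; this package uses the natural log because that reading, applied
to the packaged 22-locus table, reproduces both published totals (7.0% of
father-to-son and 4.7% of sibling heritability), which the test suite
verifies as an oracle check. X-chromosome loci enter the father-to-son
sum identically to autosomal loci; genetically a father does not transmit
an X to his son, but the published totals require their inclusion, and
fidelity to the published computation was preferred over genetic realism.

# Polygenic risk score

Scores are weighted allele counts, $S_j = \sum_k d_{jk}\beta_k$, with
weights always taken from an external table and never re-fit on the
scored samples. Missing dosages contribute their expectation $2f$; a
model variant genotyped on the opposite allele contributes $2 - d$. If
more than 20% of the model's variants are absent from the genotypes the
score is declared non-comparable and scoring fails rather than silently
shrinking.

Percentile bins use edges $0, 5, \ldots, 100$ on the combined
case+control distribution, with the 45–55th percentile stratum as the
reference (OR ≡ 1) and [95, 100] as the top bin. Bin odds ratios come
from the 2×2 case/control table against the reference with Woolf
(log-OR) confidence intervals and a Haldane–Anscombe 0.5 correction on
zero cells. Absolute lifetime risk applies the rare-disease scaling
$\mathrm{risk} = \mathrm{RR} \times K$ with $K = 0.005$ by default,
capped at 1.

The AUC is the concordance probability (ties count one half), identical
to the Wilcoxon–Mann–Whitney statistic. Because the weights are external,
leave-one-out cross-validation of a fixed score cannot change the
ranking, so the LOOCV AUC equals the plain AUC; `auc_loocv` documents
this and also offers a literal refit mode, which re-estimates a
univariate logistic calibration with each sample held out — the two agree
whenever the score carries signal, and both interpretations are
selectable because the original description does not say what was
re-estimated inside the cross-validation loop.

# Gene adjudication

The variant-to-gene score is a five-component point system. Region: 2
points for a single-gene region, 1 for two or more genes, 0 for none.
Location: 1 point if the lead signal is exonic, intronic, or within
±10 kb of the gene (inclusive at exactly 10 kb). eQTL colocalization: a
base of 0 / 0.5 / 1 for none / one / two-or-more significant
colocalizations in non-testis tissues plus 1 for a significant testis
colocalization, where significance requires $PP_3 + PP_4 > 0.8$ *and*
$PP_4/(PP_3+PP_4) > 0.9$, both strict, and an undefined ratio fails.
Fetal germ cell expression: 0 / 0.5 / 1 by tertile, where the package
can compute tertiles from supplied values (inclusive empirical quantiles)
or use the published cutoffs 698 / 2348 for replication. Chromatin
connections: 0 / 0.5 / 1 for connections in zero / one / two-or-more
cell lines, where a connection requires a proxy SNP in open chromatin
(1 bp overlap with an ATAC peak suffices), a loop linking that fragment
to the gene's promoter, and the promoter also open — loops come from the
one cell line with a Capture-C library while openness is evaluated per
cell line. The proxy threshold for this mapping defaults to $r^2 \ge
0.4$, deliberately distinct from the 0.8 CRV threshold.

The total (ceiling 7.0, in half-point steps) maps to a category: highly
likely at $\ge 3.0$, moderately likely at exactly 2.0 or 2.5, unlikely
below 2.0. The source rubric states both "unlikely (score ≤ 2.0)" and
"moderately likely (score = 2.0 or 2.5)"; the explicit enumeration of
the moderate band is taken to govern the 2.0 boundary. When an evidence
type is unavailable (as for X-chromosome genes) it contributes 0 and is
flagged, and a reduced-scheme category is reported alongside the full
one by rescaling the observed total to the diminished ceiling; a gene
scored under several signals takes its best category.

Testis specificity: a gene is testis-*enriched* with ≥ 1 TPM in testis
and at least five-fold the maximum of all other tissues, else
testis-*enhanced* with ≥ 1 TPM and five-fold the mean of the others,
else neither — checked in that order so the classes partition.
Over-representation of such genes in a selected set is the upper-tail
hypergeometric probability.

# The synthetic-cohort generator

The generator's purpose is statistical shape, not population-genetic
realism. Haplotypes are binary strings organised in LD blocks; within a
block each variant copies the previous variant's allele with probability
$\rho$ and otherwise draws fresh at the block's frequency, giving a
stationary chain with correlation $\rho^k$ at distance $k$ and
independence across blocks. Frequencies are block-constant, drawn once
per block from a configurable range, so the nominal frequency is also
the marginal frequency. Genotypes are sums of two independently drawn
haplotypes — Hardy–Weinberg by construction.

Disease follows an additive logistic model whose intercept is *solved*,
not set: the mean case probability over the exact distribution of
genotype scores implied by the panel is driven to the target prevalence
(default 0.5%, the assumed TGCT lifetime risk) by monotone root finding.
Cohorts are drawn by rejection sampling from that population model —
consistent with the logistic generative model, unlike a liability
threshold — with exact per-study case/control quotas, disjoint samples,
center labels S1…Sk, and per-study random substreams derived
deterministically from one master seed. Per-study case-control ratios
default to uniform because the source design does not state them site by
site. Missingness is injected uniformly at a configurable rate (default
0) purely to exercise QC.

What the generator does **not** model: coalescent or demographic
structure, imputation error, relatedness, X-chromosome dosage (a male
{0,2} coding is the documented convention but cohorts here are
autosomal), allele-frequency drift within blocks, or realistic
genome-scale LD beyond the block-geometric decay. Tests that pass on
these cohorts therefore validate the *statistical machinery* —
calibration, recovery, invariances — and say nothing about robustness to
population structure or imputation artifacts in real data.

The evidence generator assigns each gene a target category and emits
coloc posteriors (margin-respecting: significant vectors are drawn with
$PP_4 \in [0.85, 0.95]$ and $PP_3 \in [0.01, 0.03]$), fetal expression
values, ATAC peaks, promoter contacts and TPM profiles that the scoring
rubric maps back to that category; the round trip is required to agree
for at least 95% of 200 genes.

# Problem sizes and numerical choices

The test suite runs its calibration and recovery checks at sizes chosen
to make Monte-Carlo noise small relative to the assertions: null
calibration over 20 replicates of 3 studies × 2,000 independent variants
× 2,000 samples (the genomic inflation factor is asserted on the mean
across replicates, since a single 2,000-variant scan estimates the
median chi-square with sampling error of roughly ±0.05); effect recovery
over 20 replicates at a combined n of 20,000; conditional-analysis
accuracy on two-variant systems at n = 20,000 across LD levels
r ∈ {0, 0.3, 0.5, 0.7}. Logistic fits converge by Newton/IRLS with a
step tolerance of 1e-10 (count path) or deviance epsilon 1e-10 to 1e-12
(glm path), 50-iteration cap, and explicit separation flags. Tertile
cutoffs use the inclusive empirical quantile (R type 7). PCA signs are
fixed by making each component's largest-magnitude loading positive. Ties
in stepwise selection break by (P, position).

# Known limitations

* The COJO-style joint solve is a linear approximation for binary
  traits; its validated regime is $|\beta| \le 0.3$ at $n \ge 20{,}000$
  and moderate LD ($r^2 < 0.9$), matching its intended use on
  genome-wide-significant common variants.
* The per-SNP heritability formula inherits the rare-disease,
  independent-loci approximations of its source; summed totals are a
  bookkeeping device, not a variance-components estimate.
* The PRS percentile ORs are in-sample unless the score is applied to an
  external cohort; with external weights that is how the original
  analysis proceeded, but AUC values on the synthetic demos are not
  comparable to published discrimination estimates.
* The generator's LD model cannot produce long-range or haplotype-phase
  structure, so CRV sets on synthetic panels are narrower and cleaner
  than on real reference panels.
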